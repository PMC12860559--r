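#' Validate a trait table
#'
#' Trait tables are long-format records of ordinal class scores:
#' one row per (accession, trait, year, replicate) with `class` an integer
#' code 1..10.
#'
#' @param traits data.frame with columns `accession_id`, `trait`, `year`,
#'   `rep`, `class`.
#' @return the validated data.frame.
#' @export
validate_trait_table <- function(traits) {
  need <- c("accession_id", "trait", "year", "rep", "class")
  miss <- setdiff(need, names(traits))
  if (length(miss)) stop_cfg("trait table lacks column(s): ",
                             paste(miss, collapse = ", "))
  if (any(traits$class %% 1 != 0 | traits$class < 1 | traits$class > 10,
          na.rm = TRUE))
    stop_cfg("class codes must be integers in 1..10")
  key <- paste(traits$accession_id, traits$trait, traits$year, traits$rep)
  if (anyDuplicated(key))
    stop_cfg("duplicate (accession, trait, year, rep) records")
  traits
}

#' Read/write trait tables as TSV
#' @param path TSV with columns accession, trait, year, rep, class.
#' @return data.frame.
#' @export
read_trait_table <- function(path) {
  tt <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_trait_table(tt)
}

#' @rdname read_trait_table
#' @param traits trait table data.frame.
#' @export
write_trait_table <- function(traits, path) {
  utils::write.table(traits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Per-accession modal class across replicates (and years if year = NULL);
# ties resolved toward the lower class code.
modal_class <- function(traits, trait, year = NULL) {
  sub <- traits[traits$trait == trait, , drop = FALSE]
  if (!is.null(year)) sub <- sub[sub$year == year, , drop = FALSE]
  sub <- sub[!is.na(sub$class), , drop = FALSE]
  if (!nrow(sub)) stop_cfg("no data for trait '", trait, "'",
                           if (!is.null(year)) paste0(" in ", year))
  vapply(split(sub$class, sub$accession_id), function(cl) {
    tab <- table(cl)
    as.integer(names(tab)[which.max(tab)])  # which.max takes first = lowest
  }, integer(1))
}

#' Class-frequency table of an ordinal trait
#'
#' Each accession is reduced to its modal class across replicates (ties
#' resolved to the lower code), then tallied into percentages over the
#' accessions with data — the layout of published trait-distribution
#' tables with columns for classes 1..10.
#'
#' @param traits a trait table (see [validate_trait_table()]).
#' @param trait trait name.
#' @param year scoring year.
#' @return data.frame of class `frequency_table` with `trait`, `year` and
#'   `percent` (length-10 numeric, zeros for absent classes), plus
#'   `n_accessions`.
#' @export
class_frequency_table <- function(traits, trait, year) {
  modal <- modal_class(traits, trait, year)
  pct <- numeric(10)
  tab <- table(factor(modal, levels = 1:10))
  pct <- as.numeric(tab) / length(modal) * 100
  structure(list(trait = trait, year = year, percent = pct,
                 n_accessions = length(modal)),
            class = "frequency_table")
}

#' Shannon-Wiener diversity index of a class-frequency vector
#'
#' H' = -sum p_i ln p_i over classes with positive frequency, with the
#' percentages renormalized to proportions summing to one. The natural
#' logarithm is used, so k equally frequent classes give ln(k).
#'
#' @param freqs a `frequency_table`, or a numeric vector of class
#'   percentages (or proportions).
#' @return H' in nats.
#' @export
shannon_index <- function(freqs) {
  p <- if (inherits(freqs, "frequency_table")) freqs$percent else
    as.numeric(freqs)
  if (any(p < 0) || all(p == 0) || anyNA(p))
    stop_cfg("frequencies must be nonnegative with a positive sum")
  p <- p[p > 0]
  p <- p / sum(p)
  -sum(p * log(p))
}

#' Broad-sense heritability of an ordinal trait
#'
#' Fits the random-effects decomposition class ~ (1|accession) + (1|year)
#' + (1|accession:year) by REML (\pkg{lme4}) on the class codes and
#' reports H2 = V_g / (V_g + V_gy / y + V_e / (r y)) on the accession-mean
#' basis, with y the number of years and r the (median) number of
#' replicates. Components are nonnegative by construction of the fit.
#' Terms that the design cannot separate (single year) are dropped
#' automatically.
#'
#' @param traits a trait table.
#' @param trait trait name.
#' @return list with `H2` and the variance components `Vg`, `Vgy`, `Ve`.
#' @export
broad_sense_heritability <- function(traits, trait) {
  sub <- traits[traits$trait == trait & !is.na(traits$class), ,
                drop = FALSE]
  if (!nrow(sub)) stop_cfg("no data for trait '", trait, "'")
  if (length(unique(sub$accession_id)) < 2)
    stop_cfg("heritability needs >= 2 accessions")
  y <- length(unique(sub$year))
  r <- stats::median(table(sub$accession_id, sub$year)[
    table(sub$accession_id, sub$year) > 0])
  if (y < 2 && r < 2)
    stop_cfg("need >= 2 years or >= 2 replicates")
  sub$accession_id <- factor(sub$accession_id)
  sub$year_f <- factor(sub$year)
  if (stats::var(sub$class) == 0)
    return(list(H2 = 0, Vg = 0, Vgy = 0, Ve = 0))
  form <- if (y >= 2)
    class ~ (1 | accession_id) + (1 | year_f) + (1 | accession_id:year_f)
  else class ~ (1 | accession_id)
  fit <- suppressWarnings(suppressMessages(lme4::lmer(form, data = sub)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  getv <- function(g) {
    v <- vc$vcov[vc$grp == g]
    if (length(v)) v else 0
  }
  Vg <- getv("accession_id")
  Vgy <- getv("accession_id:year_f")
  Ve <- getv("Residual")
  den <- Vg + Vgy / y + Ve / (r * y)
  list(H2 = if (den == 0) 0 else Vg / den, Vg = Vg, Vgy = Vgy, Ve = Ve)
}

#' Pairwise Pearson correlations between traits
#'
#' Correlations are computed on per-accession modal class codes for one
#' scoring year, pairwise-complete, with two-sided t-test p-values and the
#' conventional significance stars (0.05 / 0.01 / 0.001).
#'
#' @param traits a trait table.
#' @param year scoring year.
#' @return list with matrices `r`, `p` and `stars`.
#' @export
trait_correlations <- function(traits, year) {
  tr_names <- sort(unique(traits$trait))
  prof <- trait_profiles(traits, year, tr_names)
  k <- length(tr_names)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(tr_names, tr_names))
  for (i in seq_len(k)) for (j in i:k) {
    x <- prof[, i]; y <- prof[, j]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3) next
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) next
    if (i == j) { r[i, j] <- 1; p[i, j] <- 0; next }
    ct <- stats::cor.test(x[ok], y[ok])
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  stars <- matrix("", k, k, dimnames = dimnames(r))
  stars[!is.na(p) & p < 0.05] <- "*"
  stars[!is.na(p) & p < 0.01] <- "**"
  stars[!is.na(p) & p < 0.001] <- "***"
  list(r = r, p = p, stars = stars)
}

# accession x trait matrix of modal class codes for one year
trait_profiles <- function(traits, year, tr_names = NULL) {
  tr_names <- tr_names %||% sort(unique(traits$trait))
  accs <- sort(unique(traits$accession_id))
  prof <- matrix(NA_real_, length(accs), length(tr_names),
                 dimnames = list(accs, tr_names))
  for (tn in tr_names) {
    m <- try(modal_class(traits, tn, year), silent = TRUE)
    if (inherits(m, "try-error")) next
    prof[names(m), tn] <- m
  }
  prof
}

#' Hierarchical clustering of accessions on trait profiles
#'
#' Euclidean distances on z-scored per-accession modal class vectors;
#' accessions with any missing trait are dropped (their ids are attached
#' as attribute `"dropped"`). Complete linkage by default.
#'
#' @param traits a trait table.
#' @param year scoring year.
#' @param method linkage: "complete" (default), "average" or "ward.D2".
#' @return Newick string of the dendrogram; the `hclust` object is
#'   attached as attribute `"hclust"`.
#' @export
trait_cluster <- function(traits, year, method = "complete") {
  prof <- trait_profiles(traits, year)
  if (ncol(prof) < 2) stop_cfg("need >= 2 traits")
  keep_tr <- apply(prof, 2, function(v) stats::sd(v, na.rm = TRUE) > 0)
  prof <- prof[, keep_tr, drop = FALSE]
  complete <- stats::complete.cases(prof)
  dropped <- rownames(prof)[!complete]
  prof <- scale(prof[complete, , drop = FALSE])
  hc <- stats::hclust(stats::dist(prof), method = method)
  nwk <- ape::write.tree(ape::as.phylo(hc))
  attr(nwk, "hclust") <- hc
  attr(nwk, "dropped") <- dropped
  nwk
}

#' PCA of the standardized trait matrix
#'
#' @param traits a trait table.
#' @param year scoring year.
#' @return list with `values` (eigenvalues), `var_explained` (fractions
#'   summing to 1) and `scores` (accession x PC).
#' @export
trait_pca <- function(traits, year) {
  prof <- trait_profiles(traits, year)
  if (ncol(prof) < 2) stop_cfg("need >= 2 traits")
  keep_tr <- apply(prof, 2, function(v) stats::sd(v, na.rm = TRUE) > 0)
  prof <- prof[, keep_tr, drop = FALSE]
  prof <- prof[stats::complete.cases(prof), , drop = FALSE]
  pc <- stats::prcomp(prof, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2
  list(values = ev, var_explained = ev / sum(ev), scores = pc$x)
}
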