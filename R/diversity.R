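#' Windowed nucleotide diversity (pi)
#'
#' Per-site pi is the expected pairwise difference among the 2n non-missing
#' alleles, x (2n - x) / C(2n, 2) with x the alternate-allele count; sites
#' with fewer than two called alleles are skipped. Window values are the
#' sum of site pi divided by the window span in bp (invariant sites
#' contribute zero), on a half-open sliding grid anchored at position 1 —
#' the convention of windowed diversity scans (default 100-kb windows,
#' 10-kb step). The last, possibly partial, window is normalized by its
#' true span.
#'
#' @param geno a [genotype_matrix()].
#' @param groups named list of accession-id vectors; one result per group.
#'   `NULL` treats the whole panel as one group `"all"`.
#' @param window_bp,step_bp window and step sizes in bp.
#' @return named list of data.frames (chrom, start, end, value, n_sites);
#'   `value` is pi per bp.
#' @export
nucleotide_diversity_windows <- function(geno, groups = NULL,
                                         window_bp = 1e5, step_bp = 1e4) {
  if (window_bp < step_bp) stop_cfg("window_bp must be >= step_bp")
  groups <- groups %||% list(all = geno$accession_ids)
  lapply(groups, function(ids) {
    if (!length(ids)) stop_cfg("empty group")
    sub <- geno$dosage[match(ids, geno$accession_ids), , drop = FALSE]
    if (anyNA(match(ids, geno$accession_ids)))
      stop_cfg("group contains unknown accession ids")
    site_pi <- site_pi_values(sub)
    window_apply(geno, site_pi, window_bp, step_bp,
                 function(v, span) sum(v, na.rm = TRUE) / span)
  })
}

# per-site pi from a dosage submatrix
site_pi_values <- function(d) {
  called <- colSums(!is.na(d))
  an <- 2 * called
  x <- colSums(d, na.rm = TRUE)
  pi <- x * (an - x) / (an * (an - 1) / 2)
  pi[an < 2] <- NA_real_
  pi
}

# Apply f(site_values_in_window, span_bp) over the sliding grid.
window_apply <- function(geno, site_values, window_bp, step_bp, f,
                         extra = NULL) {
  out <- list()
  for (ch in unique(geno$chrom)) {
    len <- geno$chrom_lengths[[ch]] %||% max(geno$pos[geno$chrom == ch])
    grid <- window_grid(len, window_bp, step_bp)
    sel <- which(geno$chrom == ch)
    p <- geno$pos[sel]
    vals <- numeric(nrow(grid)); nn <- integer(nrow(grid))
    for (w in seq_len(nrow(grid))) {
      in_w <- sel[p >= grid$start[w] & p <= grid$end[w]]
      v <- site_values[in_w]
      v_ok <- v[!is.na(v)]
      nn[w] <- length(v_ok)
      vals[w] <- f(v_ok, grid$end[w] - grid$start[w] + 1)
    }
    out[[ch]] <- data.frame(chrom = ch, start = grid$start,
                            end = grid$end, value = vals, n_sites = nn)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Weir & Cockerham (1984) per-site variance components for two groups.
# Returns matrix with columns a (among-population) and abc (total).
wc_components <- function(dA, dB) {
  nA <- colSums(!is.na(dA)); nB <- colSums(!is.na(dB))
  pA <- colSums(dA, na.rm = TRUE) / (2 * nA)
  pB <- colSums(dB, na.rm = TRUE) / (2 * nB)
  hA <- colMeans(dA == 1, na.rm = TRUE)
  hB <- colMeans(dB == 1, na.rm = TRUE)
  r <- 2
  nbar <- (nA + nB) / 2
  nc <- (r * nbar - (nA^2 + nB^2) / (r * nbar)) / (r - 1)
  pbar <- (nA * pA + nB * pB) / (r * nbar)
  s2 <- (nA * (pA - pbar)^2 + nB * (pB - pbar)^2) / ((r - 1) * nbar)
  hbar <- (nA * hA + nB * hB) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 -
       (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  bad <- nA < 1 | nB < 1 | !is.finite(a + b + cc)
  a[bad] <- NA_real_; b[bad] <- NA_real_; cc[bad] <- NA_real_
  cbind(a = a, abc = a + b + cc)
}

#' Windowed and genome-wide Weir-Cockerham FST between two groups
#'
#' Per-site among-population (a) and total (a + b + c) variance components
#' follow Weir & Cockerham (1984); window and genome-wide estimates are
#' ratio-of-sums sum(a) / sum(a + b + c), the estimator used by the common
#' VCF toolkits. Negative window values are reported as computed.
#'
#' @param geno a [genotype_matrix()].
#' @param groupA,groupB disjoint accession-id vectors (>= 2 each).
#' @param window_bp,step_bp sliding-window grid in bp.
#' @return list with `windows` (chrom, start, end, value, n_sites) and
#'   `genomewide` (scalar ratio-of-sums FST).
#' @export
pairwise_fst_windows <- function(geno, groupA, groupB,
                                 window_bp = 1e5, step_bp = 1e4) {
  if (length(intersect(groupA, groupB)))
    stop_cfg("groups must not overlap")
  if (length(groupA) < 2 || length(groupB) < 2)
    stop_cfg("both groups need >= 2 accessions")
  iA <- match(groupA, geno$accession_ids)
  iB <- match(groupB, geno$accession_ids)
  if (anyNA(iA) || anyNA(iB)) stop_cfg("unknown accession ids in groups")
  comp <- wc_components(geno$dosage[iA, , drop = FALSE],
                        geno$dosage[iB, , drop = FALSE])
  ratio <- function(a, abc) {
    den <- sum(abc, na.rm = TRUE)
    if (!is.finite(den) || den == 0) NA_real_
    else sum(a, na.rm = TRUE) / den
  }
  # window over the component pairs: carry both sums through the grid
  out <- list()
  for (ch in unique(geno$chrom)) {
    len <- geno$chrom_lengths[[ch]] %||% max(geno$pos[geno$chrom == ch])
    grid <- window_grid(len, window_bp, step_bp)
    sel <- which(geno$chrom == ch)
    p <- geno$pos[sel]
    vals <- numeric(nrow(grid)); nn <- integer(nrow(grid))
    for (w in seq_len(nrow(grid))) {
      in_w <- sel[p >= grid$start[w] & p <= grid$end[w]]
      ok <- in_w[!is.na(comp[in_w, "abc"])]
      nn[w] <- length(ok)
      vals[w] <- if (length(ok)) ratio(comp[ok, "a"], comp[ok, "abc"])
                 else NA_real_
    }
    out[[ch]] <- data.frame(chrom = ch, start = grid$start,
                            end = grid$end, value = vals, n_sites = nn)
  }
  windows <- do.call(rbind, out)
  rownames(windows) <- NULL
  list(windows = windows,
       genomewide = ratio(comp[, "a"], comp[, "abc"]))
}

#' Write windowed statistics as BED-like TSV
#'
#' Columns: chrom, start0 (0-based), end, value, n_sites.
#' @param windows data.frame as returned by the windowed statistics.
#' @param path output path.
#' @export
write_window_stats <- function(windows, path) {
  utils::write.table(
    data.frame(chrom = windows$chrom, start0 = windows$start - 1,
               end = windows$end, value = windows$value,
               n_sites = windows$n_sites),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
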