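#' Configuration for the ordinal-trait simulator
#'
#' Traits are scored as ordinal class codes 1..n_classes, the way
#' horticultural descriptors (leaf shape, plant width, anthocyanin
#' coloration, ...) are recorded in germplasm trials: an underlying
#' quantitative liability is discretized at fixed thresholds. The liability
#' is genotype value + year effect + genotype-by-year deviation + residual,
#' with the variance components chosen so the broad-sense heritability on
#' an accession-mean basis, V_g / (V_g + V_gy/y + V_e/(r y)), equals
#' `target_H2` for the configured design of y years and r replicates.
#'
#' @param n_classes number of ordinal classes (2-10).
#' @param target_H2 target broad-sense heritability in [0, 1].
#' @param qtl_sites optional data.frame (chrom, pos, effect) of major-QTL
#'   sites; effects are in liability SD units before rescaling.
#' @param n_years,n_reps trial design: years and replicates per year.
#' @param year_effect_sd SD of the common year effect (liability units).
#' @param gxy_var genotype-by-year variance V_gy (liability units^2).
#' @param class_probs optional class probabilities used to place the
#'   liability cut points (defaults to equal probabilities; skew these to
#'   mimic descriptors dominated by one class).
#' @param trait_name trait label in the output table.
#' @param seed integer seed.
#' @return a list of class `trait_sim_config`.
#' @export
trait_sim_config <- function(n_classes = 5, target_H2 = 0.8,
                             qtl_sites = NULL, n_years = 2, n_reps = 3,
                             year_effect_sd = 0.2, gxy_var = 0,
                             class_probs = NULL,
                             trait_name = "trait1", seed = 1) {
  if (target_H2 < 0 || target_H2 > 1)
    stop_cfg("target_H2 must be in [0, 1]")
  if (n_classes < 2 || n_classes > 10)
    stop_cfg("n_classes must be in 2..10")
  if (n_years < 1 || n_reps < 1) stop_cfg("design counts must be >= 1")
  class_probs <- class_probs %||% rep(1 / n_classes, n_classes)
  if (length(class_probs) != n_classes || any(class_probs <= 0))
    stop_cfg("class_probs must be ", n_classes, " positive values")
  class_probs <- class_probs / sum(class_probs)
  structure(list(n_classes = as.integer(n_classes),
                 target_H2 = target_H2, qtl_sites = qtl_sites,
                 n_years = as.integer(n_years), n_reps = as.integer(n_reps),
                 year_effect_sd = year_effect_sd, gxy_var = gxy_var,
                 class_probs = class_probs, trait_name = trait_name,
                 seed = as.integer(seed)),
            class = "trait_sim_config")
}

#' Simulate an ordinal trait table from genotypes
#'
#' The genotypic value of each accession is the sum of configured QTL
#' effects times dosage plus a polygenic normal deviate, centred and
#' rescaled so its in-sample variance is exactly V_g. V_g and V_e are set
#' from `target_H2` (V_g = H2, V_e = (1 - H2) * r * y / max(H2, tiny) ...
#' more precisely V_e solves H2 = V_g / (V_g + V_gy/y + V_e/(r y))), so a
#' variance-components analysis of the emitted table should recover the
#' target up to discretization loss. Liabilities are cut at the quantiles
#' implied by `class_probs` into class codes 1..n_classes. Years are
#' labelled 2020, 2021, ...
#'
#' @param geno a [genotype_matrix()].
#' @param cfg a [trait_sim_config()].
#' @return a trait table data.frame with columns `accession_id`, `trait`,
#'   `year`, `rep`, `class`; the generating liabilities and genotypic
#'   values are attached as attribute `"truth"`.
#' @export
simulate_traits <- function(geno, cfg) {
  stopifnot(inherits(cfg, "trait_sim_config"))
  n <- n_accessions(geno)
  with_seed(cfg$seed, {
    g_raw <- stats::rnorm(n)
    if (!is.null(cfg$qtl_sites)) {
      key <- paste(geno$chrom, geno$pos)
      idx <- match(paste(cfg$qtl_sites$chrom, cfg$qtl_sites$pos), key)
      if (anyNA(idx)) stop_cfg("qtl_sites not present in the panel")
      for (j in seq_along(idx)) {
        d <- geno$dosage[, idx[j]]
        d[is.na(d)] <- mean(d, na.rm = TRUE)
        g_raw <- g_raw + cfg$qtl_sites$effect[j] * d
      }
    }
    h2 <- cfg$target_H2
    y <- cfg$n_years; r <- cfg$n_reps
    Vg <- h2
    # solve H2 = Vg / (Vg + Vgy/y + Ve/(r*y)) for Ve; H2 = 0 -> Vg = 0.
    Ve <- if (h2 == 0) 1 else
      max(0, (Vg / h2 - Vg - cfg$gxy_var / y) * r * y)
    g <- if (Vg == 0) rep(0, n) else
      (g_raw - mean(g_raw)) / stats::sd(g_raw) * sqrt(Vg)
    year_labels <- 2019 + seq_len(y)
    year_eff <- stats::rnorm(y, 0, cfg$year_effect_sd)
    gxy <- matrix(stats::rnorm(n * y, 0, sqrt(cfg$gxy_var)), n, y)
    recs <- expand.grid(rep = seq_len(r), year = seq_len(y),
                        acc = seq_len(n), KEEP.OUT.ATTRS = FALSE)
    liab <- g[recs$acc] + year_eff[recs$year] +
      gxy[cbind(recs$acc, recs$year)] +
      stats::rnorm(nrow(recs), 0, sqrt(Ve))
    cuts <- stats::qnorm(cumsum(cfg$class_probs)[-cfg$n_classes],
                         mean = mean(liab), sd = stats::sd(liab))
    cls <- findInterval(liab, cuts) + 1L
    out <- data.frame(accession_id = geno$accession_ids[recs$acc],
                      trait = cfg$trait_name,
                      year = year_labels[recs$year],
                      rep = recs$rep, class = cls,
                      stringsAsFactors = FALSE)
    attr(out, "truth") <- list(genotypic_value = stats::setNames(
      g, geno$accession_ids), Vg = Vg, Ve = Ve, Vgy = cfg$gxy_var,
      liability = liab)
    out
  })
}
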