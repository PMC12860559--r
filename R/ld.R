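#' Composite LD r^2 between two sites
#'
#' Squared Pearson correlation of the dosage vectors over accessions with
#' both sites called — the standard composite measure of linkage
#' disequilibrium on unphased diploid genotypes.
#'
#' @param a,b numeric dosage vectors of equal length ({0,1,2,NA}).
#' @return r^2 in [0, 1], or `NA` when either site has zero variance or
#'   fewer than two complete pairs.
#' @export
ld_r2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2) return(NA_real_)
  if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) return(NA_real_)
  stats::cor(a[ok], b[ok])^2
}

#' Genome-wide LD decay curve
#'
#' All intra-chromosomal site pairs within `max_dist_bp` are binned by
#' physical distance and the mean r^2 per bin is reported. Pairs where
#' either site is monomorphic (undefined r^2) are excluded.
#'
#' @param geno a [genotype_matrix()].
#' @param max_dist_bp maximum pair distance considered.
#' @param bin_bp distance bin width.
#' @return data.frame of class `ld_decay_curve` with columns
#'   `distance_bin` (bp midpoint), `mean_r2`, `n_pairs`.
#' @export
ld_decay_curve <- function(geno, max_dist_bp = 5e5, bin_bp = 1e4) {
  if (max_dist_bp <= bin_bp) stop_cfg("max_dist_bp must exceed bin_bp")
  nb <- ceiling(max_dist_bp / bin_bp)
  sum_r2 <- numeric(nb); n_pair <- integer(nb)
  d <- geno$dosage
  for (ch in unique(geno$chrom)) {
    sel <- which(geno$chrom == ch)
    p <- geno$pos[sel]
    for (i in seq_along(sel)) {
      js <- which(p > p[i] & p - p[i] <= max_dist_bp)
      if (!length(js)) next
      for (j in js) {
        r2 <- ld_r2(d[, sel[i]], d[, sel[j]])
        if (is.na(r2)) next
        b <- min(nb, ceiling((p[j] - p[i]) / bin_bp))
        sum_r2[b] <- sum_r2[b] + r2
        n_pair[b] <- n_pair[b] + 1L
      }
    }
  }
  if (!sum(n_pair)) stop_cfg("no site pairs within max_dist_bp")
  curve <- data.frame(
    distance_bin = (seq_len(nb) - 0.5) * bin_bp,
    mean_r2 = ifelse(n_pair > 0, sum_r2 / pmax(n_pair, 1), NA_real_),
    n_pairs = n_pair)
  class(curve) <- c("ld_decay_curve", "data.frame")
  curve
}

#' Half-decay distance of an LD curve
#'
#' The physical distance at which the mean r^2 first falls to half its
#' maximum, linearly interpolated between the flanking distance bins. If
#' the very first bin is already at or below half-maximum, its midpoint is
#' returned.
#'
#' @param curve an [ld_decay_curve()] result.
#' @return distance in bp.
#' @export
ld_half_decay_distance <- function(curve) {
  ok <- !is.na(curve$mean_r2)
  x <- curve$distance_bin[ok]; y <- curve$mean_r2[ok]
  if (!length(y)) stop_cfg("empty LD curve")
  half <- max(y) / 2
  below <- which(y <= half)
  if (!length(below)) return(x[length(x)])
  j <- below[1]
  if (j == 1) return(x[1])
  x[j - 1] + (x[j] - x[j - 1]) * (y[j - 1] - half) / (y[j - 1] - y[j])
}
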