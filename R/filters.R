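#' Filter variants by minor allele frequency and missingness
#'
#' A site is retained iff its MAF (computed from non-missing alleles only)
#' is at least `maf_min` and its missing fraction is strictly below
#' `miss_max`. Monomorphic sites are dropped whenever `maf_min > 0`. The
#' panel studies this mirrors typically use MAF >= 0.05 with missing < 0.10
#' for population-genetic inference and MAF > 0.1 for association scans;
#' both regimes are reachable through the parameters.
#'
#' @param geno a [genotype_matrix()].
#' @param maf_min minimum minor allele frequency in [0, 0.5].
#' @param miss_max maximum (exclusive) per-site missing fraction.
#' @param biallelic_only kept for interface completeness; the container is
#'   biallelic by construction.
#' @return the filtered `genotype_matrix`; the numbers of sites dropped per
#'   rule are attached as attribute `"filter_summary"`.
#' @export
filter_variants <- function(geno, maf_min = 0.05, miss_max = 0.10,
                            biallelic_only = TRUE) {
  if (maf_min < 0 || maf_min > 0.5) stop_cfg("maf_min must be in [0, 0.5]")
  maf <- site_maf(geno)
  miss <- site_missing_rate(geno)
  pass_maf <- !is.na(maf) & maf >= maf_min
  pass_miss <- miss < miss_max
  keep <- pass_maf & pass_miss
  out <- subset_geno(geno, sites = which(keep))
  attr(out, "filter_summary") <- data.frame(
    rule = c("input", "fail_maf", "fail_missing", "retained"),
    n_sites = c(n_sites(geno), sum(!pass_maf), sum(!pass_miss), sum(keep)))
  out
}

# One pruning sweep. Windows are anchored at every `step_sites`-th retained
# site and span window_bp from the anchor's position; within a window the
# worst pair above r2_max loses one member: higher missing rate first, then
# the later position. Returns the updated keep vector and whether anything
# was removed.
prune_pass <- function(geno, keep, window_bp, step_sites, r2_max, miss) {
  d <- geno$dosage
  removed_any <- FALSE
  for (ch in unique(geno$chrom)) {
    idx <- which(keep & geno$chrom == ch)
    if (length(idx) < 2) next
    a <- 1L
    while (a <= length(idx)) {
      anchor <- idx[a]
      if (keep[anchor]) {
        win <- idx[keep[idx] & idx >= anchor &
                   geno$pos[idx] < geno$pos[anchor] + window_bp]
        if (length(win) >= 2) {
          r2 <- suppressWarnings(stats::cor(d[, win, drop = FALSE],
                                            use = "pairwise.complete.obs"))^2
          r2[!is.finite(r2)] <- 0
          diag(r2) <- 0
          while (max(r2) > r2_max) {
            viol <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
            pair <- win[as.integer(viol)]
            drop <- if (miss[pair[1]] != miss[pair[2]])
              pair[which.max(miss[pair])] else max(pair)
            keep[drop] <- FALSE
            removed_any <- TRUE
            j <- match(drop, win)
            r2[j, ] <- 0; r2[, j] <- 0
          }
        }
      }
      a <- a + step_sites
    }
  }
  list(keep = keep, removed = removed_any)
}

#' Prune sites in approximate linkage equilibrium
#'
#' Sliding-window LD pruning in the style of the usual `--indep-pairwise`
#' procedure: within each window of `window_bp`, any retained pair with
#' dosage-based r^2 above `r2_max` loses one member (the site with the
#' higher missing rate, ties broken by dropping the later position); the
#' window anchor then advances by `step_sites` retained sites. A final
#' step-1 sweep repeats until no retained in-window pair violates the
#' threshold, so the output provably satisfies the constraint regardless of
#' step size. The result does not depend on accession order.
#'
#' @param geno a [genotype_matrix()].
#' @param window_bp window span in bp (default 20 kb).
#' @param step_sites anchor advance in sites (default 5).
#' @param r2_max maximum allowed pairwise r^2 in (0, 1].
#' @return pruned `genotype_matrix`.
#' @export
ld_prune <- function(geno, window_bp = 20000, step_sites = 5,
                     r2_max = 0.2) {
  if (r2_max <= 0 || r2_max > 1) stop_cfg("r2_max must be in (0, 1]")
  keep <- rep(TRUE, n_sites(geno))
  miss <- site_missing_rate(geno)
  res <- prune_pass(geno, keep, window_bp, step_sites, r2_max, miss)
  repeat {
    res <- prune_pass(geno, res$keep, window_bp, 1L, r2_max, miss)
    if (!res$removed) break
  }
  subset_geno(geno, sites = which(res$keep))
}
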