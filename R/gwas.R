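#' Per-marker association scan with PC covariates
#'
#' A documented linear-model scan: for each site, ordinary least squares of
#' phenotype on intercept + dosage + the leading genomic PCs, restricted to
#' accessions with a called genotype at that site, with a two-sided t-test
#' on the dosage coefficient. The PC covariates absorb population
#' stratification the way mixed-model scans use them as fixed effects.
#' Monomorphic sites get p = 1 so site indexing stays aligned.
#'
#' @param geno a [genotype_matrix()].
#' @param phenotype numeric vector, one value per accession (may be named
#'   by accession id).
#' @param n_pcs number of genomic PCs included as covariates (0 for none).
#' @return data.frame of class `scan_result` with columns `chrom`, `pos`,
#'   `effect`, `p_value`, `neglog10p`, ordered by (chrom, pos).
#' @export
association_scan <- function(geno, phenotype, n_pcs = 3) {
  n <- n_accessions(geno)
  if (length(phenotype) != n)
    stop_cfg("phenotype length must equal the number of accessions")
  if (!is.null(names(phenotype)))
    phenotype <- phenotype[geno$accession_ids]
  y <- as.numeric(phenotype)
  if (anyNA(y)) stop_cfg("phenotype must be complete")
  if (stats::sd(y) == 0) stop_cfg("constant phenotype")
  if (n_pcs >= n) stop_cfg("n_pcs must be < number of accessions")
  covar <- if (n_pcs > 0) pca_grm(geno, n_pcs)$vectors else NULL
  d <- geno$dosage
  m <- ncol(d)
  eff <- rep(NA_real_, m); pv <- rep(1, m)
  X0 <- cbind(intercept = rep(1, n), covar)
  for (s in seq_len(m)) {
    x <- d[, s]
    ok <- !is.na(x)
    if (sum(ok) < ncol(X0) + 2 || stats::var(x[ok]) == 0) next
    X <- cbind(X0[ok, , drop = FALSE], dosage = x[ok])
    fit <- stats::lm.fit(X, y[ok])
    df <- sum(ok) - fit$rank
    if (df < 1 || is.na(fit$coefficients["dosage"])) next
    rss <- sum(fit$residuals^2)
    XtXinv <- chol2inv(chol(crossprod(X)))
    se <- sqrt(rss / df * XtXinv[ncol(X), ncol(X)])
    tval <- fit$coefficients["dosage"] / se
    eff[s] <- unname(fit$coefficients["dosage"])
    pv[s] <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  }
  pv[pv <= 0] <- .Machine$double.xmin
  out <- data.frame(chrom = geno$chrom, pos = geno$pos, effect = eff,
                    p_value = pv, neglog10p = -log10(pv))
  class(out) <- c("scan_result", "data.frame")
  out
}

#' Genome-wide significance thresholds
#'
#' Returns the two conventional thresholds on the -log10 scale for a scan
#' of `n_snps` markers: the permutation-style threshold log10(n_snps)
#' (i.e. -log10(1/n)) and the Bonferroni threshold log10(n_snps / alpha)
#' (i.e. -log10(alpha/n)). Values are exact; round only for display.
#'
#' @param n_snps number of markers tested.
#' @param alpha family-wise error rate for Bonferroni (default 0.05).
#' @return named numeric vector `c(perm_style =, bonferroni =)`.
#' @export
significance_thresholds <- function(n_snps, alpha = 0.05) {
  if (n_snps < 1) stop_cfg("n_snps must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop_cfg("alpha must be in (0, 1)")
  c(perm_style = log10(n_snps), bonferroni = log10(n_snps / alpha))
}

#' Genomic inflation factor (lambda)
#'
#' lambda = median of the 1-df chi-square statistics implied by the
#' p-values divided by the null median qchisq(0.5, 1) ~ 0.4549. Values
#' near 1 indicate a calibrated scan; > 1 inflation (stratification),
#' < 1 deflation.
#'
#' @param pvals p-values in (0, 1].
#' @return lambda.
#' @export
genomic_inflation <- function(pvals) {
  if (length(pvals) < 10) stop_cfg("need >= 10 p-values")
  if (any(is.na(pvals)) || any(pvals <= 0 | pvals > 1))
    stop_cfg("p-values must lie in (0, 1]")
  chisq <- stats::qchisq(pvals, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' Multi-year BLUPs of accession effects
#'
#' Fits class ~ year (fixed) + (1 | accession) by REML (\pkg{lme4}) across
#' all years of one trait and returns the best linear unbiased predictions
#' of the accession effects — shrunken, mean-zero genotype values suited
#' as a multi-environment phenotype for association scans. A single-year
#' table is an error (per-year means are an explicit, separate choice, not
#' a silent fallback).
#'
#' @param traits a trait table.
#' @param trait trait name.
#' @return named numeric vector of BLUPs, one per accession.
#' @export
blup_across_years <- function(traits, trait) {
  sub <- traits[traits$trait == trait & !is.na(traits$class), ,
                drop = FALSE]
  if (!nrow(sub)) stop_cfg("no data for trait '", trait, "'")
  if (length(unique(sub$year)) < 2)
    stop_cfg("BLUP combination needs >= 2 years")
  sub$accession_id <- factor(sub$accession_id)
  sub$year_f <- factor(sub$year)
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(class ~ year_f + (1 | accession_id), data = sub)))
  re <- lme4::ranef(fit)$accession_id
  stats::setNames(re[, 1], rownames(re))
}

#' Clump significant SNPs into QTL regions
#'
#' Sites at or above `sig_threshold` (on -log10 p) are grouped per
#' chromosome by merging consecutive significant SNPs whose gap is at most
#' `gap_bp`; groups with fewer than `min_snps` significant SNPs are
#' discarded. A region spans the min..max significant positions; its lead
#' SNP is the most significant one (ties to the smaller position). The
#' defaults mirror common GWAS reporting practice for dense panels:
#' -log10(p) >= 7, 200-kb gap, >= 3 SNPs.
#'
#' @param scan a `scan_result` (must be sorted by chrom, pos).
#' @param sig_threshold significance cutoff on the -log10(p) scale.
#' @param gap_bp maximum gap between adjacent significant SNPs in one
#'   region.
#' @param min_snps minimum significant SNPs per reported region.
#' @param trait optional trait label carried into the output.
#' @return data.frame with `trait`, `chrom`, `start`, `end`, `lead_snp`,
#'   `lead_neglog10p`, `n_sig_snps`; zero rows when nothing is
#'   significant.
#' @export
clump_qtl <- function(scan, sig_threshold = 7.0, gap_bp = 2e5,
                      min_snps = 3, trait = NA_character_) {
  if (gap_bp <= 0) stop_cfg("gap_bp must be > 0")
  ord <- order(scan$chrom, scan$pos)
  if (any(ord != seq_len(nrow(scan))))
    stop_cfg("scan must be sorted by (chrom, pos)")
  sig <- scan[scan$neglog10p >= sig_threshold, , drop = FALSE]
  empty <- data.frame(trait = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      lead_snp = character(0),
                      lead_neglog10p = numeric(0), n_sig_snps = integer(0))
  if (!nrow(sig)) return(empty)
  regions <- list()
  for (ch in unique(sig$chrom)) {
    s <- sig[sig$chrom == ch, , drop = FALSE]
    grp <- cumsum(c(1, diff(s$pos) > gap_bp))
    for (g in unique(grp)) {
      r <- s[grp == g, , drop = FALSE]
      if (nrow(r) < min_snps) next
      lead <- r[order(-r$neglog10p, r$pos)[1], ]
      regions[[length(regions) + 1]] <- data.frame(
        trait = trait, chrom = ch, start = min(r$pos), end = max(r$pos),
        lead_snp = paste0(lead$chrom, ":", lead$pos),
        lead_neglog10p = lead$neglog10p, n_sig_snps = nrow(r))
    }
  }
  if (!length(regions)) return(empty)
  out <- do.call(rbind, regions)
  out[order(out$chrom, out$start), , drop = FALSE]
}
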