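test_that("association scan pinpoints a planted signal", {
  sim <- simulate_structured_population(pop_sim_config(
    n_subpops = 1, n_per_subpop = 200, n_sites = 300, seed = 61))
  g <- sim$geno
  set.seed(62)
  y <- g$dosage[, 100] + rnorm(200, 0, 0.01)
  scan <- association_scan(g, y, n_pcs = 0)
  expect_equal(which.min(scan$p_value), 100)
  expect_lt(scan$p_value[100], 1e-10)
  expect_true(all(scan$p_value > 0 & scan$p_value <= 1))
  expect_false(is.unsorted(order(scan$chrom, scan$pos)))
  expect_error(association_scan(g, rep(1, 200)), "constant phenotype")
  expect_error(association_scan(g, y[1:10]), "length")
})

test_that("permuted phenotypes give uniform p-values", {
  sim <- simulate_structured_population(pop_sim_config(
    n_subpops = 1, n_per_subpop = 150, n_sites = 2000, seed = 63))
  tr <- simulate_traits(sim$geno, trait_sim_config(target_H2 = 0.6,
                                                   seed = 64))
  y <- blup_across_years(tr, "trait1")[sim$geno$accession_ids]
  set.seed(65)
  scan <- association_scan(sim$geno, sample(y), n_pcs = 0)
  expect_gt(suppressWarnings(
    stats::ks.test(scan$p_value, "punif")$p.value), 0.01)
})

test_that("PC covariates deflate stratification-driven inflation", {
  wins <- sapply(1:10, function(s) {
    sim <- simulate_structured_population(pop_sim_config(
      n_subpops = 2, n_per_subpop = 60, n_sites = 800, divergence = 0.25,
      seed = 1900 + s))
    # phenotype confounded with subpopulation
    lab <- sim$meta$horticultural_type
    set.seed(2000 + s)
    y <- as.numeric(factor(lab)) + rnorm(120, 0, 0.5)
    l0 <- genomic_inflation(
      association_scan(sim$geno, y, n_pcs = 0)$p_value)
    l3 <- genomic_inflation(
      association_scan(sim$geno, y, n_pcs = 3)$p_value)
    l3 < l0
  })
  expect_gte(sum(wins), 9)
})

test_that("significance thresholds follow the closed forms", {
  thr <- significance_thresholds(3842327, 0.05)
  expect_equal(round(unname(thr), 3), c(6.585, 7.886))
  expect_equal(unname(significance_thresholds(100, 0.05)),
               c(2, log10(100 / 0.05)), tolerance = 1e-12)
  expect_equal(unname(significance_thresholds(1)["perm_style"]), 0)
  expect_error(significance_thresholds(0), "n_snps")
  expect_error(significance_thresholds(10, 1.5), "alpha")
})

test_that("genomic inflation is calibrated and detects deflation", {
  set.seed(67)
  expect_lt(abs(genomic_inflation(runif(10000)) - 1), 0.05)
  # constructed deflation: push p-values toward 1
  p <- runif(5000)
  expect_lt(genomic_inflation(1 - (1 - p)^2), 1)
  # all p = 0.5 sits exactly at the null median
  expect_equal(genomic_inflation(rep(0.5, 100)), 1, tolerance = 1e-12)
  expect_error(genomic_inflation(c(0.5, 0)), "10 p-values")
  expect_error(genomic_inflation(rep(1.5, 20)), "0, 1")
})

test_that("BLUPs shrink correctly in the variance limits", {
  # pure-noise trait: BLUPs collapse toward zero
  sim <- simulate_structured_population(pop_sim_config(
    n_subpops = 1, n_per_subpop = 100, n_sites = 50, seed = 71))
  tr0 <- simulate_traits(sim$geno, trait_sim_config(target_H2 = 0,
                                                    seed = 72))
  b0 <- blup_across_years(tr0, "trait1")
  expect_lt(stats::sd(b0), 0.25 * stats::sd(tr0$class))
  expect_lt(abs(mean(b0)), 1e-8)
  # near-noiseless trait: BLUPs approach centred genotype means
  tr1 <- simulate_traits(sim$geno, trait_sim_config(
    target_H2 = 0.99, n_classes = 10, year_effect_sd = 0, seed = 73))
  b1 <- blup_across_years(tr1, "trait1")
  gm <- tapply(tr1$class, tr1$accession_id, mean)
  gm <- gm - mean(gm)
  expect_gt(stats::cor(b1, gm[names(b1)]), 0.99)
  expect_error(blup_across_years(tr1[tr1$year == 2020, ], "trait1"),
               "2 years")
})

test_that("multi-year BLUP scans detect a planted QTL at least as often", {
  blup_hits <- 0; single_hits <- 0
  for (s in 1:10) {
    sim <- simulate_structured_population(pop_sim_config(
      n_subpops = 1, n_per_subpop = 150, n_sites = 200, seed = 2100 + s))
    qi <- 77
    tr <- simulate_traits(sim$geno, trait_sim_config(
      target_H2 = 0.35, n_classes = 8,
      qtl_sites = data.frame(chrom = sim$geno$chrom[qi],
                             pos = sim$geno$pos[qi], effect = 2),
      seed = 2200 + s))
    thr_rank <- 3  # "detected" = planted site among the top 3
    yb <- blup_across_years(tr, "trait1")[sim$geno$accession_ids]
    sb <- association_scan(sim$geno, yb, n_pcs = 0)
    y1 <- tapply(tr$class[tr$year == 2020],
                 tr$accession_id[tr$year == 2020],
                 mean)[sim$geno$accession_ids]
    s1 <- association_scan(sim$geno, as.numeric(y1), n_pcs = 0)
    blup_hits <- blup_hits + (rank(sb$p_value)[qi] <= thr_rank)
    single_hits <- single_hits + (rank(s1$p_value)[qi] <= thr_rank)
  }
  expect_gte(blup_hits, 9)
  expect_gte(blup_hits, single_hits)
})

test_that("QTL clumping follows the gap/density/lead rules", {
  mk_scan <- function(pos, nl, chrom = "3") {
    s <- data.frame(chrom = chrom, pos = pos, effect = 1,
                    p_value = 10^(-nl), neglog10p = nl)
    class(s) <- c("scan_result", "data.frame")
    s
  }
  # worked example: gaps 50k, 100k, 350k around threshold 7
  scan <- mk_scan(c(100e3, 150e3, 250e3, 600e3), c(8.2, 7.5, 9.1, 7.2))
  q <- clump_qtl(scan, sig_threshold = 7, gap_bp = 2e5, min_snps = 3)
  expect_equal(nrow(q), 1)
  expect_equal(c(q$start, q$end), c(100000, 250000))
  expect_equal(q$lead_snp, "3:250000")
  expect_equal(q$n_sig_snps, 3)
  # nothing significant
  expect_equal(nrow(clump_qtl(mk_scan(1:5 * 1e5, rep(3, 5)), 7)), 0)
  # one chain
  q2 <- clump_qtl(mk_scan(1:5 * 1e5, rep(8, 5)), 7, gap_bp = 1e5,
                  min_snps = 3)
  expect_equal(nrow(q2), 1)
  expect_equal(c(q2$start, q2$end), c(1e5, 5e5))
  # lead SNP inside its interval; idempotence on a region's own SNPs
  expect_true(q$start <= 250000 && 250000 <= q$end)
  sub <- scan[scan$pos <= 250e3, ]
  class(sub) <- c("scan_result", "data.frame")
  q3 <- clump_qtl(sub, 7, 2e5, 3)
  expect_equal(q3[c("start", "end", "lead_snp")],
               q[c("start", "end", "lead_snp")])
  expect_error(clump_qtl(mk_scan(c(200, 100), c(8, 8))), "sorted")
})

test_that("clumping agrees with the exhaustive gap-partition oracle", {
  set.seed(81)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    pos <- sort(sample.int(5e6, n))
    nl <- runif(n, 7, 15)
    scan <- data.frame(chrom = "1", pos = pos, effect = 0,
                       p_value = 10^(-nl), neglog10p = nl)
    class(scan) <- c("scan_result", "data.frame")
    gap <- sample(c(1e5, 2e5, 5e5), 1)
    mn <- sample(2:4, 1)
    got <- clump_qtl(scan, 7, gap, mn)
    want <- oracle_clump(pos, nl, gap, mn)
    expect_equal(nrow(got), length(want))
    if (length(want)) {
      expect_equal(got$start, sapply(want, `[[`, "start"))
      expect_equal(got$end, sapply(want, `[[`, "end"))
      expect_equal(as.integer(sub(".*:", "", got$lead_snp)),
                   sapply(want, `[[`, "lead"))
    }
    # regions disjoint and sorted
    if (nrow(got) > 1)
      expect_true(all(got$start[-1] > got$end[-nrow(got)]))
  }
})

test_that("scan plus clump recovers a planted QTL region", {
  hits <- sapply(1:10, function(s) {
    sim <- simulate_structured_population(pop_sim_config(
      n_subpops = 1, n_per_subpop = 300, n_sites = 400,
      chrom_length_bp = 2e7, seed = 2300 + s))
    g <- sim$geno
    qi <- 200
    set.seed(2400 + s)
    x <- g$dosage[, qi]
    y <- x * sqrt(0.2 / var(x)) + rnorm(300, 0, sqrt(0.8))
    scan <- association_scan(g, y, n_pcs = 0)
    q <- clump_qtl(scan, sig_threshold = 5, gap_bp = 2e5, min_snps = 1)
    any(q$chrom == g$chrom[qi] & q$start <= g$pos[qi] & g$pos[qi] <= q$end)
  })
  expect_gte(sum(hits), 9)
})
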