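test_that("windowed pi matches the pairwise-difference oracle", {
  # two accessions both heterozygous: alleles R,A,R,A -> pi = 4/6
  g <- tiny_geno(matrix(1, 2, 1), chrom_len = 10000)
  pw <- nucleotide_diversity_windows(g, list(g = g$accession_ids),
                                     window_bp = 10000, step_bp = 10000)$g
  expect_equal(pw$value[1] * 10000, 2 / 3, tolerance = 1e-12)
  expect_equal(oracle_site_pi(c(1, 1)), 2 / 3, tolerance = 1e-12)
  # monomorphic window is zero
  g0 <- tiny_geno(matrix(2, 4, 3))
  w0 <- nucleotide_diversity_windows(g0, NULL, 10000, 10000)$all
  expect_equal(w0$value, rep(0, nrow(w0)))
  expect_error(nucleotide_diversity_windows(g, list(x = character(0))),
               "empty group")
  # oracle equality on random panels with missingness
  for (s in 1:5) {
    panel <- random_panel(8, 30, miss = 0.1, seed = 700 + s)
    got <- nucleotide_diversity_windows(
      panel, NULL, window_bp = 30000, step_bp = 30000)$all
    want <- sum(sapply(seq_len(30), function(j)
      oracle_site_pi(panel$dosage[, j])), na.rm = TRUE) / 30000
    expect_equal(got$value[1], want, tolerance = 1e-10)
  }
})

test_that("wild-like high-diversity group exceeds a drifted derived group", {
  wins <- sapply(1:10, function(s) {
    sim <- simulate_structured_population(pop_sim_config(
      n_subpops = 2, n_per_subpop = 30, n_sites = 400,
      divergence = c(0.02, 0.5), seed = 800 + s))
    grp <- split(sim$meta$accession_id, sim$meta$horticultural_type)
    pis <- nucleotide_diversity_windows(sim$geno, grp, 1e5, 1e5)
    mean(pis[[1]]$value, na.rm = TRUE) > mean(pis[[2]]$value, na.rm = TRUE)
  })
  # subpop 1 has weak drift (retains founder diversity), subpop 2 strong
  expect_gte(sum(wins), 9)
})

test_that("Weir-Cockerham FST behaves at its analytic anchors", {
  # fixed alternate alleles -> FST = 1
  d <- rbind(matrix(0, 4, 10), matrix(2, 4, 10))
  rownames(d) <- paste0("a", 1:8)
  g <- tiny_geno(d)
  fst <- pairwise_fst_windows(g, paste0("a", 1:4), paste0("a", 5:8))
  expect_equal(fst$genomewide, 1.0, tolerance = 1e-12)
  expect_error(pairwise_fst_windows(g, paste0("a", 1:4), paste0("a", 4:8)),
               "overlap")
  # identical frequencies, large n -> ~0
  sim <- simulate_structured_population(pop_sim_config(
    n_subpops = 2, n_per_subpop = 100, n_sites = 5000, divergence = 0,
    seed = 17))
  grp <- split(sim$meta$accession_id, sim$meta$horticultural_type)
  expect_lt(abs(pairwise_fst_windows(sim$geno, grp[[1]],
                                     grp[[2]])$genomewide), 0.01)
  # symmetry
  panel <- random_panel(12, 40, miss = 0.05, seed = 19)
  A <- panel$accession_ids[1:6]; B <- panel$accession_ids[7:12]
  expect_equal(pairwise_fst_windows(panel, A, B)$genomewide,
               pairwise_fst_windows(panel, B, A)$genomewide)
})

test_that("Balding-Nichols drift parameter is recovered as FST", {
  fsts <- sapply(1:10, function(s) {
    sim <- simulate_structured_population(pop_sim_config(
      n_subpops = 2, n_per_subpop = 50, n_sites = 2000,
      divergence = 0.1, seed = 1000 + s))
    grp <- split(sim$meta$accession_id, sim$meta$horticultural_type)
    pairwise_fst_windows(sim$geno, grp[[1]], grp[[2]])$genomewide
  })
  expect_lt(abs(mean(fsts) - 0.1), 0.02)
})

test_that("r2 equals the direct correlation formula", {
  expect_equal(ld_r2(c(0, 1, 2, 0), c(0, 1, 2, 0)), 1.0)
  expect_equal(ld_r2(c(0, 0, 2, 2), c(0, 2, 0, 2)), 0.0)
  expect_true(is.na(ld_r2(c(1, 1, 1), c(0, 1, 2))))
  set.seed(5)
  for (i in 1:20) {
    a <- rbinom(15, 2, 0.5); b <- rbinom(15, 2, 0.5)
    a[sample(15, 2)] <- NA
    ok <- !is.na(a) & !is.na(b)
    if (sd(a[ok]) == 0 || sd(b[ok]) == 0) next
    num <- sum((a[ok] - mean(a[ok])) * (b[ok] - mean(b[ok])))
    den <- sqrt(sum((a[ok] - mean(a[ok]))^2) * sum((b[ok] - mean(b[ok]))^2))
    expect_equal(ld_r2(a, b), (num / den)^2, tolerance = 1e-12)
  }
})

test_that("LD decay curve recovers the generator's half-decay distance", {
  # duplicated-site panel: max mean r2 = 1 in the first bin
  base <- rbinom(40, 2, 0.5)
  gdup <- genotype_matrix(cbind(base, base), c("1", "1"), c(100L, 600L))
  cv <- ld_decay_curve(gdup, max_dist_bp = 2000, bin_bp = 1000)
  expect_equal(cv$mean_r2[1], 1.0)
  # Markov copying process: r2(d) = exp(-2d/decay); half-decay relative
  # to the measured maximum at the first bin midpoint m0 is
  # m0 + (decay/2) ln 2
  halves <- sapply(1:5, function(s) {
    g <- simulate_ld_population(n_haplotypes = 120, n_sites = 250,
                                chrom_length_bp = 1.5e6,
                                decay_bp = 2e5, seed = 1100 + s)
    ld_half_decay_distance(ld_decay_curve(g, 1e6, 5e4))
  })
  analytic <- 25000 + 1e5 * log(2)
  expect_lt(abs(mean(halves) - analytic) / analytic, 0.25)
  # unlinked sites: flat curve near the 1/n sampling floor; half-decay
  # collapses to the first bin
  set.seed(33)
  gind <- tiny_geno(matrix(rbinom(50 * 60, 2, 0.5), 50, 60))
  cvi <- ld_decay_curve(gind, max_dist_bp = 30000, bin_bp = 5000)
  expect_lt(max(cvi$mean_r2, na.rm = TRUE), 0.15)
  expect_error(ld_decay_curve(gdup, 2000, 3000), "exceed")
})

test_that("GRM has unit-mean diagonal and separates subpopulations", {
  # identical homozygous accessions: off-diagonal equals diagonal
  g2 <- tiny_geno(rbind(x = c(0, 2, 0, 2), y = c(0, 2, 0, 2),
                        z = c(2, 0, 2, 0)))
  A <- grm(g2)
  expect_equal(A["x", "y"], A["x", "x"], tolerance = 1e-12)
  # Hardy-Weinberg panel: mean diagonal ~ 1, PSD
  sim <- simulate_structured_population(pop_sim_config(
    n_subpops = 1, n_per_subpop = 80, n_sites = 5000, divergence = 0,
    seed = 23))
  A2 <- grm(sim$geno)
  expect_lt(abs(mean(diag(A2)) - 1), 0.05)
  expect_gte(min(eigen(A2, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)
  # two-subpopulation panel: PC1 linearly separates the labels
  sim2 <- simulate_structured_population(pop_sim_config(
    n_subpops = 2, n_per_subpop = 40, n_sites = 1000, divergence = 0.3,
    seed = 29))
  pc <- pca_grm(sim2$geno, 3)
  expect_false(is.unsorted(rev(pc$values)))
  lab <- sim2$meta$horticultural_type[match(rownames(pc$vectors),
                                            sim2$meta$accession_id)]
  s1 <- pc$vectors[lab == unique(lab)[1], 1]
  s2 <- pc$vectors[lab == unique(lab)[2], 1]
  expect_true(max(s1) < min(s2) || max(s2) < min(s1))
  expect_error(pca_grm(sim2$geno, 1000), "k must not")
})

test_that("IBS distances and neighbour joining recover known trees", {
  g <- tiny_geno(rbind(a = c(0, 0, 0), b = c(0, 0, 0), c = c(2, 2, 2)))
  D <- ibs_distance(g)
  expect_equal(D["a", "b"], 0)
  expect_equal(D["a", "c"], 1)
  expect_equal(D, t(D))
  expect_error(nj_tree(D[1:2, 1:2]), ">= 3 taxa")
  # additive 4-taxon matrix from a known tree: ((A:1,B:2):1,(C:3,D:1):1)
  tr <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:1):1);")
  D4 <- ape::cophenetic.phylo(tr)
  nwk <- nj_tree(D4)
  back <- attr(nwk, "phylo")
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(back)), 0,
               ignore_attr = TRUE)
  expect_equal(sort(as.vector(ape::cophenetic.phylo(back))),
               sort(as.vector(D4)), tolerance = 1e-10)
  # wild outgroup forms a clade on a structured panel
  sim <- simulate_structured_population(pop_sim_config(
    n_subpops = 3, n_per_subpop = 8, n_sites = 800,
    divergence = c(0.05, 0.1, 0.6), seed = 37))
  nwk2 <- nj_tree(ibs_distance(sim$geno))
  ph <- attr(nwk2, "phylo")
  wild <- sim$meta$accession_id[sim$meta$horticultural_type == "wild"]
  expect_true(ape::is.monophyletic(ph, wild))
})
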