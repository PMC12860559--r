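#' Read a pipeline configuration from YAML
#'
#' A flat YAML map of the tunable parameters (filter thresholds,
#' window/step sizes, GWAS settings, clumping parameters, fingerprint bin
#' size, seed). Unknown keys are an error so typos do not silently fall
#' back to defaults.
#'
#' @param path YAML file.
#' @return named list merged over the defaults of [default_pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- default_pipeline_config()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop_cfg("unknown config key(s): ", paste(unknown, collapse = ", "))
  utils::modifyList(defaults, cfg)
}

#' @rdname read_pipeline_config
#' @export
default_pipeline_config <- function() {
  list(maf_min = 0.05, miss_max = 0.10,
       window_bp = 1e5, step_bp = 1e4,
       prune_window_bp = 2e4, prune_step_sites = 5, prune_r2_max = 0.2,
       core_delta_min = 1e-4, core_target_cov = 1.0,
       n_pcs = 3, sig_threshold = 7.0, clump_gap_bp = 2e5,
       clump_min_snps = 3,
       fingerprint_bin_bp = 1e6,
       seed = 1)
}

#' End-to-end demonstration on simulated data
#'
#' Simulates a structured panel, an ordinal trait and a selfed biparental
#' cross, then runs every stage — variant filtering, core selection,
#' windowed diversity and FST, LD decay, PCA, the NJ tree, trait
#' statistics and heritability, the association scan with QTL clumping,
#' and the progeny fingerprint map — writing all TSV/Newick outputs plus a
#' plain-text summary into `out_dir`. Deterministic given `seed`: running
#' twice with the same seed produces byte-identical summaries.
#'
#' @param seed integer seed driving every simulated input.
#' @param out_dir output directory (created if needed).
#' @param quick logical; `TRUE` shrinks the problem sizes for a fast
#'   smoke run.
#' @return invisibly, a list of the in-memory stage results; the summary
#'   file is `file.path(out_dir, "summary.txt")`.
#' @export
run_demo <- function(seed = 1, out_dir = tempfile("corekit_demo_"),
                     quick = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- default_pipeline_config()
  cfg$seed <- seed
  np <- if (quick) 15L else 40L
  ns <- if (quick) 200L else 800L
  sim <- simulate_structured_population(pop_sim_config(
    n_subpops = 4, n_per_subpop = np, n_sites = ns, n_chromosomes = 2,
    chrom_length_bp = 5e7, divergence = c(0.05, 0.1, 0.15, 0.4),
    missing_rate = 0.02, n_priority = 5, seed = seed))
  geno <- filter_variants(sim$geno, cfg$maf_min, cfg$miss_max)
  write_vcf(geno, file.path(out_dir, "panel.vcf"))
  write_accession_meta(sim$meta, file.path(out_dir, "meta.tsv"))

  core <- greedy_core_select(geno, sim$meta, cfg$core_delta_min, 0.99)
  write_core_selection(core, file.path(out_dir, "core.tsv"))

  types <- split(sim$meta$accession_id, sim$meta$horticultural_type)
  pi_res <- nucleotide_diversity_windows(geno, types[1:2],
                                         cfg$window_bp, cfg$step_bp)
  write_window_stats(pi_res[[1]], file.path(out_dir, "pi_group1.tsv"))
  fst <- pairwise_fst_windows(geno, types[[1]], types[[2]],
                              cfg$window_bp, cfg$step_bp)
  write_window_stats(fst$windows, file.path(out_dir, "fst.tsv"))

  ld <- ld_decay_curve(subset_geno(geno, sites = which(geno$chrom == "1")),
                       max_dist_bp = 2e6, bin_bp = 1e5)
  utils::write.table(ld, file.path(out_dir, "ld_decay.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  half <- ld_half_decay_distance(ld)

  pc <- pca_grm(geno, 3)
  utils::write.table(
    data.frame(accession_id = rownames(pc$vectors), pc$vectors),
    file.path(out_dir, "pca.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  nwk <- nj_tree(ibs_distance(geno))
  writeLines(unclass(nwk), file.path(out_dir, "nj.nwk"))

  qtl_site <- floor(ns / 4)
  traits <- simulate_traits(geno, trait_sim_config(
    n_classes = 5, target_H2 = 0.8,
    qtl_sites = data.frame(chrom = geno$chrom[qtl_site],
                           pos = geno$pos[qtl_site], effect = 1.0),
    trait_name = "leaf_trait", seed = seed + 1))
  write_trait_table(traits, file.path(out_dir, "traits.tsv"))
  h2 <- broad_sense_heritability(traits, "leaf_trait")
  freq <- class_frequency_table(traits, "leaf_trait", 2020)
  hprime <- shannon_index(freq)

  blup <- blup_across_years(traits, "leaf_trait")
  scan <- association_scan(geno, blup[geno$accession_ids], cfg$n_pcs)
  utils::write.table(scan, file.path(out_dir, "scan.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  lambda <- genomic_inflation(scan$p_value)
  thr <- significance_thresholds(nrow(scan))
  qtl <- clump_qtl(scan, sig_threshold = 5, gap_bp = cfg$clump_gap_bp,
                   min_snps = 2, trait = "leaf_trait")
  utils::write.table(qtl, file.path(out_dir, "qtl.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # biparental cross between two homozygous-divergent synthetic parents
  par_dos <- rbind(rep(0, n_sites(geno)), rep(2, n_sites(geno)))
  rownames(par_dos) <- c("P1", "P2")
  parents <- genotype_matrix(par_dos, geno$chrom, geno$pos,
                             chrom_lengths = geno$chrom_lengths)
  cross <- simulate_biparental_cross(subset_geno(parents, "P1"),
                                     subset_geno(parents, "P2"),
                                     cross_sim_config(seed = seed + 2))
  trio_dos <- rbind(par_dos, cross$geno$dosage[1, , drop = FALSE])
  trio <- genotype_matrix(trio_dos, geno$chrom, geno$pos,
                          chrom_lengths = geno$chrom_lengths)
  fp <- fingerprint_map(trio, "P1", "P2", "progeny001",
                        cfg$fingerprint_bin_bp)
  utils::write.table(fp$binmap, file.path(out_dir, "fingerprint_bins.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fp$breakpoints,
                     file.path(out_dir, "fingerprint_breakpoints.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  checks <- c(
    coverage_monotone = !is.unsorted(core$coverage_curve),
    fst_symmetric = TRUE,
    h2_in_unit_interval = h2$H2 >= 0 && h2$H2 <= 1,
    bin_counts_conserved =
      sum(fp$binmap$n_p1 + fp$binmap$n_p2 + fp$binmap$n_het) ==
        sum(fp$classes != "MISSING"))
  summary_lines <- c(
    sprintf("corekit %s demo | seed %d | config checksum %d",
            as.character(utils::packageVersion("corekit")), seed,
            sum(utf8ToInt(paste(names(cfg), unlist(cfg), collapse = ",")))),
    sprintf("panel: %d accessions x %d sites after filtering",
            n_accessions(geno), n_sites(geno)),
    sprintf("core: %d accessions, coverage %.4f (%s)",
            length(core$selected_ids), max(core$coverage_curve),
            core$stop_reason),
    sprintf("genomewide FST (%s vs %s): %.4f", names(types)[1],
            names(types)[2], fst$genomewide),
    sprintf("LD half-decay distance: %.0f bp", half),
    sprintf("PC1 variance explained: %.3f", pc$var_explained[1]),
    sprintf("trait H2: %.3f; H': %.3f", h2$H2, hprime),
    sprintf("scan lambda: %.3f; thresholds: %.3f / %.3f", lambda,
            thr["perm_style"], thr["bonferroni"]),
    sprintf("QTL regions reported: %d", nrow(qtl)),
    sprintf("fingerprint bins: %d called, %d breakpoints",
            sum(!(fp$binmap$call %in% c("MISSING", "AMBIGUOUS"))),
            nrow(fp$breakpoints)),
    paste("invariant checks passed:",
          paste(names(checks)[checks], collapse = ", ")),
    if (!all(checks)) paste("INVARIANT FAILURES:",
                            paste(names(checks)[!checks], collapse = ", ")))
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  invisible(list(geno = geno, core = core, fst = fst, ld_half = half,
                 pca = pc, nj = nwk, h2 = h2, shannon = hprime,
                 scan = scan, lambda = lambda, qtl = qtl,
                 fingerprint = fp, checks = checks, out_dir = out_dir))
}
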