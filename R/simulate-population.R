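#' Configuration for the structured-population simulator
#'
#' Defaults emulate a germplasm panel of several horticultural types with
#' type-specific divergence from a common founder pool: founder minor
#' allele frequencies are Uniform(0.05, 0.5) (the post-filter MAF regime of
#' resequenced panels) and each subpopulation drifts from the founders
#' under a Balding-Nichols reparameterization, so the realized FST between
#' subpopulations is controlled by `divergence`.
#'
#' @param n_subpops number of subpopulations (<= 8; they are labelled with
#'   lettuce horticultural types for downstream grouping).
#' @param n_per_subpop accessions per subpopulation.
#' @param n_sites total number of biallelic SNPs.
#' @param n_chromosomes number of chromosomes the sites are spread over.
#' @param chrom_length_bp chromosome length in bp.
#' @param divergence Balding-Nichols drift parameter in [0, 1); scalar or
#'   one value per subpopulation.
#' @param missing_rate fraction of genotype calls set missing uniformly at
#'   random.
#' @param maf_range founder allele-frequency law Uniform(min, max).
#' @param n_priority number of accessions flagged as breeding priorities in
#'   the metadata (taken evenly across subpopulations).
#' @param seed integer seed; the single source of randomness.
#' @return a list of class `pop_sim_config`.
#' @export
pop_sim_config <- function(n_subpops = 4, n_per_subpop = 50,
                           n_sites = 1000, n_chromosomes = 2,
                           chrom_length_bp = 5e7, divergence = 0.1,
                           missing_rate = 0, maf_range = c(0.05, 0.5),
                           n_priority = 0, seed = 1) {
  cfg <- list(n_subpops = as.integer(n_subpops),
              n_per_subpop = as.integer(n_per_subpop),
              n_sites = as.integer(n_sites),
              n_chromosomes = as.integer(n_chromosomes),
              chrom_length_bp = as.integer(chrom_length_bp),
              divergence = as.numeric(divergence),
              missing_rate = as.numeric(missing_rate),
              maf_range = as.numeric(maf_range),
              n_priority = as.integer(n_priority),
              seed = as.integer(seed))
  if (cfg$n_sites < 1 || cfg$n_subpops < 1 || cfg$n_per_subpop < 1 ||
      cfg$n_chromosomes < 1)
    stop_cfg("counts must be >= 1")
  if (cfg$n_subpops > length(horticultural_types))
    stop_cfg("at most ", length(horticultural_types), " subpopulations")
  if (any(cfg$divergence < 0) || any(cfg$divergence >= 1))
    stop_cfg("divergence must be in [0, 1)")
  if (cfg$missing_rate < 0 || cfg$missing_rate > 1)
    stop_cfg("missing_rate must be in [0, 1]")
  if (cfg$chrom_length_bp < cfg$n_sites)
    stop_cfg("chrom_length_bp too small for n_sites")
  class(cfg) <- "pop_sim_config"
  cfg
}

#' Simulate a structured diploid SNP panel
#'
#' Founder allele frequencies p are drawn from the configured uniform law;
#' subpopulation k gets site frequencies from
#' Beta(p (1-F_k)/F_k, (1-p)(1-F_k)/F_k) with F_k the drift parameter
#' (F_k = 0 keeps the founder frequency exactly), and diploid genotypes are
#' Binomial(2, p_k) dosages. Sites are placed at sorted uniform positions
#' on each chromosome. Deterministic given `cfg$seed`.
#'
#' @param cfg a [pop_sim_config()].
#' @return list with `geno` (a [genotype_matrix()]) and `meta`
#'   (accession metadata with `horticultural_type` = subpopulation label,
#'   wild assigned last when present, and a `priority` flag).
#' @export
simulate_structured_population <- function(cfg) {
  stopifnot(inherits(cfg, "pop_sim_config"))
  with_seed(cfg$seed, {
    K <- cfg$n_subpops
    Fk <- rep(cfg$divergence, length.out = K)
    m <- cfg$n_sites
    n <- K * cfg$n_per_subpop
    per_chr <- diff(floor(seq(0, m, length.out = cfg$n_chromosomes + 1)))
    chrom <- rep(as.character(seq_len(cfg$n_chromosomes)), per_chr)
    pos <- unlist(lapply(per_chr, function(k)
      sort(sample.int(cfg$chrom_length_bp, k))), use.names = FALSE)
    p0 <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
    dosage <- matrix(NA_real_, n, m)
    labels <- character(n)
    type_pool <- c(setdiff(horticultural_types, "wild"), "wild")
    types <- type_pool[c(seq_len(max(0, K - 1)), length(type_pool))[seq_len(K)]]
    if (K == 1) types <- type_pool[1]
    for (k in seq_len(K)) {
      rows <- (k - 1) * cfg$n_per_subpop + seq_len(cfg$n_per_subpop)
      labels[rows] <- types[k]
      pk <- if (Fk[k] == 0) p0 else
        stats::rbeta(m, p0 * (1 - Fk[k]) / Fk[k],
                     (1 - p0) * (1 - Fk[k]) / Fk[k])
      dosage[rows, ] <- matrix(
        stats::rbinom(length(rows) * m, 2, rep(pk, each = length(rows))),
        nrow = length(rows))
    }
    if (cfg$missing_rate > 0) {
      miss <- stats::runif(length(dosage)) < cfg$missing_rate
      dosage[miss] <- NA_real_
    }
    ids <- sprintf("%s%03d", substr(labels, 1, 3),
                   stats::ave(seq_len(n), labels, FUN = seq_along))
    rownames(dosage) <- ids
    geno <- genotype_matrix(dosage, chrom, pos, accession_ids = ids,
                            chrom_lengths = stats::setNames(
                              rep(cfg$chrom_length_bp, cfg$n_chromosomes),
                              as.character(seq_len(cfg$n_chromosomes))))
    priority <- rep(FALSE, n)
    if (cfg$n_priority > 0)
      priority[seq(1, n, length.out = min(cfg$n_priority, n))] <- TRUE
    meta <- data.frame(accession_id = ids, horticultural_type = labels,
                       country = "synthetic", priority = priority,
                       stringsAsFactors = FALSE)
    list(geno = geno, meta = meta)
  })
}

#' Simulate a panel with exponentially decaying linkage disequilibrium
#'
#' Haplotypes are mosaics of two ancestral haplotypes, switching ancestry
#' along the chromosome as a symmetric two-state Markov process with switch
#' rate 1/(2 * decay_bp) per bp. The allelic correlation between two sites
#' separated by d bp is then exp(-d / decay_bp) and the expected r^2 is
#' exp(-2 d / decay_bp), so the analytic half-decay distance of r^2 is
#' decay_bp * ln(2) / 2 — a known truth for validating LD-decay estimators.
#'
#' @param n_haplotypes number of haplotypes (2 per diploid accession; must
#'   be even).
#' @param n_sites sites per chromosome.
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length_bp chromosome length.
#' @param decay_bp correlation length in bp.
#' @param seed integer seed.
#' @return a [genotype_matrix()] of `n_haplotypes / 2` accessions.
#' @export
simulate_ld_population <- function(n_haplotypes = 100, n_sites = 300,
                                   n_chromosomes = 1,
                                   chrom_length_bp = 2e6,
                                   decay_bp = 2e5, seed = 1) {
  stopifnot(n_haplotypes %% 2 == 0, n_haplotypes >= 4, n_sites >= 2)
  with_seed(seed, {
    n_acc <- n_haplotypes / 2
    chrom <- character(0); pos <- integer(0)
    dosage <- NULL
    for (ch in seq_len(n_chromosomes)) {
      p <- sort(sample.int(chrom_length_bp, n_sites))
      gaps <- diff(p)
      hap <- matrix(0L, n_haplotypes, n_sites)
      state <- stats::rbinom(n_haplotypes, 1, 0.5)
      hap[, 1] <- state
      for (s in seq_len(n_sites - 1)) {
        # switch probability so that corr(d) = exp(-d / decay_bp)
        pr_switch <- (1 - exp(-gaps[s] / decay_bp)) / 2
        flip <- stats::runif(n_haplotypes) < pr_switch
        state <- ifelse(flip, 1L - state, state)
        hap[, s + 1] <- state
      }
      dos <- hap[seq(1, n_haplotypes, 2), ] + hap[seq(2, n_haplotypes, 2), ]
      dosage <- cbind(dosage, dos)
      chrom <- c(chrom, rep(as.character(ch), n_sites))
      pos <- c(pos, p)
    }
    genotype_matrix(dosage, chrom, pos,
                    accession_ids = sprintf("acc%03d", seq_len(n_acc)),
                    chrom_lengths = stats::setNames(
                      rep(chrom_length_bp, n_chromosomes),
                      as.character(seq_len(n_chromosomes))))
  })
}
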