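#' Configuration for the biparental selfing-cross simulator
#'
#' Emulates the development of an inbred line from a biparental cross: an
#' F1 followed by successive generations of self-pollination with single
#' seed descent, as used when pyramiding QTL alleles from two parents.
#' Crossovers per chromosome per meiosis are Poisson with positions
#' uniform along the chromosome.
#'
#' @param n_progeny number of independent progeny lines.
#' @param n_selfing_generations selfing generations after the F1
#'   (5 gives an F6-genotype "F5-derived" line with expected residual
#'   heterozygosity (1/2)^5 per informative site).
#' @param crossovers_per_chrom_mean Poisson mean crossover count.
#' @param seed integer seed.
#' @return a list of class `cross_sim_config`.
#' @export
cross_sim_config <- function(n_progeny = 1, n_selfing_generations = 5,
                             crossovers_per_chrom_mean = 1.5, seed = 1) {
  if (n_progeny < 1 || n_selfing_generations < 0)
    stop_cfg("counts must be >= 1 (selfing generations >= 0)")
  if (crossovers_per_chrom_mean < 0)
    stop_cfg("crossover mean must be >= 0")
  structure(list(n_progeny = as.integer(n_progeny),
                 n_selfing_generations = as.integer(n_selfing_generations),
                 crossovers_per_chrom_mean = crossovers_per_chrom_mean,
                 seed = as.integer(seed)),
            class = "cross_sim_config")
}

# A homolog is, per chromosome, a data.frame(start, end, origin) of
# founder-origin segments (origin 1 = parent 1 haplotype, 2 = parent 2),
# tiling [1, chrom_len].
new_homolog <- function(chrom_lengths, origin) {
  lapply(chrom_lengths, function(L)
    data.frame(start = 1, end = L, origin = origin))
}

# Recombine two homologs of one individual into a gamete.
make_gamete <- function(hom1, hom2, chrom_lengths, xo_mean) {
  out <- vector("list", length(chrom_lengths))
  names(out) <- names(chrom_lengths)
  for (ci in seq_along(chrom_lengths)) {
    L <- chrom_lengths[ci]
    n_xo <- stats::rpois(1, xo_mean)
    bp <- if (n_xo > 0) sort(stats::runif(n_xo, 1, L)) else numeric(0)
    cur <- sample(1:2, 1)  # which homolog the gamete starts on
    bounds <- c(1, bp, L)
    segs <- list()
    for (s in seq_len(length(bounds) - 1)) {
      src <- if (cur == 1) hom1[[ci]] else hom2[[ci]]
      lo <- bounds[s]; hi <- bounds[s + 1]
      ov <- src[src$end >= lo & src$start <= hi, , drop = FALSE]
      ov$start <- pmax(ov$start, lo); ov$end <- pmin(ov$end, hi)
      segs[[s]] <- ov
      cur <- 3 - cur
    }
    seg <- do.call(rbind, segs)
    # merge adjacent same-origin segments
    if (nrow(seg) > 1) {
      keep <- c(TRUE, seg$origin[-1] != seg$origin[-nrow(seg)])
      grp <- cumsum(keep)
      seg <- data.frame(start = tapply(seg$start, grp, min),
                        end = tapply(seg$end, grp, max),
                        origin = seg$origin[keep])
    }
    rownames(seg) <- NULL
    out[[ci]] <- seg
  }
  out
}

origin_at_sites <- function(homolog, chrom, pos) {
  ori <- integer(length(pos))
  for (ci in names(homolog)) {
    sel <- which(chrom == ci)
    if (!length(sel)) next
    seg <- homolog[[ci]]
    j <- findInterval(pos[sel], seg$start)
    ori[sel] <- seg$origin[j]
  }
  ori
}

#' Simulate progeny of a biparental cross with repeated selfing
#'
#' Both parents must be inbred (homozygous) rows of the same site space;
#' sites where either parent is heterozygous or missing are carried through
#' with `NA` dosage in the progeny. Each progeny line descends from the F1
#' by `n_selfing_generations` rounds of selfing (single seed descent), with
#' Poisson crossovers per chromosome per meiosis. The true parental-origin
#' mosaic of both homologs is returned alongside the genotypes.
#'
#' @param p1,p2 single-accession [genotype_matrix()] objects (or one row
#'   each of a shared matrix, via [subset_geno()]).
#' @param cfg a [cross_sim_config()].
#' @return list with `geno` (progeny `genotype_matrix`) and `truth`, a list
#'   per progeny of two homolog segment lists (`hom1`, `hom2`).
#' @export
simulate_biparental_cross <- function(p1, p2, cfg) {
  stopifnot(inherits(cfg, "cross_sim_config"))
  if (!identical(p1$pos, p2$pos) || !identical(p1$chrom, p2$chrom))
    stop_cfg("parents must share the same site space")
  d1 <- p1$dosage[1, ]; d2 <- p2$dosage[1, ]
  hom_ok <- !is.na(d1) & !is.na(d2) & d1 %in% c(0, 2) & d2 %in% c(0, 2)
  informative <- hom_ok & d1 != d2
  if (!any(informative))
    stop_cfg("parents share no informative (homozygous-divergent) sites")
  chrom_lengths <- p1$chrom_lengths
  a1 <- d1 / 2  # founder haplotype allele (0/1) of parent 1
  a2 <- d2 / 2
  with_seed(cfg$seed, {
    truth <- vector("list", cfg$n_progeny)
    dosage <- matrix(NA_real_, cfg$n_progeny, length(d1))
    for (i in seq_len(cfg$n_progeny)) {
      hom1 <- new_homolog(chrom_lengths, 1L)
      hom2 <- new_homolog(chrom_lengths, 2L)
      for (gen in seq_len(cfg$n_selfing_generations)) {
        g1 <- make_gamete(hom1, hom2, chrom_lengths,
                          cfg$crossovers_per_chrom_mean)
        g2 <- make_gamete(hom1, hom2, chrom_lengths,
                          cfg$crossovers_per_chrom_mean)
        hom1 <- g1; hom2 <- g2
      }
      o1 <- origin_at_sites(hom1, p1$chrom, p1$pos)
      o2 <- origin_at_sites(hom2, p1$chrom, p1$pos)
      al1 <- ifelse(o1 == 1L, a1, a2)
      al2 <- ifelse(o2 == 1L, a1, a2)
      dos <- al1 + al2
      dos[!hom_ok] <- NA_real_
      dosage[i, ] <- dos
      truth[[i]] <- list(hom1 = hom1, hom2 = hom2)
    }
    ids <- sprintf("progeny%03d", seq_len(cfg$n_progeny))
    rownames(dosage) <- ids
    geno <- genotype_matrix(dosage, p1$chrom, p1$pos, p1$ref, p1$alt,
                            accession_ids = ids,
                            chrom_lengths = chrom_lengths)
    names(truth) <- ids
    list(geno = geno, truth = truth,
         informative = which(informative))
  })
}

# True origin class per site for one progeny: "P1", "P2" or "HET".
truth_site_classes <- function(truth_one, chrom, pos) {
  o1 <- origin_at_sites(truth_one$hom1, chrom, pos)
  o2 <- origin_at_sites(truth_one$hom2, chrom, pos)
  ifelse(o1 == o2, ifelse(o1 == 1L, "P1", "P2"), "HET")
}
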