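# Small deterministic fixtures shared across test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Tiny genotype matrix from a plain dosage matrix; positions restart at
# 1000 per chromosome in 1000-bp steps.
tiny_geno <- function(dosage, chrom_len = NULL, chrom = NULL) {
  dosage <- as.matrix(dosage)
  m <- ncol(dosage)
  chrom <- chrom %||% rep("1", m)
  pos <- integer(m)
  for (ch in unique(chrom))
    pos[chrom == ch] <- seq_len(sum(chrom == ch)) * 1000L
  cl <- NULL
  if (!is.null(chrom_len))
    cl <- stats::setNames(rep(chrom_len, length(unique(chrom))),
                          unique(chrom))
  genotype_matrix(dosage, chrom, pos, chrom_lengths = cl)
}

# Homozygous-divergent parent pair over m sites at sorted uniform
# positions on n_chrom chromosomes of length len.
parent_pair <- function(m, len = 5e7, n_chrom = 1, seed = 1) {
  set.seed(seed)
  per <- diff(floor(seq(0, m, length.out = n_chrom + 1)))
  chrom <- rep(as.character(seq_len(n_chrom)), per)
  pos <- unlist(lapply(per, function(k) sort(sample.int(len, k))))
  d <- rbind(P1 = rep(0, m), P2 = rep(2, m))
  genotype_matrix(d, chrom, pos,
                  chrom_lengths = stats::setNames(
                    rep(len, n_chrom), as.character(seq_len(n_chrom))))
}

# Random small panel for oracle comparisons.
random_panel <- function(n, m, miss = 0, seed = 1) {
  set.seed(seed)
  p <- runif(m, 0.1, 0.9)
  d <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
  if (miss > 0) d[runif(n * m) < miss] <- NA
  tiny_geno(d)
}

# Brute-force per-site pi: mean pairwise allele differences over all
# C(2n, 2) pairs of called alleles, enumerated explicitly.
oracle_site_pi <- function(dos) {
  dos <- dos[!is.na(dos)]
  alleles <- unlist(lapply(dos, function(d) c(rep(1, d), rep(0, 2 - d))))
  n <- length(alleles)
  if (n < 2) return(NA_real_)
  diffs <- 0; pairs <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    diffs <- diffs + (alleles[i] != alleles[j])
    pairs <- pairs + 1
  }
  diffs / pairs
}

# Scalar Weir-Cockerham (1984) components for one site and two groups,
# written out term by term as an independent check.
oracle_wc_site <- function(dA, dB) {
  dA <- dA[!is.na(dA)]; dB <- dB[!is.na(dB)]
  n1 <- length(dA); n2 <- length(dB)
  if (n1 < 1 || n2 < 1) return(c(a = NA, abc = NA))
  p1 <- sum(dA) / (2 * n1); p2 <- sum(dB) / (2 * n2)
  h1 <- mean(dA == 1); h2 <- mean(dB == 1)
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, abc = a + b + cc)
}

# Exhaustive gap-partition clumping oracle: split significant positions at
# gaps > gap_bp, keep groups with >= min_snps members.
oracle_clump <- function(pos, neglog, gap_bp, min_snps) {
  ord <- order(pos)
  pos <- pos[ord]; neglog <- neglog[ord]
  if (!length(pos)) return(list())
  grp <- cumsum(c(1, diff(pos) > gap_bp))
  out <- list()
  for (g in unique(grp)) {
    sel <- grp == g
    if (sum(sel) < min_snps) next
    p <- pos[sel]; nl <- neglog[sel]
    lead_idx <- which(nl == max(nl))
    lead <- p[lead_idx[which.min(p[lead_idx])]]
    out[[length(out) + 1]] <- list(start = min(p), end = max(p),
                                   lead = lead, n = sum(sel))
  }
  out
}
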