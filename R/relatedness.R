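#' Genomic relationship matrix
#'
#' VanRaden-style GRM on standardized dosages:
#' A_jk = (1/M) * sum_i (x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i)),
#' with p_i the alternate-allele frequency from non-missing calls. Missing
#' dosages are mean-imputed per site (so they contribute zero after
#' centring); monomorphic sites are excluded.
#'
#' @param geno a [genotype_matrix()].
#' @return symmetric n x n matrix with accession ids as dimnames.
#' @export
grm <- function(geno) {
  if (n_accessions(geno) < 2) stop_cfg("need >= 2 accessions")
  d <- geno$dosage
  called <- colSums(!is.na(d))
  p <- colSums(d, na.rm = TRUE) / (2 * called)
  keep <- called > 0 & p > 0 & p < 1
  d <- d[, keep, drop = FALSE]; p <- p[keep]
  M <- ncol(d)
  if (M == 0) stop_cfg("no polymorphic sites")
  z <- sweep(d, 2, 2 * p)
  z[is.na(z)] <- 0
  z <- sweep(z, 2, sqrt(2 * p * (1 - p)), "/")
  A <- tcrossprod(z) / M
  dimnames(A) <- list(geno$accession_ids, geno$accession_ids)
  A
}

#' Principal components of the genomic relationship matrix
#'
#' Top-k eigenpairs of [grm()], eigenvalues in non-increasing order — the
#' PCs used as stratification covariates in association scans and for
#' population-structure plots.
#'
#' @param geno a [genotype_matrix()].
#' @param k number of components (< number of accessions).
#' @return list with `values` (length k), `vectors` (n x k, accession ids
#'   as rownames) and `var_explained` (fractions of total variance).
#' @export
pca_grm <- function(geno, k = 3) {
  n <- n_accessions(geno)
  if (k > n) stop_cfg("k must not exceed the number of accessions")
  A <- grm(geno)
  e <- eigen(A, symmetric = TRUE)
  pos <- pmax(e$values, 0)
  list(values = e$values[seq_len(k)],
       vectors = structure(e$vectors[, seq_len(k), drop = FALSE],
                           dimnames = list(geno$accession_ids, NULL)),
       var_explained = pos[seq_len(k)] / sum(pos))
}

#' Identity-by-state distance matrix
#'
#' IBS between two accessions is the mean over pairwise-complete sites of
#' (2 - |d_j - d_k|) / 2; the distance is 1 - IBS. Identical genotypes
#' give distance 0, opposite homozygotes distance 1.
#'
#' @param geno a [genotype_matrix()].
#' @return symmetric distance matrix with zero diagonal.
#' @export
ibs_distance <- function(geno) {
  d <- geno$dosage
  n <- nrow(d)
  D <- matrix(0, n, n, dimnames = list(rownames(d), rownames(d)))
  for (j in seq_len(n - 1)) {
    for (k in (j + 1):n) {
      ok <- !is.na(d[j, ]) & !is.na(d[k, ])
      ibs <- if (any(ok)) mean((2 - abs(d[j, ok] - d[k, ok])) / 2)
             else NA_real_
      D[j, k] <- D[k, j] <- 1 - ibs
    }
  }
  D
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei neighbour joining (via \pkg{ape}); negative branch lengths —
#' an artifact of the agglomeration on noisy distances — are clamped to
#' zero with the deficit transferred to the sibling edge, the usual
#' post-processing convention.
#'
#' @param dist symmetric distance matrix with labelled rows/columns, or a
#'   `dist` object; at least 3 taxa.
#' @return a Newick string (also invisibly returns the `phylo` object as
#'   attribute `"phylo"`).
#' @export
nj_tree <- function(dist) {
  D <- as.matrix(dist)
  if (nrow(D) < 3) stop_cfg("neighbour joining needs >= 3 taxa")
  tr <- ape::nj(as.dist(D))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1]
    sibs <- which(tr$edge[, 1] == parent & seq_along(tr$edge[, 2]) != e)
    deficit <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    if (length(sibs))
      tr$edge.length[sibs[1]] <- tr$edge.length[sibs[1]] + deficit
  }
  nwk <- ape::write.tree(tr)
  attr(nwk, "phylo") <- tr
  nwk
}
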