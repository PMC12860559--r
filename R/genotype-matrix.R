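#' Genotype matrix container
#'
#' A `genotype_matrix` holds diploid biallelic genotypes as alternate-allele
#' dosages (0, 1, 2, or `NA` for missing) for a set of accessions, together
#' with per-site chromosome, position and REF/ALT alleles. Sites are kept
#' sorted by (chromosome, position) with unique positions per chromosome.
#'
#' @param dosage numeric matrix, accessions x sites, values in {0,1,2,NA}.
#' @param chrom character vector of per-site chromosome labels.
#' @param pos integer vector of per-site 1-based positions (bp).
#' @param ref,alt per-site alleles; defaults "A"/"T" when unknown.
#' @param accession_ids accession identifiers (unique); defaults from
#'   `rownames(dosage)` or `acc1..accN`.
#' @param chrom_lengths optional named vector of chromosome lengths in bp;
#'   when absent, the maximum observed position per chromosome is used.
#'
#' @return an object of class `genotype_matrix` with fields
#'   `accession_ids`, `chrom`, `pos`, `ref`, `alt`, `dosage`,
#'   `chrom_lengths`.
#' @export
genotype_matrix <- function(dosage, chrom, pos, ref = NULL, alt = NULL,
                            accession_ids = NULL, chrom_lengths = NULL) {
  dosage <- as.matrix(dosage)
  m <- ncol(dosage)
  if (length(chrom) != m || length(pos) != m)
    stop_cfg("chrom/pos length must equal the number of sites")
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  ref <- ref %||% rep("A", m)
  alt <- alt %||% rep("T", m)
  accession_ids <- accession_ids %||% rownames(dosage) %||%
    sprintf("acc%03d", seq_len(nrow(dosage)))
  if (anyDuplicated(accession_ids))
    stop_cfg("accession ids must be unique")
  bad <- !(dosage %in% c(0, 1, 2) | is.na(dosage))
  if (any(bad)) stop_cfg("dosage values must be 0, 1, 2 or NA")
  ord <- order(chrom, pos)
  if (any(ord != seq_len(m))) {
    chrom <- chrom[ord]; pos <- pos[ord]
    ref <- ref[ord]; alt <- alt[ord]
    dosage <- dosage[, ord, drop = FALSE]
  }
  if (anyDuplicated(paste(chrom, pos)))
    stop_cfg("positions must be unique within a chromosome")
  rownames(dosage) <- accession_ids
  if (m > 0) colnames(dosage) <- paste0(chrom, ":", pos)
  if (is.null(chrom_lengths) && m > 0) {
    chrom_lengths <- tapply(pos, chrom, max)
    chrom_lengths <- stats::setNames(as.numeric(chrom_lengths),
                                     names(chrom_lengths))
  }
  structure(list(accession_ids = accession_ids, chrom = chrom, pos = pos,
                 ref = as.character(ref), alt = as.character(alt),
                 dosage = dosage, chrom_lengths = chrom_lengths),
            class = "genotype_matrix")
}

#' @exportS3Method base::print
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d accessions x %d sites on %d chromosome(s)\n",
              length(x$accession_ids), length(x$pos),
              length(unique(x$chrom))))
  cat(sprintf("  missing: %.2f%%\n", 100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

n_sites <- function(geno) length(geno$pos)
n_accessions <- function(geno) length(geno$accession_ids)

#' Subset a genotype matrix by accessions and/or sites
#'
#' @param geno a [genotype_matrix()].
#' @param accessions accession ids or indices (optional).
#' @param sites site indices (optional).
#' @return a `genotype_matrix`.
#' @export
subset_geno <- function(geno, accessions = NULL, sites = NULL) {
  d <- geno$dosage
  if (!is.null(accessions)) {
    if (is.character(accessions)) {
      missing_ids <- setdiff(accessions, geno$accession_ids)
      if (length(missing_ids))
        stop_cfg("unknown accession id(s): ",
                 paste(missing_ids, collapse = ", "))
    }
    d <- d[accessions, , drop = FALSE]
  }
  sites <- sites %||% seq_len(ncol(d))
  genotype_matrix(d[, sites, drop = FALSE], geno$chrom[sites],
                  geno$pos[sites], geno$ref[sites], geno$alt[sites],
                  accession_ids = rownames(d),
                  chrom_lengths = geno$chrom_lengths)
}

# Per-site minor allele frequency from non-missing calls.
site_maf <- function(geno) {
  d <- geno$dosage
  called <- colSums(!is.na(d))
  p <- colSums(d, na.rm = TRUE) / (2 * called)
  p[called == 0] <- NA_real_
  pmin(p, 1 - p)
}

site_missing_rate <- function(geno) colMeans(is.na(geno$dosage))
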