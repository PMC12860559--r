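#' Read a VCF file into a genotype matrix
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}) and returns the diploid dosage
#' matrix. Multiallelic records are skipped with a message giving the count;
#' phased (`|`) and unphased (`/`) genotypes are treated identically; missing
#' genotypes (`./.` or `.`) become `NA`. Contig lengths are taken from
#' `##contig` header lines when present.
#'
#' @param path path to a VCF file.
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop_cfg("no such file: ", path)
  if (file.size(path) == 0) stop_cfg("empty VCF file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi))
    message(sum(multi), " multiallelic record(s) skipped")
  keep <- !multi
  if (!any(keep)) stop_cfg("no biallelic records in ", path)
  gt <- v@gt[keep, -1, drop = FALSE]
  samples <- colnames(gt)
  # strip any extra FORMAT fields, keep GT
  gt_only <- sub(":.*$", "", gt)
  allele1 <- substr(gt_only, 1, 1)
  allele2 <- substr(gt_only, 3, 3)
  to_num <- function(a) {
    out <- suppressWarnings(as.numeric(a))
    out
  }
  dos <- to_num(allele1) + to_num(allele2)
  # haploid-style single-allele calls ("." or "0"): treat bare "." as missing
  dos[gt_only == "." | gt_only == "./." | gt_only == ".|."] <- NA
  dosage <- t(matrix(dos, nrow = sum(keep),
                     dimnames = list(NULL, samples)))
  chrom_lengths <- NULL
  meta <- v@meta
  contig <- meta[grepl("^##contig=", meta)]
  if (length(contig)) {
    ids <- sub('.*ID=([^,>]+).*', '\\1', contig)
    lens <- suppressWarnings(as.numeric(sub('.*length=([0-9]+).*', '\\1',
                                            contig)))
    ok <- !is.na(lens)
    if (any(ok)) chrom_lengths <- stats::setNames(lens[ok], ids[ok])
  }
  genotype_matrix(dosage,
                  chrom = fix[keep, "CHROM"],
                  pos = as.integer(fix[keep, "POS"]),
                  ref = fix[keep, "REF"], alt = alt[keep],
                  accession_ids = samples,
                  chrom_lengths = chrom_lengths)
}

#' Write a genotype matrix as a minimal VCF 4.2 file
#'
#' Emits a GT-only, unphased VCF with `##contig` lines carrying chromosome
#' lengths, so that `read_vcf(write_vcf(g))` round-trips chrom, pos, ref,
#' alt and dosages exactly.
#'
#' @param geno a [genotype_matrix()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_vcf <- function(geno, path) {
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop_cfg("cannot write to ", path)
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>",
                       names(geno$chrom_lengths),
                       as.integer(geno$chrom_lengths)),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", geno$accession_ids),
                     collapse = "\t")), con)
  if (n_sites(geno) == 0) return(invisible(path))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  d <- geno$dosage
  gt <- matrix("./.", nrow = nrow(d), ncol = ncol(d))
  ok <- !is.na(d)
  gt[ok] <- gt_code[as.character(d[ok])]
  lines <- paste(geno$chrom, geno$pos, ".", geno$ref, geno$alt, ".",
                 "PASS", ".", "GT",
                 apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read or write accession metadata
#'
#' Metadata tables carry one row per accession with its horticultural type,
#' country of origin and a breeding-priority flag used to seed core
#' selection.
#'
#' @param path TSV file with columns `accession_id`, `horticultural_type`,
#'   `country`, `priority`.
#' @return data.frame.
#' @export
read_accession_meta <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_accession_meta(meta)
}

#' @rdname read_accession_meta
#' @param meta metadata data.frame.
#' @export
write_accession_meta <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

horticultural_types <- c("butterhead", "crisphead", "looseleaf", "oilseed",
                         "romaine", "stem", "wild", "youmaicai")

validate_accession_meta <- function(meta) {
  need <- c("accession_id", "horticultural_type", "country", "priority")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop_cfg("metadata lacks column(s): ",
                             paste(miss, collapse = ", "))
  if (anyDuplicated(meta$accession_id))
    stop_cfg("duplicate accession ids in metadata")
  bad <- setdiff(unique(meta$horticultural_type), horticultural_types)
  if (length(bad)) stop_cfg("unknown horticultural type(s): ",
                            paste(bad, collapse = ", "))
  meta$priority <- as.logical(meta$priority)
  meta
}
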