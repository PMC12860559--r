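#' Parent-informative SNP set
#'
#' Retains sites where both parents are homozygous, non-missing and carry
#' different alleles — the only sites at which the parental origin of a
#' progeny genotype is decodable.
#'
#' @param p1,p2 numeric dosage vectors over a shared site space (one row
#'   of a [genotype_matrix()]), or single-accession `genotype_matrix`
#'   objects.
#' @return list of class `informative_sites` with `sites` (indices),
#'   `p1_dosage` and `p2_dosage` (0 or 2 at each retained site).
#' @export
informative_sites <- function(p1, p2) {
  d1 <- if (inherits(p1, "genotype_matrix")) p1$dosage[1, ] else p1
  d2 <- if (inherits(p2, "genotype_matrix")) p2$dosage[1, ] else p2
  if (length(d1) != length(d2))
    stop_cfg("parents must share the site index space")
  keep <- !is.na(d1) & !is.na(d2) & d1 %in% c(0, 2) & d2 %in% c(0, 2) &
    d1 != d2
  if (!any(keep)) stop_cfg("no informative sites between these parents")
  structure(list(sites = which(keep), p1_dosage = d1[keep],
                 p2_dosage = d2[keep]),
            class = "informative_sites")
}

#' Classify progeny genotypes by parental origin
#'
#' At each informative site the progeny call is `P1` when it matches
#' parent 1's homozygous dosage, `P2` for parent 2's, `HET` for a
#' heterozygote, and `MISSING` otherwise (uncalled, or a dosage impossible
#' under the biparental cross — the latter are counted and reported via
#' attribute `"n_impossible"`).
#'
#' @param progeny numeric dosage vector over the full site space (or a
#'   single-accession [genotype_matrix()]).
#' @param sites an [informative_sites()] set.
#' @return character vector of classes, one per informative site.
#' @export
classify_progeny <- function(progeny, sites) {
  d <- if (inherits(progeny, "genotype_matrix")) progeny$dosage[1, ]
       else progeny
  if (!length(sites$sites)) stop_cfg("empty informative site set")
  x <- d[sites$sites]
  cls <- rep("MISSING", length(x))
  cls[!is.na(x) & x == sites$p1_dosage] <- "P1"
  cls[!is.na(x) & x == sites$p2_dosage] <- "P2"
  cls[!is.na(x) & x == 1] <- "HET"
  n_imp <- sum(!is.na(x) & !(x %in% c(0, 1, 2)))
  attr(cls, "n_impossible") <- n_imp
  cls
}

#' Majority-vote bin map of parental origin
#'
#' Classified informative sites are grouped into nonoverlapping bins of
#' `bin_bp` (default 1 Mb) anchored at position 1 along each chromosome
#' (the last bin may be short). Within a bin the P1 / P2 / HET calls are
#' tallied (MISSING excluded) and the majority class becomes the bin call;
#' empty bins are `MISSING` and exact ties `AMBIGUOUS`.
#'
#' @param geno a [genotype_matrix()] providing chrom/pos and lengths.
#' @param classes per-informative-site classes from [classify_progeny()].
#' @param sites the matching [informative_sites()] set.
#' @param bin_bp bin width in bp (> 0).
#' @return data.frame of class `bin_map`: `chrom`, `bin_start`, `bin_end`,
#'   `n_p1`, `n_p2`, `n_het`, `call`.
#' @export
bin_genotypes <- function(geno, classes, sites, bin_bp = 1e6) {
  if (bin_bp <= 0) stop_cfg("bin_bp must be > 0")
  chrom <- geno$chrom[sites$sites]
  pos <- geno$pos[sites$sites]
  ord <- order(chrom, pos)
  chrom <- chrom[ord]; pos <- pos[ord]; classes <- classes[ord]
  out <- list()
  for (ch in names(geno$chrom_lengths)) {
    len <- geno$chrom_lengths[[ch]]
    starts <- seq.int(1, len, by = bin_bp)
    ends <- pmin(starts + bin_bp - 1, len)
    sel <- chrom == ch
    b <- findInterval(pos[sel], starts)
    tab <- function(lbl) tabulate(b[classes[sel] == lbl],
                                  nbins = length(starts))
    n1 <- tab("P1"); n2 <- tab("P2"); nh <- tab("HET")
    call <- character(length(starts))
    for (w in seq_along(starts)) {
      cnt <- c(P1 = n1[w], P2 = n2[w], HET = nh[w])
      if (sum(cnt) == 0) { call[w] <- "MISSING"; next }
      top <- which(cnt == max(cnt))
      call[w] <- if (length(top) > 1) "AMBIGUOUS" else names(top)
    }
    out[[ch]] <- data.frame(chrom = ch, bin_start = starts,
                            bin_end = ends, n_p1 = n1, n_p2 = n2,
                            n_het = nh, call = call)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("bin_map", "data.frame")
  res
}

#' Breakpoints between parental-origin segments of a bin map
#'
#' A breakpoint is emitted at each boundary between consecutive called
#' (non-MISSING, non-AMBIGUOUS) bins with different calls; runs of
#' MISSING/AMBIGUOUS bins are skipped, with the breakpoint placed between
#' the flanking called bins and the skipped span reported.
#'
#' @param binmap a [bin_genotypes()] result.
#' @return data.frame with `chrom`, `boundary_bp` (midpoint between the
#'   flanking called bins), `from_call`, `to_call`, `skipped_bp`.
#' @export
detect_breakpoints <- function(binmap) {
  out <- list()
  for (ch in unique(binmap$chrom)) {
    bm <- binmap[binmap$chrom == ch, , drop = FALSE]
    called <- which(!(bm$call %in% c("MISSING", "AMBIGUOUS")))
    if (length(called) < 2) next
    for (k in seq_len(length(called) - 1)) {
      i <- called[k]; j <- called[k + 1]
      if (bm$call[i] == bm$call[j]) next
      out[[length(out) + 1]] <- data.frame(
        chrom = ch,
        boundary_bp = (bm$bin_end[i] + bm$bin_start[j]) / 2,
        from_call = bm$call[i], to_call = bm$call[j],
        skipped_bp = bm$bin_start[j] - bm$bin_end[i] - 1)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), boundary_bp = numeric(0),
                      from_call = character(0), to_call = character(0),
                      skipped_bp = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fingerprint a progeny line against its two parents
#'
#' Convenience wrapper running [informative_sites()],
#' [classify_progeny()], [bin_genotypes()] and [detect_breakpoints()] on
#' three samples of one genotype matrix.
#'
#' @param geno a [genotype_matrix()] holding all three samples.
#' @param p1,p2,progeny accession ids of parent 1, parent 2 and the
#'   progeny line.
#' @param bin_bp bin width in bp.
#' @return list with `sites`, `classes`, `binmap`, `breakpoints`.
#' @export
fingerprint_map <- function(geno, p1, p2, progeny, bin_bp = 1e6) {
  ids <- geno$accession_ids
  for (s in c(p1, p2, progeny))
    if (!s %in% ids) stop_cfg("sample not in panel: ", s)
  sites <- informative_sites(geno$dosage[p1, ], geno$dosage[p2, ])
  classes <- classify_progeny(geno$dosage[progeny, ], sites)
  binmap <- bin_genotypes(geno, classes, sites, bin_bp)
  list(sites = sites, classes = classes, binmap = binmap,
       breakpoints = detect_breakpoints(binmap))
}
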