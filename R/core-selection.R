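#' Allele-state coverage of a subset of accessions
#'
#' Coverage is counted on per-site dosage states: for each site, the
#' distinct non-missing dosage values {0, 1, 2} present in the full panel
#' define the states to be captured; the score of a subset is the fraction
#' of those (site, state) pairs also observed within the subset. Selecting
#' every accession therefore scores 1, and a single accession
#' heterozygous everywhere scores 1/3 of sites segregating all three
#' states.
#'
#' @param selected_ids accession ids of the candidate subset.
#' @param geno the full-panel [genotype_matrix()].
#' @return coverage fraction in [0, 1].
#' @export
coverage_score <- function(selected_ids, geno) {
  unknown <- setdiff(selected_ids, geno$accession_ids)
  if (length(unknown))
    stop_cfg("unknown accession id(s): ", paste(unknown, collapse = ", "))
  inc <- state_incidence(geno)
  total <- sum(inc$state_present)
  if (total == 0) return(1)
  sel <- match(selected_ids, geno$accession_ids)
  if (!length(sel)) return(0)
  covered <- colSums(inc$acc_state[sel, , drop = FALSE]) > 0
  sum(covered & inc$state_present) / total
}

# Incidence structures shared by coverage_score and greedy_core_select:
# acc_state is an accessions x (3 * n_sites) 0/1 matrix marking which
# dosage state each accession shows at each site; state_present flags the
# (site, state) columns realized in the full panel.
state_incidence <- function(geno) {
  d <- geno$dosage
  n <- nrow(d); m <- ncol(d)
  acc_state <- matrix(0, n, 3 * m)
  for (s in 0:2) acc_state[, 3 * seq_len(m) - 2 + s] <-
    (!is.na(d) & d == s) * 1
  state_present <- colSums(acc_state) > 0
  list(acc_state = acc_state, state_present = state_present)
}

#' Greedy core-collection selection by allele-state coverage
#'
#' Accessions flagged as breeding priorities are seeded first (in input
#' order), then the accession with the largest coverage gain is added
#' iteratively — ties broken by lexicographic accession id — until the
#' target coverage is reached, the marginal gain falls below `delta_min`,
#' or the panel is exhausted. `delta_min = 1e-4` corresponds to a 0.01%
#' minimum-gain stopping rule; `target_cov = 1` asks for full allelic
#' coverage.
#'
#' @param geno the full-panel [genotype_matrix()].
#' @param meta optional accession metadata with a logical `priority`
#'   column; `NULL` means no seeds.
#' @param delta_min minimum absolute coverage gain to continue.
#' @param target_cov stop once coverage reaches this fraction.
#' @return list of class `core_selection_result` with `selected_ids`
#'   (ordered), `coverage_curve` (coverage after each selection) and
#'   `stop_reason` (`"target_reached"`, `"delta_below_min"` or
#'   `"exhausted"`).
#' @export
greedy_core_select <- function(geno, meta = NULL, delta_min = 1e-4,
                               target_cov = 1.0) {
  if (n_accessions(geno) == 0 || n_sites(geno) == 0)
    stop_cfg("empty panel")
  if (delta_min < 0) stop_cfg("delta_min must be >= 0")
  if (target_cov <= 0 || target_cov > 1)
    stop_cfg("target_cov must be in (0, 1]")
  inc <- state_incidence(geno)
  M <- inc$acc_state
  uncovered <- inc$state_present  # logical over (site, state) columns
  total <- sum(uncovered)
  ids <- geno$accession_ids
  selected <- character(0)
  curve <- numeric(0)
  covered_n <- 0
  add_one <- function(i) {
    newly <- uncovered & (M[i, ] > 0)
    uncovered[newly] <<- FALSE
    covered_n <<- covered_n + sum(newly)
    selected <<- c(selected, ids[i])
    curve <<- c(curve, if (total == 0) 1 else covered_n / total)
  }
  seeds <- if (!is.null(meta))
    meta$accession_id[as.logical(meta$priority)] else character(0)
  for (id in intersect(seeds, ids)) add_one(match(id, ids))
  stop_reason <- "exhausted"
  while (length(selected) < length(ids)) {
    if (length(curve) && curve[length(curve)] >= target_cov) {
      stop_reason <- "target_reached"; break
    }
    remaining <- setdiff(seq_along(ids), match(selected, ids))
    gains <- as.vector(M[remaining, , drop = FALSE] %*% uncovered)
    best_gain <- max(gains)
    if (total > 0 && best_gain / total < delta_min && length(selected)) {
      stop_reason <- "delta_below_min"; break
    }
    cand <- remaining[gains == best_gain]
    add_one(cand[order(ids[cand])[1]])
  }
  if (length(curve) && curve[length(curve)] >= target_cov)
    stop_reason <- "target_reached"
  structure(list(selected_ids = selected, coverage_curve = curve,
                 stop_reason = stop_reason),
            class = "core_selection_result")
}

#' @exportS3Method base::print
print.core_selection_result <- function(x, ...) {
  cat(sprintf("core selection: %d accessions, final coverage %.4f (%s)\n",
              length(x$selected_ids),
              if (length(x$coverage_curve)) max(x$coverage_curve) else NA,
              x$stop_reason))
  invisible(x)
}

#' Write a core-selection result as TSV
#'
#' Columns: rank, accession_id, coverage_after.
#' @param result a `core_selection_result`.
#' @param path output path.
#' @export
write_core_selection <- function(result, path) {
  utils::write.table(
    data.frame(rank = seq_along(result$selected_ids),
               accession_id = result$selected_ids,
               coverage_after = result$coverage_curve),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
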