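# Internal helpers shared across modules.

#' Evaluate code under a fixed RNG seed, restoring global RNG state after
#'
#' All simulators route their randomness through this helper so that one
#' integer seed fully determines the output and the caller's RNG stream is
#' left untouched.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cfg <- function(...) stop(..., call. = FALSE)

# Half-open window grid anchored at 1 covering [1, chrom_len].
# Returns data.frame(start, end) in 1-based inclusive bp coordinates;
# the last window may be shorter than window_bp.
window_grid <- function(chrom_len, window_bp, step_bp) {
  starts <- seq.int(1L, max(1L, chrom_len), by = step_bp)
  starts <- starts[starts <= chrom_len]
  ends <- pmin(starts + window_bp - 1, chrom_len)
  data.frame(start = starts, end = ends)
}
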