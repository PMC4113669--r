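#' Run an expression under a fixed RNG seed, restoring RNG state afterwards
#'
#' Internal helper: every stochastic operation in the package routes its
#' randomness through this so that results are reproducible from a seed and
#' never disturb the caller's RNG stream.
#'
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return value of `expr`
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single non-missing number")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-stage seed from a global seed
#'
#' Splits one user-facing seed into independent per-stage seeds via a
#' documented multiplicative rule, so any pipeline stage can be rerun in
#' isolation and still match the full run. Results stay below 2^31.
#'
#' @param seed global integer seed
#' @param stage integer stage index (>= 1)
#' @return an integer seed
#' @export
stage_seed <- function(seed, stage) {
  s <- (as.double(seed) * 48271 + as.double(stage) * 16807) %% 2147483629
  as.integer(s) + 1L
}

# variance of the standard logistic distribution (residual variance of the
# liability model, scale parameter s = 1)
logistic_variance <- function() pi^2 / 3
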