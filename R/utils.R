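`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Runs \code{code} with the global random number generator seeded at
#' \code{seed}, then restores the previous RNG state so surrounding code is
#' unaffected. All stochastic stages of the pipeline (phantom generation,
#' training, token resampling, decoder dropout) route their randomness
#' through this helper, which is what makes whole-pipeline runs exactly
#' reproducible from a single experiment seed.
#'
#' @param seed integer seed, or \code{NULL} to run unseeded.
#' @param code expression to evaluate.
#' @return The value of \code{code}.
#' @export
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

row_max <- function(m) m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]

# row-wise log(sum(exp(m))) for a matrix; safe for -Inf rows
row_logsumexp <- function(m) {
  mx <- row_max(m)
  out <- mx + log(rowSums(exp(m - mx)))
  out[!is.finite(mx)] <- -Inf
  out
}

row_softmax <- function(S) {
  E <- exp(S - row_max(S))
  E / rowSums(E)
}

stop_ <- function(...) stop(..., call. = FALSE)
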