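#' @useDynLib splitaudit, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats pnorm qnorm rnorm rbinom t.test lm quantile coef
#' @importFrom utils write.csv read.csv head
NULL

# classed errors so callers can condition on failure mode
sa_stop <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "splitaudit_error"),
                      call = sys.call(-1)))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    sa_stop("sa_argument_error", "seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# deterministic counter scheme; keeps derived seeds inside 32-bit range
derive_seed <- function(master_seed, counter) {
  as.integer((as.numeric(master_seed) + 1009 * as.numeric(counter)) %%
               .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# round to nearest integer, exact halves rounded DOWN (documented convention
# for stratified allocation: ties go to fewer positives in the larger arm)
round_ties_down <- function(x) ceiling(x - 0.5)
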