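#' Nested incremental cohorts for the learning-curve experiment
#'
#' For each of `n_cohorts` random chains, draws index sets of sizes
#' `step, 2*step, ..., n` where each set contains the previous (growth
#' without replacement) and each set's positive count follows the
#' prevalence-preserving allocation at its size (round to nearest, ties
#' down).  Every chain's full-size set is the whole cohort.
#'
#' @param cohort A cohort data frame.
#' @param step Size increment in cases (default 100).
#' @param n_cohorts Number of random chains (default 20).
#' @param seed Master seed; chain `j` uses a derived seed.
#' @return List of chains; each chain is a list with `sizes` and `indices`
#'   (one index vector per size).
#' @export
nested_cohorts <- function(cohort, step = 100L, n_cohorts = 20L, seed = 1L) {
  n <- nrow(cohort)
  if (step < 2L || n %/% step < 2L)
    sa_stop("sa_argument_error", "step must fit at least twice into the cohort")
  sizes <- seq(step, n, by = step)
  if (sizes[length(sizes)] != n) sizes <- c(sizes, n)
  pos <- which(cohort$label == 1L); neg <- which(cohort$label == 0L)
  n_pos <- length(pos)
  pos_at <- round_ties_down(n_pos * sizes / n)
  if (any(pos_at < 1L) || any(sizes - pos_at < 1L))
    sa_stop("sa_infeasible_cohort_error",
            "prevalence-preserving allocation infeasible at size %d",
            sizes[which(pos_at < 1L | sizes - pos_at < 1L)[1L]])
  lapply(seq_len(n_cohorts), function(j) {
    with_seed(derive_seed(seed, j), {
      p <- sample(pos); ng <- sample(neg)
      idx <- lapply(seq_along(sizes), function(i)
        sort(c(p[seq_len(pos_at[i])],
               ng[seq_len(sizes[i] - pos_at[i])])))
      list(chain_id = j, sizes = sizes, indices = idx)
    })
  })
}

#' Cross-validated AUC at each cohort size
#'
#' Runs [repeated_nested_cv()] on every chain's index set at every size and
#' summarizes, per size, the distribution of mean validation AUCs across
#' chains (quartiles by linear interpolation, `stats::quantile` type 7).
#' The CV seed comes from `config` alone, so at full size -- where all
#' chains hold the identical whole cohort -- every chain reproduces the
#' same AUC and the spread is exactly zero.
#'
#' @param cohort A cohort data frame.
#' @param chains Output of [nested_cohorts()].
#' @param config A [cv_config()] (desk-scale runs reduce `n_repeats`).
#' @param features Feature pool for the model (default radiomics block).
#' @return A `learning_curve`: list of points, each with `n_cases`,
#'   `auc_values`, `q1`, `median`, `q3`, `iqr`.
#' @export
cv_at_sizes <- function(cohort, chains, config = cv_config(),
                        features = "radiomics") {
  sizes <- chains[[1L]]$sizes
  full <- vapply(chains, function(ch) identical(ch$sizes, sizes), logical(1L))
  if (!all(full)) sa_stop("sa_argument_error", "chains disagree on sizes")
  points <- lapply(seq_along(sizes), function(i) {
    aucs <- vapply(chains, function(ch) {
      repeated_nested_cv(cohort, ch$indices[[i]], config,
                         features = features)$mean_validation_auc
    }, numeric(1L))
    q <- unname(quantile(aucs, c(0.25, 0.5, 0.75)))   # type 7: linear interp
    list(n_cases = sizes[i], auc_values = aucs,
         q1 = q[1L], median = q[2L], q3 = q[3L], iqr = q[3L] - q[1L])
  })
  structure(points, class = "learning_curve")
}

#' @export
as.data.frame.learning_curve <- function(x, ...) {
  do.call(rbind, lapply(x, function(p)
    data.frame(n_cases = p$n_cases, cohort = seq_along(p$auc_values),
               auc = p$auc_values)))
}

#' Convergence rule for an incremental-cohort learning curve
#'
#' Formalizes "the median stopped changing": for each consecutive size pair
#' the absolute change in median AUC is compared with the IQR at the larger
#' size, and the curve is converged from the smallest size after which
#' every pair satisfies `|delta median| <= IQR`.  If every pair satisfies
#' the rule, `converged_at` is the smallest evaluated size; if the rule is
#' never sustained, it is `NA`.  A terminal pair whose larger size has zero
#' spread because every chain holds the identical full pool (all AUC values
#' equal by construction) is excluded from the rule -- its IQR of exactly 0
#' reflects the degenerate design point, not sampling convergence.
#'
#' @param points A `learning_curve` (or list of points with `n_cases`,
#'   `median`, `iqr`, `auc_values`).
#' @return A `convergence_report`: per-pair data frame (`size_from`,
#'   `size_to`, `delta_median`, `iqr_larger`, `satisfied`, `degenerate`)
#'   with attribute/field `converged_at` (numeric or `NA`).
#' @export
convergence_check <- function(points) {
  sizes <- vapply(points, `[[`, numeric(1L), "n_cases")
  if (length(sizes) < 3L)
    sa_stop("sa_argument_error", "need at least 3 sizes")
  if (is.unsorted(sizes, strictly = TRUE))
    sa_stop("sa_argument_error", "sizes must be strictly increasing")
  med <- vapply(points, `[[`, numeric(1L), "median")
  iqr <- vapply(points, `[[`, numeric(1L), "iqr")
  degen <- vapply(points, function(p)
    length(unique(p$auc_values)) == 1L, logical(1L))
  m <- length(sizes)
  pairs <- data.frame(size_from = sizes[-m], size_to = sizes[-1L],
                      delta_median = abs(diff(med)),
                      iqr_larger = iqr[-1L])
  pairs$degenerate <- degen[-1L] & pairs$iqr_larger == 0
  pairs$satisfied <- pairs$delta_median <= pairs$iqr_larger | pairs$degenerate
  eligible <- which(!pairs$degenerate)
  failed <- eligible[!pairs$satisfied[eligible]]
  converged_at <- if (!length(failed)) sizes[1L]
  else {
    nxt <- eligible[eligible > max(failed)]
    if (length(nxt)) pairs$size_to[nxt[1L]] else NA_real_
  }
  structure(list(pairs = pairs, converged_at = converged_at),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  print(x$pairs)
  cat(if (is.na(x$converged_at)) "not converged\n"
      else sprintf("converged_at = %g cases\n", x$converged_at))
  invisible(x)
}
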