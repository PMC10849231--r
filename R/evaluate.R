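#' Area under the ROC curve (Mann-Whitney estimator)
#'
#' Over all positive/negative pairs, the fraction where the positive case
#' outscores the negative, with ties counted one half -- computed from
#' midranks in O(n log n).  Equals the trapezoidal area under the empirical
#' ROC curve.
#'
#' @param scores Numeric decision scores, higher = more positive.
#' @param labels Binary 0/1 labels with at least one case per class.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  if (length(scores) != length(labels))
    sa_stop("sa_argument_error", "scores and labels differ in length")
  if (any(!is.finite(scores)))
    sa_stop("sa_argument_error", "non-finite scores")
  n1 <- as.numeric(sum(labels == 1)); n0 <- as.numeric(sum(labels == 0))
  if (n1 < 1 || n0 < 1)
    sa_stop("sa_degenerate_labels_error", "need both classes to compute AUC")
  r <- rank(scores)                       # midranks handle ties as 1/2
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Test-set AUC of a fixed model
#'
#' Applies the model's stored per-vendor standardizer and classifier to the
#' test rows only, and returns the AUC of the resulting scores against the
#' test labels.  Nothing is refit.
#'
#' @param model A `fitted_model_spec` from [fit_final()] (or
#'   [read_model_spec()]).
#' @param cohort A cohort data frame.
#' @param test_indices Rows to score.
#' @return Test AUC.
#' @export
evaluate_split <- function(model, cohort, test_indices) {
  X <- feature_matrix(cohort, model$features)[test_indices, , drop = FALSE]
  Xs <- std_apply_matrix(X, cohort$vendor[test_indices], model$standardizer)
  auc(predict_scores(model$classifier, Xs), cohort$label[test_indices])
}

#' Train-versus-test AUC tradeoff regression
#'
#' Ordinary least squares of test AUC on train AUC across shuffle-splits.
#' On a limited pool the two estimates share the finite cohort, so splits
#' that hand the "easier" cases to training leave harder ones for testing:
#' the audited phenomenon is a negative (anti-diagonal) slope.  `pearson_r`
#' carries the tradeoff's sign; `p_value` is the two-sided OLS slope t-test.
#'
#' @param results Data frame with numeric `train_auc` and `test_auc`
#'   columns, one row per split (>= 3 rows).
#' @return A `tradeoff_summary`: `n_points`, `slope`, `intercept`,
#'   `r_squared`, `p_value`, `pearson_r`.
#' @export
tradeoff_analysis <- function(results) {
  if (!all(c("train_auc", "test_auc") %in% names(results)))
    sa_stop("sa_argument_error", "results must have train_auc and test_auc")
  x <- results$train_auc; y <- results$test_auc
  if (length(x) < 3L)
    sa_stop("sa_insufficient_data_error", "need at least 3 splits")
  if (stats::var(x) == 0)
    sa_stop("sa_insufficient_data_error", "train AUCs are all identical")
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))   # exact fits trip a precision warning
  structure(list(n_points = length(x),
                 slope = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 r_squared = sm$r.squared,
                 p_value = sm$coefficients[2L, 4L],
                 pearson_r = stats::cor(x, y)),
            class = "tradeoff_summary")
}

#' @export
print.tradeoff_summary <- function(x, ...) {
  cat(sprintf(
    "<tradeoff> n = %d, slope = %.3f, r^2 = %.3f, pearson r = %.3f, p = %.3g\n",
    x$n_points, x$slope, x$r_squared, x$pearson_r, x$p_value))
  invisible(x)
}

#' Paired comparison of two models across the same splits
#'
#' Sign-flip permutation test on the per-split test-AUC differences: the
#' observed mean difference is compared with its distribution under random
#' sign flips of each paired difference (two-sided, add-one rule).
#'
#' @param results_a,results_b Data frames with `split_id` and `test_auc`,
#'   covering the same split ids.
#' @param n_permutations Number of random sign flips (default 1e4).
#' @param seed RNG seed for the flips.
#' @return List with `mean_difference` (a minus b), `p_value`, `n_pairs`.
#' @export
compare_models <- function(results_a, results_b, n_permutations = 10000L,
                           seed = 1L) {
  a <- results_a[order(results_a$split_id), ]
  b <- results_b[order(results_b$split_id), ]
  if (!identical(a$split_id, b$split_id))
    sa_stop("sa_pairing_error", "split_ids do not match between models")
  d <- a$test_auc - b$test_auc
  obs <- mean(d)
  n <- length(d)
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_permutations), function(i) {
      abs(mean(d * sample(c(-1, 1), n, replace = TRUE))) >= abs(obs) - 1e-12
    }, logical(1L)))
  })
  list(mean_difference = obs,
       p_value = (exceed + 1) / (n_permutations + 1),
       n_pairs = n)
}
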