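#' Fit a single classifier at fixed hyperparameters
#'
#' The two classifier kinds the audit exercises:
#' * `"logistic_l2"` -- logistic regression minimizing the L2-penalized
#'   negative log-likelihood `sum log(1+exp(eta)) - y*eta + ||w||^2/(2C)`
#'   (intercept unpenalized; larger `C` = weaker penalty), solved by a
#'   damped Newton method to an objective tolerance of 1e-8.
#' * `"svm"` -- soft-margin support vector machine (linear or RBF kernel)
#'   via \pkg{e1071}; raw decision values are used as scores, since the
#'   rank-based AUC is calibration-free.
#'
#' @param x Numeric feature matrix (rows = cases), already standardized.
#' @param y Binary 0/1 label vector.
#' @param kind `"logistic_l2"` or `"svm"`.
#' @param hyperparams For logistic: `list(C = ...)`. For svm:
#'   `list(kernel = "linear"|"rbf", C = ..., gamma = ...)` (`gamma` ignored
#'   for the linear kernel).
#' @return An `sa_classifier`: for logistic, intercept + weights; for svm,
#'   the fitted model plus a score orientation flag.  Score new cases with
#'   [predict_scores()] (higher score = more positive).
#' @export
train_classifier <- function(x, y, kind = c("logistic_l2", "svm"),
                             hyperparams = list(C = 1)) {
  kind <- match.arg(kind)
  x <- as.matrix(x)
  if (!all(is.finite(x))) sa_stop("sa_argument_error", "non-finite features")
  if (length(unique(y)) < 2L)
    sa_stop("sa_degenerate_labels_error", "labels contain a single class")
  if (!all(y %in% c(0, 1)))
    sa_stop("sa_argument_error", "labels must be 0/1")
  if (kind == "logistic_l2") {
    C <- hyperparams$C %||% 1
    if (C <= 0) sa_stop("sa_argument_error", "C must be > 0")
    beta <- .ridge_logistic_path(x, as.numeric(y), C)[, 1L]
    structure(list(kind = kind, hyperparams = list(C = C),
                   intercept = beta[1L], weights = beta[-1L],
                   features = colnames(x)),
              class = "sa_classifier")
  } else {
    kernel <- hyperparams$kernel %||% "linear"
    if (!kernel %in% c("linear", "rbf"))
      sa_stop("sa_argument_error", "svm kernel must be 'linear' or 'rbf'")
    C <- hyperparams$C %||% 1
    gamma <- hyperparams$gamma %||% (1 / ncol(x))
    yf <- factor(y, levels = c(0, 1))
    fit <- e1071::svm(x = x, y = yf, kernel = if (kernel == "rbf") "radial"
                      else "linear",
                      cost = C, gamma = gamma, scale = FALSE)
    # libsvm orients decision values toward the first class seen; record it
    dv <- attr(stats::predict(fit, x, decision.values = TRUE),
               "decision.values")
    flip <- grepl("^0", colnames(dv)[1L])
    structure(list(kind = kind,
                   hyperparams = list(kernel = kernel, C = C, gamma = gamma),
                   svm_fit = fit, flip = flip, features = colnames(x)),
              class = "sa_classifier")
  }
}

#' Decision scores of a fitted classifier on new cases
#'
#' @param object An `sa_classifier` from [train_classifier()].
#' @param x Feature matrix on the same (standardized) scale as training.
#' @return Numeric vector of decision scores, higher = more positive.
#' @export
predict_scores <- function(object, x) {
  x <- as.matrix(x)
  if (object$kind == "logistic_l2")
    return(drop(x %*% object$weights) + object$intercept)
  dv <- attr(stats::predict(object$svm_fit, x, decision.values = TRUE),
             "decision.values")[, 1L]
  if (object$flip) -dv else dv
}

# penalized objective of a logistic fit; used by tests and invariant checks
logistic_objective <- function(x, y, intercept, weights, C) {
  eta <- drop(as.matrix(x) %*% weights) + intercept
  sum(pmax(eta, 0) + log1p(exp(-abs(eta))) - y * eta) +
    sum(weights^2) / (2 * C)
}
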