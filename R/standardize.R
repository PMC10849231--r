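#' Fit a per-vendor feature standardizer
#'
#' Computes per-(vendor, feature) centering/scaling parameters so features
#' can be z-scored separately within each imaging-vendor stratum, the only
#' preprocessing the audited pipeline applies.  Under `scope = "train_only"`
#' the statistics come exclusively from `fit_indices` (no test-set leakage);
#' `scope = "whole_dataset"` uses every row regardless of `fit_indices`.
#'
#' @param cohort A cohort data frame.
#' @param fit_indices Row indices used for fitting (default: all rows).
#' @param scope `"train_only"` (default) or `"whole_dataset"`.
#' @param variance `"population"` (divide by n, default) or `"sample"`
#'   (divide by n - 1).
#' @param features Feature columns to standardize (default: all).
#' @return A `standardizer` object storing mean/SD per vendor and feature.
#' @export
fit_standardizer <- function(cohort, fit_indices = seq_len(nrow(cohort)),
                             scope = c("train_only", "whole_dataset"),
                             variance = c("population", "sample"),
                             features = NULL) {
  scope <- match.arg(scope)
  variance <- match.arg(variance)
  rows <- if (scope == "whole_dataset") seq_len(nrow(cohort)) else fit_indices
  fn <- features %||% grep("^(f|c)_\\d+$", names(cohort), value = TRUE)
  X <- feature_matrix(cohort, fn)[rows, , drop = FALSE]
  prm <- std_fit_matrix(X, cohort$vendor[rows], variance)
  structure(list(vendors = prm, features = fn, scope = scope,
                 variance = variance),
            class = "standardizer")
}

# matrix-level fit shared with the nested-CV hot path
std_fit_matrix <- function(X, vendor, variance = "population") {
  out <- list()
  for (v in unique(vendor)) {
    idx <- which(vendor == v)
    if (length(idx) < 2L)
      sa_stop("sa_degenerate_feature_error",
              "vendor '%s' has fewer than 2 cases on the fit set", v)
    Xv <- X[idx, , drop = FALSE]
    m <- colMeans(Xv)
    ss <- colMeans(Xv^2) - m^2
    ss[ss < 0] <- 0
    s <- if (variance == "sample")
      sqrt(ss * length(idx) / (length(idx) - 1)) else sqrt(ss)
    bad <- which(s <= 0)
    if (length(bad))
      sa_stop("sa_degenerate_feature_error",
              "feature '%s' is constant within vendor '%s' on the fit set",
              colnames(X)[bad[1L]], v)
    out[[v]] <- list(mean = m, sd = s)
  }
  out
}

std_apply_matrix <- function(X, vendor, prm, invert = FALSE) {
  if (length(prm) && length(prm[[1L]]$mean) != ncol(X))
    sa_stop("sa_configuration_error",
            "standardizer holds %d features but matrix has %d columns",
            length(prm[[1L]]$mean), ncol(X))
  unseen <- setdiff(unique(vendor), names(prm))
  if (length(unseen))
    sa_stop("sa_missing_stratum_error",
            "no standardization parameters for vendor(s): %s",
            paste(unseen, collapse = ", "))
  for (v in unique(vendor)) {
    idx <- which(vendor == v)
    p <- prm[[v]]
    if (invert)
      X[idx, ] <- sweep(sweep(X[idx, , drop = FALSE], 2L, p$sd, "*"),
                        2L, p$mean, "+")
    else
      X[idx, ] <- sweep(sweep(X[idx, , drop = FALSE], 2L, p$mean, "-"),
                        2L, p$sd, "/")
  }
  X
}

#' Apply (or invert) a fitted standardizer
#'
#' Maps each feature value to `(x - mean) / sd` with the parameters stored
#' for the row's vendor.  Labels and covariates are untouched; the input
#' cohort is not modified.  The transform is affine and exactly invertible.
#'
#' @param cohort A cohort data frame.
#' @param params A [fit_standardizer()] object.
#' @param invert If `TRUE`, applies the inverse transform `x * sd + mean`.
#' @return A standardized copy of the cohort.
#' @export
apply_standardizer <- function(cohort, params, invert = FALSE) {
  if (!inherits(params, "standardizer"))
    sa_stop("sa_argument_error", "params must come from fit_standardizer()")
  X <- feature_matrix(cohort, params$features)
  X <- std_apply_matrix(X, cohort$vendor, params$vendors, invert = invert)
  out <- cohort
  out[, params$features] <- X
  out
}

#' Serialize a standardizer to JSON for audit
#'
#' @param params A [fit_standardizer()] object.
#' @param path Optional file path; if `NULL`, the JSON string is returned.
#' @return JSON string (invisibly, when written to file).
#' @export
standardizer_to_json <- function(params, path = NULL) {
  js <- jsonlite::toJSON(list(scope = params$scope, variance = params$variance,
                              features = params$features,
                              vendors = lapply(params$vendors, function(p)
                                list(mean = p$mean, sd = p$sd))),
                         digits = NA, auto_unbox = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
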