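#' Population AUC of the binormal model at a given class separation
#'
#' Under the binormal model -- two Gaussian class-conditional score
#' distributions with equal variance -- the area under the ROC curve is
#' determined by the standardized (Mahalanobis) separation `d` between the
#' class means: `AUC = pnorm(d / sqrt(2))`.  The synthetic cohort generator
#' uses this closed form so that the population discriminability of every
#' generated cohort is known exactly.
#'
#' @param mahalanobis_distance Non-negative standardized separation between
#'   the two class-conditional distributions.
#' @return Population AUC in `[0.5, 1)`; strictly increasing in the distance.
#' @seealso [separation_for_target_auc()] for the exact inverse.
#' @examples
#' population_auc_from_separation(0)   # 0.5, identical classes
#' population_auc_from_separation(1)   # ~0.760
#' @export
population_auc_from_separation <- function(mahalanobis_distance) {
  if (!is.numeric(mahalanobis_distance) || any(!is.finite(mahalanobis_distance)))
    sa_stop("sa_argument_error", "mahalanobis_distance must be finite numeric")
  if (any(mahalanobis_distance < 0))
    sa_stop("sa_argument_error", "mahalanobis_distance must be >= 0")
  pnorm(mahalanobis_distance / sqrt(2))
}

#' Class separation achieving a target population AUC
#'
#' Exact inverse of [population_auc_from_separation()]:
#' `d = sqrt(2) * qnorm(target_auc)`.
#'
#' @param target_auc Desired population AUC, in `[0.5, 1)`.
#' @return Non-negative Mahalanobis separation.
#' @export
separation_for_target_auc <- function(target_auc) {
  if (!is.numeric(target_auc) || any(!is.finite(target_auc)))
    sa_stop("sa_argument_error", "target_auc must be finite numeric")
  if (any(target_auc < 0.5) || any(target_auc >= 1))
    sa_stop("sa_argument_error", "target_auc must lie in [0.5, 1)")
  sqrt(2) * qnorm(target_auc)
}
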