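#' Parameters for the synthetic cohort generator
#'
#' Defines a case-control cohort emulating a single-institution screening
#' population: a binary outcome (1 = upstaged at surgery, 0 = pure) at a
#' fixed prevalence, two imaging-vendor strata, a block of continuous
#' "radiomic" features plus a small "clinical" block drawn from
#' class-conditional multivariate Gaussians with an equicorrelated shared
#' covariance, and two nuisance covariates (age in years, lesion size in
#' millimetres) with class-specific means.  The class-mean difference is
#' scaled so its Mahalanobis norm matches
#' [separation_for_target_auc()]`(target_population_auc)`, making the
#' population AUC of the cohort known in closed form.
#'
#' @param n_cases Number of cases (rows).
#' @param prevalence Positive-class fraction in (0, 1); the generated
#'   positive count is exactly `round(prevalence * n_cases)`.
#' @param n_radiomic,n_clinical Sizes of the two feature blocks.
#' @param target_population_auc Population AUC in `[0.5, 1)` of the oracle
#'   linear discriminant.
#' @param feature_correlation Pairwise correlation of the equicorrelated
#'   shared covariance, in `[0, 1)`.
#' @param n_informative_radiomic,n_informative_clinical How many features of
#'   each block carry the class-mean shift; the rest are pure noise.
#' @param vendor_fractions Named proportions over vendor strata, summing
#'   to 1; vendor is assigned independently of the outcome.
#' @param vendor_shift,vendor_scale Location/scale offsets applied to the
#'   features of each vendor stratum after the first (stratum j gets shift
#'   `vendor_shift * (j-1)` and scale `vendor_scale^(j-1)`), so per-vendor
#'   standardization genuinely matters.
#' @param age_mean_by_class,age_sd Age model: means (negative, positive)
#'   in years and common SD.
#' @param lesion_size_mean_by_class,lesion_size_sd Lesion-size model: means
#'   and SDs (negative, positive), millimetres.
#' @param seed Integer RNG seed; identical seeds give identical cohorts.
#' @return A `generator_params` list, validated.
#' @export
generator_params <- function(n_cases = 700,
                             prevalence = 0.163,
                             n_radiomic = 109,
                             n_clinical = 4,
                             target_population_auc = 0.70,
                             feature_correlation = 0.3,
                             n_informative_radiomic = 20,
                             n_informative_clinical = 3,
                             vendor_fractions = c(GE = 0.5, Hologic = 0.5),
                             vendor_shift = 0.5,
                             vendor_scale = 1.25,
                             age_mean_by_class = c(62, 66),
                             age_sd = 10,
                             lesion_size_mean_by_class = c(12, 16),
                             lesion_size_sd = c(6, 8),
                             seed = 1L) {
  if (n_cases < 2) sa_stop("sa_argument_error", "n_cases must be >= 2")
  if (prevalence <= 0 || prevalence >= 1)
    sa_stop("sa_argument_error", "prevalence must lie in (0, 1)")
  n_pos <- round_half_nearest(prevalence * n_cases)
  if (n_pos < 1 || n_pos >= n_cases)
    sa_stop("sa_argument_error",
            "prevalence * n_cases must round to a count in [1, n_cases - 1]")
  if (target_population_auc < 0.5 || target_population_auc >= 1)
    sa_stop("sa_argument_error", "target_population_auc must lie in [0.5, 1)")
  if (feature_correlation < 0 || feature_correlation >= 1)
    sa_stop("sa_configuration_error",
            "feature_correlation must lie in [0, 1) to keep the covariance positive definite")
  if (n_informative_radiomic > n_radiomic || n_informative_clinical > n_clinical)
    sa_stop("sa_argument_error", "informative counts exceed block sizes")
  if (n_informative_radiomic + n_informative_clinical < 1)
    sa_stop("sa_argument_error", "at least one informative feature required")
  if (is.null(names(vendor_fractions)) || any(!nzchar(names(vendor_fractions))))
    sa_stop("sa_argument_error", "vendor_fractions must be named")
  if (abs(sum(vendor_fractions) - 1) > 1e-8 || any(vendor_fractions <= 0))
    sa_stop("sa_argument_error", "vendor_fractions must be positive and sum to 1")
  if (any(lesion_size_sd <= 0) || age_sd <= 0)
    sa_stop("sa_argument_error", "covariate SDs must be positive")
  p <- list(n_cases = as.integer(n_cases), prevalence = prevalence,
            n_radiomic = as.integer(n_radiomic),
            n_clinical = as.integer(n_clinical),
            target_population_auc = target_population_auc,
            feature_correlation = feature_correlation,
            n_informative_radiomic = as.integer(n_informative_radiomic),
            n_informative_clinical = as.integer(n_informative_clinical),
            vendor_fractions = vendor_fractions,
            vendor_shift = vendor_shift, vendor_scale = vendor_scale,
            age_mean_by_class = age_mean_by_class, age_sd = age_sd,
            lesion_size_mean_by_class = lesion_size_mean_by_class,
            lesion_size_sd = rep_len(lesion_size_sd, 2L),
            seed = as.integer(seed))
  class(p) <- "generator_params"
  p
}

# standard round-to-nearest, exact halves up (used only for the prevalence
# count, where the documented contract is "rounds to an integer count")
round_half_nearest <- function(x) floor(x + 0.5)

feature_names_for <- function(n_radiomic, n_clinical) {
  c(sprintf("f_%03d", seq_len(n_radiomic)),
    sprintf("c_%03d", seq_len(n_clinical)))
}

#' Generate a synthetic cohort with known population discriminability
#'
#' Draws `n_cases` rows under the model described in [generator_params()].
#' Features are class-conditional multivariate Gaussian with the shared
#' equicorrelated covariance `Sigma = (1-rho) I + rho J`; the positive-class
#' mean shift is confined to the informative features and scaled so its
#' Mahalanobis norm equals `separation_for_target_auc(target_population_auc)`.
#' The exact positive count is `round(prevalence * n_cases)`.  The returned
#' data frame carries the generating truth (oracle discriminant direction,
#' vendor transform) as attributes, consumed by [oracle_scores()].
#'
#' @param params A [generator_params()] object.
#' @return A `cohort` data frame with columns `case_id`, `vendor`, `label`,
#'   `age`, `lesion_size`, then `f_001...` and `c_001...` feature columns.
#' @export
generate_cohort <- function(params = generator_params()) {
  if (!inherits(params, "generator_params"))
    sa_stop("sa_argument_error", "params must come from generator_params()")
  n <- params$n_cases
  p_r <- params$n_radiomic; p_c <- params$n_clinical
  p <- p_r + p_c
  rho <- params$feature_correlation
  n_pos <- as.integer(round_half_nearest(params$prevalence * n))

  # informative direction: leading features of each block
  fn <- feature_names_for(p_r, p_c)
  inf_idx <- c(seq_len(params$n_informative_radiomic),
               if (params$n_informative_clinical > 0)
                 p_r + seq_len(params$n_informative_clinical))
  u <- numeric(p); u[inf_idx] <- 1
  # Sigma^{-1} for the equicorrelated matrix, applied analytically
  sigma_inv_mult <- function(v) {
    (v - rho / (1 + (p - 1) * rho) * sum(v)) / (1 - rho)
  }
  quad <- sum(u * sigma_inv_mult(u))          # u' Sigma^{-1} u
  d <- separation_for_target_auc(params$target_population_auc)
  delta <- (d / sqrt(quad)) * u               # Mahalanobis norm(delta) = d
  beta_true <- sigma_inv_mult(delta)          # oracle discriminant direction

  with_seed(params$seed, {
    label <- sample(rep(c(1L, 0L), c(n_pos, n - n_pos)))
    vendors <- names(params$vendor_fractions)
    vendor <- vendors[sample.int(length(vendors), n, replace = TRUE,
                                 prob = params$vendor_fractions)]
    # equicorrelated draw: sqrt(1-rho) Z + sqrt(rho) g 1'
    X <- matrix(rnorm(n * p), n, p) * sqrt(1 - rho)
    if (rho > 0) X <- X + sqrt(rho) * rnorm(n)
    X <- X + tcrossprod(label, delta)
    # vendor location/scale offsets (label-independent)
    vi <- match(vendor, vendors)
    shift <- params$vendor_shift * (vi - 1)
    scale <- params$vendor_scale^(vi - 1)
    X <- X * scale + shift
    age <- rnorm(n, params$age_mean_by_class[label + 1L], params$age_sd)
    lesion <- rnorm(n, params$lesion_size_mean_by_class[label + 1L],
                    params$lesion_size_sd[label + 1L])
    colnames(X) <- fn
    cohort <- data.frame(case_id = sprintf("case_%05d", seq_len(n)),
                         vendor = vendor, label = label,
                         age = age, lesion_size = lesion,
                         X, stringsAsFactors = FALSE)
    attr(cohort, "generator") <- params
    attr(cohort, "beta_true") <- stats::setNames(beta_true, fn)
    attr(cohort, "separation") <- d
    attr(cohort, "informative_features") <- fn[inf_idx]
    class(cohort) <- c("cohort", "data.frame")
    cohort
  })
}

#' Oracle discriminant scores of a generated cohort
#'
#' Projects the features on the true discriminant direction
#' `Sigma^{-1} delta` of the generating model, after inverting the known
#' vendor location/scale transform.  The population AUC of these scores is
#' exactly `pnorm(d / sqrt(2))` by construction; the empirical AUC converges
#' to it as the cohort grows, which is how generator calibration is tested.
#'
#' @param cohort A cohort produced by [generate_cohort()] (the generating
#'   truth travels as attributes; cohorts read back from CSV do not carry it).
#' @return Numeric score per case, higher = more positive.
#' @export
oracle_scores <- function(cohort) {
  beta <- attr(cohort, "beta_true")
  params <- attr(cohort, "generator")
  if (is.null(beta) || is.null(params))
    sa_stop("sa_state_error",
            "cohort carries no generating truth (was it read from disk?)")
  X <- feature_matrix(cohort)
  vendors <- names(params$vendor_fractions)
  vi <- match(cohort$vendor, vendors)
  shift <- params$vendor_shift * (vi - 1)
  scale <- params$vendor_scale^(vi - 1)
  X <- (X - shift) / scale
  drop(X %*% beta)
}

#' Extract the feature matrix of a cohort
#'
#' @param cohort A cohort data frame.
#' @param features Optional character vector restricting the columns.
#' @return Numeric matrix, rows in cohort order.
#' @export
feature_matrix <- function(cohort, features = NULL) {
  fn <- features %||% grep("^(f|c)_\\d+$", names(cohort), value = TRUE)
  missing <- setdiff(fn, names(cohort))
  if (length(missing))
    sa_stop("sa_configuration_error", "features absent from cohort: %s",
            paste(missing, collapse = ", "))
  as.matrix(cohort[, fn, drop = FALSE])
}

#' Resolve a model feature set by name
#'
#' Model definitions refer to feature blocks symbolically: `"clinical"`
#' (the `c_*` block), `"radiomics"` (the `f_*` block), `"all"` (both), or
#' an explicit character vector of column names.
#'
#' @param cohort A cohort data frame.
#' @param features Symbolic block name or explicit column names.
#' @return Character vector of feature column names.
#' @export
resolve_features <- function(cohort, features) {
  all_f <- grep("^f_\\d+$", names(cohort), value = TRUE)
  all_c <- grep("^c_\\d+$", names(cohort), value = TRUE)
  if (length(features) == 1L && features %in% c("clinical", "radiomics", "all"))
    return(switch(features, clinical = all_c, radiomics = all_f,
                  all = c(all_f, all_c)))
  missing <- setdiff(features, c(all_f, all_c))
  if (length(missing))
    sa_stop("sa_configuration_error", "unknown features: %s",
            paste(missing, collapse = ", "))
  features
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d cases, %d positive (%.1f%%), %d features, vendors: %s\n",
              nrow(x), sum(x$label), 100 * mean(x$label),
              length(grep("^(f|c)_\\d+$", names(x))),
              paste(unique(x$vendor), collapse = "/")))
  invisible(x)
}
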