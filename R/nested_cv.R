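#' Default hyperparameter grid for a classifier kind
#'
#' For `"logistic_l2"`: the inverse-penalty `C` on a log grid, one point per
#' decade from 1e-10 to 1e10 (21 values).  For `"svm"`: linear and RBF
#' kernels, `C` per decade over 1e-3..1e3 and kernel coefficient `gamma`
#' per decade over 1e-3..1e1.  Rows are in canonical "regularization-first"
#' order (linear before RBF, then ascending `gamma`, then ascending `C`);
#' ties in modal selection are broken toward the earliest row.
#'
#' @param kind `"logistic_l2"` or `"svm"`.
#' @param C,gamma Optional overrides for the grid axes.
#' @return Data frame of hyperparameter configurations, one row each.
#' @export
default_grid <- function(kind = c("logistic_l2", "svm"),
                         C = NULL, gamma = NULL) {
  kind <- match.arg(kind)
  if (kind == "logistic_l2") {
    C <- sort(C %||% 10^seq(-10, 10, by = 1))
    if (any(C <= 0)) sa_stop("sa_argument_error", "all C must be > 0")
    return(data.frame(C = C))
  }
  C <- sort(C %||% 10^seq(-3, 3, by = 1))
  gamma <- sort(gamma %||% 10^seq(-3, 1, by = 1))
  rbind(data.frame(kernel = "linear", gamma = NA_real_, C = C),
        expand.grid(kernel = "rbf", gamma = gamma, C = C,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)[
          order(rep(gamma, times = length(C))), c("kernel", "gamma", "C")])
}

#' Configuration for repeated nested cross-validation
#'
#' @param k_folds Outer stratified folds per repeat (default 5).
#' @param n_repeats Number of shuffled CV repeats whose validation AUCs are
#'   averaged into the training result (default 200; desk-scale runs
#'   typically reduce this to 10--20).
#' @param classifier `"logistic_l2"` or `"svm"`.
#' @param grid Hyperparameter grid data frame (default [default_grid()]).
#' @param feature_selection `"none"` or `"stability"`; under stability mode
#'   each inner-selection event also tunes the number of top-ranked features
#'   (by absolute two-sample t statistic) over `k_features_grid`.
#' @param k_features_grid Candidate feature-subset sizes for stability mode.
#' @param stability_threshold Fraction of selection events a feature must
#'   win to enter the final model (default 0.5).
#' @param inner_folds Inner stratified folds used for selection (default 3).
#' @param seed Integer seed for the fold-shuffling stream.
#' @return A `cv_config` list, validated.
#' @export
cv_config <- function(k_folds = 5L, n_repeats = 200L,
                      classifier = c("logistic_l2", "svm"),
                      grid = NULL,
                      feature_selection = c("none", "stability"),
                      k_features_grid = c(8L, 16L, 32L, 64L),
                      stability_threshold = 0.5,
                      inner_folds = 3L, seed = 1L) {
  classifier <- match.arg(classifier)
  feature_selection <- match.arg(feature_selection)
  if (k_folds < 2L) sa_stop("sa_argument_error", "k_folds must be >= 2")
  if (inner_folds < 2L) sa_stop("sa_argument_error", "inner_folds must be >= 2")
  if (n_repeats < 1L) sa_stop("sa_argument_error", "n_repeats must be >= 1")
  if (stability_threshold <= 0 || stability_threshold > 1)
    sa_stop("sa_argument_error", "stability_threshold must lie in (0, 1]")
  grid <- grid %||% default_grid(classifier)
  grid <- as.data.frame(grid, stringsAsFactors = FALSE)  # YAML gives lists
  if (!nrow(grid)) sa_stop("sa_argument_error", "empty hyperparameter grid")
  structure(list(k_folds = as.integer(k_folds),
                 n_repeats = as.integer(n_repeats),
                 classifier = classifier, grid = grid,
                 feature_selection = feature_selection,
                 k_features_grid = sort(as.integer(k_features_grid)),
                 stability_threshold = stability_threshold,
                 inner_folds = as.integer(inner_folds),
                 seed = as.integer(seed)),
            class = "cv_config")
}

# stratified k-fold assignment: permute each class, deal round-robin.
# Guarantees every fold holds >= 1 positive whenever n_pos >= k.
stratified_folds <- function(y, k) {
  if (sum(y == 1L) < k || sum(y == 0L) < k)
    sa_stop("sa_stratification_error",
            "cannot form %d stratified folds with class counts %d/%d",
            k, sum(y == 1L), sum(y == 0L))
  fold <- integer(length(y))
  for (cls in c(1L, 0L)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# per-feature absolute two-sample t statistic (Welch), vectorized;
# ranks candidate features for stability selection
feature_t_stats <- function(X, y) {
  i1 <- y == 1L
  n1 <- sum(i1); n0 <- sum(!i1)
  m1 <- colMeans(X[i1, , drop = FALSE]); m0 <- colMeans(X[!i1, , drop = FALSE])
  v1 <- (colMeans(X[i1, , drop = FALSE]^2) - m1^2) * n1 / (n1 - 1)
  v0 <- (colMeans(X[!i1, , drop = FALSE]^2) - m0^2) * n0 / (n0 - 1)
  abs(m1 - m0) / sqrt(pmax(v1 / n1 + v0 / n0, 1e-300))
}

# Inner-selection event for logistic: k-fold CV over the C path (and, in
# stability mode, over feature-subset size), vectorized over the whole grid.
# Returns the winning grid row and subset size; ties break to the earliest
# grid row / smallest subset (regularization-first).
select_logistic <- function(X, y, config) {
  Cs <- config$grid$C
  sel <- config$feature_selection == "stability"
  ks <- if (sel) pmin(config$k_features_grid, ncol(X)) else NA_integer_
  ks <- unique(ks)
  fold <- stratified_folds(y, config$inner_folds)
  auc_sum <- matrix(0, nrow = length(ks), ncol = length(Cs))
  for (f in seq_len(config$inner_folds)) {
    tr <- fold != f
    Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
    Xva <- X[!tr, , drop = FALSE]; yva <- y[!tr]
    rank_idx <- if (sel) order(feature_t_stats(Xtr, ytr), decreasing = TRUE)
    for (ki in seq_along(ks)) {
      cols <- if (sel) rank_idx[seq_len(ks[ki])] else seq_len(ncol(X))
      B <- .ridge_logistic_path(Xtr[, cols, drop = FALSE], as.numeric(ytr), Cs)
      S <- cbind(1, Xva[, cols, drop = FALSE]) %*% B
      auc_sum[ki, ] <- auc_sum[ki, ] + apply(S, 2L, auc, labels = yva)
    }
  }
  best <- which(auc_sum == max(auc_sum), arr.ind = TRUE)
  best <- best[order(best[, 1L], best[, 2L]), , drop = FALSE][1L, ]
  list(grid_row = best[[2L]], n_features = if (sel) ks[best[[1L]]] else NA_integer_)
}

# Inner-selection event for svm: plain grid search (toy scale only)
select_svm <- function(X, y, config) {
  fold <- stratified_folds(y, config$inner_folds)
  auc_sum <- numeric(nrow(config$grid))
  for (f in seq_len(config$inner_folds)) {
    tr <- fold != f
    for (g in seq_len(nrow(config$grid))) {
      hp <- as.list(config$grid[g, , drop = FALSE])
      clf <- train_classifier(X[tr, , drop = FALSE], y[tr], "svm", hp)
      auc_sum[g] <- auc_sum[g] +
        auc(predict_scores(clf, X[!tr, , drop = FALSE]), y[!tr])
    }
  }
  list(grid_row = which.max(auc_sum), n_features = NA_integer_)
}

#' Repeated nested cross-validation on a training set
#'
#' For each of `n_repeats` repeats the training cases are reshuffled into
#' `k_folds` stratified outer folds.  For each outer fold, features are
#' re-standardized per vendor on the outer-training portion only (no leakage
#' into the held-out fold), an inner `inner_folds`-fold grid search selects
#' the hyperparameter configuration (and, in stability mode, the feature
#' subset) maximizing inner validation AUC, the outer model is refit with
#' that configuration on the outer-training portion, and scored on the
#' held-out fold.  The repeat-level validation AUC is the mean over that
#' repeat's outer folds; `mean_validation_auc` averages the repeats and is
#' the quantity reported as "training performance" throughout the audit.
#' Every inner-selection event (one per outer fold per repeat) is tallied
#' for [modal_selection()].
#'
#' @param cohort A cohort data frame.
#' @param train_indices Rows forming the training set; no other row is ever
#'   touched by any fitting or selection computation.
#' @param config A [cv_config()].
#' @param features Feature columns the model may use (symbolic block name or
#'   explicit names; see [resolve_features()]).
#' @return A `cv_outcome`: `mean_validation_auc`, per-repeat AUCs, selection
#'   tallies (`hyper_tally` indexed by grid row, `feature_tally` by name),
#'   `n_events`, and the resolved feature pool.
#' @export
repeated_nested_cv <- function(cohort, train_indices, config = cv_config(),
                               features = "all") {
  fn <- resolve_features(cohort, features)
  X_all <- feature_matrix(cohort, fn)[train_indices, , drop = FALSE]
  y <- cohort$label[train_indices]
  vendor <- cohort$vendor[train_indices]
  if (sum(y == 1L) < config$k_folds)
    sa_stop("sa_stratification_error",
            "fewer positives (%d) than outer folds (%d)", sum(y == 1L),
            config$k_folds)
  sel <- config$feature_selection == "stability"
  if (sel && config$classifier != "logistic_l2")
    sa_stop("sa_configuration_error",
            "stability feature selection is implemented for logistic_l2 only")
  hyper_tally <- integer(nrow(config$grid))
  feature_tally <- stats::setNames(integer(length(fn)), fn)
  repeat_aucs <- numeric(config$n_repeats)
  n_events <- 0L
  for (r in seq_len(config$n_repeats)) {
    with_seed(derive_seed(config$seed, r), {
      fold <- stratified_folds(y, config$k_folds)
      fold_aucs <- numeric(config$k_folds)
      for (f in seq_len(config$k_folds)) {
        tr <- fold != f
        prm <- std_fit_matrix(X_all[tr, , drop = FALSE], vendor[tr])
        Xtr <- std_apply_matrix(X_all[tr, , drop = FALSE], vendor[tr], prm)
        Xva <- std_apply_matrix(X_all[!tr, , drop = FALSE], vendor[!tr], prm)
        ev <- if (config$classifier == "logistic_l2")
          select_logistic(Xtr, y[tr], config)
        else select_svm(Xtr, y[tr], config)
        cols <- seq_len(ncol(Xtr))
        if (sel && !is.na(ev$n_features)) {
          cols <- order(feature_t_stats(Xtr, y[tr]),
                        decreasing = TRUE)[seq_len(ev$n_features)]
          feature_tally[fn[cols]] <- feature_tally[fn[cols]] + 1L
        }
        hyper_tally[ev$grid_row] <- hyper_tally[ev$grid_row] + 1L
        n_events <- n_events + 1L
        hp <- as.list(config$grid[ev$grid_row, , drop = FALSE])
        clf <- train_classifier(Xtr[, cols, drop = FALSE], y[tr],
                                config$classifier, hp)
        fold_aucs[f] <- auc(predict_scores(clf, Xva[, cols, drop = FALSE]),
                            y[!tr])
      }
      repeat_aucs[r] <- mean(fold_aucs)
    })
  }
  structure(list(mean_validation_auc = mean(repeat_aucs),
                 repeat_aucs = repeat_aucs,
                 hyper_tally = hyper_tally, feature_tally = feature_tally,
                 n_events = n_events, features = fn, config = config),
            class = "cv_outcome")
}

#' Modal hyperparameter and feature selection from nested-CV tallies
#'
#' Picks the hyperparameter configuration selected most often across all
#' inner-selection events; exact ties go to the earliest grid row, i.e. the
#' stronger regularization / simpler kernel.  Under stability selection,
#' features chosen in at least `stability_threshold` of the events form the
#' final subset (if none reaches threshold, the single most frequent
#' feature is kept so the final model is never empty).
#'
#' @param outcome A `cv_outcome` from [repeated_nested_cv()].
#' @return List with `hyperparams` (named list, a grid row) and `features`
#'   (character vector, or `NULL` when no feature selection was active).
#' @export
modal_selection <- function(outcome) {
  if (!inherits(outcome, "cv_outcome"))
    sa_stop("sa_argument_error", "outcome must come from repeated_nested_cv()")
  if (outcome$n_events < 1L || sum(outcome$hyper_tally) < 1L)
    sa_stop("sa_state_error", "no selection events tallied")
  row <- which.max(outcome$hyper_tally)        # first max = earliest grid row
  hp <- as.list(outcome$config$grid[row, , drop = FALSE])
  feats <- NULL
  if (outcome$config$feature_selection == "stability") {
    frac <- outcome$feature_tally / outcome$n_events
    feats <- names(frac)[frac >= outcome$config$stability_threshold]
    if (!length(feats))
      feats <- names(which.max(outcome$feature_tally))
  }
  list(hyperparams = hp, features = feats)
}

#' Fit the single fixed model for a training set
#'
#' Applies the modally selected configuration once across the entire
#' training set: the per-vendor standardizer and the classifier are fit on
#' all training rows restricted to the chosen features, yielding a frozen
#' model that scores new cases with zero refitting.
#'
#' @param cohort A cohort data frame.
#' @param train_indices Training rows.
#' @param choice Output of [modal_selection()] (or a compatible list with
#'   `hyperparams` and optional `features`).
#' @param config The [cv_config()] used for training.
#' @param features Feature pool (used when `choice$features` is `NULL`).
#' @return A `fitted_model_spec`: classifier kind, hyperparameters, feature
#'   names, per-vendor standardization parameters, fitted weights (or the
#'   svm support description), and a training-set fingerprint.
#' @export
fit_final <- function(cohort, train_indices, choice, config = cv_config(),
                      features = "all") {
  fn <- choice$features %||% resolve_features(cohort, features)
  missing <- setdiff(fn, names(cohort))
  if (length(missing))
    sa_stop("sa_configuration_error", "chosen features absent from cohort: %s",
            paste(missing, collapse = ", "))
  X <- feature_matrix(cohort, fn)[train_indices, , drop = FALSE]
  vendor <- cohort$vendor[train_indices]
  prm <- std_fit_matrix(X, vendor)
  Xs <- std_apply_matrix(X, vendor, prm)
  clf <- train_classifier(Xs, cohort$label[train_indices],
                          config$classifier, choice$hyperparams)
  ids <- sort(cohort$case_id[train_indices])
  structure(list(kind = config$classifier,
                 hyperparams = choice$hyperparams,
                 features = fn, standardizer = prm, classifier = clf,
                 fingerprint = list(n_train = length(train_indices),
                                    id_checksum = sum(utf8ToInt(paste(ids, collapse = ""))))),
            class = "fitted_model_spec")
}

#' Serialize a fitted logistic model specification to JSON
#'
#' Captures everything needed to score new cases (features, per-vendor
#' standardization, weights) as plain JSON.  The svm kind stores the
#' support-vector fit in-memory only and refuses JSON export.
#'
#' @param spec A `fitted_model_spec` from [fit_final()].
#' @param path Optional output path.
#' @return JSON string (invisibly when written to file).
#' @export
write_model_spec <- function(spec, path = NULL) {
  if (spec$kind != "logistic_l2")
    sa_stop("sa_configuration_error",
            "only logistic_l2 model specs are JSON-serializable")
  js <- jsonlite::toJSON(list(kind = spec$kind, hyperparams = spec$hyperparams,
                              features = spec$features,
                              standardizer = lapply(spec$standardizer,
                                function(p) list(mean = p$mean, sd = p$sd)),
                              intercept = spec$classifier$intercept,
                              weights = spec$classifier$weights,
                              fingerprint = spec$fingerprint),
                         digits = NA, auto_unbox = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Read back a serialized logistic model specification
#'
#' @param path JSON path produced by [write_model_spec()].
#' @return A `fitted_model_spec` whose scores match the original to
#'   round-off.
#' @export
read_model_spec <- function(path) {
  o <- jsonlite::fromJSON(path)
  clf <- structure(list(kind = o$kind, hyperparams = o$hyperparams,
                        intercept = o$intercept,
                        weights = stats::setNames(unlist(o$weights), o$features),
                        features = o$features),
                   class = "sa_classifier")
  structure(list(kind = o$kind, hyperparams = o$hyperparams,
                 features = o$features,
                 standardizer = lapply(o$standardizer, function(p)
                   list(mean = stats::setNames(unlist(p$mean), o$features),
                        sd = stats::setNames(unlist(p$sd), o$features))),
                 classifier = clf, fingerprint = o$fingerprint),
            class = "fitted_model_spec")
}
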