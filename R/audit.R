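#' Configuration for a full train/test bias audit
#'
#' Single source of truth for every stage: the cohort (a generator block or
#' a CSV path, exactly one), the shuffle-split design, the model
#' definitions, the evaluation settings, and (optionally) the
#' learning-curve design.
#'
#' @param generator A [generator_params()] object, or `NULL` when reading a
#'   cohort from disk.
#' @param cohort_path CSV path of an existing cohort, or `NULL`.
#' @param n_train Training-arm size per split.
#' @param n_splits Number of shuffle-splits.
#' @param master_seed Seed governing the split sequence.
#' @param models List of model definitions, each a list with `label`,
#'   `features` (symbolic block or explicit names), `classifier`, and
#'   optional `feature_selection`.
#' @param cv A [cv_config()] shared by all models (classifier kind and
#'   feature selection are overridden per model).
#' @param alpha Significance level for per-split covariate balance flags.
#' @param n_permutations Sign flips for paired model comparisons.
#' @param learning_curve Optional list with `step` and `n_cohorts`.
#' @return An `audit_config` list, validated.
#' @export
audit_config <- function(generator = generator_params(),
                         cohort_path = NULL,
                         n_train = 400L, n_splits = 50L, master_seed = 1L,
                         models = list(list(label = "radiomics",
                                            features = "radiomics",
                                            classifier = "logistic_l2")),
                         cv = cv_config(),
                         alpha = 0.05, n_permutations = 10000L,
                         learning_curve = NULL) {
  if (is.null(generator) == is.null(cohort_path))
    sa_stop("sa_configuration_error",
            "exactly one of generator / cohort_path must be given")
  labels <- vapply(models, `[[`, character(1L), "label")
  if (anyDuplicated(labels))
    sa_stop("sa_configuration_error", "model labels must be unique")
  structure(list(generator = generator, cohort_path = cohort_path,
                 n_train = as.integer(n_train),
                 n_splits = as.integer(n_splits),
                 master_seed = as.integer(master_seed),
                 models = models, cv = cv, alpha = alpha,
                 n_permutations = as.integer(n_permutations),
                 learning_curve = learning_curve),
            class = "audit_config")
}

#' Read an audit configuration from YAML
#'
#' @param path YAML file whose top-level keys mirror the [audit_config()]
#'   arguments (`generator:` holds [generator_params()] fields, `cv:` holds
#'   [cv_config()] fields).
#' @return An `audit_config`.
#' @export
read_audit_config <- function(path) {
  y <- yaml::read_yaml(path)
  gen <- if (!is.null(y$generator)) {
    g <- y$generator
    if (!is.null(g$vendor_fractions)) g$vendor_fractions <- unlist(g$vendor_fractions)
    for (f in c("age_mean_by_class", "lesion_size_mean_by_class", "lesion_size_sd"))
      if (!is.null(g[[f]])) g[[f]] <- unlist(g[[f]])
    do.call(generator_params, g)
  }
  cv <- if (!is.null(y$cv)) do.call(cv_config, y$cv) else cv_config()
  audit_config(generator = gen, cohort_path = y$cohort_path,
               n_train = y$n_train %||% 400L,
               n_splits = y$n_splits %||% 50L,
               master_seed = y$master_seed %||% 1L,
               models = y$models %||% list(list(label = "radiomics",
                                                features = "radiomics",
                                                classifier = "logistic_l2")),
               cv = cv, alpha = y$alpha %||% 0.05,
               n_permutations = y$n_permutations %||% 10000L,
               learning_curve = y$learning_curve)
}

# serializable copy of the config (drops classes, keeps every value)
config_as_list <- function(config) {
  out <- unclass(config)
  if (!is.null(out$generator)) {
    g <- unclass(out$generator)
    g$vendor_fractions <- as.list(g$vendor_fractions)
    out$generator <- g
  }
  cv <- unclass(out$cv)
  cv$grid <- as.list(cv$grid)
  out$cv <- cv
  out
}

model_cv_config <- function(cv, model) {
  cv$classifier <- model$classifier %||% cv$classifier
  cv$feature_selection <- model$feature_selection %||% "none"
  if (!identical(cv$classifier, cv_classifier_of_grid(cv$grid)))
    cv$grid <- default_grid(cv$classifier)
  cv
}

cv_classifier_of_grid <- function(grid) {
  if ("kernel" %in% names(grid)) "svm" else "logistic_l2"
}

#' Run the full resampling-and-evaluation audit
#'
#' Executes the audited pipeline end to end: obtain the cohort, draw
#' `n_splits` prevalence-balanced shuffle-splits, and for every split and
#' model definition run repeated nested CV on the training arm, select the
#' modal configuration, fit the single fixed model, and score the held-out
#' test arm; covariate balance is checked once per split.  The per-split
#' ledger, the per-model tradeoff summaries, all pairwise model
#' comparisons, the split assignments, and a copy of the configuration are
#' written to `out_dir`.  Re-running with the same config reproduces every
#' file byte for byte.
#'
#' @param config An [audit_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `ledger` (data frame), `tradeoff` (per
#'   model label), `comparisons` (per label pair), and `paths`.
#' @export
run_audit <- function(config, out_dir) {
  if (!inherits(config, "audit_config"))
    sa_stop("sa_argument_error", "config must come from audit_config()")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- if (!is.null(config$generator)) generate_cohort(config$generator)
  else read_cohort(config$cohort_path)
  splits <- shuffle_split(cohort, config$n_train, config$n_splits,
                          config$master_seed)
  rows <- list()
  for (s in splits) {
    bal <- balance_check(cohort, s, alpha = config$alpha)
    for (m in config$models) {
      cv <- model_cv_config(config$cv, m)
      cv$seed <- derive_seed(config$master_seed, 7919L * s$split_id)
      out <- tryCatch({
        cvo <- repeated_nested_cv(cohort, s$train_indices, cv,
                                  features = m$features)
        choice <- modal_selection(cvo)
        model <- fit_final(cohort, s$train_indices, choice, cv,
                           features = m$features)
        list(train_auc = cvo$mean_validation_auc,
             test_auc = evaluate_split(model, cohort, s$test_indices))
      }, splitaudit_error = function(e) {
        sa_stop(class(e)[1L], "split %d, model '%s': %s",
                s$split_id, m$label, conditionMessage(e))
      })
      rows[[length(rows) + 1L]] <- data.frame(
        split_id = s$split_id, model_label = m$label,
        train_auc = out$train_auc, test_auc = out$test_auc,
        balance_p_age = bal$p_value[bal$covariate == "age"],
        balance_p_lesion_size = bal$p_value[bal$covariate == "lesion_size"],
        any_significant = attr(bal, "any_significant"))
    }
  }
  ledger <- do.call(rbind, rows)
  labels <- vapply(config$models, `[[`, character(1L), "label")
  # tradeoff regression needs >= 3 splits with non-constant train AUC;
  # smaller designs still get the ledger and comparisons
  tradeoff <- lapply(stats::setNames(labels, labels), function(lb)
    tryCatch(tradeoff_analysis(ledger[ledger$model_label == lb, ]),
             sa_insufficient_data_error = function(e) NULL))
  comparisons <- list()
  if (length(labels) > 1L) {
    for (i in seq_len(length(labels) - 1L)) for (j in (i + 1L):length(labels)) {
      key <- paste(labels[i], "vs", labels[j])
      comparisons[[key]] <- compare_models(
        ledger[ledger$model_label == labels[i], ],
        ledger[ledger$model_label == labels[j], ],
        config$n_permutations, seed = config$master_seed)
    }
  }
  paths <- list(ledger = file.path(out_dir, "ledger.csv"),
                splits = file.path(out_dir, "splits.csv"),
                config = file.path(out_dir, "config.yaml"),
                summary = file.path(out_dir, "summary.json"))
  write.csv(format(ledger, digits = 15), paths$ledger,
            row.names = FALSE, quote = FALSE)
  export_splits(splits, cohort, paths$splits)
  yaml::write_yaml(config_as_list(config), paths$config)
  jsonlite::write_json(list(tradeoff = lapply(tradeoff, unclass),
                            comparisons = comparisons),
                       paths$summary, digits = NA, auto_unbox = TRUE)
  invisible(list(ledger = ledger, tradeoff = tradeoff,
                 comparisons = comparisons, paths = paths))
}
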