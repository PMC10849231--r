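test_that("ridge logistic obeys its penalty limits and symmetry", {
  set.seed(40)
  X <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("f_00", 1:4)))
  y <- rbinom(50, 1, plogis(X[, 1]))
  y[1:2] <- c(0, 1)
  # infinite-penalty limit: weights collapse, scores nearly constant
  clf0 <- train_classifier(X, y, "logistic_l2", list(C = 1e-10))
  expect_lt(sqrt(sum(clf0$weights^2)), 1e-6)
  s0 <- predict_scores(clf0, X)
  expect_lt(max(s0) - min(s0), 1e-6)
  # mirror-symmetric data: intercept 0
  Xm <- rbind(X, -X)
  ym <- c(y, 1 - y)
  clfm <- train_classifier(Xm, ym, "logistic_l2", list(C = 1))
  expect_equal(clfm$intercept, 0, tolerance = 1e-6)
  # stronger penalty never increases the weight norm
  norms <- sapply(10^seq(-6, 6, by = 2), function(C)
    sqrt(sum(train_classifier(X, y, "logistic_l2", list(C = C))$weights^2)))
  expect_true(all(diff(norms) >= -1e-8))
  expect_error(train_classifier(X, rep(1, 50), "logistic_l2"),
               class = "sa_degenerate_labels_error")
  X[1, 1] <- NA
  expect_error(train_classifier(X, y, "logistic_l2"),
               class = "sa_argument_error")
})

test_that("near-unpenalized fit matches an independent generic optimizer", {
  # 1-D data: 20 copies of (-1 -> 0) and (+1 -> 1) plus one overlap pair,
  # so the unpenalized MLE is finite
  x <- matrix(c(rep(c(-1, 1), 20), 1, -1), ncol = 1,
              dimnames = list(NULL, "f_001"))
  y <- c(rep(c(0, 1), 20), 0, 1)
  clf <- train_classifier(x, y, "logistic_l2", list(C = 1e10))
  nll <- function(b) sum(log1p(exp((x %*% b[2] + b[1]))) - y * (x %*% b[2] + b[1]))
  ora <- optim(c(0, 0), nll, method = "BFGS", control = list(reltol = 1e-14))
  expect_equal(unname(clf$weights), ora$par[2], tolerance = 1e-3)
  expect_equal(clf$intercept, ora$par[1], tolerance = 1e-3)
})

test_that("penalized objective matches an independent optimizer at moderate C", {
  set.seed(41)
  X <- matrix(rnorm(150), 50, 3, dimnames = list(NULL, paste0("f_00", 1:3)))
  y <- rbinom(50, 1, plogis(0.8 * X[, 2]))
  y[1:2] <- c(0, 1)
  for (C in c(0.1, 1, 10)) {
    clf <- train_classifier(X, y, "logistic_l2", list(C = C))
    obj <- function(b) splitaudit:::logistic_objective(X, y, b[1], b[-1], C)
    ora <- optim(rep(0, 4), obj, method = "BFGS",
                 control = list(reltol = 1e-14, maxit = 1000))
    expect_equal(obj(c(clf$intercept, clf$weights)), ora$value,
                 tolerance = 1e-7)
  }
})

test_that("the Newton objective trace decreases monotonically", {
  set.seed(42)
  X <- matrix(rnorm(400), 100, 4)
  y <- rbinom(100, 1, plogis(X[, 1] - X[, 3]))
  y[1:2] <- c(0, 1)
  tr <- splitaudit:::.ridge_logistic_trace(X, y, C = 100)
  expect_true(all(diff(tr$objective) <= 1e-12))
  expect_gt(length(tr$objective), 2)
})

test_that("svm classifier scores orient toward the positive class", {
  set.seed(43)
  X <- matrix(rnorm(120), 60, 2, dimnames = list(NULL, c("f_001", "f_002")))
  y <- as.integer(X[, 1] + 0.3 * rnorm(60) > 0)
  y[1:2] <- c(0, 1)
  for (kern in c("linear", "rbf")) {
    clf <- train_classifier(X, y, "svm",
                            list(kernel = kern, C = 1, gamma = 0.5))
    expect_gt(auc(predict_scores(clf, X), y), 0.85)
  }
  expect_error(train_classifier(X, y, "svm", list(kernel = "poly")),
               class = "sa_argument_error")
})

test_that("repeated nested CV is deterministic and finds real signal", {
  co <- generate_cohort(tiny_params(n_cases = 150, seed = 12))
  idx <- 1:100
  cfg <- cv_config(n_repeats = 3, grid = small_grid(), seed = 6)
  a <- repeated_nested_cv(co, idx, cfg)
  b <- repeated_nested_cv(co, idx, cfg)
  expect_identical(a, b)
  expect_identical(a$n_events, 3L * 5L)
  expect_identical(sum(a$hyper_tally), a$n_events)
  expect_true(a$mean_validation_auc >= 0 && a$mean_validation_auc <= 1)
  # near-separable features: label + tiny noise
  cos <- co
  cos$f_001 <- cos$label + rnorm(150, 0, 0.01)
  sep <- repeated_nested_cv(cos, idx, cfg)
  expect_gt(sep$mean_validation_auc, 0.99)
  expect_error(repeated_nested_cv(co, 1:6, cfg),
               class = "sa_stratification_error")
})

test_that("pure-noise features yield chance-level validation AUC", {
  for (seed in c(3, 14, 25)) {
    co <- generate_cohort(tiny_params(n_cases = 200, prevalence = 0.25,
                                      seed = seed,
                                      target_population_auc = 0.5))
    cfg <- cv_config(n_repeats = 2, grid = small_grid(), seed = seed)
    out <- repeated_nested_cv(co, 1:200, cfg)
    expect_gt(out$mean_validation_auc, 0.40)
    expect_lt(out$mean_validation_auc, 0.60)
  }
})

test_that("modal selection follows the counting and tie-break rules", {
  grid <- default_grid("logistic_l2", C = c(0.1, 1, 10))
  fake <- function(tally, feats = NULL, n_events = sum(tally),
                   selection = "none", thr = 0.5) {
    cfg <- cv_config(grid = grid, feature_selection = selection,
                     stability_threshold = thr, n_repeats = 2)
    structure(list(hyper_tally = tally,
                   feature_tally = feats %||% integer(0),
                   n_events = n_events, config = cfg,
                   mean_validation_auc = 0.6),
              class = "cv_outcome")
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  # unanimous tallies
  expect_equal(modal_selection(fake(c(0L, 12L, 0L)))$hyperparams$C, 1)
  # spec counting oracle: {C=0.1:1, C=1:7, C=10:2}; f3 6/10, f7 4/10
  feats <- c(f_003 = 6L, f_007 = 4L)
  out <- modal_selection(fake(c(1L, 7L, 2L), feats, n_events = 10L,
                              selection = "stability"))
  expect_equal(out$hyperparams$C, 1)
  expect_identical(out$features, "f_003")
  # tie between two C values: the smaller C (stronger shrinkage) wins
  expect_equal(modal_selection(fake(c(5L, 5L, 0L)))$hyperparams$C, 0.1)
  expect_error(modal_selection(fake(c(0L, 0L, 0L), n_events = 0L)),
               class = "sa_state_error")
})

test_that("stability selection tallies features and respects the threshold", {
  co <- generate_cohort(tiny_params(n_cases = 150, seed = 13))
  cfg <- cv_config(n_repeats = 3, grid = small_grid(),
                   feature_selection = "stability",
                   k_features_grid = c(2L, 4L), seed = 2)
  out <- repeated_nested_cv(co, 1:150, cfg, features = "radiomics")
  expect_identical(sum(out$hyper_tally), out$n_events)
  expect_true(all(out$feature_tally <= out$n_events))
  choice <- modal_selection(out)
  expect_true(length(choice$features) >= 1)
  expect_true(all(choice$features %in% out$features))
  expect_error(repeated_nested_cv(co, 1:150,
                                  cv_config(classifier = "svm",
                                            feature_selection = "stability",
                                            n_repeats = 2)),
               class = "sa_configuration_error")
})

test_that("the fixed final model reproduces training scores and serializes", {
  co <- generate_cohort(tiny_params(n_cases = 120, seed = 17))
  idx <- 1:80
  cfg <- cv_config(n_repeats = 2, grid = small_grid(), seed = 4)
  choice <- modal_selection(repeated_nested_cv(co, idx, cfg))
  model <- fit_final(co, idx, choice, cfg)
  # consistency: scoring the training set equals train_classifier on
  # identically standardized input
  X <- feature_matrix(co, model$features)[idx, ]
  Xs <- splitaudit:::std_apply_matrix(X, co$vendor[idx], model$standardizer)
  clf <- train_classifier(Xs, co$label[idx], "logistic_l2",
                          choice$hyperparams)
  expect_equal(predict_scores(model$classifier, Xs), predict_scores(clf, Xs))
  # serialization round trip preserves test scores to 1e-12
  path <- withr::local_tempfile(fileext = ".json")
  write_model_spec(model, path)
  back <- read_model_spec(path)
  test_idx <- 81:120
  expect_equal(evaluate_split(back, co, test_idx),
               evaluate_split(model, co, test_idx), tolerance = 1e-12)
  expect_error(fit_final(co, idx, list(hyperparams = list(C = 1),
                                       features = "f_999"), cfg),
               class = "sa_configuration_error")
})

test_that("a large training set recovers the population discriminability", {
  p <- generator_params(n_cases = 10000, prevalence = 0.163,
                        target_population_auc = 0.70, seed = 19)
  co <- generate_cohort(p)
  cfg <- cv_config()
  model <- fit_final(co, seq_len(10000),
                     list(hyperparams = list(C = 100), features = NULL), cfg,
                     features = "all")
  fresh <- generate_cohort(generator_params(n_cases = 30000,
                                            prevalence = 0.163,
                                            target_population_auc = 0.70,
                                            seed = 23))
  expect_equal(evaluate_split(model, fresh, seq_len(30000)), 0.70,
               tolerance = 0.03)
})
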