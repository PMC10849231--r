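test_that("rank-based AUC equals exhaustive pair enumeration", {
  # worked example: pairs (0.35>0.1), (0.35<0.4), (0.8>0.1), (0.8>0.4) = 3/4
  expect_equal(auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(auc(rep(1, 10), rep(c(0, 1), 5)), 0.5)       # all ties
  expect_equal(auc(c(1, 2, 3, 11, 12), c(0, 0, 0, 1, 1)), 1)
  set.seed(20)
  for (i in 1:50) {
    n <- sample(4:50, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # inject ties
    labels <- c(0, 1, rbinom(n - 2, 1, 0.4))
    expect_equal(auc(scores, labels), auc_pairs(scores, labels))
  }
})

test_that("AUC respects rank invariances and degeneracy contracts", {
  set.seed(21)
  scores <- rnorm(40)
  labels <- rbinom(40, 1, 0.3)
  labels[1:2] <- c(0, 1)
  # complement identity for tie-free scores
  expect_equal(auc(scores, labels) + auc(-scores, labels), 1)
  # invariance under strictly increasing transforms
  expect_equal(auc(exp(scores), labels), auc(scores, labels))
  expect_equal(auc(rank(scores), labels), auc(scores, labels))
  # duplicating every case leaves AUC unchanged
  expect_equal(auc(rep(scores, 2), rep(labels, 2)), auc(scores, labels))
  expect_error(auc(scores, rep(1, 40)), class = "sa_degenerate_labels_error")
  expect_error(auc(c(1, NA), c(0, 1)), class = "sa_argument_error")
})

test_that("evaluate_split scores only the test rows with the frozen model", {
  co <- generate_cohort(tiny_params(n_cases = 160, seed = 9))
  s <- shuffle_split(co, 100, 1, master_seed = 5)[[1]]
  cfg <- cv_config(n_repeats = 2, grid = small_grid(), seed = 3)
  cvo <- repeated_nested_cv(co, s$train_indices, cfg, features = "all")
  model <- fit_final(co, s$train_indices, modal_selection(cvo), cfg,
                     features = "all")
  # resubstitution AUC beats the coin-flip bound
  expect_gte(evaluate_split(model, co, s$train_indices), 0.5)
  test_auc <- evaluate_split(model, co, s$test_indices)
  expect_true(test_auc >= 0 && test_auc <= 1)
  # permuting test labels centers the AUC on 0.5
  y <- co$label[s$test_indices]
  X <- feature_matrix(co, model$features)[s$test_indices, ]
  Xs <- splitaudit:::std_apply_matrix(X, co$vendor[s$test_indices],
                                      model$standardizer)
  scores <- predict_scores(model$classifier, Xs)
  set.seed(14)
  null_aucs <- replicate(500, auc(scores, sample(y)))
  expect_equal(mean(null_aucs), 0.5, tolerance = 0.02)
  # duplicating every test case leaves the AUC unchanged
  expect_equal(auc(rep(scores, 2), rep(y, 2)), auc(scores, y))
})

test_that("tradeoff regression matches closed-form OLS", {
  # exact anti-diagonal: test = 1.3 - train
  tr <- seq(0.55, 0.75, by = 0.05)
  perfect <- data.frame(train_auc = tr, test_auc = 1.3 - tr)
  ts <- tradeoff_analysis(perfect)
  expect_equal(ts$slope, -1)
  expect_equal(ts$intercept, 1.3)
  expect_equal(ts$r_squared, 1)
  expect_equal(ts$pearson_r, -1)
  # 3-point hand oracle: Sxy = -0.0045, Sx = 0.005, Sy = 0.0040667
  pts <- data.frame(train_auc = c(0.60, 0.65, 0.70),
                    test_auc = c(0.70, 0.66, 0.61))
  ts3 <- tradeoff_analysis(pts)
  expect_equal(ts3$slope, -0.9, tolerance = 1e-10)
  expect_equal(ts3$r_squared, 0.99590, tolerance = 1e-4)
  expect_equal(ts3$r_squared, ts3$pearson_r^2, tolerance = 1e-10)
  # shifting both axes by a constant changes neither slope nor r^2
  shifted <- data.frame(train_auc = pts$train_auc + 0.07,
                        test_auc = pts$test_auc + 0.07)
  tss <- tradeoff_analysis(shifted)
  expect_equal(tss$slope, ts3$slope)
  expect_equal(tss$r_squared, ts3$r_squared)
  expect_error(tradeoff_analysis(pts[1:2, ]),
               class = "sa_insufficient_data_error")
  expect_error(tradeoff_analysis(data.frame(train_auc = rep(0.6, 5),
                                            test_auc = runif(5))),
               class = "sa_insufficient_data_error")
})

test_that("paired sign-flip comparison matches exact enumeration", {
  a <- data.frame(split_id = 1:50, test_auc = seq(0.5, 0.7, length.out = 50))
  # a model against itself: zero difference, p = 1
  self <- compare_models(a, a)
  expect_equal(self$mean_difference, 0)
  expect_equal(self$p_value, 1)
  # constant +0.05 difference across 50 splits: only the two all-same-sign
  # flip patterns reach the observed magnitude -> p bounded by 2e-4
  b <- a; b$test_auc <- a$test_auc - 0.05
  expect_lte(compare_models(a, b)$p_value, 2e-4)
  expect_equal(compare_models(a, b)$mean_difference, 0.05)
  # 10 pairs: exhaustive 2^10 enumeration oracle vs 1e4 random flips
  set.seed(33)
  d <- rnorm(10, 0.02, 0.05)
  obs <- mean(d)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 10)))
  exact <- mean(abs(signs %*% d / 10) >= abs(obs) - 1e-12)
  x <- data.frame(split_id = 1:10, test_auc = d)
  y <- data.frame(split_id = 1:10, test_auc = rep(0, 10))
  expect_equal(compare_models(x, y, n_permutations = 10000)$p_value, exact,
               tolerance = 0.02)
  expect_error(compare_models(a, a[1:49, ]), class = "sa_pairing_error")
})
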