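# Independent oracles kept deliberately naive: they must not share code
# with the implementation paths they check.

# exhaustive O(n^2) pair-enumeration AUC, ties counted one half
auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + (p > n) + 0.5 * (p == n)
  total / (length(pos) * length(neg))
}

# brute-force prevalence-preserving allocation: enumerate every feasible
# (train_pos, train_neg), keep the pair whose training prevalence is
# closest to the pool prevalence, ties to fewer positives
alloc_brute <- function(n_pos, n_neg, n_train) {
  pool_prev <- n_pos / (n_pos + n_neg)
  best <- NULL
  best_err <- Inf
  for (tp in 0:min(n_pos, n_train)) {
    tn <- n_train - tp
    if (tn < 0 || tn > n_neg) next
    err <- abs(tp / n_train - pool_prev)
    if (err < best_err - 1e-12) {
      best <- c(tp, tn)
      best_err <- err
    }
  }
  c(train_pos = best[1], train_neg = best[2],
    test_pos = n_pos - best[1], test_neg = n_neg - best[2])
}

# small fast cohort for plumbing tests: 8+2 features, single informative core
tiny_params <- function(n_cases = 120, prevalence = 0.2, seed = 1, ...) {
  generator_params(n_cases = n_cases, prevalence = prevalence,
                   n_radiomic = 8, n_clinical = 2,
                   n_informative_radiomic = 4, n_informative_clinical = 1,
                   seed = seed, ...)
}

# reduced hyperparameter grid keeping the decade structure
small_grid <- function() default_grid("logistic_l2", C = 10^seq(-4, 4, by = 2))

`%||%` <- function(a, b) if (is.null(a)) b else a
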