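#' Prevalence-preserving allocation of cases to train and test arms
#'
#' Splits `n_pos` positives and `n_neg` negatives into a training arm of
#' exactly `n_train` cases and its complement while keeping each arm's
#' prevalence as close as possible to the pool prevalence: the training
#' positive count is `n_pos * n_train / (n_pos + n_neg)` rounded to the
#' nearest integer with exact ties rounded down.  For a pool of 114
#' positives and 586 negatives with `n_train = 400` this yields the 65/335
#' train and 49/251 test composition.
#'
#' @param n_pos,n_neg Pool class counts (each >= 1).
#' @param n_train Training-arm size, strictly between 0 and the pool size.
#' @return Named integer vector `(train_pos, train_neg, test_pos, test_neg)`.
#' @export
stratified_allocation <- function(n_pos, n_neg, n_train) {
  if (n_pos < 1 || n_neg < 1)
    sa_stop("sa_argument_error", "need at least one case per class")
  n <- n_pos + n_neg
  if (n_train <= 0 || n_train >= n)
    sa_stop("sa_argument_error", "n_train must satisfy 0 < n_train < n_pos + n_neg")
  train_pos <- round_ties_down(n_pos * n_train / n)
  train_neg <- n_train - train_pos
  test_pos <- n_pos - train_pos
  test_neg <- n_neg - train_neg
  out <- c(train_pos = train_pos, train_neg = train_neg,
           test_pos = test_pos, test_neg = test_neg)
  if (any(out < 1))
    sa_stop("sa_infeasible_split_error",
            "allocation (%d, %d, %d, %d) leaves a class empty in one arm",
            train_pos, train_neg, test_pos, test_neg)
  storage.mode(out) <- "integer"
  out
}

#' Repeated prevalence-balanced shuffle-splits of a cohort
#'
#' Each split permutes positives and negatives separately (an independent
#' uniform stratified draw) and assigns the first `train_pos` positives and
#' `train_neg` negatives to the training arm per [stratified_allocation()].
#' Per-split seeds are derived deterministically from `master_seed` by a
#' counter scheme, so any single split can be re-created in isolation.
#'
#' @param cohort A cohort data frame with a binary `label` column.
#' @param n_train Training-arm size.
#' @param n_splits Number of independent splits (default 50).
#' @param master_seed Integer seed governing the whole sequence.
#' @return List of `split_spec` objects with fields `split_id`, `seed`,
#'   `train_indices`, `test_indices`, `counts`.
#' @export
shuffle_split <- function(cohort, n_train, n_splits = 50L, master_seed = 1L) {
  if (n_splits < 1) sa_stop("sa_argument_error", "n_splits must be >= 1")
  y <- cohort$label
  alloc <- stratified_allocation(sum(y == 1L), sum(y == 0L), n_train)
  pos <- which(y == 1L); neg <- which(y == 0L)
  lapply(seq_len(n_splits), function(i) {
    seed_i <- derive_seed(master_seed, i)
    with_seed(seed_i, {
      p <- sample(pos); ng <- sample(neg)
      train <- sort(c(p[seq_len(alloc[["train_pos"]])],
                      ng[seq_len(alloc[["train_neg"]])]))
      test <- sort(setdiff(seq_along(y), train))
      structure(list(split_id = i, seed = seed_i,
                     train_indices = train, test_indices = test,
                     counts = alloc),
                class = "split_spec")
    })
  })
}

#' Covariate balance between the arms of one split
#'
#' Welch two-sample t-test (two-sided) per covariate between the training
#' and test arms, with no multiplicity correction: each split is flagged
#' on its own, so the flag rate under label-independent covariates stays
#' calibrated at `alpha` per covariate.
#'
#' @param cohort A cohort data frame.
#' @param split A `split_spec` from [shuffle_split()].
#' @param covariates Numeric covariate columns to test.
#' @param alpha Per-test significance level.
#' @return A `balance_report`: data frame with one row per covariate
#'   (train/test means, p-value) plus attributes `alpha`, `any_significant`.
#' @export
balance_check <- function(cohort, split,
                          covariates = c("age", "lesion_size"),
                          alpha = 0.05) {
  missing <- setdiff(covariates, names(cohort))
  if (length(missing))
    sa_stop("sa_argument_error", "covariates absent from cohort: %s",
            paste(missing, collapse = ", "))
  rows <- lapply(covariates, function(cv) {
    a <- cohort[[cv]][split$train_indices]
    b <- cohort[[cv]][split$test_indices]
    if (!is.numeric(a))
      sa_stop("sa_argument_error", "covariate '%s' is not numeric", cv)
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      if (isTRUE(all.equal(mean(a), mean(b))))   # identical constants: t = 0
        return(data.frame(covariate = cv, train_mean = mean(a),
                          test_mean = mean(b), p_value = 1))
      sa_stop("sa_undefined_test_error",
              "covariate '%s' has zero variance in both arms", cv)
    }
    tt <- t.test(a, b)                            # Welch by default
    data.frame(covariate = cv, train_mean = mean(a), test_mean = mean(b),
               p_value = tt$p.value)
  })
  rep <- do.call(rbind, rows)
  attr(rep, "alpha") <- alpha
  attr(rep, "any_significant") <- any(rep$p_value < alpha)
  class(rep) <- c("balance_report", "data.frame")
  rep
}

#' Export split assignments as a long CSV for external audit
#'
#' @param splits List of `split_spec` objects.
#' @param cohort The cohort the splits index into.
#' @param path Output CSV path (columns `split_id`, `case_id`, `arm`).
#' @return The path, invisibly.
#' @export
export_splits <- function(splits, cohort, path) {
  df <- do.call(rbind, lapply(splits, function(s)
    data.frame(split_id = s$split_id,
               case_id = cohort$case_id[c(s$train_indices, s$test_indices)],
               arm = rep(c("train", "test"),
                         c(length(s$train_indices), length(s$test_indices))))))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
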