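#' Write a cohort to CSV
#'
#' Columns `case_id, vendor, label, age, lesion_size, f_001..., c_001...`,
#' header row, UTF-8, '.' decimal separator.  The round-trip through
#' [read_cohort()] is lossless for all columns (generator attributes, which
#' only exist on freshly generated cohorts, do not travel).
#'
#' @param cohort A cohort data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  fn <- grep("^(f|c)_\\d+$", names(cohort), value = TRUE)
  df <- cohort[, c("case_id", "vendor", "label", "age", "lesion_size", fn)]
  write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a cohort from CSV with schema validation
#'
#' Rejects files violating the documented schema with row/column
#' diagnostics: missing mandatory columns, duplicate `case_id`, non-binary
#' labels, missing values, or non-numeric feature columns.
#'
#' @param path CSV path as written by [write_cohort()].
#' @return A `cohort` data frame.
#' @export
read_cohort <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  mandatory <- c("case_id", "vendor", "label", "age", "lesion_size")
  missing <- setdiff(mandatory, names(df))
  if (length(missing))
    sa_stop("sa_schema_error", "missing mandatory column(s): %s",
            paste(missing, collapse = ", "))
  dup <- df$case_id[duplicated(df$case_id)]
  if (length(dup))
    sa_stop("sa_schema_error", "duplicated case_id: %s",
            paste(unique(dup), collapse = ", "))
  if (!all(df$label %in% c(0L, 1L)))
    sa_stop("sa_schema_error", "label must be 0/1; offending row(s): %s",
            paste(head(which(!df$label %in% c(0L, 1L)), 5L), collapse = ", "))
  fn <- grep("^(f|c)_\\d+$", names(df), value = TRUE)
  if (!length(fn))
    sa_stop("sa_schema_error", "no feature columns (f_*/c_*) found")
  for (col in c("age", "lesion_size", fn)) {
    if (!is.numeric(df[[col]]))
      sa_stop("sa_schema_error", "column '%s' is not numeric", col)
    if (anyNA(df[[col]]))
      sa_stop("sa_schema_error", "column '%s' has missing values (row %d)",
              col, which(is.na(df[[col]]))[1L])
  }
  df$label <- as.integer(df$label)
  class(df) <- c("cohort", "data.frame")
  df
}
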