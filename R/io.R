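#' Cohort CSV input/output
#'
#' A cohort file is a UTF-8 CSV with "." decimal separator and the fixed
#' header `id, age, sex, race, weight_now_kg, weight_past_kg, height_m,
#' survey_weight`. Numbers are written at full round-trip precision, so
#' write-then-read is lossless.
#'
#' @name cohort-io
NULL

.cohort_columns <- c("id", "age", "sex", "race", "weight_now_kg",
                     "weight_past_kg", "height_m", "survey_weight")

#' Validate cohort records
#'
#' Checks the column contract and the per-record invariants (strictly
#' positive weights, heights and survey weights; derived BMI inside
#' (10, 100)). Errors name the offending column or row.
#'
#' @param records A data frame of cohort records.
#' @return The records as a tibble, invisibly usable downstream.
#' @export
validate_cohort <- function(records) {
  missing_cols <- setdiff(.cohort_columns, names(records))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("Cohort is missing required column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  records <- tibble::as_tibble(records)
  bad_row <- function(ok, what) {
    if (!all(ok)) {
      rows <- which(!ok)
      rlang::abort(paste0(
        what, " in row(s) ", paste(utils::head(rows, 5), collapse = ", "),
        if (length(rows) > 5) paste0(" (and ", length(rows) - 5, " more)") else ""
      ))
    }
  }
  num_ok <- function(x) is.finite(x) & x > 0
  bad_row(num_ok(records$weight_now_kg), "Non-positive weight_now_kg")
  bad_row(num_ok(records$weight_past_kg), "Non-positive weight_past_kg")
  bad_row(num_ok(records$height_m), "Non-positive height_m")
  bad_row(num_ok(records$survey_weight), "Non-positive survey_weight")
  bad_row(!duplicated(records$id), "Duplicate id")
  records
}

#' @describeIn cohort-io Write cohort records to CSV.
#' @param records Cohort tibble (see [generate_cohort()]).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(records, path) {
  records <- validate_cohort(records)
  out <- records[.cohort_columns]
  # 17 significant digits round-trips doubles exactly
  for (col in names(out)) {
    if (is.numeric(out[[col]])) out[[col]] <- sprintf("%.17g", out[[col]])
  }
  readr::write_csv(out, path)
  invisible(path)
}

#' @describeIn cohort-io Read and validate cohort records from CSV.
#' @export
read_cohort <- function(path) {
  records <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character())
  )
  missing_cols <- setdiff(.cohort_columns, names(records))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("Cohort file is missing required column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  # parse numerics through base R's strtod for correctly rounded doubles
  num_cols <- setdiff(.cohort_columns, c("id", "sex", "race"))
  for (col in num_cols) {
    parsed <- suppressWarnings(as.numeric(records[[col]]))
    bad <- is.na(parsed) & !is.na(records[[col]])
    if (any(bad)) {
      rlang::abort(paste0("Malformed numeric value for ", col, " in row(s) ",
                          paste(utils::head(which(bad), 5), collapse = ", ")))
    }
    records[[col]] <- parsed
  }
  validate_cohort(records)
}

#' Transition-matrix CSV input/output
#'
#' Matrices are written with a header row naming destination states and a
#' leading `from` column naming origin states, values at full precision.
#'
#' @param tm A [transition_matrix] object or bare row-stochastic matrix.
#' @param path File path.
#' @return `path` invisibly for the writer; a matrix for the reader.
#' @export
write_transition_matrix <- function(tm, path) {
  P <- if (inherits(tm, "transition_matrix")) tm$P else as.matrix(tm)
  df <- tibble::as_tibble(P, .name_repair = "minimal")
  for (col in names(df)) df[[col]] <- sprintf("%.17g", df[[col]])
  df <- tibble::add_column(df, from = rownames(P), .before = 1)
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_transition_matrix
#' @export
read_transition_matrix <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    from = readr::col_character(), .default = readr::col_double()
  ))
  P <- as.matrix(df[setdiff(names(df), "from")])
  rownames(P) <- df$from
  if (any(abs(rowSums(P) - 1) > 1e-9)) {
    rlang::abort("Transition-matrix rows read from file do not sum to 1.")
  }
  P
}
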