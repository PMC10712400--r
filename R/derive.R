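#' Derive analysis variables from raw cohort records
#'
#' Computes BMI at both time points, assigns CDC weight categories under the
#' chosen scheme, the decade weight change (current minus past), and the
#' loss/gain classification. Records breaching the record invariants
#' (non-positive weight, height or survey weight) and adults-only inclusion
#' (age below `min_age`) are rejected per-record, tallied by reason, and
#' reported — never dropped silently.
#'
#' A change of exactly 0 kg is classed `GAINED_OR_MAINTAINED`.
#'
#' @param records Cohort tibble with the columns of [read_cohort()].
#' @param scheme `"scheme3"` (default, merged normal/underweight) or
#'   `"scheme4"`.
#' @param min_age Inclusion threshold in years (default 18). Set to `NULL`
#'   to skip the age filter.
#' @param quiet Suppress the exclusion message.
#' @return A tibble of derived records with added columns `bmi_now`,
#'   `bmi_past`, `state_now`, `state_past`, `weight_change_kg`,
#'   `change_class`; the exclusion tally is attached as attribute
#'   `"exclusions"` and the scheme as `"scheme"`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n = 20, seed = 3))
#' derived <- derive_cohort(cohort)
#' dplyr::count(derived, state_past, state_now)
derive_cohort <- function(records, scheme = c("scheme3", "scheme4"),
                          min_age = 18, quiet = FALSE) {
  scheme <- match.arg(scheme)
  missing_cols <- setdiff(.cohort_columns, names(records))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("Cohort is missing required column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  records <- tibble::as_tibble(records)

  pos <- function(x) is.finite(x) & x > 0
  reasons <- list(
    nonpositive_weight_now  = !pos(records$weight_now_kg),
    nonpositive_weight_past = !pos(records$weight_past_kg),
    nonpositive_height      = !pos(records$height_m),
    nonpositive_survey_weight = !pos(records$survey_weight)
  )
  if (!is.null(min_age)) {
    reasons$below_min_age <- !is.finite(records$age) | records$age < min_age
  }
  excl <- tibble::tibble(
    reason = names(reasons),
    n_excluded = vapply(reasons, sum, integer(1))
  )
  drop <- Reduce(`|`, reasons)
  if (any(drop) && !quiet) {
    rlang::inform(paste0(
      "Excluded ", sum(drop), " of ", nrow(records), " record(s): ",
      paste0(excl$reason[excl$n_excluded > 0], " (",
             excl$n_excluded[excl$n_excluded > 0], ")", collapse = ", ")
    ))
  }
  kept <- records[!drop, , drop = FALSE]

  out <- dplyr::mutate(
    kept,
    bmi_now = bmi(.data$weight_now_kg, .data$height_m),
    bmi_past = bmi(.data$weight_past_kg, .data$height_m),
    state_now = categorize_bmi(.data$bmi_now, scheme),
    state_past = categorize_bmi(.data$bmi_past, scheme),
    weight_change_kg = .data$weight_now_kg - .data$weight_past_kg,
    change_class = factor(
      ifelse(.data$weight_change_kg < 0, "LOST", "GAINED_OR_MAINTAINED"),
      levels = c("LOST", "GAINED_OR_MAINTAINED")
    )
  )
  attr(out, "exclusions") <- excl
  attr(out, "scheme") <- scheme
  out
}

.derived_scheme <- function(derived, scheme = NULL) {
  if (!is.null(scheme)) return(match.arg(scheme, c("scheme3", "scheme4")))
  s <- attr(derived, "scheme")
  if (is.null(s)) {
    k <- nlevels(derived$state_now)
    s <- if (k == 4) "scheme4" else "scheme3"
  }
  s
}
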