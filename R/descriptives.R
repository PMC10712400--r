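#' Descriptive summary table, stratified by weight loss vs gain
#'
#' Builds the classic cohort characteristics table: each variable summarised
#' overall and within the `LOST` and `GAINED_OR_MAINTAINED` groups, with a
#' two-group test per variable — Welch two-sample t-test for continuous
#' variables (set `var_equal = TRUE` for the pooled-variance test) and
#' Pearson chi-square without continuity correction for categorical ones.
#' Descriptive tests are computed unweighted on raw counts; survey weights
#' enter only prevalence and transition estimation.
#'
#' @param derived Derived records from [derive_cohort()].
#' @param variables Character vector of column names to summarise. Numeric
#'   columns get mean (SD) rows; character/factor columns get one
#'   count (proportion) row per level.
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return Tibble with columns `variable`, `level`, `overall`, `lost`,
#'   `gained_or_maintained` (formatted summaries), `statistic`, `p_value`
#'   (numeric), `p_label` (3 significant figures, `"<0.001"` below), and
#'   `test`. Per-variable missing-value counts are attached as attribute
#'   `"n_missing"`; group sizes as `"group_n"`.
#' @export
#' @examples
#' d <- derive_cohort(generate_cohort(cohort_config(n = 300, seed = 4)))
#' cohort_summary(d, c("age", "sex", "weight_change_kg"))
cohort_summary <- function(derived,
                           variables = c("age", "sex", "race",
                                         "weight_now_kg", "weight_change_kg",
                                         "bmi_now"),
                           var_equal = FALSE) {
  missing_vars <- setdiff(variables, names(derived))
  if (length(missing_vars) > 0) {
    rlang::abort(paste0("Variable(s) not found: ",
                        paste(missing_vars, collapse = ", ")))
  }
  grp <- derived$change_class
  fmt_p <- function(p) {
    if (is.na(p)) NA_character_
    else if (p < 0.001) "<0.001"
    else format(signif(p, 3), scientific = FALSE)
  }
  fmt_ms <- function(x) sprintf("%.2f (%.2f)", mean(x), stats::sd(x))
  fmt_np <- function(nlev, ntot) sprintf("%d (%.2f)", nlev, nlev / ntot)

  n_missing <- stats::setNames(integer(length(variables)), variables)
  rows <- purrr::map(variables, function(v) {
    x <- derived[[v]]
    keep <- !is.na(x)
    n_missing[[v]] <<- sum(!keep)
    x <- x[keep]
    g <- grp[keep]
    is_lost <- g == "LOST"
    if (is.numeric(x)) {
      if (stats::sd(x) == 0 || sum(is_lost) < 2 || sum(!is_lost) < 2) {
        tt <- NULL
        test <- "skipped (constant or degenerate groups)"
        stat <- NA_real_; p <- NA_real_
      } else {
        tt <- stats::t.test(x[is_lost], x[!is_lost], var.equal = var_equal)
        test <- if (var_equal) "pooled t-test" else "Welch t-test"
        stat <- unname(tt$statistic); p <- tt$p.value
      }
      tibble::tibble(
        variable = v, level = NA_character_,
        overall = fmt_ms(x), lost = fmt_ms(x[is_lost]),
        gained_or_maintained = fmt_ms(x[!is_lost]),
        statistic = stat, p_value = p, p_label = fmt_p(p), test = test
      )
    } else {
      xf <- factor(x)
      tab <- table(xf, g)
      if (nlevels(xf) < 2) {
        test <- "skipped (constant)"
        stat <- NA_real_; p <- NA_real_
      } else {
        ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
        test <- "chi-square"
        stat <- unname(ct$statistic); p <- ct$p.value
      }
      tibble::tibble(
        variable = v, level = levels(xf),
        overall = fmt_np(as.integer(table(xf)), length(x)),
        lost = fmt_np(as.integer(tab[, "LOST"]), sum(is_lost)),
        gained_or_maintained = fmt_np(as.integer(tab[, "GAINED_OR_MAINTAINED"]),
                                      sum(!is_lost)),
        statistic = c(stat, rep(NA_real_, nlevels(xf) - 1)),
        p_value = c(p, rep(NA_real_, nlevels(xf) - 1)),
        p_label = c(fmt_p(p), rep(NA_character_, nlevels(xf) - 1)),
        test = c(test, rep(NA_character_, nlevels(xf) - 1))
      )
    }
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "n_missing") <- n_missing
  attr(out, "group_n") <- c(
    total = length(grp),
    lost = sum(grp == "LOST"),
    gained_or_maintained = sum(grp == "GAINED_OR_MAINTAINED")
  )
  out
}

#' Paired t-test for decade weight change
#'
#' One-sample t-test of the per-individual decade weight change against
#' zero — algebraically the paired t-test of current vs decade-ago weight.
#'
#' @param derived Derived records from [derive_cohort()].
#' @return One-row tibble: `estimate` (mean change, kg), `statistic`,
#'   `df`, `p_value`, `conf_low`, `conf_high`, `method`.
#' @export
paired_change_test <- function(derived) {
  x <- derived$weight_change_kg
  if (length(x) < 2) rlang::abort("Need at least 2 records.")
  if (stats::sd(x) == 0) {
    rlang::abort("Weight changes have zero variance; the paired t-test is degenerate.")
  }
  tt <- stats::t.test(x, mu = 0)
  tibble::tibble(
    estimate = unname(tt$estimate),
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    conf_low = tt$conf.int[1],
    conf_high = tt$conf.int[2],
    method = "paired t-test (change vs 0)"
  )
}

#' Histogram of decade weight change
#'
#' Uniform bins of width `bin_width_kg`, right-open `[low, high)`, with
#' edges aligned at multiples of the bin width (so 0 is always an edge and
#' a symmetric change distribution yields a symmetric histogram). Counts
#' sum to the cohort size.
#'
#' @param derived Derived records from [derive_cohort()].
#' @param bin_width_kg Bin width in kg, positive (default 5).
#' @return Tibble with columns `bin_low`, `bin_high`, `midpoint`, `count`.
#' @export
change_histogram <- function(derived, bin_width_kg = 5) {
  if (nrow(derived) == 0) rlang::abort("Cohort is empty.")
  if (bin_width_kg <= 0) rlang::abort("`bin_width_kg` must be > 0.")
  x <- derived$weight_change_kg
  lo <- bin_width_kg * floor(min(x) / bin_width_kg)
  hi <- bin_width_kg * (floor(max(x) / bin_width_kg) + 1)
  breaks <- seq(lo, hi, by = bin_width_kg)
  idx <- findInterval(x, breaks, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = length(breaks) - 1)
  tibble::tibble(
    bin_low = breaks[-length(breaks)],
    bin_high = breaks[-1],
    midpoint = (breaks[-length(breaks)] + breaks[-1]) / 2,
    count = counts
  )
}
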