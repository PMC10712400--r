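#' Seeded synthetic-cohort generator
#'
#' Generates a cohort of paired (decade-ago, current) weight records with
#' the statistical structure the downstream pipeline assumes: demographic
#' strata, heights by sex, positive right-skewed survey weights normalized
#' to mean 1, and either category-driven (`state_mode`) or
#' continuous-change-driven (`weight_mode`) weights. See [cohort_config()]
#' for the knobs and their defaults.
#'
#' Height is held constant within an individual across the decade, so BMI
#' change is entirely weight-driven.
#'
#' @param config A [cohort_config()] object.
#' @return A tibble with one row per individual and columns `id`, `age`,
#'   `sex`, `race`, `weight_now_kg`, `weight_past_kg`, `height_m`,
#'   `survey_weight`. In `state_mode` the generating categories are attached
#'   as attributes `true_state_past` / `true_state_now` for diagnostics.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n = 50, seed = 1))
#' head(cohort)
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    rlang::abort("`config` must be a `cohort_config` object.")
  }
  withr::with_seed(config$seed, .generate_cohort_impl(config))
}

# truncated-normal draw by inverse-CDF; exact under the seeded stream
.rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

.generate_cohort_impl <- function(config) {
  n <- config$n
  sex <- sample(names(config$sex_proportions), n, replace = TRUE,
                prob = config$sex_proportions)
  race <- sample(names(config$race_proportions), n, replace = TRUE,
                 prob = config$race_proportions)
  age <- .rtruncnorm(n, 58.39, 12.94, 18, 100)
  hm <- unname(config$height_mean_by_sex[sex])
  hs <- unname(config$height_sd_by_sex[sex])
  height <- .rtruncnorm(n, hm, hs, hm - 3.5 * hs, hm + 3.5 * hs)

  if (config$mode == "state_mode") {
    states <- weight_states(config$scheme)
    k <- length(states)
    past_i <- sample.int(k, n, replace = TRUE,
                         prob = config$past_state_marginals)
    now_i <- integer(n)
    for (i in seq_len(k)) {
      sel <- past_i == i
      if (any(sel)) {
        now_i[sel] <- sample.int(k, sum(sel), replace = TRUE,
                                 prob = config$true_transition_matrix[i, ])
      }
    }
    draw_bmi <- function(state_i) {
      out <- numeric(n)
      for (i in seq_len(k)) {
        sel <- state_i == i
        if (!any(sel)) next
        iv <- .state_bmi_interval(states[i])
        mid <- mean(iv)
        out[sel] <- .rtruncnorm(sum(sel), mid, diff(iv) / 4, iv[1], iv[2])
      }
      out
    }
    bmi_past <- draw_bmi(past_i)
    bmi_now <- draw_bmi(now_i)
    weight_past <- bmi_past * height^2
    weight_now <- bmi_now * height^2
  } else {
    wm <- ifelse(sex == "male", 85, 75)
    # the past-weight floor rises with height so that even a far-left-tail
    # change draw almost never pushes current BMI below 10; this keeps the
    # realized change distribution within ~1e-4 total variation of the
    # configured normal
    lo <- pmax(55, 10 * height^2 + 42)
    weight_past <- .rtruncnorm(n, wm, 20, lo, 170)
    change <- stats::rnorm(n, config$weight_change_mean,
                           config$weight_change_sd)
    weight_now <- weight_past + change
    # redraw the rare change that pushes BMI outside (10, 100)
    for (iter in 1:100) {
      b <- weight_now / height^2
      bad <- b <= 10 | b >= 100
      if (!any(bad)) break
      weight_now[bad] <- weight_past[bad] +
        stats::rnorm(sum(bad), config$weight_change_mean,
                     config$weight_change_sd)
    }
  }

  sw <- stats::rlnorm(n, meanlog = 0, sdlog = config$survey_weight_dispersion)
  sw <- sw / mean(sw)

  out <- tibble::tibble(
    id = sprintf("S%07d", seq_len(n)),
    age = age,
    sex = sex,
    race = race,
    weight_now_kg = weight_now,
    weight_past_kg = weight_past,
    height_m = height,
    survey_weight = sw
  )
  if (config$mode == "state_mode") {
    states <- weight_states(config$scheme)
    attr(out, "true_state_past") <- factor(states[past_i], levels = states)
    attr(out, "true_state_now") <- factor(states[now_i], levels = states)
  }
  out
}
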