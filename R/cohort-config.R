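#' Default three-state decade transition matrix
#'
#' The row-stochastic matrix of decade-scale transition probabilities between
#' the merged normal/underweight, overweight, and obese categories that the
#' synthetic generator uses as ground truth in `state_mode`. Rows are origin
#' states, columns destinations.
#'
#' @param scheme `"scheme3"` or `"scheme4"`. The four-state default expands
#'   the merged normal/underweight row to underweight and normal rows with
#'   identical transition behaviour (destination mass within the merged state
#'   is split 3%/97% between underweight and normal, mirroring the thinness
#'   of the underweight stratum).
#' @return A row-stochastic matrix with state dimnames.
#' @export
#' @examples
#' default_transition_matrix()
default_transition_matrix <- function(scheme = c("scheme3", "scheme4")) {
  scheme <- match.arg(scheme)
  P3 <- matrix(c(
    0.58, 0.32, 0.10,
    0.16, 0.49, 0.35,
    0.03, 0.19, 0.78
  ), nrow = 3, byrow = TRUE,
  dimnames = list(.scheme3_states, .scheme3_states))
  if (scheme == "scheme3") return(P3)
  split <- c(0.03, 0.97) # underweight vs normal share of merged destination
  P4 <- matrix(0, 4, 4, dimnames = list(.scheme4_states, .scheme4_states))
  from3 <- c(1, 1, 2, 3)
  for (i in 1:4) {
    row3 <- P3[from3[i], ]
    P4[i, ] <- c(row3[1] * split, row3[2], row3[3])
  }
  P4
}

#' Default past-state prevalence vector
#'
#' The survey prints only current-state prevalences; the generator's default
#' anchors the past-state marginals at the merged current-state prevalences
#' (34%, 22%, 43%, renormalized). This is a documented default, not a claim
#' about the unobserved decade-ago distribution.
#'
#' @inheritParams default_transition_matrix
#' @return Named probability vector summing to 1.
#' @export
default_state_marginals <- function(scheme = c("scheme3", "scheme4")) {
  scheme <- match.arg(scheme)
  if (scheme == "scheme3") {
    m <- c(0.34, 0.22, 0.43)
    stats::setNames(m / sum(m), .scheme3_states)
  } else {
    m <- c(0.01, 0.33, 0.22, 0.43)
    stats::setNames(m / sum(m), .scheme4_states)
  }
}

.default_race_proportions <- c(
  White = 2252, Hispanic = 1257, Black = 1636, Asian = 739, Other = 262
) / 6146

.default_sex_proportions <- c(male = 3024, female = 3122) / 6146

#' Configuration for the synthetic-cohort generator
#'
#' Bundles and validates every knob of [generate_cohort()]. Two generation
#' modes are provided because a single mechanism cannot simultaneously match
#' the published continuous weight-change distribution and the published
#' category-transition matrix:
#'
#' * `state_mode` draws each individual's past category from
#'   `past_state_marginals` and the current category from the matching row of
#'   `true_transition_matrix`, then realises a BMI inside each category's
#'   interval and converts it to weight through the individual's height.
#' * `weight_mode` draws a past weight from a sex-specific distribution and
#'   adds a `Normal(weight_change_mean, weight_change_sd^2)` decade change.
#'
#' @param n Cohort size, positive integer.
#' @param seed Integer seed; identical `seed` + config reproduces the cohort.
#' @param mode `"state_mode"` or `"weight_mode"`.
#' @param scheme Category scheme used in `state_mode`.
#' @param past_state_marginals Probability vector over the scheme's states.
#' @param true_transition_matrix Row-stochastic matrix over the scheme's
#'   states (used in `state_mode`).
#' @param weight_change_mean,weight_change_sd Decade weight-change
#'   distribution in kg (used in `weight_mode`). Defaults 3.27 and 14.97.
#' @param sex_proportions Named probability vector over `male`, `female`.
#' @param race_proportions Named probability vector over the five race
#'   groups.
#' @param height_mean_by_sex,height_sd_by_sex Named numeric vectors (metres)
#'   for `male` and `female`.
#' @param survey_weight_dispersion Log-scale SD of the lognormal survey
#'   weights (normalized to mean 1 after drawing). Positive.
#' @return A validated list with class `"cohort_config"`.
#' @export
#' @examples
#' cfg <- cohort_config(n = 100, seed = 1)
#' cfg$mode
cohort_config <- function(n,
                          seed,
                          mode = c("state_mode", "weight_mode"),
                          scheme = c("scheme3", "scheme4"),
                          past_state_marginals = NULL,
                          true_transition_matrix = NULL,
                          weight_change_mean = 3.27,
                          weight_change_sd = 14.97,
                          sex_proportions = .default_sex_proportions,
                          race_proportions = .default_race_proportions,
                          height_mean_by_sex = c(male = 1.75, female = 1.62),
                          height_sd_by_sex = c(male = 0.07, female = 0.07),
                          survey_weight_dispersion = 0.5) {
  mode <- match.arg(mode)
  scheme <- match.arg(scheme)
  if (length(n) != 1 || !is.finite(n) || n < 1 || n != round(n)) {
    rlang::abort("`n` must be a positive integer.")
  }
  if (length(seed) != 1 || !is.finite(seed) || seed != round(seed)) {
    rlang::abort("`seed` must be a single integer.")
  }
  if (is.null(past_state_marginals)) {
    past_state_marginals <- default_state_marginals(scheme)
  }
  if (is.null(true_transition_matrix)) {
    true_transition_matrix <- default_transition_matrix(scheme)
  }
  states <- weight_states(scheme)
  k <- length(states)

  norm_prob <- function(p, what) {
    if (any(!is.finite(p)) || any(p < 0) || sum(p) <= 0) {
      rlang::abort(paste0("`", what, "` must be non-negative with positive sum."))
    }
    p / sum(p)
  }
  past_state_marginals <- norm_prob(unname(past_state_marginals),
                                    "past_state_marginals")
  if (length(past_state_marginals) != k) {
    rlang::abort(paste0("`past_state_marginals` must have length ", k,
                        " for ", scheme, "."))
  }
  names(past_state_marginals) <- states

  P <- as.matrix(true_transition_matrix)
  if (!all(dim(P) == c(k, k))) {
    rlang::abort(paste0("`true_transition_matrix` must be ", k, "x", k,
                        " for ", scheme, "."))
  }
  if (any(!is.finite(P)) || any(P < 0) ||
      any(abs(rowSums(P) - 1) > 1e-12)) {
    rlang::abort("`true_transition_matrix` rows must be probabilities summing to 1 (within 1e-12).")
  }
  dimnames(P) <- list(states, states)

  if (weight_change_sd <= 0) rlang::abort("`weight_change_sd` must be > 0.")
  if (survey_weight_dispersion <= 0) {
    rlang::abort("`survey_weight_dispersion` must be > 0.")
  }
  sex_proportions <- norm_prob(sex_proportions[c("male", "female")],
                               "sex_proportions")
  names(sex_proportions) <- c("male", "female")
  race_names <- c("White", "Hispanic", "Black", "Asian", "Other")
  if (!all(race_names %in% names(race_proportions))) {
    rlang::abort("`race_proportions` must name White, Hispanic, Black, Asian, Other.")
  }
  race_proportions <- norm_prob(race_proportions[race_names], "race_proportions")
  names(race_proportions) <- race_names
  for (nm in c("male", "female")) {
    if (!is.finite(height_mean_by_sex[[nm]]) || height_mean_by_sex[[nm]] <= 0 ||
        !is.finite(height_sd_by_sex[[nm]]) || height_sd_by_sex[[nm]] <= 0) {
      rlang::abort("height means and SDs must be positive for both sexes.")
    }
  }

  structure(
    list(
      n = as.integer(n), seed = as.integer(seed), mode = mode, scheme = scheme,
      past_state_marginals = past_state_marginals,
      true_transition_matrix = P,
      weight_change_mean = weight_change_mean,
      weight_change_sd = weight_change_sd,
      sex_proportions = sex_proportions,
      race_proportions = race_proportions,
      height_mean_by_sex = height_mean_by_sex,
      height_sd_by_sex = height_sd_by_sex,
      survey_weight_dispersion = survey_weight_dispersion
    ),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config> n =", x$n, "| mode =", x$mode,
      "| scheme =", x$scheme, "| seed =", x$seed, "\n")
  invisible(x)
}
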