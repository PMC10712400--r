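# Shared fixtures, built in code.

# Minimal derived-record tibble from explicit states and weights, for
# hand-computable estimation examples.
derived_from_states <- function(past, now, weight = rep(1, length(past)),
                                scheme = "scheme3") {
  states <- weight_states(scheme)
  out <- tibble::tibble(
    id = sprintf("R%03d", seq_along(past)),
    state_past = factor(past, levels = states),
    state_now = factor(now, levels = states),
    survey_weight = weight,
    sex = rep_len(c("male", "female"), length(past)),
    race = rep_len("White", length(past))
  )
  attr(out, "scheme") <- scheme
  out
}

# A raw cohort of n identical records (useful for degenerate-case tests).
constant_cohort <- function(n, weight_now = 90, weight_past = 90,
                            height = 1.7) {
  tibble::tibble(
    id = sprintf("C%04d", seq_len(n)),
    age = 50,
    sex = rep_len(c("male", "female"), n),
    race = "White",
    weight_now_kg = weight_now,
    weight_past_kg = weight_past,
    height_m = height,
    survey_weight = 1
  )
}

# Random row-stochastic matrix with strictly positive entries (irreducible
# and aperiodic almost surely).
random_stochastic <- function(k) {
  m <- matrix(stats::rexp(k * k), nrow = k)
  m / rowSums(m)
}

# The published three-state decade transition matrix, spelled out so tests
# do not depend on the package default they are checking.
published_matrix <- function() {
  matrix(c(
    0.58, 0.32, 0.10,
    0.16, 0.49, 0.35,
    0.03, 0.19, 0.78
  ), nrow = 3, byrow = TRUE,
  dimnames = list(weight_states("scheme3"), weight_states("scheme3")))
}
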