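#' Survey-weighted transition-matrix estimation
#'
#' `estimate_transition_matrix()` tallies survey weight over (past state,
#' current state) pairs and normalizes each origin row:
#' \deqn{\hat P_{ij} = \frac{\sum_r w_r \, 1\{past_r = i,\; now_r = j\}}
#'                          {\sum_r w_r \, 1\{past_r = i\}}.}
#' With `use_survey_weights = FALSE` every record counts 1. Rows are origin
#' states, columns destinations; state distributions are row vectors
#' multiplied on the left.
#'
#' An origin state carrying zero total weight is an error by default
#' (`empty_row = "error"`); `empty_row = "self_loop"` substitutes an
#' identity row with a warning instead, flagged via `row_mass = 0`.
#'
#' @param derived Derived records from [derive_cohort()].
#' @param scheme Optional scheme override; defaults to the scheme the
#'   records were derived under.
#' @param use_survey_weights Use the per-record survey weights (default) or
#'   treat every record as weight 1.
#' @param empty_row Policy for origin states with zero weight.
#' @return A `transition_matrix` object: list with `P` (row-stochastic
#'   matrix), `states`, `row_mass` (summed survey weight per origin row),
#'   and `scheme`.
#' @export
#' @examples
#' d <- derive_cohort(generate_cohort(cohort_config(n = 500, seed = 1)))
#' tm <- estimate_transition_matrix(d)
#' tm$P
estimate_transition_matrix <- function(derived, scheme = NULL,
                                       use_survey_weights = TRUE,
                                       empty_row = c("error", "self_loop")) {
  empty_row <- match.arg(empty_row)
  scheme <- .derived_scheme(derived, scheme)
  states <- weight_states(scheme)
  k <- length(states)
  past_i <- as.integer(factor(as.character(derived$state_past), levels = states))
  now_i <- as.integer(factor(as.character(derived$state_now), levels = states))
  if (anyNA(past_i) || anyNA(now_i)) {
    rlang::abort("Derived states do not match the requested scheme.")
  }
  w <- if (use_survey_weights) derived$survey_weight else rep(1, nrow(derived))
  counts <- .weighted_pair_counts(past_i, now_i, w, k)
  row_mass <- rowSums(counts)
  empty <- row_mass == 0
  if (any(empty)) {
    if (empty_row == "error") {
      rlang::abort(paste0("No records observed in past state(s): ",
                          paste(states[empty], collapse = ", "),
                          ". Use empty_row = \"self_loop\" to substitute identity rows."))
    }
    rlang::warn(paste0("Substituting self-loop row(s) for empty past state(s): ",
                       paste(states[empty], collapse = ", ")))
  }
  P <- counts / ifelse(row_mass == 0, 1, row_mass)
  for (i in which(empty)) P[i, i] <- 1
  dimnames(P) <- list(states, states)
  new_transition_matrix(P, states, row_mass, scheme)
}

# C-level weighted cross-tabulation: counts[i, j] = sum of w where
# past == i and now == j
.weighted_pair_counts <- function(past_i, now_i, w, k) {
  cross <- (past_i - 1L) * k + now_i
  sums <- numeric(k * k)
  agg <- rowsum(w, cross)
  sums[as.integer(rownames(agg))] <- agg
  matrix(sums, k, k, byrow = TRUE)
}

new_transition_matrix <- function(P, states, row_mass, scheme) {
  stopifnot(all(abs(rowSums(P) - 1) < 1e-9), all(P >= 0), all(P <= 1))
  structure(
    list(P = P, states = states,
         row_mass = stats::setNames(row_mass, states), scheme = scheme),
    class = "transition_matrix"
  )
}

#' Build a transition_matrix object from a bare matrix
#'
#' @param P Row-stochastic matrix; dimnames, if present, must match the
#'   scheme's states.
#' @param scheme `"scheme3"` or `"scheme4"`; inferred from the dimension
#'   when omitted.
#' @param row_mass Optional per-row weight mass (defaults to `NA`).
#' @return A `transition_matrix` object.
#' @export
as_transition_matrix <- function(P, scheme = NULL, row_mass = NULL) {
  P <- as.matrix(P)
  k <- nrow(P)
  if (is.null(scheme)) {
    scheme <- switch(as.character(k), "3" = "scheme3", "4" = "scheme4",
                     rlang::abort("Matrix must be 3x3 or 4x4."))
  }
  states <- weight_states(scheme)
  if (!all(dim(P) == k) || k != length(states)) {
    rlang::abort(paste0("Matrix must be ", length(states), "x",
                        length(states), " for ", scheme, "."))
  }
  if (any(abs(rowSums(P) - 1) > 1e-9) || any(P < 0)) {
    rlang::abort("Matrix rows must be probabilities summing to 1 (within 1e-9).")
  }
  dimnames(P) <- list(states, states)
  if (is.null(row_mass)) row_mass <- rep(NA_real_, k)
  new_transition_matrix(P, states, row_mass, scheme)
}

#' @export
print.transition_matrix <- function(x, digits = 4, ...) {
  cat("<transition_matrix> ", x$scheme, " (rows = origin, cols = destination)\n",
      sep = "")
  print(round(x$P, digits))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a transition matrix into long form
#'
#' @param x A `transition_matrix`.
#' @param ... Unused.
#' @return Tibble with columns `from`, `to`, `prob`, `row_mass`.
#' @export
tidy.transition_matrix <- function(x, ...) {
  tibble::tibble(
    from = factor(rep(x$states, each = length(x$states)), levels = x$states),
    to = factor(rep(x$states, times = length(x$states)), levels = x$states),
    prob = as.vector(t(x$P)),
    row_mass = rep(unname(x$row_mass), each = length(x$states))
  )
}

#' One-row summary of a transition matrix
#'
#' @param x A `transition_matrix`.
#' @param ... Unused.
#' @return Tibble with the number of states, the smallest row mass, the
#'   smallest diagonal (persistence) probability, and whether any row was
#'   flagged empty.
#' @export
glance.transition_matrix <- function(x, ...) {
  tibble::tibble(
    n_states = length(x$states),
    min_row_mass = min(x$row_mass),
    min_self_transition = min(diag(x$P)),
    any_empty_row = any(x$row_mass == 0, na.rm = TRUE)
  )
}

#' Survey-weighted state prevalence at one time point
#'
#' The survey-weighted distribution over weight states, anchored by default
#' at the current (survey-time) state; `anchor = "past"` uses the recalled
#' decade-ago state instead.
#'
#' @inheritParams estimate_transition_matrix
#' @param anchor `"now"` (default) or `"past"`.
#' @return Tibble with columns `state` (factor) and `prob`, summing to 1.
#' @export
#' @examples
#' d <- derive_cohort(generate_cohort(cohort_config(n = 500, seed = 1)))
#' initial_distribution(d)
initial_distribution <- function(derived, scheme = NULL,
                                 use_survey_weights = TRUE,
                                 anchor = c("now", "past")) {
  anchor <- match.arg(anchor)
  if (nrow(derived) == 0) rlang::abort("Cohort is empty.")
  scheme <- .derived_scheme(derived, scheme)
  states <- weight_states(scheme)
  s <- if (anchor == "now") derived$state_now else derived$state_past
  si <- as.integer(factor(as.character(s), levels = states))
  w <- if (use_survey_weights) derived$survey_weight else rep(1, nrow(derived))
  mass <- numeric(length(states))
  agg <- rowsum(w, si)
  mass[as.integer(rownames(agg))] <- agg
  tibble::tibble(
    state = factor(states, levels = states),
    prob = mass / sum(mass)
  )
}

# accept a state-distribution tibble or a bare (named) probability vector
.as_pi_vector <- function(initial, states) {
  if (is.data.frame(initial)) {
    if (!all(c("state", "prob") %in% names(initial))) {
      rlang::abort("`initial` must have columns `state` and `prob`.")
    }
    v <- stats::setNames(initial$prob, as.character(initial$state))
  } else {
    v <- initial
    if (is.null(names(v))) names(v) <- states
  }
  if (!setequal(names(v), states)) {
    rlang::abort("State lists of the matrix and the initial distribution differ.")
  }
  v <- v[states]
  if (any(v < 0) || abs(sum(v) - 1) > 1e-9) {
    rlang::abort("`initial` must be a probability vector summing to 1 (within 1e-9).")
  }
  v
}
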