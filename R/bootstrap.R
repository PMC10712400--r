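#' Bootstrap confidence bands for projected prevalences
#'
#' Resamples individuals uniformly with replacement (each record carrying
#' its survey weight into re-estimation), re-estimates the transition matrix
#' and initial distribution, and re-projects the whole chain per replicate.
#' Bands are the empirical `alpha/2` and `1 - alpha/2` percentiles across
#' replicates for every (state, decade) cell — so the compounding of
#' estimation error through repeated projection is captured by construction
#' rather than approximated cell-by-cell.
#'
#' Replicates in which some origin state receives no resampled records are
#' redrawn (the count is recorded); if more than 10% of replicates needed a
#' redraw a warning names the sparsest state.
#'
#' @inheritParams estimate_transition_matrix
#' @inheritParams initial_distribution
#' @param B Number of bootstrap replicates (default 10000).
#' @param seed Integer seed; identical seed reproduces identical bands.
#' @param horizon Decade steps to project (default 10).
#' @param alpha Two-sided level (default 0.05 for 95% bands).
#' @param keep_replicates Retain the replicate-level trajectories (array
#'   `B x (horizon + 1) x states`) as attribute `"replicates"`.
#' @return A tibble of class `bootstrap_bands` with columns `state`,
#'   `decade`, `point` (full-cohort estimate), `lower`, `upper`. Attributes:
#'   `B`, `seed`, `alpha`, `horizon`, `n_redrawn`.
#' @export
#' @examples
#' d <- derive_cohort(generate_cohort(cohort_config(n = 400, seed = 2)))
#' bootstrap_projection(d, B = 50, seed = 9, horizon = 3)
bootstrap_projection <- function(derived, scheme = NULL, B = 10000,
                                 seed = 1, horizon = 10, alpha = 0.05,
                                 use_survey_weights = TRUE,
                                 anchor = c("now", "past"),
                                 keep_replicates = FALSE) {
  anchor <- match.arg(anchor)
  if (nrow(derived) == 0) rlang::abort("Cohort is empty.")
  if (length(B) != 1 || B < 1) rlang::abort("`B` must be >= 1.")
  if (alpha <= 0 || alpha >= 1) rlang::abort("`alpha` must be in (0, 1).")
  scheme <- .derived_scheme(derived, scheme)
  states <- weight_states(scheme)
  k <- length(states)
  n <- nrow(derived)
  past_i <- as.integer(factor(as.character(derived$state_past), levels = states))
  now_i <- as.integer(factor(as.character(derived$state_now), levels = states))
  anchor_i <- if (anchor == "now") now_i else past_i
  w <- if (use_survey_weights) derived$survey_weight else rep(1, n)

  # origin rows empty in the FULL cohort get self-loops (once, with a
  # warning); the per-replicate redraw below applies only to rows that the
  # full cohort does occupy, so bootstrap resampling can never demand a
  # state the data does not contain
  tm <- estimate_transition_matrix(derived, scheme, use_survey_weights,
                                   empty_row = "self_loop")
  occupied <- unname(tm$row_mass > 0)
  pi0 <- initial_distribution(derived, scheme, use_survey_weights, anchor)
  point <- project(tm, pi0, horizon)

  reps <- array(NA_real_, dim = c(B, horizon + 1, k))
  n_redrawn <- 0L
  withr::with_seed(seed, {
    for (b in seq_len(B)) {
      for (attempt in seq_len(1000)) {
        idx <- sample.int(n, n, replace = TRUE)
        counts <- .weighted_pair_counts(past_i[idx], now_i[idx], w[idx], k)
        row_mass <- rowSums(counts)
        if (all(row_mass[occupied] > 0)) break
        n_redrawn <- n_redrawn + 1L
        if (attempt == 1000) {
          rlang::abort("Could not draw a bootstrap replicate with all origin states occupied.")
        }
      }
      P <- counts / ifelse(row_mass == 0, 1, row_mass)
      for (i in which(row_mass == 0)) P[i, i] <- 1
      wb <- w[idx]
      mass0 <- numeric(k)
      agg <- rowsum(wb, anchor_i[idx])
      mass0[as.integer(rownames(agg))] <- agg
      v <- mass0 / sum(mass0)
      reps[b, 1, ] <- v
      for (t in seq_len(horizon)) {
        v <- as.vector(v %*% P)
        reps[b, t + 1, ] <- v
      }
    }
  })
  if (n_redrawn > 0.1 * B) {
    sparse <- states[which.min(tabulate(past_i, k))]
    rlang::warn(paste0(
      n_redrawn, " of ", B, " replicate draws were redrawn for an empty ",
      "origin row; sparsest past state: ", sparse
    ))
  }

  qs <- apply(reps, c(2, 3), stats::quantile,
              probs = c(alpha / 2, 1 - alpha / 2), names = FALSE)
  out <- tibble::tibble(
    state = point$state,
    decade = point$decade,
    point = point$prob,
    lower = as.vector(t(qs[1, , ])),
    upper = as.vector(t(qs[2, , ]))
  )
  class(out) <- c("bootstrap_bands", class(out))
  attr(out, "B") <- as.integer(B)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "alpha") <- alpha
  attr(out, "horizon") <- as.integer(horizon)
  attr(out, "scheme") <- scheme
  attr(out, "n_redrawn") <- n_redrawn
  if (keep_replicates) attr(out, "replicates") <- reps
  out
}

#' Stratified estimate + bootstrap runs
#'
#' Splits the cohort by a demographic variable, then estimates and
#' bootstraps each stratum independently. Per-stratum seeds are derived
#' deterministically from the shared seed (stratum `i` in sorted label
#' order uses `seed + (i - 1) * 100003`), so a run with a single stratum is
#' identical to the unstratified run with the same seed.
#'
#' @inheritParams bootstrap_projection
#' @param stratify_by Column to stratify on: `"sex"` or `"race"`.
#' @return A named list of `bootstrap_bands`, one per stratum, with class
#'   `stratified_bands`.
#' @export
stratified_run <- function(derived, scheme = NULL,
                           stratify_by = c("sex", "race"), B = 10000,
                           seed = 1, horizon = 10, alpha = 0.05,
                           use_survey_weights = TRUE,
                           anchor = c("now", "past")) {
  stratify_by <- match.arg(stratify_by)
  anchor <- match.arg(anchor)
  scheme <- .derived_scheme(derived, scheme)
  labels <- sort(unique(as.character(derived[[stratify_by]])))
  if (length(labels) == 0) rlang::abort("No strata found.")
  out <- vector("list", length(labels))
  names(out) <- labels
  for (i in seq_along(labels)) {
    sub <- derived[derived[[stratify_by]] == labels[i], , drop = FALSE]
    attr(sub, "scheme") <- scheme
    if (nrow(sub) < 50) {
      rlang::warn(paste0("Stratum '", labels[i], "' has only ", nrow(sub),
                         " records; estimates will be unstable."))
    }
    out[[i]] <- bootstrap_projection(
      sub, scheme = scheme, B = B, seed = seed + (i - 1L) * 100003L,
      horizon = horizon, alpha = alpha,
      use_survey_weights = use_survey_weights, anchor = anchor
    )
  }
  structure(out, class = "stratified_bands", stratify_by = stratify_by)
}

#' Combine stratified bands into one long tibble
#'
#' @param x A `stratified_bands` list.
#' @param ... Unused.
#' @return Tibble with a leading `stratum` column.
#' @export
tidy.stratified_bands <- function(x, ...) {
  dplyr::bind_rows(purrr::map(x, tibble::as_tibble), .id = "stratum")
}
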