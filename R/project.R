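#' Project state prevalences forward by decades
#'
#' Repeated left-multiplication of a prevalence row vector by the transition
#' matrix, one decade per step, assuming time-homogeneity:
#' `pi[t + 1] = pi[t] %*% P`.
#'
#' @param tm A [transition_matrix] (or a bare row-stochastic matrix, which
#'   is passed through [as_transition_matrix()]).
#' @param initial Initial state distribution: the tibble returned by
#'   [initial_distribution()] or a named probability vector over the same
#'   states.
#' @param horizon Number of decade steps, `>= 0` (default 10).
#' @return A tibble of class `markov_projection` in long form with columns
#'   `decade` (0 = initial), `state`, `prob`; `horizon + 1` decades in all.
#' @export
#' @examples
#' tm <- as_transition_matrix(default_transition_matrix())
#' project(tm, c(normal_or_under = 1, overweight = 0, obese = 0), horizon = 2)
project <- function(tm, initial, horizon = 10) {
  if (!inherits(tm, "transition_matrix")) tm <- as_transition_matrix(tm)
  if (length(horizon) != 1 || !is.finite(horizon) || horizon < 0 ||
      horizon != round(horizon)) {
    rlang::abort("`horizon` must be a non-negative integer.")
  }
  pi0 <- .as_pi_vector(initial, tm$states)
  k <- length(tm$states)
  traj <- matrix(NA_real_, nrow = horizon + 1, ncol = k,
                 dimnames = list(NULL, tm$states))
  traj[1, ] <- pi0
  v <- pi0
  for (t in seq_len(horizon)) {
    v <- as.vector(v %*% tm$P)
    traj[t + 1, ] <- v
  }
  out <- tibble::tibble(
    decade = rep(0:horizon, each = k),
    state = factor(rep(tm$states, times = horizon + 1), levels = tm$states),
    prob = as.vector(t(traj))
  )
  class(out) <- c("markov_projection", class(out))
  attr(out, "scheme") <- tm$scheme
  out
}

#' Stationary distribution of a transition matrix
#'
#' Power iteration from the uniform vector until `||pi P - pi||_1 <= tol`,
#' cross-checked against the direct solution of the linear system
#' `pi P = pi`, `sum(pi) = 1`. Periodic or reducible chains that fail to
#' converge raise an error.
#'
#' @inheritParams project
#' @param tol L1 convergence tolerance (default 1e-12).
#' @param max_iter Iteration cap (default 10000).
#' @param check_tol Maximum allowed L-infinity disagreement between the
#'   power-iteration and linear-system solutions (default 1e-8).
#' @return Tibble with columns `state`, `prob`; the iteration count is
#'   attached as attribute `"iterations"` and the linear-system solution as
#'   `"linear_solution"`.
#' @export
#' @examples
#' stationary_distribution(as_transition_matrix(default_transition_matrix()))
stationary_distribution <- function(tm, tol = 1e-12, max_iter = 10000,
                                    check_tol = 1e-8) {
  if (!inherits(tm, "transition_matrix")) tm <- as_transition_matrix(tm)
  P <- tm$P
  k <- nrow(P)
  power_iterate <- function(v) {
    iter <- 0L
    repeat {
      v_new <- as.vector(v %*% P)
      iter <- iter + 1L
      if (sum(abs(v_new - v)) <= tol) return(list(v = v_new, iter = iter))
      v <- v_new
      if (iter >= max_iter) {
        rlang::abort(paste0(
          "Power iteration did not converge within ", max_iter,
          " iterations; the chain may be periodic or reducible."
        ))
      }
    }
  }
  res <- power_iterate(rep(1 / k, k))
  # a second, asymmetric start exposes periodic chains (which oscillate)
  # and reducible chains (which converge to a different fixed point)
  res2 <- power_iterate(c(1 - 0.1 * (k - 1), rep(0.1, k - 1)))
  if (max(abs(res$v - res2$v)) > max(check_tol, 10 * tol)) {
    rlang::abort("The chain has no unique limiting distribution (reducible chain).")
  }
  iter <- res$iter
  v <- res$v / sum(res$v)
  # independent cross-check: solve (t(P) - I) pi = 0 with sum constraint
  A <- rbind(t(P) - diag(k), rep(1, k))
  pi_lin <- as.vector(qr.solve(A, c(rep(0, k), 1)))
  if (max(abs(v - pi_lin)) > check_tol) {
    rlang::abort(paste0(
      "Power-iteration and linear-system stationary solutions disagree by ",
      format(max(abs(v - pi_lin)), digits = 3),
      "; the chain may not have a unique stationary distribution."
    ))
  }
  out <- tibble::tibble(
    state = factor(tm$states, levels = tm$states),
    prob = v
  )
  attr(out, "iterations") <- iter
  attr(out, "linear_solution") <- stats::setNames(pi_lin, tm$states)
  out
}

#' Multiplicative compounding of a per-step error over repeated projection
#'
#' A relative error of `e` per projection step compounds to
#' `(1 + e)^steps - 1` after `steps` iterations — e.g. a 5% per-decade error
#' becomes a 62.9% error after ten decades, which is why confidence bands
#' are built by re-projecting whole bootstrap-resampled chains rather than
#' by attaching intervals to individual matrix cells.
#'
#' @param per_step_error Non-negative per-step relative error (fraction).
#' @param steps Non-negative number of projection steps.
#' @return Compounded relative error as a fraction.
#' @export
#' @examples
#' compounding_error(0.05, 10)
compounding_error <- function(per_step_error, steps) {
  if (any(per_step_error < 0)) rlang::abort("`per_step_error` must be >= 0.")
  if (any(steps < 0)) rlang::abort("`steps` must be >= 0.")
  (1 + per_step_error)^steps - 1
}
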