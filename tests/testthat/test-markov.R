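test_that("weighted transition estimation matches a hand tally", {
  d <- derived_from_states(
    past = c("normal_or_under", "normal_or_under", "overweight", "obese"),
    now = c("normal_or_under", "obese", "obese", "obese"),
    weight = c(2, 1, 1, 5)
  )
  tm <- estimate_transition_matrix(d)
  expected <- rbind(
    c(2 / 3, 0, 1 / 3),
    c(0, 0, 1),
    c(0, 0, 1)
  )
  dimnames(expected) <- list(tm$states, tm$states)
  expect_equal(tm$P, expected, tolerance = 1e-15)
  expect_equal(unname(tm$row_mass), c(3, 1, 5))
  # unweighted estimation treats every record as weight 1
  tm_u <- estimate_transition_matrix(d, use_survey_weights = FALSE)
  expect_equal(tm_u$P[1, ], c(normal_or_under = 0.5, overweight = 0,
                              obese = 0.5))
})

test_that("a no-movement cohort estimates the identity matrix", {
  d <- derive_cohort(constant_cohort(40, weight_now = 70, weight_past = 70),
                     quiet = TRUE)
  d$state_past <- d$state_now <- factor(
    rep(weight_states("scheme3"), length.out = 40),
    levels = weight_states("scheme3")
  )
  tm <- estimate_transition_matrix(d)
  expect_equal(unname(tm$P), diag(3), tolerance = 1e-15)
})

test_that("empty origin rows error by default and self-loop on request", {
  d <- derived_from_states(
    past = c("normal_or_under", "normal_or_under"),
    now = c("overweight", "obese")
  )
  expect_error(estimate_transition_matrix(d), "overweight.*obese|obese")
  expect_warning(tm <- estimate_transition_matrix(d, empty_row = "self_loop"),
                 "self-loop")
  expect_equal(tm$P["obese", "obese"], 1)
  expect_equal(unname(tm$row_mass[c("overweight", "obese")]), c(0, 0))
})

test_that("initial_distribution is the survey-weighted prevalence", {
  d1 <- derived_from_states("obese", "obese")
  expect_equal(initial_distribution(d1)$prob, c(0, 0, 1))
  d2 <- derived_from_states(
    past = c("normal_or_under", "obese"),
    now = c("normal_or_under", "obese"),
    weight = c(3, 1)
  )
  expect_equal(initial_distribution(d2)$prob, c(0.75, 0, 0.25))
  expect_error(initial_distribution(d2[0, ]), "empty")
})

test_that("unweighted scheme4 prevalences reproduce the printed cohort counts", {
  counts <- c(underweight = 87, normal = 2058, overweight = 1376,
              obese = 2625)
  states <- rep(names(counts), counts)
  d <- tibble::tibble(
    state_now = factor(states, levels = weight_states("scheme4")),
    state_past = factor(states, levels = weight_states("scheme4")),
    survey_weight = 1
  )
  attr(d, "scheme") <- "scheme4"
  pi0 <- initial_distribution(d, use_survey_weights = FALSE)
  expect_equal(pi0$prob, unname(counts) / 6146, tolerance = 1e-12)
  # rounded to the printed precision: 1%, 33%, 22%, 43%
  expect_equal(round(pi0$prob, 2), c(0.01, 0.33, 0.22, 0.43))
})

test_that("projection iterates left multiplication by the matrix", {
  P <- published_matrix()
  tm <- as_transition_matrix(P)
  pi0 <- c(normal_or_under = 1, overweight = 0, obese = 0)
  tr1 <- project(tm, pi0, horizon = 1)
  expect_equal(tr1$prob[tr1$decade == 1], c(0.58, 0.32, 0.10),
               tolerance = 1e-12)
  tr2 <- project(tm, pi0, horizon = 2)
  expect_equal(tr2$prob[tr2$decade == 2], c(0.3906, 0.3614, 0.2480),
               tolerance = 1e-12)
  # identity chain: constant trajectory
  tri <- project(as_transition_matrix(diag(3)), pi0, horizon = 10)
  expect_true(all(tri$prob[tri$state == "normal_or_under"] == 1))
  expect_error(project(tm, c(a = 1, b = 0, c = 0), 2), "State lists")
  expect_error(as_transition_matrix(matrix(0.4, 3, 3)), "sum")
})

test_that("trajectories conserve probability mass and stay non-negative", {
  withr::with_seed(31, {
    for (k in c(3, 4)) {
      for (rep in 1:20) {
        P <- random_stochastic(k)
        pi0 <- stats::rexp(k)
        pi0 <- pi0 / sum(pi0)
        names(pi0) <- weight_states(if (k == 3) "scheme3" else "scheme4")
        tr <- project(as_transition_matrix(P), pi0, horizon = 25)
        sums <- tapply(tr$prob, tr$decade, sum)
        expect_true(all(abs(sums - 1) < 1e-9))
        expect_true(all(tr$prob >= 0))
      }
    }
  })
})

test_that("stationary distribution solves pi P = pi, cross-checked", {
  # rank-one chain: all rows equal r, so pi = r after one step
  r <- c(0.2, 0.3, 0.5)
  Pr <- matrix(r, 3, 3, byrow = TRUE)
  s <- stationary_distribution(as_transition_matrix(Pr))
  expect_equal(s$prob, r, tolerance = 1e-12)

  s3 <- stationary_distribution(as_transition_matrix(published_matrix()))
  expect_equal(s3$prob, c(0.153304, 0.299899, 0.546796), tolerance = 1e-4)
  expect_true(attr(s3, "iterations") >= 1)

  # period-2 chain never converges
  flip <- matrix(c(0, 1, 1, 0), 2, 2)
  tmf <- structure(list(P = flip, states = c("a", "b"),
                        row_mass = c(a = 1, b = 1), scheme = "scheme3"),
                   class = "transition_matrix")
  expect_error(stationary_distribution(tmf, max_iter = 500),
               "periodic|converge")
})

test_that("power iteration agrees with the linear solver on random chains", {
  withr::with_seed(77, {
    for (rep in 1:200) {
      k <- sample(c(3, 4), 1)
      P <- random_stochastic(k)
      tm <- as_transition_matrix(P)
      s <- stationary_distribution(tm)
      expect_lt(max(abs(s$prob - attr(s, "linear_solution"))), 1e-8)
      # fixed point: projecting from pi is constant
      pi_named <- stats::setNames(s$prob, tm$states)
      tr <- project(tm, pi_named / sum(pi_named), horizon = 100)
      expect_lt(max(abs(tr$prob - rep(s$prob, 101))), 1e-8)
    }
  })
})

test_that("rescaling all survey weights leaves estimates unchanged", {
  d <- derive_cohort(generate_cohort(cohort_config(n = 1500, seed = 21)),
                     quiet = TRUE)
  d2 <- d
  d2$survey_weight <- d2$survey_weight * 731.7
  expect_equal(estimate_transition_matrix(d)$P,
               estimate_transition_matrix(d2)$P, tolerance = 1e-14)
  expect_equal(initial_distribution(d)$prob, initial_distribution(d2)$prob,
               tolerance = 1e-14)
})

test_that("the weighted estimator is consistent for the generating matrix", {
  P <- published_matrix()
  n <- 100000
  cfg <- cohort_config(n = n, seed = 88, true_transition_matrix = P)
  d <- derive_cohort(generate_cohort(cfg), quiet = TRUE)
  tm <- estimate_transition_matrix(d)
  n_row <- as.vector(table(d$state_past))
  for (i in 1:3) {
    se <- sqrt(P[i, ] * (1 - P[i, ]) / n_row[i])
    # allow the survey-weight design effect on top of binomial SE
    expect_true(all(abs(tm$P[i, ] - P[i, ]) <= 3 * 1.3 * se + 1e-12))
  }
})

test_that("compounding error follows its closed form", {
  expect_equal(compounding_error(0.05, 10), 1.05^10 - 1, tolerance = 1e-15)
  expect_equal(compounding_error(0, 7), 0)
  expect_equal(compounding_error(0.10, 2), 0.21, tolerance = 1e-12)
  expect_error(compounding_error(-0.1, 2), ">= 0")
})
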