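test_that("a degenerate cohort yields zero-width bands at the point", {
  coh <- constant_cohort(30, weight_now = 95, weight_past = 90)
  d <- derive_cohort(coh, quiet = TRUE)
  # only the obese state is occupied; the two empty origin rows self-loop
  bb <- suppressWarnings(bootstrap_projection(d, B = 40, seed = 4, horizon = 3))
  expect_equal(bb$lower, bb$point, tolerance = 1e-12)
  expect_equal(bb$upper, bb$point, tolerance = 1e-12)
})

test_that("bands are reproducible under a fixed seed", {
  d <- derive_cohort(generate_cohort(cohort_config(n = 400, seed = 14)),
                     quiet = TRUE)
  b1 <- bootstrap_projection(d, B = 60, seed = 99, horizon = 4)
  b2 <- bootstrap_projection(d, B = 60, seed = 99, horizon = 4)
  expect_identical(tibble::as_tibble(b1), tibble::as_tibble(b2))
  b3 <- bootstrap_projection(d, B = 60, seed = 100, horizon = 4)
  expect_false(identical(b1$lower, b3$lower))
})

test_that("bands satisfy ordering, range, and decade-0 bracketing", {
  d <- derive_cohort(generate_cohort(cohort_config(n = 2000, seed = 15)),
                     quiet = TRUE)
  bb <- bootstrap_projection(d, B = 200, seed = 5, horizon = 5)
  expect_true(all(bb$lower <= bb$upper))
  expect_true(all(bb$lower >= 0 & bb$upper <= 1))
  pi0 <- initial_distribution(d)
  at0 <- bb[bb$decade == 0, ]
  expect_true(all(at0$lower <= pi0$prob & pi0$prob <= at0$upper))
})

test_that("point estimates are invariant to record order", {
  d <- derive_cohort(generate_cohort(cohort_config(n = 600, seed = 16)),
                     quiet = TRUE)
  perm <- withr::with_seed(1, sample(nrow(d)))
  dp <- d[perm, ]
  attr(dp, "scheme") <- "scheme3"
  b1 <- bootstrap_projection(d, B = 20, seed = 7, horizon = 2)
  b2 <- bootstrap_projection(dp, B = 20, seed = 7, horizon = 2)
  expect_equal(b1$point, b2$point, tolerance = 1e-12)
})

test_that("replicates with empty origin rows are redrawn and flagged", {
  past <- c(rep("normal_or_under", 25), rep("overweight", 4), "obese")
  now <- c(rep("normal_or_under", 20), rep("obese", 10))
  d <- derived_from_states(past, now)
  expect_warning(
    bb <- bootstrap_projection(d, B = 100, seed = 3, horizon = 2),
    "redrawn"
  )
  expect_gt(attr(bb, "n_redrawn"), 0)
  expect_true(all(abs(tapply(bb$point, bb$decade, sum) - 1) < 1e-9))
})

test_that("band width shrinks as the cohort grows", {
  P <- published_matrix()
  widths <- sapply(c(2000, 20000), function(n) {
    cfg <- cohort_config(n = n, seed = 61, true_transition_matrix = P)
    d <- derive_cohort(generate_cohort(cfg), quiet = TRUE)
    bb <- bootstrap_projection(d, B = 200, seed = 62, horizon = 1)
    at1 <- bb[bb$decade == 1, ]
    stats::median(at1$upper - at1$lower)
  })
  expect_lt(widths[2], widths[1])
})

test_that("stratified runs split the cohort and recover per-stratum truth", {
  # contract: a sex-stratified run yields exactly the two sex strata
  d <- derive_cohort(generate_cohort(cohort_config(n = 800, seed = 17)),
                     quiet = TRUE)
  sr <- stratified_run(d, stratify_by = "sex", B = 20, seed = 8, horizon = 2)
  expect_setequal(names(sr), c("male", "female"))
  td <- tidy(sr)
  expect_true(all(c("stratum", "state", "decade", "point") %in% names(td)))

  # one stratum only: identical to the unstratified run with the same seed
  d1 <- d[d$sex == "male", ]
  attr(d1, "scheme") <- "scheme3"
  sr1 <- stratified_run(d1, stratify_by = "sex", B = 25, seed = 8,
                        horizon = 2)
  un <- bootstrap_projection(d1, B = 25, seed = 8, horizon = 2)
  expect_identical(tibble::as_tibble(sr1$male), tibble::as_tibble(un))

  # two strata generated from different true matrices: each recovered
  Pa <- published_matrix()
  Pb <- matrix(c(0.90, 0.08, 0.02,
                 0.10, 0.80, 0.10,
                 0.05, 0.15, 0.80), 3, byrow = TRUE)
  n <- 4000
  ca <- generate_cohort(cohort_config(n = n, seed = 18,
                                      true_transition_matrix = Pa))
  cb <- generate_cohort(cohort_config(n = n, seed = 19,
                                      true_transition_matrix = Pb))
  ca$sex <- "female"; cb$sex <- "male"
  cb$id <- sub("^S", "T", cb$id)
  both <- derive_cohort(dplyr::bind_rows(ca, cb), quiet = TRUE)
  sr2 <- stratified_run(both, stratify_by = "sex", B = 10, seed = 20,
                        horizon = 1)
  for (sx in c("female", "male")) {
    truth <- if (sx == "female") Pa else Pb
    sub <- both[both$sex == sx, ]
    attr(sub, "scheme") <- "scheme3"
    est <- estimate_transition_matrix(sub)$P
    n_row <- as.vector(table(sub$state_past))
    for (i in 1:3) {
      se <- sqrt(truth[i, ] * (1 - truth[i, ]) / n_row[i])
      expect_true(all(abs(est[i, ] - truth[i, ]) <= 3 * 1.3 * se + 0.005))
    }
    # the stratified point trajectory starts at the stratum's own prevalence
    expect_equal(sr2[[sx]]$point[sr2[[sx]]$decade == 0],
                 initial_distribution(sub)$prob, tolerance = 1e-12)
  }

  # a thin stratum triggers a warning
  thin <- both[c(1:30, (n + 1):(n + 30)), ]
  attr(thin, "scheme") <- "scheme3"
  warns <- testthat::capture_warnings(
    stratified_run(thin, stratify_by = "sex", B = 5, seed = 1, horizon = 1)
  )
  expect_true(any(grepl("only 30 records", warns)))
})
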