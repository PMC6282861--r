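design1_calibration <- function() {
  pop <- population_set(c(0.5, 0.5))
  d <- design_spec(pop, effect_config(c(0.5, 0)),
                   power_definition = "select-target-and-reject",
                   target = "S1")
  calibrate_design(d)
}

test_that("identical seed and configuration reproduce the record stream", {
  cal <- design1_calibration()
  a <- simulate_trials(cal, n_reps = 2000, seed = 99)
  b <- simulate_trials(cal, n_reps = 2000, seed = 99)
  expect_identical(a, b)
  c <- simulate_trials(cal, n_reps = 2000, seed = 100)
  expect_false(identical(a$z_stop, c$z_stop))
})

test_that("records satisfy the stopping-rule invariants", {
  pop <- population_set(c(0.5, 0.5))
  d <- design_spec(pop, effect_config(c(0.5, 0)), stages = 2,
                   lower_bound = "zero", binding = FALSE)
  b <- calibrate_boundaries(d)
  rec <- simulate_trials(d, n = 200, boundaries = b, n_reps = 5e4, seed = 3)
  expect_true(all(rec$z_stop[rec$rejected] >=
                    b$upper[rec$stage[rec$rejected]]))
  early_fut <- rec$stage < 2 & !rec$rejected
  expect_true(all(rec$z_stop[early_fut] <= b$lower[1]))
  # MLE definition: z / information at the stopping stage
  expect_equal(rec$mle_S1[rec$selected == "S1"],
               (rec$z_stop / rec$info_stop)[rec$selected == "S1"],
               tolerance = 1e-12)
})

test_that("empirical FWER at the calibrated single-stage design matches alpha", {
  cal <- design1_calibration()
  rec <- simulate_trials(cal, n_reps = 1e6, seed = 7,
                         effects = effect_config(c(0, 0)))
  expect_lt(abs(mean(rec$rejected) - 0.025), tol_prop(0.025, 1e6))
})

test_that("sufficient-statistics and patient-level modes agree", {
  pop <- population_set(c(0.5, 0.5))
  d <- design_spec(pop, effect_config(c(0.5, 0)), stages = 2,
                   lower_bound = "zero", binding = FALSE)
  b <- calibrate_boundaries(d)
  n_reps <- 1e5
  s <- simulate_trials(d, n = 96, boundaries = b, n_reps = n_reps, seed = 51,
                       mode = "sufficient")
  p <- simulate_trials(d, n = 96, boundaries = b, n_reps = n_reps, seed = 52,
                       mode = "patient")
  # selection proportions
  ps <- mean(s$selected == "S1"); pp <- mean(p$selected == "S1")
  expect_lt(abs(ps - pp), tol_prop(ps, n_reps, two_sided_mc = TRUE))
  # rejection rates and mean estimates
  expect_lt(abs(mean(s$rejected) - mean(p$rejected)),
            tol_prop(mean(s$rejected), n_reps, two_sided_mc = TRUE))
  expect_lt(abs(mean(s$mle_S1) - mean(p$mle_S1)),
            3 * sqrt(var(s$mle_S1) / n_reps * 2))
  # patient mode: the MLE is exactly the difference of arm sample means
  expect_equal(p$mle_S1, p$meandiff_S1, tolerance = 1e-10)
  expect_equal(p$mle_F[p$stage == 1], p$meandiff_F[p$stage == 1],
               tolerance = 1e-10)
})

test_that("mle() returns per-trial estimates and flags frozen populations", {
  pop <- population_set(c(0.5, 0.5))
  d <- design_spec(pop, effect_config(c(0.5, 0)), stages = 2,
                   lower_bound = "zero", binding = FALSE)
  b <- calibrate_boundaries(d)
  rec <- simulate_trials(d, n = 200, boundaries = b, n_reps = 2000, seed = 8)
  expect_warning(est <- mle(rec, "F"), "deselected")
  expect_equal(length(est), 2000)
  # unconditional mean of the S1 estimator in a single-stage design is theta1
  cal <- design1_calibration()
  rec1 <- simulate_trials(cal, n_reps = 2e5, seed = 70)
  e1 <- mle(rec1, "S1")
  expect_lt(abs(mean(e1) - 0.5), 3 * sqrt(var(e1) / length(e1)))
})

test_that("multinomial subgroup counts only perturb summaries slightly", {
  pop <- population_set(c(0.5, 0.5))
  d <- design_spec(pop, effect_config(c(0.5, 0)))
  b <- new_boundaries(2.2, 2.2, "single-stage", TRUE, 0.025)
  fixed <- simulate_trials(d, n = 200, boundaries = b, n_reps = 5e4,
                           seed = 81, mode = "patient")
  rand <- simulate_trials(d, n = 200, boundaries = b, n_reps = 5e4,
                          seed = 82, mode = "patient",
                          random_prevalence = TRUE)
  pf <- mean(fixed$selected == "S1"); pr <- mean(rand$selected == "S1")
  expect_lt(abs(pf - pr), tol_prop(pf, 5e4, two_sided_mc = TRUE) + 0.005)
})
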