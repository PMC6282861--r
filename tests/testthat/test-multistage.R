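test_that("the transition density is the independent-increment Gaussian law", {
  # theta = 0, equal information increments: mean z/sqrt(2), variance 1/2
  z_prev <- 0.7
  dens <- transition_density(seq(-2, 2, 0.5), z_prev, sqrt(2), 1, 0)
  expect_equal(dens, dnorm(seq(-2, 2, 0.5), z_prev / sqrt(2), sqrt(0.5)),
               tolerance = 1e-12)
  expect_error(transition_density(0, 0, 1, 2, 0), "increasing")
  # marginalizing a standard-normal previous stage returns a N(0,1) margin
  marg <- integrate(function(zp) {
    dnorm(zp) * transition_density(0.4, zp, sqrt(2), 1, 0)
  }, -9, 9, rel.tol = 1e-10)$value
  expect_equal(marg, dnorm(0.4), tolerance = 1e-8)
})

test_that("simulated accumulation matches the transition law's moments", {
  set.seed(41)
  n_draws <- 1e6
  theta <- 0.5
  I1 <- 3; I2 <- 3 * sqrt(2) # equal stage sizes
  z1 <- rnorm(n_draws, theta * I1, 1)
  # accumulate an independent second-stage increment
  z_inc <- rnorm(n_draws, theta * sqrt(I2^2 - I1^2), 1)
  z2 <- (I1 * z1 + sqrt(I2^2 - I1^2) * z_inc) / I2
  m_th <- mean(z1) * I1 / I2 + theta * (I2^2 - I1^2) / I2
  expect_lt(abs(mean(z2) - m_th), 3 / sqrt(n_draws) * 2)
  expect_lt(abs(var(z2) - 1), 3 * sqrt(2 / n_draws))
  cond_var_th <- (I2^2 - I1^2) / I2^2
  resid <- z2 - (z1 * I1 / I2 + theta * (I2^2 - I1^2) / I2)
  expect_lt(abs(var(resid) - cond_var_th), 3 * sqrt(2 / n_draws))
})

test_that("single-population two-stage OBF bounds match the classical oracle", {
  pop1 <- population_set(c(1), members = list(1))
  d <- design_spec(pop1, effect_config(0.5), stages = 2,
                   lower_bound = "none", binding = FALSE)
  b <- calibrate_boundaries(d)
  C_oracle <- gs_obf_constant(2, 0.025)
  expect_equal(b$constant, C_oracle, tolerance = 1e-4)
  expect_equal(b$upper, C_oracle * sqrt(2 / 1:2), tolerance = 1e-4)
})

test_that("one-stage multistage machinery degenerates to the single-stage design", {
  pop <- population_set(c(0.5, 0.5))
  d <- design_spec(pop, effect_config(c(0.23, 0), 0.72), stages = 1,
                   power_definition = "reject-any")
  b <- calibrate_boundaries(d)
  expect_equal(b$upper[1], critical_value(d), tolerance = 1e-6)
  tab <- stagewise_probabilities(d, 684, b)
  eff_sum <- sum(tab$probability[tab$decision == "efficacy"])
  C1 <- new_boundaries(b$upper[1], b$upper[1], "single-stage", TRUE, 0.025)
  expect_equal(eff_sum, design_power(d, 684, C1), tolerance = 1e-6)
})

test_that("stage-wise probabilities are a complete partition of the trials", {
  pop <- population_set(c(1, 1, 1) / 3, list(1, 1:2, 1:3))
  d <- design_spec(pop, effect_config(c(0.5, 0, 0)), stages = 2,
                   lower_bound = "zero", binding = FALSE)
  b <- calibrate_boundaries(d)
  tab <- stagewise_probabilities(d, 335, b)
  resolved <- sum(tab$probability[tab$decision != "continue"])
  expect_equal(resolved, 1, tolerance = 1e-5)
  # continuation mass at the final stage is zero
  expect_equal(max(tab$probability[tab$decision == "continue" &
                                     tab$stage == 2]), 0, tolerance = 1e-6)
})

test_that("boundary families behave monotonically", {
  pop <- population_set(c(0.5, 0.5))
  d2 <- design_spec(pop, effect_config(c(0.5, 0)), stages = 2,
                    lower_bound = "zero", binding = FALSE)
  b2 <- calibrate_boundaries(d2)
  expect_true(all(diff(b2$upper) < 0)) # OBF bounds decrease in k
  # the OBF constant grows with the number of candidate populations
  pop1 <- population_set(c(1), members = list(1))
  d1 <- design_spec(pop1, effect_config(0.5), stages = 2,
                    lower_bound = "zero", binding = FALSE)
  expect_gt(b2$constant, calibrate_boundaries(d1)$constant)
  # nonbinding calibration never yields smaller upper bounds than binding
  d2b <- design_spec(pop, effect_config(c(0.5, 0)), stages = 2,
                     lower_bound = "zero", binding = TRUE)
  expect_true(all(b2$upper >= calibrate_boundaries(d2b)$upper - 1e-9))
})

test_that("error-spending bounds match their classical oracle", {
  pop1 <- population_set(c(1), members = list(1))
  # all error at the final stage: no stage-1 stopping, final bound z_{1-a}
  d_all2 <- design_spec(pop1, effect_config(0.5), stages = 2,
                        boundary_family = "error-spending",
                        lower_bound = "none", binding = FALSE,
                        alpha_schedule = c(0, 0.025))
  b_all2 <- error_spending_boundaries(d_all2)
  expect_true(is.infinite(b_all2$upper[1]))
  expect_equal(b_all2$upper[2], qnorm(0.975), tolerance = 1e-5)
  # all error at stage 1: equals the single-stage critical value
  pop <- population_set(c(0.5, 0.5))
  d_first <- design_spec(pop, effect_config(c(0.5, 0)), stages = 2,
                         boundary_family = "error-spending",
                         lower_bound = "none", binding = FALSE,
                         alpha_schedule = c(0.025, 0))
  b_first <- error_spending_boundaries(d_first)
  d_single <- design_spec(pop, effect_config(c(0.5, 0)))
  expect_equal(b_first$upper[1], critical_value(d_single), tolerance = 1e-5)
  # 0.005 / 0.020 split, single population, versus the direct integral oracle
  d_split <- design_spec(pop1, effect_config(0.5), stages = 2,
                         boundary_family = "error-spending",
                         lower_bound = "none", binding = FALSE,
                         alpha_schedule = c(0.005, 0.020))
  b_split <- error_spending_boundaries(d_split)
  oracle <- es_oracle_two_look(0.005, 0.020)
  expect_equal(b_split$upper, oracle, tolerance = 1e-4)
  # infeasible schedules are rejected
  expect_error(design_spec(pop1, effect_config(0.5), stages = 2,
                           boundary_family = "error-spending",
                           alpha_schedule = c(0.01, 0.01)), "sum to")
})

test_that("two-stage FWER at calibrated bounds is recovered by simulation", {
  pop <- population_set(c(0.5, 0.5))
  d <- design_spec(pop, effect_config(c(0.5, 0)), stages = 2,
                   lower_bound = "zero", binding = TRUE)
  b <- calibrate_boundaries(d)
  rec <- simulate_trials(d, n = 300, boundaries = b, n_reps = 1e6, seed = 13,
                         effects = effect_config(c(0, 0)))
  expect_lt(abs(mean(rec$rejected) - 0.025), tol_prop(0.025, 1e6))
})

test_that("the stage-wise sample-size search is consistent and monotone", {
  pop <- population_set(c(0.5, 0.5))
  d <- design_spec(pop, effect_config(c(0.5, 0)), stages = 2,
                   power_definition = "reject-any",
                   lower_bound = "zero", binding = FALSE)
  b <- calibrate_boundaries(d)
  r <- required_stagewise_sample_size(d, b)
  expect_gte(r$achieved_power, 0.8)
  expect_lt(design_power(d, r$n_stage - 1, b), 0.8)
  d_big <- design_spec(pop, effect_config(c(1, 0)), stages = 2,
                       power_definition = "reject-any",
                       lower_bound = "zero", binding = FALSE)
  expect_lt(required_stagewise_sample_size(d_big)$n_stage, r$n_stage)
})
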