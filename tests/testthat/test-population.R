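test_that("information level follows the reciprocal-standard-error convention", {
  expect_equal(information_level(100, 1), 5)
  # unequal explicit arms via allocation: n_T = n_C = 100
  expect_equal(information_level(200, 1), 1 / sqrt(0.02), tolerance = 1e-10)
  expect_equal(information_level(100, 2), 2.5)
  expect_error(information_level(1, 1), "at least 2")
  expect_error(information_level(100, -1), "positive")
  # strictly increasing in n; squared accumulation is additive
  expect_true(information_level(101, 1) > information_level(100, 1))
  expect_equal(information_level(150, 1)^2,
               information_level(100, 1)^2 + information_level(50, 1)^2,
               tolerance = 1e-10)
})

test_that("population sets validate prevalences and member structure", {
  expect_error(population_set(c(0.5, 0.6)), "sum to 1")
  expect_error(population_set(c(1, 0)), "positive")
  expect_error(population_set(c(0.5, 0.5), members = list(1, 1)), "distinct")
  pop <- population_set(c(1, 1, 1) / 3, list(1, 1:2, 1:3))
  expect_equal(pop$labels, c("S1", "S1+2", "F"))
  expect_equal(unname(member_prevalence(pop)), c(1 / 3, 2 / 3, 1))
})

test_that("composite effects are prevalence-weighted averages", {
  pop2 <- population_set(c(0.5, 0.5))
  eff2 <- effect_config(c(0.5, 0))
  expect_equal(composite_effect(pop2, eff2, "F"), 0.25)
  pop3 <- population_set(c(1, 1, 1) / 3, list(1, 1:2, 1:3))
  eff3 <- effect_config(c(0.5, 0, 0))
  expect_equal(composite_effect(pop3, eff3, "F"), 1 / 6, tolerance = 1e-4)
  expect_equal(composite_effect(pop3, eff3, c(1, 2)), 0.25)
  expect_error(composite_effect(pop3, eff3, integer(0)), "nonempty")
  # full-population composite equals sum(lambda * theta) exactly
  for (i in 1:5) {
    lam <- abs(rnorm(3)) + 0.1; lam <- lam / sum(lam)
    th <- rnorm(3)
    popr <- population_set(lam, list(1, 1:2, 1:3))
    expect_equal(composite_effect(popr, effect_config(th), "F"),
                 sum(lam * th), tolerance = 1e-12)
  }
})

test_that("nested correlation is the square root of the prevalence ratio", {
  pop2 <- population_set(c(0.5, 0.5))
  R2 <- correlation_matrix(pop2)
  expect_equal(R2["S1", "F"], sqrt(0.5), tolerance = 1e-10)
  expect_equal(diag(R2), c(S1 = 1, F = 1))
  pop3 <- population_set(c(1, 1, 1) / 3, list(1, 1:2, 1:3))
  R3 <- correlation_matrix(pop3)
  expect_equal(R3["S1", "S1+2"], sqrt(1 / 2), tolerance = 1e-6)
  expect_equal(R3["S1+2", "F"], sqrt(2 / 3), tolerance = 1e-6)
  expect_equal(R3["S1", "F"], sqrt(1 / 3), tolerance = 1e-6)
  # disjoint members are uncorrelated
  popd <- population_set(c(0.3, 0.7), members = list(1, 2))
  expect_equal(correlation_matrix(popd)[1, 2], 0)
  # partial overlap without nesting is rejected
  popx <- population_set(c(0.3, 0.3, 0.4), members = list(1:2, 2:3))
  expect_error(correlation_matrix(popx), "overlap without nesting")
})

test_that("nested correlation matrices are positive semidefinite (J <= 5)", {
  set.seed(11)
  for (J in 2:5) {
    lam <- abs(rnorm(J)) + 0.05; lam <- lam / sum(lam)
    members <- lapply(seq_len(J), function(k) 1:k) # full nested chain
    pop <- population_set(lam, members)
    ev <- eigen(correlation_matrix(pop), symmetric = TRUE,
                only.values = TRUE)$values
    expect_gt(min(ev), -1e-10)
  }
})

test_that("enrichment accumulates all later recruits in the selected population", {
  pop <- population_set(c(0.5, 0.5))
  up <- enrichment_information_update("S1", c(276, 276), pop, sigma = 0.72)
  expect_equal(up$n_selected_cum, c(138, 414))
  expect_equal(up$fraction_selected[2], 0.75)
  expect_equal(up$info_cum[2], sqrt(414) / (2 * 0.72), tolerance = 1e-10)
  upf <- enrichment_information_update("F", c(276, 276), pop, sigma = 0.72)
  expect_equal(upf$fraction_selected[2], 1) # F's own share is everyone
  # selecting F keeps subgroup shares at prevalence: S1 gets half of stage 2
  expect_equal(0.5 * sum(c(276, 276)) / sum(c(276, 276)), 0.5)
})

test_that("patient-level generator reproduces the nested correlation structure", {
  pop <- population_set(c(0.5, 0.5))
  d <- design_spec(pop, effect_config(c(0.3, 0)))
  b <- new_boundaries(2.2, 2.2, "single-stage", TRUE, 0.025)
  rec <- simulate_trials(d, n = 96, boundaries = b, n_reps = 1e5, seed = 21,
                         mode = "patient")
  rho_hat <- cor(rec$z1_S1, rec$z1_F)
  expect_lt(abs(rho_hat - sqrt(0.5)), 3 * (1 - 0.5) / sqrt(1e5))
})
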