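sim_design4 <- function(n_reps = 2e5, seed = 19) {
  pop <- population_set(c(1, 1, 1) / 3, list(1, 1:2, 1:3))
  d <- design_spec(pop, effect_config(c(0.5, 0, 0)), stages = 2,
                   power_definition = "select-target-and-reject",
                   target = "S1", lower_bound = "zero", binding = FALSE)
  b <- calibrate_boundaries(d)
  simulate_trials(d, n = 335, boundaries = b, n_reps = n_reps, seed = seed)
}

test_that("the unconditional single-stage MLE anchors the standardization", {
  pop <- population_set(c(0.5, 0.5))
  d <- design_spec(pop, effect_config(c(0.5, 0)))
  C <- critical_value(d)
  rec <- simulate_trials(d, n = 400,
                         boundaries = new_boundaries(C, C, "single-stage",
                                                     TRUE, 0.025),
                         n_reps = 4e5, seed = 23)
  for (lab in c("S1", "F")) {
    row <- standardized_assessment(rec, lab, "none")
    expect_lt(abs(row$bias_over_se), 3 / sqrt(4e5))
    expect_lt(abs(row$rmse_over_se - 1), 3 / sqrt(2 * 4e5))
    expect_gte(row$rmse_over_se, abs(row$bias_over_se))
  }
})

test_that("stage-wise rows mix exactly into the overall row", {
  rec <- sim_design4()
  for (cc in c("selected", "selected+rejected")) {
    rows <- lapply(c("1", "2", "overall"), function(st) {
      standardized_assessment(rec, "S1", cc, st)
    })
    w <- c(rows[[1]]$n_cell, rows[[2]]$n_cell)
    expect_equal(rows[[3]]$n_cell, sum(w))
    expect_equal(rows[[3]]$bias_over_se,
                 sum(w * c(rows[[1]]$bias_over_se, rows[[2]]$bias_over_se)) /
                   sum(w), tolerance = 1e-10)
    expect_equal(rows[[3]]$rmse_over_se^2,
                 sum(w * c(rows[[1]]$rmse_over_se, rows[[2]]$rmse_over_se)^2) /
                   sum(w), tolerance = 1e-10)
  }
})

test_that("family-wise rows are the selection-weighted mix of member rows", {
  rec <- sim_design4()
  pop <- attr(rec, "pop")
  fw <- familywise_assessment(rec, "selected", "overall")
  per <- lapply(pop$labels, function(l) {
    standardized_assessment(rec, l, "selected", "overall")
  })
  w <- vapply(per, function(r) r$n_cell, integer(1))
  b <- vapply(per, function(r) r$bias_over_se, numeric(1))
  expect_equal(fw$bias_over_se, sum(w * b) / sum(w), tolerance = 1e-10)
  expect_equal(fw$n_cell, sum(w))
})

test_that("reporting conditioning amplifies selection bias under the null", {
  pop <- population_set(c(0.3, 0.7))
  d <- design_spec(pop, effect_config(c(0, 0)))
  C <- critical_value(d)
  rec <- simulate_trials(d, n = 400,
                         boundaries = new_boundaries(C, C, "single-stage",
                                                     TRUE, 0.025),
                         n_reps = 3e5, seed = 29,
                         effects = effect_config(c(0, 0)))
  for (lab in c("S1", "F")) {
    sel <- standardized_assessment(rec, lab, "selected")
    rep_ <- standardized_assessment(rec, lab, "selected+rejected")
    expect_gte(abs(rep_$bias_over_se), abs(sel$bias_over_se))
  }
})

test_that("empty conditioning cells yield missing-value rows with proportion 0", {
  pop <- population_set(c(0.5, 0.5))
  d <- design_spec(pop, effect_config(c(0, 0)))
  b <- new_boundaries(2.24, 2.24, "single-stage", TRUE, 0.025)
  # force selection of F in every trial: S1 cells are empty
  rec <- simulate_trials(d, n = 100, boundaries = b, n_reps = 500, seed = 5,
                         custom_rule = function(z) rep(2L, nrow(z)))
  row <- standardized_assessment(rec, "S1", "selected")
  expect_equal(row$proportion_pct, 0)
  expect_true(is.na(row$bias_over_se) && is.na(row$rmse_over_se))
  tab <- assess_estimates(rec)
  expect_true(any(tab$proportion_pct == 0 & is.na(tab$bias_over_se)))
})

test_that("the assessment table is laid out full population first", {
  rec <- sim_design4(n_reps = 5000)
  tab <- assess_estimates(rec)
  expect_equal(unique(tab$population), c("F", "S1", "S1+2", "familywise"))
  expect_setequal(unique(tab$stage), c("1", "2", "overall"))
  # selection-cell proportions over members partition the replicate set
  sel_overall <- dplyr::filter(tab, conditioning == "selected",
                               stage == "overall",
                               population != "familywise")
  expect_equal(sum(sel_overall$proportion_pct), 100, tolerance = 1e-9)
})
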