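# Standardized bias and root-MSE of the naive MLE. All summaries work on the
# z-scored residual r = (theta_hat - theta) * I, where I is the nominal
# information (reciprocal standard error) of the reported estimator at its
# last observed stage. On this scale the unconditional single-stage MLE has
# bias 0 and root-MSE 1, and stage-wise values combine into overall values by
# proportion-weighted mixing (linear for bias, in squares for root-MSE).

true_member_effects <- function(records, effects = NULL) {
  pop <- attr(records, "pop")
  if (is.null(effects)) effects <- attr(records, "effects")
  stopifnot(inherits(pop, "population_set"), inherits(effects, "effect_config"))
  setNames(member_effects(pop, effects), pop$labels)
}

conditioning_mask <- function(records, label,
                              conditioning = c("none", "selected",
                                               "selected+rejected")) {
  conditioning <- match.arg(conditioning)
  switch(conditioning,
    "none" = rep(TRUE, nrow(records)),
    "selected" = records$selected == label,
    "selected+rejected" = records$selected == label & records$rejected
  )
}

stage_mask <- function(records, stage) {
  if (identical(stage, "overall")) rep(TRUE, nrow(records))
  else records$stage == as.integer(stage)
}

assessment_row <- function(r, in_cell, n_reps, label, conditioning, stage) {
  n_cell <- sum(in_cell)
  if (n_cell == 0) {
    return(tibble::tibble(
      population = label, conditioning = conditioning, stage = as.character(stage),
      bias_over_se = NA_real_, rmse_over_se = NA_real_,
      proportion_pct = 0, n_cell = 0L
    ))
  }
  rr <- r[in_cell]
  tibble::tibble(
    population = label, conditioning = conditioning, stage = as.character(stage),
    bias_over_se = mean(rr), rmse_over_se = sqrt(mean(rr^2)),
    proportion_pct = 100 * n_cell / n_reps, n_cell = n_cell
  )
}

#' Standardized assessment of one estimator in one conditioning cell
#'
#' Computes the standardized bias (mean of \eqn{r = (\hat\theta_s - \theta_s)
#' I_s}) and standardized root-MSE (\eqn{\sqrt{\mathrm{mean}(r^2)}}) of the
#' MLE for population `label`, restricted to the requested conditioning cell
#' (`"none"`: all trials; `"selected"`: trials selecting `label`;
#' `"selected+rejected"`: additionally significant) and stage scope (a stage
#' number, or `"overall"`). Empty cells yield a missing-value row with
#' proportion 0 — the situation where a rarely selected population provides
#' no bias estimate.
#'
#' @param records A tibble from [simulate_trials()].
#' @param label Member label.
#' @param conditioning `"none"`, `"selected"`, or `"selected+rejected"`.
#' @param stage Stage number or `"overall"`.
#' @param effects True effect configuration (defaults to the one stored in
#'   `records`).
#' @return A one-row tibble: `population`, `conditioning`, `stage`,
#'   `bias_over_se`, `rmse_over_se`, `proportion_pct` (share of all
#'   replicates in the cell), `n_cell`.
#' @export
standardized_assessment <- function(records, label,
                                    conditioning = c("none", "selected",
                                                     "selected+rejected"),
                                    stage = "overall", effects = NULL) {
  conditioning <- match.arg(conditioning)
  pop <- attr(records, "pop")
  theta <- true_member_effects(records, effects)
  key <- label_key(pop$labels)[match(label, pop$labels)]
  if (is.na(key)) abort(sprintf("unknown member label '%s'.", label))
  r <- (records[[paste0("mle_", key)]] - theta[[label]]) *
    records[[paste0("info_", key)]]
  in_cell <- conditioning_mask(records, label, conditioning) &
    stage_mask(records, stage)
  assessment_row(r, in_cell, nrow(records), label, conditioning, stage)
}

#' Family-wise standardized assessment
#'
#' As [standardized_assessment()], but in each replicate the residual uses
#' the estimator of whichever population was selected, against that
#' population's true effect — the bias and MSE averaged over all possible
#' selections. `conditioning = "selected"` therefore covers all replicates
#' (every trial selects something) and `"selected+rejected"` the significant
#' ones.
#'
#' @inheritParams standardized_assessment
#' @param conditioning `"selected"` or `"selected+rejected"`.
#' @return A one-row tibble as in [standardized_assessment()], with
#'   `population = "familywise"`.
#' @export
familywise_assessment <- function(records,
                                  conditioning = c("selected",
                                                   "selected+rejected"),
                                  stage = "overall", effects = NULL) {
  conditioning <- match.arg(conditioning)
  theta <- true_member_effects(records, effects)
  r <- (records$z_stop / records$info_stop - theta[records$selected]) *
    records$info_stop
  in_cell <- stage_mask(records, stage) &
    (conditioning == "selected" | records$rejected)
  assessment_row(r, in_cell, nrow(records), "familywise", conditioning, stage)
}

#' Full estimator-assessment table
#'
#' Standardized bias / root-MSE of every candidate population's MLE under
#' the three conditioning situations (no conditioning, selection, selection
#' plus rejection), per stopping stage and overall, with the family-wise
#' rows appended. Row order follows the reporting layout: full population
#' first (if present), then the remaining members in priority order, then
#' family-wise.
#'
#' @param records A tibble from [simulate_trials()].
#' @param effects True effect configuration (defaults to the one stored in
#'   `records`).
#' @param stages Stage scopes to report; defaults to each stage plus
#'   `"overall"` for multistage records, `"overall"` alone for single-stage.
#' @return A tibble, one row per population x conditioning x stage scope.
#' @examples
#' pop <- population_set(c(0.5, 0.5))
#' d <- design_spec(pop, effect_config(c(0.5, 0)))
#' b <- new_boundaries(2.2, 2.2, "single-stage", TRUE, 0.025)
#' sim <- simulate_trials(d, n = 200, boundaries = b, n_reps = 500, seed = 1)
#' assess_estimates(sim)
#' @export
assess_estimates <- function(records, effects = NULL, stages = NULL) {
  pop <- attr(records, "pop")
  stopifnot(inherits(pop, "population_set"))
  K <- max(records$stage)
  if (is.null(stages)) {
    stages <- if (K > 1) c(as.character(seq_len(K)), "overall") else "overall"
  }
  labels <- pop$labels
  full <- labels[vapply(pop$members, function(m) length(m) == pop$J, logical(1))]
  ordered <- c(full, setdiff(labels, full))
  per_pop <- purrr::map_dfr(ordered, function(lab) {
    purrr::map_dfr(c("none", "selected", "selected+rejected"), function(cc) {
      purrr::map_dfr(stages, function(st) {
        standardized_assessment(records, lab, cc, st, effects)
      })
    })
  })
  fw <- purrr::map_dfr(c("selected", "selected+rejected"), function(cc) {
    purrr::map_dfr(stages, function(st) {
      familywise_assessment(records, cc, st, effects)
    })
  })
  dplyr::bind_rows(per_pop, fw)
}
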