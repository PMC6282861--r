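# Planning-level comparison of evaluation strategies for a two-subgroup
# question: separate per-subgroup studies (with or without multiplicity
# adjustment), a single-stage selection design, and a two-stage enrichment
# design. Reports total sample size, maximal FWER, the share of patients
# studied in the truly superior subgroup, and trial duration.

#' Plan separate per-subgroup studies
#'
#' Classical two-arm normal sample size per study,
#' \eqn{n_{arm} = \lceil 2\sigma^2 (z_{1-\alpha'} + z_{1-\beta})^2 /
#' \delta^2 \rceil} with \eqn{\alpha' = \alpha} (no adjustment) or
#' \eqn{\alpha / G} (Bonferroni over `n_groups` studies). The maximal FWER
#' of `G` independent unadjusted studies is \eqn{1 - (1-\alpha')^G}.
#'
#' @param delta Clinically relevant treatment difference.
#' @param sigma Outcome standard deviation.
#' @param alpha One-sided significance level per study.
#' @param power Target power per study.
#' @param n_groups Number of subgroup studies.
#' @param multiplicity `"none"` or `"bonferroni"`.
#' @return A tibble with `strategy`, `n_total`, `max_fwer`, `n_per_study`.
#' @examples
#' separate_studies_plan(0.23, 0.72)
#' @export
separate_studies_plan <- function(delta, sigma, alpha = 0.025, power = 0.8,
                                  n_groups = 2,
                                  multiplicity = c("none", "bonferroni")) {
  multiplicity <- match.arg(multiplicity)
  a <- if (multiplicity == "bonferroni") alpha / n_groups else alpha
  n_arm <- ceiling(2 * sigma^2 * (qnorm(1 - a) + qnorm(power))^2 / delta^2)
  tibble::tibble(
    strategy = paste0("separate-studies",
                      if (multiplicity == "bonferroni") "-bonferroni" else ""),
    n_total = n_groups * 2 * n_arm,
    max_fwer = 1 - (1 - a)^n_groups,
    n_per_study = 2 * n_arm
  )
}

#' Trial duration
#'
#' Recruitment time plus the endpoint follow-up delay. Each stage recruits
#' at the base rate scaled by the prevalence of the population recruited
#' from (stage 1: the full population; enriched stages: the selected
#' population). Interim-analysis activities overlap continued conduct and do
#' not extend the duration.
#'
#' @param n_stage Per-stage recruited patient totals.
#' @param rate Recruitment rate in the full population, patients/month.
#' @param delay Time from last recruit to primary endpoint, months.
#' @param stage_prevalence Prevalence of the population each stage recruits
#'   from (same length as `n_stage`, default all 1).
#' @return Duration in months.
#' @examples
#' trial_duration(684, rate = 25, delay = 3) # single stage
#' trial_duration(c(276, 276), 25, 3, c(1, 0.5)) # enriched to a 50% subgroup
#' @export
trial_duration <- function(n_stage, rate, delay = 0,
                           stage_prevalence = rep(1, length(n_stage))) {
  if (rate <= 0) abort("`rate` must be positive.")
  sum(n_stage / (rate * stage_prevalence)) + delay
}

#' Percentage of patients studied in the superior subgroup
#'
#' @param n_stage Per-stage recruited totals.
#' @param superior_fraction Fraction of each stage's recruits belonging to
#'   the truly superior subgroup (e.g. its prevalence at stage 1; 1 after
#'   enrichment to it).
#' @return Percentage in \[0, 100\].
#' @examples
#' percent_superior(c(276, 276), c(0.5, 1)) # 75
#' @export
percent_superior <- function(n_stage, superior_fraction) {
  100 * sum(n_stage * superior_fraction) / sum(n_stage)
}

#' Compare evaluation strategies for a two-subgroup question
#'
#' Reproduces the planning comparison for one predictive-biomarker subgroup
#' versus the full population: (i) separate per-subgroup studies, optionally
#' Bonferroni-adjusted, (ii) a single-stage selection design over
#' \{S1, F\}, and (iii) a two-stage enrichment design with O'Brien-Fleming
#' efficacy bounds and futility bound zero, the best-performing population
#' selected at the halfway point. Sample sizes for (ii) and (iii) come from
#' the FWER-calibrated searches with power to reject any false null.
#'
#' @param delta Treatment difference in the benefiting subgroup.
#' @param sigma Outcome standard deviation.
#' @param prevalence Prevalence of the benefiting subgroup.
#' @param alpha One-sided FWER level.
#' @param power Target power.
#' @param rate Recruitment rate, patients/month.
#' @param delay Endpoint follow-up, months.
#' @param bonferroni Include the Bonferroni separate-studies variant?
#' @return A tibble with one row per strategy (two rows for the two-stage
#'   design's selection paths): `strategy`, `max_fwer`, `n_total`,
#'   `pct_superior`, `duration_months`, `path`.
#' @examples
#' \donttest{
#' compare_strategies(0.23, 0.72, prevalence = 0.5, rate = 25, delay = 3)
#' }
#' @export
compare_strategies <- function(delta, sigma, prevalence = 0.5, alpha = 0.025,
                               power = 0.8, rate = 25, delay = 3,
                               bonferroni = TRUE) {
  sep <- separate_studies_plan(delta, sigma, alpha, power)
  rows <- list(tibble::tibble(
    strategy = "separate-studies", max_fwer = sep$max_fwer,
    n_total = sep$n_total, pct_superior = percent_superior(sep$n_total, 0.5),
    duration_months = trial_duration(sep$n_total, rate, delay), path = "-"
  ))
  if (bonferroni) {
    sepb <- separate_studies_plan(delta, sigma, alpha, power,
                                  multiplicity = "bonferroni")
    rows <- c(rows, list(tibble::tibble(
      strategy = "separate-studies-bonferroni", max_fwer = sepb$max_fwer,
      n_total = sepb$n_total,
      pct_superior = percent_superior(sepb$n_total, 0.5),
      duration_months = trial_duration(sepb$n_total, rate, delay), path = "-"
    )))
  }
  pop <- population_set(c(prevalence, 1 - prevalence))
  eff <- effect_config(c(delta, 0), sigma)
  d1 <- design_spec(pop, eff, alpha = alpha, beta = 1 - power,
                    power_definition = "reject-any")
  r1 <- required_sample_size(d1)
  rows <- c(rows, list(tibble::tibble(
    strategy = "single-stage", max_fwer = alpha, n_total = r1$n_total,
    pct_superior = percent_superior(r1$n_total, prevalence),
    duration_months = trial_duration(r1$n_total, rate, delay), path = "-"
  )))
  d2 <- design_spec(pop, eff, alpha = alpha, beta = 1 - power, stages = 2,
                    power_definition = "reject-any",
                    lower_bound = "zero", binding = FALSE)
  r2 <- required_stagewise_sample_size(d2)
  ns <- rep(r2$n_stage, 2)
  rows <- c(rows, list(
    tibble::tibble(
      strategy = "two-stage", max_fwer = alpha, n_total = r2$n_total,
      pct_superior = percent_superior(ns, c(prevalence, prevalence)),
      duration_months = trial_duration(ns, rate, delay, c(1, 1)),
      path = "full population selected"
    ),
    tibble::tibble(
      strategy = "two-stage", max_fwer = alpha, n_total = r2$n_total,
      pct_superior = percent_superior(ns, c(prevalence, 1)),
      duration_months = trial_duration(ns, rate, delay, c(1, prevalence)),
      path = "subgroup selected"
    )
  ))
  dplyr::bind_rows(rows)
}
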