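#' Specify a subpopulation-selection design
#'
#' Bundles the candidate population structure, the effect configuration used
#' for powering, the error rates, the number of stages and the boundary /
#' selection conventions into a design specification consumed by
#' [critical_value()], [calibrate_boundaries()], [required_sample_size()],
#' [calibrate_design()] and [simulate_trials()].
#'
#' @param pop A [population_set()].
#' @param effects An [effect_config()] giving the alternative used for
#'   powering (typically exactly one subgroup carries the assumed effect
#'   \eqn{\delta}, all others zero).
#' @param alpha One-sided family-wise error level (default 0.025).
#' @param beta Type-II error rate; power is `1 - beta` (default 0.2).
#' @param stages Number of analysis stages `K` (1 = fixed design).
#' @param power_definition `"select-target-and-reject"` powers the event that
#'   the target member is selected and its null rejected;
#'   `"reject-any"` powers any rejection among the members in `interest`.
#' @param target Member label powered under `"select-target-and-reject"`
#'   (default: first member).
#' @param interest Member labels forming the interest set under
#'   `"reject-any"` (default: all members).
#' @param boundary_family `"obf"` (O'Brien-Fleming upper bounds
#'   \eqn{C\sqrt{K/k}}), `"error-spending"`, or `"no-stage1-stopping"`
#'   (stage 1 used for selection only).
#' @param lower_bound Futility rule for stages before the last: `"zero"`
#'   (stop if the statistic falls below 0) or `"none"`.
#' @param binding Should the futility bounds be enforced during error-rate
#'   calibration? Nonbinding calibration replaces them by \eqn{-\infty}.
#' @param selection Selection rule name: `"max"` or `"sequential3"`.
#' @param allocation Treatment:control allocation ratio (default 1).
#' @param alpha_schedule Per-stage error spend (sums to `alpha`); only used
#'   with `boundary_family = "error-spending"`.
#' @return An object of class `design_spec`.
#' @examples
#' pop <- population_set(c(0.5, 0.5))
#' design_spec(pop, effect_config(c(0.23, 0), sigma = 0.72),
#'             power_definition = "reject-any")
#' @export
design_spec <- function(pop, effects, alpha = 0.025, beta = 0.2, stages = 1,
                        power_definition = c("select-target-and-reject",
                                             "reject-any"),
                        target = pop$labels[1], interest = pop$labels,
                        boundary_family = c("obf", "error-spending",
                                            "no-stage1-stopping"),
                        lower_bound = c("zero", "none"), binding = TRUE,
                        selection = c("max", "sequential3"),
                        allocation = 1, alpha_schedule = NULL) {
  stopifnot(inherits(pop, "population_set"), inherits(effects, "effect_config"))
  if (!(alpha > 0 && alpha < 0.5)) abort("`alpha` must lie in (0, 0.5).")
  if (!(beta > 0 && beta < 1)) abort("`beta` must lie in (0, 1).")
  stages <- as.integer(stages)
  if (stages < 1) abort("`stages` must be at least 1.")
  power_definition <- match.arg(power_definition)
  boundary_family <- match.arg(boundary_family)
  lower_bound <- match.arg(lower_bound)
  selection <- match.arg(selection)
  if (!target %in% pop$labels) abort("`target` must be a member label.")
  if (!all(interest %in% pop$labels)) {
    abort("`interest` must be member labels.")
  }
  if (!is.null(alpha_schedule)) {
    if (length(alpha_schedule) != stages || any(alpha_schedule < 0) ||
        abs(sum(alpha_schedule) - alpha) > 1e-12) {
      abort("`alpha_schedule` must be nonnegative, length `stages`, and sum to `alpha`.")
    }
  }
  structure(
    list(pop = pop, effects = effects, alpha = alpha, beta = beta,
         stages = stages, power_definition = power_definition,
         target = target, interest = interest,
         boundary_family = boundary_family, lower_bound = lower_bound,
         binding = binding, selection = selection, allocation = allocation,
         alpha_schedule = alpha_schedule),
    class = "design_spec"
  )
}

#' @export
print.design_spec <- function(x, ...) {
  cat("<design_spec>", length(x$pop$labels), "candidate populations,",
      x$stages, "stage(s)\n")
  cat("  alpha =", x$alpha, " power =", 1 - x$beta,
      " definition =", x$power_definition,
      if (x$power_definition == "select-target-and-reject") {
        paste0("(target ", x$target, ")")
      } else "", "\n")
  if (x$stages > 1) {
    cat("  boundaries:", x$boundary_family, " lower =", x$lower_bound,
        if (x$binding) "(binding)" else "(nonbinding)", "\n")
  }
  invisible(x)
}

null_effects <- function(design) {
  effect_config(rep(0, design$pop$J), design$effects$sigma)
}

#' Critical value of a single-stage selection design
#'
#' Finds the shared critical value \eqn{C_\alpha} with
#' \eqn{\sum_w \int_{C}^{\infty} p(z, w; \Theta_0)\,dz = \alpha}
#' by bracketed root search between the single-test quantile
#' \eqn{z_{1-\alpha}} and just above the Bonferroni quantile
#' \eqn{z_{1-\alpha/|S|}}. Weak control at the global null implies strong
#' control for maximum-statistic selection. The value does not depend on the
#' sample size: under the global null the statistics' joint law is fixed by
#' the prevalences alone.
#'
#' @param design A [design_spec()] with `stages = 1`.
#' @param tol Root-search tolerance on the critical value (default 1e-8).
#' @return The critical value, a scalar.
#' @examples
#' pop <- population_set(c(0.5, 0.5))
#' d <- design_spec(pop, effect_config(c(0.23, 0), 0.72))
#' critical_value(d)
#' @export
critical_value <- function(design, tol = 1e-8) {
  stopifnot(inherits(design, "design_spec"))
  m <- length(design$pop$labels)
  ctx <- selection_context(design$pop, null_effects(design), n = 100,
                           design$allocation)
  f <- function(C) {
    sum(vapply(seq_len(m), function(i) integrate_density(i, ctx, lower = C),
               numeric(1))) - design$alpha
  }
  lo <- qnorm(1 - design$alpha)
  if (m == 1) return(lo)
  hi <- qnorm(1 - design$alpha / m) + 0.5
  uniroot(f, c(lo - 1e-9, hi), tol = tol)$root
}

# single-stage power at full-population size n, critical value C
single_stage_power <- function(design, n, C, effects = design$effects) {
  ctx <- selection_context(design$pop, effects, n, design$allocation)
  labels <- design$pop$labels
  if (design$power_definition == "select-target-and-reject") {
    i <- match(design$target, labels)
    return(integrate_density(i, ctx, lower = C))
  }
  sum(vapply(match(design$interest, labels), function(i) {
    integrate_density(i, ctx, lower = C)
  }, numeric(1)))
}

#' Power of a calibrated design
#'
#' Probability of the powered event at full-population per-stage size `n`
#' under effect configuration `effects`. For a single-stage design this is
#' the integral of the selection density above the critical value (for the
#' target member, or summed over the interest set under `"reject-any"`); for
#' multistage designs efficacy-stopping probabilities accumulate over stages.
#'
#' @param design A [design_spec()].
#' @param n Per-stage full-population sample size (scalar: equal stages; or
#'   vector of length `stages`).
#' @param boundaries A `boundaries` object from [calibrate_boundaries()] or
#'   [error_spending_boundaries()]; computed on the fly if `NULL`.
#' @param effects Effect configuration (default: the design's powering
#'   alternative).
#' @return A probability.
#' @export
design_power <- function(design, n, boundaries = NULL,
                         effects = design$effects) {
  stopifnot(inherits(design, "design_spec"))
  n_stage <- rep_len(n, design$stages)
  if (is.null(boundaries)) boundaries <- calibrate_boundaries(design)
  if (design$stages == 1) {
    return(single_stage_power(design, n_stage[1], boundaries$upper[1],
                              effects))
  }
  tab <- stagewise_probabilities(design, n_stage, boundaries, effects)
  eff <- dplyr::filter(tab, .data$decision == "efficacy")
  if (design$power_definition == "select-target-and-reject") {
    sum(eff$probability[eff$member == design$target])
  } else {
    sum(eff$probability[eff$member %in% design$interest])
  }
}

# smallest integer n with f(n) >= target, given monotone f; continuous
# bisection then integer refinement
search_sample_size <- function(f, target, n_lo = 8, n_max = 1e7) {
  hi <- n_lo
  while (f(hi) < target) {
    n_lo <- hi
    hi <- hi * 2
    if (hi > n_max) abort("power target unattainable within the search limit.")
  }
  lo <- n_lo
  while (hi - lo > 0.5) {
    mid <- (lo + hi) / 2
    if (f(mid) >= target) hi <- mid else lo <- mid
  }
  n <- ceiling(hi)
  while (n > 2 && f(n - 1) >= target) n <- n - 1
  while (f(n) < target) n <- n + 1
  n
}

#' Required sample size of a single-stage design
#'
#' Smallest integer full-population sample size whose power reaches
#' `1 - beta` at the calibrated critical value. Subgroup sizes are treated as
#' continuous (\eqn{\lambda_j n}) inside the information formulas; only the
#' full-population total is rounded (up).
#'
#' @param design A [design_spec()] with `stages = 1`.
#' @return A tibble with `n_total`, `critical_value`, and `achieved_power`.
#' @examples
#' \donttest{
#' pop <- population_set(c(0.5, 0.5))
#' d <- design_spec(pop, effect_config(c(0.23, 0), 0.72),
#'                  power_definition = "reject-any")
#' required_sample_size(d)
#' }
#' @export
required_sample_size <- function(design) {
  stopifnot(inherits(design, "design_spec"))
  if (design$stages != 1) {
    abort("use required_stagewise_sample_size() for multistage designs.")
  }
  C <- critical_value(design)
  f <- function(n) single_stage_power(design, n, C)
  n <- search_sample_size(f, 1 - design$beta)
  tibble::tibble(n_total = n, critical_value = C, achieved_power = f(n))
}
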