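# Multistage machinery: transition densities along the accumulating
# statistic, stage-wise stopping probabilities by recursive quadrature,
# boundary calibration (O'Brien-Fleming / error spending / no-stage-1
# -stopping) and the stage-wise sample-size search.

#' Construct a boundaries object
#'
#' Low-level constructor for stopping boundaries; most users obtain
#' boundaries from [calibrate_boundaries()] or
#' [error_spending_boundaries()]. The final-stage lower bound should equal
#' the final upper bound (the last analysis forces a decision).
#'
#' @param upper,lower Numeric vectors of per-stage upper (efficacy) and
#'   lower (futility) bounds.
#' @param family Character tag for the boundary family.
#' @param binding Are the futility bounds enforced in calibration?
#' @param alpha One-sided FWER level the bounds are meant to protect.
#' @param constant Free boundary constant, if the family has one.
#' @return An object of class `boundaries`.
#' @export
new_boundaries <- function(upper, lower, family, binding, alpha,
                           constant = NA_real_) {
  K <- length(upper)
  stopifnot(length(lower) == K)
  structure(
    list(upper = upper, lower = lower, family = family, binding = binding,
         alpha = alpha, constant = constant, stages = K),
    class = "boundaries"
  )
}

#' @export
print.boundaries <- function(x, ...) {
  cat("<boundaries>", x$family, "K =", x$stages,
      if (x$binding) "(binding lower)" else "(nonbinding lower)", "\n")
  cat("  upper:", paste(signif(x$upper, 6), collapse = ", "), "\n")
  cat("  lower:", paste(signif(x$lower, 6), collapse = ", "), "\n")
  invisible(x)
}

#' @method tidy boundaries
#' @export
tidy.boundaries <- function(x, ...) {
  tibble::tibble(stage = seq_len(x$stages), upper = x$upper, lower = x$lower)
}

#' Conditional density of the accumulated statistic
#'
#' Given the accumulated statistic \eqn{Z^{1:(k-1)} = z_{prev}} at
#' information \eqn{I_{prev}}, the next accumulated statistic at information
#' \eqn{I_{curr}} is normal with mean
#' \eqn{z_{prev} I_{prev}/I_{curr} + \theta (I_{curr}^2 - I_{prev}^2)/I_{curr}}
#' and variance \eqn{(I_{curr}^2 - I_{prev}^2)/I_{curr}^2} — the unique
#' Gaussian law consistent with unit-variance margins and independent
#' stage-wise increments.
#'
#' @param z Value(s) of the current accumulated statistic.
#' @param z_prev Value of the previous accumulated statistic.
#' @param info,info_prev Accumulated information levels, `info > info_prev`.
#' @param theta True effect of the followed population.
#' @return Density value(s).
#' @export
transition_density <- function(z, z_prev, info, info_prev, theta) {
  if (!(info > info_prev && info_prev > 0)) {
    abort("need `info > info_prev > 0` (strictly increasing information).")
  }
  v <- (info^2 - info_prev^2) / info^2
  m <- z_prev * info_prev / info + theta * (info^2 - info_prev^2) / info
  dnorm(z, mean = m, sd = sqrt(v))
}

# Stage-wise stopping probabilities for one member, by grid propagation.
# Returns list(eff = K-vector, fut = K-vector). lower/upper are the bounds
# actually applied (use -Inf lower for nonbinding calibration).
stagewise_member <- function(design, n_stage, i, upper, lower,
                             effects, nodes = 256L) {
  pop <- design$pop
  K <- length(n_stage)
  ctx <- selection_context(pop, effects, n_stage[1], design$allocation)
  w <- pop$labels[i]
  I <- accumulated_information(pop, effects$sigma, n_stage, w,
                               design$allocation)
  theta_w <- composite_effect(pop, effects, w)
  mu1 <- ctx$mu[i]
  eff <- fut <- numeric(K)
  eff[1] <- if (is.finite(upper[1])) {
    integrate_density(i, ctx, lower = upper[1])
  } else 0
  fut[1] <- if (K > 1 && lower[1] > -Inf) {
    integrate_density(i, ctx, upper = lower[1])
  } else if (K == 1) {
    integrate_density(i, ctx, upper = upper[1])
  } else 0
  if (K == 1) return(list(eff = eff, fut = fut))
  gl <- gauss_legendre(nodes)
  lo <- max(lower[1], mu1 - 8.5)
  hi <- min(upper[1], mu1 + 8.5)
  if (lo >= hi) return(list(eff = eff, fut = fut))
  half <- (hi - lo) / 2
  z <- half * gl$nodes + (hi + lo) / 2
  g <- half * gl$weights * joint_density_ctx(z, i, ctx)
  for (k in 2:K) {
    v <- (I[k]^2 - I[k - 1]^2) / I[k]^2
    s <- sqrt(v)
    m <- z * I[k - 1] / I[k] + theta_w * (I[k]^2 - I[k - 1]^2) / I[k]
    eff[k] <- sum(g * pnorm((upper[k] - m) / s, lower.tail = FALSE))
    fut[k] <- sum(g * pnorm((lower[k] - m) / s))
    if (k < K) {
      mu_k <- theta_w * I[k]
      lo <- max(lower[k], mu_k - 8.5)
      hi <- min(upper[k], mu_k + 8.5)
      if (lo >= hi) break
      half <- (hi - lo) / 2
      z_new <- half * gl$nodes + (hi + lo) / 2
      dens <- vapply(seq_along(z_new), function(j) {
        sum(g * dnorm((z_new[j] - m) / s) / s)
      }, numeric(1))
      g <- half * gl$weights * dens
      z <- z_new
    }
  }
  list(eff = eff, fut = fut)
}

#' Stage-wise stopping probabilities of a multistage selection design
#'
#' For every candidate population and stage, the probability of stopping for
#' efficacy or futility (and of continuing), computed by recursive quadrature
#' of the selection density propagated through the group-sequential
#' transition densities. Probabilities are joint with the selection event, so
#' efficacy + futility sums over all members and stages total 1.
#'
#' @param design A [design_spec()].
#' @param n Per-stage full-population size (scalar or length-`stages`).
#' @param boundaries A `boundaries` object.
#' @param effects Effect configuration (default: the design's alternative).
#' @return A tibble with columns `member`, `stage`, `decision`
#'   (`"efficacy"`, `"futility"`, `"continue"`), and `probability`.
#' @export
stagewise_probabilities <- function(design, n, boundaries,
                                    effects = design$effects) {
  stopifnot(inherits(design, "design_spec"))
  n_stage <- rep_len(n, design$stages)
  labels <- design$pop$labels
  K <- design$stages
  purrr::map_dfr(seq_along(labels), function(i) {
    res <- stagewise_member(design, n_stage, i, boundaries$upper,
                            boundaries$lower, effects)
    cont <- numeric(K)
    sel <- NA_real_
    # continuation mass = selection prob minus everything resolved so far
    tot <- cumsum(res$eff + res$fut)
    ctx <- selection_context(design$pop, effects, n_stage[1],
                             design$allocation)
    sel <- integrate_density(i, ctx)
    cont <- pmax(sel - tot, 0)
    tibble::tibble(
      member = labels[i],
      stage = rep(seq_len(K), 3),
      decision = rep(c("efficacy", "futility", "continue"), each = K),
      probability = c(res$eff, res$fut, cont)
    )
  })
}

#' Probability of one stage-wise decision
#'
#' Scalar accessor over [stagewise_probabilities()].
#'
#' @inheritParams stagewise_probabilities
#' @param w Member label.
#' @param k Stage index.
#' @param decision `"efficacy"`, `"futility"`, or `"continue"`.
#' @return A probability.
#' @export
stagewise_probability <- function(design, n, boundaries, w, k,
                                  decision = c("efficacy", "futility",
                                               "continue"),
                                  effects = design$effects) {
  decision <- match.arg(decision)
  tab <- stagewise_probabilities(design, n, boundaries, effects)
  row <- dplyr::filter(tab, .data$member == w, .data$stage == k,
                       .data$decision == !!decision)
  if (nrow(row) != 1) abort("no such member/stage combination.")
  row$probability
}

# lower bounds implied by the design's futility rule, given upper bounds
design_lower_bounds <- function(design, upper) {
  K <- design$stages
  if (K == 1) return(upper)
  low <- if (design$lower_bound == "zero") rep(0, K) else rep(-Inf, K)
  if (design$boundary_family == "no-stage1-stopping") low[1] <- -Inf
  low[K] <- upper[K]
  low
}

# FWER of given bounds under the global null (binding flag respected)
boundary_fwer <- function(design, n_stage, upper, lower) {
  eff0 <- null_effects(design)
  cal_lower <- if (design$binding) lower else {
    c(rep(-Inf, design$stages - 1), upper[design$stages])
  }
  sum(vapply(seq_along(design$pop$labels), function(i) {
    sum(stagewise_member(design, n_stage, i, upper, cal_lower, eff0)$eff)
  }, numeric(1)))
}

#' Calibrate group-sequential boundaries for a selection design
#'
#' Tunes the single free boundary constant so that the sum over members and
#' stages of efficacy-stopping probabilities under the global null equals
#' `alpha`. For the O'Brien-Fleming family the upper bounds are
#' \eqn{C_{OBF}\sqrt{K/k}}; for `"no-stage1-stopping"` the stage-1 bounds
#' are infinite (stage 1 only selects) and the constant scales the remaining
#' OBF-shaped bounds. Futility bounds follow the design's `lower_bound` rule
#' and are honoured during calibration only when `binding = TRUE`. Because
#' the global-null law depends only on prevalences and the relative stage
#' sizes, the calibrated bounds do not change with the absolute sample size.
#'
#' @param design A [design_spec()].
#' @param n_stage Relative per-stage sizes (default equal stages).
#' @param tol Tolerance on the attained error rate (default 1e-5 is imposed
#'   via a tighter root tolerance on the constant).
#' @return A `boundaries` object.
#' @examples
#' \donttest{
#' pop <- population_set(c(0.5, 0.5), members = list(1))
#' d <- design_spec(pop, effect_config(c(0.5, 0)), stages = 2,
#'                  lower_bound = "none", binding = FALSE)
#' calibrate_boundaries(d)
#' }
#' @export
calibrate_boundaries <- function(design, n_stage = NULL, tol = 1e-7) {
  stopifnot(inherits(design, "design_spec"))
  K <- design$stages
  if (is.null(n_stage)) n_stage <- rep(1000, K)
  n_stage <- rep_len(n_stage, K)
  m <- length(design$pop$labels)
  if (K == 1) {
    C <- critical_value(design)
    return(new_boundaries(C, C, "single-stage", design$binding,
                          design$alpha, C))
  }
  if (design$boundary_family == "error-spending") {
    return(error_spending_boundaries(design, design$alpha_schedule, n_stage))
  }
  shape <- sqrt(K / seq_len(K))
  if (design$boundary_family == "no-stage1-stopping") shape[1] <- Inf
  f <- function(C) {
    upper <- C * shape
    lower <- design_lower_bounds(design, upper)
    boundary_fwer(design, n_stage, upper, lower) - design$alpha
  }
  lo <- qnorm(1 - design$alpha) - 0.7
  hi <- qnorm(1 - design$alpha / (m * K)) + 1
  C <- uniroot(f, c(lo, hi), tol = tol)$root
  upper <- C * shape
  new_boundaries(upper, design_lower_bounds(design, upper),
                 design$boundary_family, design$binding, design$alpha, C)
}

#' Error-spending boundaries
#'
#' Solves the upper bounds stage by stage so that the cumulative efficacy
#' probability under the global null through stage `k` equals
#' \eqn{\sum_{i\le k}\alpha_i}, with earlier bounds held fixed. Bounds are
#' shared by all candidate populations. A zero first-stage spend yields an
#' infinite stage-1 bound (the no-stage-1-stopping design).
#'
#' @param design A [design_spec()].
#' @param alpha_schedule Nonnegative per-stage spends summing to the design
#'   `alpha` (defaults to the design's `alpha_schedule`).
#' @param n_stage Relative per-stage sizes (default equal).
#' @return A `boundaries` object.
#' @export
error_spending_boundaries <- function(design,
                                      alpha_schedule = design$alpha_schedule,
                                      n_stage = NULL) {
  stopifnot(inherits(design, "design_spec"))
  K <- design$stages
  if (is.null(n_stage)) n_stage <- rep(1000, K)
  n_stage <- rep_len(n_stage, K)
  if (is.null(alpha_schedule)) abort("`alpha_schedule` is required.")
  if (length(alpha_schedule) != K || any(alpha_schedule < 0) ||
      abs(sum(alpha_schedule) - design$alpha) > 1e-12) {
    abort("`alpha_schedule` must be nonnegative, length K, sum to alpha.")
  }
  cum_target <- cumsum(alpha_schedule)
  if (cum_target[K] <= 0) abort("infeasible schedule: no error to spend.")
  upper <- rep(Inf, K)
  m <- length(design$pop$labels)
  for (k in seq_len(K)) {
    if (alpha_schedule[k] <= 0) {
      # no spend at this stage: no rejection opportunity there
      upper[k] <- Inf
      next
    }
    g <- function(C) {
      up <- upper; up[k] <- C
      low <- design_lower_bounds(design, up)
      up_k <- up[seq_len(k)]
      low_k <- low[seq_len(k)]
      if (k < K) low_k[k] <- if (design$lower_bound == "zero" &&
                                 design$binding) 0 else -Inf
      dsub <- design
      dsub$stages <- k
      sum(vapply(seq_len(m), function(i) {
        sum(stagewise_member(dsub, n_stage[seq_len(k)], i, up_k, low_k,
                             null_effects(design))$eff)
      }, numeric(1))) - cum_target[k]
    }
    lo <- qnorm(1 - cum_target[k]) - 1e-9
    hi <- qnorm(1 - min(cum_target[k], alpha_schedule[k] + 1e-12) /
                  (m * K)) + 1.5
    upper[k] <- uniroot(g, c(lo, hi), tol = 1e-7)$root
  }
  new_boundaries(upper, design_lower_bounds(design, upper), "error-spending",
                 design$binding, design$alpha)
}

#' Required per-stage sample size of a multistage design
#'
#' Smallest integer per-stage full-population size (equal across stages)
#' whose cumulative efficacy probability for the powered event reaches
#' `1 - beta` at the calibrated boundaries. The boundaries are invariant to
#' the absolute size (they depend only on prevalences and relative stage
#' sizes), so they are calibrated once at the equal-stage schedule.
#'
#' @param design A [design_spec()].
#' @param boundaries Optional precalibrated `boundaries`.
#' @return A tibble with `n_stage` (per-stage full-population size),
#'   `n_total`, and `achieved_power`.
#' @export
required_stagewise_sample_size <- function(design, boundaries = NULL) {
  stopifnot(inherits(design, "design_spec"))
  if (is.null(boundaries)) boundaries <- calibrate_boundaries(design)
  f <- function(n) design_power(design, n, boundaries)
  n <- search_sample_size(f, 1 - design$beta)
  tibble::tibble(n_stage = n, n_total = n * design$stages,
                 achieved_power = f(n))
}

#' Calibrate a design end to end
#'
#' Computes the boundaries (critical value for a single stage) and the
#' required (per-stage) sample size for the powered event, returning a
#' calibration object that can be piped into [simulate_trials()].
#'
#' @param design A [design_spec()].
#' @return An object of class `enrich_calibration` with elements `design`,
#'   `boundaries`, `n_stage` (per-stage vector), `n_total`, and
#'   `achieved_power`.
#' @examples
#' \donttest{
#' pop <- population_set(c(0.5, 0.5))
#' d <- design_spec(pop, effect_config(c(0.23, 0), 0.72),
#'                  power_definition = "reject-any")
#' calibrate_design(d)
#' }
#' @export
calibrate_design <- function(design) {
  stopifnot(inherits(design, "design_spec"))
  boundaries <- calibrate_boundaries(design)
  res <- if (design$stages == 1) {
    r <- required_sample_size(design)
    list(n_stage = r$n_total, n_total = r$n_total,
         achieved_power = r$achieved_power)
  } else {
    r <- required_stagewise_sample_size(design, boundaries)
    list(n_stage = rep(r$n_stage, design$stages), n_total = r$n_total,
         achieved_power = r$achieved_power)
  }
  structure(
    list(design = design, boundaries = boundaries, n_stage = res$n_stage,
         n_total = res$n_total, achieved_power = res$achieved_power),
    class = "enrich_calibration"
  )
}

#' @export
print.enrich_calibration <- function(x, ...) {
  cat("<enrich_calibration>", x$design$stages, "stage(s), n_total =",
      x$n_total, "\n")
  cat("  per-stage n:", paste(x$n_stage, collapse = ", "),
      " achieved power:", round(x$achieved_power, 4), "\n")
  print(x$boundaries)
  invisible(x)
}

#' @method tidy enrich_calibration
#' @export
tidy.enrich_calibration <- function(x, ...) {
  tibble::tibble(
    stage = seq_len(x$design$stages),
    n_stage = x$n_stage,
    upper = x$boundaries$upper,
    lower = x$boundaries$lower
  )
}

#' @method glance enrich_calibration
#' @export
glance.enrich_calibration <- function(x, ...) {
  tibble::tibble(
    stages = x$design$stages,
    n_total = x$n_total,
    alpha = x$design$alpha,
    power_target = 1 - x$design$beta,
    achieved_power = x$achieved_power,
    power_definition = x$design$power_definition,
    boundary_family = x$boundaries$family
  )
}
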