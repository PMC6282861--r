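# Joint density of the selected test statistic and the selection index under
# maximum-statistic selection:
#
#   p(z, w; Theta) = phi(z - theta_w I_w) * Psi_{S \ w}(z, ..., z; Theta),
#
# where Psi is the CDF of the conditional multivariate normal of the
# non-selected statistics given Z_w = z, evaluated at the all-z corner
# (the event that every other statistic lies below the selected one).

# Precompute the pieces that do not depend on z.
selection_context <- function(pop, effects, n, allocation = 1) {
  stopifnot(inherits(pop, "population_set"), inherits(effects, "effect_config"))
  R <- correlation_matrix(pop)
  info <- unname(stage1_information(pop, effects$sigma, n, allocation))
  mu <- unname(member_effects(pop, effects)) * info
  m <- length(pop$labels)
  cond <- vector("list", m)
  for (i in seq_len(m)) {
    if (m == 1) { cond[[i]] <- list(d = 0L); next }
    rho <- unname(R[-i, i, drop = TRUE])
    Rc <- unname(R[-i, -i, drop = FALSE]) - tcrossprod(rho)
    sd_c <- sqrt(pmax(diag(Rc), 1e-14))
    d <- m - 1L
    rho_c <- if (d == 2) {
      Rc[1, 2] / (sd_c[1] * sd_c[2])
    } else NA_real_
    cond[[i]] <- list(d = d, rho = rho, Rc = Rc, sd = sd_c, rho_c = rho_c,
                      mu_other = mu[-i])
  }
  list(pop = pop, effects = effects, n = n, allocation = allocation,
       R = R, info = info, mu = mu, cond = cond)
}

# Density p(z, w) for a vector of z values, member index i.
joint_density_ctx <- function(z, i, ctx) {
  mu <- ctx$mu
  cc <- ctx$cond[[i]]
  base <- dnorm(z - mu[i])
  if (cc$d == 0) return(base)
  # conditional mean of the others given Z_i = z
  if (cc$d == 1) {
    h <- (z - cc$mu_other - cc$rho * (z - mu[i])) / cc$sd
    return(base * pnorm(h))
  }
  h <- vapply(seq_len(cc$d), function(s) {
    (z - cc$mu_other[s] - cc$rho[s] * (z - mu[i])) / cc$sd[s]
  }, numeric(length(z)))
  h <- matrix(h, ncol = cc$d)
  if (cc$d == 2) {
    return(base * bvn_cdf(h[, 1], h[, 2], cc$rho_c))
  }
  psi <- vapply(seq_along(z), function(j) {
    mvn_cdf(h[j, ], rep(0, cc$d), cc$Rc / tcrossprod(cc$sd))
  }, numeric(1))
  base * psi
}

#' Joint density of the selected statistic and selection index
#'
#' Evaluates \eqn{p(z, w) = \varphi(z - \theta_w I_w^{(1)})\,
#' \Psi_{S \setminus w}(z, \dots, z)}, the joint density of the stage-1
#' statistic of the selected population and the event that member `w` attains
#' the maximum, under effect configuration `effects` at full-population
#' stage-1 size `n`. All numerical pieces are deterministic, so repeated
#' evaluation is exactly reproducible.
#'
#' @param z Numeric vector of statistic values.
#' @param w Member label.
#' @param pop A [population_set()].
#' @param effects An [effect_config()].
#' @param n Full-population stage-1 sample size.
#' @param allocation Allocation ratio (default 1).
#' @return Numeric vector of density values.
#' @examples
#' pop <- population_set(c(0.5, 0.5))
#' eff <- effect_config(c(0, 0))
#' joint_density(0, "F", pop, eff, n = 100)
#' @export
joint_density <- function(z, w, pop, effects, n, allocation = 1) {
  ctx <- selection_context(pop, effects, n, allocation)
  i <- match(w, pop$labels)
  if (is.na(i)) abort(sprintf("unknown member label '%s'.", w))
  joint_density_ctx(z, i, ctx)
}

# integral of p(z, w) over [lo, hi] by adaptive quadrature
integrate_density <- function(i, ctx, lower = -Inf, upper = Inf) {
  mu_i <- ctx$mu[i]
  lo <- max(lower, mu_i - 8.5)
  hi <- min(upper, mu_i + 8.5)
  if (lo >= hi) return(0)
  res <- integrate(function(z) joint_density_ctx(z, i, ctx), lo, hi,
                   rel.tol = 1e-10, abs.tol = 1e-10, subdivisions = 400L,
                   stop.on.error = FALSE)
  if (!res$message %in% "OK") {
    abort(sprintf("quadrature failed for member %d: %s", i, res$message))
  }
  res$value
}

#' Selection probability of a candidate population
#'
#' Probability that member `w` attains the maximum stage-1 statistic,
#' obtained by adaptive quadrature of [joint_density()] over the real line.
#' Probabilities over all members sum to 1 (within quadrature tolerance).
#'
#' @inheritParams joint_density
#' @return A probability.
#' @examples
#' pop <- population_set(c(0.5, 0.5))
#' selection_probability("S1", pop, effect_config(c(0, 0)), n = 100)
#' @export
selection_probability <- function(w, pop, effects, n, allocation = 1) {
  ctx <- selection_context(pop, effects, n, allocation)
  i <- match(w, pop$labels)
  if (is.na(i)) abort(sprintf("unknown member label '%s'.", w))
  integrate_density(i, ctx)
}
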