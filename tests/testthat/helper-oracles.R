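# Independent oracles used to freeze expected values. These deliberately use
# different numerics from the package (trapezoid grids, Monte Carlo,
# closed forms) so that agreement is evidence, not tautology.

# Classical single-population group-sequential oracle: probability of ever
# crossing the upper bounds for a K-stage design with equal information
# increments, by fine trapezoid-grid recursion on the accumulated statistic.
gs_cross_probability <- function(upper, lower = rep(-Inf, length(upper)),
                                 theta_drift = 0, grid_n = 4001L) {
  K <- length(upper)
  # stage 1: Z^{1:1} ~ N(drift * sqrt(1/K) in accumulated scale, 1)
  mean1 <- theta_drift * sqrt(1 / K)
  cross <- pnorm(upper[1], mean1, 1, lower.tail = FALSE)
  if (K == 1) return(cross)
  lo <- max(lower[1], mean1 - 8)
  hi <- min(upper[1], mean1 + 8)
  z <- seq(lo, hi, length.out = grid_n)
  wts <- rep(diff(z)[1], grid_n); wts[c(1, grid_n)] <- wts[1] / 2
  dens <- dnorm(z, mean1, 1) * wts
  for (k in 2:K) {
    # accumulated info fractions k/K; transition N(z*sqrt((k-1)/k) + dk, 1/k)
    r <- sqrt((k - 1) / k)
    dk <- theta_drift * (1 / sqrt(K)) / sqrt(k)
    s <- sqrt(1 / k)
    m <- z * r + dk
    cross <- cross + sum(dens * pnorm((upper[k] - m) / s, lower.tail = FALSE))
    if (k < K) {
      lo <- max(lower[k], -8); hi <- min(upper[k], 8)
      z_new <- seq(lo, hi, length.out = grid_n)
      w_new <- rep(diff(z_new)[1], grid_n); w_new[c(1, grid_n)] <- w_new[1] / 2
      dens_new <- vapply(z_new, function(zz) sum(dens * dnorm((zz - m) / s) / s),
                         numeric(1))
      dens <- dens_new * w_new
      z <- z_new
    }
  }
  cross
}

# O'Brien-Fleming constant for a single population, K stages, by the oracle.
gs_obf_constant <- function(K, alpha) {
  uniroot(function(C) {
    gs_cross_probability(C * sqrt(K / seq_len(K))) - alpha
  }, c(1.5, 3.5), tol = 1e-9)$root
}

# Two-look error-spending oracle (single population, equal increments):
# Cu1 = qnorm(1 - a1); Cu2 solves P(Z1 < Cu1, Z2 >= Cu2) = a2 where
# corr(Z1, Z2) = sqrt(1/2), via direct 1-d integration.
es_oracle_two_look <- function(a1, a2) {
  c1 <- qnorm(1 - a1)
  f <- function(c2) {
    integrate(function(z) {
      dnorm(z) * pnorm((c2 - z / sqrt(2)) / sqrt(1 / 2), lower.tail = FALSE)
    }, -8.5, c1, rel.tol = 1e-12)$value - a2
  }
  c(c1, uniroot(f, c(1, 4), tol = 1e-9)$root)
}

# Monte-Carlo draw of the stage-1 statistics of a population set.
mc_stage1 <- function(pop, theta, sigma, n, n_draws, seed) {
  set.seed(seed)
  R <- correlation_matrix(pop)
  info <- enrichsel:::stage1_information(pop, sigma, n)
  drift <- vapply(pop$labels, function(l) {
    composite_effect(pop, effect_config(theta, sigma), l)
  }, numeric(1)) * info
  Z <- matrix(rnorm(n_draws * length(pop$labels)), n_draws) %*% chol(R)
  sweep(Z, 2, drift, "+")
}

# tolerance: 3 standard errors of a proportion (optionally two independent
# estimates of the same size compared against each other)
tol_prop <- function(p, n, two_sided_mc = FALSE) {
  3 * sqrt(p * (1 - p) / n * (if (two_sided_mc) 2 else 1))
}
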