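# Deterministic multivariate-normal CDF evaluation.
#
# The selection density needs the conditional CDF of the remaining statistics
# given the selected one, evaluated at the all-z point, inside quadratures and
# root searches. For the common |S| = 3 case this is a bivariate normal CDF on
# a vector of z values; a fixed Gauss-Legendre rule makes it fast, vectorized
# and exactly reproducible. Dimensions >= 3 fall back to mvtnorm's
# deterministic Miwa algorithm.

# Gauss-Legendre nodes/weights on [-1, 1], cached per order.
gl_cache <- new.env(parent = emptyenv())

gauss_legendre <- function(n) {
  key <- as.character(n)
  if (!is.null(gl_cache[[key]])) return(gl_cache[[key]])
  # Golub-Welsch: eigen-decomposition of the Jacobi matrix
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  res <- list(nodes = e$values, weights = 2 * e$vectors[1, ]^2)
  ord <- order(res$nodes)
  res <- list(nodes = res$nodes[ord], weights = res$weights[ord])
  gl_cache[[key]] <- res
  res
}

# Standard bivariate normal CDF P(X1 <= h, X2 <= k; rho), vectorized over
# h and k (recycled). Reduction to a single integral over the first margin,
# integrated with a 128-point Gauss-Legendre rule on [-8.5, h].
bvn_cdf <- function(h, k, rho, n_nodes = 128L) {
  m <- max(length(h), length(k))
  h <- rep_len(pmin(pmax(h, -8.5), 8.5), m)
  k <- rep_len(pmin(pmax(k, -8.5), 8.5), m)
  rho <- min(max(rho, -1 + 1e-12), 1 - 1e-12)
  gl <- gauss_legendre(n_nodes)
  lo <- -8.5
  half <- (h - lo) / 2
  mid <- (h + lo) / 2
  # x: m x n matrix of integration nodes
  x <- outer(half, gl$nodes) + mid
  s <- sqrt(1 - rho^2)
  inner <- pnorm((k - rho * x) / s)
  vals <- dnorm(x) * inner
  out <- half * as.vector(vals %*% gl$weights)
  pmax(out, 0)
}

# P(X <= upper) for X ~ N(mean, sigma), any small dimension, deterministic.
mvn_cdf <- function(upper, mean, sigma) {
  d <- length(upper)
  if (d == 0) return(1)
  sd <- sqrt(pmax(diag(sigma), 1e-300))
  h <- (upper - mean) / sd
  if (d == 1) return(pnorm(h))
  if (d == 2) {
    rho <- sigma[1, 2] / (sd[1] * sd[2])
    return(bvn_cdf(h[1], h[2], rho))
  }
  corr <- stats::cov2cor(sigma)
  as.numeric(mvtnorm::pmvnorm(
    lower = rep(-Inf, d), upper = h, corr = corr,
    algorithm = mvtnorm::Miwa(steps = 128)
  ))
}
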