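# Seeded Monte-Carlo engine. Default mode draws the sufficient statistics of
# the fully Gaussian model exactly (stage-1 multivariate normal, then the
# group-sequential transition law for the selected population under
# enrichment). Patient-level mode regenerates the same trials from
# per-subgroup, per-arm outcome sums with integer patient counts and serves
# as an end-to-end consistency check of the information bookkeeping.

label_key <- function(labels) gsub("[^0-9A-Za-z]", "_", labels)

#' Simulate selection trials
#'
#' Generates `n_reps` independent trials of a (calibrated) subpopulation
#' selection design: stage-1 statistics for every candidate population,
#' selection by the design's rule, stage-wise stopping against the
#' boundaries, enrichment of later stages to the selected population, and
#' naive maximum-likelihood estimates for every candidate population.
#' Identical `seed` and configuration reproduce the record stream exactly.
#'
#' Populations deselected at the interim receive no later data: their
#' statistics, information and MLEs stay frozen at the stage-1 values.
#'
#' @param x An `enrich_calibration` from [calibrate_design()], or a
#'   [design_spec()] (then `n` and `boundaries` must be given).
#' @param n Per-stage full-population sample size (scalar or vector).
#' @param boundaries A `boundaries` object.
#' @param n_reps Number of simulated trials.
#' @param seed Integer seed.
#' @param mode `"sufficient"` (exact sufficient statistics, default) or
#'   `"patient"` (integer patient counts and per-arm outcome sums).
#' @param effects True effect configuration generating the data (defaults to
#'   the design's powering alternative; scenarios often differ).
#' @param random_prevalence Patient mode only: draw stage-1 subgroup counts
#'   multinomially instead of fixing them at the prevalences.
#' @param custom_rule Optional selection function: takes the `n_reps x m`
#'   matrix of stage-1 statistics (columns in member priority order) and
#'   returns member indices. Overrides the design's named rule.
#' @return A tibble with one row per trial: `rep`, `selected`, `stage`
#'   (stopping stage `M`), `rejected`, `z_stop`, `info_stop`, and per member
#'   `<key>` the columns `z1_<key>`, `mle_<key>`, `info_<key>` (information
#'   at the member's last observed stage). Patient mode adds
#'   `meandiff_<key>`, the pooled treatment-minus-control mean difference.
#'   Attributes `pop`, `effects`, `n_stage`, `boundaries`, `mode` carry the
#'   generating configuration.
#' @examples
#' pop <- population_set(c(0.5, 0.5))
#' d <- design_spec(pop, effect_config(c(0.5, 0)))
#' b <- new_boundaries(2.2, 2.2, "single-stage", TRUE, 0.025)
#' sim <- simulate_trials(d, n = 100, boundaries = b, n_reps = 100, seed = 1)
#' @export
simulate_trials <- function(x, n = NULL, boundaries = NULL, n_reps = 1e5,
                            seed = 1L, mode = c("sufficient", "patient"),
                            effects = NULL, random_prevalence = FALSE,
                            custom_rule = NULL) {
  if (inherits(x, "enrich_calibration")) {
    design <- x$design
    if (is.null(n)) n <- x$n_stage
    if (is.null(boundaries)) boundaries <- x$boundaries
  } else {
    design <- x
  }
  stopifnot(inherits(design, "design_spec"))
  if (is.null(n) || is.null(boundaries)) {
    abort("`n` and `boundaries` are required unless `x` is a calibration.")
  }
  mode <- match.arg(mode)
  if (is.null(effects)) effects <- design$effects
  pop <- design$pop
  K <- design$stages
  n_stage <- rep_len(n, K)
  m <- length(pop$labels)
  keys <- label_key(pop$labels)
  set.seed(as.integer(seed))

  if (mode == "sufficient") {
    R <- correlation_matrix(pop)
    info1 <- stage1_information(pop, effects$sigma, n_stage[1],
                                design$allocation)
    drift <- member_effects(pop, effects) * info1
    Z1 <- matrix(rnorm(n_reps * m), n_reps, m) %*% chol(R)
    Z1 <- sweep(Z1, 2, drift, "+")
    meandiff <- NULL
  } else {
    gen <- patient_stage1(pop, effects, n_stage[1], n_reps,
                          random_prevalence, design$allocation)
    Z1 <- gen$z
    info1 <- gen$info # may be a matrix (random counts) or vector
    meandiff <- gen$meandiff
    sums <- gen$sums
  }

  sel <- select_indices(Z1, design$selection, custom = custom_rule)
  z_sel <- Z1[cbind(seq_len(n_reps), sel)]
  info_of <- function(i, rep_idx) {
    if (is.matrix(info1)) info1[cbind(rep_idx, i)] else info1[i]
  }

  stage <- rep(1L, n_reps)
  rejected <- z_sel >= boundaries$upper[1]
  z_stop <- z_sel
  info_stop <- if (is.matrix(info1)) info1[cbind(seq_len(n_reps), sel)] else info1[sel]
  if (K > 1) {
    active <- !rejected & z_sel > boundaries$lower[1]
    for (k in 2:K) {
      idx_active <- which(active)
      if (length(idx_active) == 0) break
      for (i in unique(sel[idx_active])) {
        idx <- idx_active[sel[idx_active] == i]
        w <- pop$labels[i]
        theta_w <- composite_effect(pop, effects, w)
        I <- accumulated_information(pop, effects$sigma, n_stage, w,
                                     design$allocation)
        if (mode == "sufficient") {
          v <- (I[k]^2 - I[k - 1]^2) / I[k]^2
          mtr <- z_stop[idx] * I[k - 1] / I[k] +
            theta_w * (I[k]^2 - I[k - 1]^2) / I[k]
          z_new <- mtr + sqrt(v) * rnorm(length(idx))
          z_stop[idx] <- z_new
          info_stop[idx] <- I[k]
        } else {
          upd <- patient_stage_next(pop, effects, n_stage[k], i, idx, sums,
                                    design$allocation)
          sums <- upd$sums
          z_stop[idx] <- upd$z
          info_stop[idx] <- upd$info
          meandiff[idx, i] <- upd$meandiff
        }
      }
      stage[idx_active] <- k
      rej_k <- z_stop[idx_active] >= boundaries$upper[k]
      rejected[idx_active] <- rej_k
      if (k < K) {
        active[idx_active] <- !rej_k & z_stop[idx_active] > boundaries$lower[k]
      }
    }
  }

  out <- tibble::tibble(
    rep = seq_len(n_reps),
    selected = pop$labels[sel],
    stage = stage,
    rejected = rejected,
    z_stop = z_stop,
    info_stop = info_stop
  )
  for (i in seq_len(m)) {
    is_sel <- sel == i
    info_i <- if (is.matrix(info1)) info1[, i] else rep(info1[i], n_reps)
    mle_i <- Z1[, i] / info_i
    info_out <- info_i
    mle_i[is_sel] <- z_stop[is_sel] / info_stop[is_sel]
    info_out[is_sel] <- info_stop[is_sel]
    out[[paste0("z1_", keys[i])]] <- Z1[, i]
    out[[paste0("mle_", keys[i])]] <- mle_i
    out[[paste0("info_", keys[i])]] <- info_out
    if (mode == "patient") {
      out[[paste0("meandiff_", keys[i])]] <- meandiff[, i]
    }
  }
  attr(out, "pop") <- pop
  attr(out, "effects") <- effects
  attr(out, "n_stage") <- n_stage
  attr(out, "boundaries") <- boundaries
  attr(out, "mode") <- mode
  attr(out, "seed") <- as.integer(seed)
  out
}

# stage-1 generation from per-subgroup per-arm outcome sums
patient_stage1 <- function(pop, effects, n1, n_reps, random_prevalence,
                           allocation) {
  J <- pop$J
  sigma <- effects$sigma
  per_arm <- n1 / (1 + allocation) # control size; treatment = allocation * it
  if (random_prevalence) {
    nT <- t(rmultinom(n_reps, round(per_arm * allocation), pop$prevalences))
    nC <- t(rmultinom(n_reps, round(per_arm), pop$prevalences))
  } else {
    nT <- matrix(round(pop$prevalences * per_arm * allocation),
                 n_reps, J, byrow = TRUE)
    nC <- matrix(round(pop$prevalences * per_arm), n_reps, J, byrow = TRUE)
  }
  if (any(nT < 1) || any(nC < 1)) {
    abort("patient mode needs at least one patient per subgroup and arm.")
  }
  # sum of n iid N(mu, sigma^2) outcomes is N(n mu, n sigma^2)
  ST <- matrix(rnorm(n_reps * J), n_reps, J) * sigma * sqrt(nT) +
    nT * matrix(effects$theta, n_reps, J, byrow = TRUE)
  SC <- matrix(rnorm(n_reps * J), n_reps, J) * sigma * sqrt(nC)
  m <- length(pop$labels)
  z <- info <- meandiff <- matrix(NA_real_, n_reps, m)
  for (i in seq_len(m)) {
    idx <- pop$members[[i]]
    nT_L <- rowSums(nT[, idx, drop = FALSE])
    nC_L <- rowSums(nC[, idx, drop = FALSE])
    md <- rowSums(ST[, idx, drop = FALSE]) / nT_L -
      rowSums(SC[, idx, drop = FALSE]) / nC_L
    I <- 1 / (sigma * sqrt(1 / nT_L + 1 / nC_L))
    z[, i] <- I * md
    info[, i] <- I
    meandiff[, i] <- md
  }
  list(z = z, info = info, meandiff = meandiff,
       sums = list(ST = ST, SC = SC, nT = nT, nC = nC))
}

# recruit stage-k patients entirely from the selected member i, update sums
patient_stage_next <- function(pop, effects, nk, i, idx, sums, allocation) {
  sigma <- effects$sigma
  member <- pop$members[[i]]
  prev_w <- pop$member_prevalence[i]
  per_arm <- nk / (1 + allocation)
  add_T <- round(pop$prevalences[member] / prev_w * per_arm * allocation)
  add_C <- round(pop$prevalences[member] / prev_w * per_arm)
  for (jj in seq_along(member)) {
    j <- member[jj]
    sums$ST[idx, j] <- sums$ST[idx, j] +
      rnorm(length(idx)) * sigma * sqrt(add_T[jj]) + add_T[jj] * effects$theta[j]
    sums$SC[idx, j] <- sums$SC[idx, j] + rnorm(length(idx)) * sigma * sqrt(add_C[jj])
    sums$nT[idx, j] <- sums$nT[idx, j] + add_T[jj]
    sums$nC[idx, j] <- sums$nC[idx, j] + add_C[jj]
  }
  nT_L <- rowSums(sums$nT[idx, member, drop = FALSE])
  nC_L <- rowSums(sums$nC[idx, member, drop = FALSE])
  md <- rowSums(sums$ST[idx, member, drop = FALSE]) / nT_L -
    rowSums(sums$SC[idx, member, drop = FALSE]) / nC_L
  I <- 1 / (sigma * sqrt(1 / nT_L + 1 / nC_L))
  list(sums = sums, z = I * md, info = I, meandiff = md)
}

#' Naive maximum-likelihood estimates from simulated records
#'
#' Returns the per-trial MLE \eqn{\hat\theta_s = Z_s^{1:M_s}/I_s^{1:M_s}} of
#' the treatment effect in candidate population `label`, where \eqn{M_s} is
#' the last stage at which that population was observed. For populations
#' deselected at the interim this is the frozen stage-1 estimate; a warning
#' flags records where that happened.
#'
#' @param records A tibble from [simulate_trials()].
#' @param label Member label.
#' @return Numeric vector of estimates, one per trial.
#' @export
mle <- function(records, label) {
  pop <- attr(records, "pop")
  if (is.null(pop) || !label %in% pop$labels) {
    abort("`records` must come from simulate_trials(); unknown label.")
  }
  key <- label_key(pop$labels)[match(label, pop$labels)]
  frozen <- records$stage > 1 & records$selected != label
  if (any(frozen)) {
    warning(sprintf(
      "'%s' was deselected before the final stage in %d records; stage-1 estimates returned for those.",
      label, sum(frozen)), call. = FALSE)
  }
  records[[paste0("mle_", key)]]
}
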