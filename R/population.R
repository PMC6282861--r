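#' Candidate population structure
#'
#' Defines the full trial population as `J` mutually disjoint subgroups with
#' known prevalences, together with the ordered set of candidate populations
#' (possibly nested unions of subgroups) among which selection takes place.
#' The order of `members` is the selection-priority order: exact ties in the
#' selection statistics are broken in favour of the first listed member.
#'
#' @param prevalences Numeric vector of subgroup prevalences
#'   \eqn{\lambda_1, \dots, \lambda_J}; must be positive and sum to 1.
#' @param members List of integer vectors, each a nonempty subset of
#'   `1:J`, giving the candidate populations. Defaults to the two-population
#'   structure `list(1, 1:J)` (first subgroup versus full population).
#' @param labels Optional character labels for the members. Defaults to
#'   `"S1"`, `"S1+2"`, ..., with the full population labelled `"F"`.
#'
#' @return An object of class `population_set`: a list with elements `J`,
#'   `prevalences`, `members` (named list of sorted integer vectors),
#'   `labels`, and `member_prevalence` (named numeric vector).
#'
#' @examples
#' pop <- population_set(c(1, 1, 1) / 3, members = list(1, 1:2, 1:3))
#' pop$labels
#' member_prevalence(pop)
#' @export
population_set <- function(prevalences,
                           members = list(1L, seq_along(prevalences)),
                           labels = NULL) {
  prevalences <- as.numeric(prevalences)
  J <- length(prevalences)
  if (J < 1 || any(!is.finite(prevalences)) || any(prevalences <= 0)) {
    abort("`prevalences` must be positive and finite.")
  }
  if (abs(sum(prevalences) - 1) > 1e-12) {
    abort("`prevalences` must sum to 1 (within 1e-12).")
  }
  members <- lapply(members, function(m) sort(unique(as.integer(m))))
  ok <- vapply(members, function(m) {
    length(m) >= 1 && all(m >= 1L) && all(m <= J)
  }, logical(1))
  if (!all(ok)) abort("every member must be a nonempty subset of 1:J.")
  keys <- vapply(members, paste, character(1), collapse = ",")
  if (anyDuplicated(keys)) abort("member labels must be distinct subsets.")
  if (is.null(labels)) {
    labels <- vapply(members, function(m) {
      if (length(m) == J) "F" else paste0("S", paste(m, collapse = "+"))
    }, character(1))
  }
  if (length(labels) != length(members) || anyDuplicated(labels)) {
    abort("`labels` must be distinct and match `members` in length.")
  }
  names(members) <- labels
  mp <- vapply(members, function(m) sum(prevalences[m]), numeric(1))
  structure(
    list(J = J, prevalences = prevalences, members = members,
         labels = labels, member_prevalence = mp),
    class = "population_set"
  )
}

#' @export
print.population_set <- function(x, ...) {
  cat("<population_set> J =", x$J,
      " prevalences =", paste(signif(x$prevalences, 4), collapse = ", "), "\n")
  cat("members (priority order):",
      paste(sprintf("%s (prev %.4g)", x$labels, x$member_prevalence),
            collapse = ", "), "\n")
  invisible(x)
}

#' Prevalence of each candidate population
#'
#' @param pop A [population_set()].
#' @return Named numeric vector of member prevalences.
#' @export
member_prevalence <- function(pop) {
  stopifnot(inherits(pop, "population_set"))
  pop$member_prevalence
}

#' Treatment-effect configuration
#'
#' Bundles the true per-subgroup treatment differences
#' \eqn{\theta_1, \dots, \theta_J} (outcome units) with the common outcome
#' standard deviation \eqn{\sigma}.
#'
#' @param theta Numeric vector of subgroup treatment differences.
#' @param sigma Positive common standard deviation (default 1).
#' @return An object of class `effect_config`.
#' @examples
#' effect_config(c(0.5, 0, 0), sigma = 1)
#' @export
effect_config <- function(theta, sigma = 1) {
  theta <- as.numeric(theta)
  if (any(!is.finite(theta))) abort("`theta` must be finite.")
  if (!is.finite(sigma) || sigma <= 0) abort("`sigma` must be positive.")
  structure(list(theta = theta, sigma = sigma), class = "effect_config")
}

#' @export
print.effect_config <- function(x, ...) {
  cat("<effect_config> theta =", paste(signif(x$theta, 4), collapse = ", "),
      " sigma =", x$sigma, "\n")
  invisible(x)
}

#' Information level of a two-arm comparison
#'
#' The information level is the reciprocal standard error of the estimated
#' treatment difference, \eqn{I = 1 / (\sigma \sqrt{1/n_T + 1/n_C})}, so that
#' the standardized test statistic is distributed \eqn{N(I\theta, 1)}. With
#' 1:1 allocation and total size \eqn{n} this is \eqn{\sqrt{n}/(2\sigma)}.
#' Squared information adds across independent stages. Non-integer `n_total`
#' is accepted: sample-size searches treat size as continuous and only round
#' the final reported totals.
#'
#' @param n_total Total sample size across both arms (may be non-integer
#'   during search); must be at least 2.
#' @param sigma Positive outcome standard deviation.
#' @param allocation Treatment:control allocation ratio \eqn{r} (default 1),
#'   so \eqn{n_T = n r/(1+r)}, \eqn{n_C = n/(1+r)}.
#' @return The information level (reciprocal standard error), a scalar.
#' @examples
#' information_level(100, 1) # 5
#' information_level(100, 2) # 2.5
#' @export
information_level <- function(n_total, sigma, allocation = 1) {
  if (!is.finite(sigma) || sigma <= 0) abort("`sigma` must be positive.")
  if (!is.finite(allocation) || allocation <= 0) {
    abort("`allocation` must be a positive ratio.")
  }
  if (any(!is.finite(n_total)) || any(n_total < 2)) {
    abort("`n_total` must be at least 2.")
  }
  n_t <- n_total * allocation / (1 + allocation)
  n_c <- n_total / (1 + allocation)
  1 / (sigma * sqrt(1 / n_t + 1 / n_c))
}

#' Composite treatment effect of a candidate population
#'
#' The effect in a union of subgroups is the prevalence-weighted average
#' \eqn{\theta_L = \sum_{j \in L} \lambda_j \theta_j / \sum_{j \in L} \lambda_j}.
#'
#' @param pop A [population_set()].
#' @param effects An [effect_config()].
#' @param label A member label (character) or an integer vector of subgroups.
#' @return The composite effect, a scalar.
#' @examples
#' pop <- population_set(c(1, 1, 1) / 3, list(1, 1:2, 1:3))
#' composite_effect(pop, effect_config(c(0.5, 0, 0)), "F")
#' @export
composite_effect <- function(pop, effects, label) {
  stopifnot(inherits(pop, "population_set"), inherits(effects, "effect_config"))
  idx <- resolve_label(pop, label)
  sum(pop$prevalences[idx] * effects$theta[idx]) / sum(pop$prevalences[idx])
}

# label -> integer subgroup indices; accepts member labels or raw subsets
resolve_label <- function(pop, label) {
  if (is.character(label)) {
    if (!label %in% pop$labels) {
      abort(sprintf("unknown member label '%s'.", label))
    }
    return(pop$members[[label]])
  }
  idx <- sort(unique(as.integer(label)))
  if (length(idx) < 1 || any(idx < 1) || any(idx > pop$J)) {
    abort("label must be a nonempty subset of 1:J.")
  }
  idx
}

# composite effects for all members, in member order
member_effects <- function(pop, effects) {
  vapply(pop$labels, function(l) composite_effect(pop, effects, l), numeric(1))
}

#' Stage-1 correlation matrix of the candidate-population test statistics
#'
#' With prevalence-proportional recruitment the test statistics of nested
#' members \eqn{U \subset V} have correlation
#' \eqn{\sqrt{n_U / n_V} = \sqrt{\mathrm{prev}(U)/\mathrm{prev}(V)}};
#' disjoint members are independent. Members that overlap without nesting are
#' not supported.
#'
#' @param pop A [population_set()].
#' @return Symmetric positive-semidefinite correlation matrix with one
#'   row/column per member, in priority order.
#' @examples
#' correlation_matrix(population_set(c(0.5, 0.5)))
#' @export
correlation_matrix <- function(pop) {
  stopifnot(inherits(pop, "population_set"))
  m <- length(pop$members)
  R <- diag(1, m)
  dimnames(R) <- list(pop$labels, pop$labels)
  if (m == 1) return(R)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      a <- pop$members[[i]]; b <- pop$members[[j]]
      common <- intersect(a, b)
      if (length(common) == 0) {
        R[i, j] <- R[j, i] <- 0
      } else if (setequal(common, a) || setequal(common, b)) {
        pa <- pop$member_prevalence[i]; pb <- pop$member_prevalence[j]
        R[i, j] <- R[j, i] <- sqrt(min(pa, pb) / max(pa, pb))
      } else {
        abort(sprintf(
          "members '%s' and '%s' overlap without nesting; unsupported structure.",
          pop$labels[i], pop$labels[j]))
      }
    }
  }
  R
}

#' Accumulated information schedule under enrichment
#'
#' After the interim selection all later recruitment is restricted to the
#' selected population (for the full population, recruitment stays
#' prevalence-proportional). The accumulated sample size of the selected
#' member at stage \eqn{k} is therefore
#' \eqn{\mathrm{prev}(w)\, n^{(1)} + \sum_{i=2}^{k} n^{(i)}}, and the
#' accumulated information is computed from it.
#'
#' @param selected Member label selected at the interim.
#' @param n_stage Numeric vector of per-stage full-population sample sizes.
#' @param pop A [population_set()].
#' @param sigma Outcome standard deviation.
#' @param allocation Allocation ratio (default 1).
#' @return A tibble with one row per stage: `stage`, `n_stage_full`,
#'   `n_selected_cum` (accumulated size of the selected member),
#'   `info_cum` (accumulated information level), and
#'   `fraction_selected` (share of all patients recruited so far that belong
#'   to the selected member).
#' @examples
#' pop <- population_set(c(0.5, 0.5))
#' enrichment_information_update("S1", c(276, 276), pop, sigma = 0.72)
#' @export
enrichment_information_update <- function(selected, n_stage, pop, sigma,
                                          allocation = 1) {
  stopifnot(inherits(pop, "population_set"))
  prev <- pop$member_prevalence[[selected]]
  K <- length(n_stage)
  n_sel <- cumsum(c(prev * n_stage[1], n_stage[-1]))
  n_all <- cumsum(n_stage)
  tibble::tibble(
    stage = seq_len(K),
    n_stage_full = n_stage,
    n_selected_cum = n_sel,
    info_cum = information_level(n_sel, sigma, allocation),
    fraction_selected = n_sel / n_all
  )
}

# per-member stage-1 information levels at full-population size n
stage1_information <- function(pop, sigma, n, allocation = 1) {
  information_level(pop$member_prevalence * n, sigma, allocation)
}

# accumulated information of member w at stages 1..K under enrichment
accumulated_information <- function(pop, sigma, n_stage, w, allocation = 1) {
  prev <- pop$member_prevalence[[w]]
  n_cum <- cumsum(c(prev * n_stage[1], n_stage[-1]))
  information_level(n_cum, sigma, allocation)
}
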