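#' Select the candidate population with the maximum test statistic
#'
#' Returns the member label attaining the largest statistic. Exact ties (a
#' probability-zero event for continuous statistics) are broken by the
#' priority order of the population set: the first listed member wins.
#'
#' @param z Named numeric vector of stage-1 test statistics, one finite value
#'   per member of `pop` (names must match the member labels).
#' @param pop A [population_set()].
#' @return A tibble with columns `selected` (label) and `rule` (`"max"`).
#' @examples
#' pop <- population_set(c(0.5, 0.5))
#' select_max(c(S1 = 2, F = 1), pop)
#' @export
select_max <- function(z, pop) {
  stopifnot(inherits(pop, "population_set"))
  if (!all(pop$labels %in% names(z))) {
    abort("`z` must carry one value per member label.")
  }
  z <- z[pop$labels]
  if (any(!is.finite(z))) abort("all statistics must be finite.")
  sel <- pop$labels[which.max(z)] # which.max: first maximum wins
  tibble::tibble(selected = sel, rule = "max")
}

#' Sequential three-population selection rule
#'
#' For the nested candidate set \{S1, S1+2, F\}: select S1 if its statistic
#' strictly exceeds both others; otherwise select S1+2 if its statistic
#' strictly exceeds that of F; otherwise select F. The rule is a sequential
#' variant of the maximum rule and agrees with it except on ties. The
#' boundary case `z12 == zf` (left open by the strict inequalities) resolves
#' to F: ties have probability zero and continuing with the larger population
#' is the conservative ethical default.
#'
#' @param z1,z12,zf Finite stage-1 statistics for S1, S1+2 and F.
#' @return A tibble with columns `selected` (one of `"S1"`, `"S1+2"`, `"F"`)
#'   and `rule` (`"sequential3"`).
#' @examples
#' select_sequential_three(1, 2, 1.5)
#' @export
select_sequential_three <- function(z1, z12, zf) {
  if (any(!is.finite(c(z1, z12, zf)))) abort("all statistics must be finite.")
  sel <- if (z1 > max(zf, z12)) "S1" else if (z12 > zf) "S1+2" else "F"
  tibble::tibble(selected = sel, rule = "sequential3")
}

# Vectorized selection over a matrix of stage-1 statistics (columns in member
# priority order). Returns integer member indices.
select_indices <- function(zmat, rule = c("max", "sequential3"),
                           custom = NULL) {
  if (is.function(custom)) return(custom(zmat))
  rule <- match.arg(rule)
  if (rule == "max") {
    return(max.col(zmat, ties.method = "first"))
  }
  if (ncol(zmat) != 3) {
    abort("the sequential rule needs exactly three members (S1, S1+2, F).")
  }
  z1 <- zmat[, 1]; z12 <- zmat[, 2]; zf <- zmat[, 3]
  ifelse(z1 > pmax(zf, z12), 1L, ifelse(z12 > zf, 2L, 3L))
}
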