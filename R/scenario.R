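# Scenario runner: a YAML config describes the design, the simulation
# settings and an optional prevalence sweep; the runner calibrates,
# simulates, assesses, and writes self-describing CSV/JSON outputs.

scenario_schema <- list(
  design = c("prevalences", "members", "theta", "sigma", "alpha", "beta",
             "stages", "power_definition", "target", "interest",
             "boundary_family", "lower_bound", "binding", "selection",
             "allocation", "alpha_schedule"),
  simulation = c("n_reps", "seed", "mode", "theta_scenarios"),
  sweep = c("prevalence1"),
  output = c("dir")
)

check_keys <- function(x, allowed, path) {
  extra <- setdiff(names(x), allowed)
  if (length(extra)) {
    abort(sprintf("unknown config key(s) at %s: %s", path,
                  paste(extra, collapse = ", ")))
  }
}

#' Read and validate a scenario configuration
#'
#' The configuration is a nested-key YAML file with blocks `design`
#' (prevalences, optional members as lists of subgroup indices, theta,
#' sigma, error rates, stages, power definition, boundary conventions),
#' `simulation` (`n_reps`, `seed`, `mode`, optional `theta_scenarios` — a
#' list of theta vectors to simulate under the calibrated design), optional
#' `sweep` (`prevalence1: {from, to, by}` for two-subgroup designs), and
#' `output` (`dir`). Unknown keys are rejected with their path.
#'
#' @param path Path to a YAML file, or a pre-parsed list.
#' @return A validated config list with defaults filled in.
#' @export
read_scenario_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  check_keys(cfg, names(scenario_schema), "top level")
  if (is.null(cfg$design)) abort("config needs a `design` block.")
  for (blk in names(scenario_schema)) {
    if (!is.null(cfg[[blk]])) check_keys(cfg[[blk]], scenario_schema[[blk]], blk)
  }
  d <- cfg$design
  if (is.null(d$prevalences) || is.null(d$theta)) {
    abort("design block needs `prevalences` and `theta`.")
  }
  defaults <- list(sigma = 1, alpha = 0.025, beta = 0.2, stages = 1,
                   power_definition = "select-target-and-reject",
                   boundary_family = "obf", lower_bound = "zero",
                   binding = FALSE, selection = "max", allocation = 1)
  cfg$design <- modifyList(defaults, d)
  sim_defaults <- list(n_reps = 0, seed = 1, mode = "sufficient")
  cfg$simulation <- modifyList(sim_defaults,
                               if (is.null(cfg$simulation)) list() else cfg$simulation)
  cfg
}

config_design <- function(dcfg) {
  members <- if (is.null(dcfg$members)) {
    list(1L, seq_along(dcfg$prevalences))
  } else {
    lapply(dcfg$members, as.integer)
  }
  pop <- population_set(dcfg$prevalences, members)
  target <- if (is.null(dcfg$target)) pop$labels[1] else dcfg$target
  interest <- if (is.null(dcfg$interest)) pop$labels else dcfg$interest
  design_spec(pop, effect_config(dcfg$theta, dcfg$sigma),
              alpha = dcfg$alpha, beta = dcfg$beta, stages = dcfg$stages,
              power_definition = dcfg$power_definition, target = target,
              interest = interest, boundary_family = dcfg$boundary_family,
              lower_bound = dcfg$lower_bound, binding = dcfg$binding,
              selection = dcfg$selection, allocation = dcfg$allocation,
              alpha_schedule = dcfg$alpha_schedule)
}

run_one <- function(design, sim_cfg, seed) {
  cal <- calibrate_design(design)
  out <- list(calibration = cal, design_summary = glance(cal))
  if (sim_cfg$n_reps > 0) {
    scen <- sim_cfg$theta_scenarios
    if (is.null(scen)) scen <- list(design$effects$theta)
    out$assessment <- purrr::map_dfr(scen, function(th) {
      eff <- effect_config(th, design$effects$sigma)
      rec <- simulate_trials(cal, n_reps = sim_cfg$n_reps, seed = seed,
                             mode = sim_cfg$mode, effects = eff)
      dplyr::mutate(assess_estimates(rec),
                    theta = paste(th, collapse = ","), .before = 1)
    })
  }
  out
}

#' Run a configured scenario end to end
#'
#' Calibrates the configured design, optionally simulates it (under one or
#' more true-effect scenarios) and assesses the MLEs, and — when a
#' prevalence sweep is configured — repeats this across the grid of
#' subgroup-1 prevalences. With `n_reps = 0` only the design calibration is
#' returned. Identical configuration and seed reproduce identical outputs.
#'
#' @param config Path to a YAML config or a config list
#'   (see [read_scenario_config()]).
#' @return A list with elements `config`, `design_summary` (tibble),
#'   `boundaries` (tidy tibble), and, if simulated, `assessment`; sweep runs
#'   return `sweep_assessment` / `sweep_designs` instead, with a
#'   `prevalence1` column, and the assessment carries class `enrich_sweep`
#'   for [autoplot()].
#' @export
run_scenario <- function(config) {
  cfg <- read_scenario_config(config)
  sim_cfg <- cfg$simulation
  if (is.null(cfg$sweep)) {
    design <- config_design(cfg$design)
    res <- run_one(design, sim_cfg, sim_cfg$seed)
    return(list(config = cfg, design_summary = res$design_summary,
                boundaries = tidy(res$calibration),
                assessment = res$assessment))
  }
  sw <- cfg$sweep$prevalence1
  if (length(cfg$design$prevalences) != 2) {
    abort("prevalence sweeps require exactly two subgroups.")
  }
  grid <- seq(sw$from, sw$to, by = sw$by)
  runs <- purrr::map(grid, function(lam) {
    dcfg <- cfg$design
    dcfg$prevalences <- c(lam, 1 - lam)
    res <- run_one(config_design(dcfg), sim_cfg, sim_cfg$seed)
    list(design = dplyr::mutate(res$design_summary, prevalence1 = lam,
                                .before = 1),
         assessment = if (!is.null(res$assessment)) {
           dplyr::mutate(res$assessment, prevalence1 = lam, .before = 1)
         })
  })
  sweep_assessment <- purrr::map_dfr(runs, "assessment")
  if (nrow(sweep_assessment) > 0) {
    class(sweep_assessment) <- c("enrich_sweep", class(sweep_assessment))
  }
  list(config = cfg,
       sweep_designs = purrr::map_dfr(runs, "design"),
       sweep_assessment = sweep_assessment)
}

#' Write scenario results to disk
#'
#' Writes the calibration summary (`design.csv`), boundaries
#' (`boundaries.csv`), assessment rows (`assessment.csv`, with empty cells
#' as `NA` and proportion 0), and a JSON manifest (`manifest.json`:
#' resolved config, seed, package version) into `dir`. Sweep results write
#' `sweep_designs.csv` and `sweep_assessment.csv` (plot-ready: prevalence
#' against standardized bias / root-MSE / proportion per conditioning).
#'
#' @param results A list from [run_scenario()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(results, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  emit <- function(obj, name) {
    if (is.null(obj) || !nrow(obj)) return()
    p <- file.path(dir, name)
    readr::write_csv(as.data.frame(obj), p)
    paths <<- c(paths, p)
  }
  emit(results$design_summary, "design.csv")
  emit(results$boundaries, "boundaries.csv")
  emit(results$assessment, "assessment.csv")
  emit(results$sweep_designs, "sweep_designs.csv")
  emit(results$sweep_assessment, "sweep_assessment.csv")
  manifest <- list(
    config = results$config,
    package_version = as.character(utils::packageVersion("enrichsel")),
    files = basename(paths)
  )
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(paths, mp))
}
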