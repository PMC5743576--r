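# Orchestration: scenario config files, scenario output writing, and the
# end-to-end demo run.

#' Read a scenario configuration file
#'
#' Reads a YAML file with optional blocks `matrix` (sub-blocks `baseline`:
#' `active_persistence`, `activation`; and `satiation`: `target_active`,
#' `active_persistence`), `emissions` (the four gamma parameters),
#' `perturbation` (`step`, `synchrony_fraction`, `use_satiation`) and
#' `run` (`n_individuals`, `n_steps`, `seed`). Missing entries fall back
#' to the package defaults.
#'
#' @param path Path to a YAML configuration file.
#' @return A named list of configuration blocks.
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config file must contain a YAML mapping")
  cfg
}

#' Build a scenario from a configuration list
#'
#' @param cfg Configuration list as returned by [read_scenario_config()]
#'   (possibly empty: all defaults).
#' @param name Which of the four standard scenarios to build.
#' @param seed Optional seed overriding `cfg$run$seed`.
#' @return A `"scenario_spec"`.
#' @export
build_scenario <- function(cfg = list(),
                           name = c("control", "synchrony", "satiation", "combined"),
                           seed = NULL) {
  name <- match.arg(name)
  g <- function(block, key, default) {
    v <- cfg[[block]][[key]]
    if (is.null(v)) default else v
  }
  em <- emission_model(
    active_shape = g("emissions", "active_shape", 2),
    active_scale = g("emissions", "active_scale", 15),
    inactive_shape = g("emissions", "inactive_shape", 2),
    inactive_scale = g("emissions", "inactive_scale", 40))
  bp <- g("matrix", "baseline", list())
  baseline <- transition_matrix(
    active_persistence = if (is.null(bp$active_persistence)) 0.55 else bp$active_persistence,
    activation = if (is.null(bp$activation)) 0.05 else bp$activation)
  sp <- g("matrix", "satiation", list())
  sat_target <- if (is.null(sp$target_active)) 0.05 else sp$target_active
  sat_persist <- if (is.null(sp$active_persistence)) 0.55 else sp$active_persistence
  step <- g("perturbation", "step", 50)
  f <- g("perturbation", "synchrony_fraction", 0.9)
  run_seed <- if (!is.null(seed)) seed else g("run", "seed", 1L)
  sc <- pulse_scenario(name,
                       emissions = em,
                       n_individuals = g("run", "n_individuals", 500),
                       n_steps = g("run", "n_steps", 100),
                       seed = as.integer(run_seed),
                       perturbation_step = step,
                       synchrony_fraction = f,
                       satiation_active = sat_target,
                       active_persistence = sat_persist)
  sc$baseline <- baseline
  if (!is.null(sc$perturbation) && !is.null(sc$perturbation$post_matrix))
    sc$perturbation$post_matrix <- build_satiation_matrix(sat_target, sat_persist)
  sc
}

serialize_scenario <- function(scenario) {
  pert <- scenario$perturbation
  list(name = scenario$name,
       baseline = list(active_persistence = scenario$baseline["active", "active"],
                       activation = scenario$baseline["active", "inactive"]),
       emissions = unclass(scenario$emissions)[c("active_shape", "active_scale",
                                                 "inactive_shape", "inactive_scale")],
       perturbation = if (is.null(pert)) NULL else list(
         time_step = pert$time_step,
         synchrony_fraction = pert$synchrony_fraction,
         post_matrix = if (is.null(pert$post_matrix)) NULL else list(
           active_persistence = pert$post_matrix["active", "active"],
           activation = pert$post_matrix["active", "inactive"])),
       n_individuals = scenario$n_individuals,
       n_steps = scenario$n_steps, seed = scenario$seed,
       rng = "Mersenne-Twister")
}

#' Run one scenario and write its trajectory files
#'
#' Runs the stochastic simulation and the analytic solution for a
#' scenario and writes a per-step CSV (`step`, `analytic_mean_perch_cm`,
#' `simulated_mean_perch_cm`, `active_fraction`) plus a JSON sidecar with
#' the fully resolved scenario and seed.
#'
#' @param scenario A `"scenario_spec"`.
#' @param out_dir Output directory (created if needed).
#' @param name File stem; defaults to the scenario's name or "scenario".
#' @return Named character vector of the files written.
#' @export
write_scenario_run <- function(scenario, out_dir, name = NULL) {
  if (is.null(name)) name <- if (is.null(scenario$name)) "scenario" else scenario$name
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_scenario(scenario)
  traj <- analytic_trajectory(scenario)
  csv <- file.path(out_dir, paste0("scenario_", name, ".csv"))
  utils::write.csv(data.frame(
    step = seq_len(scenario$n_steps),
    analytic_mean_perch_cm = traj,
    simulated_mean_perch_cm = sim$mean_perch_by_step,
    active_fraction = sim$active_fraction_by_step), csv, row.names = FALSE)
  js <- file.path(out_dir, paste0("scenario_", name, ".json"))
  jsonlite::write_json(serialize_scenario(scenario), js, auto_unbox = TRUE,
                       digits = NA, null = "null")
  c(trajectory = csv, sidecar = js)
}

test_result_to_list <- function(tr) {
  out <- list(term = tr$term, statistic = tr$statistic, df = tr$df,
              p_value = tr$p_value, alpha = tr$alpha, model = tr$model)
  if (!is.null(tr$slope)) out$slope <- tr$slope
  out
}

#' End-to-end demonstration run
#'
#' Generates a synthetic field study, runs the full behavioural pipeline
#' (per-bout summaries, emission fitting from control bouts, the
#' treatment-by-time tests for all three responses, the perch/distance
#' test and the stage-interaction test), runs all four pulse scenarios
#' (stochastic and analytic), and writes every output plus a manifest to
#' `out_dir`. With the same seed the run is fully reproducible (manifests
#' differ only in timestamps).
#'
#' @param out_dir Writable output directory (created if needed).
#' @param seed Integer seed controlling the study and all simulations.
#' @param config Optional `"study_config"`; defaults to
#'   `study_config(seed = seed)`.
#' @return The manifest, invisibly: a list with the command, seed,
#'   package version, resolved configuration, test results and output
#'   file list.
#' @export
run_demo <- function(out_dir, seed = 1L, config = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  if (is.null(config)) config <- study_config(seed = seed)
  stopifnot(inherits(config, "study_config"))

  files <- character(0)
  step <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("demo stage `", stage, "` failed: ", conditionMessage(e), call. = FALSE))
  }

  study <- step("generate_study", generate_study(config))
  f_bouts <- file.path(out_dir, "bouts.csv")
  write_bout_table(study, f_bouts)
  files <- c(files, f_bouts)

  summaries <- step("summarize_bouts", summarize_bouts(study))
  f_sum <- file.path(out_dir, "bout_summaries.csv")
  utils::write.csv(summaries, f_sum, row.names = FALSE)
  files <- c(files, f_sum)

  em_fit <- step("fit_emission_model", fit_emission_model(study))
  f_em <- file.path(out_dir, "fitted_emissions.json")
  jsonlite::write_json(
    c(unclass(em_fit)[c("active_shape", "active_scale",
                        "inactive_shape", "inactive_scale")],
      list(n = as.list(attr(em_fit, "n")))),
    f_em, auto_unbox = TRUE, digits = NA)
  files <- c(files, f_em)

  tests <- step("hypothesis_tests", {
    out <- list()
    for (resp in c("perch", "moves", "attacks"))
      out[[paste0("treatment_by_time_", resp)]] <-
        test_result_to_list(test_treatment_by_time(summaries, resp))
    out$perch_vs_distance <- test_result_to_list(test_perch_vs_distance(summaries))
    out$stage_interaction_perch <-
      test_result_to_list(test_stage_interaction(summaries, "perch"))
    out
  })
  f_tests <- file.path(out_dir, "test_results.json")
  jsonlite::write_json(tests, f_tests, auto_unbox = TRUE, digits = NA)
  files <- c(files, f_tests)

  scen_files <- step("scenarios", {
    unlist(lapply(c("control", "synchrony", "satiation", "combined"),
                  function(nm) write_scenario_run(
                    pulse_scenario(nm, seed = seed), out_dir, nm)))
  })
  files <- c(files, unname(scen_files))

  manifest <- list(
    command = "run_demo",
    package = "foragepulse",
    version = as.character(utils::packageVersion("foragepulse")),
    seed = as.integer(seed),
    config = serialize_study_config(config),
    tests = tests,
    files = basename(files),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  f_manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, f_manifest, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}

serialize_study_config <- function(cfg) {
  out <- unclass(cfg)
  out$emissions <- unclass(cfg$emissions)[c("active_shape", "active_scale",
                                            "inactive_shape", "inactive_scale")]
  out$baseline <- list(active_persistence = cfg$baseline["active", "active"],
                       activation = cfg$baseline["active", "inactive"])
  out
}
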