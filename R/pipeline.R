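#' Read a run configuration file
#'
#' Configurations are plain YAML (`.yml`/`.yaml`) or JSON (`.json`) mappings;
#' the same keys can be passed directly as a named list to every `run_*`
#' function. Recognized keys (all optional unless noted):
#'
#' * `rates_pre`: mapping `k1..k4` (default: the warm reference rates)
#' * one of `scenario` (see [scenario_names()]), `factors` (mapping
#'   `f1..f4`) or `rates_post` (mapping `k1..k4`) -- required by
#'   [run_simulate()]
#' * `shift_time` (default 400), `duration` (default 1200), `n_points`
#' * control keys: `points`, `split`, `mode`, `target_species`
#' * Pareto keys: `level`, `n_grid`
#' * synthesis keys: `time_points_h`, `n_replicates`, `proteins`, `cv`,
#'   `amplitude`, `period`, `seed`, `hours_per_unit`
#' * fit keys: `data_file`, `known`, `bounds`, `n_starts`
#'
#' @param path config file path
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config must be YAML or JSON", call. = FALSE)
  }
}

as_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_run_config(config)
  }
  if (!is.list(config)) stop("config must be a list or a file path",
                             call. = FALSE)
  config
}

cfg <- function(config, key, default) {
  if (!is.null(config[[key]])) config[[key]] else default
}

#' Resolve a configuration into a shift protocol
#'
#' @param config named list (or config file path); see [read_run_config()]
#' @return A [shift_protocol].
#' @export
resolve_protocol <- function(config) {
  config <- as_config(config)
  rates_pre <- as_rate_constants(cfg(config, "rates_pre",
                                     reference_rates(24)))
  rates_post <- if (!is.null(config$scenario)) {
    apply_shift(rates_pre, scenario_factors(config$scenario))
  } else if (!is.null(config$factors)) {
    f <- config$factors
    apply_shift(rates_pre, shift_factors(f$f1, f$f2, f$f3, f$f4))
  } else if (!is.null(config$rates_post)) {
    as_rate_constants(config$rates_post)
  } else {
    stop("config must provide a scenario, shift factors, or explicit ",
         "post-shift rates", call. = FALSE)
  }
  shift_protocol(rates_pre, rates_post,
                 shift_time = cfg(config, "shift_time", 400),
                 duration = cfg(config, "duration", 1200))
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

ensure_dir <- function(out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  out_dir
}

#' Run a temperature-shift simulation and write its outputs
#'
#' Resolves the configuration into a [shift_protocol], integrates it, and
#' writes `trajectory.tsv` plus `summary.json` (pre/post rate sets, exact
#' pre/post steady states, final state, and whether the post-shift segment
#' settled). The configuration is validated and the simulation completed
#' before any file is written.
#'
#' @param config named list or config file path (see [read_run_config()])
#' @param out_dir output directory (created if missing)
#' @return Invisibly, a list with the trajectory and the summary.
#' @examples
#' \donttest{
#' out <- run_simulate(list(scenario = "degradation_spared"), tempdir())
#' out$summary$post_steady_state
#' }
#' @export
run_simulate <- function(config, out_dir) {
  config <- as_config(config)
  protocol <- resolve_protocol(config)
  traj <- simulate_shift(protocol,
                         n_points = cfg(config, "n_points", 601))
  post <- traj[traj$time >= protocol$shift_time, , drop = FALSE]
  class(post) <- class(traj)
  summary <- list(
    scenario = cfg(config, "scenario", NULL),
    rates_pre = as.list(unclass(protocol$rates_pre)),
    rates_post = as.list(unclass(protocol$rates_post)),
    shift_time = protocol$shift_time,
    duration = protocol$duration,
    pre_steady_state = unclass(steady_state(protocol$rates_pre)),
    post_steady_state = unclass(steady_state(protocol$rates_post)),
    final_state = list(time = traj$time[nrow(traj)],
                       mrna = traj$mrna[nrow(traj)],
                       protein = traj$protein[nrow(traj)]),
    settled_after_shift = is_steady(post)
  )
  ensure_dir(out_dir)
  write_trajectory(traj, file.path(out_dir, "trajectory.tsv"))
  write_json_report(summary, file.path(out_dir, "summary.json"))
  invisible(list(trajectory = traj, summary = summary))
}

#' Run the control-point analysis and write its report
#'
#' For each requested control point (default: all four, singly) computes
#' the required fold-change to restore the pre-shift protein steady state,
#' the mRNA side effect, the transition time (rate-sum formula and the
#' relaxation-time alternative), and simulates the requested response modes;
#' multi-point sets are handled through [combined_control()]. Writes
#' `control_report.json` and one trajectory TSV per point set and mode.
#'
#' @param config named list or config file path. Keys: `points` (character
#'   vector = single points, or list of character vectors for combinations),
#'   `mode` (subset of `immediate`/`settled`, default both), `split`,
#'   `target_species`, plus the protocol keys of [resolve_protocol()].
#' @param out_dir output directory
#' @return Invisibly, the report list.
#' @export
run_control <- function(config, out_dir) {
  config <- as_config(config)
  if (is.null(config$scenario) && is.null(config$factors) &&
      is.null(config$rates_post)) {
    config$scenario <- "degradation_spared"
  }
  protocol <- resolve_protocol(config)
  pre_ss <- steady_state(protocol$rates_pre)
  point_sets <- cfg(config, "points", as.list(control_points()))
  if (is.character(point_sets)) point_sets <- as.list(point_sets)
  modes <- cfg(config, "mode", c("immediate", "settled"))
  entries <- list()
  trajs <- list()
  for (pts in point_sets) {
    label <- paste(pts, collapse = "+")
    entry <- tryCatch({
      sol <- if (length(pts) == 1L) {
        required_fold_change(pts, protocol$rates_post, pre_ss,
                             target_species = cfg(config, "target_species",
                                                  if (pts == "mrna_degradation")
                                                    "protein" else NULL))
      } else {
        combined_control(pts, protocol$rates_post, pre_ss,
                         split = cfg(config, "split", "equal"))
      }
      for (m in modes) {
        trajs[[paste0("control_", gsub("\\+", "_", label), "_", m, ".tsv")]] <-
          response_simulation(sol, mode = m)
      }
      list(
        points = as.list(pts),
        fold_changes = sol$fold_changes,
        adjusted_rates = as.list(unclass(sol$adjusted_rates)),
        achieved_steady_state = unclass(sol$achieved_ss),
        mrna_side_effect = mrna_side_effect(sol, pre_ss),
        transition_time = list(
          rate_sum = list(
            mrna = transition_time(sol$adjusted_rates, "mrna"),
            protein = transition_time(sol$adjusted_rates, "protein")),
          relaxation = list(
            mrna = transition_time(sol$adjusted_rates, "mrna", "relaxation"),
            protein = transition_time(sol$adjusted_rates, "protein",
                                      "relaxation")))
      )
    }, error = function(e) list(points = as.list(pts),
                                error = conditionMessage(e)))
    entries[[label]] <- entry
  }
  report <- list(
    rates_post = as.list(unclass(protocol$rates_post)),
    target_steady_state = unclass(pre_ss),
    solutions = entries
  )
  ensure_dir(out_dir)
  write_json_report(report, file.path(out_dir, "control_report.json"))
  for (nm in names(trajs)) write_trajectory(trajs[[nm]],
                                            file.path(out_dir, nm))
  invisible(report)
}

#' Compute and write the compensation Pareto front
#'
#' Sweeps the production up-factor against the degradation down-factor at
#' the constrained product (see [pareto_front()]) and writes `pareto.tsv`
#' (`up_factor`, `down_factor`, `tau`). The boundary rows are the
#' pure-degradation (first) and pure-production (last) solutions.
#'
#' @param config named list or config file path; keys `level` (default
#'   `"mrna"`), `n_grid` (default 50) plus the protocol keys
#' @param out_dir output directory
#' @return Invisibly, the `pareto_front` data frame.
#' @export
run_pareto <- function(config, out_dir) {
  config <- as_config(config)
  if (is.null(config$scenario) && is.null(config$factors) &&
      is.null(config$rates_post)) {
    config$scenario <- "degradation_spared"
  }
  protocol <- resolve_protocol(config)
  front <- pareto_front(protocol$rates_post,
                        steady_state(protocol$rates_pre),
                        level = cfg(config, "level", "mrna"),
                        n_grid = cfg(config, "n_grid", 50))
  message(sprintf("Pareto front: tau from %g (cheapest) to %g (fastest)",
                  front$tau[1], front$tau[nrow(front)]))
  ensure_dir(out_dir)
  write_pareto(front, file.path(out_dir, "pareto.tsv"))
  invisible(front)
}

#' Generate and write a synthetic blot dataset
#'
#' Builds the [blot_design] and [noise_model] from the configuration,
#' generates the dataset (deterministic given `seed`), and writes
#' `blots_tidy.tsv`, `blots_averaged.tsv` and `provenance.json` (all
#' parameters, the seed and the package version -- enough to regenerate the
#' files byte-identically).
#'
#' @param config named list or config file path; keys `time_points_h`,
#'   `n_replicates`, `proteins`, `cv`, `amplitude`, `period`, `seed`,
#'   `hours_per_unit` plus the protocol keys
#' @param out_dir output directory
#' @return Invisibly, the `blot_dataset`.
#' @export
run_synth <- function(config, out_dir) {
  config <- as_config(config)
  if (is.null(config$scenario) && is.null(config$factors) &&
      is.null(config$rates_post)) {
    config$scenario <- "degradation_spared"
  }
  protocol <- resolve_protocol(config)
  design <- blot_design(
    time_points_h = cfg(config, "time_points_h",
                        c(0, 0.5 / 60, 5 / 60, 20 / 60, 1, 5, 24, 48)),
    n_replicates = cfg(config, "n_replicates", 3),
    proteins = cfg(config, "proteins", c("PetA", "PsbA", "AtpA")))
  noise <- noise_model(
    multiplicative_cv = cfg(config, "cv", 0.1),
    fluctuation_amplitude = cfg(config, "amplitude", 0.15),
    fluctuation_period = cfg(config, "period", 24),
    seed = cfg(config, "seed", 1L))
  hours_per_unit <- cfg(config, "hours_per_unit", 1)
  dataset <- generate_blots(design, protocol, noise,
                            hours_per_unit = hours_per_unit)
  provenance <- list(
    package = "coldshift",
    version = as.character(utils::packageVersion("coldshift")),
    rates_pre = as.list(unclass(protocol$rates_pre)),
    rates_post = as.list(unclass(protocol$rates_post)),
    design = unclass(design),
    noise = unclass(noise),
    hours_per_unit = hours_per_unit
  )
  ensure_dir(out_dir)
  write_blots(dataset, file.path(out_dir, "blots_tidy.tsv"),
              file.path(out_dir, "blots_averaged.tsv"))
  write_json_report(provenance, file.path(out_dir, "provenance.json"))
  invisible(dataset)
}

#' Fit rate constants to a time-course file and write the report
#'
#' Reads a TSV time course (absolute columns `time`/`mrna`/`protein`, or a
#' normalized series with `time`/`relative`), runs [fit_rates()], and
#' writes `fit.json` with the estimates, fixed parameters, residual sum of
#' squares, convergence flag and identifiability notes.
#'
#' @param config named list or config file path; keys `data_file`
#'   (required), `known`, `bounds`, `seed`, `n_starts`
#' @param out_dir output directory
#' @return Invisibly, the `rate_fit`.
#' @export
run_fit <- function(config, out_dir) {
  config <- as_config(config)
  if (is.null(config$data_file)) stop("config needs data_file",
                                      call. = FALSE)
  data <- utils::read.delim(config$data_file, check.names = FALSE)
  fit <- fit_rates(data,
                   known = cfg(config, "known", NULL),
                   bounds = cfg(config, "bounds", c(1e-3, 1e3)),
                   seed = cfg(config, "seed", 1L),
                   n_starts = cfg(config, "n_starts", 5L))
  report <- list(
    estimates = if (is.null(fit$estimates)) NULL
                else as.list(unclass(fit$estimates)),
    free = fit$free,
    fixed = fit$fixed,
    rss = fit$rss,
    converged = fit$converged,
    scale_identifiable = fit$scale_identifiable,
    ratios = fit$ratios,
    n_data = fit$n_data
  )
  ensure_dir(out_dir)
  write_json_report(report, file.path(out_dir, "fit.json"))
  invisible(fit)
}
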