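#' Default pipeline configuration
#'
#' The canonical configuration for the staged LPA scenario: baseline rates,
#' perturbation timing, observable parameters and synthetic-data settings.
#' All times are seconds, concentrations µM, amplitudes pA, fluorescence
#' arbitrary units.
#'
#' @return A nested list with blocks `baseline`, `scenario`, `observables`,
#'   `synth`, `grid` and `seed`.
#' @export
default_config <- function() {
  list(
    baseline = list(alpha = 0.008, beta = 0.5, sigma = 1.67),
    scenario = list(t_exo_up = 300, lead = 60, alpha_factor = 1.5,
                    beta_change_value = 0.01, beta_change_mode = "multiplicative"),
    observables = list(n_pool = 200, gain = 1000, baseline_f = 100),
    synth = list(
      amplitude = list(meanlog = log(20), sdlog = 0.4, floor_pA = 5),
      noise = list(phluorin_add_sd = 5, ca_add_sd = 2, dose_mult_sd = 0.10),
      dose_response = list(concentrations = c(0.1, 0.3, 1, 3, 10, 30, 50),
                           reps = 5, r_min = 0, r_max = 100,
                           ec50 = 1.2, slope = 0.4)
    ),
    grid = list(t_end = 1080, dt = 1),
    seed = 20260101
  )
}

config_blocks <- c("baseline", "scenario", "observables", "synth", "grid", "seed")

#' Read and validate a pipeline configuration
#'
#' Reads a JSON configuration, rejects unknown keys (typo safety), fills in
#' defaults for missing ones, and validates every block before any
#' computation runs.
#'
#' @param path Path to a JSON file, or a list already in memory.
#' @return A validated configuration list.
#' @export
read_config <- function(path) {
  cfg <- if (is.list(path)) path
         else jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(cfg), config_blocks)
  if (length(unknown)) {
    abort(sprintf("unknown configuration key(s): %s", paste(unknown, collapse = ", ")))
  }
  full <- modifyList(default_config(), cfg)
  # validation via the constructors; errors propagate with their diagnostics
  b <- full$baseline
  rate_set(b$alpha, b$beta, b$sigma)
  config_scenario_params(full)
  if (full$observables$n_pool <= 0) abort("`observables$n_pool` must be positive.")
  if (full$grid$t_end <= 0 || full$grid$dt <= 0) abort("`grid` times must be positive.")
  full
}

config_scenario_params <- function(cfg) {
  s <- cfg$scenario
  scenario_params(t_exo_up = s$t_exo_up, lead = s$lead,
                  alpha_factor = s$alpha_factor,
                  beta_change_value = s$beta_change_value,
                  beta_change_mode = s$beta_change_mode,
                  baseline = rate_set(cfg$baseline$alpha, cfg$baseline$beta,
                                      cfg$baseline$sigma))
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Run the scenario simulation pipeline
#'
#' Simulates the configured staged scenario and its alpha-only control,
#' writes the trajectory and release-flux series as CSV and the
#' [masking_check()] report as JSON. Purely deterministic: identical
#' configurations give byte-identical outputs.
#'
#' @param config A configuration list or JSON path (see [read_config()]).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the output paths and the masking report.
#' @export
run_simulate <- function(config = default_config(), out_dir = ".") {
  cfg <- read_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- config_scenario_params(cfg)
  times <- seq(0, cfg$grid$t_end, by = cfg$grid$dt)
  traj_full <- simulate_pool(build_lpa_schedule(params), times = times)
  traj_ctrl <- simulate_pool(build_lpa_schedule(params, alpha_only = TRUE), times = times)
  report <- masking_check(traj_full, traj_ctrl)

  paths <- file.path(out_dir, c("trajectory.csv", "trajectory_alpha_only.csv",
                                "flux.csv", "masking_report.json"))
  readr::write_csv(as_tibble(traj_full), paths[1])
  readr::write_csv(as_tibble(traj_ctrl), paths[2])
  readr::write_csv(as_tibble(release_flux(traj_full)), paths[3])
  write_json_report(list(
    t_beta = attr(report, "t_beta"),
    scenarios = purrr::transpose(as.list(as_tibble(report)))
  ), paths[4])
  invisible(list(paths = paths, report = report,
                 trajectory = traj_full, control = traj_ctrl))
}

#' Generate the synthetic inputs of the pipeline
#'
#' Writes seeded synthetic data for every analysis stage: miniature-event
#' trains under the full scenario and under baseline rates, a
#' SynaptopHluorin trace, a somatic calcium trace, a dose-response table,
#' and a manifest JSON recording all parameters and derived per-stream
#' seeds. Rerunning with the same configuration and seed reproduces every
#' file byte for byte.
#'
#' @inheritParams run_simulate
#' @param seed Overrides the configuration seed when given.
#' @return Invisibly, a list with output paths and the manifest.
#' @export
run_synth <- function(config = default_config(), out_dir = ".", seed = NULL) {
  cfg <- read_config(config)
  if (!is.null(seed)) cfg$seed <- seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- config_scenario_params(cfg)
  n_pool <- cfg$observables$n_pool
  amp <- do.call(amplitude_model, cfg$synth$amplitude)
  seeds <- purrr::map(setNames(nm = c("events_lpa", "events_baseline", "phluorin",
                                      "calcium", "dose")),
                      ~ substream_seed(cfg$seed, .x))

  dur <- cfg$grid$t_end
  rf_full <- scenario_rate_fn(params, n_pool = n_pool)
  base_flux <- n_pool * cfg$baseline$alpha *
    steady_state(params$baseline)[["u1"]]
  train_lpa <- sample_event_train(rf_full, dur, amp, seed = seeds$events_lpa)
  train_base <- sample_event_train(base_flux, dur, amp, seed = seeds$events_baseline)

  times <- seq(0, dur, by = cfg$grid$dt)
  traj <- simulate_pool(build_lpa_schedule(params), times = times)
  ph <- synth_phluorin_trace(traj, cfg$observables$gain, cfg$observables$baseline_f,
                             noise_add_sd = cfg$synth$noise$phluorin_add_sd,
                             seed = seeds$phluorin)
  ca <- synth_ca_trace(noise_add_sd = cfg$synth$noise$ca_add_sd, seed = seeds$calcium)
  dr_cfg <- cfg$synth$dose_response
  dr <- synth_dose_response(concentrations = dr_cfg$concentrations,
                            reps = dr_cfg$reps, r_min = dr_cfg$r_min,
                            r_max = dr_cfg$r_max, ec50 = dr_cfg$ec50,
                            slope = dr_cfg$slope,
                            noise_mult_sd = cfg$synth$noise$dose_mult_sd,
                            seed = seeds$dose)

  paths <- file.path(out_dir, c("events_lpa.csv", "events_baseline.csv",
                                "phluorin_trace.csv", "ca_trace.csv",
                                "dose_response.csv", "manifest.json"))
  readr::write_csv(as_tibble(train_lpa), paths[1])
  readr::write_csv(as_tibble(train_base), paths[2])
  readr::write_csv(as_tibble(ph), paths[3])
  ca_out <- as_tibble(ca)
  ca_out$stim_time_s <- attr(ca, "stim_time")
  readr::write_csv(ca_out, paths[4])
  readr::write_csv(dr, paths[5])
  manifest <- list(config = cfg, substream_seeds = seeds,
                   n_events = list(lpa = nrow(train_lpa), baseline = nrow(train_base)),
                   files = basename(paths[1:5]))
  write_json_report(manifest, paths[6])
  invisible(list(paths = paths, manifest = manifest))
}

read_event_train_csv <- function(path, duration = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!"time_s" %in% names(df)) {
    abort(sprintf("%s: missing required column `time_s`.", basename(path)))
  }
  event_train(df$time_s,
              if ("amplitude_pA" %in% names(df)) df$amplitude_pA else NULL,
              duration %||% max(df$time_s) * (1 + 1e-9))
}

#' Fit a model to a data file and write a JSON report
#'
#' Dispatches to [fit_boltzmann()] (`kind = "boltzmann"`,
#' dose-response CSV), [fit_exp_decay()] (`kind = "expdecay"`, trace CSV) or
#' [fit_scenario()] (`kind = "scenario"`, event-train CSV). The report
#' records the estimates, their uncertainties, the residual sum of squares
#' or log-likelihood, convergence flags, and the MD5 checksum of the input
#' file.
#'
#' @param kind One of `"boltzmann"`, `"expdecay"`, `"scenario"`.
#' @param data_file Path to the input CSV.
#' @param config Configuration list or JSON path (used for the scenario
#'   baseline and fixed parameters).
#' @param out_file Path of the JSON report to write.
#' @param ... Further arguments passed to the fitting function.
#' @return Invisibly, the fit object.
#' @export
run_fit <- function(kind = c("boltzmann", "expdecay", "scenario"),
                    data_file, config = default_config(),
                    out_file = "fit_report.json", ...) {
  kind <- match.arg(kind)
  cfg <- read_config(config)
  checksum <- unname(tools::md5sum(data_file))
  fit <- switch(kind,
    boltzmann = {
      df <- readr::read_csv(data_file, show_col_types = FALSE)
      if (!all(c("concentration_um", "response") %in% names(df))) {
        abort(sprintf("%s: need columns `concentration_um` and `response`.",
                      basename(data_file)))
      }
      fit_boltzmann(df, ...)
    },
    expdecay = {
      df <- readr::read_csv(data_file, show_col_types = FALSE)
      fit_exp_decay(df, ...)
    },
    scenario = {
      train <- read_event_train_csv(data_file, duration = cfg$grid$t_end)
      fit_scenario(train,
                   baseline = rate_set(cfg$baseline$alpha, cfg$baseline$beta,
                                       cfg$baseline$sigma),
                   ...)
    })
  report <- list(kind = kind,
                 input = basename(data_file),
                 input_md5 = checksum,
                 parameters = as.list(tidy(fit)),
                 summary = as.list(glance(fit)))
  write_json_report(report, out_file)
  invisible(fit)
}
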