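#' Parameters of the staged LPA perturbation
#'
#' LPA signalling is represented in the model as a staged change of two rate
#' constants: the recycling rate `beta` collapses first, then the exocytosis
#' rate `alpha` rises by `alpha_factor` a fixed `lead` seconds later. The
#' endocytosis rate `sigma` is never touched. The default stage encodes the
#' reported perturbation: `alpha` multiplied by 1.5 at `t_exo_up`, `beta`
#' reduced "by 0.01" 60 s earlier.
#'
#' The phrase "reduced by 0.01" admits two readings, both available here:
#'
#' * `beta_change_mode = "multiplicative"` (default): `beta -> 0.01 * beta`
#'   (0.5 -> 0.005 s^-1), a near-collapse of recycling;
#' * `beta_change_mode = "absolute"`: `beta -> beta - 0.01` (0.5 -> 0.49
#'   s^-1), a barely perceptible reduction.
#'
#' @param t_exo_up Time of the exocytosis increase (s).
#' @param lead Interval by which the recycling reduction precedes it (s,
#'   `>= 0`).
#' @param alpha_factor Multiplier applied to `alpha` (> 0).
#' @param beta_change_value Magnitude of the `beta` change (scale factor or
#'   absolute decrement, depending on `beta_change_mode`).
#' @param beta_change_mode `"multiplicative"` or `"absolute"`.
#' @param baseline Resting [rate_set()].
#' @return A `scenario_params` object.
#' @examples
#' scenario_params()
#' @export
scenario_params <- function(t_exo_up = 300,
                            lead = 60,
                            alpha_factor = 1.5,
                            beta_change_value = 0.01,
                            beta_change_mode = c("multiplicative", "absolute"),
                            baseline = default_rates()) {
  beta_change_mode <- match.arg(beta_change_mode)
  assert_rate_set(baseline)
  if (!is.numeric(lead) || length(lead) != 1L || is.na(lead) || lead < 0) {
    abort("`lead` must be a single non-negative duration in seconds.")
  }
  if (!is.numeric(alpha_factor) || length(alpha_factor) != 1L ||
      is.na(alpha_factor) || alpha_factor <= 0) {
    abort("`alpha_factor` must be a single positive number.")
  }
  if (!is.numeric(t_exo_up) || length(t_exo_up) != 1L || is.na(t_exo_up)) {
    abort("`t_exo_up` must be a single time in seconds.")
  }
  beta_new <- perturbed_beta(baseline$beta, beta_change_value, beta_change_mode)
  if (beta_new < 0) {
    abort(sprintf(
      "the beta change (%s mode, value %g) would drive beta negative (%g -> %g).",
      beta_change_mode, beta_change_value, baseline$beta, beta_new))
  }
  structure(list(t_exo_up = t_exo_up, lead = lead, alpha_factor = alpha_factor,
                 beta_change_value = beta_change_value,
                 beta_change_mode = beta_change_mode, baseline = baseline),
            class = "scenario_params")
}

perturbed_beta <- function(beta, value, mode) {
  if (mode == "multiplicative") beta * value else beta - value
}

#' @export
print.scenario_params <- function(x, ...) {
  cat(sprintf(
    "<scenario_params> alpha x%g at t = %g s; beta %s %g at t = %g s (lead %g s)\n",
    x$alpha_factor,
    x$t_exo_up,
    if (x$beta_change_mode == "multiplicative") "x" else "-",
    x$beta_change_value,
    x$t_exo_up - x$lead,
    x$lead))
  print(x$baseline)
  invisible(x)
}

assert_scenario_params <- function(x) {
  if (!inherits(x, "scenario_params")) abort("expected `scenario_params()`.")
  invisible(x)
}

#' Build the rate schedule of the staged LPA perturbation
#'
#' Three segments: baseline until `t_exo_up - lead`; then `beta` changed with
#' `alpha` untouched; then additionally `alpha` multiplied by `alpha_factor`
#' from `t_exo_up` onward. `sigma` is constant throughout. A null
#' perturbation (lead 0, `alpha_factor` 1, beta unchanged) collapses to a
#' single baseline segment.
#'
#' @param params A [scenario_params()].
#' @param alpha_only If `TRUE`, build the control in which only the `alpha`
#'   step is applied (recycling untouched) — the comparison trajectory used
#'   by [masking_check()].
#' @return A [rate_schedule()].
#' @examples
#' build_lpa_schedule(scenario_params())
#' @export
build_lpa_schedule <- function(params = scenario_params(), alpha_only = FALSE) {
  assert_scenario_params(params)
  b <- params$baseline
  beta_new <- if (alpha_only) b$beta
              else perturbed_beta(b$beta, params$beta_change_value, params$beta_change_mode)
  stage1 <- rate_set(b$alpha, beta_new, b$sigma)
  stage2 <- rate_set(b$alpha * params$alpha_factor, beta_new, b$sigma)
  t_beta <- params$t_exo_up - params$lead
  bps <- c(t_beta, params$t_exo_up)
  segs <- list(b, stage1, stage2)
  # drop zero-length or no-op segments so the breakpoints stay strictly increasing
  if (params$lead == 0) { segs <- segs[-2L]; bps <- bps[-1L] }
  null_change <- purrr::map2_lgl(segs[-length(segs)], segs[-1L],
                                 ~ identical(unclass(.x), unclass(.y)))
  while (any(null_change)) {
    i <- which(null_change)[1L]
    segs <- segs[-(i + 1L)]
    bps <- bps[-i]
    if (length(segs) == 1L) break
    null_change <- purrr::map2_lgl(segs[-length(segs)], segs[-1L],
                                   ~ identical(unclass(.x), unclass(.y)))
  }
  rate_schedule(segs, bps)
}

#' Instantaneous release flux along a trajectory
#'
#' The release flux `alpha(t) * u1(t)` is the fraction of the vesicle pool
#' fusing per second — the model quantity that drives miniature-EPSC
#' frequency. At a rate breakpoint the flux inherits the right-continuous
#' rate convention of the trajectory.
#'
#' @param traj A `pool_trajectory` from [simulate_pool()].
#' @return A tibble of class `flux_series` with columns `time_s` and
#'   `flux_per_s`.
#' @export
release_flux <- function(traj) {
  assert_pool_trajectory(traj)
  out <- tibble(time_s = traj$time_s, flux_per_s = traj$alpha * traj$u1)
  structure(out, class = c("flux_series", class(tibble())),
            schedule = attr(traj, "schedule"))
}

#' Does the early recycling collapse mask the release increase?
#'
#' Compares the release flux of the full staged scenario against the
#' alpha-only control on a common time grid. For each trajectory the peak
#' flux after the recycling change is expressed relative to the
#' pre-perturbation baseline flux; a scenario is flagged `masked` when its
#' flux never exceeds that baseline after the `beta` change (within `tol`).
#'
#' Besides the grid samples, the exact right-hand limit of the flux at every
#' rate breakpoint is included in the peak search (the flux jumps with
#' `alpha` while `u1` is continuous), so the verdict does not depend on
#' whether the sampling grid happens to resolve a short-lived excursion.
#'
#' @param traj_full Trajectory of the staged scenario.
#' @param traj_alpha_only Trajectory of the alpha-only control, on the same
#'   time grid.
#' @param t_beta Time of the recycling change (s); taken from the full
#'   trajectory's schedule when `NULL`.
#' @param tol Relative tolerance on "exceeds baseline" (default 0: strict).
#' @return A tibble of class `masking_report`, one row per scenario
#'   (`"full"`, `"alpha_only"`), with columns `peak_flux_ratio` (peak
#'   post-change flux / baseline flux), `t_peak` (s) and `masked`.
#' @examples
#' p <- scenario_params()
#' tr_full <- simulate_pool(build_lpa_schedule(p))
#' tr_ctrl <- simulate_pool(build_lpa_schedule(p, alpha_only = TRUE))
#' masking_check(tr_full, tr_ctrl)
#' @export
masking_check <- function(traj_full, traj_alpha_only, t_beta = NULL, tol = 0) {
  assert_pool_trajectory(traj_full)
  assert_pool_trajectory(traj_alpha_only)
  if (!isTRUE(all.equal(traj_full$time_s, traj_alpha_only$time_s))) {
    abort("the two trajectories must share a common time grid.")
  }
  if (is.null(t_beta)) {
    bps <- schedule_breakpoints(attr(traj_full, "schedule"))
    t_beta <- if (length(bps)) bps[1L] else traj_full$time_s[1L]
  }
  rows <- purrr::map2(list(traj_full, traj_alpha_only), c("full", "alpha_only"),
                      function(traj, label) {
    fl <- release_flux(traj)
    baseline <- fl$flux_per_s[1L]
    cand <- dplyr::filter(fl, .data$time_s >= t_beta)
    # exact right limits at breakpoints: new alpha times the continuous u1
    sched <- attr(traj, "schedule")
    for (bp in schedule_breakpoints(sched)) {
      if (bp < t_beta || bp < min(traj$time_s) || bp > max(traj$time_s)) next
      u_bp <- state_at(sched, bp, attr(traj, "initial"))["u1", 1L]
      a_bp <- rates_at(sched, bp)$alpha
      cand <- dplyr::bind_rows(cand, tibble(time_s = bp, flux_per_s = a_bp * u_bp))
    }
    peak <- unname(cand$flux_per_s[which.max(cand$flux_per_s)])
    tibble(scenario = label,
           baseline_flux = unname(baseline),
           peak_flux_ratio = peak / unname(baseline),
           t_peak = unname(cand$time_s[which.max(cand$flux_per_s)]),
           masked = peak <= unname(baseline) * (1 + tol))
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("masking_report", class(tibble())), t_beta = t_beta)
}
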