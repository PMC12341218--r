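#' Miniature-event train
#'
#' Timestamps (and optional amplitudes) of miniature postsynaptic currents
#' recorded over a known duration. Times must be non-decreasing and lie
#' within `[0, duration]`; amplitudes, when present, must be positive.
#'
#' @param times Event times (s).
#' @param amplitudes Optional per-event amplitudes (pA, > 0).
#' @param duration Recording length (s).
#' @return A tibble of class `event_train` with column `time_s` (and
#'   `amplitude_pA` when amplitudes are given); the recording length is kept
#'   in attribute `"duration"`.
#' @export
event_train <- function(times, amplitudes = NULL, duration) {
  times <- as.numeric(times)
  if (anyNA(times) || is.unsorted(times)) {
    abort("event `times` must be non-missing and non-decreasing.")
  }
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0) {
    abort("`duration` must be a single positive recording length in seconds.")
  }
  if (length(times) && (min(times) < 0 || max(times) > duration)) {
    abort("event times must lie within [0, duration].")
  }
  out <- tibble(time_s = times)
  if (!is.null(amplitudes)) {
    amplitudes <- as.numeric(amplitudes)
    if (length(amplitudes) != length(times)) {
      abort("`amplitudes` must have one value per event.")
    }
    if (anyNA(amplitudes) || any(amplitudes <= 0)) {
      abort("amplitudes must all be positive (pA).")
    }
    out$amplitude_pA <- amplitudes
  }
  structure(out, class = c("event_train", class(tibble())), duration = duration)
}

assert_event_train <- function(x) {
  if (!inherits(x, "event_train")) abort("expected an `event_train` (see `event_train()`).")
  invisible(x)
}

train_duration <- function(train) attr(train, "duration")

#' Expected miniature-EPSC rate along a trajectory
#'
#' Under the one-fused-vesicle-one-mEPSC convention the expected event rate
#' is `n_pool * alpha(t) * u1(t)` events per second, where `n_pool` is the
#' effective releasable pool size (detectability losses folded in).
#'
#' @param traj A `pool_trajectory`.
#' @param n_pool Effective pool size (> 0, events per unit flux).
#' @return A tibble with columns `time_s` and `rate_hz`.
#' @examples
#' traj <- simulate_pool(rate_schedule(default_rates()), times = 0:10)
#' mepsc_rate(traj, n_pool = 100)
#' @export
mepsc_rate <- function(traj, n_pool) {
  assert_pool_trajectory(traj)
  if (!is.numeric(n_pool) || length(n_pool) != 1L || is.na(n_pool) || n_pool <= 0) {
    abort("`n_pool` must be a single positive pool size.")
  }
  fl <- release_flux(traj)
  tibble(time_s = fl$time_s, rate_hz = n_pool * fl$flux_per_s)
}

#' SynaptopHluorin fluorescence predicted from a trajectory
#'
#' SynaptopHluorin is quenched at the acidic intravesicular pH and fluoresces
#' while the vesicle lumen is exposed to extracellular pH, so the signal
#' reports the fused fraction: `F(t) = baseline_f + gain * u2(t)`.
#'
#' @param traj A `pool_trajectory`.
#' @param gain Fluorescence per unit fused fraction (a.f.u., > 0).
#' @param baseline_f Baseline fluorescence (a.f.u.).
#' @return A tibble of class `phluorin_trace` with columns `time_s`, `f_afu`.
#' @export
phluorin_signal <- function(traj, gain, baseline_f = 0) {
  assert_pool_trajectory(traj)
  if (!is.numeric(gain) || length(gain) != 1L || is.na(gain) || gain < 0) {
    abort("`gain` must be a single non-negative number (a.f.u. per unit fraction).")
  }
  out <- tibble(time_s = traj$time_s, f_afu = baseline_f + gain * traj$u2)
  structure(out, class = c("phluorin_trace", class(tibble())))
}

#' Ratiometric calcium trace
#'
#' A background-corrected fluorescence-ratio (or calibrated concentration)
#' time series with a known stimulus time.
#'
#' @param times Sample times (s), strictly increasing.
#' @param values Trace values (ratio units or nM), finite.
#' @param stim_time Stimulus application time (s).
#' @return A tibble of class `ca_trace` with columns `time_s`, `value` and
#'   attribute `"stim_time"`.
#' @export
ca_trace <- function(times, values, stim_time) {
  times <- as.numeric(times); values <- as.numeric(values)
  if (anyNA(times) || is.unsorted(times, strictly = TRUE)) {
    abort("`times` must be strictly increasing.")
  }
  if (length(values) != length(times) || anyNA(values) || any(!is.finite(values))) {
    abort("`values` must be finite and match `times` in length.")
  }
  if (!is.numeric(stim_time) || length(stim_time) != 1L || is.na(stim_time)) {
    abort("`stim_time` must be a single time in seconds.")
  }
  structure(tibble(time_s = times, value = values),
            class = c("ca_trace", class(tibble())), stim_time = stim_time)
}

#' Peak amplitude of a calcium response
#'
#' Implements the top-five quantification rule: the peak is the mean of the
#' five highest post-stimulus values minus the baseline. The baseline is the
#' mean of all pre-stimulus samples (or of the samples inside
#' `baseline_window` when given). Adding a constant to the whole trace
#' leaves the result unchanged.
#'
#' @param trace A [ca_trace()] (or a tibble with `time_s`, `value` plus
#'   `stim_time` supplied explicitly).
#' @param stim_time Stimulus time (s); defaults to the trace attribute.
#' @param baseline_window Optional `c(start, end)` window (s) over which the
#'   baseline is averaged; default: all samples strictly before `stim_time`.
#' @param n_top Number of highest post-stimulus values averaged (default 5).
#' @return The peak amplitude, in the units of the trace.
#' @examples
#' tr <- ca_trace(1:10, c(100, 100, 100, 200, 300, 280, 260, 240, 150, 120), stim_time = 3.5)
#' ca_peak(tr) # 156
#' @export
ca_peak <- function(trace, stim_time = NULL, baseline_window = NULL, n_top = 5) {
  if (!is_tibble(trace) || !all(c("time_s", "value") %in% names(trace))) {
    abort("`trace` must have columns `time_s` and `value`.")
  }
  stim_time <- stim_time %||% attr(trace, "stim_time")
  if (is.null(stim_time)) abort("`stim_time` is required (attribute or argument).")
  pre <- if (is.null(baseline_window)) trace$value[trace$time_s < stim_time]
         else trace$value[trace$time_s >= baseline_window[1] & trace$time_s <= baseline_window[2]]
  post <- trace$value[trace$time_s >= stim_time]
  if (length(pre) < 1L) abort("no pre-stimulus samples to estimate the baseline from.")
  if (length(post) < n_top) {
    abort(sprintf("need at least %d post-stimulus samples, got %d.", n_top, length(post)))
  }
  mean(sort(post, decreasing = TRUE)[seq_len(n_top)]) - mean(pre)
}

#' Normalise a response peak to a reference peak
#'
#' Expresses a peak as a percentage of a reference response (e.g. an LPA
#' calcium peak relative to the glutamate peak that marks the cell's maximal
#' response).
#'
#' @param peak Peak amplitude.
#' @param ref_peak Reference peak amplitude (> 0).
#' @return `100 * peak / ref_peak` (percent).
#' @export
normalize_to_reference <- function(peak, ref_peak) {
  if (!is.numeric(ref_peak) || any(is.na(ref_peak)) || any(ref_peak <= 0)) {
    abort("`ref_peak` must be positive.")
  }
  100 * peak / ref_peak
}

#' Bin an event train into a frequency series
#'
#' @param train An [event_train()].
#' @param edges Strictly increasing bin edges (s) within `[0, duration]`.
#' @return A tibble with columns `bin_start_s`, `bin_end_s`, `count`,
#'   `rate_hz` (count / width). The sum of `rate_hz * width` equals the
#'   number of events in `[min(edges), max(edges))`.
#' @export
bin_events <- function(train, edges) {
  assert_event_train(train)
  edges <- as.numeric(edges)
  if (length(edges) < 2L || anyNA(edges) || is.unsorted(edges, strictly = TRUE)) {
    abort("`edges` must be at least two strictly increasing times.")
  }
  if (min(edges) < 0 || max(edges) > train_duration(train)) {
    abort("`edges` must lie within [0, duration].")
  }
  idx <- findInterval(train$time_s, edges, rightmost.closed = FALSE)
  counts <- tabulate(idx[idx >= 1L & idx < length(edges)], nbins = length(edges) - 1L)
  tibble(bin_start_s = edges[-length(edges)],
         bin_end_s = edges[-1L],
         count = counts,
         rate_hz = counts / diff(edges))
}

#' Per-recording frequency ratio before vs after treatment
#'
#' The ratio of the event rate in a post-treatment window to the rate in a
#' pre-treatment window — the per-neuron statistic used to show the relative
#' frequency reduction after LPA.
#'
#' @param train An [event_train()].
#' @param pre_window,post_window `c(start, end)` windows (s); events are
#'   counted in `[start, end)`. Windows must not overlap, and the
#'   pre-window must contain at least one event.
#' @return `(post count / post width) / (pre count / pre width)`.
#' @examples
#' tr <- event_train(c(seq(1, 59, 2), seq(61, 119, 4)), duration = 120)
#' frequency_ratio(tr, pre_window = c(0, 60), post_window = c(60, 120))
#' @export
frequency_ratio <- function(train, pre_window, post_window) {
  assert_event_train(train)
  for (w in list(pre_window, post_window)) {
    if (length(w) != 2L || anyNA(w) || w[2] <= w[1]) {
      abort("each window must be c(start, end) with end > start.")
    }
  }
  if (pre_window[2] > post_window[1] && post_window[2] > pre_window[1]) {
    abort("`pre_window` and `post_window` must be disjoint.")
  }
  n_in <- function(w) sum(train$time_s >= w[1] & train$time_s < w[2])
  n_pre <- n_in(pre_window)
  if (n_pre == 0L) {
    abort("no events in `pre_window`: the frequency ratio is undefined (zero denominator).")
  }
  (n_in(post_window) / diff(post_window)) / (n_pre / diff(pre_window))
}

#' Pooled empirical cumulative distribution of event amplitudes
#'
#' Pools the amplitudes of one or more event trains and returns their
#' empirical cumulative distribution — the cumulative amplitude histogram
#' used to compare conditions (amplitude distributions are expected to be
#' condition-invariant when a treatment acts purely presynaptically on
#' release frequency).
#'
#' @param ... One or more [event_train()] objects with amplitudes (a single
#'   list of trains is also accepted).
#' @return A tibble with columns `amplitude_pA` (sorted) and `ecdf`
#'   (nondecreasing, reaching 1 at the largest amplitude), plus the pooled
#'   sample in attribute `"amplitudes"`.
#' @export
cumulative_amplitudes <- function(...) {
  trains <- list(...)
  if (length(trains) == 1L && !inherits(trains[[1L]], "event_train") && is.list(trains[[1L]])) {
    trains <- trains[[1L]]
  }
  purrr::walk(trains, assert_event_train)
  amps <- unlist(purrr::map(trains, function(tr) {
    if (!"amplitude_pA" %in% names(tr)) {
      abort("every train must carry an `amplitude_pA` column.")
    }
    tr$amplitude_pA
  }))
  if (!length(amps)) abort("no amplitudes to pool.")
  xs <- sort(amps)
  structure(tibble(amplitude_pA = xs, ecdf = seq_along(xs) / length(xs)),
            amplitudes = amps)
}
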