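#' Amplitude distribution for simulated miniature events
#'
#' Amplitudes are drawn i.i.d. from a log-normal distribution truncated at a
#' detection floor, independently of event times and of any treatment
#' condition — the statistical structure implied by cumulative amplitude
#' histograms that do not differ between control and treated neurons. The
#' absolute scale is arbitrary (no published value to pin it to); the
#' defaults give a median near 20 pA.
#'
#' @param meanlog,sdlog Location and scale of the log-normal on the log-pA
#'   scale (`sdlog > 0`).
#' @param floor_pA Minimum detectable amplitude (pA, `>= 0`); sampling is by
#'   inverse-CDF truncation, so no draws fall below it.
#' @return An `amplitude_model` object.
#' @export
amplitude_model <- function(meanlog = log(20), sdlog = 0.4, floor_pA = 5) {
  if (!is.numeric(sdlog) || sdlog <= 0) abort("`sdlog` must be > 0.")
  if (!is.numeric(floor_pA) || floor_pA < 0) abort("`floor_pA` must be >= 0.")
  structure(list(meanlog = meanlog, sdlog = sdlog, floor_pA = floor_pA),
            class = "amplitude_model")
}

sample_amplitudes <- function(n, model) {
  if (!inherits(model, "amplitude_model")) abort("expected an `amplitude_model()`.")
  p0 <- plnorm(model$floor_pA, model$meanlog, model$sdlog)
  qlnorm(runif(n, p0, 1), model$meanlog, model$sdlog)
}

# Derive a reproducible per-stream seed from one global seed, so adding a
# generator call for one stream does not perturb the draws of another.
substream_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

#' Sample an event train from a time-varying rate
#'
#' Draws an inhomogeneous Poisson process by Lewis-Shedler thinning:
#' candidates are generated at a constant envelope rate `rate_max` and kept
#' with probability `rate(t)/rate_max`. The rate function must be
#' non-negative and bounded by the envelope; both are checked at the
#' candidate times and violations are rejected loudly.
#'
#' @param rate_fn A vectorised function of time returning the rate in Hz, or
#'   a single non-negative number for a homogeneous process. Functions built
#'   by [scenario_rate_fn()] carry their own envelope.
#' @param duration Recording length (s).
#' @param amp_model Optional [amplitude_model()]; when given, every event
#'   receives an amplitude drawn independently of its time.
#' @param seed Integer seed; the draw is fully reproducible given
#'   (`rate_fn`, `duration`, `amp_model`, `seed`).
#' @param rate_max Envelope rate (Hz). Defaults to the attribute attached by
#'   [scenario_rate_fn()], or to a fine-grid maximum (2049 points plus any
#'   rate breakpoints) inflated by 0.1%.
#' @return An [event_train()].
#' @examples
#' tr <- sample_event_train(1, duration = 60, seed = 42)
#' nrow(tr)
#' @export
sample_event_train <- function(rate_fn, duration, amp_model = NULL, seed = NULL,
                               rate_max = NULL) {
  if (is.numeric(rate_fn) && length(rate_fn) == 1L) {
    lam0 <- rate_fn
    if (is.na(lam0) || lam0 < 0) abort("a constant rate must be >= 0.")
    rate_fn <- function(t) rep(lam0, length(t))
    rate_max <- rate_max %||% lam0
  }
  if (!is.function(rate_fn)) abort("`rate_fn` must be a function of time (or a constant).")
  if (!is.numeric(duration) || duration <= 0) abort("`duration` must be positive (s).")
  if (is.null(rate_max)) rate_max <- attr(rate_fn, "rate_max")
  if (is.null(rate_max)) {
    grid <- sort(unique(c(seq(0, duration, length.out = 2049),
                          attr(rate_fn, "breaks"))))
    grid <- grid[grid >= 0 & grid <= duration]
    vals <- rate_fn(grid)
    if (anyNA(vals) || any(!is.finite(vals))) abort("`rate_fn` returned non-finite rates.")
    if (any(vals < 0)) abort("`rate_fn` must be non-negative.")
    rate_max <- max(vals) * 1.001
  }
  if (!is.finite(rate_max)) abort("the rate envelope must be finite.")
  with_seed_if(seed, {
    if (rate_max <= 0) {
      times <- numeric()
    } else {
      n_cand <- rpois(1, rate_max * duration)
      cand <- sort(runif(n_cand, 0, duration))
      lam <- rate_fn(cand)
      if (any(is.na(lam)) || any(lam < 0)) abort("`rate_fn` must be non-negative over [0, duration].")
      if (any(lam > rate_max * (1 + 1e-9))) {
        abort(sprintf("rate exceeds its envelope (%.4g > %.4g Hz): thinning would be biased.",
                      max(lam), rate_max))
      }
      times <- cand[runif(n_cand) < lam / rate_max]
    }
    amps <- if (is.null(amp_model)) NULL else sample_amplitudes(length(times), amp_model)
    event_train(times, amps, duration)
  })
}

#' Expected mEPSC rate function of a perturbation scenario
#'
#' Builds the continuous rate-vs-time function `n_pool * alpha(t) * u1(t)`
#' for a staged scenario, ready to drive [sample_event_train()] or
#' [poisson_loglik()]. The returned function carries its rate breakpoints,
#' a valid thinning envelope, and an exact integrator (attribute
#' `"integral"`, a function of `(t0, t1)`) computed from the spectral
#' decomposition of each constant-rate segment.
#'
#' @param params A [scenario_params()].
#' @param n_pool Effective releasable pool size (> 0).
#' @param initial Initial [pool_state()]; default: baseline steady state.
#' @param alpha_only Build the alpha-only control instead of the full
#'   scenario.
#' @return A vectorised function of time (s) returning Hz.
#' @export
scenario_rate_fn <- function(params = scenario_params(), n_pool = 200,
                             initial = NULL, alpha_only = FALSE) {
  assert_scenario_params(params)
  if (!is.numeric(n_pool) || n_pool <= 0) abort("`n_pool` must be positive.")
  sched <- build_lpa_schedule(params, alpha_only = alpha_only)
  if (is.null(initial)) initial <- steady_state(segment_rate_set(sched, 1L))
  f <- function(t) {
    ord <- order(t)
    u <- state_at(sched, t[ord], initial)["u1", ]
    a <- rates_at(sched, t[ord])$alpha
    out <- numeric(length(t))
    out[ord] <- n_pool * a * u
    out
  }
  bps <- schedule_breakpoints(sched)
  # u1 is an exponential mixture within each segment: one interior extremum at
  # most, so a dense per-segment grid bounds the maximum tightly; 0.1% headroom
  probe <- sort(unique(c(seq(0, params$t_exo_up + 4000, length.out = 4097), bps)))
  rate_max <- max(f(probe)) * 1.001
  structure(f,
            rate_max = rate_max,
            breaks = bps,
            schedule = sched,
            initial = initial,
            integral = function(t0, t1) flux_integral(sched, initial, t0, t1, n_pool))
}

# Exact time integral of n_pool * alpha(t) * u1(t) over [t0, t1] for a
# piecewise-constant schedule, via the eigendecomposition of each segment's
# generator; numerical quadrature only if a segment is defective.
flux_integral <- function(schedule, initial, t0, t1, n_pool = 1) {
  stopifnot(t1 >= t0)
  initial <- assert_pool_state(initial)
  nseg <- nrow(schedule)
  total <- 0
  u_s <- as.numeric(initial)
  for (i in seq_len(nseg)) {
    seg_lo <- schedule$t_start[i]
    seg_hi <- schedule$t_end[i]
    M <- generator_matrix(segment_rate_set(schedule, i))
    lo <- max(t0, seg_lo)
    hi <- min(t1, seg_hi)
    if (hi > lo) {
      e <- tryCatch(eigen(M), error = function(err) NULL)
      Vi <- if (is.null(e)) NULL else tryCatch(solve(e$vectors), error = function(err) NULL)
      ok <- !is.null(Vi) && all(is.finite(Mod(Vi))) && max(Mod(Vi)) < 1e10
      if (ok) {
        w <- Vi %*% u_s
        lam <- e$values
        dlo <- lo - seg_lo; dhi <- hi - seg_lo
        psi <- ifelse(abs(lam) < 1e-14, dhi - dlo,
                      (exp(lam * dhi) - exp(lam * dlo)) / lam)
        int_u1 <- Re(sum(e$vectors[1, ] * as.vector(w) * psi))
      } else {
        P <- segment_propagator(M)
        int_u1 <- integrate(function(tt) P(u_s, tt - seg_lo)[1, ], lo, hi,
                            rel.tol = 1e-10)$value
      }
      total <- total + schedule$alpha[i] * int_u1
    }
    if (seg_hi <= t1 && is.finite(seg_hi)) {
      u_s <- as.vector(segment_propagator(M)(u_s, seg_hi - seg_lo))
    }
    if (seg_lo > t1) break
  }
  n_pool * total
}

#' Synthetic Boltzmann dose-response table
#'
#' Evaluates a Boltzmann curve at the given concentrations and perturbs each
#' replicate with multiplicative and/or additive Gaussian noise. Defaults
#' reproduce the study conditions: EC50 1.2 µM over 0.1-50 µM, responses
#' normalised to a 0-100% scale.
#'
#' @param concentrations Test concentrations (µM, > 0).
#' @param reps Replicates per concentration (>= 1).
#' @param r_min,r_max,ec50,slope Curve parameters, see
#'   [boltzmann_response()].
#' @param noise_mult_sd SD of multiplicative Gaussian noise (fraction of the
#'   mean response).
#' @param noise_add_sd SD of additive Gaussian noise (response units).
#' @param seed Integer seed for reproducibility.
#' @return A tibble with columns `concentration_um`, `rep`, `response`.
#' @export
synth_dose_response <- function(concentrations = c(0.1, 0.3, 1, 3, 10, 30, 50),
                                reps = 5,
                                r_min = 0, r_max = 100, ec50 = 1.2, slope = 0.4,
                                noise_mult_sd = 0.10, noise_add_sd = 0,
                                seed = NULL) {
  if (any(concentrations <= 0)) abort("concentrations must be positive (µM).")
  if (reps < 1) abort("`reps` must be >= 1.")
  if (noise_mult_sd < 0 || noise_add_sd < 0) abort("noise SDs must be >= 0.")
  mu <- boltzmann_response(concentrations, r_min, r_max, ec50, slope)
  with_seed_if(seed, {
    out <- tidyr::expand_grid(concentration_um = concentrations, rep = seq_len(reps))
    mu_rep <- rep(mu, each = reps)
    out$response <- mu_rep * (1 + rnorm(nrow(out), 0, noise_mult_sd)) +
      rnorm(nrow(out), 0, noise_add_sd)
    out
  })
}

#' Synthetic somatic calcium trace
#'
#' A flat baseline followed by a smooth difference-of-exponentials transient
#' that peaks `peak_time_offset` seconds after the stimulus (drawn uniformly
#' from 75-85 s when not given, matching the reported somatic response
#' latency) with maximum `baseline_level + peak_delta`, then returns towards
#' baseline. Sampled every `sampling_interval` seconds (default 2 s) with
#' optional additive Gaussian noise.
#'
#' @param baseline_level Resting level (trace units; default 117, a typical
#'   resting calcium concentration in nM).
#' @param peak_delta Peak response above baseline (trace units).
#' @param stim_time Stimulus time (s).
#' @param peak_time_offset Time from stimulus to peak (s); `NULL` draws
#'   uniformly from `peak_offset_range`.
#' @param peak_offset_range Range for the drawn offset (s).
#' @param duration Total trace length (s).
#' @param sampling_interval Sampling period (s).
#' @param noise_add_sd Additive Gaussian noise SD (trace units).
#' @param seed Integer seed.
#' @return A [ca_trace()].
#' @export
synth_ca_trace <- function(baseline_level = 117, peak_delta = 150,
                           stim_time = 60, peak_time_offset = NULL,
                           peak_offset_range = c(75, 85),
                           duration = stim_time + 420,
                           sampling_interval = 2,
                           noise_add_sd = 0, seed = NULL) {
  if (sampling_interval <= 0) abort("`sampling_interval` must be positive.")
  if (noise_add_sd < 0) abort("`noise_add_sd` must be >= 0.")
  if (duration <= stim_time) abort("`duration` must extend past `stim_time`.")
  with_seed_if(seed, {
    offset <- peak_time_offset %||% runif(1, peak_offset_range[1], peak_offset_range[2])
    if (offset <= 0) abort("the peak must follow the stimulus (`peak_time_offset` > 0).")
    # difference of exponentials with tau_decay = 4 * tau_rise; the peak of
    # exp(-t/td) - exp(-t/tr) sits at tr * (4/3) * log(4)
    tau_r <- offset / ((4 / 3) * log(4))
    tau_d <- 4 * tau_r
    kernel <- function(t) exp(-t / tau_d) - exp(-t / tau_r)
    k_max <- kernel(offset)
    times <- seq(0, duration, by = sampling_interval)
    rel <- pmax(times - stim_time, 0)
    values <- baseline_level + peak_delta * ifelse(times < stim_time, 0, kernel(rel) / k_max)
    values <- values + rnorm(length(times), 0, noise_add_sd)
    ca_trace(times, values, stim_time)
  })
}

#' Synthetic SynaptopHluorin trace
#'
#' The deterministic fluorescence predicted by [phluorin_signal()] plus
#' additive Gaussian recording noise.
#'
#' @inheritParams phluorin_signal
#' @param noise_add_sd Additive noise SD (a.f.u.).
#' @param seed Integer seed.
#' @return A `phluorin_trace` tibble (`time_s`, `f_afu`).
#' @export
synth_phluorin_trace <- function(traj, gain = 1000, baseline_f = 100,
                                 noise_add_sd = 0, seed = NULL) {
  if (noise_add_sd < 0) abort("`noise_add_sd` must be >= 0.")
  clean <- phluorin_signal(traj, gain, baseline_f)
  with_seed_if(seed, {
    clean$f_afu <- clean$f_afu + rnorm(nrow(clean), 0, noise_add_sd)
    clean
  })
}
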