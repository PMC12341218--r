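#' Boltzmann (sigmoid) dose-response function
#'
#' Evaluated on a log10 concentration axis:
#' \deqn{R(c) = r_{min} + \frac{r_{max} - r_{min}}
#'   {1 + \exp\{(\log_{10} EC_{50} - \log_{10} c)/k\}}}
#' with `k` (`slope`) the steepness in decades. `R(EC50)` is the midpoint
#' between the two asymptotes.
#'
#' @param concentration Concentrations (> 0, µM).
#' @param r_min,r_max Lower/upper response asymptotes.
#' @param ec50 Half-maximal concentration (µM).
#' @param slope Steepness on the log10-concentration axis (decades, > 0).
#' @return Response values.
#' @export
boltzmann_response <- function(concentration, r_min, r_max, ec50, slope) {
  r_min + (r_max - r_min) / (1 + exp((log10(ec50) - log10(concentration)) / slope))
}

#' Fit a Boltzmann dose-response curve
#'
#' Least-squares fit of [boltzmann_response()] to concentration-response
#' data, parameterised internally by `log10(EC50)` so the midpoint is
#' searched on the axis the curve lives on. Initial values come from the
#' data (asymptotes from the response extremes, midpoint from the
#' half-maximum crossing, slope 0.5 decades); on failure up to
#' `max_restarts` perturbed restarts are attempted before the fit is
#' reported as failed. The fit is equivariant under linear rescaling of the
#' response: `r_min`/`r_max` transform with the data while `ec50` and
#' `slope` are unchanged.
#'
#' @param data A data frame with columns `concentration_um` (> 0) and
#'   `response`; replicate rows per concentration are welcome. At least 4
#'   distinct concentrations are required.
#' @param max_restarts Maximum number of perturbed restarts after a failed
#'   attempt.
#' @return An object of class `boltzmann_fit`: a list with `estimates`
#'   (named vector: `r_min`, `r_max`, `log10_ec50`, `slope`, `ec50`),
#'   standard errors, `rss`, `converged`, the number of observations and the
#'   underlying `nls` object. Supports [tidy()], [glance()] and
#'   [autoplot()][ggplot2::autoplot()].
#' @examples
#' d <- synth_dose_response(noise_mult_sd = 0, seed = 1)
#' fit_boltzmann(d)
#' @export
fit_boltzmann <- function(data, max_restarts = 10) {
  if (!is.data.frame(data) || !all(c("concentration_um", "response") %in% names(data))) {
    abort("`data` must have columns `concentration_um` and `response`.")
  }
  conc <- data$concentration_um
  resp <- data$response
  if (any(is.na(conc)) || any(conc <= 0)) abort("concentrations must be positive.")
  if (any(!is.finite(resp))) abort("responses must be finite.")
  if (length(unique(conc)) < 4L) {
    abort("at least 4 distinct concentrations are needed to fit a 4-parameter curve.")
  }
  if (sd(resp) == 0) {
    abort("responses are constant across concentrations: the slope and midpoint are unidentifiable.")
  }
  df <- tibble(lc = log10(conc), response = resp)
  r_min0 <- min(resp); r_max0 <- max(resp)
  half <- (r_min0 + r_max0) / 2
  lec0 <- stats::approx(resp[order(conc)], sort(log10(conc)), xout = half,
                        ties = mean, rule = 2)$y
  if (!is.finite(lec0)) lec0 <- mean(log10(conc))
  start0 <- c(r_min = r_min0, r_max = r_max0, log10_ec50 = lec0, slope = 0.5)

  attempt <- function(start) {
    tryCatch(
      minpack.lm::nlsLM(
        response ~ r_min + (r_max - r_min) / (1 + exp((log10_ec50 - lc) / slope)),
        data = df, start = as.list(start),
        lower = c(-Inf, -Inf, min(df$lc) - 2, 1e-3),
        upper = c(Inf, Inf, max(df$lc) + 2, 10),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  fit <- attempt(start0)
  tries <- 0L
  while (is.null(fit) && tries < max_restarts) {
    tries <- tries + 1L
    jitter <- start0 * (1 + 0.2 * (runif(4) - 0.5))
    jitter["log10_ec50"] <- start0["log10_ec50"] + (runif(1) - 0.5)
    fit <- attempt(jitter)
  }
  if (is.null(fit)) {
    abort(sprintf(
      "Boltzmann fit failed to converge after %d restart(s); starting values were (r_min=%.3g, r_max=%.3g, log10_ec50=%.3g, slope=%.3g).",
      max_restarts, start0[1], start0[2], start0[3], start0[4]))
  }
  est <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 4))
  ec50 <- 10^est[["log10_ec50"]]
  in_range <- ec50 >= 0.1 * min(conc) && ec50 <= 10 * max(conc)
  if (!in_range) {
    warn(sprintf("fitted EC50 (%.3g) lies outside the tested concentration range x [0.1, 10]; treat the midpoint as extrapolated.", ec50))
  }
  structure(list(
    estimates = c(est, ec50 = ec50),
    std_errors = se,
    rss = sum(stats::resid(fit)^2),
    converged = TRUE,
    ec50_in_range = in_range,
    n = nrow(df),
    data = df,
    fit = fit
  ), class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  e <- x$estimates
  cat(sprintf(
    "<boltzmann_fit> EC50 = %.4g uM, slope = %.3g dec, range [%.4g, %.4g], RSS = %.4g (n = %d)\n",
    e[["ec50"]], e[["slope"]], e[["r_min"]], e[["r_max"]], x$rss, x$n))
  invisible(x)
}

#' @export
tidy.boltzmann_fit <- function(x, ...) {
  terms <- c("r_min", "r_max", "log10_ec50", "slope")
  tibble(term = c(terms, "ec50"),
         estimate = unname(x$estimates[c(terms, "ec50")]),
         std.error = c(unname(x$std_errors[terms]),
                       # delta method on the log10 scale
                       unname(x$std_errors["log10_ec50"]) * log(10) * x$estimates[["ec50"]]))
}

#' @export
glance.boltzmann_fit <- function(x, ...) {
  tibble(rss = x$rss, n = x$n, converged = x$converged,
         ec50_in_range = x$ec50_in_range)
}

#' Fit a single-exponential decay
#'
#' Least-squares fit of `F(t) = amplitude * exp(-(t - t0)/tau) + offset` to a
#' fluorescence trace, where `t0` is the start of the fitting window — the
#' standard quantification of SynaptopHluorin re-quenching after an
#' exocytosis transient, whose time constant reports the membrane residence
#' of fused vesicles. Traces that do not decay over the window (fitted
#' amplitude <= 0) are reported as failures.
#'
#' @param trace A data frame with columns `time_s` and `f_afu` (a
#'   `phluorin_trace`), or `time_s`/`value`.
#' @param window Optional `c(start, end)` fitting window (s), starting at or
#'   after the fluorescence peak; default: from the peak sample to the end
#'   of the trace.
#' @param max_restarts Perturbed restarts after a failed attempt.
#' @return An object of class `exp_decay_fit` with `estimates` (`amplitude`,
#'   `tau`, `offset`), standard errors, `rss`, `window`, `converged`.
#'   Supports [tidy()] and [glance()].
#' @export
fit_exp_decay <- function(trace, window = NULL, max_restarts = 10) {
  if (!is.data.frame(trace) || !"time_s" %in% names(trace)) {
    abort("`trace` must have a `time_s` column.")
  }
  ycol <- if ("f_afu" %in% names(trace)) "f_afu" else "value"
  if (!ycol %in% names(trace)) abort("`trace` must have an `f_afu` or `value` column.")
  t <- trace$time_s
  y <- trace[[ycol]]
  if (is.null(window)) window <- c(t[which.max(y)], max(t))
  sel <- t >= window[1] & t <= window[2]
  if (sum(sel) < 4L) abort("need at least 4 samples inside the fitting window.")
  tw <- t[sel] - window[1]
  yw <- y[sel]
  start0 <- c(amplitude = max(yw[1] - min(yw), diff(range(yw)) / 2, 1e-12),
              tau = max(diff(range(tw)) / 3, 1e-6),
              offset = min(yw))
  df <- tibble(tw = tw, yw = yw)
  attempt <- function(start) {
    tryCatch(
      minpack.lm::nlsLM(yw ~ amplitude * exp(-tw / tau) + offset,
                        data = df, start = as.list(start),
                        lower = c(-Inf, 1e-9, -Inf),
                        upper = c(Inf, 1e9, Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  fit <- attempt(start0)
  tries <- 0L
  while (is.null(fit) && tries < max_restarts) {
    tries <- tries + 1L
    fit <- attempt(start0 * (1 + 0.3 * (runif(3) - 0.5)))
  }
  if (is.null(fit)) {
    if (stats::cor(tw, yw) > 0) {
      abort("trace does not decay over the window (fluorescence rises); a single-exponential decay is the wrong model for it.")
    }
    abort(sprintf("exponential-decay fit failed to converge after %d restart(s).", max_restarts))
  }
  est <- coef(fit)
  if (est[["amplitude"]] <= 0) {
    abort(sprintf(
      "trace does not decay over the window: fitted amplitude = %.3g <= 0 (tau = %.3g s); a single-exponential decay is the wrong model for it.",
      est[["amplitude"]], est[["tau"]]))
  }
  if (est[["tau"]] <= 2e-9 || est[["tau"]] >= 5e8) {
    abort(sprintf("fitted tau = %.3g s hit its search bound; the decay is unresolved by this window.", est[["tau"]]))
  }
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  structure(list(estimates = est, std_errors = se,
                 rss = sum(stats::resid(fit)^2),
                 window = window, n = sum(sel), converged = TRUE,
                 data = tibble(time_s = t[sel], value = yw), fit = fit),
            class = "exp_decay_fit")
}

#' @export
print.exp_decay_fit <- function(x, ...) {
  e <- x$estimates
  cat(sprintf("<exp_decay_fit> tau = %.4g s, amplitude = %.4g, offset = %.4g, RSS = %.4g (n = %d)\n",
              e[["tau"]], e[["amplitude"]], e[["offset"]], x$rss, x$n))
  invisible(x)
}

#' @export
tidy.exp_decay_fit <- function(x, ...) {
  tibble(term = names(x$estimates),
         estimate = unname(x$estimates),
         std.error = unname(x$std_errors))
}

#' @export
glance.exp_decay_fit <- function(x, ...) {
  tibble(tau = x$estimates[["tau"]], rss = x$rss, n = x$n, converged = x$converged)
}
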