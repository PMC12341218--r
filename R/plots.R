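#' Plot a pool trajectory
#'
#' One line per pool fraction (ready, fused, recycling) over time, with
#' dashed marks at the rate breakpoints.
#'
#' @param object A `pool_trajectory` from [simulate_pool()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pool_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), c("u1", "u2", "u3"),
                              names_to = "state", values_to = "fraction")
  long$state <- factor(long$state, c("u1", "u2", "u3"),
                       c("ready (u1)", "fused (u2)", "recycling (u3)"))
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$time_s, .data$fraction,
                                          colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "fraction of pool", colour = NULL) +
    ggplot2::theme_minimal()
  bps <- schedule_breakpoints(attr(object, "schedule"))
  if (length(bps)) p <- p + ggplot2::geom_vline(xintercept = bps, linetype = "dashed",
                                                colour = "grey50")
  p
}

#' Plot a release-flux series
#'
#' @param object A `flux_series` from [release_flux()].
#' @param ... Unused.
#' @return A ggplot with the pre-perturbation baseline flux as a dotted
#'   reference line.
#' @export
autoplot.flux_series <- function(object, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(.data$time_s, .data$flux_per_s)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$flux_per_s[1L], linetype = "dotted") +
    ggplot2::labs(x = "time (s)", y = "release flux (fraction / s)") +
    ggplot2::theme_minimal()
  sched <- attr(object, "schedule")
  if (!is.null(sched)) {
    bps <- schedule_breakpoints(sched)
    if (length(bps)) p <- p + ggplot2::geom_vline(xintercept = bps,
                                                  linetype = "dashed", colour = "grey50")
  }
  p
}

#' Plot a Boltzmann dose-response fit
#'
#' Data points on a log10 concentration axis with the fitted sigmoid.
#'
#' @param object A `boltzmann_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.boltzmann_fit <- function(object, ...) {
  e <- object$estimates
  curve_df <- tibble(
    lc = seq(min(object$data$lc) - 0.2, max(object$data$lc) + 0.2, length.out = 200))
  curve_df$response <- boltzmann_response(10^curve_df$lc, e[["r_min"]], e[["r_max"]],
                                          e[["ec50"]], e[["slope"]])
  ggplot2::ggplot(object$data, ggplot2::aes(.data$lc, .data$response)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = curve_df, colour = "firebrick") +
    ggplot2::geom_vline(xintercept = e[["log10_ec50"]], linetype = "dashed") +
    ggplot2::labs(x = "log10 concentration (uM)", y = "response",
                  subtitle = sprintf("EC50 = %.3g uM", e[["ec50"]])) +
    ggplot2::theme_minimal()
}

#' Plot a single-exponential decay fit
#'
#' @param object An `exp_decay_fit`.
#' @param ... Unused.
#' @return A ggplot of the windowed trace with the fitted decay.
#' @export
autoplot.exp_decay_fit <- function(object, ...) {
  e <- object$estimates
  d <- object$data
  d$fitted <- e[["amplitude"]] * exp(-(d$time_s - object$window[1]) / e[["tau"]]) +
    e[["offset"]]
  ggplot2::ggplot(d, ggplot2::aes(.data$time_s, .data$value)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::labs(x = "time (s)", y = "fluorescence (a.f.u.)",
                  subtitle = sprintf("tau = %.3g s", e[["tau"]])) +
    ggplot2::theme_minimal()
}

#' Plot an event train as a raster and cumulative count
#'
#' @param object An [event_train()].
#' @param ... Unused.
#' @return A ggplot of cumulative event count over time.
#' @export
autoplot.event_train <- function(object, ...) {
  d <- as_tibble(object)
  d$n <- seq_len(nrow(d))
  ggplot2::ggplot(d, ggplot2::aes(.data$time_s, .data$n)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time (s)", y = "cumulative events") +
    ggplot2::theme_minimal()
}

#' Compare pooled amplitude distributions across conditions
#'
#' Overlaid empirical cumulative amplitude distributions, the standard
#' display for checking that a treatment leaves amplitudes (detectability)
#' unchanged.
#'
#' @param ... Named [event_train()] objects (names become condition labels).
#' @return A ggplot.
#' @export
plot_amplitude_ecdf <- function(...) {
  trains <- list(...)
  if (is.null(names(trains)) || any(names(trains) == "")) {
    names(trains) <- paste0("condition_", seq_along(trains))
  }
  d <- purrr::imap(trains, function(tr, nm) {
    ec <- cumulative_amplitudes(tr)
    ec$condition <- nm
    ec
  })
  d <- dplyr::bind_rows(d)
  ggplot2::ggplot(d, ggplot2::aes(.data$amplitude_pA, .data$ecdf,
                                  colour = .data$condition)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "amplitude (pA)", y = "cumulative probability", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
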