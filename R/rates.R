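#' Kinetic rate constants of the three-state vesicle cycle
#'
#' The single-pool model tracks the fractions of synaptic vesicles that are
#' ready for release (`u1`), fused with the presynaptic membrane (`u2`), or
#' being recycled after endocytosis (`u3`). Three first-order rate constants
#' connect the states:
#'
#' * `alpha` — activation/exocytosis rate (s^-1): flow `u1 -> u2`;
#' * `sigma` — endocytosis rate (s^-1): flow `u2 -> u3`;
#' * `beta`  — recycling rate (s^-1): flow `u3 -> u1`, returning retrieved
#'   vesicles to the release-ready pool.
#'
#' All three must be finite and non-negative.
#'
#' @param alpha,beta,sigma Rate constants in s^-1.
#' @return A `rate_set` object (a named list with elements `alpha`, `beta`,
#'   `sigma`).
#' @seealso [default_rates()] for the literature values used as the baseline
#'   condition throughout the package.
#' @examples
#' rate_set(0.008, 0.5, 1.67)
#' @export
rate_set <- function(alpha, beta, sigma) {
  r <- c(alpha = alpha, beta = beta, sigma = sigma)
  if (length(r) != 3L || !is.numeric(r) || anyNA(r) || any(!is.finite(r))) {
    abort("`alpha`, `beta` and `sigma` must each be a single finite number.")
  }
  if (any(r < 0)) {
    abort(sprintf(
      "rate constants must be >= 0; got alpha = %g, beta = %g, sigma = %g",
      r[["alpha"]], r[["beta"]], r[["sigma"]]
    ))
  }
  structure(list(alpha = r[["alpha"]], beta = r[["beta"]], sigma = r[["sigma"]]),
            class = "rate_set")
}

#' Baseline rate constants for hippocampal synapses
#'
#' The literature estimates used as the resting condition everywhere in this
#' package: alpha = 0.008 s^-1, beta = 0.5 s^-1, sigma = 1.67 s^-1.
#'
#' @return A [rate_set()].
#' @export
default_rates <- function() rate_set(0.008, 0.5, 1.67)

#' @export
print.rate_set <- function(x, ...) {
  cat(sprintf("<rate_set> alpha = %g, beta = %g, sigma = %g (s^-1)\n",
              x$alpha, x$beta, x$sigma))
  invisible(x)
}

is_rate_set <- function(x) inherits(x, "rate_set")

assert_rate_set <- function(x) {
  if (!is_rate_set(x)) abort("expected a `rate_set` (see `rate_set()`).")
  invisible(x)
}

#' Vesicle pool occupancy state
#'
#' A point on the 2-simplex: the fractions of vesicles ready for release
#' (`u1`), fused with the membrane (`u2`) and in recycling (`u3`). Components
#' must lie in \[0, 1\] and sum to 1 within 1e-9; violations are rejected
#' rather than renormalised, because in an exactly conservative model they
#' indicate a bug, not noise.
#'
#' @param u1,u2,u3 State fractions. `u1` may also be a length-3 numeric
#'   vector holding all three.
#' @return A named numeric vector of class `pool_state`.
#' @examples
#' pool_state(1, 0, 0)
#' @export
pool_state <- function(u1, u2 = NULL, u3 = NULL) {
  u <- if (is.null(u2) && is.null(u3) && length(u1) == 3L) as.numeric(u1)
       else c(u1, u2, u3)
  if (length(u) != 3L || !is.numeric(u) || anyNA(u)) {
    abort("a pool state needs exactly three numeric components (u1, u2, u3).")
  }
  slop <- 1e-9
  if (any(u < -slop) || any(u > 1 + slop)) {
    abort(sprintf("pool-state components must lie in [0, 1]; got (%g, %g, %g)",
                  u[1], u[2], u[3]))
  }
  if (abs(sum(u) - 1) > slop) {
    abort(sprintf("pool-state components must sum to 1 (tolerance 1e-9); got sum = %.12g",
                  sum(u)))
  }
  structure(setNames(u, c("u1", "u2", "u3")), class = "pool_state")
}

#' @export
print.pool_state <- function(x, ...) {
  cat(sprintf("<pool_state> u1 = %.6g, u2 = %.6g, u3 = %.6g\n", x[1], x[2], x[3]))
  invisible(x)
}

assert_pool_state <- function(x) {
  if (!inherits(x, "pool_state")) x <- pool_state(x)
  x
}

#' Piecewise-constant schedule of rate constants
#'
#' Encodes time-varying kinetics as a sequence of intervals on each of which
#' the rates are constant: `length(breakpoints) + 1` segments, the last
#' extending to infinity. Rates are right-continuous at breakpoints.
#'
#' @param rates A list of [rate_set()] objects, one per segment.
#' @param breakpoints Strictly increasing segment-boundary times (s); may be
#'   empty for a single constant-rate segment.
#' @param t_start Time at which the schedule's domain begins (s).
#' @return A tibble of class `rate_schedule` with one row per segment and
#'   columns `t_start`, `t_end`, `alpha`, `beta`, `sigma`.
#' @examples
#' rate_schedule(list(default_rates()))
#' @export
rate_schedule <- function(rates, breakpoints = numeric(), t_start = 0) {
  if (is_rate_set(rates)) rates <- list(rates)
  purrr::walk(rates, assert_rate_set)
  breakpoints <- as.numeric(breakpoints)
  if (anyNA(breakpoints) || is.unsorted(breakpoints, strictly = TRUE)) {
    abort("`breakpoints` must be strictly increasing and non-missing.")
  }
  if (length(breakpoints) && breakpoints[1] <= t_start) {
    abort("all breakpoints must lie after `t_start`.")
  }
  if (length(rates) != length(breakpoints) + 1L) {
    abort(sprintf("need one rate set per segment: %d breakpoints require %d rate sets, got %d.",
                  length(breakpoints), length(breakpoints) + 1L, length(rates)))
  }
  starts <- c(t_start, breakpoints)
  ends <- c(breakpoints, Inf)
  out <- tibble(
    t_start = starts,
    t_end = ends,
    alpha = purrr::map_dbl(rates, "alpha"),
    beta = purrr::map_dbl(rates, "beta"),
    sigma = purrr::map_dbl(rates, "sigma")
  )
  structure(out, class = c("rate_schedule", class(out)))
}

is_rate_schedule <- function(x) inherits(x, "rate_schedule")

assert_rate_schedule <- function(x) {
  if (!is_rate_schedule(x)) abort("expected a `rate_schedule` (see `rate_schedule()`).")
  invisible(x)
}

schedule_breakpoints <- function(schedule) schedule$t_start[-1L]

#' Extract the rate set in force at given times
#'
#' Rates are right-continuous: a time equal to a breakpoint belongs to the
#' segment that starts there.
#'
#' @param schedule A [rate_schedule()].
#' @param times Query times (s), at or after the schedule start.
#' @return A tibble with columns `time_s`, `alpha`, `beta`, `sigma`.
#' @export
rates_at <- function(schedule, times) {
  assert_rate_schedule(schedule)
  idx <- segment_index(schedule, times)
  tibble(time_s = times,
         alpha = schedule$alpha[idx],
         beta = schedule$beta[idx],
         sigma = schedule$sigma[idx])
}

segment_index <- function(schedule, times) {
  if (any(times < schedule$t_start[1L])) {
    abort("query times precede the schedule's domain.")
  }
  # findInterval with default left.open = FALSE puts t == breakpoint into the
  # following segment, i.e. rates are cadlag
  findInterval(times, schedule$t_start)
}

segment_rate_set <- function(schedule, i) {
  rate_set(schedule$alpha[i], schedule$beta[i], schedule$sigma[i])
}
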