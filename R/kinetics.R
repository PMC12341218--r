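#' Time derivative of the pool state
#'
#' The three-state vesicle cycle obeys the linear system
#' \deqn{du_1/dt = -\alpha u_1 + \beta u_3}
#' \deqn{du_2/dt = +\alpha u_1 - \sigma u_2}
#' \deqn{du_3/dt = +\sigma u_2 - \beta u_3}
#' Total mass is conserved: the three components of the derivative sum to
#' zero exactly.
#'
#' @param state A [pool_state()] (or a valid length-3 numeric).
#' @param rates A [rate_set()].
#' @return Named numeric vector `(du1, du2, du3)` in s^-1.
#' @examples
#' pool_derivative(pool_state(1, 0, 0), default_rates())
#' @export
pool_derivative <- function(state, rates) {
  state <- assert_pool_state(state)
  assert_rate_set(rates)
  c(du1 = -rates$alpha * state[["u1"]] + rates$beta * state[["u3"]],
    du2 = rates$alpha * state[["u1"]] - rates$sigma * state[["u2"]],
    du3 = rates$sigma * state[["u2"]] - rates$beta * state[["u3"]])
}

#' Generator matrix of the vesicle cycle
#'
#' Returns the 3x3 matrix `M` with `d(state)/dt = M %*% state`. Columns sum
#' to zero (conservation) and off-diagonal entries are non-negative, so `M`
#' generates a continuous-time Markov semigroup on the simplex.
#'
#' @inheritParams pool_derivative
#' @return A 3x3 numeric matrix.
#' @export
generator_matrix <- function(rates) {
  assert_rate_set(rates)
  matrix(c(-rates$alpha, rates$alpha, 0,
           0, -rates$sigma, rates$sigma,
           rates$beta, 0, -rates$beta),
         nrow = 3, ncol = 3,
         dimnames = list(c("u1", "u2", "u3"), c("u1", "u2", "u3")))
}

#' Closed-form steady state of the vesicle cycle
#'
#' For strictly positive rates the unique equilibrium on the simplex is
#' \deqn{u_1 = 1 / (1 + \alpha/\sigma + \alpha/\beta),\quad
#'       u_2 = (\alpha/\sigma) u_1,\quad u_3 = (\alpha/\beta) u_1.}
#' With `alpha = 0` no vesicle ever leaves the ready pool and the steady
#' state is (1, 0, 0). With `alpha > 0` but `beta = 0` or `sigma = 0` mass
#' accumulates in a downstream state and no interior equilibrium exists;
#' such rate sets are rejected.
#'
#' @inheritParams pool_derivative
#' @return A [pool_state()].
#' @examples
#' steady_state(default_rates())
#' @export
steady_state <- function(rates) {
  assert_rate_set(rates)
  if (rates$alpha == 0 && rates$beta == 0 && rates$sigma == 0) {
    abort("all rates are zero: every state is stationary; steady_state() needs at least one positive rate.")
  }
  if (rates$alpha == 0) return(pool_state(1, 0, 0))
  if (rates$beta == 0 || rates$sigma == 0) {
    abort(sprintf(
      "degenerate kinetics: alpha = %g > 0 with beta = %g, sigma = %g; mass accumulates and no interior steady state exists.",
      rates$alpha, rates$beta, rates$sigma))
  }
  u1 <- 1 / (1 + rates$alpha / rates$sigma + rates$alpha / rates$beta)
  pool_state(u1, (rates$alpha / rates$sigma) * u1, (rates$alpha / rates$beta) * u1)
}

# Spectral decomposition of the generator, with a scaling-and-squaring
# fallback for (measure-zero) defective cases. Returns a function
# mapping (u0, dt-vector) -> 3 x length(dt) matrix of states.
segment_propagator <- function(M) {
  e <- tryCatch(eigen(M), error = function(err) NULL)
  Vi <- if (is.null(e)) NULL else tryCatch(solve(e$vectors), error = function(err) NULL)
  ok <- !is.null(Vi) && all(is.finite(Mod(Vi))) && max(Mod(Vi)) < 1e10
  if (ok) {
    V <- e$vectors
    lam <- e$values
    function(u0, dts) {
      w <- Vi %*% u0
      # 3 x n: V %*% (exp(lam * t) * w) for each t
      out <- V %*% (exp(outer(lam, dts)) * as.vector(w))
      clamp_simplex(Re(out))
    }
  } else {
    function(u0, dts) {
      out <- vapply(dts, function(dt) expm_ss(M * dt) %*% u0, numeric(3))
      clamp_simplex(out)
    }
  }
}

# Dense matrix exponential by scaling and squaring with a truncated Taylor
# series; only used when the 3x3 generator is (numerically) defective.
expm_ss <- function(A) {
  nrm <- norm(A, "1")
  s <- max(0L, ceiling(log2(max(nrm, 1e-300))) + 1L)
  As <- A / 2^s
  E <- diag(nrow(A))
  term <- diag(nrow(A))
  for (k in 1:16) {
    term <- term %*% As / k
    E <- E + term
  }
  for (i in seq_len(s)) E <- E %*% E
  E
}

# Round off negative dust from the spectral route; anything beyond floating
# slop is left alone so pool_state() validation can catch real violations.
clamp_simplex <- function(x) {
  x[x < 0 & x > -1e-12] <- 0
  x
}

#' Propagate the pool state exactly over a constant-rate interval
#'
#' Because the model is linear with constant coefficients on each interval,
#' the flow is the matrix exponential `exp(M * dt)` of the generator; this
#' propagation is exact up to floating-point rounding, with no discretisation
#' error and no step-size to tune.
#'
#' @inheritParams pool_derivative
#' @param dt Duration (s), `>= 0`.
#' @return The [pool_state()] after `dt` seconds.
#' @examples
#' propagate(pool_state(1, 0, 0), default_rates(), 120)
#' @export
propagate <- function(state, rates, dt) {
  state <- assert_pool_state(state)
  assert_rate_set(rates)
  if (!is.numeric(dt) || length(dt) != 1L || is.na(dt) || dt < 0) {
    abort("`dt` must be a single non-negative duration in seconds.")
  }
  if (dt == 0) return(state)
  P <- segment_propagator(generator_matrix(rates))
  pool_state(as.vector(P(as.numeric(state), dt)))
}

# States at arbitrary sorted times under a piecewise-constant schedule.
# Chains exact segment propagation: the state at each segment start is
# computed once, then all query times inside the segment are evaluated
# from it in one vectorised spectral step, so results do not depend on the
# query grid.
state_at <- function(schedule, times, initial) {
  assert_rate_schedule(schedule)
  initial <- assert_pool_state(initial)
  if (is.unsorted(times)) abort("query `times` must be sorted increasing.")
  if (length(times) && times[1] < schedule$t_start[1L]) {
    abort("query times precede the schedule's domain.")
  }
  nseg <- nrow(schedule)
  props <- vector("list", nseg)
  for (i in seq_len(nseg)) {
    props[[i]] <- segment_propagator(generator_matrix(segment_rate_set(schedule, i)))
  }
  # state at the start of every segment
  seg_start_state <- matrix(NA_real_, 3, nseg)
  seg_start_state[, 1] <- as.numeric(initial)
  if (nseg > 1) {
    for (i in seq_len(nseg - 1)) {
      seg_start_state[, i + 1] <- props[[i]](seg_start_state[, i],
                                             schedule$t_end[i] - schedule$t_start[i])
    }
  }
  idx <- segment_index(schedule, times)
  out <- matrix(NA_real_, 3, length(times))
  for (i in unique(idx)) {
    sel <- idx == i
    out[, sel] <- props[[i]](seg_start_state[, i], times[sel] - schedule$t_start[i])
  }
  rownames(out) <- c("u1", "u2", "u3")
  out
}

#' Simulate the vesicle cycle over a time grid
#'
#' Chains exact constant-rate propagation across the segments of a
#' [rate_schedule()], evaluating the state at each requested output time.
#' Because propagation is exact, refining the output grid does not change
#' the states at shared times. The default grid covers an 18-minute
#' recording (0 to 1080 s) at 1-s resolution; the default initial condition
#' is the steady state of the first segment's rates, i.e. the preparation is
#' assumed to be at rest before any perturbation.
#'
#' @param schedule A [rate_schedule()].
#' @param initial Initial [pool_state()]; `NULL` for the first segment's
#'   steady state.
#' @param times Sorted output times (s) within the schedule's domain.
#' @return A tibble of class `pool_trajectory` with columns `time_s`, `u1`,
#'   `u2`, `u3`, `alpha`, `beta`, `sigma` (the rates in force at each time,
#'   right-continuous at breakpoints). The schedule is attached as attribute
#'   `"schedule"`.
#' @examples
#' traj <- simulate_pool(rate_schedule(default_rates()), times = seq(0, 60, 10))
#' traj
#' @export
simulate_pool <- function(schedule, initial = NULL, times = NULL) {
  assert_rate_schedule(schedule)
  if (is.null(times)) times <- seq(schedule$t_start[1L], schedule$t_start[1L] + 1080, by = 1)
  if (is.unsorted(times)) abort("output `times` must be sorted increasing.")
  if (is.null(initial)) initial <- steady_state(segment_rate_set(schedule, 1L))
  st <- state_at(schedule, times, initial)
  r <- rates_at(schedule, times)
  out <- tibble(time_s = times,
                u1 = st["u1", ], u2 = st["u2", ], u3 = st["u3", ],
                alpha = r$alpha, beta = r$beta, sigma = r$sigma)
  structure(out,
            class = c("pool_trajectory", class(tibble())),
            schedule = schedule,
            initial = initial)
}

is_pool_trajectory <- function(x) inherits(x, "pool_trajectory")

assert_pool_trajectory <- function(x) {
  if (!is_pool_trajectory(x)) abort("expected a `pool_trajectory` from `simulate_pool()`.")
  invisible(x)
}
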