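# Forward-Euler oracle for the linear three-state model.
#
# One Euler step is u <- (I + dt * M) %*% u; n steps compose to
# (I + dt * M)^n %*% u because the system is linear and autonomous, so the
# n-step map is computed by binary matrix-power squaring. This is
# algebraically identical to the sequential loop (test below cross-checks)
# but fast enough to run dt = 1e-4 oracles inside the suite.

oracle_generator <- function(alpha, beta, sigma) {
  matrix(c(-alpha, alpha, 0, 0, -sigma, sigma, beta, 0, -beta), 3, 3)
}

mat_pow <- function(A, n) {
  R <- diag(nrow(A))
  while (n > 0) {
    if (n %% 2 == 1) R <- A %*% R
    A <- A %*% A
    n <- n %/% 2
  }
  R
}

euler_propagate <- function(u0, alpha, beta, sigma, t_end, dt) {
  n <- round(t_end / dt)
  stopifnot(abs(n * dt - t_end) < 1e-8 * max(1, t_end))
  as.vector(mat_pow(diag(3) + dt * oracle_generator(alpha, beta, sigma), n) %*% u0)
}

euler_propagate_loop <- function(u0, alpha, beta, sigma, t_end, dt) {
  M <- oracle_generator(alpha, beta, sigma)
  n <- round(t_end / dt)
  u <- u0
  for (i in seq_len(n)) u <- u + dt * (M %*% u)
  as.vector(u)
}

# Euler across a piecewise-constant schedule (breakpoints must be multiples
# of dt); returns the state at t_end.
euler_schedule <- function(u0, schedule, t_end, dt) {
  u <- u0
  for (i in seq_len(nrow(schedule))) {
    lo <- schedule$t_start[i]
    hi <- min(schedule$t_end[i], t_end)
    if (hi <= lo) break
    u <- euler_propagate(u, schedule$alpha[i], schedule$beta[i], schedule$sigma[i],
                         hi - lo, dt)
    if (hi >= t_end) break
  }
  u
}

# random valid simplex point
random_state <- function() {
  x <- runif(3)
  pool_state(x / sum(x))
}

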