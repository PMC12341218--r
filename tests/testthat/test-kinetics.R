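test_that("pool_derivative matches the model equations and conserves mass", {
  r <- default_rates()
  d <- pool_derivative(pool_state(1, 0, 0), r)
  expect_equal(unname(d), c(-0.008, 0.008, 0))

  d_eq <- pool_derivative(steady_state(r), r)
  expect_lt(max(abs(d_eq)), 1e-12)

  withr::with_seed(11, {
    for (i in 1:20) {
      rr <- rate_set(runif(1, 0, 2), runif(1, 0, 2), runif(1, 0, 2))
      expect_lt(abs(sum(pool_derivative(random_state(), rr))), 1e-15)
    }
  })
})

test_that("invalid pool states are rejected with a diagnostic", {
  expect_error(pool_state(0.5, 0.5, 0.5), "sum to 1")
  expect_error(pool_state(-0.2, 0.6, 0.6), "\\[0, 1\\]")
  expect_error(pool_derivative(c(0.5, 0.5, 0.5), default_rates()), "sum to 1")
  expect_error(rate_set(-0.1, 0.5, 1), ">= 0")
  expect_error(rate_set(Inf, 0.5, 1), "finite")
})

test_that("generator_matrix is the matrix form of the derivative", {
  M <- generator_matrix(default_rates())
  expect_equal(unname(colSums(M)), c(0, 0, 0))
  expect_true(all(M[row(M) != col(M)] >= 0))
  expect_equal(generator_matrix(rate_set(0, 0, 0)), matrix(0, 3, 3), ignore_attr = TRUE)

  withr::with_seed(12, {
    for (i in 1:10) {
      rr <- rate_set(runif(1, 0, 2), runif(1, 0, 2), runif(1, 0, 2))
      s <- random_state()
      expect_equal(as.vector(generator_matrix(rr) %*% as.numeric(s)),
                   unname(pool_derivative(s, rr)))
    }
  })
})

test_that("steady_state has the closed form checked by long Euler integration", {
  # frozen from the forward-Euler oracle (dt = 1e-3 s to t = 1e4 s)
  ss <- steady_state(default_rates())
  expect_equal(unname(as.numeric(ss)), c(0.979634, 0.004693, 0.015674),
               tolerance = 1e-5)
  eu <- euler_propagate(c(1, 0, 0), 0.008, 0.5, 1.67, 1e4, 1e-3)
  expect_lt(max(abs(as.numeric(ss) - eu)), 1e-6)

  expect_equal(unname(as.numeric(steady_state(rate_set(0, 0.5, 1.67)))), c(1, 0, 0))
  for (k in c(0.05, 1, 1.9)) {
    expect_equal(unname(as.numeric(steady_state(rate_set(k, k, k)))), rep(1 / 3, 3))
  }
  expect_error(steady_state(rate_set(0.1, 0, 1)), "degenerate")
  expect_error(steady_state(rate_set(0.1, 1, 0)), "degenerate")
  expect_error(steady_state(rate_set(0, 0, 0)), "at least one")
})

test_that("steady state is independent of the Euler starting point", {
  ss <- as.numeric(steady_state(default_rates()))
  withr::with_seed(13, {
    for (i in 1:5) {
      eu <- euler_propagate(as.numeric(random_state()), 0.008, 0.5, 1.67, 1e4, 1e-3)
      expect_lt(max(abs(ss - eu)), 1e-6)
    }
  })
})

test_that("propagate is the exact flow of the linear model", {
  r <- default_rates()
  s0 <- pool_state(1, 0, 0)
  expect_identical(propagate(s0, r, 0), s0)

  # long-time limit reaches the stationary distribution
  far <- propagate(s0, r, 1e6)
  expect_lt(max(abs(as.numeric(far) - as.numeric(steady_state(r)))), 1e-9)

  # against the dt = 1e-4 Euler oracle over 120 s
  eu <- euler_propagate(c(1, 0, 0), 0.008, 0.5, 1.67, 120, 1e-4)
  expect_lt(max(abs(as.numeric(propagate(s0, r, 120)) - eu)), 1e-5)

  expect_error(propagate(s0, r, -1), "non-negative")
})

test_that("power-form Euler oracle agrees with the sequential loop", {
  seq_u <- euler_propagate_loop(c(1, 0, 0), 0.3, 0.7, 1.1, 2, 1e-3)
  pow_u <- euler_propagate(c(1, 0, 0), 0.3, 0.7, 1.1, 2, 1e-3)
  expect_equal(pow_u, seq_u, tolerance = 1e-12)
})

test_that("propagate agrees with an independent matrix-exponential and maps the simplex into itself", {
  skip_if_not_installed("Matrix")
  withr::with_seed(14, {
    for (i in 1:20) {
      rr <- rate_set(runif(1, 0, 2), runif(1, 0, 2), runif(1, 0, 2))
      s <- random_state()
      dt <- runif(1, 0, 200)
      out <- propagate(s, rr, dt)
      expect_true(all(as.numeric(out) >= 0 & as.numeric(out) <= 1))
      expect_lt(abs(sum(as.numeric(out)) - 1), 1e-9)
      ref <- as.numeric(Matrix::expm(Matrix::Matrix(generator_matrix(rr) * dt)) %*%
                          as.numeric(s))
      expect_equal(as.numeric(out), ref, tolerance = 1e-9)
    }
  })
})

test_that("simulate_pool chains exact propagation across segments", {
  r <- default_rates()
  sched <- rate_schedule(r)
  eq <- steady_state(r)
  traj <- simulate_pool(sched, initial = eq, times = seq(0, 500, 25))
  expect_lt(max(abs(traj$u1 - eq[["u1"]])), 1e-12)
  expect_lt(max(abs(traj$u2 - eq[["u2"]])), 1e-12)

  # grid refinement leaves shared times untouched: exact propagation is grid-free
  p <- scenario_params()
  sched_lpa <- build_lpa_schedule(p)
  coarse <- simulate_pool(sched_lpa, times = seq(0, 1080, 10))
  fine <- simulate_pool(sched_lpa, times = seq(0, 1080, 1))
  shared <- fine[fine$time_s %in% coarse$time_s, ]
  expect_lt(max(abs(shared$u1 - coarse$u1)), 1e-12)
  expect_lt(max(abs(shared$u3 - coarse$u3)), 1e-12)

  expect_error(simulate_pool(sched, times = c(3, 1, 2)), "sorted")
})

test_that("the staged scenario trajectory matches the piecewise Euler oracle", {
  sched <- build_lpa_schedule(scenario_params())
  traj <- simulate_pool(sched, times = c(0, 120, 240, 270, 300, 600, 1080))
  for (i in seq_len(nrow(traj))) {
    eu <- euler_schedule(as.numeric(steady_state(default_rates())), sched,
                         traj$time_s[i], 1e-4)
    got <- c(traj$u1[i], traj$u2[i], traj$u3[i])
    expect_lt(max(abs(got - eu)), 1e-5)
  }
})

test_that("rate schedules validate their segment structure", {
  r <- default_rates()
  expect_error(rate_schedule(list(r, r), breakpoints = c(10, 5)), "strictly increasing")
  expect_error(rate_schedule(list(r, r), breakpoints = numeric()), "one rate set per segment")
  sch <- rate_schedule(list(r, rate_set(0.012, 0.5, 1.67)), breakpoints = 300)
  # right-continuity at the breakpoint
  expect_equal(rates_at(sch, 300)$alpha, 0.012)
  expect_equal(rates_at(sch, 299.999)$alpha, 0.008)
})
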