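test_that("mepsc_rate scales the release flux by the pool size", {
  traj <- simulate_pool(rate_schedule(default_rates()), times = seq(0, 60, 10))
  r100 <- mepsc_rate(traj, n_pool = 100)
  expect_equal(r100$rate_hz, rep(0.78371, 7), tolerance = 1e-4)
  r200 <- mepsc_rate(traj, n_pool = 200)
  expect_equal(r200$rate_hz, 2 * r100$rate_hz)
  expect_error(mepsc_rate(traj, 0), "positive")
  expect_error(mepsc_rate(traj, -5), "positive")
})

test_that("phluorin_signal is an affine readout of the fused fraction", {
  traj <- simulate_pool(rate_schedule(default_rates()), times = seq(0, 60, 5))
  tr <- phluorin_signal(traj, gain = 1000, baseline_f = 100)
  expect_equal(tr$f_afu, rep(100 + 1000 * 0.004692853, 13), tolerance = 1e-6)
  flat <- phluorin_signal(traj, gain = 0, baseline_f = 50)
  expect_equal(flat$f_afu, rep(50, 13))

  # under the staged scenario the end-of-horizon fluorescence sits below rest,
  # mirroring the drained fused fraction
  lpa <- simulate_pool(build_lpa_schedule(scenario_params()))
  f <- phluorin_signal(lpa, gain = 1000, baseline_f = 100)
  expect_lt(f$f_afu[f$time_s == 1080], f$f_afu[1])
})

test_that("ca_peak implements the top-five-minus-baseline rule", {
  tr <- ca_trace(1:10, c(100, 100, 100, 200, 300, 280, 260, 240, 150, 120),
                 stim_time = 3.5)
  expect_identical(ca_peak(tr), 156)

  flat <- ca_trace(1:20, rep(42, 20), stim_time = 10)
  expect_identical(ca_peak(flat), 0)

  # exactly five post-stimulus samples: their mean minus baseline
  five <- ca_trace(1:7, c(10, 10, 11, 12, 13, 14, 15), stim_time = 2.5)
  expect_equal(ca_peak(five), mean(c(11, 12, 13, 14, 15)) - 10)

  # invariant under adding a constant to the entire trace
  shifted <- ca_trace(1:10, c(100, 100, 100, 200, 300, 280, 260, 240, 150, 120) + 37.5,
                      stim_time = 3.5)
  expect_equal(ca_peak(shifted), ca_peak(tr))

  expect_error(ca_peak(ca_trace(1:5, 1:5, stim_time = 0.5)), "pre-stimulus")
  expect_error(ca_peak(ca_trace(1:6, 1:6, stim_time = 3.5)), "at least 5")
})

test_that("normalize_to_reference gives percent of the reference response", {
  expect_equal(normalize_to_reference(50, 200), 25)
  expect_equal(normalize_to_reference(150, 150), 100)
  expect_equal(normalize_to_reference(11.8, 200), 5.9)
  expect_error(normalize_to_reference(50, 0), "positive")
  expect_error(normalize_to_reference(50, -1), "positive")
})

test_that("bin_events computes per-bin rates and conserves counts", {
  tr <- event_train(seq(1, 59, length.out = 30), duration = 60)
  one <- bin_events(tr, c(0, 60))
  expect_equal(one$rate_hz, 0.5)

  empty <- event_train(numeric(), duration = 60)
  z <- bin_events(empty, seq(0, 60, 10))
  expect_equal(z$rate_hz, rep(0, 6))
  expect_equal(z$count, rep(0L, 6))

  withr::with_seed(21, {
    for (i in 1:10) {
      times <- sort(runif(rpois(1, 80), 0, 120))
      trn <- event_train(times, duration = 120)
      edges <- sort(c(0, runif(5, 1, 119), 120))
      b <- bin_events(trn, edges)
      expect_equal(sum(b$count), sum(times >= 0 & times < 120))
      expect_equal(sum(b$rate_hz * (b$bin_end_s - b$bin_start_s)), sum(b$count))
    }
  })
  expect_error(bin_events(tr, c(30, 10)), "strictly increasing")
})

test_that("frequency_ratio is the post/pre rate ratio per recording", {
  tr <- event_train(c(seq(1, 59, length.out = 30), seq(61, 119, length.out = 15)),
                    duration = 120)
  expect_equal(frequency_ratio(tr, c(0, 60), c(60, 120)), 0.5)

  # adjacent equal-width windows with equal counts give 1
  sym <- event_train(c(seq(5, 55, 10), seq(65, 115, 10)), duration = 120)
  expect_equal(frequency_ratio(sym, c(0, 60), c(60, 120)), 1)

  none_pre <- event_train(c(70, 80), duration = 120)
  expect_error(frequency_ratio(none_pre, c(0, 60), c(60, 120)), "pre_window")
  expect_error(frequency_ratio(tr, c(0, 70), c(60, 120)), "disjoint")
})

test_that("cumulative_amplitudes pools trains into a proper ECDF", {
  t1 <- event_train(c(1, 2, 3), amplitudes = c(10, 20, 30), duration = 10)
  ec <- cumulative_amplitudes(t1)
  expect_equal(ec$ecdf[ec$amplitude_pA == 20], 2 / 3)
  expect_equal(ec$ecdf[nrow(ec)], 1)
  expect_true(all(diff(ec$ecdf) >= 0))

  t2 <- event_train(c(0.5, 4), amplitudes = c(15, 25), duration = 10)
  pooled <- cumulative_amplitudes(t1, t2)
  expect_equal(nrow(pooled), 5)
  expect_equal(pooled$ecdf, (1:5) / 5)

  no_amp <- event_train(c(1, 2), duration = 10)
  expect_error(cumulative_amplitudes(no_amp), "amplitude")
})

test_that("event trains validate their invariants", {
  expect_error(event_train(c(2, 1), duration = 10), "non-decreasing")
  expect_error(event_train(c(1, 11), duration = 10), "within")
  expect_error(event_train(c(1, 2), amplitudes = c(5, -1), duration = 10), "positive")
  expect_error(event_train(c(1, 2), amplitudes = 5, duration = 10), "one value per event")
})
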