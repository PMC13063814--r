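test_that("zero concentration gives an event-free trace at the open-pore level", {
  acq <- acq_coarse(duration_s = 2)
  pore <- pore_default()
  tr <- simulate_trace(acq, pore, nanolock_mix(0, 0), seed = 1)
  expect_equal(nrow(tr$truth), 0)
  i0 <- pore$open_conductance_ns * acq$voltage_mv
  n <- length(tr$current_pa)
  expect_equal(n, round(acq$duration_s * acq$sampling_hz))
  expect_lt(abs(mean(tr$current_pa) - i0),
            5 * pore$noise_rms_pa / sqrt(n) + 1)
})

test_that("per-species event counts follow Poisson statistics across seeds", {
  acq <- acq_coarse(duration_s = 6)
  pore <- pore_model(noise_rms_pa = 0)
  sp <- closed_nanolock(capture_rate_per_nm_hz = 50 / 30)
  counts <- vapply(1:120, function(s) {
    tr <- simulate_trace(acq, pore, mix_spec(sp, 30), seed = 1000 + s)
    nrow(tr$truth)
  }, numeric(1))
  lambda <- 50 * 6
  expect_lt(abs(mean(counts) - lambda), 4 * sqrt(lambda / 120))
  # index of dispersion ~ chi2_{n-1}/(n-1) under the Poisson law
  disp <- stats::var(counts) / mean(counts)
  expect_gt(disp, stats::qchisq(0.005, 119) / 119)
  expect_lt(disp, stats::qchisq(0.995, 119) / 119)
})

test_that("identical seed and configuration give a bit-identical trace", {
  acq <- acq_coarse(duration_s = 1)
  pore <- pore_default()
  mix <- nanolock_mix(30, 0.4,
                      open = open_nanolock(capture_rate_per_nm_hz = 1),
                      closed = closed_nanolock(capture_rate_per_nm_hz = 1))
  t1 <- simulate_trace(acq, pore, mix, seed = 7)
  t2 <- simulate_trace(acq, pore, mix, seed = 7)
  expect_identical(t1$current_pa, t2$current_pa)
  expect_identical(t1$truth, t2$truth)
})

test_that("a circular event blocks Delta G x V of current before noise", {
  acq <- acq_default()
  pore <- pore_model(noise_rms_pa = 0)
  tr <- simulate_event_windows(acq, pore, closed_nanolock(), 5, seed = 3)
  i0 <- pore$open_conductance_ns * acq$voltage_mv
  depth <- i0 - min(tr$current_pa)
  # Delta I = Delta G x V, up to the analog stage's small transition ringing
  expect_equal(depth, 10 * 150, tolerance = 0.03)   # 1.5 nA at 150 mV
})

test_that("event pile-up beyond the retry budget fails with advice", {
  acq <- acq_coarse(duration_s = 0.5)
  pore <- pore_model(noise_rms_pa = 0)
  sp <- closed_nanolock(capture_rate_per_nm_hz = 4000 / 30,
                        dwell_median_s = 5e-3)
  expect_error(simulate_trace(acq, pore, mix_spec(sp, 30), seed = 1),
               "pile-up")
})
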