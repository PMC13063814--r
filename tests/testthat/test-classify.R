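ruler_cal <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tr <- simulate_event_windows(acq_default(), pore_default(),
                                   ruler_species(), 200, seed = 20)
      cache <<- calibrate_ruler(detect_events(tr))
    }
    cache
  }
})

test_that("ruler calibration recovers the 1x level within 2%", {
  cal <- ruler_cal()
  expect_equal(cal$delta_g_1x_ns, 5, tolerance = 0.02)
  expect_lt(cal$sigma_ns, 5 / 2)
  # effectively noiseless ruler: sub-0.5% recovery
  tr0 <- simulate_event_windows(acq_default(),
                                pore_model(noise_rms_pa = 0.5),
                                ruler_species(), 60, seed = 21)
  cal0 <- calibrate_ruler(detect_events(tr0))
  expect_equal(cal0$delta_g_1x_ns, 5, tolerance = 0.005)
  expect_lt(cal0$sigma_ns, 0.05)
})

test_that("calibration fails on starved or contaminated ruler runs", {
  ev <- data.frame(max_blockage_ns = rep(5, 10))
  expect_error(calibrate_ruler(ev), "at least 20")
  set.seed(22)
  contaminated <- data.frame(
    max_blockage_ns = c(rnorm(300, 5, 0.15), rnorm(250, 10, 0.15)))
  expect_error(calibrate_ruler(contaminated), "bimodal")
})

test_that("classification is invariant to pore scale (different pore size)", {
  acq <- acq_default()
  mix <- nanolock_mix(30, 0.5)
  tr_a <- simulate_event_windows(acq, pore_model(blockade_1x_ns = 5),
                                 mix, 250, seed = 23)
  tr_b <- simulate_event_windows(acq,
                                 pore_model(blockade_1x_ns = 6.2,
                                            noise_rms_pa = 60 * 6.2 / 5),
                                 mix, 250, seed = 23)
  ev_a <- detect_events(tr_a); ev_b <- detect_events(tr_b)
  cal_b <- calibrate_ruler(data.frame(
    max_blockage_ns = detect_events(simulate_event_windows(
      acq, pore_model(blockade_1x_ns = 6.2, noise_rms_pa = 60 * 6.2 / 5),
      ruler_species(), 150, seed = 24))$max_blockage_ns))
  expect_equal(cal_b$delta_g_1x_ns, 6.2, tolerance = 0.02)
  cl_a <- classify_events(ev_a, ruler_cal())
  cl_b <- classify_events(ev_b, cal_b)
  # same seed, same geometry draws: identical type sequences
  expect_gte(nrow(cl_a), 245)
  expect_equal(nrow(cl_a), nrow(cl_b))
  expect_gte(mean(cl_a$event_type == cl_b$event_type), 0.98)
})

test_that("shape taxonomy follows the three-type rules", {
  t <- 0.35; mt <- 4e-6
  cs <- nanolockr:::classify_shape
  expect_equal(cs(2.0, 100e-6, t, mt), "circular")
  expect_equal(cs(c(2.0, 1.0), c(50e-6, 50e-6), t, mt), "folded")
  expect_equal(cs(c(2.0, 1.0), c(50e-6, 1e-6), t, mt), "circular") # FP path
  expect_equal(cs(1.0, 100e-6, t, mt), "single_file")
  expect_equal(cs(1.5, 100e-6, t, mt), "reject")     # between bands
  expect_equal(cs(2.6, 100e-6, t, mt), "reject")     # co-translocation
  expect_equal(cs(c(1.0, 2.0), c(50e-6, 50e-6), t, mt), "reject") # shallow 1st
  # a fold at exactly the midpoint has no tail: indistinguishable from circular
  pore <- pore_default()
  seg <- data.frame(event = 1L, seg = 1L, level_ns = 10, duration_s = 5e-5)
  expect_equal(classify_waveforms(seg, pore)$event_type, "circular")
})

test_that("false-positive accounting handles edge cases", {
  run <- simulate_run(1, duration_s = 600, seed = 25)   # all circular
  expect_error(false_positive_rate(run$classified, run$classified$true_bit),
               "no counted ground-truth-negative")
  # pure end capture: no fold channel, FP identically zero
  run0 <- simulate_run(0, duration_s = 20000,
                       open = open_nanolock(end_capture_weight = 1),
                       seed = 26)
  fp <- false_positive_rate(run0$classified, run0$classified$true_bit)
  expect_equal(fp$n_false_positive, 0)
  expect_lt(fp$ci[2], 0.001)
})

test_that("counted fraction recovers the true mixture fraction", {
  # without the fold channel the counted fraction is exactly binomial
  set.seed(27)
  for (f in c(0, 0.3, 0.7, 1)) {
    run <- simulate_run(f, duration_s = 6000,
                        open = open_nanolock(end_capture_weight = 1))
    cf <- closed_fraction(run$classified)
    expect_gte(f, cf$ci_low - 1e-9)
    expect_lte(f, cf$ci_high + 1e-9)
  }
  # with the default capture-position law the excess is the known FP rate
  run <- simulate_run(0.3, duration_s = 60000, seed = 28)
  cf <- closed_fraction(run$classified)
  fp_excess <- cf$f - 0.3
  expect_lt(abs(fp_excess - 0.7 * 0.008), 4 * sqrt(0.3 * 0.7 / cf$n_1))
  # reject fraction stays small
  expect_lt(cf$n_rejected / (cf$n_1 + cf$n_0), 0.05)
})
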