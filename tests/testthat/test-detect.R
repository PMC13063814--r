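test_that("sublevel segmentation recovers piecewise-constant windows", {
  # degenerate window: all samples identical -> one sublevel
  s <- segment_sublevels(rep(5, 100), sigma = 1, delta_pa = 10, h = 5)
  expect_equal(nrow(s), 1)
  expect_equal(s$mean_pa, 5)
  # clean two-level step at high SNR: change point at the boundary
  set.seed(5)
  x <- c(rep(-1500, 400), rep(-750, 400)) + stats::rnorm(800, 0, 10)
  s <- segment_sublevels(x, sigma = 10, delta_pa = 450, h = 6)
  expect_equal(nrow(s), 2)
  expect_lt(abs(s$end[1] - 400), 5)
  expect_equal(s$mean_pa, c(-1500, -750), tolerance = 0.01)
  # single level: no spurious change points
  x <- rep(-1500, 500) + stats::rnorm(500, 0, 10)
  s <- segment_sublevels(x, sigma = 10, delta_pa = 450, h = 6)
  expect_equal(nrow(s), 1)
})

test_that("CUSUM change points match the exhaustive least-squares oracle", {
  set.seed(6)
  for (i in 1:15) {
    cp_true <- sample(300:1500, 1)
    n <- 1800
    x <- c(rep(-1500, cp_true), rep(-750, n - cp_true)) +
      stats::rnorm(n, 0, 60)
    s <- segment_sublevels(x, sigma = 60, delta_pa = 450, h = 8)
    expect_equal(nrow(s), 2)
    cp_dp <- dp_changepoints(x, 2)
    expect_lt(abs(s$end[1] - cp_dp), 4)
  }
})

test_that("two-step change point lands within 2x rise time at SNR 10", {
  set.seed(7)
  fs <- 4.17e6
  rise <- filter_rise_time(bessel_lowpass(2e5, fs))
  hits <- vapply(1:150, function(i) {
    x <- c(rep(-1500, 300), rep(-750, 300)) + stats::rnorm(600, 0, 75)
    s <- segment_sublevels(x, sigma = 75, delta_pa = 450, h = 8)
    nrow(s) == 2 && abs(s$end[1] - 300) <= 2 * rise * fs
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("noiseless-regime detection matches ground truth exactly", {
  acq <- acq_default()
  pore <- pore_model(noise_rms_pa = 0.5)   # effectively noiseless
  tr <- simulate_event_windows(acq, pore,
                               open_nanolock(end_capture_weight = 0),
                               30, seed = 8)
  ev <- detect_events(tr)
  expect_equal(nrow(ev), nrow(tr$truth))
  rise <- attr(ev, "rise_time_s")
  # boundaries within the filter rise time of the truth
  expect_lt(max(abs(ev$start_s - tr$truth$start_s)), 2 * rise)
  expect_lt(max(abs((ev$end_s - ev$start_s) - tr$truth$duration_s)),
            4 * rise)
  # folded events resolve into two sublevels unless the fold is extreme
  m <- tr$truth$fold_m; tau <- tr$truth$dwell_s
  resolvable <- pmin(m, 1 - 2 * m) * tau > 3 * rise
  expect_equal(ev$n_sublevels[resolvable] >= 2,
               rep(TRUE, sum(resolvable)))
  sl <- attr(ev, "sublevels")
  expect_true(all(sl$duration_s > 0))
})

test_that("detection at default noise has high recall and no spurious events", {
  acq <- acq_default()
  pore <- pore_default()
  mix <- nanolock_mix(30, 0.5)
  tr <- simulate_event_windows(acq, pore, mix, 800, seed = 9)
  ev <- detect_events(tr)
  ev <- match_truth(ev, tr$truth)
  rise <- attr(ev, "rise_time_s")
  long_enough <- tr$truth$duration_s >= 3 * rise
  recall <- mean(tr$truth$event[long_enough] %in% ev$truth_event)
  expect_gte(recall, 0.99)
  expect_lte(mean(is.na(ev$truth_event)), 0.01)
})

test_that("event-free noise yields no detections after duration filtering", {
  acq <- acq_coarse(duration_s = 5)
  tr <- simulate_trace(acq, pore_default(), nanolock_mix(0, 0), seed = 10)
  ev <- detect_events(tr, detection_config(min_event_s = 2e-4))
  expect_equal(nrow(ev), 0)
})

test_that("detected features agree with ground truth (levels, ECD)", {
  acq <- acq_default()
  pore <- pore_default()
  tr <- simulate_event_windows(acq, pore, closed_nanolock(), 120, seed = 11)
  ev <- match_truth(detect_events(tr), tr$truth)
  expect_gte(nrow(ev), 118)
  expect_equal(median(ev$max_blockage_ns), 10, tolerance = 0.03)
  # ECD survives detection: compare to blockade_1x * tau * V (pC)
  truth_ecd <- 5 * tr$truth$dwell_s[ev$truth_event] * 150
  rel <- abs(ev$ecd_pc - truth_ecd) / truth_ecd
  expect_lt(median(rel), 0.05)
  # zero voltage is rejected
  expect_error(compute_features(attr(ev, "sublevels"), 0), "voltage")
})
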