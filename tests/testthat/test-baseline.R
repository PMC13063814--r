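test_that("constant trace recovers the constant exactly with zero sigma", {
  bl <- estimate_baseline(rep(22500, 5000), 1e5, window_s = 5e-3)
  expect_equal(bl$baseline, rep(22500, 5000))
  expect_equal(bl$sigma, rep(0, 5000))
})

test_that("a rectangular event is masked out of the baseline", {
  x <- rep(1000, 20000)
  x[8000:8200] <- 250   # deep event, shorter than the baseline window
  x <- x + stats::rnorm(20000, 0, 2)
  bl <- estimate_baseline(x, 1e5, window_s = 5e-3)
  expect_lt(max(abs(bl$baseline - 1000)), 2)
  naive <- mean(x[7900:8300])
  expect_gt(abs(naive - 1000), 20)  # the mask matters
})

test_that("baseline tracks a linear drift within 1 pA", {
  set.seed(4)
  n <- 50000; fs <- 1e5
  ramp <- 1000 + 10 * (seq_len(n) - 1) / fs   # 10 pA/s
  x <- ramp + stats::rnorm(n, 0, 3)
  bl <- estimate_baseline(x, fs, window_s = 5e-3)
  expect_lt(max(abs(bl$baseline - ramp)), 1)
})

test_that("trace shorter than the window fails", {
  expect_error(estimate_baseline(rep(1, 10), 1e5, window_s = 5e-3),
               "shorter than")
})
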