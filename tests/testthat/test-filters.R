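test_that("Bessel filter has unit DC gain and preserves pulse area", {
  f <- bessel_lowpass(2e5, 4.17e6)
  x <- rep(17.5, 2000)
  expect_equal(apply_bessel_filter(x, f), x, tolerance = 1e-12)
  # isolated rectangular pulse much longer than the rise time
  x <- c(rep(0, 500), rep(-1500, 2000), rep(0, 4000))
  y <- apply_bessel_filter(x, f)
  expect_lt(abs(sum(y) / sum(x) - 1), 1e-3)
})

test_that("step-response rise time is near 0.34/fc and response is monotone", {
  f <- bessel_lowpass(2e5, 4.17e6)
  rt <- filter_rise_time(f)
  expect_gt(rt * f$cutoff_hz, 0.30)
  expect_lt(rt * f$cutoff_hz, 0.45)
  fr <- signal::freqz(f$b, f$a, n = 2048, Fs = f$sampling_hz)
  m <- Mod(fr$h)
  expect_true(all(diff(m) < 1e-9))              # Bessel: monotone magnitude
  i3 <- which(m <= 1 / sqrt(2))[1]              # -3 dB at the cutoff
  expect_equal(fr$f[i3] / f$cutoff_hz, 1, tolerance = 0.02)
})

test_that("cutoff at or above Nyquist is rejected", {
  expect_error(bessel_lowpass(2.5e6, 4.17e6), "Nyquist")
  expect_error(acquisition_config(sampling_hz = 1e6,
                                  analog_bandwidth_hz = 8e5,
                                  digital_cutoff_hz = 2e5), "<=")
})
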