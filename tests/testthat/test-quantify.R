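test_that("closed fraction and Wilson interval match the closed form", {
  cf <- closed_fraction(c(rep(1L, 0), rep(0L, 500)))
  expect_equal(cf$f, 0)
  cf <- closed_fraction(c(rep(1L, 250), rep(0L, 250)))
  expect_equal(cf$f, 0.5)
  expect_equal(cf$ci_low, 0.4563, tolerance = 1e-3)
  expect_equal(cf$ci_high, 0.5437, tolerance = 1e-3)
  expect_error(closed_fraction(rep(NA_integer_, 5)), "no counted")
})

test_that("Wilson interval has nominal coverage at n = 1000", {
  set.seed(30)
  p <- 0.3
  cover <- vapply(1:500, function(i) {
    k <- stats::rbinom(1, 1000, p)
    ci <- wilson_interval(k, 1000)
    ci[1] <= p && p <= ci[2]
  }, logical(1))
  expect_gte(mean(cover), 0.93)
  expect_lte(mean(cover), 0.97)
})

test_that("capture-rate estimators are exact and unbiased", {
  cr <- capture_rate(300, 600)
  expect_equal(cr$rate_hz, 0.5)
  expect_equal(capture_rate(300, 1200)$rate_hz, 0.25)   # doubling T halves
  set.seed(31)
  est <- t(vapply(1:150, function(i) {
    tt <- poisson_arrivals(0.12, 600)
    c(capture_rate(tt, 600)$rate_hz,
      capture_rate(tt, 600, "interevent_exponential")$rate_hz)
  }, numeric(2)))
  se <- apply(est, 2, stats::sd) / sqrt(nrow(est))
  expect_lt(abs(mean(est[, 1]) - 0.12), 2 * se[1])
  expect_lt(abs(mean(est[, 2]) - 0.12), 3 * se[2])
  # no events with the interevent method: one-sided upper limit
  cr0 <- capture_rate(numeric(0), 600, "interevent_exponential")
  expect_true(cr0$upper_bound)
  expect_equal(cr0$ci_high, log(2) / 600)
})

test_that("4PL fit round-trips noiseless data and stays unbiased with noise", {
  x <- c(0, 0.03, 0.1, 0.3, 1, 3, 10, 30)
  truth <- list(a = 0.82, b = -1.3, c = 2.4, d = 0.01)
  y <- truth$d + (truth$a - truth$d) / (1 + (x / truth$c)^truth$b)
  fit <- fit_4pl(x, y, blank_sd = 0.002)
  for (p in names(truth))
    expect_equal(fit[[p]], truth[[p]], tolerance = 1e-4)
  # inverse round trip on the calibrated span
  xr <- c(0.05, 0.5, 2.4, 5, 25)
  expect_equal(invert_4pl(fit, predict_4pl(fit, xr)), xr, tolerance = 1e-6)
  # 2% noise, 100 replicates: |bias(c)| < 5%
  set.seed(32)
  chat <- vapply(1:100, function(i) {
    yy <- y * (1 + stats::rnorm(length(y), 0, 0.02))
    fit_4pl(x, yy, blank_sd = 0.002)$c
  }, numeric(1))
  expect_lt(abs(mean(chat) / truth$c - 1), 0.05)
  expect_error(fit_4pl(x, rep(0.5, length(x))), "degenerate")
  expect_error(fit_4pl(c(0, 1), c(0, 1)), "fewer points")
})

test_that("LoD sits at blank + 2.5 SD and matches a grid-search oracle", {
  x <- c(0, 0, 0, 0.03, 0.1, 0.3, 1, 3, 10, 30)
  set.seed(33)
  f_true <- 0.008 + 0.99 * (x / 30)
  y <- vapply(f_true, function(p) stats::rbinom(1, 2000, p) / 2000,
              numeric(1))
  fit <- fit_4pl(x, y)
  est <- lod(fit)
  thr <- fit$blank_mean + 2.5 * fit$blank_sd
  expect_equal(est$threshold_response, thr)
  grid <- exp(seq(log(0.001), log(30), length.out = 20000))
  oracle <- grid[which(predict_4pl(fit, grid) >= thr)[1]]
  expect_equal(est$lod, oracle, tolerance = 0.002)
  # degenerate blank SD: lowest calibrated concentration, flagged
  fit0 <- fit_4pl(x, f_true, blank_sd = 0)
  est0 <- lod(fit0)
  expect_true(est0$degenerate_blank)
  expect_equal(est0$lod, 0.03)
})

test_that("sample quantification inverts the curve and flags the hook", {
  x <- c(0, 0.03, 0.1, 0.3, 1, 3, 10, 30)
  y <- 0.01 + (0.8 - 0.01) / (1 + (x / 2)^-1.2)
  curve <- fit_4pl(x, y, blank_sd = 1e-3)
  mid <- predict_4pl(curve, 2)
  expect_equal(quantify_sample(mid, curve)$conc, 2, tolerance = 1e-6)
  expect_equal(quantify_sample(mid, curve, dilution_factor = 25)$conc,
               50, tolerance = 1e-6)
  expect_error(quantify_sample(0.85, curve), "hook")
  expect_equal(spike_recovery(2, 2)$recovery_pct, 100)
  expect_error(spike_recovery(1, 0), "positive")
  rec <- spike_recovery(2.2, 2, measured_ci = c(1.8, 2.6))
  expect_true(rec$ci_pct[1] < 100 && rec$ci_pct[2] > 100)
})

test_that("split/dilution picks the aliquot on the rising flank", {
  x <- c(0, 0.5, 1, 2, 4, 8, 16, 33, 66)
  y1 <- 0.008 + (0.62 - 0.008) / (1 + (x / 18)^-1.4)
  curve1 <- fit_4pl(x, y1, blank_sd = 1e-3)
  x2 <- c(0, 13, 26, 51, 103, 206, 411, 822, 1645)
  y2 <- 0.008 + (0.62 - 0.008) / (1 + (x2 / 450)^-1.4)
  curve2 <- fit_4pl(x2, y2, blank_sd = 1e-3)
  # fractions measured for a low spike: undiluted aliquot reads higher
  r1 <- split_dilution_resolve(0.38, 0.086, curve1, curve2)
  expect_equal(r1$branch, "undiluted")
  expect_equal(r1$conc, invert_4pl(curve1, 0.38), tolerance = 1e-9)
  # high spike: undiluted aliquot is hooked, diluted one reads higher
  r2 <- split_dilution_resolve(0.25, 0.4, curve1, curve2)
  expect_equal(r2$branch, "diluted")
  expect_equal(r2$conc, invert_4pl(curve2, 0.4), tolerance = 1e-9)
  # ties prefer the undiluted branch
  expect_equal(split_dilution_resolve(0.3, 0.3, curve1, curve2)$branch,
               "undiluted")
  expect_error(split_dilution_resolve(0.7, 0.7, curve1, curve2),
               "both aliquots out of range|hook")
})

test_that("running fraction converges with a 1/sqrt(k) Wilson band", {
  rf <- running_fraction(rep(1L, 50))
  expect_true(all(rf$f_k == 1))
  bits <- rep(c(1L, 0L), 1000)
  rf <- running_fraction(bits)
  expect_equal(rf$f_k[2000], 0.5)
  w500 <- rf$ci_high[500] - rf$ci_low[500]
  w2000 <- rf$ci_high[2000] - rf$ci_low[2000]
  expect_equal(w500 / w2000, 2, tolerance = 0.1)
  # streams at f = 0.2 vs 0.4 separate; a larger gap separates sooner
  set.seed(34)
  s2 <- running_fraction(stats::rbinom(3000, 1, 0.2))
  s4 <- running_fraction(stats::rbinom(3000, 1, 0.4))
  s6 <- running_fraction(stats::rbinom(3000, 1, 0.6))
  k24 <- separation_index(s2, s4)
  k26 <- separation_index(s2, s6)
  expect_false(is.na(k24))
  expect_lt(k26, k24)
})
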