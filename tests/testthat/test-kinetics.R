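test_that("no reporter means no closure, ever", {
  sim <- simulate_kinetics(kinetics_config(ratio = 0, t_end_s = 1e4))
  expect_true(all(sim$trajectory$C == 0))
  expect_equal(sim$f_eq, 0)
  expect_equal(time_to_equilibrium(kinetics_config(ratio = 0)), 0)
})

test_that("fast-closure limit reproduces f = x below stoichiometry", {
  xg <- c(0.05, 0.1, 0.25, 0.5, 0.75, 1)
  dr <- dose_response(xg, kinetics_config(ratio = 1, t_end_s = 3e6),
                      fast_closure = TRUE)
  expect_lt(max(abs(dr$f_model / dr$x - 1)), 0.01)
})

test_that("equilibrium dose response peaks at stoichiometric ratio 1", {
  xg <- 10^seq(-2, 1, length.out = 25)
  dr <- dose_response(xg, kinetics_config(ratio = 1, t_end_s = 3e6),
                      fast_closure = TRUE)
  expect_equal(peak_ratio(dr), 1)
  # hook: monotone decline past the stoichiometric plateau
  past <- dr$f_model[dr$x > 1.5]
  expect_true(all(diff(past) < 0))
  expect_lt(dr$f_model[25], dr$f_model[17])   # f(10) < f(1)
  # a floor shifts the response additively without moving the peak
  dr_fl <- dose_response(c(0, 1), kinetics_config(ratio = 1, t_end_s = 3e6),
                         fast_closure = TRUE, floor = 0.008)
  expect_equal(dr_fl$f_model[1], 0.008)
})

test_that("probe and reporter mass are conserved by both solvers", {
  kd <- kinetics_config(ratio = 0.7, t_end_s = 5e4)
  tr <- simulate_kinetics(kd)$trajectory
  expect_lt(max(abs(tr$P + tr$H + tr$C + tr$X - 30)), 1e-7)
  expect_lt(max(abs(tr$R + tr$H + tr$C + 2 * tr$X - 21)), 1e-7)
  ks <- kinetics_config(ratio = 0.7, t_end_s = 5e4,
                        mode = "stochastic_exact", seed = 40)
  trs <- simulate_kinetics(ks, times = seq(0, 5e4, length.out = 11))
  tr <- trs$trajectory
  # exactly conserved (up to molecule-count discretization of the totals)
  expect_equal(tr$P + tr$H + tr$C + tr$X,
               rep((tr$P + tr$H + tr$C + tr$X)[1], 11), tolerance = 1e-12)
  expect_equal(tr$R + tr$H + tr$C + 2 * tr$X,
               rep((tr$R + tr$H + tr$C + 2 * tr$X)[1], 11),
               tolerance = 1e-12)
  expect_equal((tr$P + tr$H + tr$C + tr$X)[1], 30, tolerance = 1e-2)
})

test_that("0.4:1 at 30 nM equilibrates in about 3 hours; rates rescale time", {
  cfg <- kinetics_config(ratio = 0.4, t_end_s = 36 * 3600)
  teq <- time_to_equilibrium(cfg)
  expect_gt(teq / 3600, 2.5)
  expect_lt(teq / 3600, 3.5)
  fast <- kinetics_config(k_bind = 1e6, k_close = 3.7e-3, ratio = 0.4,
                          t_end_s = 3.6 * 3600)
  expect_equal(time_to_equilibrium(fast) / teq, 0.1, tolerance = 0.05)
  slow <- kinetics_config(ratio = 0.4, t_end_s = 600)
  expect_error(time_to_equilibrium(slow), "not equilibrated")
})

test_that("stochastic mean trajectory matches the rate equations", {
  times <- seq(0, 2e4, length.out = 5)
  det <- simulate_kinetics(kinetics_config(ratio = 0.4, t_end_s = 2e4),
                           times = times)$trajectory$f
  set.seed(41)
  M <- vapply(1:100, function(i)
    simulate_kinetics(kinetics_config(ratio = 0.4, t_end_s = 2e4,
                                      mode = "stochastic_exact"),
                      times = times)$trajectory$f,
    numeric(5))
  mse <- apply(M, 1, stats::sd) / sqrt(ncol(M))
  dev <- abs(rowMeans(M) - det)
  expect_true(all(dev[-1] <= 3 * mse[-1]))
  expect_equal(dev[1], 0)
})

test_that("assay chain arithmetic and monotonicity", {
  a <- assay_config(target_conc_pm = 1, capture_efficiency = 1,
                    reporters_per_target = 200, release_efficiency = 1,
                    volume_concentration_factor = 1, probe_nm = 30)
  out <- assay_chain(a, fast_closure = TRUE)
  expect_equal(out$x, 0.2 / 30, tolerance = 1e-12)     # 200 pM / 30 nM
  expect_equal(out$reporter_nm, 0.2)
  a0 <- assay_config(target_conc_pm = 1, reporters_per_target = 0)
  out0 <- assay_chain(a0, fast_closure = TRUE, floor = 0.008)
  expect_equal(out0$x, 0)
  expect_equal(out0$f, 0.008)                          # blank level
  ah <- assay_config(target_conc_pm = 1, release_efficiency = 0.5,
                     volume_concentration_factor = 1)
  outh <- assay_chain(ah, fast_closure = TRUE)
  expect_equal(outh$x, out$x / 2, tolerance = 1e-12)   # halves exactly
  expect_lt(outh$f, out$f)
  expect_error(assay_config(target_conc_pm = 1, capture_efficiency = 1.2))
})
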