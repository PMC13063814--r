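test_that("waveform geometries produce the expected segments and bits", {
  pore <- pore_default()
  set.seed(1)
  wc <- sample_event_waveforms(closed_nanolock(), pore, 50)
  expect_true(all(wc$events$true_bit == 1L))
  expect_true(all(wc$segments$level_ns == 10))
  expect_equal(wc$segments$duration_s, wc$events$dwell_s / 2)  # tau/2

  ws <- sample_event_waveforms(ruler_species(), pore, 50)
  expect_true(all(ws$segments$level_ns == 5))
  expect_equal(ws$segments$duration_s, ws$events$dwell_s)

  # pure end capture: always single file
  we <- sample_event_waveforms(open_nanolock(end_capture_weight = 1),
                               pore, 50)
  expect_true(all(we$segments$level_ns == 5))

  # forced mid-contour capture: 2x segment of m*tau then 1x tail
  wf <- sample_event_waveforms(open_nanolock(end_capture_weight = 0),
                               pore, 200)
  m <- wf$events$fold_m
  expect_true(all(m > 0 & m <= 0.5))
  first <- wf$segments[!duplicated(wf$segments$event), ]
  expect_true(all(first$level_ns == 10))
  expect_equal(first$duration_s, m * wf$events$dwell_s)
  tails <- wf$segments[duplicated(wf$segments$event), ]
  expect_true(all(tails$level_ns == 5))
})

test_that("unfiltered ECD is conserved across fold configurations", {
  pore <- pore_default()
  v <- 150
  set.seed(2)
  for (sp in list(ruler_species(), closed_nanolock(),
                  open_nanolock(end_capture_weight = 0),
                  open_nanolock())) {
    w <- sample_event_waveforms(sp, pore, 100)
    ecd <- waveform_ecd(w$segments, v)
    # identical to blockade_1x * tau * V for every geometry
    expect_equal(as.numeric(ecd[order(as.integer(names(ecd)))]),
                 5 * w$events$dwell_s * v, tolerance = 1e-12)
  }
})

test_that("unknown geometry is rejected with a diagnostic", {
  sp <- ruler_species()
  sp$geometry <- "moebius"
  expect_error(sample_event_waveforms(sp, pore_default(), 1),
               "unknown species geometry")
  expect_error(species_model("x", "moebius"), "arg")
})
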