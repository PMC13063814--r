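# Event-level run simulation: draws classified event streams for counting
# studies (standard curves, LoD comparisons, running fractions) through the
# real waveform sampler and shape classifier, without rendering traces.
# Trace-level studies use simulate_event_windows() + detect_events().

#' Simulate one nanopore recording at the event level
#'
#' Draws a Poisson number of captures for a NanoLock population with the
#' given closed fraction, samples each event's ground-truth waveform, and
#' classifies the waveforms with the shape taxonomy (ideal, noiseless
#' levels). The geometric false-positive channel - open molecules folded
#' near their midpoint - is fully preserved. Capture-rate variability
#' enters through `rate_multiplier`.
#'
#' @param closed_fraction true fraction of closed probes.
#' @param duration_s recording duration (s).
#' @param probe_nm probe concentration (nM).
#' @param rate_multiplier run-specific capture-rate factor (pore size,
#'   drift, ...); scales event counts, not the closed fraction.
#' @param pore a [pore_model()].
#' @param open,closed species models for the two probe states.
#' @param tolerance,min_tail_s classifier settings (see [classify_events()]).
#' @param seed optional seed.
#' @return list: `classified` (data.frame `event`, `start_s`, `true_bit`,
#'   `event_type`, `digital_bit`), `duration_s`, `n_events`.
#' @export
simulate_run <- function(closed_fraction, duration_s, probe_nm = 30,
                         rate_multiplier = 1, pore = pore_model(),
                         open = open_nanolock(), closed = closed_nanolock(),
                         tolerance = 0.35, min_tail_s = NULL, seed = NULL) {
  stopifnot(closed_fraction >= 0, closed_fraction <= 1, duration_s > 0,
            rate_multiplier >= 0)
  if (!is.null(seed)) set.seed(seed)
  rate <- open$capture_rate_per_nm_hz * probe_nm * rate_multiplier
  n <- stats::rpois(1, rate * duration_s)
  if (n == 0)
    return(list(classified = data.frame(event = integer(0),
                                        start_s = numeric(0),
                                        true_bit = integer(0),
                                        event_type = character(0),
                                        digital_bit = integer(0)),
                duration_s = duration_s, n_events = 0L))
  n1 <- stats::rbinom(1, n, closed_fraction)
  n0 <- n - n1
  parts <- list()
  if (n0 > 0) parts$open <- sample_event_waveforms(open, pore, n0)
  if (n1 > 0) parts$closed <- sample_event_waveforms(closed, pore, n1)
  off <- 0L
  evs <- list(); segs <- list()
  for (p in parts) {
    p$events$event <- p$events$event + off
    p$segments$event <- p$segments$event + off
    off <- off + nrow(p$events)
    evs[[length(evs) + 1]] <- p$events
    segs[[length(segs) + 1]] <- p$segments
  }
  events <- do.call(rbind, evs)
  segments <- do.call(rbind, segs)
  cls <- classify_waveforms(segments, pore, tolerance, min_tail_s)
  out <- merge(events[, c("event", "true_bit")], cls, by = "event")
  # random arrival order
  ord <- sample.int(n)
  out <- out[ord, ]
  out$event <- seq_len(n)
  out$start_s <- sort(stats::runif(n, 0, duration_s))
  rownames(out) <- NULL
  list(classified = out[, c("event", "start_s", "true_bit", "event_type",
                            "digital_bit")],
       duration_s = duration_s, n_events = n)
}

#' Simulate a digital + analog standard-curve data set
#'
#' One run per reporter concentration plus replicate blanks, each with an
#' independent log-normal capture-rate multiplier (mean 1, given CV)
#' emulating pore-to-pore and run-to-run variability. True closed fractions
#' come from the binding-model dose response; each run is simulated at the
#' event level and summarized by its digital (closed fraction) and analog
#' ("1"-event capture rate) responses.
#'
#' Run durations are set so blanks accrue `events_blank` expected captures
#' and standards `events_standard`: the digital blank SD must be dominated
#' by the run-to-run variability floor rather than by counting noise for
#' the self-calibration advantage to be expressed (see the methods
#' vignette on run sizing).
#'
#' @param reporter_nm reporter concentrations of the standards (nM).
#' @param probe_nm probe concentration (nM).
#' @param n_blanks number of blank replicate runs.
#' @param events_standard,events_blank expected event counts per run.
#' @param rate_cv coefficient of variation of the log-normal run-to-run
#'   rate multiplier (default 0.5).
#' @param kinetics a [kinetics_config()] for the dose response.
#' @param fast_closure evaluate the dose response in the fast-closure limit.
#' @param floor additive closed-fraction floor (spontaneous misfolding).
#' @param pore,open,closed,tolerance,min_tail_s passed to [simulate_run()].
#' @return data.frame, one row per run: `conc_nm`, `role`, `multiplier`,
#'   `n_events`, `n_1`, `duration_s`, `f_digital`, `rate_analog_hz`.
#' @export
simulate_standard_runs <- function(reporter_nm = c(0.03, 0.1, 0.3, 1, 3, 10,
                                                   30),
                                   probe_nm = 30, n_blanks = 3,
                                   events_standard = 1e5,
                                   events_blank = 6e5,
                                   rate_cv = 0.5,
                                   kinetics = kinetics_config(ratio = 1),
                                   fast_closure = TRUE, floor = 0.008,
                                   pore = pore_model(),
                                   open = open_nanolock(),
                                   closed = closed_nanolock(),
                                   tolerance = 0.35, min_tail_s = NULL) {
  kin <- kinetics; kin$probe_nm <- probe_nm
  dr <- dose_response(reporter_nm / probe_nm, kin,
                      fast_closure = fast_closure, floor = floor)
  conc <- c(rep(0, n_blanks), reporter_nm)
  ftrue <- c(rep(floor, n_blanks), pmin(1, dr$f_model))
  role <- c(rep("blank", n_blanks), rep("standard", length(reporter_nm)))
  targets <- c(rep(events_blank, n_blanks),
               rep(events_standard, length(reporter_nm)))
  sdlog <- sqrt(log(1 + rate_cv^2))
  base_rate <- open$capture_rate_per_nm_hz * probe_nm
  out <- vector("list", length(conc))
  for (i in seq_along(conc)) {
    mult <- stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    dur <- targets[i] / base_rate
    run <- simulate_run(ftrue[i], dur, probe_nm, mult, pore, open, closed,
                        tolerance, min_tail_s)
    bit <- run$classified$digital_bit
    n1 <- sum(bit == 1L, na.rm = TRUE)
    ncounted <- sum(!is.na(bit))
    out[[i]] <- data.frame(
      conc_nm = conc[i], role = role[i], multiplier = mult,
      n_events = run$n_events, n_1 = n1, duration_s = dur,
      f_digital = if (ncounted > 0) n1 / ncounted else NA_real_,
      rate_analog_hz = n1 / dur)
  }
  do.call(rbind, out)
}

#' Digital vs analog limit of detection on paired standard curves
#'
#' Fits a 4PL standard curve to the digital responses (closed fraction) and
#' another to the analog responses ("1"-event capture rate) of the *same*
#' simulated runs, computes each LoD at the blank mean + 2.5 blank SD, and
#' reports the analog/digital LoD ratio - the sensitivity advantage of the
#' self-calibrating digital readout under capture-rate variability.
#'
#' @param runs output of [simulate_standard_runs()].
#' @return list `digital` (curve, lod), `analog` (curve, lod),
#'   `lod_ratio`.
#' @export
lod_comparison <- function(runs) {
  dig <- fit_4pl(runs$conc_nm, runs$f_digital)
  ana <- fit_4pl(runs$conc_nm, runs$rate_analog_hz)
  ld <- lod_or_bound(dig); la <- lod_or_bound(ana)
  list(digital = list(curve = dig, lod = ld),
       analog = list(curve = ana, lod = la),
       lod_ratio = la$lod / ld$lod)
}

# lod() with a grid-search fallback: when the 2.5-SD threshold is not
# invertible on the fitted curve (very noisy responses can leave it above
# the fitted asymptote), report the smallest calibrated concentration whose
# fitted response reaches the threshold, or the top of the calibrated span
# as a lower bound when none does.
lod_or_bound <- function(curve, k_sd = 2.5) {
  out <- tryCatch(lod(curve, k_sd), error = function(e) NULL)
  if (!is.null(out)) return(out)
  thr <- curve$blank_mean + k_sd * curve$blank_sd
  span <- range(curve$conc[curve$conc > 0])
  grid <- exp(seq(log(span[1]), log(span[2]), length.out = 2000))
  hit <- which(predict_4pl(curve, grid) >= thr)
  x <- if (length(hit)) grid[hit[1]] else span[2]
  structure(list(lod = x, threshold_response = thr,
                 extrapolated = FALSE, degenerate_blank = FALSE,
                 lower_bound = length(hit) == 0),
            class = "lod_estimate")
}
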