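#' Event detection settings
#'
#' Thresholds and CUSUM parameters for translocation event detection on the
#' digitally filtered trace. An event opens when the current deviates below
#' the local baseline by `start_threshold` sigma and closes when it returns
#' within `end_hysteresis` sigma. Within each event window, sublevels are fit
#' by a two-sided CUSUM for mean shifts.
#'
#' `cusum_delta_pa` (the smallest level shift of interest) defaults to 0.6 x
#' the 1x-dsDNA blockade current, and `cusum_h` to the threshold giving an
#' in-control average run length of at least ten times the longest allowed
#' event (Siegmund's approximation), floored at 4; both are resolved against
#' the trace being analyzed when left `NULL`.
#'
#' @param start_threshold event opening threshold, in baseline-sigma units.
#' @param end_hysteresis event closing threshold, in sigma units; must be
#'   below `start_threshold`.
#' @param cusum_delta_pa expected minimal sublevel shift (pA), or `NULL`.
#' @param cusum_h CUSUM alarm threshold (sigma units), or `NULL`.
#' @param min_event_s,max_event_s dwell limits; detections outside are
#'   rejected (tallied, not returned).
#' @param min_sublevel_s shortest sublevel kept; shorter segments are merged
#'   into the neighbouring level with the closer mean.
#' @param baseline_window_s block length for [estimate_baseline()].
#' @return object of class `detection_config`.
#' @export
detection_config <- function(start_threshold = 5, end_hysteresis = 1,
                             cusum_delta_pa = NULL, cusum_h = NULL,
                             min_event_s = 5e-6, max_event_s = 1e-2,
                             min_sublevel_s = 2e-6,
                             baseline_window_s = 5e-3) {
  stopifnot(start_threshold > end_hysteresis, end_hysteresis >= 0,
            min_event_s < max_event_s, min_sublevel_s > 0)
  structure(list(start_threshold = start_threshold,
                 end_hysteresis = end_hysteresis,
                 cusum_delta_pa = cusum_delta_pa, cusum_h = cusum_h,
                 min_event_s = min_event_s, max_event_s = max_event_s,
                 min_sublevel_s = min_sublevel_s,
                 baseline_window_s = baseline_window_s),
            class = "detection_config")
}

# CUSUM alarm threshold from a target in-control average run length
# (Siegmund's approximation for a one-sided scheme with allowance k):
# ARL ~ (exp(2kb) - 2kb - 1) / (2k^2) with b = h + 1.166. Solved for b by
# fixed-point iteration in log space (robust to the exponential overflowing
# for large allowances).
cusum_h_for_arl <- function(k, arl) {
  b <- 1
  for (i in 1:100) {
    b_new <- log(2 * k^2 * arl + 2 * k * b + 1) / (2 * k)
    if (abs(b_new - b) < 1e-10) break
    b <- b_new
  }
  max(4, b - 1.166)
}

#' Detect candidate event windows by threshold crossing
#'
#' @param current filtered current samples (pA).
#' @param baseline output of [estimate_baseline()] on the same samples.
#' @param config a [detection_config()].
#' @param sampling_hz sampling rate (Hz).
#' @return data.frame with `start_idx`, `end_idx` (hysteresis bounds,
#'   inclusive) plus attribute `rejected`, a named count of windows excluded
#'   by the duration limits or trace boundaries.
#' @export
detect_event_bounds <- function(current, baseline, config, sampling_hz) {
  dev <- baseline$baseline - current
  sig <- pmax(baseline$sigma, 1e-12)
  seeds <- which(dev > config$start_threshold * sig)
  rejected <- c(too_short = 0L, too_long = 0L, boundary = 0L)
  empty <- data.frame(start_idx = integer(0), end_idx = integer(0))
  if (length(seeds) == 0) {
    attr(empty, "rejected") <- rejected
    return(empty)
  }
  inblock <- dev > config$end_hysteresis * sig
  # run ids over the hysteresis mask; an event is a TRUE-run containing a seed
  runid <- cumsum(c(TRUE, inblock[-1] != inblock[-length(inblock)]))
  ev_runs <- unique(runid[seeds])
  run_start <- which(c(TRUE, runid[-1] != runid[-length(runid)]))
  run_end <- c(run_start[-1] - 1L, length(runid))
  a <- run_start[ev_runs]; b <- run_end[ev_runs]
  o <- order(a); a <- a[o]; b <- b[o]
  n <- length(current)
  at_boundary <- (a == 1L) | (b == n)
  rejected["boundary"] <- sum(at_boundary)
  a <- a[!at_boundary]; b <- b[!at_boundary]
  dur <- (b - a + 1) / sampling_hz
  rejected["too_short"] <- sum(dur < config$min_event_s)
  rejected["too_long"] <- sum(dur > config$max_event_s)
  keep <- dur >= config$min_event_s & dur <= config$max_event_s
  out <- data.frame(start_idx = a[keep], end_idx = b[keep])
  attr(out, "rejected") <- rejected
  out
}

#' Segment an event window into current sublevels (CUSUM)
#'
#' Runs the two-sided CUSUM change-point procedure on a window of filtered
#' samples, then merges adjacent segments whose means differ by less than
#' `delta_pa` and segments shorter than the minimum sublevel duration.
#'
#' @param window numeric vector of filtered samples (pA).
#' @param sigma local noise SD (pA).
#' @param delta_pa minimal level shift (pA).
#' @param h CUSUM alarm threshold (sigma units).
#' @param min_sublevel_samples shortest retained segment, in samples.
#' @param guard_samples samples trimmed from each segment end when computing
#'   its mean (filter rise-time guard).
#' @return data.frame with `start`, `end` (1-based, inclusive, relative to
#'   the window), `mean_pa`.
#' @export
segment_sublevels <- function(window, sigma, delta_pa, h,
                              min_sublevel_samples = 1L, guard_samples = 0L) {
  n <- length(window)
  if (n < 1) stop("empty window")
  if (sigma <= 0 || stats::var(window) == 0)
    return(data.frame(start = 1L, end = n,
                      mean_pa = guarded_mean(window, guard_samples)))
  k <- delta_pa / (2 * sigma)
  cps <- cusum_changepoints(window, sigma, k, h)
  bounds <- c(0L, cps, n)
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1]
  repeat {
    means <- vapply(seq_along(starts), function(i)
      guarded_mean(window[starts[i]:ends[i]], guard_samples), numeric(1))
    if (length(starts) == 1L) break
    len <- ends - starts + 1L
    # merge short segments first, then indistinct neighbours
    short <- which(len < min_sublevel_samples)
    if (length(short) > 0) {
      i <- short[which.min(len[short])]
      j <- merge_partner(i, means)
    } else {
      dm <- abs(diff(means))
      if (all(dm >= delta_pa)) break
      i <- which.min(dm); j <- i + 1L
    }
    lo <- min(i, j); hi <- max(i, j)
    starts <- starts[-hi]; ends <- ends[-lo]
    if (length(starts) == 1L) {
      means <- guarded_mean(window[starts:ends], guard_samples)
      break
    }
  }
  data.frame(start = starts, end = ends,
             mean_pa = vapply(seq_along(starts), function(i)
               guarded_mean(window[starts[i]:ends[i]], guard_samples),
               numeric(1)))
}

guarded_mean <- function(x, guard) {
  g <- min(guard, (length(x) - 1L) %/% 2L)
  if (g > 0) mean(x[(g + 1L):(length(x) - g)]) else mean(x)
}

merge_partner <- function(i, means) {
  if (i == 1L) return(2L)
  if (i == length(means)) return(i - 1L)
  if (abs(means[i - 1] - means[i]) <= abs(means[i + 1] - means[i]))
    i - 1L else i + 1L
}

#' Detect and characterize translocation events in a trace
#'
#' Full detection chain: applies the digital analysis Bessel filter, tracks
#' the local baseline, finds threshold-crossing event windows, fits current
#' sublevels by CUSUM within each window (padded by the filter rise time),
#' and computes per-event features: maximum blockage (deepest fitted
#' sublevel, as a conductance), dwell time and event charge deficit (the
#' integral of the blockade over the padded window).
#'
#' @param trace a `nanopore_trace` (from [simulate_trace()],
#'   [simulate_event_windows()] or [read_trace()]).
#' @param config a [detection_config()].
#' @return a `detected_events` data.frame (one row per accepted event:
#'   `event_id`, `start_s`, `end_s`, `dwell_s`, `max_blockage_ns`, `ecd_pc`,
#'   `n_sublevels`, `baseline_pa`, `sigma_pa`), with attributes `sublevels`
#'   (per-sublevel table), `voltage_mv`, `duration_s`, `rise_time_s`,
#'   `rejected` (tally of excluded windows) and `config`.
#' @export
detect_events <- function(trace, config = detection_config()) {
  stopifnot(inherits(trace, "nanopore_trace"))
  acq <- trace$acq
  if (acq$voltage_mv == 0) stop("zero voltage: conductance undefined")
  fs <- acq$sampling_hz
  fd <- cached_filter(acq$digital_cutoff_hz, fs, acq$filter_poles)
  rise_s <- filter_rise_time(fd)
  y <- apply_bessel_filter(trace$current_pa, fd)
  bl <- estimate_baseline(y, fs, config$baseline_window_s,
                          config$start_threshold)
  bounds <- detect_event_bounds(y, bl, config, fs)
  delta <- config$cusum_delta_pa
  if (is.null(delta))
    delta <- 0.6 * trace$pore$blockade_1x_ns * abs(acq$voltage_mv)
  sig_glob <- stats::median(bl$sigma)
  h <- config$cusum_h
  if (is.null(h))
    h <- cusum_h_for_arl(delta / (2 * max(sig_glob, 1e-12)),
                         10 * config$max_event_s * fs)
  pad <- ceiling(rise_s * fs)
  guard <- ceiling(rise_s * fs)
  min_sub <- max(1L, round(config$min_sublevel_s * fs))
  n <- length(y)
  nev <- nrow(bounds)
  ev <- vector("list", nev); subs <- vector("list", nev)
  for (i in seq_len(nev)) {
    a <- bounds$start_idx[i]; b <- bounds$end_idx[i]
    wa <- max(1L, a - pad); wb <- min(n, b + pad)
    base_i <- mean(bl$baseline[c(wa, wb)])
    sig_i <- max(mean(bl$sigma[c(wa, wb)]), 1e-12)
    seg <- segment_sublevels(y[wa:wb], sig_i, delta, h,
                             min_sublevel_samples = min_sub,
                             guard_samples = guard)
    seg$blockade_pa <- base_i - seg$mean_pa
    # retain event sublevels; leading/trailing baseline segments drop out
    keep <- seg$blockade_pa > config$start_threshold * sig_i
    if (!any(keep)) next
    kept <- seg[keep, , drop = FALSE]
    dev <- bl$baseline[wa:wb] - y[wa:wb]
    ecd <- sum(dev[-c(1, length(dev))]) + (dev[1] + dev[length(dev)]) / 2
    ecd <- ecd / fs  # pA*s = pC
    ev[[i]] <- data.frame(
      event_id = i,
      start_s = (a - 1) / fs,
      end_s = b / fs,
      dwell_s = (b - a + 1) / fs,
      max_blockage_ns = max(kept$blockade_pa) / abs(acq$voltage_mv),
      ecd_pc = ecd,
      n_sublevels = nrow(kept),
      baseline_pa = base_i,
      sigma_pa = sig_i)
    subs[[i]] <- data.frame(
      event_id = i,
      start_s = (wa + kept$start - 2) / fs,
      end_s = (wa + kept$end - 1) / fs,
      duration_s = (kept$end - kept$start + 1) / fs,
      mean_pa = kept$mean_pa,
      blockade_pa = kept$blockade_pa,
      blockade_ns = kept$blockade_pa / abs(acq$voltage_mv))
  }
  found <- !vapply(ev, is.null, logical(1))
  events <- if (any(found)) do.call(rbind, ev[found]) else
    data.frame(event_id = integer(0), start_s = numeric(0),
               end_s = numeric(0), dwell_s = numeric(0),
               max_blockage_ns = numeric(0), ecd_pc = numeric(0),
               n_sublevels = integer(0), baseline_pa = numeric(0),
               sigma_pa = numeric(0))
  events$event_id <- seq_len(nrow(events))
  sublevels <- if (any(found)) {
    sl <- do.call(rbind, subs[found])
    sl$event_id <- rep(events$event_id, events$n_sublevels)
    sl
  } else NULL
  rej <- attr(bounds, "rejected")
  rej["no_sublevel"] <- sum(!found)
  structure(events, sublevels = sublevels, voltage_mv = acq$voltage_mv,
            duration_s = acq$duration_s, rise_time_s = rise_s,
            rejected = rej, config = config,
            class = c("detected_events", "data.frame"))
}

#' Compute per-event features from fitted sublevels
#'
#' Mostly used internally by [detect_events()]; exposed for recomputing
#' features at a different voltage or after editing sublevels.
#'
#' @param sublevels sublevel table (`event_id`, `duration_s`,
#'   `blockade_pa`).
#' @param voltage_mv applied voltage, mV (non-zero).
#' @return data.frame with `event_id`, `max_blockage_ns`, `ecd_pc`, `dwell_s`.
#' @export
compute_features <- function(sublevels, voltage_mv) {
  if (voltage_mv == 0) stop("zero voltage: conductance undefined")
  mx <- tapply(sublevels$blockade_pa, sublevels$event_id, max)
  ecd <- tapply(sublevels$blockade_pa * sublevels$duration_s,
                sublevels$event_id, sum)
  dw <- tapply(sublevels$duration_s, sublevels$event_id, sum)
  data.frame(event_id = as.integer(names(mx)),
             max_blockage_ns = as.numeric(mx) / abs(voltage_mv),
             ecd_pc = as.numeric(ecd), dwell_s = as.numeric(dw))
}

#' Match detected events to the ground-truth log
#'
#' Pairs each detected event with the ground-truth event whose time span
#' overlaps it (if any), for recall/precision and classification accuracy
#' studies on synthetic traces.
#'
#' @param events a `detected_events` table.
#' @param truth ground-truth table of a `nanopore_trace`.
#' @return `events` with an added `truth_event` column (`NA` when spurious).
#' @export
match_truth <- function(events, truth) {
  te <- rep(NA_integer_, nrow(events))
  if (nrow(truth) > 0 && nrow(events) > 0) {
    for (i in seq_len(nrow(events))) {
      ov <- which(truth$start_s < events$end_s[i] &
                  truth$start_s + truth$duration_s > events$start_s[i])
      if (length(ov) >= 1) te[i] <- truth$event[ov[1]]
    }
  }
  events$truth_event <- te
  events
}
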