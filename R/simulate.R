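# Trace synthesis: Poisson capture, piecewise-constant event waveforms,
# hardware (analog-bandwidth) Bessel stage and baseline noise.

filter_cache <- new.env(parent = emptyenv())
cached_filter <- function(cutoff_hz, sampling_hz, poles,
                          method = "bilinear") {
  key <- paste(cutoff_hz, sampling_hz, poles, method, sep = "|")
  if (is.null(filter_cache[[key]]))
    filter_cache[[key]] <- bessel_lowpass(cutoff_hz, sampling_hz, poles,
                                          method)
  filter_cache[[key]]
}

# white-noise input SD (pA, per sample at sampling_hz) such that after the
# analog stage and the digital analysis filter the RMS equals noise_rms_pa
noise_input_sd <- function(acq, pore) {
  if (pore$noise_rms_pa == 0) return(0)
  fa <- cached_filter(acq$analog_bandwidth_hz, acq$sampling_hz,
                      acq$filter_poles, "matched_z")
  fd <- cached_filter(acq$digital_cutoff_hz, acq$sampling_hz,
                      acq$filter_poles)
  pore$noise_rms_pa / sqrt(noise_gain(fa, fd))
}

# total dwell (trace occupancy) of each event in a waveform segment table
event_total_durations <- function(segments) {
  as.numeric(tapply(segments$duration_s, segments$event, sum))
}

render_trace <- function(starts_s, events, segments, acq, pore) {
  fs <- acq$sampling_hz
  n <- round(acq$duration_s * fs)
  i0 <- pore$open_conductance_ns * acq$voltage_mv # pA
  cur <- rep(i0, n)
  if (pore$drift_pa_per_s != 0)
    cur <- cur + pore$drift_pa_per_s * (seq_len(n) - 1) / fs
  if (nrow(events) > 0) {
    seg_start_within <- unlist(tapply(segments$duration_s, segments$event,
                                      function(d) cumsum(c(0, d[-length(d)]))))
    abs_start <- starts_s[segments$event] + seg_start_within
    a <- pmax(1L, floor(abs_start * fs) + 1L)
    b <- pmin(n, floor((abs_start + segments$duration_s) * fs))
    drop_pa <- segments$level_ns * acq$voltage_mv
    for (k in seq_along(a)) if (b[k] >= a[k])
      cur[a[k]:b[k]] <- cur[a[k]:b[k]] - drop_pa[k]
  }
  sd_in <- noise_input_sd(acq, pore)
  if (sd_in > 0) cur <- cur + stats::rnorm(n, 0, sd_in)
  fa <- cached_filter(acq$analog_bandwidth_hz, acq$sampling_hz,
                      acq$filter_poles, "matched_z")
  apply_bessel_filter(cur, fa)
}

#' Simulate a nanopore current trace with known ground truth
#'
#' Event start times are drawn as independent Poisson processes per species
#' (rate = capture rate per nM x concentration); each event's waveform is
#' drawn by [sample_event_waveforms()]; the baseline is the open-pore current
#' plus optional linear drift; Gaussian white input noise is shaped by the
#' analog-bandwidth Bessel stage, which is applied to the whole trace
#' (signal + noise) as in acquisition hardware. The digital analysis filter
#' is *not* applied here; detection applies it (see [detect_events()]).
#'
#' Overlapping events are resolved by re-drawing the later start time (up to
#' 100 attempts); at the capture rates typical of these experiments
#' (<= 0.5 Hz) pile-up is negligible.
#'
#' @param acq an [acquisition_config()].
#' @param pore a [pore_model()].
#' @param mix a [mix_spec()] (or [nanolock_mix()]).
#' @param seed optional integer seed; identical seed and configuration give a
#'   bit-identical trace.
#' @return object of class `nanopore_trace`: list with `current_pa`, `acq`,
#'   `pore`, and `truth` (per-event table: `event`, `species`, `start_s`,
#'   `p`, `fold_m`, `dwell_s`, `duration_s`, `true_bit`).
#' @export
simulate_trace <- function(acq, pore, mix, seed = NULL) {
  stopifnot(inherits(acq, "acquisition_config"), inherits(pore, "pore_model"),
            inherits(mix, "mix_spec"))
  if (!is.null(seed)) set.seed(seed)
  dur <- acq$duration_s
  all_events <- list(); all_segments <- list(); off <- 0L
  for (j in seq_along(mix$species)) {
    sp <- mix$species[[j]]
    rate <- sp$capture_rate_per_nm_hz * mix$conc_nm[j]
    nev <- stats::rpois(1, rate * dur)
    if (nev == 0) next
    w <- sample_event_waveforms(sp, pore, nev)
    w$events$event <- w$events$event + off
    w$segments$event <- w$segments$event + off
    off <- off + nev
    all_events[[length(all_events) + 1L]] <- w$events
    all_segments[[length(all_segments) + 1L]] <- w$segments
  }
  if (length(all_events) == 0) {
    events <- data.frame(event = integer(0), species = character(0),
                         p = numeric(0), fold_m = numeric(0),
                         dwell_s = numeric(0), true_bit = integer(0))
    segments <- data.frame(event = integer(0), seg = integer(0),
                           level_ns = numeric(0), duration_s = numeric(0))
    starts <- numeric(0)
  } else {
    events <- do.call(rbind, all_events)
    segments <- do.call(rbind, all_segments)
    segments <- segments[order(segments$event, segments$seg), ]
    totdur <- event_total_durations(segments)
    guard <- 20 / acq$digital_cutoff_hz # keep events resolvable as separate
    starts <- stats::runif(nrow(events), 0, pmax(0, dur - totdur - guard))
    for (try in seq_len(100)) {
      o <- order(starts)
      gap_ok <- c(TRUE, starts[o][-1] >
                    (starts[o] + totdur[o] + guard)[-length(o)])
      if (all(gap_ok)) break
      bad <- o[!gap_ok]
      if (try == 100)
        stop("event pile-up persists after 100 re-draws; ",
             "lower the concentration or shorten dwell times")
      starts[bad] <- stats::runif(length(bad), 0,
                                  pmax(0, dur - totdur[bad] - guard))
    }
    o <- order(starts)
    events <- events[o, ]; starts <- starts[o]
    relab <- match(segments$event, events$event)
    segments <- segments[order(relab, segments$seg), ]
    segments$event <- rep(seq_len(nrow(events)),
                          tabulate(relab, nbins = nrow(events)))
    events$event <- seq_len(nrow(events))
    rownames(events) <- NULL
  }
  truth <- events
  truth$start_s <- starts
  truth$duration_s <- if (nrow(truth)) event_total_durations(segments) else numeric(0)
  cur <- render_trace(starts, events, segments, acq, pore)
  structure(list(current_pa = cur, acq = acq, pore = pore, truth = truth,
                 segments = segments),
            class = "nanopore_trace")
}

#' Simulate a batch of single-event windows as one trace
#'
#' For controlled classifier studies: draws `n_events` events of one species
#' (or of a mixture, sampled by concentration weight) and places one event
#' per fixed-length window, at one third of the window. The result is a
#' regular `nanopore_trace` of duration `n_events * window_s` that the
#' standard detection chain can process; every ground-truth event is well
#' separated and fully contained.
#'
#' @param acq an [acquisition_config()] (its `duration_s` is ignored).
#' @param pore a [pore_model()].
#' @param species a [species_model()] or a [mix_spec()].
#' @param n_events number of events.
#' @param window_s window length per event (s); events whose waveform would
#'   not fit in two thirds of the window are re-drawn.
#' @param seed optional integer seed.
#' @return a `nanopore_trace`.
#' @export
simulate_event_windows <- function(acq, pore, species, n_events,
                                   window_s = 1.5e-3, seed = NULL) {
  stopifnot(n_events >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (inherits(species, "mix_spec")) {
    stopifnot(sum(species$conc_nm) > 0)
    pick <- sample.int(length(species$species), n_events, replace = TRUE,
                       prob = species$conc_nm)
    sp_list <- species$species
  } else {
    pick <- rep(1L, n_events)
    sp_list <- list(species)
  }
  events <- vector("list", n_events); segments <- vector("list", n_events)
  maxdur <- 2 * window_s / 3
  for (i in seq_len(n_events)) {
    repeat {
      w <- sample_event_waveforms(sp_list[[pick[i]]], pore, 1L)
      if (sum(w$segments$duration_s) <= maxdur) break
    }
    w$events$event <- i; w$segments$event <- i
    events[[i]] <- w$events; segments[[i]] <- w$segments
  }
  events <- do.call(rbind, events)
  segments <- do.call(rbind, segments)
  starts <- (seq_len(n_events) - 1) * window_s + window_s / 3
  acq2 <- acq; acq2$duration_s <- n_events * window_s
  truth <- events
  truth$start_s <- starts
  truth$duration_s <- event_total_durations(segments)
  cur <- render_trace(starts, events, segments, acq2, pore)
  structure(list(current_pa = cur, acq = acq2, pore = pore, truth = truth,
                 segments = segments, window_s = window_s),
            class = "nanopore_trace")
}

#' @export
print.nanopore_trace <- function(x, ...) {
  cat(sprintf(
    "<nanopore_trace> %d samples (%.3g s at %.3g MHz), %d ground-truth events\n",
    length(x$current_pa), x$acq$duration_s, x$acq$sampling_hz / 1e6,
    nrow(x$truth)))
  invisible(x)
}
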