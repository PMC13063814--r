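#' Sample ideal event waveforms for a species
#'
#' Draws `n` ground-truth translocation events for one species as
#' piecewise-constant conductance-blockade waveforms, before any filtering or
#' noise. Let tau be the single-file dwell draw:
#' * single-file: one segment at the 1x blockade lasting tau;
#' * circular: one segment at the 2x blockade lasting tau/2 (two helices
#'   translocate simultaneously over half the contour);
#' * foldable linear: with probability `end_capture_weight` pure single file;
#'   otherwise a capture position p ~ U(0,1) gives a fold fraction
#'   m = min(p, 1-p), a 2x segment of length m*tau and a 1x tail of length
#'   (1-2m)*tau.
#'
#' The unfiltered blockade area (event charge deficit) is
#' `blockade_1x * tau * V` for every realization of the same dwell draw,
#' regardless of geometry.
#'
#' @param species a [species_model()].
#' @param pore a [pore_model()].
#' @param n number of events to draw.
#' @return list with `events` (one row per event: `event`, `species`, `p`,
#'   `fold_m`, `dwell_s`, `true_bit`) and `segments` (one row per
#'   piecewise-constant segment: `event`, `seg`, `level_ns`, `duration_s`).
#'   Zero-duration tails (capture exactly at the midpoint) are dropped.
#' @export
sample_event_waveforms <- function(species, pore, n) {
  stopifnot(inherits(species, "species_model"), inherits(pore, "pore_model"),
            n >= 1)
  g1 <- pore$blockade_1x_ns; g2 <- pore$blockade_2x_ns
  tau <- stats::rlnorm(n, meanlog = log(species$dwell_median_s),
                       sdlog = species$dwell_sigma)
  p <- rep(NA_real_, n)
  if (species$geometry == "single_file_only") {
    ev_levels <- lapply(seq_len(n), function(i) c(g1))
    ev_durs <- lapply(seq_len(n), function(i) tau[i])
    bit <- rep(0L, n)
  } else if (species$geometry == "circular") {
    ev_levels <- lapply(seq_len(n), function(i) c(g2))
    ev_durs <- lapply(seq_len(n), function(i) tau[i] / 2)
    bit <- rep(1L, n)
  } else if (species$geometry == "foldable_linear") {
    endcap <- stats::runif(n) < species$end_capture_weight
    p[!endcap] <- stats::runif(sum(!endcap))
    m <- pmin(p, 1 - p)
    ev_levels <- vector("list", n); ev_durs <- vector("list", n)
    for (i in seq_len(n)) {
      if (endcap[i]) {
        ev_levels[[i]] <- g1; ev_durs[[i]] <- tau[i]
      } else {
        lv <- c(g2, g1); du <- c(m[i] * tau[i], (1 - 2 * m[i]) * tau[i])
        keep <- du > 0
        ev_levels[[i]] <- lv[keep]; ev_durs[[i]] <- du[keep]
      }
    }
    bit <- rep(0L, n)
  } else {
    stop("unknown species geometry: ", species$geometry)
  }
  nseg <- lengths(ev_levels)
  events <- data.frame(event = seq_len(n), species = species$name,
                       p = p, fold_m = pmin(p, 1 - p), dwell_s = tau,
                       true_bit = bit, stringsAsFactors = FALSE)
  segments <- data.frame(event = rep(seq_len(n), nseg),
                         seg = sequence(nseg),
                         level_ns = unlist(ev_levels),
                         duration_s = unlist(ev_durs))
  list(events = events, segments = segments)
}

#' @rdname sample_event_waveforms
#' @export
sample_event_waveform <- function(species, pore) {
  w <- sample_event_waveforms(species, pore, 1L)
  list(event = w$events[1, ], segments = w$segments)
}

#' Unfiltered event charge deficit of ground-truth waveforms
#'
#' Integrates blockade current over each event's segments:
#' `sum(level_ns * duration_s) * voltage_mv`, in pC.
#'
#' @param segments segment table from [sample_event_waveforms()].
#' @param voltage_mv applied voltage (mV).
#' @return named numeric vector of ECDs (pC), one per event.
#' @export
waveform_ecd <- function(segments, voltage_mv) {
  area <- tapply(segments$level_ns * segments$duration_s, segments$event, sum)
  area * voltage_mv  # nS * s * mV = pA * s = pC
}
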