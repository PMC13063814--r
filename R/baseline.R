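#' Robust local baseline and noise estimate
#'
#' Estimates the open-pore baseline and noise level along a trace by
#' blockwise robust statistics (median and MAD per block of
#' `window_s`, linearly interpolated between block centres), iteratively
#' masking excursions beyond `threshold` sigma below the current baseline
#' estimate and re-estimating until stable. Tracks slow drift while ignoring
#' translocation events.
#'
#' @param current numeric vector of (filtered) current samples, pA.
#' @param sampling_hz sampling rate (Hz).
#' @param window_s block length (s); the trace must be at least one block
#'   long.
#' @param threshold masking threshold in sigma units (default 5).
#' @param max_iter maximum mask/re-estimate iterations.
#' @return list with numeric vectors `baseline` and `sigma` (same length as
#'   `current`).
#' @export
estimate_baseline <- function(current, sampling_hz, window_s = 5e-3,
                              threshold = 5, max_iter = 4) {
  n <- length(current)
  wlen <- round(window_s * sampling_hz)
  if (n < wlen) stop("trace (", n, " samples) shorter than baseline window (",
                     wlen, " samples)")
  nb <- max(1L, floor(n / wlen))
  lo <- (seq_len(nb) - 1L) * wlen + 1L
  hi <- c(lo[-1L] - 1L, n)
  centres <- (lo + hi) / 2
  mask <- rep(FALSE, n)
  base <- sig <- NULL
  for (it in seq_len(max_iter)) {
    bm <- bs <- rep(NA_real_, nb)
    for (j in seq_len(nb)) {
      xj <- current[lo[j]:hi[j]][!mask[lo[j]:hi[j]]]
      if (length(xj) >= 2) {
        bm[j] <- stats::median(xj)
        bs[j] <- stats::mad(xj)
      }
    }
    # blocks fully masked (long events): carry over neighbours via interpolation
    ok <- !is.na(bm) & !is.na(bs) & bs > 0
    if (!any(ok)) { ok <- !is.na(bm); bs[is.na(bs)] <- 0 }
    if (sum(ok) == 1L) {
      base <- rep(bm[ok], n); sig <- rep(max(bs[ok], 0), n)
    } else {
      base <- stats::approx(centres[ok], bm[ok], xout = seq_len(n),
                            rule = 2)$y
      sig <- stats::approx(centres[ok], bs[ok], xout = seq_len(n),
                           rule = 2)$y
    }
    new_mask <- (base - current) > threshold * pmax(sig, 1e-12)
    if (identical(new_mask, mask)) break
    mask <- new_mask
  }
  list(baseline = base, sigma = pmax(sig, 0))
}
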