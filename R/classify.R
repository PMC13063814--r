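#' Calibrate the 1x-dsDNA blockage level from a molecular-ruler run
#'
#' A 400 bp dsDNA run (no sticky ends, single-file only) is used as a
#' molecular ruler: the dominant mode of its maximum-blockage histogram
#' fixes the 1x-dsDNA conductance level for the pore at hand, normalizing
#' away pore-to-pore geometry variation. The mode is located on a kernel
#' density estimate and refined by a single-Gaussian fit (trimmed
#' mean/SD within +-30% of the mode, iterated).
#'
#' @param ruler_events a `detected_events` table from a ruler run (>= 100
#'   events recommended; fewer than 20 is an error).
#' @return object of class `ruler_calibration`: `delta_g_1x_ns`, `sigma_ns`,
#'   `n_events`, `source`.
#' @export
calibrate_ruler <- function(ruler_events, source = "ruler") {
  b <- ruler_events$max_blockage_ns
  b <- b[is.finite(b)]
  if (length(b) < 20)
    stop("ruler calibration needs at least 20 events, got ", length(b))
  d <- stats::density(b, bw = "SJ", n = 1024)
  # candidate modes: local maxima of the KDE
  pk <- which(diff(sign(diff(d$y))) == -2) + 1L
  pk <- pk[order(d$y[pk], decreasing = TRUE)]
  if (length(pk) >= 2) {
    sep <- abs(d$x[pk[2]] - d$x[pk[1]]) > 0.3 * d$x[pk[1]]
    if (sep && d$y[pk[2]] > 0.5 * d$y[pk[1]])
      stop("bimodal ruler histogram (modes at ",
           signif(d$x[pk[1]], 3), " and ", signif(d$x[pk[2]], 3),
           " nS): contaminated ruler run")
  }
  mode <- d$x[pk[1]]
  for (it in 1:3) {
    w <- b[b > 0.7 * mode & b < 1.3 * mode]
    mode <- mean(w)
  }
  structure(list(delta_g_1x_ns = mode, sigma_ns = stats::sd(w),
                 n_events = length(b), source = source),
            class = "ruler_calibration")
}

# Shared shape taxonomy on normalized levels. Inputs: per-sublevel
# normalized blockades b_i = blockade / delta_g_1x and durations, in
# translocation order. Returns the event type.
#   single_file : max level in the 1x band
#   circular    : max level in the 2x band, no resolvable 1x tail after it
#   folded      : 2x level followed by a 1x tail lasting >= min_tail
#   reject      : mid-band / too deep / shallow-first two-step shapes
classify_shape <- function(b_levels, durations, tolerance, min_tail_s) {
  bmax <- max(b_levels)
  in1 <- function(b) b >= 1 - tolerance & b <= 1 + tolerance
  in2 <- function(b) b >= 2 - tolerance & b <= 2 + tolerance
  if (bmax > 2 + tolerance) return("reject")       # co-translocation
  if (in1(bmax)) return("single_file")
  if (!in2(bmax)) return("reject")                 # between bands
  i2 <- which(in2(b_levels))[1]
  before <- seq_len(length(b_levels)) < i2
  after <- seq_len(length(b_levels)) > i2
  if (any(before & in1(b_levels) & durations >= min_tail_s))
    return("reject")                               # shallow level first
  if (any(after & in1(b_levels) & durations >= min_tail_s))
    return("folded")
  "circular"
}

#' Classify detected events into digital bits
#'
#' Normalizes each event's blockades by the ruler level
#' (`b = blockade / delta_g_1x`) and applies the three-type shape taxonomy:
#' a single level in the 1x band is a single-file open molecule (bit 0); a
#' 2x-deep level followed by a resolvable 1x tail is a folded open molecule
#' (bit 0); a 2x-deep level with no such tail is a circular closed molecule
#' (bit 1). Events outside both bands, deeper than the 2x band (multi-
#' molecule co-translocation) or with a shallow-first two-step shape are
#' rejected and excluded from counting.
#'
#' A fold placed close enough to the molecule's midpoint leaves a tail
#' shorter than the filter can resolve; such events fall in the circular
#' class and are the scheme's intrinsic false positives.
#'
#' @param events a `detected_events` table (with its `sublevels` attribute).
#' @param cal a [calibrate_ruler()] calibration.
#' @param tolerance half-width of the 1x and 2x acceptance bands on the
#'   normalized level (default 0.35, splitting the bands at 1.5x).
#' @param min_tail_s minimum resolvable tail duration; defaults to 2x the
#'   filter rise time recorded on `events`.
#' @return a `classified_events` data.frame: `events` plus `b`
#'   (normalized max blockage), `event_type` and `digital_bit` (0, 1 or NA
#'   for rejects).
#' @export
classify_events <- function(events, cal, tolerance = 0.35,
                            min_tail_s = NULL) {
  stopifnot(inherits(cal, "ruler_calibration"))
  if (is.null(min_tail_s)) {
    rise <- attr(events, "rise_time_s")
    if (is.null(rise)) stop("min_tail_s not given and no rise time on events")
    min_tail_s <- 2 * rise
  }
  sl <- attr(events, "sublevels")
  out <- as.data.frame(events)
  out$b <- out$max_blockage_ns / cal$delta_g_1x_ns
  type <- character(nrow(out))
  for (i in seq_len(nrow(out))) {
    si <- sl[sl$event_id == out$event_id[i], , drop = FALSE]
    type[i] <- classify_shape(si$blockade_ns / cal$delta_g_1x_ns,
                              si$duration_s, tolerance, min_tail_s)
  }
  out$event_type <- type
  out$digital_bit <- ifelse(type == "circular", 1L,
                            ifelse(type == "reject", NA_integer_, 0L))
  structure(out, voltage_mv = attr(events, "voltage_mv"),
            duration_s = attr(events, "duration_s"),
            tolerance = tolerance, min_tail_s = min_tail_s,
            calibration = cal,
            class = c("classified_events", "data.frame"))
}

#' Classify ideal (ground-truth) waveforms
#'
#' Applies the same shape taxonomy directly to noiseless ground-truth
#' segment tables from [sample_event_waveforms()], normalizing by the true
#' 1x level. This is the event-level fast path for large counting studies:
#' it preserves the geometric false-positive mechanism (mid-contour folds
#' whose tails are shorter than `min_tail_s`) without rendering traces.
#'
#' @param segments segment table (`event`, `level_ns`, `duration_s`).
#' @param pore the [pore_model()] used to generate the waveforms.
#' @param tolerance band half-width (as in [classify_events()]).
#' @param min_tail_s minimum resolvable tail (s); default 2x the rise time
#'   of the default 200 kHz analysis filter at the default sampling rate.
#' @return data.frame `event`, `event_type`, `digital_bit`.
#' @export
classify_waveforms <- function(segments, pore, tolerance = 0.35,
                               min_tail_s = NULL) {
  if (is.null(min_tail_s)) min_tail_s <- 2 * default_rise_time()
  g1 <- pore$blockade_1x_ns
  ids <- unique(segments$event)
  # vectorized taxonomy: ideal waveforms carry one or two exact levels and
  # are always deep-first, so the shape rules reduce to band membership of
  # the maximum level plus the tail-duration test
  first <- !duplicated(segments$event)
  second <- duplicated(segments$event)
  b1 <- segments$level_ns[first] / g1
  b2 <- rep(NA_real_, length(ids)); d2 <- rep(NA_real_, length(ids))
  idx2 <- match(segments$event[second], ids)
  b2[idx2] <- segments$level_ns[second] / g1
  d2[idx2] <- segments$duration_s[second]
  bmax <- pmax(b1, b2, na.rm = TRUE)
  t <- tolerance
  type <- rep("reject", length(ids))
  type[bmax >= 1 - t & bmax <= 1 + t] <- "single_file"
  in2 <- bmax >= 2 - t & bmax <= 2 + t
  tail_ok <- !is.na(b2) & b2 >= 1 - t & b2 <= 1 + t & d2 >= min_tail_s
  type[in2 & tail_ok] <- "folded"
  type[in2 & !tail_ok] <- "circular"
  data.frame(event = ids, event_type = type,
             digital_bit = ifelse(type == "circular", 1L,
                                  ifelse(type == "reject", NA_integer_, 0L)))
}

default_rise_time <- local({
  val <- NULL
  function() {
    if (is.null(val))
      val <<- filter_rise_time(cached_filter(2e5, 4.17e6, 4L))
    val
  }
})

#' False-positive rate of the digital classification
#'
#' Fraction of counted ground-truth-open (bit 0) events that were classified
#' as circular (bit 1), with an exact binomial confidence interval. With no
#' ground truth the run is assumed to be a negative control containing only
#' open molecules.
#'
#' @param classified a `classified_events` table (or any data.frame with
#'   `digital_bit`).
#' @param true_bit optional vector of ground-truth bits aligned with
#'   `classified` rows; `NULL` treats every counted event as a true negative.
#' @param conf confidence level.
#' @return list `fp_rate`, `n_negatives`, `n_false_positive`, `ci`.
#' @export
false_positive_rate <- function(classified, true_bit = NULL, conf = 0.95) {
  bit <- classified$digital_bit
  counted <- !is.na(bit)
  if (is.null(true_bit)) true_bit <- rep(0L, length(bit))
  neg <- counted & true_bit == 0
  n <- sum(neg)
  if (n == 0) stop("no counted ground-truth-negative events: ",
                   "false-positive rate undefined")
  k <- sum(bit[neg] == 1L)
  ci <- stats::binom.test(k, n, conf.level = conf)$conf.int
  list(fp_rate = k / n, n_negatives = n, n_false_positive = k,
       ci = as.numeric(ci))
}
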