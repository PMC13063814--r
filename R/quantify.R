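#' Wilson score interval for a binomial fraction
#'
#' @param k successes, @param n trials, @param conf confidence level.
#' @return numeric `c(low, high)`.
#' @export
wilson_interval <- function(k, n, conf = 0.95) {
  stopifnot(n >= 1, k >= 0, k <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, ctr - hw), min(1, ctr + hw))
}

#' Digital readout: closed fraction with Wilson interval
#'
#' The digital estimate of the assay response: the fraction of counted
#' events classified as circular ("1") among all counted events ("1" and
#' "0"); rejected events are excluded from the denominator and tallied.
#'
#' @param classified a `classified_events` table, or a vector of digital
#'   bits (0/1, `NA` = rejected).
#' @param conf confidence level for the Wilson interval.
#' @return object of class `closed_fraction`: `n_1`, `n_0`, `n_rejected`,
#'   `f`, `ci_low`, `ci_high`.
#' @export
closed_fraction <- function(classified, conf = 0.95) {
  bit <- if (is.data.frame(classified)) classified$digital_bit else classified
  n1 <- sum(bit == 1L, na.rm = TRUE)
  n0 <- sum(bit == 0L, na.rm = TRUE)
  if (n1 + n0 == 0) stop("no counted events: closed fraction undefined")
  ci <- wilson_interval(n1, n1 + n0, conf)
  structure(list(n_1 = n1, n_0 = n0, n_rejected = sum(is.na(bit)),
                 f = n1 / (n1 + n0), ci_low = ci[1], ci_high = ci[2]),
            class = "closed_fraction")
}

#' Analog readout: capture rate of an event class
#'
#' Estimates the capture rate either as the total event count over the
#' recording time, or by maximum likelihood on the interevent intervals
#' (exponential waiting times with the final open interval right-censored).
#' Both agree within sampling error on Poisson data.
#'
#' @param times event times (s) within the run (`count_over_time` also
#'   accepts just a count).
#' @param duration_s recording duration (s).
#' @param method `"count_over_time"` or `"interevent_exponential"`.
#' @param conf confidence level.
#' @return object of class `capture_rate`: `rate_hz`, `n_events`,
#'   `duration_s`, `method`, `ci_low`, `ci_high` (and `upper_bound = TRUE`
#'   when n = 0 forced a one-sided limit).
#' @export
capture_rate <- function(times, duration_s,
                         method = c("count_over_time",
                                    "interevent_exponential"),
                         conf = 0.95) {
  method <- match.arg(method)
  stopifnot(duration_s > 0)
  n <- if (length(times) == 1 && is.numeric(times) &&
           method == "count_over_time" && times == round(times) &&
           is.null(attr(times, "times"))) times else length(times)
  upper_bound <- FALSE
  if (method == "count_over_time") {
    rate <- n / duration_s
    ci <- stats::poisson.test(round(n), conf.level = conf)$conf.int /
      duration_s
  } else {
    if (n == 0) {
      # no event observed: one-sided upper limit (median of exp posterior)
      rate <- 0
      ci <- c(0, log(2) / duration_s)
      upper_bound <- TRUE
    } else {
      tt <- sort(times)
      # MLE with n-1 complete gaps and the final open interval censored
      tot <- (tt[n] - tt[1]) + (duration_s - tt[n])
      rate <- if (n > 1) (n - 1) / tot else 1 / tot
      df <- 2 * max(n - 1, 1)
      ci <- rate * stats::qchisq(c((1 - conf) / 2, 1 - (1 - conf) / 2),
                                 df) / df
    }
  }
  structure(list(rate_hz = rate, n_events = n, duration_s = duration_s,
                 method = method, ci_low = ci[1], ci_high = ci[2],
                 upper_bound = upper_bound),
            class = "capture_rate")
}

#' Fit a four-parameter logistic standard curve
#'
#' Least-squares fit of `y = d + (a - d) / (1 + (x / c)^b)` (4PL) to
#' concentration/response pairs, with multi-start Levenberg-Marquardt
#' initialization. Blank runs (x = 0) contribute the blank mean and SD used
#' for the limit of detection; they enter the fit at x = 0 (where the 4PL
#' evaluates to `d` for b < 0, i.e. an increasing curve).
#'
#' @param conc concentrations (>= 0; zeros are blanks). At least 5 distinct
#'   levels including the blank are recommended; fewer points than
#'   parameters is an error.
#' @param response responses (closed fraction or capture rate).
#' @param weights optional fit weights (default unweighted).
#' @param blank_sd optional blank SD override; default `sd(response[conc ==
#'   0])`.
#' @return object of class `standard_curve`: 4PL parameters `a`, `b`, `c`,
#'   `d`, `blank_mean`, `blank_sd`, the data, fitted values and convergence
#'   info.
#' @export
fit_4pl <- function(conc, response, weights = NULL, blank_sd = NULL) {
  stopifnot(length(conc) == length(response), all(conc >= 0))
  if (any(!is.finite(response))) stop("non-finite responses")
  if (length(conc) < 4) stop("fewer points than 4PL parameters")
  if (stats::sd(response) == 0) stop("degenerate fit: constant responses")
  blanks <- conc == 0
  blank_mean <- if (any(blanks)) mean(response[blanks]) else NA_real_
  if (is.null(blank_sd))
    blank_sd <- if (sum(blanks) >= 2) stats::sd(response[blanks]) else
      NA_real_
  if (is.null(weights)) weights <- rep(1, length(conc))
  xpos <- conc[conc > 0]
  f4 <- function(x, a, b, c, d) d + (a - d) / (1 + (x / c)^b)
  lo <- min(response); hi <- max(response); span <- hi - lo
  # anchor the zero-concentration asymptote at the blank: without this the
  # weakly-constrained lower asymptote can drift above blank + 2.5 SD and
  # make the LoD threshold non-invertible
  d_upper <- if (any(blanks)) blank_mean else Inf
  starts <- expand.grid(
    c = exp(stats::quantile(log(xpos), c(0.25, 0.5, 0.75))),
    b = c(-0.5, -1, -2))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        response ~ f4(conc, a, b, c, d),
        start = list(a = hi + 0.05 * span, b = starts$b[i], c = starts$c[i],
                     d = min(lo - 0.05 * span, d_upper)),
        lower = c(a = -Inf, b = -Inf, c = 1e-12, d = -Inf),
        upper = c(a = Inf, b = Inf, c = Inf, d = d_upper),
        weights = weights,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) stop("4PL fit failed to converge from all starts")
  p <- as.list(stats::coef(best$fit))
  structure(list(a = p$a, b = p$b, c = p$c, d = p$d,
                 blank_mean = blank_mean, blank_sd = blank_sd,
                 conc = conc, response = response,
                 fitted = f4(conc, p$a, p$b, p$c, p$d),
                 rss = best$rss, converged = TRUE),
            class = "standard_curve")
}

#' Evaluate / invert a fitted 4PL curve
#'
#' @param curve a `standard_curve`.
#' @param x concentrations (for `predict_4pl`) or responses (for
#'   `invert_4pl`).
#' @return predicted responses, or concentrations. `invert_4pl` returns
#'   `NA` with a warning for responses outside the open interval between
#'   the two asymptotes.
#' @export
predict_4pl <- function(curve, x) {
  with(curve, d + (a - d) / (1 + (x / c)^b))
}

#' @rdname predict_4pl
#' @export
invert_4pl <- function(curve, x) {
  with(curve, {
    lo <- min(a, d); hi <- max(a, d)
    out <- rep(NA_real_, length(x))
    ok <- x > lo & x < hi
    out[ok] <- c * ((a - x[ok]) / (x[ok] - d))^(1 / b)
    if (any(!ok)) warning("response(s) outside the asymptote range")
    out
  })
}

#' Limit of detection from a standard curve
#'
#' The LoD is the concentration whose fitted response equals the blank mean
#' plus 2.5 blank standard deviations, obtained by inverse-4PL evaluation.
#'
#' @param curve a `standard_curve` with blank statistics.
#' @param k_sd multiple of the blank SD (default 2.5).
#' @return object of class `lod_estimate`: `lod`, `threshold_response`,
#'   `extrapolated` (TRUE when the LoD falls below the lowest non-blank
#'   calibrated concentration), `degenerate_blank` (TRUE when blank SD = 0
#'   forced the lowest calibrated concentration to be returned as a bound).
#' @export
lod <- function(curve, k_sd = 2.5) {
  stopifnot(inherits(curve, "standard_curve"))
  if (!is.finite(curve$blank_mean) || !is.finite(curve$blank_sd))
    stop("blank mean/SD unavailable: cannot compute LoD")
  xmin <- min(curve$conc[curve$conc > 0])
  if (curve$blank_sd == 0) {
    return(structure(list(lod = xmin, threshold_response = curve$blank_mean,
                          extrapolated = FALSE, degenerate_blank = TRUE),
                     class = "lod_estimate"))
  }
  thr <- curve$blank_mean + k_sd * curve$blank_sd
  hi <- max(curve$a, curve$d)
  if (thr >= hi)
    stop("LoD undefined: blank + ", k_sd, " SD (", signif(thr, 4),
         ") exceeds the curve's upper asymptote (", signif(hi, 4), ")")
  x <- suppressWarnings(invert_4pl(curve, thr))
  if (!is.finite(x)) stop("LoD threshold not invertible on the fitted curve")
  structure(list(lod = x, threshold_response = thr,
                 extrapolated = x < xmin, degenerate_blank = FALSE),
            class = "lod_estimate")
}

#' Interpolate a sample concentration from a standard curve
#'
#' Inverse 4PL of the measured response, times the dilution factor. A
#' response above the curve's upper asymptote fails with a hook-suspect
#' diagnostic (use [split_dilution_resolve()]).
#'
#' @param response measured response (e.g. closed fraction).
#' @param curve a `standard_curve`.
#' @param dilution_factor pre-measurement dilution to undo (default 1).
#' @return list `conc`, `in_range` (FALSE when the response lies outside
#'   the calibrated response span, flagged not failed).
#' @export
quantify_sample <- function(response, curve, dilution_factor = 1) {
  hi <- max(curve$a, curve$d); lo <- min(curve$a, curve$d)
  if (response >= hi)
    stop("response ", signif(response, 4), " at/above the upper asymptote: ",
         "hook effect suspected - re-measure diluted (split/dilution)")
  if (response <= lo)
    stop("response at/below the lower asymptote: not invertible")
  rng <- range(curve$fitted)
  x <- invert_4pl(curve, response)
  list(conc = x * dilution_factor,
       in_range = response >= rng[1] & response <= rng[2])
}

#' Resolve the hook effect by split/dilution
#'
#' Each sample is measured twice: undiluted against a low-range curve and
#' diluted against a high-range curve. The aliquot with the *higher*
#' fraction is the one on the rising flank of its dose response; it is
#' inverted on its own curve with its dilution factor applied (ties prefer
#' the undiluted branch).
#'
#' @param f_undiluted,f_diluted measured responses of the two aliquots.
#' @param curve1 standard curve for the undiluted regime.
#' @param curve2 standard curve for the diluted regime (built at full
#'   concentrations, measured diluted - its inversion already reports the
#'   undiluted concentration, so no dilution factor is re-applied unless
#'   given).
#' @param dilution_factor1,dilution_factor2 factors applied to the inverted
#'   concentration of each branch (defaults 1).
#' @return list `conc`, `branch` ("undiluted" or "diluted"), `response_used`.
#' @export
split_dilution_resolve <- function(f_undiluted, f_diluted, curve1, curve2,
                                   dilution_factor1 = 1,
                                   dilution_factor2 = 1) {
  use_undil <- f_undiluted >= f_diluted
  q <- NULL
  for (branch in if (use_undil) c("undiluted", "diluted") else
       c("diluted", "undiluted")) {
    q <- tryCatch({
      if (branch == "undiluted")
        c(quantify_sample(f_undiluted, curve1, dilution_factor1),
          branch = branch, response_used = f_undiluted)
      else
        c(quantify_sample(f_diluted, curve2, dilution_factor2),
          branch = branch, response_used = f_diluted)
    }, error = function(e) NULL)
    if (!is.null(q)) break
  }
  if (is.null(q))
    stop("both aliquots out of range: hook beyond both calibrated regimes")
  q
}

#' Spike recovery
#'
#' @param measured_conc measured concentration (same units as nominal).
#' @param nominal_conc nominal spiked concentration (> 0).
#' @param measured_ci optional CI on the measured concentration; propagated
#'   by scaling.
#' @return list `recovery_pct` (100 x measured/nominal) and `ci_pct`.
#' @export
spike_recovery <- function(measured_conc, nominal_conc, measured_ci = NULL) {
  if (nominal_conc <= 0) stop("nominal concentration must be positive")
  out <- list(recovery_pct = 100 * measured_conc / nominal_conc)
  if (!is.null(measured_ci))
    out$ci_pct <- 100 * sort(measured_ci) / nominal_conc
  out
}

#' Running closed fraction with confidence band
#'
#' Cumulative fraction of "1" events after each counted event, with a
#' Wilson band; shows how many events are needed before concentrations
#' separate.
#'
#' @param classified a `classified_events` table or a bit vector (rejects
#'   `NA` are skipped).
#' @param conf confidence level for the band.
#' @return data.frame `k` (counted-event index), `f_k`, `ci_low`, `ci_high`.
#' @export
running_fraction <- function(classified, conf = 0.95) {
  bit <- if (is.data.frame(classified)) classified$digital_bit else classified
  bit <- bit[!is.na(bit)]
  k <- seq_along(bit)
  s <- cumsum(bit)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- s / k
  den <- 1 + z^2 / k
  ctr <- (p + z^2 / (2 * k)) / den
  hw <- z * sqrt(p * (1 - p) / k + z^2 / (4 * k^2)) / den
  data.frame(k = k, f_k = p, ci_low = pmax(0, ctr - hw),
             ci_high = pmin(1, ctr + hw))
}

#' First event count at which two running fractions separate
#'
#' @param rf1,rf2 outputs of [running_fraction()].
#' @return smallest k at which the two Wilson bands are disjoint (and stay
#'   disjoint for all larger shared k); `NA` if they never separate.
#' @export
separation_index <- function(rf1, rf2) {
  n <- min(nrow(rf1), nrow(rf2))
  if (n == 0) return(NA_integer_)
  disjoint <- rf1$ci_low[1:n] > rf2$ci_high[1:n] |
    rf2$ci_low[1:n] > rf1$ci_high[1:n]
  if (!any(disjoint)) return(NA_integer_)
  stay <- rev(cumprod(rev(disjoint))) > 0
  if (!any(stay)) return(NA_integer_)
  which(stay)[1]
}
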