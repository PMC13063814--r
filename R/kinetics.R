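# Circularization kinetics of NanoLock probes by bridging reporter strands.
#
# Irreversible reaction network (concentrations in nM):
#   R + P -> H   rate 2*k_bind*R*P  (reporter half binds either free overhang)
#   H     -> C   rate k_close*H     (bound reporter bridges the other overhang)
#   R + H -> X   rate k_bind*R*H    (second reporter caps the remaining end)
# P = probe with both ends free, H = half-bridge, C = closed (circular),
# X = capped (both overhangs occupied by different reporters - terminal).
# Probe mass P+H+C+X and reporter mass R+H+C+2X are conserved.

#' Kinetics configuration for NanoLock circularization
#'
#' @param k_bind bimolecular hybridization rate of a reporter half to a free
#'   overhang, 1/(M s). Default 1e5, the typical order for short-overhang
#'   DNA hybridization.
#' @param k_close unimolecular closure rate of a half-bridge, 1/s. The
#'   default 3.7e-4 anchors the 0.4:1, 30 nM condition to reach equilibrium
#'   in about 3 hours.
#' @param probe_nm probe concentration P0 (nM), default 30.
#' @param ratio reporter:probe ratio x (R0 = ratio * probe_nm); give either
#'   `ratio` or `reporter_nm`.
#' @param reporter_nm reporter concentration R0 (nM).
#' @param t_end_s integration horizon (s).
#' @param mode `"deterministic_rate_equations"` or `"stochastic_exact"`.
#' @param volume_l reaction volume for stochastic mode (L); must give at
#'   least ~100 probe molecules. The femtolitre-scale default (1e-13 L,
#'   ~1800 probe molecules at 30 nM)
#'   keeps exact simulation affordable while satisfying that bound.
#' @param seed RNG seed for stochastic mode.
#' @return object of class `kinetics_config`.
#' @export
kinetics_config <- function(k_bind = 1e5, k_close = 3.7e-4, probe_nm = 30,
                            ratio = NULL, reporter_nm = NULL, t_end_s = 1e5,
                            mode = c("deterministic_rate_equations",
                                     "stochastic_exact"),
                            volume_l = 1e-13, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(k_bind >= 0, k_close >= 0, probe_nm >= 0, t_end_s > 0)
  if (is.null(reporter_nm)) {
    if (is.null(ratio)) stop("give either ratio or reporter_nm")
    stopifnot(ratio >= 0)
    reporter_nm <- ratio * probe_nm
  }
  cfg <- structure(list(k_bind = k_bind, k_close = k_close,
                        probe_nm = probe_nm, reporter_nm = reporter_nm,
                        ratio = reporter_nm / probe_nm, t_end_s = t_end_s,
                        mode = mode, volume_l = volume_l, seed = seed),
                   class = "kinetics_config")
  if (mode == "stochastic_exact") {
    nmol <- conc_to_count(probe_nm, volume_l)
    if (nmol < 100)
      stop("stochastic mode needs >= 100 probe molecules; volume gives ",
           nmol)
  }
  cfg
}

avogadro <- 6.02214076e23
conc_to_count <- function(conc_nm, volume_l)
  round(conc_nm * 1e-9 * avogadro * volume_l)

#' Simulate the circularization reaction network
#'
#' Deterministic mode integrates the rate equations with a stiff-capable
#' adaptive integrator (lsoda); stochastic mode runs an exact event-driven
#' (Gillespie) simulation with identical propensities. Both report the full
#' species time course and the closed fraction `f = C / P0` at `t_end_s`.
#'
#' @param config a [kinetics_config()].
#' @param times output time grid (s); default 401 points to `t_end_s`.
#' @return list with `trajectory` (data.frame `t_s`, `R`, `P`, `H`, `C`,
#'   `X`, `f`, in nM) and `f_eq` (closed fraction at `t_end_s`).
#' @export
simulate_kinetics <- function(config, times = NULL) {
  stopifnot(inherits(config, "kinetics_config"))
  if (is.null(times))
    times <- seq(0, config$t_end_s, length.out = 401)
  kb <- config$k_bind * 1e-9   # 1/(nM s)
  kc <- config$k_close
  P0 <- config$probe_nm; R0 <- config$reporter_nm
  if (config$mode == "deterministic_rate_equations") {
    rhs <- function(t, y, parms) {
      vRP <- 2 * kb * y[1] * y[2]; vHC <- kc * y[3]; vRH <- kb * y[1] * y[3]
      list(c(-vRP - vRH, -vRP, vRP - vHC - vRH, vHC, vRH))
    }
    sol <- deSolve::ode(c(R = R0, P = P0, H = 0, C = 0, X = 0), times, rhs,
                        NULL, method = "lsoda", rtol = 1e-10, atol = 1e-12)
    if (attr(sol, "istate")[1] < 0)
      stop("rate-equation integration failed (istate ",
           attr(sol, "istate")[1], "); see deSolve diagnostics")
    tr <- as.data.frame(sol)
    names(tr)[1] <- "t_s"
  } else {
    if (!is.null(config$seed)) set.seed(config$seed)
    V <- config$volume_l
    nR <- conc_to_count(R0, V); nP <- conc_to_count(P0, V)
    kbc <- kb / (1e-9 * avogadro * V)  # per-pair rate, 1/s
    nH <- 0L; nC <- 0L; nX <- 0L; t <- 0
    out <- matrix(NA_real_, length(times), 6)
    fill <- 1L
    repeat {
      a1 <- 2 * kbc * nR * nP; a2 <- kc * nH; a3 <- kbc * nR * nH
      atot <- a1 + a2 + a3
      tnext <- if (atot > 0) t + stats::rexp(1, atot) else Inf
      while (fill <= length(times) && times[fill] < tnext) {
        out[fill, ] <- c(times[fill], nR, nP, nH, nC, nX)
        fill <- fill + 1L
      }
      if (fill > length(times) || atot == 0) break
      t <- tnext
      u <- stats::runif(1, 0, atot)
      if (u < a1) { nR <- nR - 1L; nP <- nP - 1L; nH <- nH + 1L }
      else if (u < a1 + a2) { nH <- nH - 1L; nC <- nC + 1L }
      else { nR <- nR - 1L; nH <- nH - 1L; nX <- nX + 1L }
    }
    scl <- 1 / (1e-9 * avogadro * V)
    tr <- data.frame(t_s = out[, 1], R = out[, 2] * scl, P = out[, 3] * scl,
                     H = out[, 4] * scl, C = out[, 5] * scl,
                     X = out[, 6] * scl)
  }
  tr$f <- if (P0 > 0) tr$C / P0 else 0
  list(trajectory = tr, f_eq = tr$f[nrow(tr)])
}

#' Equilibrium dose response over a reporter:probe ratio grid
#'
#' Integrates the rate equations to `t_end_s` for each ratio and reports the
#' closed fraction, optionally rescaled by an additive floor accounting for
#' spontaneous misfolding/misassembly (`f_obs = floor + (1 - floor) * f`).
#' In the fast-closure limit the response rises as `f = x` up to ratio 1 and
#' declines beyond it (hook effect: excess reporters cap both overhangs
#' before closure).
#'
#' @param x_grid reporter:probe ratios (> 0 allowed to include 0 for blanks).
#' @param config a [kinetics_config()] providing rates, probe concentration
#'   and horizon (its own ratio is ignored).
#' @param fast_closure if TRUE, override `k_close` to 1000 x `k_bind` x P0
#'   (molar), the fast-closure regime.
#' @param floor additive closed-fraction floor (default 0, i.e. the bare
#'   model).
#' @return data.frame `x`, `f_model`.
#' @export
dose_response <- function(x_grid, config = kinetics_config(ratio = 1),
                          fast_closure = FALSE, floor = 0) {
  stopifnot(all(x_grid >= 0), floor >= 0, floor < 1)
  cfg <- config
  if (fast_closure)
    cfg$k_close <- 1000 * cfg$k_bind * 1e-9 * cfg$probe_nm
  f <- vapply(x_grid, function(x) {
    if (x == 0) return(0)
    ci <- cfg; ci$reporter_nm <- x * cfg$probe_nm; ci$ratio <- x
    simulate_kinetics(ci, times = c(0, cfg$t_end_s))$f_eq
  }, numeric(1))
  data.frame(x = x_grid, f_model = floor + (1 - floor) * f)
}

#' Ratio at which a dose response peaks
#'
#' Returns the smallest grid ratio whose response is within `resolution` of
#' the maximum. Counting experiments cannot resolve closed-fraction
#' differences below ~1/sqrt(n) per run, so sub-resolution differences near
#' the stoichiometric plateau are treated as ties and the onset of the
#' plateau is reported.
#'
#' @param dr output of [dose_response()].
#' @param resolution absolute closed-fraction resolution (default 0.005).
#' @return the peak ratio.
#' @export
peak_ratio <- function(dr, resolution = 0.005) {
  mx <- max(dr$f_model)
  min(dr$x[dr$f_model >= mx - resolution])
}

#' Time to reach equilibrium
#'
#' First time after which the closed fraction stays within `tolerance`
#' (relative) of its value at `t_end_s`.
#'
#' @param config a [kinetics_config()].
#' @param tolerance relative tolerance (default 0.02).
#' @param n_times time-grid resolution.
#' @return time in seconds (0 when the closed fraction never moves).
#' @export
time_to_equilibrium <- function(config, tolerance = 0.02, n_times = 2001) {
  sim <- simulate_kinetics(config,
                           times = seq(0, config$t_end_s,
                                       length.out = n_times))
  tr <- sim$trajectory
  feq <- sim$f_eq
  if (feq == 0) return(0)
  resid <- abs(tr$f - feq) / feq
  # the trajectory must actually have flattened: require the closed fraction
  # to move by less than half the tolerance over the last 10% of the horizon
  tail10 <- tr$t_s >= 0.9 * config$t_end_s
  if (diff(range(tr$f[tail10])) > 0.5 * tolerance * feq) {
    n <- nrow(tr)
    slope <- (tr$f[n] - tr$f[n - 1]) / (tr$t_s[n] - tr$t_s[n - 1])
    stop("not equilibrated by t_end (residual slope ", signif(slope, 3),
         " 1/s); increase t_end_s")
  }
  bad <- which(resid > tolerance)
  if (length(bad) == 0) return(0)
  tr$t_s[max(bad) + 1L]
}

#' Assay amplification-chain configuration
#'
#' Captured targets each carry one nanoparticle bearing ~200 releasable
#' reporter strands; released reporters are concentrated by the volume
#' reduction before NanoLock readout.
#'
#' @param target_conc_pm target (analyte) concentration, pM.
#' @param capture_efficiency fraction of targets captured, in `[0, 1]`.
#' @param reporters_per_target reporter strands per captured target
#'   (default 200 = 1 AuNP x ~200 strands).
#' @param release_efficiency fraction of reporters released, in `[0, 1]`.
#' @param volume_concentration_factor volume reduction before readout
#'   (default 500/30).
#' @param probe_nm NanoLock probe concentration at readout (nM).
#' @return object of class `assay_config`.
#' @export
assay_config <- function(target_conc_pm, capture_efficiency = 1,
                         reporters_per_target = 200,
                         release_efficiency = 1,
                         volume_concentration_factor = 500 / 30,
                         probe_nm = 30) {
  stopifnot(target_conc_pm >= 0,
            capture_efficiency >= 0, capture_efficiency <= 1,
            release_efficiency >= 0, release_efficiency <= 1,
            reporters_per_target >= 0, volume_concentration_factor > 0,
            probe_nm > 0)
  structure(as.list(environment()), class = "assay_config")
}

#' End-to-end assay chain: target concentration to expected readout
#'
#' Chains the amplification arithmetic (released reporter concentration =
#' target x capture efficiency x reporters/target x release efficiency x
#' volume concentration factor), converts to an effective reporter:probe
#' ratio, evaluates the binding-model dose response at that ratio, and
#' emits the NanoLock mixture for trace synthesis - closing the in silico
#' loop from analyte to current trace.
#'
#' @param assay an [assay_config()].
#' @param kinetics a [kinetics_config()] for the readout incubation.
#' @param fast_closure,floor passed to [dose_response()].
#' @return list `reporter_nm`, `x` (effective ratio), `f` (expected closed
#'   fraction), `mix` (a [nanolock_mix()]).
#' @export
assay_chain <- function(assay, kinetics = kinetics_config(ratio = 1),
                        fast_closure = FALSE, floor = 0) {
  stopifnot(inherits(assay, "assay_config"))
  reporter_nm <- assay$target_conc_pm * 1e-3 * assay$capture_efficiency *
    assay$reporters_per_target * assay$release_efficiency *
    assay$volume_concentration_factor
  x <- reporter_nm / assay$probe_nm
  kin <- kinetics; kin$probe_nm <- assay$probe_nm
  f <- dose_response(x, kin, fast_closure = fast_closure,
                     floor = floor)$f_model
  list(reporter_nm = reporter_nm, x = x, f = f,
       mix = nanolock_mix(assay$probe_nm, min(1, f)))
}
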