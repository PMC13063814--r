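#' Acquisition settings for a nanopore recording
#'
#' Defaults mirror a high-bandwidth solid-state nanopore setup: 4.17 MHz
#' sampling with a 1 MHz analog bandwidth, software low-pass Bessel filtered
#' at 200 kHz for analysis, at 150 mV applied bias.
#'
#' @param sampling_hz sampling rate (Hz).
#' @param analog_bandwidth_hz analog (hardware) low-pass bandwidth (Hz).
#' @param digital_cutoff_hz software low-pass Bessel cutoff used for analysis
#'   (Hz); must not exceed the analog bandwidth.
#' @param filter_poles Bessel pole count for both stages.
#' @param voltage_mv applied voltage (mV).
#' @param duration_s recording duration (s).
#' @param seed integer RNG seed attached to traces generated under this
#'   configuration (optional).
#' @return object of class `acquisition_config`.
#' @export
acquisition_config <- function(sampling_hz = 4.17e6,
                               analog_bandwidth_hz = 1e6,
                               digital_cutoff_hz = 2e5,
                               filter_poles = 4L,
                               voltage_mv = 150,
                               duration_s = 1,
                               seed = NULL) {
  stopifnot(duration_s > 0, voltage_mv != 0, sampling_hz > 0)
  if (!(digital_cutoff_hz <= analog_bandwidth_hz &&
        analog_bandwidth_hz <= sampling_hz / 2))
    stop("require digital_cutoff_hz <= analog_bandwidth_hz <= sampling_hz/2")
  structure(list(sampling_hz = sampling_hz,
                 analog_bandwidth_hz = analog_bandwidth_hz,
                 digital_cutoff_hz = digital_cutoff_hz,
                 filter_poles = as.integer(filter_poles),
                 voltage_mv = voltage_mv,
                 duration_s = duration_s,
                 seed = seed),
            class = "acquisition_config")
}

#' Electrical model of a nanopore
#'
#' Conductance-blockade levels for one and two double-stranded DNA helices
#' in the pore (the 2x level is twice the 1x level by construction), open-pore
#' conductance, baseline noise and optional linear baseline drift.
#'
#' @param open_conductance_ns open-pore conductance (nS). The default (150 nS)
#'   corresponds to a ~10 nm pore in concentrated LiCl, giving a ~22.5 nA
#'   open-pore current at 150 mV.
#' @param blockade_1x_ns conductance blockade of a single dsDNA helix (nS).
#' @param noise_rms_pa RMS baseline current noise (pA) referred to the digital
#'   analysis bandwidth (i.e. after the 200 kHz filter).
#' @param drift_pa_per_s linear baseline drift (pA/s), default 0.
#' @return object of class `pore_model`; `blockade_2x_ns` is derived.
#' @export
pore_model <- function(open_conductance_ns = 150,
                       blockade_1x_ns = 5,
                       noise_rms_pa = 60,
                       drift_pa_per_s = 0) {
  stopifnot(blockade_1x_ns > 0, noise_rms_pa >= 0,
            open_conductance_ns > 2 * blockade_1x_ns)
  structure(list(open_conductance_ns = open_conductance_ns,
                 blockade_1x_ns = blockade_1x_ns,
                 blockade_2x_ns = 2 * blockade_1x_ns,
                 noise_rms_pa = noise_rms_pa,
                 drift_pa_per_s = drift_pa_per_s),
            class = "pore_model")
}
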