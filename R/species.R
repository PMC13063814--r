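#' Translocating species model
#'
#' Describes one molecular species in a nanopore experiment: its geometry
#' (how it can pass the pore), its single-file dwell-time distribution and
#' its capture rate per unit concentration.
#'
#' Geometries:
#' * `"single_file_only"` - e.g. the 400 bp dsDNA molecular ruler: always a
#'   single 1x-blockade level.
#' * `"foldable_linear"` - an open (linear) NanoLock: captured by an end with
#'   probability `end_capture_weight` (pure single file); otherwise captured
#'   at a uniform position along its contour, yielding a 2x-deep folded
#'   segment followed by a 1x single-file tail.
#' * `"circular"` - a closed NanoLock: both strands translocate together,
#'   one uniform 2x-blockade level lasting half the single-file dwell.
#'
#' @param name species label.
#' @param geometry one of `"single_file_only"`, `"foldable_linear"`,
#'   `"circular"`.
#' @param dwell_median_s median of the log-normal single-file dwell (s).
#' @param dwell_sigma log-normal shape parameter of the dwell.
#' @param capture_rate_per_nm_hz capture rate per nM of concentration (Hz/nM).
#'   The default gives ~0.5 Hz at a 30 nM probe concentration.
#' @param end_capture_weight probability of pure end capture for
#'   `foldable_linear` (ignored otherwise). The 0.8 default reflects the
#'   persistence-length argument (a 400 bp probe with ~150 bp persistence
#'   length is most often captured by an end) and places the mid-fold
#'   false-positive channel below the 1% bound, at the level seen in blank
#'   controls.
#' @return object of class `species_model`.
#' @export
species_model <- function(name,
                          geometry = c("single_file_only", "foldable_linear",
                                       "circular"),
                          dwell_median_s = 100e-6,
                          dwell_sigma = 0.4,
                          capture_rate_per_nm_hz = 0.5 / 30,
                          end_capture_weight = 0.8) {
  geometry <- match.arg(geometry)
  stopifnot(dwell_median_s > 0, dwell_sigma > 0, capture_rate_per_nm_hz >= 0,
            end_capture_weight >= 0, end_capture_weight <= 1)
  structure(list(name = name, geometry = geometry,
                 dwell_median_s = dwell_median_s, dwell_sigma = dwell_sigma,
                 capture_rate_per_nm_hz = capture_rate_per_nm_hz,
                 end_capture_weight = end_capture_weight),
            class = "species_model")
}

#' @rdname species_model
#' @param ... passed on to [species_model()].
#' @export
ruler_species <- function(...)
  species_model("ruler_400bp", "single_file_only", ...)

#' @rdname species_model
#' @export
open_nanolock <- function(...)
  species_model("nanolock_open", "foldable_linear", ...)

#' @rdname species_model
#' @export
closed_nanolock <- function(...)
  species_model("nanolock_closed", "circular", ...)

#' Species mixture at given concentrations
#'
#' @param species list of [species_model()] objects.
#' @param conc_nm numeric vector of concentrations (nM), one per species.
#' @return object of class `mix_spec`.
#' @export
mix_spec <- function(species, conc_nm) {
  if (inherits(species, "species_model")) species <- list(species)
  stopifnot(length(species) == length(conc_nm), all(conc_nm >= 0),
            all(vapply(species, inherits, logical(1), "species_model")))
  structure(list(species = species, conc_nm = as.numeric(conc_nm)),
            class = "mix_spec")
}

#' NanoLock mixture from a closed fraction
#'
#' Convenience constructor: a probe population at `probe_nm` total
#' concentration of which a fraction `closed_fraction` is circularized.
#'
#' @param probe_nm total NanoLock probe concentration (nM), default 30.
#' @param closed_fraction fraction of probes in the closed (circular) state,
#'   in `[0, 1]`.
#' @param open,closed optional species overrides.
#' @return a `mix_spec` with open and closed NanoLock components.
#' @export
nanolock_mix <- function(probe_nm = 30, closed_fraction = 0,
                         open = open_nanolock(), closed = closed_nanolock()) {
  stopifnot(probe_nm >= 0, closed_fraction >= 0, closed_fraction <= 1)
  mix_spec(list(open, closed),
           c(probe_nm * (1 - closed_fraction), probe_nm * closed_fraction))
}
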