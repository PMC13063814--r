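# nanolockr

Simulation and analysis of a **digital solid-state nanopore immunoassay**
built on circularizable DNA probes ("NanoLocks").

A NanoLock is a ~400 bp linear DNA probe with two single-stranded
overhangs; a bridging reporter strand hybridizes both ends and closes the
probe into a circle. In a nanopore, an open probe translocates single file
and blocks ~5 nS (one duplex, the 1x level), while a closed probe carries
two duplexes at once and blocks ~10 nS (2x) for half the time. Counting
2x events as "1" and 1x events as "0" gives a *digital* readout: the
closed fraction

    f = n1 / (n0 + n1)

reports the reporter (and hence target) concentration, with the open
probes serving as their own internal calibration standard - a ratio of
counts from one recording cancels pore-to-pore and run-to-run capture-rate
variability, unlike the *analog* readout (capture rate of "1" events).
Standard curves are 4PL fits `y = d + (a-d) / (1 + (x/c)^b)` with the
limit of detection at the blank mean + 2.5 blank SD; reporter excess caps
both probe ends before closure (the hook effect, maximal response at
reporter:probe ratio 1), which the assay resolves by split/dilution.

The package implements, with tests:

- **Trace synthesis** with known ground truth: Poisson capture, log-normal
  dwells, single-file / folded / circular event waveforms, white noise and
  the 4.17 MHz / 1 MHz / 200 kHz Bessel acquisition chain
  (`simulate_trace`, `simulate_event_windows`, `write_trace`).
- **Event detection**: robust drift-tracking baseline, threshold-crossing
  bounds, two-sided CUSUM sublevel segmentation (Rcpp), per-event features
  (max blockage conductance, dwell, event charge deficit)
  (`detect_events`, `segment_sublevels`, `estimate_baseline`).
- **Digital classification** against a 400 bp molecular-ruler calibration:
  three-type shape taxonomy (single-file / folded / circular), rejects,
  false-positive accounting (`calibrate_ruler`, `classify_events`,
  `false_positive_rate`).
- **Binding kinetics** of circularization (R+P -> H -> C, capping R+H -> X),
  deterministic and exact stochastic solvers, equilibrium dose response
  with hook, time-to-equilibrium, and the nanoparticle-amplified assay
  chain (`simulate_kinetics`, `dose_response`, `assay_chain`).
- **Quantification**: Wilson intervals, capture rates, 4PL standard
  curves, LoD, inverse prediction, split/dilution hook resolution, spike
  recovery, running-fraction convergence (`closed_fraction`, `fit_4pl`,
  `lod`, `split_dilution_resolve`, `running_fraction`).
- **Pipeline orchestration** over a run manifest plus trace/table format
  validation (`run_pipeline`, `validate_formats`).

## Worked example

Simulate a recording of a half-closed probe population, detect and
classify events, and estimate the closed fraction:

```r
library(nanolockr)

acq  <- acquisition_config(voltage_mv = 150)   # 4.17 MHz, 200 kHz filter
pore <- pore_model()                           # 5 / 10 nS levels, 60 pA noise

# ruler run calibrates the 1x level for this pore
ruler <- simulate_event_windows(acq, pore, ruler_species(), 300, seed = 1)
cal   <- calibrate_ruler(detect_events(ruler))

tr <- simulate_event_windows(acq, pore, nanolock_mix(30, 0.5), 500, seed = 2)
cl <- classify_events(detect_events(tr), cal)
table(cl$event_type)
closed_fraction(cl)
```

prints (seed-exact):

```
   circular      folded single_file
        258          41         201
$f       0.516        # 258 "1" among 500 counted events
$ci_low  0.4722415
$ci_high 0.5595146
```

258 of 500 counted events are circular ("1"), recovering the simulated
closed fraction 0.5 within the Wilson interval; folded events (2x level
with a resolvable 1x tail) are correctly counted as "0", and only
mid-fold shapes leak into the "1" class (<1% of open probes).

The numbered scripts under `analysis/` reproduce the full studies and
write their tables to `results/`: `01` trace synthesis + level recovery,
`02` ruler calibration + false-positive bound, `03` kinetics and the hook,
`04` digital-vs-analog LoD under capture-rate variability, `05` the
end-to-end amplified immunoassay with split/dilution spike recovery, e.g.

```sh
Rscript analysis/02_classification_validation.R
# ruler calibration: delta_g_1x = 4.996 nS (sigma 0.063, n = 400)
# open-only classification over 9996 events: FP rate 0.76% [0.60, 0.95]% ...
```

## Layout

```
R/                 package implementation (every analysis step lives here)
src/               CUSUM change-point core (Rcpp)
analysis/01..05    numbered study drivers writing results/
scripts/acceptance.R
tests/testthat/    unit, property and acceptance tests
vignettes/         methods vignette (model, parameters, design choices)
```
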