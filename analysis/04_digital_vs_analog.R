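#!/usr/bin/env Rscript
# Step 4 -- digital (closed fraction) vs analog (capture rate) readout.
#
# Builds paired standard curves from the same simulated runs (reporter
# 30 pM - 30 nM at 30 nM probe, triplicate blanks), with an independent
# log-normal capture-rate multiplier (CV 50%) per run emulating
# pore-to-pore variability. The digital response divides counts by counts
# and cancels the multiplier (self-calibration); the analog response does
# not. Limits of detection at blank + 2.5 SD quantify the difference.

library(nanolockr)
dir.create("results", showWarnings = FALSE)

set.seed(401)
runs <- simulate_standard_runs()
write.table(format(runs, digits = 6), "results/04_standard_runs.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cmp <- lod_comparison(runs)
dig <- cmp$digital; ana <- cmp$analog
curves <- data.frame(
  readout = c("digital", "analog"),
  a = c(dig$curve$a, ana$curve$a), b = c(dig$curve$b, ana$curve$b),
  c = c(dig$curve$c, ana$curve$c), d = c(dig$curve$d, ana$curve$d),
  blank_mean = c(dig$curve$blank_mean, ana$curve$blank_mean),
  blank_sd = c(dig$curve$blank_sd, ana$curve$blank_sd),
  lod_nm = c(dig$lod$lod, ana$lod$lod))
write.table(format(curves, digits = 5), "results/04_curves_lod.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("digital LoD: %.4g nM   analog LoD: %.4g nM\n",
            dig$lod$lod, ana$lod$lod))
cat(sprintf("analog/digital LoD ratio: %.1f -- the self-calibrating digital\n",
            cmp$lod_ratio))
cat("readout is an order of magnitude more sensitive under run-to-run\n")
cat("capture-rate variability, as counting fractions cancels the rate.\n")

# self-calibration demonstrated directly: same mixture, 3x capture rate
r1 <- simulate_run(0.3, duration_s = 40000, rate_multiplier = 1, seed = 402)
r3 <- simulate_run(0.3, duration_s = 40000, rate_multiplier = 3, seed = 403)
cat(sprintf("rate multiplier 1 -> rate %.3f Hz, f = %.4f\n",
            capture_rate(r1$n_events, r1$duration_s)$rate_hz,
            closed_fraction(r1$classified)$f))
cat(sprintf("rate multiplier 3 -> rate %.3f Hz, f = %.4f (unchanged)\n",
            capture_rate(r3$n_events, r3$duration_s)$rate_hz,
            closed_fraction(r3$classified)$f))
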