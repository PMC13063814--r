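#' Run manifest for a full pipeline execution
#'
#' @param df data.frame with columns `run_id` (unique), `role` (one of
#'   `ruler`, `blank`, `standard`, `sample`), `conc_nm` (reporter
#'   concentration; required for standards, ignored for ruler/blank),
#'   `dilution` (factor applied to sample quantification, default 1),
#'   `duration_s`, `seed`.
#' @return validated manifest (class `run_manifest`).
#' @export
run_manifest <- function(df) {
  need <- c("run_id", "role", "conc_nm", "duration_s", "seed")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("manifest missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(df) == 0) stop("empty manifest")
  if (anyDuplicated(df$run_id)) stop("run_ids not unique")
  if (!all(df$role %in% c("ruler", "blank", "standard", "sample")))
    stop("unknown role(s): ",
         paste(setdiff(df$role, c("ruler", "blank", "standard", "sample")),
               collapse = ", "))
  std <- df$role == "standard"
  if (any(std & (is.na(df$conc_nm) | df$conc_nm < 0)))
    stop("every standard needs a nonnegative concentration")
  if (!"dilution" %in% names(df)) df$dilution <- 1
  df$dilution[is.na(df$dilution)] <- 1
  structure(df, class = c("run_manifest", "data.frame"))
}

#' Execute the full in silico assay pipeline
#'
#' For every run in the manifest: simulate an event-window trace of the
#' appropriate species mixture (ruler: 400 bp dsDNA; blank/standard/sample:
#' NanoLock mixture at the closed fraction given by the binding-model dose
#' response), detect events, then calibrate the 1x level from the ruler
#' run, classify all runs, fit the digital standard curve from blanks +
#' standards, compute the LoD and quantify samples. Deterministic given the
#' manifest seeds.
#'
#' @param manifest a [run_manifest()].
#' @param acq,pore,det acquisition, pore and detection configurations.
#' @param kinetics a [kinetics_config()] for the dose response;
#'   `fast_closure` and `floor` as in [dose_response()].
#' @param events_per_run expected translocations simulated per run (the
#'   in silico stand-in for `duration_s` x capture rate; kept configurable
#'   so round-trip tests stay affordable).
#' @param sample_conc_nm named numeric vector giving each sample run's true
#'   reporter concentration (nM) used for simulation (its quantification is
#'   then compared against the curve); defaults to `conc_nm` in the
#'   manifest.
#' @param out_dir optional directory; per-run event tables and a report
#'   are written there as TSV/text.
#' @return `pipeline_report`: list with `runs` (per-run summary), `cal`,
#'   `curve`, `lod`, `samples`, `seeds`, `configs`.
#' @export
run_pipeline <- function(manifest, acq = acquisition_config(),
                         pore = pore_model(), det = detection_config(),
                         kinetics = kinetics_config(ratio = 1),
                         fast_closure = TRUE, floor = 0.008,
                         events_per_run = 200, sample_conc_nm = NULL,
                         out_dir = NULL) {
  manifest <- run_manifest(manifest)
  if (!any(manifest$role == "ruler"))
    stop("manifest has no ruler run: classification needs a calibration")
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  kin <- kinetics
  f_for_conc <- function(conc_nm) {
    if (is.na(conc_nm) || conc_nm <= 0) return(floor)
    min(1, dose_response(conc_nm / kin$probe_nm, kin,
                         fast_closure = fast_closure, floor = floor)$f_model)
  }
  detected <- list(); truths <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    species <- if (row$role == "ruler") ruler_species() else {
      conc <- if (row$role == "sample" && !is.null(sample_conc_nm))
        sample_conc_nm[[as.character(row$run_id)]] else row$conc_nm
      nanolock_mix(kin$probe_nm, f_for_conc(conc))
    }
    tr <- simulate_event_windows(acq, pore, species, events_per_run,
                                 seed = row$seed)
    dt <- tryCatch(detect_events(tr, det), error = function(e)
      stop("stage 'detect' failed for run ", row$run_id, ": ",
           conditionMessage(e)))
    detected[[as.character(row$run_id)]] <- dt
    truths[[as.character(row$run_id)]] <- tr$truth
    if (!is.null(out_dir))
      utils::write.table(as.data.frame(dt),
                         file.path(out_dir, paste0(row$run_id,
                                                   "_events.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  ruler_id <- as.character(manifest$run_id[manifest$role == "ruler"][1])
  cal <- calibrate_ruler(detected[[ruler_id]], source = ruler_id)
  runs <- list(); classified <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    id <- as.character(row$run_id)
    cl <- classify_events(detected[[id]], cal)
    classified[[id]] <- cl
    cf <- tryCatch(closed_fraction(cl), error = function(e) NULL)
    tally <- table(factor(cl$event_type,
                          c("circular", "single_file", "folded", "reject")))
    runs[[i]] <- data.frame(
      run_id = row$run_id, role = row$role, conc_nm = row$conc_nm,
      n_detected = nrow(cl),
      n_circular = tally[["circular"]], n_single_file = tally[["single_file"]],
      n_folded = tally[["folded"]], n_reject = tally[["reject"]],
      f = if (is.null(cf)) NA_real_ else cf$f,
      ci_low = if (is.null(cf)) NA_real_ else cf$ci_low,
      ci_high = if (is.null(cf)) NA_real_ else cf$ci_high,
      seed = row$seed)
    if (!is.null(out_dir))
      utils::write.table(as.data.frame(cl),
                         file.path(out_dir, paste0(id, "_classified.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  runs <- do.call(rbind, runs)
  cal_runs <- runs[runs$role %in% c("blank", "standard"), ]
  curve <- NULL; lod_est <- NULL
  if (sum(cal_runs$role == "standard") >= 4) {
    conc <- ifelse(cal_runs$role == "blank", 0, cal_runs$conc_nm)
    # with a single blank run, the blank SD falls back to its counting
    # (binomial) standard error
    blank_sd <- NULL
    if (sum(cal_runs$role == "blank") < 2) {
      bl <- runs[runs$role == "blank", ][1, ]
      nb <- bl$n_circular + bl$n_single_file + bl$n_folded
      blank_sd <- sqrt(bl$f * (1 - bl$f) / nb)
    }
    curve <- fit_4pl(conc, cal_runs$f, blank_sd = blank_sd)
    lod_est <- tryCatch(lod(curve), error = function(e) NULL)
  }
  samples <- NULL
  sm <- manifest[manifest$role == "sample", ]
  if (nrow(sm) > 0 && !is.null(curve)) {
    qs <- lapply(seq_len(nrow(sm)), function(j) {
      id <- as.character(sm$run_id[j])
      f <- runs$f[runs$run_id == sm$run_id[j]]
      q <- tryCatch(quantify_sample(f, curve, sm$dilution[j]),
                    error = function(e) list(conc = NA_real_,
                                             in_range = FALSE))
      data.frame(run_id = sm$run_id[j], f = f, conc_nm = q$conc,
                 in_range = q$in_range, dilution = sm$dilution[j])
    })
    samples <- do.call(rbind, qs)
  }
  report <- structure(list(
    runs = runs, cal = cal, curve = curve, lod = lod_est, samples = samples,
    seeds = stats::setNames(manifest$seed, manifest$run_id),
    configs = list(acq = unclass(acq), pore = unclass(pore),
                   det = unclass(det), kinetics = unclass(kin),
                   fast_closure = fast_closure, floor = floor,
                   events_per_run = events_per_run)),
    class = "pipeline_report")
  if (!is.null(out_dir)) {
    utils::write.table(runs, file.path(out_dir, "runs_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(format_report(report), file.path(out_dir, "report.txt"))
  }
  report
}

format_report <- function(report) {
  ln <- c("pipeline report",
          sprintf("ruler: delta_g_1x = %.4f nS (sigma %.4f, n = %d, %s)",
                  report$cal$delta_g_1x_ns, report$cal$sigma_ns,
                  report$cal$n_events, report$cal$source))
  if (!is.null(report$curve))
    ln <- c(ln, sprintf("4PL: a=%.5g b=%.5g c=%.5g d=%.5g (blank %.5g +- %.5g)",
                        report$curve$a, report$curve$b, report$curve$c,
                        report$curve$d, report$curve$blank_mean,
                        report$curve$blank_sd))
  if (!is.null(report$lod))
    ln <- c(ln, sprintf("LoD: %.5g nM%s", report$lod$lod,
                        if (report$lod$extrapolated) " (extrapolated)" else ""))
  if (!is.null(report$samples))
    ln <- c(ln, sprintf("sample %s: f=%.4f conc=%.5g nM (dilution %g)",
                        report$samples$run_id, report$samples$f,
                        report$samples$conc_nm, report$samples$dilution))
  ln <- c(ln, paste("seeds:", paste(names(report$seeds), report$seeds,
                                    sep = "=", collapse = " ")))
  ln
}

#' @export
print.pipeline_report <- function(x, ...) {
  writeLines(format_report(x))
  invisible(x)
}
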