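# Trace file format: <prefix>.raw holds little-endian float64 current samples
# in pA; <prefix>.meta is a textual key=value sidecar; <prefix>.truth.tsv is
# the ground-truth event table (absent for traces without ground truth).

#' Write / read a trace in the package's raw + sidecar format
#'
#' @param trace a `nanopore_trace`.
#' @param prefix path prefix; `<prefix>.raw`, `<prefix>.meta` and
#'   `<prefix>.truth.tsv` are written.
#' @return `write_trace` returns `prefix` invisibly; `read_trace` returns a
#'   `nanopore_trace` whose samples round-trip bit-exactly.
#' @export
write_trace <- function(trace, prefix) {
  stopifnot(inherits(trace, "nanopore_trace"))
  con <- file(paste0(prefix, ".raw"), "wb")
  on.exit(close(con))
  writeBin(trace$current_pa, con, size = 8, endian = "little")
  meta <- c(
    sampling_hz = trace$acq$sampling_hz,
    analog_bandwidth_hz = trace$acq$analog_bandwidth_hz,
    digital_cutoff_hz = trace$acq$digital_cutoff_hz,
    filter_poles = trace$acq$filter_poles,
    voltage_mv = trace$acq$voltage_mv,
    duration_s = trace$acq$duration_s,
    seed = if (is.null(trace$acq$seed)) NA else trace$acq$seed,
    open_conductance_ns = trace$pore$open_conductance_ns,
    blockade_1x_ns = trace$pore$blockade_1x_ns,
    noise_rms_pa = trace$pore$noise_rms_pa,
    drift_pa_per_s = trace$pore$drift_pa_per_s)
  writeLines(paste0(names(meta), "=", unname(meta)), paste0(prefix, ".meta"))
  if (!is.null(trace$truth) && nrow(trace$truth) > 0) {
    utils::write.table(
      trace$truth[, c("event", "species", "start_s", "p", "true_bit",
                      "dwell_s", "duration_s")],
      paste0(prefix, ".truth.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  invisible(prefix)
}

#' @rdname write_trace
#' @export
read_trace <- function(prefix) {
  meta <- read_sidecar(paste0(prefix, ".meta"))
  need <- c("sampling_hz", "analog_bandwidth_hz", "digital_cutoff_hz",
            "filter_poles", "voltage_mv", "duration_s", "open_conductance_ns",
            "blockade_1x_ns", "noise_rms_pa")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("sidecar missing field(s): ",
                         paste(miss, collapse = ", "))
  acq <- acquisition_config(
    sampling_hz = meta[["sampling_hz"]],
    analog_bandwidth_hz = meta[["analog_bandwidth_hz"]],
    digital_cutoff_hz = meta[["digital_cutoff_hz"]],
    filter_poles = meta[["filter_poles"]],
    voltage_mv = meta[["voltage_mv"]],
    duration_s = meta[["duration_s"]],
    seed = if (is.na(meta["seed"])) NULL else meta[["seed"]])
  pore <- pore_model(
    open_conductance_ns = meta[["open_conductance_ns"]],
    blockade_1x_ns = meta[["blockade_1x_ns"]],
    noise_rms_pa = meta[["noise_rms_pa"]],
    drift_pa_per_s = if (is.na(meta["drift_pa_per_s"])) 0
                     else meta[["drift_pa_per_s"]])
  n <- round(acq$duration_s * acq$sampling_hz)
  con <- file(paste0(prefix, ".raw"), "rb")
  on.exit(close(con))
  cur <- readBin(con, "double", n = n, size = 8, endian = "little")
  tf <- paste0(prefix, ".truth.tsv")
  truth <- if (file.exists(tf))
    utils::read.table(tf, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE) else NULL
  structure(list(current_pa = cur, acq = acq, pore = pore, truth = truth),
            class = "nanopore_trace")
}

read_sidecar <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln))]
  kv <- strsplit(ln, "=", fixed = TRUE)
  val <- suppressWarnings(as.numeric(vapply(kv, `[`, "", 2L)))
  names(val) <- vapply(kv, `[`, "", 1L)
  val
}

#' Validate a pipeline file against its format contract
#'
#' Checks trace sidecars for completeness, raw traces for non-finite samples,
#' and events / truth / classified TSV tables for their column contracts.
#' The file kind is inferred from the extension (`.meta`, `.raw`,
#' `.truth.tsv`, `.tsv`).
#'
#' @param path file path (for `.raw`, the matching `.meta` sidecar must sit
#'   alongside).
#' @return character vector of violations; empty when the file is well formed.
#' @export
validate_formats <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  bad <- character(0)
  if (grepl("\\.meta$", path)) {
    meta <- tryCatch(read_sidecar(path), error = function(e) NULL)
    if (is.null(meta)) return(paste0("unreadable sidecar: ", path))
    need <- c("sampling_hz", "analog_bandwidth_hz", "digital_cutoff_hz",
              "voltage_mv", "duration_s", "blockade_1x_ns")
    for (k in setdiff(need, names(meta)))
      bad <- c(bad, paste0("sidecar missing field: ", k))
    for (k in intersect(need, names(meta)))
      if (is.na(meta[[k]])) bad <- c(bad, paste0("sidecar field not numeric: ", k))
  } else if (grepl("\\.raw$", path)) {
    sz <- file.info(path)$size
    if (sz %% 8 != 0) bad <- c(bad, "raw size not a multiple of 8 bytes")
    con <- file(path, "rb"); on.exit(close(con))
    x <- readBin(con, "double", n = sz / 8, size = 8, endian = "little")
    if (anyNA(x) || any(!is.finite(x)))
      bad <- c(bad, paste0("non-finite sample at index ",
                           which(!is.finite(x))[1]))
  } else if (grepl("\\.truth\\.tsv$", path)) {
    tb <- utils::read.table(path, header = TRUE, sep = "\t", nrows = 5)
    for (k in setdiff(c("event", "species", "start_s", "true_bit"),
                      names(tb)))
      bad <- c(bad, paste0("truth table missing column: ", k))
  } else if (grepl("\\.tsv$", path)) {
    tb <- utils::read.table(path, header = TRUE, sep = "\t", nrows = 5)
    core <- c("event_id", "start_s", "dwell_s", "max_blockage_ns", "ecd_pc")
    for (k in setdiff(core, names(tb)))
      bad <- c(bad, paste0("events table missing column: ", k))
  } else {
    bad <- "unrecognized file kind (expect .meta/.raw/.truth.tsv/.tsv)"
  }
  bad
}
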