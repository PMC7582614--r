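#' Read a waveform record from delimited text
#'
#' Accepts one-column (PPG amplitude), two-column (`time_s`, `ppg`) or
#' three-column (`time_s`, `ppg`, `abp`) files, comma- or
#' whitespace-delimited, with or without a header line. The sampling rate
#' is inferred from the time column when present, otherwise taken from
#' `fs` (default 125 Hz).
#'
#' @param path File path.
#' @param fs Sampling rate in Hz for single-column files.
#' @param record_id Identifier; defaults to the file name.
#' @return A `waveform_record`.
#' @export
read_waveform <- function(path, fs = 125, record_id = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  header <- grepl("[A-Za-z]", first)
  cf <- utils::count.fields(path, sep = sep)
  if (length(unique(cf[!is.na(cf)])) > 1) {
    bad <- which(cf != cf[1])[1]
    stop("malformed (ragged) row at line ", bad, " of ", path)
  }
  d <- utils::read.table(path, sep = sep, header = header)
  if (ncol(d) > 3) stop("expected 1-3 columns, got ", ncol(d))
  if (!all(vapply(d, is.numeric, TRUE)))
    stop("non-numeric data in ", path)
  if (ncol(d) == 1) {
    ppg <- d[[1]]; abp <- numeric(0)
  } else {
    dt <- diff(d[[1]])
    if (any(dt <= 0)) stop("time column must be strictly increasing")
    fs <- 1 / stats::median(dt)
    ppg <- d[[2]]
    abp <- if (ncol(d) == 3) d[[3]] else numeric(0)
  }
  structure(list(ppg = ppg,
                 abp = if (length(abp)) abp else rep(0, length(ppg)),
                 clean = NULL, sampling_rate_hz = fs,
                 record_id = record_id,
                 ground_truth = NULL, config = NULL),
            class = "waveform_record")
}

#' Write a waveform record as delimited text
#'
#' Emits `time_s, ppg[, abp]` as CSV, plus the ground-truth table (when
#' present) next to it as `<path>.ground_truth.csv`.
#'
#' @param record A `waveform_record`.
#' @param path Output CSV path.
#' @param ground_truth Also write the ground-truth table if available.
#' @return `path`, invisibly.
#' @export
write_waveform <- function(record, path, ground_truth = TRUE) {
  stopifnot(inherits(record, "waveform_record"))
  n <- length(record$ppg)
  d <- data.frame(time_s = (seq_len(n) - 1) / record$sampling_rate_hz,
                  ppg = record$ppg)
  if (!is.null(record$abp) && !all(record$abp == 0)) d$abp <- record$abp
  utils::write.csv(d, path, row.names = FALSE)
  if (ground_truth && !is.null(record$ground_truth))
    utils::write.csv(record$ground_truth,
                     paste0(path, ".ground_truth.csv"), row.names = FALSE)
  invisible(path)
}

#' Write per-cycle fiducials and labels as CSV
#'
#' @param segments List of `cycle_segment` objects.
#' @param path Output CSV path.
#' @param record_id Identifier column value.
#' @return The data frame written, invisibly.
#' @export
write_cycle_table <- function(segments, path, record_id = "record") {
  rows <- lapply(seq_along(segments), function(i) {
    s <- segments[[i]]; f <- s$fiducials
    data.frame(record_id = record_id, cycle_index = i,
               start_idx = s$start_idx,
               onset_idx = f$onset_idx, max_slope_idx = f$max_slope_idx,
               systolic_peak_idx = f$systolic_peak_idx,
               min_slope_idx = f$min_slope_idx,
               dicrotic_notch_idx = f$dicrotic_notch_idx,
               offset_idx = f$offset_idx,
               sbp_mmHg = s$sbp_mmHg, dbp_mmHg = s$dbp_mmHg)
  })
  d <- do.call(rbind, rows)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(d)
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys fall back to
#' [pipeline_config()] defaults. Nested sections mirror the stages:
#' `synthetic`, `preprocess`, `criteria`, `gamma`, `selection`,
#' `regressor`.
#'
#' @param path YAML file path.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}
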