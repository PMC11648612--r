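#' Read event timestamps from a text file
#'
#' One timestamp per line, in seconds (decimal text). Blank lines and lines
#' starting with `#` are ignored. The result is sorted ascending; duplicates
#' are allowed.
#'
#' @param path file path.
#' @return Sorted numeric vector (possibly empty).
#' @export
read_timestamps <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  vals <- suppressWarnings(as.numeric(trimws(lines[keep])))
  bad <- which(is.na(vals))
  if (length(bad))
    stopf("%s: cannot parse line %d: '%s'", path, keep[bad[1]],
          lines[keep[bad[1]]])
  sort(vals)
}

#' Write a table atomically as tab-separated text
#'
#' Writes to a temporary file in the destination directory and renames it
#' into place, so readers never observe a half-written file.
#'
#' @param records data.frame to write.
#' @param path destination path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(records, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  utils::write.table(records, tmp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!file.rename(tmp, path)) {
    unlink(tmp)
    stopf("could not move temporary file into place at %s", path)
  }
  invisible(path)
}

#' Read a tab-separated table written by [write_table()]
#' @param path file path.
#' @return data.frame.
#' @export
read_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read per-ROI fluorescence traces from tidy tabular text
#'
#' Expects comma- or tab-separated columns `time_s`, `roi_id`,
#' `fluorescence` (long format, one row per ROI per frame). All ROIs must
#' share the same frame times.
#'
#' @param path data file path.
#' @param stim_times stimulus onsets (seconds), e.g. from
#'   [read_timestamps()] on a sidecar file.
#' @param condition condition tag.
#' @return A [roi_trace_set()].
#' @export
read_roi_traces <- function(path, stim_times = numeric(),
                            condition = "control") {
  tab <- utils::read.csv(path, sep = "", stringsAsFactors = FALSE)
  if (ncol(tab) == 1L)  # comma-separated fallback
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "roi_id", "fluorescence")
  if (!all(need %in% names(tab)))
    stopf("%s: need columns %s", path, paste(need, collapse = ", "))
  times <- sort(unique(tab$time_s))
  rois <- unique(tab$roi_id)
  raw <- matrix(NA_real_, length(rois), length(times),
                dimnames = list(rois, NULL))
  ri <- match(tab$roi_id, rois)
  ci <- match(tab$time_s, times)
  raw[cbind(ri, ci)] <- tab$fluorescence
  if (anyNA(raw))
    stopf("%s: ROIs do not share a common frame-time grid", path)
  roi_trace_set(times, raw, stim_times, labels = rois,
                condition = condition)
}

#' Write a roi_trace_set as tidy tabular text
#' @param traces a [roi_trace_set()].
#' @param path destination path (long-format TSV with columns `time_s`,
#'   `roi_id`, `fluorescence`).
#' @return Invisibly, `path`.
#' @export
write_roi_traces <- function(traces, path) {
  stopifnot(inherits(traces, "roi_trace_set"))
  long <- data.frame(
    time_s = rep(traces$times, each = nrow(traces$raw)),
    roi_id = rep(traces$labels, times = ncol(traces$raw)),
    fluorescence = as.vector(traces$raw))
  write_table(long, path)
}

#' Write event timestamps, one per line
#' @param times numeric vector of seconds.
#' @param path destination path.
#' @return Invisibly, `path`.
#' @export
write_timestamps <- function(times, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  writeLines(format(times, digits = 15, trim = TRUE, scientific = FALSE),
             tmp)
  if (!file.rename(tmp, path)) {
    unlink(tmp)
    stopf("could not move temporary file into place at %s", path)
  }
  invisible(path)
}

#' Read a pulse-sequence description from a key-value text file
#'
#' Flat `key = value` lines with keys `carrier_hz`, `prf_hz`, `duty`,
#' `duration_s` and optionally `ispta_w_cm2`, `area_cm2`. `#` comments and
#' blank lines are ignored.
#'
#' @param path config file path.
#' @return A [pulse_sequence()].
#' @export
read_pulse_config <- function(path) {
  kv <- read_keyvals(path)
  need <- c("carrier_hz", "prf_hz", "duty", "duration_s")
  miss <- setdiff(need, names(kv))
  if (length(miss))
    stopf("%s: missing keys: %s", path, paste(miss, collapse = ", "))
  pulse_sequence(kv[["carrier_hz"]], kv[["prf_hz"]], kv[["duty"]],
                 kv[["duration_s"]],
                 ispta_w_cm2 = if ("ispta_w_cm2" %in% names(kv))
                   kv[["ispta_w_cm2"]] else NA_real_,
                 area_cm2 = if ("area_cm2" %in% names(kv))
                   kv[["area_cm2"]] else NA_real_)
}

read_keyvals <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  out <- list()
  for (i in keep) {
    parts <- strsplit(lines[i], "=", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stopf("%s: cannot parse line %d: '%s'", path, i, lines[i])
    key <- trimws(parts[1])
    val <- suppressWarnings(as.numeric(trimws(parts[2])))
    out[[key]] <- if (is.na(val)) trimws(parts[2]) else val
  }
  out
}

#' Read a session manifest
#'
#' Tab- or whitespace-separated table with columns `session_id`,
#' `data_file`, `stim_file`, `intensity`, `condition`, `kind`
#' (`calcium` or `spikes`). Paths are resolved relative to the manifest's
#' directory. Session ids must be unique and referenced files must exist.
#'
#' @param path manifest file path.
#' @return data.frame with resolved absolute paths.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  man <- utils::read.csv(path, sep = "", stringsAsFactors = FALSE)
  need <- c("session_id", "data_file", "stim_file", "intensity",
            "condition", "kind")
  miss <- setdiff(need, names(man))
  if (length(miss))
    stopf("%s: manifest missing columns: %s", path,
          paste(miss, collapse = ", "))
  if (nrow(man) == 0L) stopf("%s: empty manifest", path)
  if (anyDuplicated(man$session_id))
    stopf("%s: duplicate session_id values", path)
  if (!all(man$kind %in% c("calcium", "spikes")))
    stopf("%s: kind must be 'calcium' or 'spikes'", path)
  base <- dirname(normalizePath(path))
  for (col in c("data_file", "stim_file")) {
    rel <- !grepl("^/", man[[col]])
    man[[col]][rel] <- file.path(base, man[[col]][rel])
    missing <- !file.exists(man[[col]])
    if (any(missing))
      stopf("%s: referenced file not found: %s", path,
            man[[col]][missing][1])
  }
  man
}
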