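#' Per-ROI fluorescence time series for one imaging session
#'
#' Container for raw fluorescence traces (one row per ROI, one column per
#' frame), frame times, stimulus onsets, and a condition tag. Frames are
#' nominally sampled at 1 Hz; times must be strictly increasing and raw
#' fluorescence strictly positive.
#'
#' @param times frame times in seconds, strictly increasing.
#' @param raw numeric matrix of fluorescence values, `n_rois x n_frames`.
#'   A vector is treated as a single ROI.
#' @param stim_times stimulus onset times in seconds.
#' @param labels per-ROI identifiers; defaults to `roi_1 ... roi_n`.
#' @param condition free-text condition tag (e.g. "control", "BI-749327").
#' @return An object of class `roi_trace_set`.
#' @export
roi_trace_set <- function(times, raw, stim_times = numeric(),
                          labels = NULL, condition = "control") {
  if (is.vector(raw)) raw <- matrix(raw, nrow = 1L)
  raw <- as.matrix(raw)
  if (!is.numeric(times) || length(times) < 2L || any(diff(times) <= 0))
    stopf("times must be a strictly increasing numeric vector")
  if (ncol(raw) != length(times))
    stopf("raw has %d columns but there are %d frame times",
          ncol(raw), length(times))
  if (nrow(raw) < 1L) stopf("need at least one ROI")
  if (any(!is.finite(raw)) || any(raw <= 0))
    stopf("raw fluorescence values must be finite and strictly positive")
  if (is.null(labels)) labels <- paste0("roi_", seq_len(nrow(raw)))
  if (length(labels) != nrow(raw))
    stopf("labels length (%d) != number of ROIs (%d)",
          length(labels), nrow(raw))
  rownames(raw) <- labels
  structure(list(times = as.numeric(times), raw = raw,
                 stim_times = sort(as.numeric(stim_times)),
                 labels = as.character(labels),
                 condition = condition),
            class = "roi_trace_set")
}

#' @export
print.roi_trace_set <- function(x, ...) {
  cat(sprintf("roi_trace_set: %d ROIs x %d frames (%.0f-%.0f s), %d stimuli, condition '%s'\n",
              nrow(x$raw), ncol(x$raw), min(x$times), max(x$times),
              length(x$stim_times), x$condition))
  invisible(x)
}

#' Pre-stimulus baseline fluorescence F0
#'
#' Per-ROI arithmetic mean of the raw fluorescence over the half-open
#' pre-stimulus window `[stim_time - baseline_s, stim_time)`. The window is
#' half-open so each frame belongs to exactly one of the baseline and
#' response windows.
#'
#' @param traces a [roi_trace_set()].
#' @param stim_time stimulus onset in seconds.
#' @param baseline_s baseline window length in seconds (default 30).
#' @return Named numeric vector of per-ROI F0 values.
#' @export
compute_f0 <- function(traces, stim_time, baseline_s = 30) {
  stopifnot(inherits(traces, "roi_trace_set"))
  if (stim_time - baseline_s < traces$times[1] - 1e-9)
    stopf("insufficient baseline: the %g s window before the stimulus at %g s starts before the recording",
          baseline_s, stim_time)
  sel <- traces$times >= stim_time - baseline_s & traces$times < stim_time
  if (!any(sel))
    stopf("no frames in the %g s baseline window before stimulus at %g s",
          baseline_s, stim_time)
  rowMeans(traces$raw[, sel, drop = FALSE])
}

#' Baseline-normalized fluorescence (dF/F0)
#'
#' Computes `(F(t) - F0) / F0` per ROI, with F0 the pre-stimulus baseline
#' mean from [compute_f0()]. F0 is recomputed for each stimulus, so repeated
#' stimuli within one recording are each normalized to their own
#' pre-stimulus baseline.
#'
#' @inheritParams compute_f0
#' @return An object of class `normalized_traces` with elements `times`,
#'   `dff` (same shape as `raw`), `f0`, `stim_time`, `stim_times`,
#'   `condition`.
#' @export
normalize_dff <- function(traces, stim_time, baseline_s = 30) {
  f0 <- compute_f0(traces, stim_time, baseline_s)
  if (any(f0 <= 0)) stopf("degenerate baseline: F0 <= 0 for some ROI")
  dff <- sweep(sweep(traces$raw, 1, f0, "-"), 1, f0, "/")
  structure(list(times = traces$times, dff = dff, f0 = f0,
                 stim_time = stim_time, stim_times = traces$stim_times,
                 condition = traces$condition),
            class = "normalized_traces")
}

#' Post-stimulus response area under the curve
#'
#' Sums the dF/F0 samples in the half-open post-stimulus window
#' `[stim_time, stim_time + response_s)` per ROI. The response statistic is
#' a plain sum of samples (units AU at the nominal 1 Hz frame rate);
#' trapezoidal integration is available but off by default.
#'
#' @param norm a `normalized_traces` object from [normalize_dff()].
#' @param stim_time stimulus onset in seconds (defaults to the stimulus the
#'   traces were normalized to).
#' @param response_s response window length in seconds (default 10).
#' @param trapezoid if `TRUE`, integrate by the trapezoidal rule over the
#'   window instead of summing samples.
#' @return Named numeric vector of per-ROI AUC values (AU).
#' @export
response_auc <- function(norm, stim_time = norm$stim_time, response_s = 10,
                         trapezoid = FALSE) {
  stopifnot(inherits(norm, "normalized_traces"))
  sel <- norm$times >= stim_time & norm$times < stim_time + response_s
  # require full coverage of the window at the nominal rate implied by
  # median frame spacing
  dt <- stats::median(diff(norm$times))
  if (sum(sel) < floor(response_s / dt) ||
      max(norm$times) < stim_time + response_s - dt)
    stopf("response window [%g, %g) s is truncated by the recording",
          stim_time, stim_time + response_s)
  if (trapezoid) {
    tt <- norm$times[sel]
    apply(norm$dff[, sel, drop = FALSE], 1,
          function(y) sum(diff(tt) * (head(y, -1) + tail(y, -1)) / 2))
  } else {
    rowSums(norm$dff[, sel, drop = FALSE])
  }
}

#' Peak dF/F0 in the response window
#'
#' @inheritParams response_auc
#' @return Named numeric vector of per-ROI peak dF/F0.
#' @export
response_peak <- function(norm, stim_time = norm$stim_time, response_s = 10) {
  stopifnot(inherits(norm, "normalized_traces"))
  sel <- norm$times >= stim_time & norm$times < stim_time + response_s
  if (!any(sel)) stopf("no frames in the response window")
  apply(norm$dff[, sel, drop = FALSE], 1, max)
}

#' Per-stimulus response table
#'
#' Runs [normalize_dff()] and [response_auc()] for every stimulus in the
#' session, re-baselining before each stimulus, and returns one row per
#' (ROI, stimulus) pair.
#'
#' @param traces a [roi_trace_set()].
#' @param baseline_s baseline window length (s).
#' @param response_s response window length (s).
#' @param trapezoid passed to [response_auc()].
#' @return data.frame with columns `roi`, `stimulus` (index),
#'   `stim_time`, `auc`, `peak_dff`, `condition`.
#' @export
response_table <- function(traces, baseline_s = 30, response_s = 10,
                           trapezoid = FALSE) {
  stopifnot(inherits(traces, "roi_trace_set"))
  if (length(traces$stim_times) == 0L)
    stopf("trace set has no stimulus times")
  if (length(traces$stim_times) > 1L &&
      any(diff(traces$stim_times) < response_s))
    stopf("stimuli closer than the %g s response window: overlapping ",
          response_s)
  out <- lapply(seq_along(traces$stim_times), function(k) {
    st <- traces$stim_times[k]
    norm <- normalize_dff(traces, st, baseline_s)
    data.frame(roi = traces$labels, stimulus = k, stim_time = st,
               auc = as.numeric(response_auc(norm, st, response_s,
                                             trapezoid)),
               peak_dff = as.numeric(response_peak(norm, st, response_s)),
               condition = traces$condition, row.names = NULL)
  })
  do.call(rbind, out)
}

#' ROI-by-frame dF/F0 matrix for heatmap display
#'
#' @param norm a `normalized_traces` object.
#' @param sort `"none"` keeps input order; `"by_peak"` orders ROIs by
#'   decreasing peak dF/F0.
#' @return list with `matrix` (values untouched) and `order` (row indices
#'   into the input).
#' @export
heatmap_matrix <- function(norm, sort = c("none", "by_peak")) {
  stopifnot(inherits(norm, "normalized_traces"))
  sort <- match.arg(sort)
  ord <- seq_len(nrow(norm$dff))
  if (sort == "by_peak")
    ord <- order(apply(norm$dff, 1, max), decreasing = TRUE)
  list(matrix = norm$dff[ord, , drop = FALSE], order = ord)
}

#' Condition-level summary of session AUCs
#'
#' The experimental unit is the session: per-(ROI, stimulus) AUCs are first
#' averaged within each session, then summarized as mean +/- SEM over
#' sessions per condition (matching n = number of independent experiments).
#'
#' @param tables data.frame with columns `session`, `condition`, `auc`
#'   (e.g. stacked [response_table()] outputs with a `session` column
#'   added), or a list of such data.frames.
#' @return data.frame with columns `condition`, `n_sessions`, `mean_auc`,
#'   `sem_auc` (`sem_auc` is `NA` for a single session).
#' @export
session_summary <- function(tables) {
  if (is.data.frame(tables)) tab <- tables
  else tab <- do.call(rbind, tables)
  need <- c("session", "condition", "auc")
  if (!all(need %in% names(tab)))
    stopf("need columns %s", paste(need, collapse = ", "))
  if (nrow(tab) == 0L) stopf("no data to summarize")
  per_sess <- stats::aggregate(auc ~ session + condition, data = tab,
                               FUN = mean)
  out <- do.call(rbind, lapply(split(per_sess, per_sess$condition),
                               function(d) {
    data.frame(condition = d$condition[1], n_sessions = nrow(d),
               mean_auc = mean(d$auc), sem_auc = sem(d$auc))
  }))
  rownames(out) <- NULL
  out
}
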