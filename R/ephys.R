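#' In vivo recording session
#'
#' Multiunit spike timestamps, stimulus onsets, and metadata for one
#' recording session. Raw voltage, when present, is carried alongside with
#' its sampling rate so spikes can be (re-)extracted with
#' [highpass_filter()] and [detect_multiunit()].
#'
#' @param spike_times multiunit spike timestamps in seconds (sorted on
#'   construction).
#' @param stim_times stimulus onset times in seconds.
#' @param intensity stimulus intensity label in mW/cm^2 (>= 0).
#' @param condition condition tag, e.g. "control" or "BI-749327".
#' @param duration_s recording length in seconds, used to drop stimuli whose
#'   analysis window is truncated; defaults to just past the last event.
#' @param raw_voltage optional raw voltage trace (numeric vector).
#' @param sample_rate_hz sampling rate of `raw_voltage` in Hz (nominal
#'   20 kHz).
#' @param session_id free-text identifier.
#' @return An object of class `session_recording`.
#' @export
session_recording <- function(spike_times, stim_times, intensity = 0,
                              condition = "control", duration_s = NULL,
                              raw_voltage = NULL, sample_rate_hz = 20000,
                              session_id = "session") {
  spike_times <- sort(as.numeric(spike_times))
  stim_times <- sort(as.numeric(stim_times))
  if (length(stim_times) < 1L) stopf("need at least one stimulus time")
  if (!is_number(intensity) || intensity < 0)
    stopf("intensity must be >= 0")
  if (is.null(duration_s))
    duration_s <- max(c(spike_times, stim_times)) + 1e-9
  structure(list(spike_times = spike_times, stim_times = stim_times,
                 intensity = intensity, condition = condition,
                 duration_s = duration_s, raw_voltage = raw_voltage,
                 sample_rate_hz = sample_rate_hz, session_id = session_id),
            class = "session_recording")
}

#' @export
print.session_recording <- function(x, ...) {
  cat(sprintf(
    "session_recording '%s': %d spikes, %d stimuli, %.0f mW/cm2, '%s', %.1f s\n",
    x$session_id, length(x$spike_times), length(x$stim_times), x$intensity,
    x$condition, x$duration_s))
  invisible(x)
}

#' Zero-phase high-pass filter for extracellular voltage
#'
#' 4th-order Butterworth high-pass applied forward and backward
#' (zero phase), the standard pre-processing to isolate multiunit spikes
#' from LFP and DC drift.
#'
#' @param v numeric voltage trace.
#' @param sample_rate_hz sampling rate in Hz.
#' @param cutoff_hz high-pass cutoff in Hz (default 300).
#' @param order filter order (default 4; the forward-backward pass doubles
#'   the effective magnitude order).
#' @return Filtered trace, same length as `v`.
#' @export
highpass_filter <- function(v, sample_rate_hz, cutoff_hz = 300, order = 4) {
  if (!is_number(cutoff_hz) || cutoff_hz <= 0)
    stopf("cutoff_hz must be positive")
  if (cutoff_hz >= sample_rate_hz / 2)
    stopf("cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
          cutoff_hz, sample_rate_hz / 2)
  bf <- signal::butter(order, cutoff_hz / (sample_rate_hz / 2),
                       type = "high")
  as.numeric(signal::filtfilt(bf, v))
}

#' Threshold-crossing multiunit detection
#'
#' Detects negative threshold crossings at `-threshold_k * sigma`, with the
#' noise level estimated robustly as `sigma = median(|v|) / 0.6745` (the
#' median absolute deviation of a zero-mean Gaussian). Each crossing is
#' timestamped at the trough (most negative sample) within the dead-time
#' window; subsequent crossings within `dead_time_s` of a detected trough
#' are suppressed.
#'
#' @param v high-pass filtered voltage trace.
#' @param sample_rate_hz sampling rate in Hz.
#' @param threshold_k detection threshold in robust-sigma units (default 4).
#' @param dead_time_s refractory window in seconds (default 1 ms).
#' @return Numeric vector of spike times in seconds.
#' @export
detect_multiunit <- function(v, sample_rate_hz, threshold_k = 4,
                             dead_time_s = 0.001) {
  sigma <- stats::median(abs(v)) / 0.6745
  if (sigma == 0) stopf("flat trace: robust noise estimate is zero")
  thr <- -threshold_k * sigma
  below <- v < thr
  # onset samples of downward crossings
  onsets <- which(below & !c(FALSE, below[-length(below)]))
  if (length(onsets) == 0L) return(numeric())
  dead_n <- max(1L, round(dead_time_s * sample_rate_hz))
  n <- length(v)
  times <- numeric(length(onsets))
  k <- 0L
  last_idx <- -Inf
  for (i in onsets) {
    if (i - last_idx <= dead_n) next
    win <- i:min(n, i + dead_n)
    trough <- win[which.min(v[win])]
    k <- k + 1L
    times[k] <- (trough - 1) / sample_rate_hz
    last_idx <- trough
  }
  times[seq_len(k)]
}

# Core binned counting shared by build_psth and the surrogate machinery.
# Offsets are spike - stimulus; half-open bins [left, right), so an offset
# exactly on an edge is counted in the bin to its right. Stimulus windows
# are assumed non-overlapping (enforced by build_psth); spikes need not be
# sorted.
psth_counts <- function(spike_times, stim_times, bin_width, pre, post) {
  nbins <- as.integer(round((pre + post) / bin_width))
  counts <- integer(nbins)
  if (length(spike_times) == 0L) return(counts)
  # nearest stimulus at or before each spike, and the one after
  idx <- findInterval(spike_times, stim_times)
  off <- rep(NA_real_, length(spike_times))
  has_prev <- idx >= 1L
  off[has_prev] <- spike_times[has_prev] - stim_times[idx[has_prev]]
  # spikes past their preceding stimulus's window may precede the next one
  nxt <- rep(NA_real_, length(spike_times))
  has_next <- idx < length(stim_times)
  nxt[has_next] <- spike_times[has_next] - stim_times[idx[has_next] + 1L]
  use_next <- has_next & (is.na(off) | off >= post) & !is.na(nxt) &
    nxt >= -pre
  off[use_next] <- nxt[use_next]
  keep <- !is.na(off) & off >= -pre & off < post
  if (!any(keep)) return(counts)
  b <- floor((off[keep] + pre) / bin_width) + 1
  b[b > nbins] <- nbins  # guard against floating-point edge spill
  counts + tabulate(as.integer(b), nbins)
}

#' Peristimulus time histogram
#'
#' Bins spike-minus-stimulus offsets into half-open bins of `bin_width`
#' seconds over a `(-pre, +post)` window around each stimulus onset, summed
#' over stimuli. Offsets exactly on a bin edge fall into the bin to the
#' right. Stimuli whose window is truncated by the recording edges are
#' dropped with a warning rather than zero-padded.
#'
#' @param rec a [session_recording()].
#' @param bin_width bin width in seconds (default 0.1).
#' @param pre,post window extent before/after stimulus onset in seconds
#'   (default 3 and 3; `(pre + post) / bin_width` must be integral).
#' @return An object of class `psth`: list with `counts` (integer per bin),
#'   `bin_left` (left edges in seconds relative to onset), `bin_width`,
#'   `pre`, `post`, `n_stimuli`.
#' @export
build_psth <- function(rec, bin_width = 0.1, pre = 3, post = 3) {
  stopifnot(inherits(rec, "session_recording"))
  nb <- (pre + post) / bin_width
  if (abs(nb - round(nb)) > 1e-9)
    stopf("(pre + post) / bin_width = %g is not integral", nb)
  stims <- rec$stim_times
  ok <- stims - pre >= 0 & stims + post <= rec$duration_s
  if (any(!ok)) {
    warning(sprintf("dropping %d stimulus/stimuli with truncated windows",
                    sum(!ok)), call. = FALSE)
    stims <- stims[ok]
  }
  if (length(stims) == 0L) stopf("no stimulus with a complete window")
  if (length(stims) > 1L && any(diff(stims) < pre + post))
    stopf("stimulus windows overlap: minimum gap %.3f s < window %g s",
          min(diff(stims)), pre + post)
  counts <- psth_counts(rec$spike_times, stims, bin_width, pre, post)
  structure(list(counts = counts,
                 bin_left = seq(-pre, post - bin_width, by = bin_width),
                 bin_width = bin_width, pre = pre, post = post,
                 n_stimuli = length(stims)),
            class = "psth")
}

#' @export
print.psth <- function(x, ...) {
  cat(sprintf(
    "psth: %d bins of %g s over (-%g, +%g) s, %d stimuli, %d spikes in window\n",
    length(x$counts), x$bin_width, x$pre, x$post, x$n_stimuli,
    sum(x$counts)))
  invisible(x)
}
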