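#' Parameters for the synthetic calcium-imaging generator
#'
#' Describes a population of ROIs imaged at a nominal 1 Hz whose
#' fluorescence is a noisy baseline carrying stimulus-evoked transients
#' (in responders) and spontaneous network events shared across ROIs.
#' The transient kernel is a double exponential
#' `exp(-t/decay_tau) - exp(-t/rise_tau)` normalized to unit peak, so the
#' amplitude parameter is directly the peak dF/F0 of the evoked transient
#' (GCaMP6s-like defaults: rise 1 s, decay 4 s).
#'
#' @param n_rois number of ROIs (default 50, within the 30-60 per-coverslip
#'   range typical of widefield imaging).
#' @param frame_rate_hz imaging rate (default 1).
#' @param duration_s recording length in seconds.
#' @param stim_times stimulus onsets in seconds.
#' @param baseline_f mean baseline fluorescence (arbitrary counts).
#' @param baseline_spread per-ROI lognormal sd (log scale) of the baseline.
#' @param noise_sd frame noise sd as a fraction of each ROI's baseline
#'   (default 0.05).
#' @param evoked_amplitude mean evoked peak dF/F0 across responders
#'   (default 1).
#' @param amplitude_spread lognormal sd (log scale) of per-ROI amplitudes.
#' @param rise_tau_s,decay_tau_s kernel time constants in seconds.
#' @param responder_fraction fraction of ROIs that respond to the stimulus.
#' @param spont_event_rate_hz rate of spontaneous network-wide events
#'   (default 0.01 Hz, i.e. about one per 100 s).
#' @param spont_amplitude peak dF/F0 of spontaneous events.
#' @param spont_participation probability an ROI takes part in a given
#'   spontaneous event.
#' @param condition_scale multiplicative factor on the evoked amplitude
#'   (drug effect; 1 = control, 0 = full blockade).
#' @param seed integer RNG seed.
#' @return list of class `calcium_sim_params`.
#' @export
calcium_sim_params <- function(n_rois = 50, frame_rate_hz = 1,
                               duration_s = 120, stim_times = 60,
                               baseline_f = 1000, baseline_spread = 0.2,
                               noise_sd = 0.05, evoked_amplitude = 1,
                               amplitude_spread = 0.3,
                               rise_tau_s = 1, decay_tau_s = 4,
                               responder_fraction = 0.8,
                               spont_event_rate_hz = 0.01,
                               spont_amplitude = 0.5,
                               spont_participation = 0.5,
                               condition_scale = 1, seed = 1L) {
  if (rise_tau_s <= 0 || decay_tau_s <= 0 || rise_tau_s >= decay_tau_s)
    stopf("need 0 < rise_tau_s < decay_tau_s")
  if (responder_fraction < 0 || responder_fraction > 1)
    stopf("responder_fraction must lie in [0, 1]")
  if (frame_rate_hz <= 0) stopf("frame_rate_hz must be positive")
  if (noise_sd < 0 || condition_scale < 0)
    stopf("noise_sd and condition_scale must be >= 0")
  structure(as.list(environment()), class = "calcium_sim_params")
}

# Unit-peak double-exponential transient evaluated at times t >= 0.
calcium_kernel <- function(t, rise_tau, decay_tau) {
  tpk <- rise_tau * decay_tau / (decay_tau - rise_tau) *
    log(decay_tau / rise_tau)
  peak <- exp(-tpk / decay_tau) - exp(-tpk / rise_tau)
  ifelse(t < 0, 0, (exp(-t / decay_tau) - exp(-t / rise_tau)) / peak)
}

#' Simulate a calcium-imaging session
#'
#' Generates `F(t) = B_i * (1 + evoked_i(t) + spont_i(t)) * (1 + eps)` per
#' ROI: a lognormal per-ROI baseline, unit-peak double-exponential evoked
#' transients at every stimulus in responders (per-ROI lognormal
#' amplitudes scaled by `condition_scale`), spontaneous network events
#' shared across participating ROIs, and multiplicative Gaussian frame
#' noise. Ground truth (per-ROI amplitude, responder flag, baseline) is
#' returned alongside the traces.
#'
#' @param params a [calcium_sim_params()].
#' @return list with `traces` (a [roi_trace_set()]) and `truth`
#'   (data.frame: `roi`, `responder`, `amplitude`, `baseline`).
#' @export
simulate_calcium <- function(params) {
  stopifnot(inherits(params, "calcium_sim_params"))
  p <- params
  with_seed(p$seed, {
    times <- seq(0, p$duration_s - 1 / p$frame_rate_hz,
                 by = 1 / p$frame_rate_hz)
    nf <- length(times)
    base <- p$baseline_f *
      stats::rlnorm(p$n_rois, -p$baseline_spread^2 / 2, p$baseline_spread)
    responder <- stats::runif(p$n_rois) < p$responder_fraction
    amp <- p$evoked_amplitude *
      stats::rlnorm(p$n_rois, -p$amplitude_spread^2 / 2,
                    p$amplitude_spread) * p$condition_scale
    amp[!responder] <- 0
    sig <- matrix(0, p$n_rois, nf)
    for (st in p$stim_times) {
      k <- calcium_kernel(times - st, p$rise_tau_s, p$decay_tau_s)
      sig <- sig + outer(amp, k)
    }
    n_spont <- stats::rpois(1, p$spont_event_rate_hz * p$duration_s)
    if (n_spont > 0) {
      ev_t <- stats::runif(n_spont, 0, p$duration_s)
      for (et in ev_t) {
        k <- calcium_kernel(times - et, p$rise_tau_s, p$decay_tau_s)
        take <- stats::runif(p$n_rois) < p$spont_participation
        sig <- sig + outer(ifelse(take, p$spont_amplitude, 0), k)
      }
    }
    raw <- base * (1 + sig) *
      (1 + matrix(stats::rnorm(p$n_rois * nf, 0, p$noise_sd), p$n_rois, nf))
    raw[raw <= 0] <- .Machine$double.eps  # fluorescence counts stay positive
    labels <- sprintf("roi_%02d", seq_len(p$n_rois))
    list(
      traces = roi_trace_set(times, raw, p$stim_times, labels),
      truth = data.frame(roi = labels, responder = responder,
                         amplitude = amp, baseline = base)
    )
  })
}

#' Parameters for the synthetic multiunit spike-train generator
#'
#' One in vivo session: 20 ultrasound stimuli at random interstimulus
#' intervals of 10-20 s, multiunit spiking as an inhomogeneous Poisson
#' process whose rate is the baseline multiplied by `evoked_gain` inside a
#' `(latency, latency + duration)` window after each stimulus.
#'
#' @param baseline_rate_hz baseline multiunit rate (default 20).
#' @param n_stimuli number of stimuli per session (default 20).
#' @param isi_range_s interstimulus-interval range in seconds
#'   (default `c(10, 20)`).
#' @param evoked_gain rate multiplier during the evoked window (1 = no
#'   modulation).
#' @param evoked_latency_s latency from stimulus onset to rate elevation.
#' @param evoked_duration_s evoked-window length in seconds (default 0.5).
#' @param condition_gain_scale factor applied to `evoked_gain - 1` (drug
#'   effect; 1 = control, 0 removes the modulation).
#' @param pre_pad_s,post_pad_s recording time before the first and after
#'   the last stimulus (must cover the PSTH window).
#' @param intensity,condition,session_id session metadata.
#' @param seed integer RNG seed.
#' @return list of class `ephys_sim_params`.
#' @export
ephys_sim_params <- function(baseline_rate_hz = 20, n_stimuli = 20,
                             isi_range_s = c(10, 20), evoked_gain = 1,
                             evoked_latency_s = 0, evoked_duration_s = 0.5,
                             condition_gain_scale = 1,
                             pre_pad_s = 5, post_pad_s = 5,
                             intensity = 0, condition = "control",
                             session_id = "sim", seed = 1L) {
  if (baseline_rate_hz < 0 || evoked_gain < 0 || condition_gain_scale < 0)
    stopf("rates and gains must be >= 0")
  if (length(isi_range_s) != 2L || any(isi_range_s <= 0) ||
      isi_range_s[1] > isi_range_s[2])
    stopf("isi_range_s must be an ordered positive pair")
  if (n_stimuli < 1) stopf("need at least one stimulus")
  structure(as.list(environment()), class = "ephys_sim_params")
}

#' Simulate a multiunit recording session
#'
#' Stimulus times are drawn with i.i.d. uniform ISIs; spikes come from an
#' inhomogeneous Poisson process generated by thinning a homogeneous
#' process at the peak rate. The effective gain is
#' `1 + (evoked_gain - 1) * condition_gain_scale`.
#'
#' @param params an [ephys_sim_params()].
#' @return list with `recording` (a [session_recording()]) and `truth`
#'   (list: `rate_fun`, effective `gain`, `evoked_window`).
#' @export
simulate_spikes <- function(params) {
  stopifnot(inherits(params, "ephys_sim_params"))
  p <- params
  gain <- 1 + (p$evoked_gain - 1) * p$condition_gain_scale
  with_seed(p$seed, {
    isis <- stats::runif(p$n_stimuli - 1, p$isi_range_s[1], p$isi_range_s[2])
    stims <- p$pre_pad_s + cumsum(c(0, isis))
    dur <- max(stims) + p$post_pad_s
    w0 <- p$evoked_latency_s
    w1 <- p$evoked_latency_s + p$evoked_duration_s
    rate_fun <- function(t) {
      idx <- findInterval(t, stims)
      off <- t - stims[pmax(idx, 1L)]
      inwin <- idx >= 1L & off > w0 & off <= w1
      p$baseline_rate_hz * ifelse(inwin, gain, 1)
    }
    rmax <- p$baseline_rate_hz * max(gain, 1)
    spikes <- numeric()
    if (rmax > 0) {
      n_cand <- stats::rpois(1, rmax * dur)
      cand <- sort(stats::runif(n_cand, 0, dur))
      keep <- stats::runif(n_cand) < rate_fun(cand) / rmax
      spikes <- cand[keep]
    }
    list(
      recording = session_recording(spikes, stims, intensity = p$intensity,
                                    condition = p$condition,
                                    duration_s = dur,
                                    session_id = p$session_id),
      truth = list(rate_fun = rate_fun, gain = gain,
                   evoked_window = c(w0, w1))
    )
  })
}

#' Synthesize an extracellular voltage trace from spike times
#'
#' Gaussian noise plus a stereotyped biphasic waveform (one cycle of a
#' sine, 1 ms long, trough-leading) centered at each spike time. The spike
#' amplitude is expressed in units of the noise sd.
#'
#' @param spike_times spike times in seconds.
#' @param duration_s trace length in seconds.
#' @param sample_rate_hz sampling rate (>= 10 kHz; default 20 kHz).
#' @param noise_sd noise standard deviation (trace units; 0 for a
#'   noiseless test trace).
#' @param spike_amplitude_sd trough amplitude in noise-sd units (default
#'   10); when `noise_sd` is 0 the amplitude is in absolute trace units.
#' @param spike_width_s waveform duration in seconds (default 1 ms).
#' @param seed integer RNG seed.
#' @return list with `voltage` (numeric vector) and `sample_rate_hz`.
#' @export
simulate_voltage <- function(spike_times, duration_s,
                             sample_rate_hz = 20000, noise_sd = 1,
                             spike_amplitude_sd = 10,
                             spike_width_s = 0.001, seed = 1L) {
  if (sample_rate_hz < 10000)
    stopf("sample_rate_hz must be >= 10 kHz")
  n <- round(duration_s * sample_rate_hz)
  amp <- spike_amplitude_sd * if (noise_sd > 0) noise_sd else 1
  wf_n <- max(4L, round(spike_width_s * sample_rate_hz))
  # trough-leading biphasic: -sin over one cycle, unit trough depth
  wf <- -amp * sin(2 * pi * seq(0, 1, length.out = wf_n))
  with_seed(seed, {
    v <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else numeric(n)
    for (st in spike_times) {
      i0 <- round(st * sample_rate_hz) + 1L
      idx <- i0:(i0 + wf_n - 1L)
      ok <- idx >= 1L & idx <= n
      v[idx[ok]] <- v[idx[ok]] + wf[ok]
    }
    list(voltage = v, sample_rate_hz = sample_rate_hz)
  })
}
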