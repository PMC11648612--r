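# Shared fixture builders; everything is generated in code.

# The in vitro stimulation train used throughout the examples.
vitro_seq <- function() {
  pulse_sequence(carrier_hz = 1e6, prf_hz = 100, duty = 0.5,
                 duration_s = 0.5, ispta_w_cm2 = 0.19, area_cm2 = 0.28)
}

# A small trace set with a constant-fluorescence ROI and one with a ramp.
flat_traces <- function(value = 100, n_frames = 80, stim = 50) {
  roi_trace_set(times = 0:(n_frames - 1),
                raw = matrix(value, nrow = 2, ncol = n_frames),
                stim_times = stim)
}

# Null (unmodulated) multiunit session; distinct seeds per replicate.
null_session <- function(seed, rate = 20) {
  simulate_spikes(ephys_sim_params(baseline_rate_hz = rate,
                                   evoked_gain = 1, seed = seed))$recording
}

evoked_session <- function(seed, gain = 3, rate = 20) {
  simulate_spikes(ephys_sim_params(baseline_rate_hz = rate,
                                   evoked_gain = gain,
                                   evoked_duration_s = 0.5,
                                   seed = seed))$recording
}
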