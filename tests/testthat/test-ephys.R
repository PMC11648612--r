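test_that("high-pass filter removes DC and keeps passband tones", {
  fs <- 20000
  t <- seq(0, 0.5, by = 1 / fs)
  # constant input -> ~0 after the edge transients
  out <- highpass_filter(rep(5, length(t)), fs)
  mid <- out[2000:(length(out) - 2000)]
  expect_lt(max(abs(mid)), 1e-6 * 5)
  # 1 kHz tone well above the 300 Hz cutoff is preserved
  tone <- sin(2 * pi * 1000 * t)
  out2 <- highpass_filter(tone, fs)
  expect_equal(stats::sd(out2[2000:(length(out2) - 2000)]),
               stats::sd(tone[2000:(length(tone) - 2000)]),
               tolerance = 0.01)
  expect_error(highpass_filter(tone, fs, cutoff_hz = 11000), "Nyquist")
})

test_that("filtered white-noise variance matches an ideal band-mask oracle", {
  fs <- 20000
  set.seed(8)
  v <- rnorm(fs * 2)
  out <- highpass_filter(v, fs, 300)
  # oracle: brick-wall FFT mask at the same cutoff
  n <- length(v)
  freqs <- (seq_len(n) - 1) * fs / n
  mask <- freqs >= 300 & freqs <= fs - 300
  oracle <- Re(stats::fft(stats::fft(v) * mask, inverse = TRUE)) / n
  expect_lt(stats::var(out), stats::var(v))
  expect_equal(stats::var(out), stats::var(oracle), tolerance = 0.05)
})

test_that("threshold detector finds injected spikes at their troughs", {
  fs <- 20000
  truth <- c(0.25, 0.61, 1.10)
  sim <- simulate_voltage(truth, duration_s = 1.5, sample_rate_hz = fs,
                          noise_sd = 1, spike_amplitude_sd = 10, seed = 2)
  det <- detect_multiunit(sim$voltage, fs, threshold_k = 6)
  expect_length(det, 3)
  # trough of the biphasic waveform sits a quarter-width after onset
  expect_equal(det, truth + 0.00025, tolerance = 2 / fs)
  expect_error(detect_multiunit(rep(0, 1000), fs), "flat trace")
})

test_that("dead time suppresses re-triggering", {
  fs <- 20000
  set.seed(9)
  v <- rnorm(2000)
  v[500] <- -30
  v[510] <- -30   # 0.5 ms later
  expect_length(detect_multiunit(v, fs, dead_time_s = 0.001), 1)
  expect_length(detect_multiunit(v, fs, dead_time_s = 0.0002), 2)
})

test_that("false-crossing rate on pure noise matches the Gaussian tail oracle", {
  fs <- 20000
  set.seed(10)
  v <- rnorm(fs * 100)
  det <- detect_multiunit(v, fs, threshold_k = 4)
  p_cross <- pnorm(-4) * (1 - pnorm(-4))
  expected <- (length(v) - 1) * p_cross
  expect_gt(length(det), expected / 2)
  expect_lt(length(det), expected * 2)
})

test_that("PSTH conserves spike counts and respects the bin-edge convention", {
  rec <- session_recording(spike_times = c(10, 10.05, 12.95), stim_times = 10,
                           duration_s = 20)
  p <- build_psth(rec)
  # a spike exactly at stimulus onset lands in bin [0, 0.1)
  expect_equal(p$counts[which(p$bin_left == 0)], 2L)
  expect_equal(sum(p$counts), 3L)
  # no spikes -> all-zero counts
  p0 <- build_psth(session_recording(numeric(), 10, duration_s = 20))
  expect_true(all(p0$counts == 0))
  # conservation against a direct window count on a simulated session
  rec2 <- null_session(31)
  p2 <- build_psth(rec2)
  direct <- sum(vapply(rec2$stim_times, function(st)
    sum(rec2$spike_times >= st - 3 & rec2$spike_times < st + 3), 0))
  expect_identical(sum(p2$counts), as.integer(direct))
})

test_that("PSTH is translation-equivariant", {
  rec <- null_session(17)
  p <- build_psth(rec)
  shift <- 123.456
  rec_s <- session_recording(rec$spike_times + shift,
                             rec$stim_times + shift,
                             duration_s = rec$duration_s + shift)
  expect_identical(build_psth(rec_s)$counts, p$counts)
})

test_that("stimuli with truncated windows are dropped with a warning", {
  rec <- session_recording(c(1, 5, 9), stim_times = c(2, 8),
                           duration_s = 15)
  expect_warning(p <- build_psth(rec), "truncated")
  expect_equal(p$n_stimuli, 1L)  # only the stimulus at 8 s has a full window
  expect_equal(sum(p$counts), 2L)  # spikes at 5 and 9 fall in [5, 11)
  # all stimuli truncated is an error
  rec2 <- session_recording(c(1), stim_times = 2, duration_s = 4)
  expect_error(suppressWarnings(build_psth(rec2)), "no stimulus")
})

test_that("mean PSTH count per bin matches the Poisson oracle", {
  rate <- 20; n_stim <- 20; bw <- 0.1
  counts <- unlist(lapply(1:5, function(i)
    build_psth(null_session(400 + i, rate = rate))$counts))
  expected <- n_stim * rate * bw
  se <- sqrt(expected / length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("detector hit and false-alarm rates on synthetic voltage", {
  fs <- 20000
  set.seed(12)
  # multiunit-like density: ~20 Hz over 10 s
  truth <- sort(runif(200, 0.1, 9.9))
  truth <- truth[c(TRUE, diff(truth) > 0.003)]  # avoid overlapping waveforms
  sim <- simulate_voltage(truth, duration_s = 10, sample_rate_hz = fs,
                          noise_sd = 1, spike_amplitude_sd = 10, seed = 13)
  filt <- highpass_filter(sim$voltage, fs)
  det <- detect_multiunit(filt, fs, threshold_k = 4)
  tol <- 0.001
  hits <- vapply(truth, function(tt) any(abs(det - tt - 0.00025) < tol),
                 logical(1))
  false_alarms <- vapply(det, function(dd)
    all(abs(truth + 0.00025 - dd) >= tol), logical(1))
  expect_gte(mean(hits), 0.95)
  expect_lte(mean(false_alarms), 0.05)
})
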