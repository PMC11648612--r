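test_that("jitter surrogate preserves counts, is deterministic, and is the identity at h = 0", {
  spikes <- sort(runif(200, 0, 100))
  cfg0 <- jitter_config(jitter_halfwidth_s = 0, rng_seed = 5)
  expect_identical(jitter_surrogate(spikes, cfg0, 1), spikes)
  cfg <- jitter_config(rng_seed = 5)
  j1 <- jitter_surrogate(spikes, cfg, 7)
  expect_length(j1, length(spikes))
  expect_false(is.unsorted(j1))
  # counter-based seeding: same (seed, index) reproduces the surrogate
  # regardless of what was generated in between
  junk <- jitter_surrogate(spikes, cfg, 3)
  expect_identical(jitter_surrogate(spikes, cfg, 7), j1)
  expect_false(identical(junk, j1))
})

test_that("jitter displacements match uniform-distribution moments", {
  spikes <- rep(1000, 2000)
  cfg <- jitter_config(jitter_halfwidth_s = 3, rng_seed = 77)
  disp <- unlist(lapply(1:10, function(i)
    jitter_surrogate(spikes, cfg, i) - 1000))
  n <- length(disp)
  h <- 3
  expect_lt(abs(mean(disp)), 3 * h / sqrt(3 * n))        # mean -> 0
  expect_equal(stats::var(disp), h^2 / 3, tolerance = 0.05) # var -> h^2/3
  expect_true(all(abs(disp) <= h))
})

test_that("bands have the required structure on a null session", {
  rec <- null_session(101)
  cfg <- jitter_config(n_surrogates = 500, rng_seed = 9)
  b <- compute_bands(rec, cfg)
  expect_true(all(b$pointwise_low <= b$surrogate_mean + 1e-9))
  expect_true(all(b$surrogate_mean <= b$pointwise_high + 1e-9))
  # global band envelops nearly all per-bin pointwise limits
  expect_gte(mean(b$pointwise_high <= b$global_high), 0.95)
  expect_gte(mean(b$pointwise_low >= b$global_low), 0.95)
  # surrogate mean matches the Poisson oracle: n_stim * rate * bin_width
  expected <- 20 * 20 * 0.1
  se <- sqrt(expected / length(b$surrogate_mean))
  expect_lt(abs(mean(b$surrogate_mean) - expected), 3 * se)
})

test_that("empty spike train gives all-zero bands and a negative call", {
  rec <- session_recording(numeric(), seq(10, 200, by = 15),
                           duration_s = 210)
  cfg <- jitter_config(n_surrogates = 200, rng_seed = 4)
  b <- compute_bands(rec, cfg)
  expect_true(all(b$surrogate_mean == 0))
  expect_equal(b$global_high, 0)
  call <- call_significance(build_psth(rec), b)
  expect_false(call$significant)
})

test_that("bands and calls are bit-identical under the same seed", {
  rec <- null_session(55)
  cfg <- jitter_config(n_surrogates = 300, rng_seed = 123)
  b1 <- compute_bands(rec, cfg)
  b2 <- compute_bands(rec, cfg)
  expect_identical(b1, b2)
  b3 <- compute_bands(rec, jitter_config(n_surrogates = 300, rng_seed = 124))
  expect_false(identical(b1$pointwise_high, b3$pointwise_high) &&
                 identical(b1$global_high, b3$global_high) &&
                 identical(b1$surrogate_mean, b3$surrogate_mean))
})

test_that("significance calls respect the post-stimulus decision window", {
  rec <- null_session(61)
  cfg <- jitter_config(n_surrogates = 500, rng_seed = 3)
  b <- compute_bands(rec, cfg)
  obs <- build_psth(rec)
  # force every count strictly inside the global band -> not significant
  obs$counts <- rep(as.integer(ceiling((b$global_low + b$global_high) / 2)),
                    length(obs$counts))
  expect_false(call_significance(obs, b)$significant)
  # one post-stimulus bin above the upper global band -> activated
  k <- which(abs(b$bin_left - 0.2) < 1e-9)
  obs2 <- obs
  obs2$counts[k] <- as.integer(b$global_high + 5)
  call <- call_significance(obs2, b)
  expect_true(call$significant)
  expect_equal(call$direction, "activated")
  expect_equal(call$first_crossing_bin, k)
  # the same excursion at -0.5 s (pre-stimulus) does not count
  obs3 <- obs
  obs3$counts[which(abs(b$bin_left + 0.5) < 1e-9)] <- as.integer(b$global_high + 5)
  expect_false(call_significance(obs3, b)$significant)
  # a bin below the lower global band -> suppressed
  obs4 <- obs
  obs4$counts[k] <- as.integer(max(0, b$global_low - 5))
  expect_equal(call_significance(obs4, b)$direction, "suppressed")
  # activation takes precedence when both excursions occur
  obs5 <- obs4
  obs5$counts[k + 1L] <- as.integer(b$global_high + 5)
  expect_equal(call_significance(obs5, b)$direction, "activated")
  # geometry mismatch is a contract error
  obs6 <- build_psth(rec, pre = 2, post = 2)
  expect_error(call_significance(obs6, b), "geometry")
})

test_that("activated fraction groups by intensity and condition", {
  calls <- data.frame(
    intensity = rep(c(0, 730), each = 12),
    condition = "control",
    direction = c(rep("none", 12),
                  rep("activated", 3), rep("none", 9)))
  out <- activated_fraction(calls)
  expect_equal(out$fraction_activated[out$intensity == 0], 0)
  expect_equal(out$fraction_activated[out$intensity == 730], 0.25)
  all_on <- data.frame(intensity = 70, condition = "drug",
                       direction = rep("activated", 10))
  expect_equal(activated_fraction(all_on)$fraction_activated, 1)
  expect_error(activated_fraction(calls[0, ]), "no sessions")
})

test_that("chi-square statistic matches hand computation and stats::chisq.test", {
  balanced <- matrix(10, 2, 2)
  res <- chi2_2x2(balanced)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  diag <- matrix(c(20, 0, 0, 20), 2)
  expect_equal(chi2_2x2(diag)$statistic, 40)
  # homogeneity: doubling every cell doubles the statistic
  set.seed(15)
  for (i in 1:10) {
    tab <- matrix(rpois(4, 15) + 1, 2)
    expect_equal(chi2_2x2(2 * tab)$statistic, 2 * chi2_2x2(tab)$statistic)
    # independent cross-check against the standard implementation
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(chi2_2x2(tab)$statistic, unname(ref$statistic))
    expect_equal(chi2_2x2(tab)$p_value, ref$p.value)
    ref_y <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
    expect_equal(chi2_2x2(tab, yates = TRUE)$statistic,
                 unname(ref_y$statistic))
  }
  expect_error(chi2_2x2(matrix(c(0, 0, 5, 5), 2)), "marginal")
})

test_that("activated fraction is non-decreasing in the evoked gain", {
  gains <- c(1, 1.5, 3)
  frac <- vapply(seq_along(gains), function(g) {
    mean(vapply(1:50, function(i) {
      sim <- simulate_spikes(ephys_sim_params(
        evoked_gain = gains[g], seed = 7000 + 100 * g + i))
      cfg <- jitter_config(n_surrogates = 250,
                           rng_seed = 8000 + 100 * g + i)
      call_significance(build_psth(sim$recording),
                        compute_bands(sim$recording, cfg))$direction ==
        "activated"
    }, logical(1)))
  }, numeric(1))
  expect_true(all(diff(frac) >= 0))
  expect_lt(frac[1], 0.15)
  expect_gt(frac[3], 0.9)
})
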