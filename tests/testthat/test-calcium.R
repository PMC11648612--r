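test_that("baseline F0 is the mean over the half-open prestimulus window", {
  tr <- flat_traces(100)
  expect_equal(unname(compute_f0(tr, 50)), c(100, 100))
  # frames {90, 110} in a 2 s window -> 100
  raw <- matrix(c(rep(100, 8), 90, 110, rep(100, 10)), nrow = 1)
  tr2 <- roi_trace_set(0:19, raw, stim_times = 10)
  expect_equal(unname(compute_f0(tr2, 10, baseline_s = 2)), 100)
  # window extending before the recording is refused
  expect_error(compute_f0(tr, 5, baseline_s = 30), "insufficient baseline")
})

test_that("dF/F0 normalization is exact elementwise arithmetic", {
  tr <- flat_traces(100)
  norm <- normalize_dff(tr, 50)
  expect_true(all(norm$dff == 0))
  raw <- matrix(c(rep(100, 40), 150, 50, rep(100, 38)), nrow = 1)
  tr2 <- roi_trace_set(0:79, raw, stim_times = 40)
  norm2 <- normalize_dff(tr2, 40)
  expect_equal(unname(norm2$dff[1, 41]), 0.5)
  expect_equal(unname(norm2$dff[1, 42]), -0.5)
})

test_that("normalization round-trips: f0 * (1 + dff) reproduces raw", {
  set.seed(3)
  raw <- matrix(runif(5 * 90, 50, 200), nrow = 5)
  tr <- roi_trace_set(0:89, raw, stim_times = 45)
  norm <- normalize_dff(tr, 45)
  expect_equal(norm$f0 * (1 + norm$dff), raw,
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("response AUC sums dF/F0 over the post-stimulus window and is linear", {
  # dff identically 1 over the 10 response frames -> AUC 10
  raw <- matrix(c(rep(100, 40), rep(200, 10), rep(100, 30)), nrow = 1)
  tr <- roi_trace_set(0:79, raw, stim_times = 40)
  norm <- normalize_dff(tr, 40)
  expect_equal(unname(response_auc(norm, 40)), 10)
  # all-zero dff -> 0
  expect_equal(unname(response_auc(normalize_dff(flat_traces(), 50), 50)),
               c(0, 0))
  # scaling dff by k scales AUC by k (scale the deviation from baseline)
  for (k in c(0.5, 2, 3)) {
    raw_k <- 100 + (raw - 100) * k
    norm_k <- normalize_dff(roi_trace_set(0:79, raw_k, 40), 40)
    expect_equal(unname(response_auc(norm_k, 40)), 10 * k)
  }
  # truncated response window is refused
  tr_short <- roi_trace_set(0:44, matrix(100, 1, 45), stim_times = 40)
  expect_error(response_auc(normalize_dff(tr_short, 40), 40), "truncated")
})

test_that("AUC is invariant to the overall fluorescence scale", {
  set.seed(4)
  sim <- simulate_calcium(calcium_sim_params(n_rois = 8, seed = 21))
  tr <- sim$traces
  norm <- normalize_dff(tr, tr$stim_times[1])
  auc <- response_auc(norm, tr$stim_times[1])
  for (k in c(0.1, 7)) {
    tr_k <- roi_trace_set(tr$times, tr$raw * k, tr$stim_times)
    norm_k <- normalize_dff(tr_k, tr$stim_times[1])
    expect_equal(response_auc(norm_k, tr$stim_times[1]), auc,
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("heatmap matrix preserves values and orders rows by peak on request", {
  raw <- matrix(c(rep(100, 40), 110, rep(100, 39),
                  rep(100, 40), 190, rep(100, 39)),
                nrow = 2, byrow = TRUE)
  tr <- roi_trace_set(0:79, raw, stim_times = 40)
  norm <- normalize_dff(tr, 40)
  hm <- heatmap_matrix(norm, "none")
  expect_equal(hm$order, 1:2)
  expect_identical(hm$matrix, norm$dff)
  hm2 <- heatmap_matrix(norm, "by_peak")
  expect_equal(hm2$order, c(2L, 1L))
  # single ROI stays a single-row matrix
  one <- normalize_dff(roi_trace_set(0:79, raw[1, , drop = FALSE], 40), 40)
  expect_equal(nrow(heatmap_matrix(one)$matrix), 1L)
})

test_that("session summary averages within sessions, then across them", {
  tab <- data.frame(
    session = rep(c("s1", "s2", "s3"), each = 2),
    condition = rep(c("control", "control", "drug"), each = 2),
    auc = c(1, 3, 3, 5, 7, 7))  # session means 2, 4, 7
  out <- session_summary(tab)
  ctrl <- out[out$condition == "control", ]
  expect_equal(ctrl$mean_auc, 3)
  expect_equal(ctrl$sem_auc, 1)
  expect_equal(ctrl$n_sessions, 2L)
  drug <- out[out$condition == "drug", ]
  expect_true(is.na(drug$sem_auc))  # single session: SEM undefined
  # all-equal session means -> SEM 0
  tab2 <- data.frame(session = c("a", "b"), condition = "c", auc = c(5, 5))
  expect_equal(session_summary(tab2)$sem_auc, 0)
  expect_error(session_summary(tab[0, ]), "no data")
})

test_that("response_table re-baselines per stimulus and refuses overlapping windows", {
  sim <- simulate_calcium(calcium_sim_params(
    n_rois = 4, duration_s = 240, stim_times = c(60, 150), seed = 5))
  tab <- response_table(sim$traces)
  expect_equal(nrow(tab), 4 * 2)
  expect_setequal(unique(tab$stimulus), 1:2)
  bad <- roi_trace_set(0:119, matrix(100, 1, 120), stim_times = c(60, 65))
  expect_error(response_table(bad), "overlap")
})
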