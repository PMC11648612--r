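#' Configuration of the jitter-surrogate null test
#'
#' The null hypothesis of no stimulus locking is materialized by displacing
#' every spike time by an independent uniform draw on
#' `[-jitter_halfwidth, +jitter_halfwidth]`, which destroys fine-timescale
#' alignment to the stimuli while preserving slow rate structure. Pointwise
#' acceptance bands are per-bin empirical quantiles of the surrogate PSTH
#' counts; global bands are quantiles of the per-surrogate extreme counts
#' over the tested bins, correcting for the many bins tested
#' simultaneously.
#'
#' @param n_surrogates number of surrogate datasets (default 1000,
#'   minimum 100).
#' @param jitter_halfwidth_s half-range of the uniform jitter in seconds
#'   (default 3).
#' @param pointwise_level pointwise band level (default 0.95: 2.5/97.5
#'   empirical percentiles).
#' @param global_level global band level (default 0.95).
#' @param post_window_s decision window after stimulus onset in which band
#'   crossings count as significant (default 1).
#' @param global_from_post_window if `TRUE` (the default), compute the
#'   global bands from the per-surrogate extrema over the decision-window
#'   bins, which calibrates the family-wise error of the crossing test at
#'   `1 - global_level`; `FALSE` uses the extrema over all bins of the
#'   PSTH window, a strictly more conservative construction.
#' @param rng_seed integer seed; surrogate `i` is generated from a
#'   counter-derived sub-seed `(rng_seed, i)`, so results are reproducible
#'   and independent of evaluation order.
#' @return An object of class `jitter_config`.
#' @export
jitter_config <- function(n_surrogates = 1000, jitter_halfwidth_s = 3,
                          pointwise_level = 0.95, global_level = 0.95,
                          post_window_s = 1, global_from_post_window = TRUE,
                          rng_seed = 1L) {
  if (!is_number(n_surrogates) || n_surrogates < 100)
    stopf("n_surrogates must be >= 100")
  for (lv in c(pointwise_level, global_level))
    if (!is_number(lv) || lv <= 0 || lv >= 1)
      stopf("band levels must lie strictly between 0 and 1")
  if (n_surrogates < 1 / (1 - global_level))
    stopf("n_surrogates too few to resolve the %g global quantile",
          global_level)
  if (!is_number(jitter_halfwidth_s) || jitter_halfwidth_s < 0)
    stopf("jitter_halfwidth_s must be >= 0")
  if (!is_number(post_window_s) || post_window_s <= 0)
    stopf("post_window_s must be positive")
  structure(list(n_surrogates = as.integer(n_surrogates),
                 jitter_halfwidth_s = jitter_halfwidth_s,
                 pointwise_level = pointwise_level,
                 global_level = global_level,
                 post_window_s = post_window_s,
                 global_from_post_window = global_from_post_window,
                 rng_seed = as.integer(rng_seed)),
            class = "jitter_config")
}

#' One jitter surrogate of a spike train
#'
#' Displaces each spike time by an independent uniform draw on
#' `[-h, +h]` and re-sorts. Deterministic given
#' `(cfg$rng_seed, surrogate_index)`. Spikes jittered outside the recording
#' bounds are kept; they simply fall outside any aligned window.
#'
#' @param spike_times numeric spike times in seconds.
#' @param cfg a [jitter_config()].
#' @param surrogate_index 1-based surrogate counter.
#' @return Sorted numeric vector, same length as `spike_times`.
#' @export
jitter_surrogate <- function(spike_times, cfg, surrogate_index = 1L) {
  stopifnot(inherits(cfg, "jitter_config"))
  h <- cfg$jitter_halfwidth_s
  if (h == 0 || length(spike_times) == 0L) return(sort(spike_times))
  with_seed(derive_seed(cfg$rng_seed, surrogate_index),
            sort(spike_times + stats::runif(length(spike_times), -h, h)))
}

# Unsorted fast path used inside compute_bands (binning does not need
# sorted spikes; the draw stream is identical to jitter_surrogate's).
jitter_raw <- function(spike_times, cfg, surrogate_index) {
  h <- cfg$jitter_halfwidth_s
  if (h == 0) return(spike_times)
  with_seed(derive_seed(cfg$rng_seed, surrogate_index),
            spike_times + stats::runif(length(spike_times), -h, h))
}

#' Surrogate-derived acceptance bands for a PSTH
#'
#' Builds `cfg$n_surrogates` jittered PSTHs with the same stimulus times
#' and bin geometry as the observed PSTH, then derives per-bin pointwise
#' bands (nearest-rank empirical quantiles at `(1 +/- pointwise_level)/2`),
#' scalar global bands (the `global_level` quantile of per-surrogate maxima
#' over bins and the `1 - global_level` quantile of per-surrogate minima),
#' and the per-bin surrogate mean.
#'
#' @param rec a [session_recording()].
#' @param cfg a [jitter_config()].
#' @param bin_width,pre,post PSTH geometry, as in [build_psth()].
#' @return An object of class `jitter_bands`: `pointwise_low`,
#'   `pointwise_high`, `surrogate_mean` (per bin), `global_low`,
#'   `global_high` (scalars), plus the bin geometry.
#' @export
compute_bands <- function(rec, cfg, bin_width = 0.1, pre = 3, post = 3) {
  stopifnot(inherits(rec, "session_recording"),
            inherits(cfg, "jitter_config"))
  if (cfg$post_window_s > post)
    stopf("post_window_s (%g s) exceeds the PSTH post extent (%g s)",
          cfg$post_window_s, post)
  stims <- rec$stim_times
  stims <- stims[stims - pre >= 0 & stims + post <= rec$duration_s]
  nbins <- as.integer(round((pre + post) / bin_width))
  bin_left <- seq(-pre, post - bin_width, by = bin_width)
  S <- cfg$n_surrogates
  counts <- matrix(0L, nrow = S, ncol = nbins)
  spikes <- rec$spike_times
  # boundaries between consecutive stimulus windows (windows are
  # non-overlapping, so each spike belongs to at most the nearest one)
  K <- length(stims)
  bounds <- if (K > 1L) (stims[-K] + post + stims[-1L] - pre) / 2
            else numeric()
  # generate per-surrogate (counter-seeded) but bin in chunks, vectorized
  chunk <- 200L
  for (s0 in seq(1L, S, by = chunk)) {
    ss <- s0:min(S, s0 + chunk - 1L)
    jit <- unlist(lapply(ss, function(i) jitter_raw(spikes, cfg, i)),
                  use.names = FALSE)
    counts[ss, ] <- bin_chunk(jit, length(ss), length(spikes), stims,
                              bounds, bin_width, pre, post, nbins)
  }
  win <- if (cfg$global_from_post_window)
    which(bin_left >= 0 & bin_left < cfg$post_window_s)
  else seq_len(nbins)
  alpha <- (1 - cfg$pointwise_level) / 2
  structure(list(
    pointwise_low = apply(counts, 2, quantile1, p = alpha),
    pointwise_high = apply(counts, 2, quantile1, p = 1 - alpha),
    surrogate_mean = colMeans(counts),
    global_high = quantile1(apply(counts[, win, drop = FALSE], 1, max),
                            cfg$global_level),
    global_low = quantile1(apply(counts[, win, drop = FALSE], 1, min),
                           1 - cfg$global_level),
    bin_left = bin_left, bin_width = bin_width, pre = pre, post = post,
    n_surrogates = S, cfg = cfg),
    class = "jitter_bands")
}

# Bin a concatenated chunk of n_surr jittered copies of an n_spike train
# into one count row per surrogate. Each spike is assigned to its nearest
# stimulus window via the precomputed inter-window boundaries, then binned
# with the same half-open edge-to-right convention as psth_counts.
bin_chunk <- function(jit, n_surr, n_spikes, stims, bounds, bin_width,
                      pre, post, nbins) {
  if (n_spikes == 0L) return(matrix(0L, n_surr, nbins))
  j <- findInterval(jit, bounds) + 1L
  off <- jit - stims[j]
  iv <- which(off >= -pre & off < post)
  if (length(iv) == 0L) return(matrix(0L, n_surr, nbins))
  b <- floor((off[iv] + pre) / bin_width) + 1
  b[b > nbins] <- nbins
  key <- ((iv - 1L) %/% n_spikes) * nbins + as.integer(b)
  matrix(tabulate(key, n_surr * nbins), nrow = n_surr, ncol = nbins,
         byrow = TRUE)
}

#' @export
print.jitter_bands <- function(x, ...) {
  cat(sprintf(
    "jitter_bands: %d surrogates, %d bins; global band [%g, %g]\n",
    x$n_surrogates, length(x$bin_left), x$global_low, x$global_high))
  invisible(x)
}

#' Per-session significance call
#'
#' Inspects the bins whose left edge lies in `[0, post_window_s)`. The
#' session is called `activated` if any such count strictly exceeds the
#' upper global band, else `suppressed` if any falls strictly below the
#' lower global band; activation takes precedence when both occur.
#' `first_crossing_bin` is the 1-based index (into the full PSTH) of the
#' earliest offending bin.
#'
#' @param observed a [build_psth()] result.
#' @param bands a [compute_bands()] result with identical bin geometry.
#' @param cfg a [jitter_config()]; defaults to the one stored in `bands`.
#' @return list with `significant` (logical), `direction`
#'   (`"activated"`, `"suppressed"` or `"none"`), `first_crossing_bin`
#'   (integer or `NA`), of class `significance_call`.
#' @export
call_significance <- function(observed, bands, cfg = bands$cfg) {
  stopifnot(inherits(observed, "psth"), inherits(bands, "jitter_bands"))
  if (length(observed$counts) != length(bands$bin_left) ||
      observed$bin_width != bands$bin_width ||
      observed$pre != bands$pre || observed$post != bands$post)
    stopf("observed PSTH and bands have mismatched bin geometry")
  win <- which(bands$bin_left >= 0 & bands$bin_left < cfg$post_window_s)
  up <- win[observed$counts[win] > bands$global_high]
  dn <- win[observed$counts[win] < bands$global_low]
  if (length(up)) {
    out <- list(significant = TRUE, direction = "activated",
                first_crossing_bin = min(up))
  } else if (length(dn)) {
    out <- list(significant = TRUE, direction = "suppressed",
                first_crossing_bin = min(dn))
  } else {
    out <- list(significant = FALSE, direction = "none",
                first_crossing_bin = NA_integer_)
  }
  structure(out, class = "significance_call")
}

#' @export
print.significance_call <- function(x, ...) {
  cat(sprintf("significance_call: %s%s\n", x$direction,
              if (x$significant)
                sprintf(" (first crossing bin %d)", x$first_crossing_bin)
              else ""))
  invisible(x)
}

#' Fraction of activated sessions per group
#'
#' @param calls data.frame with one row per session and columns
#'   `intensity`, `condition`, `direction` (as produced by
#'   [run_pipeline()] or assembled by hand).
#' @return data.frame with columns `intensity`, `condition`, `n_sessions`,
#'   `n_activated`, `fraction_activated`.
#' @export
activated_fraction <- function(calls) {
  need <- c("intensity", "condition", "direction")
  if (!is.data.frame(calls) || !all(need %in% names(calls)))
    stopf("calls must be a data.frame with columns %s",
          paste(need, collapse = ", "))
  if (nrow(calls) == 0L) stopf("no sessions to summarize")
  grp <- interaction(calls$intensity, calls$condition, drop = TRUE)
  out <- do.call(rbind, lapply(split(calls, grp), function(d) {
    data.frame(intensity = d$intensity[1], condition = d$condition[1],
               n_sessions = nrow(d),
               n_activated = sum(d$direction == "activated"),
               fraction_activated = mean(d$direction == "activated"))
  }))
  rownames(out) <- NULL
  out[order(out$condition, out$intensity), , drop = FALSE]
}

#' Pearson chi-square test on a 2x2 table
#'
#' Closed-form Pearson statistic `N (ad - bc)^2 / (r1 r2 c1 c2)` on a 2x2
#' frequency table (e.g. significant/not x control/drug), with 1 df.
#' Continuity correction is off by default.
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @param yates apply the Yates continuity correction.
#' @return list with `statistic`, `p_value`, `df` (= 1).
#' @examples
#' chi2_2x2(matrix(c(20, 0, 0, 20), 2))  # statistic 40
#' @export
chi2_2x2 <- function(tab, yates = FALSE) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L)))
    stopf("tab must be 2x2")
  if (any(tab < 0) || any(abs(tab - round(tab)) > 1e-9))
    stopf("tab must hold nonnegative integer counts")
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  if (any(rs == 0) || any(cs == 0))
    stopf("degenerate table: a row or column marginal is zero")
  d <- abs(tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])
  if (yates) d <- max(0, d - n / 2)
  stat <- n * d^2 / prod(c(rs, cs))
  list(statistic = stat, p_value = stats::pchisq(stat, df = 1,
                                                 lower.tail = FALSE),
       df = 1L)
}
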