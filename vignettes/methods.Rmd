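---
title: "Methods: dosimetry, calcium quantification, and the jitter-surrogate test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dosimetry, calcium quantification, and the jitter-surrogate test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonoresponse)
```

This vignette documents the statistical models behind the package, the
choices made where the procedures admit more than one reasonable
construction, and what the synthetic generators do and do not emulate.

## Burst-train dosimetry

An ultrasound stimulation train is a carrier tone (typically 1 MHz) gated
into rectangular bursts at a pulse repetition frequency (PRF), with a duty
cycle $d \in (0, 1]$ and total train duration $T$. The derived quantities
are elementary but worth pinning down because intensity conventions are a
recurring source of unit errors:

* burst count $= T \cdot \mathrm{PRF}$ (must be a whole number; the
  constructor refuses fractional trains rather than rounding silently);
* $I_\mathrm{SPPA} = I_\mathrm{SPTA} / d$ for rectangular gating — the
  temporal average spreads the pulse-average intensity over the whole
  period;
* per-stimulus energy $E = I_\mathrm{SPTA} \cdot A \cdot T$, with $A$ the
  radiating area. Because $I_\mathrm{SPTA}$ is already a temporal average,
  the duty cycle must *not* be applied a second time here;
* adiabatic heating bound $\Delta\Theta = E / (V \rho c)$ for a bath of
  volume $V$. The defaults are the physical constants of water
  ($\rho = 1$ g/mL, $c = 4.184$ J/g/°C); the bound assumes every joule is
  absorbed with no loss, so it is a deliberate overestimate. The bath
  constants are a reconstruction — reasonable defaults, not a measured
  property of any particular rig — and are exposed in
  `thermal_context()`.

Values are kept at full precision internally and rounded only for
display (two significant figures in the worked examples).

The envelope generator produces the idealized rectangular gate (no
ramping). When the sampling rate is an integer multiple of the PRF the
phase is computed in integer arithmetic so that the envelope mean equals
the duty cycle exactly; otherwise floating-point phase is used.

## Calcium-transient quantification

Per-ROI fluorescence $F(t)$, sampled nominally at 1 Hz, is normalized as
$\Delta F/F_0 = (F(t) - F_0)/F_0$ with $F_0$ the arithmetic mean over the
30 s immediately preceding the stimulus. The response statistic is the
plain sum of $\Delta F/F_0$ samples over the 10 s after stimulus onset
("area under the curve" in AU at the nominal frame rate); a trapezoidal
variant exists behind a flag but is off by default so that the default
statistic is exactly the summed form.

Choices the procedure leaves open, and what this package does:

* **Window conventions.** Both windows are half-open —
  $[t_s - 30, t_s)$ for baseline, $[t_s, t_s + 10)$ for response — so a
  frame belongs to exactly one window. A baseline window that starts
  before the first frame is an error, not a shorter average: a truncated
  baseline biases $F_0$ in a way the caller should decide about
  explicitly.
* **Per-stimulus baselines.** When a session contains repeated stimuli,
  $F_0$ is recomputed before each one. This absorbs slow drift and makes
  repeated responses comparable.
* **Overlapping stimuli.** Stimuli closer together than the response
  window are refused rather than analyzed with a guessed attribution.
* **Unit of inference.** Group summaries average AUC within a session
  first and compute mean ± SEM across sessions, so `n` counts independent
  experiments, not cells. Group hypothesis testing (ANOVA and post hoc
  contrasts) is deliberately left to the standard `stats` routines.

## PSTH construction

Spike-minus-stimulus offsets are binned into half-open 100-ms bins over a
(−3 s, +3 s) window around each stimulus, summed over the (nominally 20)
stimuli. An offset exactly on a bin edge goes to the bin on its right.
Bins are indexed 1-based, matching R indexing throughout the package.
Stimuli whose window would be truncated by the recording edges are
dropped with a warning, never zero-padded, so every bin is an equal-time
count. Stimulus windows must not overlap; with the study's 10–20 s
interstimulus intervals and the ±3 s window they cannot.

Where raw voltage is the input, multiunit extraction uses standard
practice: a 4th-order Butterworth high-pass (300 Hz default) run forward
and backward for zero phase, then negative threshold crossings at
$-4\hat\sigma$ with the robust noise estimate
$\hat\sigma = \mathrm{median}(|v|)/0.6745$, a 1-ms dead time, and
timestamps at the trough. None of these constants are canonical; all are
arguments.

## The jitter-surrogate null test

The core statistic asks whether spiking is locked to the stimulus beyond
what slow rate fluctuations explain. The null is materialized by
resampling: every spike is displaced by an independent uniform draw on
±3 s and the PSTH rebuilt; 1,000 such surrogates give, per bin, a
pointwise 95% acceptance band (2.5/97.5 empirical percentiles,
nearest-rank convention) and the surrogate mean. Because 10 bins are
inspected (left edges in [0, 1 s)), pointwise bands alone would flag
many null sessions; the multiple-comparison correction is the *global*
band: the 95th percentile of each surrogate's maximum count over the
inspected bins (and symmetrically the 5th percentile of minima). A
session is called **activated** if any inspected bin strictly exceeds the
upper global band, else **suppressed** if any falls strictly below the
lower one; activation wins if both occur, and the first crossing bin is
reported.

Design choices worth stating explicitly:

* **Which bins feed the global band.** Two constructions are defensible:
  extrema over *all* 60 bins of the ±3 s window, or extrema over the 10
  bins actually inspected. The package defaults to the inspected-bin
  construction (`global_from_post_window = TRUE`) because it is the one
  that calibrates the family-wise error at the nominal level: under
  exchangeability of the observed PSTH with its surrogates, the
  probability that the observed maximum over the inspected bins exceeds
  the 95th percentile of surrogate maxima over those same bins is ≈5%
  per direction. The all-bins construction compares a 10-bin maximum
  against a 60-bin-maximum quantile and is far more conservative — on
  simulated null sessions its rejection rate is a few per mille rather
  than a few percent — so it remains available behind the flag for
  sensitivity analysis but is not the default.
* **Jitter granularity.** Each spike is jittered independently
  (per-spike, not per-trial or interval jitter), which preserves the
  total count and rate structure slower than the ±3 s scale while
  destroying stimulus locking.
* **Out-of-bounds spikes.** Spikes jittered past the recording edges are
  kept; they simply fall outside every aligned window. Clipping or
  wrapping would distort edge-bin rates.
* **Determinism.** Surrogate $i$ draws its jitters under a sub-seed
  derived from `(rng_seed, i)`, so any surrogate is reproducible in
  isolation and results do not depend on evaluation order or chunking.
  All generator and band computations restore the caller's RNG state.
* **Quantiles on discrete counts.** Nearest-rank (type-1) empirical
  quantiles, fixed everywhere. Ties between counts make the strict
  crossing test slightly conservative; this shows up in simulation as a
  null rejection rate a little below twice the per-direction nominal 5%.

The condition-level contrast (e.g. control versus a channel blocker)
compares significant/non-significant session counts between two
conditions with the closed-form Pearson $\chi^2$ on the 2×2 table, 1 df,
no continuity correction by default (Yates available behind a flag).

## What the synthetic generators emulate

`simulate_spikes()` draws stimulus times with i.i.d. uniform 10–20 s
intervals and generates multiunit spiking as an inhomogeneous Poisson
process by thinning: baseline rate 20 Hz, multiplied by an evoked gain
inside a configurable post-stimulus window (default 0.5 s). A condition
scale multiplies the gain excess, mirroring a drug that attenuates the
evoked response without touching the baseline. Defaults reflect the
modeled recordings: 20 stimuli per session, 20 kHz voltage sampling when
voltage is synthesized, intensities labeled from the experimental set.

`simulate_calcium()` builds per-ROI fluorescence as
$B_i (1 + \text{evoked}_i(t) + \text{spont}_i(t))(1 + \varepsilon)$: a
lognormal per-ROI baseline, a unit-peak double-exponential transient
(rise 1 s, decay 4 s, GCaMP6s-like) at each stimulus with per-ROI
lognormal amplitudes applied to a responder subset (default 80%),
spontaneous network-wide events shared across a random participating
subset of ROIs (default rate 0.01 Hz, participation 0.5), and 5%
multiplicative Gaussian frame noise. Amplitude is interpretable as peak
$\Delta F/F_0$ because the kernel is normalized to unit peak. The
spontaneous events exist specifically to stress the AUC statistic with
correlated non-stimulus transients.

What the generators do **not** emulate: photobleaching and slow drift,
movement artifacts, spike-waveform overlap and bursting structure,
non-Poisson spiking statistics, and any acoustic-to-rate transduction
physics. Passing tests on synthetic data therefore demonstrate that the
analysis chain recovers what it claims from data obeying its own
assumptions — calibration of the null test, power under a programmed
effect, amplitude recovery — not that those assumptions hold in any
particular recording.

## Problem sizes and numerical tolerances in the test suite

The statistical properties are checked at sizes chosen to make binomial
and Poisson sampling error small relative to the asserted tolerances:
null calibration on 400 simulated sessions (each with 1,000 surrogates),
pointwise-band coverage pooled over 500 sessions, power on 100 sessions,
dose–response monotonicity over 3 gains × 50 sessions with 250
surrogates, and amplitude recovery over 60 ROIs. Where an estimate is
compared against a band (e.g. per-bin coverage against 95% ± 2%), the
assertion allows two binomial standard errors of the estimator on top of
the band — that allowance is estimation noise of the finite replicate
count, not a loosening of the underlying tolerance. Exact identities
(count conservation, normalization round trips, determinism under a
fixed seed) are asserted exactly.

## Known limitations

* The jitter test assumes stimulus windows are far enough apart that a
  spike can contribute to only one window; the constructor enforces it
  rather than handling overlap.
* Session significance is a single binary call per session; latency and
  magnitude of the evoked response are summarized only by the first
  crossing bin.
* The spike detector is a plain threshold crossing; no spike sorting,
  artifact rejection, or electrode drift handling.
* The calcium AUC depends on the nominal 1 Hz frame rate (a sum, not an
  integral); the trapezoid flag exists for irregular sampling but
  changes the units subtly, which is why it is off by default.
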