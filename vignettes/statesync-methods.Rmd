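---
title: "State-resolved spike-train anticorrelation analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{State-resolved spike-train anticorrelation analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statesync)
```

## The problem

During nonREM sleep, neocortical populations alternate between UP states
(hundreds of milliseconds of population firing) and DOWN states (~100 ms
silences aligned with LFP delta waves), which synchronizes most neuron pairs
at the ~1 s timescale. A minority of pairs nevertheless becomes
*anticorrelated* specifically in nonREM: their cross-correlogram (CCG) shows
a trough at zero lag rather than a peak. `statesync` implements the full
analysis chain needed to detect, validate and dissect this phenomenon in
long (24 h scale) extracellular recordings, together with a synthetic
generator that reproduces the relevant mechanisms with known ground truth.

## The statistic: normalized CCG and DCE

For units $a, b$ with spike times inside a set of epochs, the CCG
$C(\tau)$ counts spike pairs at lag $\tau = t_b - t_a$ in 5 ms bins out to
$\pm 1$ s ($\pm 2$ s for UP-state-only analyses). CCGs are computed
separately within each epoch — only same-epoch pairs are counted — and
summed, so state boundaries never contribute spurious lags.

Raw CCGs mix timescales: slow co-modulation (state structure, UP/DOWN
alternation) and fine spike timing. The normalization removes the slow part
by dividing the CCG by a baseline that contains only its coarse structure,
then taking the natural log:

$$ V(\tau) = \ln\frac{C(\tau) + 1}{B(\tau) + 1}. $$

Two interchangeable baselines are provided:

* `smooth_triangular()` — the raw CCG convolved with a unit-area triangular
  window of 1 s total width. Content coarser than ~500 ms survives in the
  baseline and cancels in the ratio.
* `jitter_baseline()` — the CCG of both spike trains after re-drawing each
  spike uniformly within fixed, contiguous 0.5 s partition windows anchored
  at each epoch start (interval jitter), averaged over repetitions. This
  preserves coarse rate structure while destroying sub-window timing.

Interval jitter has, in expectation, the effect of convolving the CCG with
a triangular kernel of twice the partition width, so the two baselines agree;
the convolution is deterministic and far cheaper and is therefore the
default. One numerical subtlety matters: a kernel truncated at the lag-range
boundary biases the baseline exactly where the edge windows of the statistic
sit. `normalized_ccg()` therefore computes the raw CCG on a grid extended by
half the kernel width, smooths, and crops back. With that correction the two
baselines agree to well under 10% of the DCE on strongly anticorrelated
pairs (this is tested).

The **DCE** ("difference between center and edges") of a normalized CCG is

$$ \mathrm{DCE} = \overline{V(|\tau| \le 125\,\mathrm{ms})} -
   \overline{V(\mathrm{edges})}, $$

with the edges being the outermost 125 ms of the $\pm1$ s range (standard
variant) or the 1–2 s lags (UP-only variant, which avoids the boundary
undershoot of bell-shaped UP-state CCGs). Significance comes from a
two-sample t test between the center-bin and edge-bin values at
$\alpha = 10^{-4}$; a pair is a *trough* (anticorrelated) when its DCE is
significantly negative and a *peak* when significantly positive. Throughout
the package, population summaries treat non-significant DCEs as zero
(`dce_sig`), so "nonzero DCE" always means statistically significant.

The log matters because a peak can grow without bound while a trough is
floored at zero counts; the log makes the two comparable. The pseudocount
of 1 on both numerator and denominator bounds the log at empty bins and
maps flat CCGs to exactly zero.

### Choices the data did not dictate

* **Bin width 5 ms, standard lag range ±1 s.** The 250 ms center and
  125 ms edge windows then contain whole bins (50 and 25 per side). The
  normalization only preserves content finer than ~500 ms, so ±1 s
  comfortably spans the informative range.
* **Welch (unequal-variance) two-sample t test** between center and edge
  bins. A paired test has no natural pairing here, and the center and edge
  windows have different bin counts and variances.
* **Natural log.** The base only rescales the DCE; it is recorded in the
  normalized object.
* **Degenerate inputs.** Empty CCGs (no spikes in the selected epochs)
  yield all-zero counts, a flag, and DCE 0 with p = 1; constant value
  vectors short-circuit the t test (p = 1 when the means agree).

## Per-state tables, matching, and specificity

`state_dce_table()` evaluates every requested pair in every present state.
`downsample_matched_dce()` controls for unequal sampling: whole nonREM and
wake epochs are drawn at random without replacement until the total
duration first reaches the shortest state's (REM's) total — stopping at the
first crossing rather than trimming a partial epoch, which is simpler and
unbiased in expectation — and spikes are then deleted at random so every
state holds the same count. DCEs are averaged over three repetitions with
majority-vote significance (the averaging is prescribed; the vote is this
package's choice for the binary flag). `state_specificity_crosstab()`
counts, for each ordered state pair, pairs with a significant negative DCE
in one state and a zero (non-significant) DCE in the other.
`compare_abs_dce()` compares |DCE| across states with one-way ANOVA and
Tukey–Kramer corrected pairwise contrasts.

## UP-state analyses

* `up_only_dce()` sums per-UP CCGs (DOWN spikes can never contribute) and
  uses the UP-only DCE windows. `trim_to` truncates each UP before
  counting, which duration-matches the scrambling control.
* `scramble_up_next()` ("UPnext") moves unit *a*'s within-UP pattern to the
  previous UP state, re-anchored as absolute offsets from UP onset (not
  phase-rescaled — the trimming rule implies absolute time), trims each
  receiving UP to the lesser of the two durations, and drops the first UP.
  This preserves per-UP statistics while destroying simultaneous pairing.
* `up_spike_profile()` is the 50-bin phase histogram of spiking within UP
  states, averaged over UPs after per-UP normalization; UPs without spikes
  are skipped rather than averaged as zero vectors (a zero vector is not a
  probability distribution, and skipping matches per-UP normalization).
* `simulate_profile_pair()` rebuilds spiking from averaged statistics
  alone: an inhomogeneous Poisson process over the 50 phase bins at the
  unit's UP rate, zero DOWN firing, trains independent. Phase-binned
  Poisson is the minimal process consistent with a histogram plus a rate.
  `dce_null_from_simulation()` z-tests an observed DCE against 100 such
  simulations.
* `up_timing_metrics()` measures, per UP where both units fire, the
  difference in first-spike and mean-spike times; only such UPs are used
  (imputing the UP end for silent units would manufacture timing structure).

## Burst analysis

A unit's log10-ISI distribution is fit with a two-component Gaussian
mixture (via `mclust`); the unit counts as bursty only if the component
means are ≥ 1 log10(s) apart. The burst threshold is
$10^{\mu_f + 2\sigma_f}$, capped at the separatrix — the density minimum
between the means, located by a 0.001 log10-s scan. Burst spikes are
maximal runs of ≥ 3 spikes with all ISIs below threshold; entire runs are
removed, including the first spike (the removal rule names spikes, not
intervals; `keep_run_head = TRUE` gives the alternative reading). Raw
log10 ISIs are fit directly rather than a binned histogram.

`removal_sweep()` recomputes the nonREM DCE after removal at increasing
levels in three count-matched modes: scaling the ISI threshold, removing a
random subset of at-threshold burst spikes of the same size, and removing
the same number of spikes anywhere in nonREM. The readout is the DCE
ratio (post/original): above 1 amplified, 0–1 reduced, below 0 reversed.

## LFP band-power analyses

Band power is Hann-windowed short-time Fourier power (1 s frames, half
overlap) integrated over each band, optionally restricted to nonREM frames
and z-scored over time with |z| > 3 outliers removed; the outlier pass is
iterated until the retained set stabilizes, which makes the normalization
idempotent. The band grid is log-spaced over 0.5–80 Hz plus the two named
example bands 3.5–4.3 Hz (delta) and 49–60 Hz (gamma).

Three analyses relate power to anticorrelation: (1) 3 h windows (anchored
at recording start, final partial window kept if ≥ 1 h): per-window
nonREM-only DCE of trough pairs against per-window mean nonREM band power,
Spearman correlation pooled over (pair, window) points — per-pair DCEs are
pooled rather than CCGs merged across pairs, keeping pairs identifiable;
(2) nonREM epochs ranked into four band-power quartiles (stable tie-break
by epoch order), one pooled CCG/DCE per pair per quartile, Pearson
correlation; (3) epoch duration against plateau power (epochs > 200 s,
first 120 s and last 50 s trimmed, where power ramps regardless of epoch
length). `dce_stability_matrix()` builds the pair × window DCE matrix for
the units participating in the most significant troughs and z-tests its
mean per-pair SD against within-window shuffles.

## The synthetic generator

`generate_recording()` emulates the statistical structure the analyses
assume, with ground truth:

* **States**: wake → nonREM → (p = 0.6) REM cycles, lognormal bout
  durations (medians ≈ 140/170/80 s) chosen to give roughly 40/50/10%
  wake/nonREM/REM time and a few hundred nonREM bouts per 24 h, REM always
  the shortest total. **UP/DOWN**: lognormal durations clipped to
  0.2–2 s (UP) and 0.05–0.5 s (DOWN), i.e. ~1.3 Hz alternation; DOWN
  firing is exactly zero.
* **Pairs**: units are rostered into designated pairs with classes
  INDEPENDENT / COACTIVE / ANTIPHASE (80/12/8% by default, half the
  antiphase pairs bursty). ANTIPHASE pairs occupy opposite halves of each
  UP, the side assignment flipping at random per UP, with a dead zone of
  10% of the UP around the midline and a confinement probability
  (depth) of 0.95 by default, scaled per pair (0.55–1) so the trough
  spectrum is heterogeneous. A fixed lag would produce an offset peak, not
  a trough; random side-swapping is the minimal mechanism that yields high
  spike-timing variance, no consistent lag, and destruction by UPnext
  scrambling. BURSTY variants emit the confined portion (75% of rate) as
  3–5-spike bursts at 3–8 ms ISIs and the rest as isolated uniform spikes,
  so bursts specifically carry the anticorrelation. COACTIVE pairs share
  an early-biased phase profile, a lognormal per-UP gain, and a small
  jittered-coincidence component, so their peak survives UPnext scrambling
  in weakened form.
* **Wake/REM**: homogeneous Poisson at the unit's overall nonREM rate. By
  default half the antiphase pairs keep a weaker (depth 0.5) block-wise
  alternation in wake; REM is always structureless. Real recordings show
  wake troughs at a lower rate than nonREM and essentially none in REM,
  and carrying part of the anticorrelation into wake is what makes the
  trough-percentage ranking nonREM > wake > REM reproducible rather than a
  tie at zero.
* **LFP** (200 Hz): white noise plus a 3.9 Hz and a 54 Hz sinusoid whose
  nonREM amplitudes rise (delta) and fall (gamma) with epoch duration,
  ramp linearly over fixed 100 s / 50 s windows at epoch boundaries, and
  drift slowly across the recording; the antiphase depth of each nonREM
  epoch is coupled to its relative delta amplitude
  (`depth × rel^delta_coupling`), so anticorrelation strength tracks delta
  and anti-tracks gamma by construction.

### What the generator does not emulate

Spike-sorting artifacts, nonstationary firing rates across hours,
cell-type differences, true LFP spectra (the oscillations are narrowband
sinusoids), DOWN-state-active neurons, and wake behavioral structure. A
passing test therefore shows the pipeline recovers these mechanisms when
present and stays quiet when absent — not that real cortical data contains
them.

### A deliberate property worth knowing

With exact DOWN-state silencing, every simultaneously recorded pair shares
UP/DOWN co-modulation at the ~0.8 s cycle timescale. The 1 s triangular
normalization removes most but not all of it, and at 24 h spike counts the
bin-level t test resolves the small positive residual for essentially every
co-UP pair — so on long synthetic recordings the *peak* percentage is high
even for INDEPENDENT pairs. This mirrors the profile-resimulation finding
(average UP statistics alone produce positive, never negative, DCEs) and
does not affect the trough side, which is what the validation suite
quantifies: troughs appear only for antiphase mechanisms, at the configured
rates.

## Problem sizes used by the tests

The validation suite uses 1.5 h schedules for pair-level populations
(50 antiphase, 30 coactive, 30 bursty pairs), three full 24 h default
recordings for state-ranking and class recovery, one 24 h delta-coupled
recording for the LFP analyses, 200 Poisson pairs of 2,000 s for null
calibration, and 100-fold profile resimulation for the z-test; these sizes
keep the whole suite within a few minutes on one CPU while leaving every
comparison overwhelmingly powered.

## Known limitations

* The t test treats bins as independent samples; smoothing-induced
  correlation between neighboring baseline bins makes it slightly
  conservative. Calibration on independent Poisson pairs stays well below
  the nominal alpha.
* Interval jitter with partitions anchored at epoch starts is quantized at
  the window width; its equivalence with triangular convolution is
  first-order, which is why the boundary-padded convolution is the default
  baseline rather than the jitter estimate itself.
* `detect_up_down()` is a convenience population-rate thresholder for
  synthetic-style data; curated UP/DOWN epochs should be supplied for real
  recordings.
* Band powers come from short-time Fourier frames, so sub-1 Hz bands are
  poorly resolved at the default 1 s frame.
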