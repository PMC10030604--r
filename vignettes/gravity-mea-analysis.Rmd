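---
title: "Analyzing MEA recordings across gravity phases: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing MEA recordings across gravity phases: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(gravimea)
library(dplyr)
```

# The problem

Multi-electrode arrays (MEAs) record extracellular voltage from cultured
neural networks on a grid of 60 microelectrodes at 25 kHz. When such a
culture rides a drop tower or a human centrifuge, the recording spans a
sequence of *gravity phases* — baseline at 1 g, a few seconds of
microgravity or minutes of hypergravity, ramps, an impact — and the
scientific question is whether and how single-unit firing and bursting
rates differ between phases.

`gravimea` implements that analysis chain end to end: denoising, spike
detection and sorting, unit curation, burst detection, phase segmentation
with safety margins, rate tables, and the statistical battery
(repeated-measures ANOVA with the Geisser–Greenhouse correction, Tukey
pairwise comparisons, Friedman test, ROUT outlier screening, firing-rate
density profiles). Because raw recordings of this kind are rarely public,
the package also contains a first-class synthetic-recording generator
with known ground truth, so that every stage of the pipeline is
verifiable: spike-sorting recall and precision, empty-channel false
positives, rate recovery, statistical calibration and end-to-end effect
recovery are all measured against planted truth in the test suite.

# The processing model

## Preprocessing

Raw traces are high-pass filtered with a second-order Butterworth filter
(cutoff 100 Hz) and then common-median referenced: at every sample the
across-channel median is subtracted from every channel, cancelling any
artifact shared by all electrodes (platform vibration, supply
interference). Two design choices deserve a note:

* **Zero-phase filtering.** The filter is applied forward–backward, so
  spike times are not shifted between phases; the cost is that the
  effective magnitude response is the *square* of the single-pass
  Butterworth response (gain 1/2 rather than 1/√2 at the cutoff). The
  tests assert the measured gain against this squared analytic response.
  Edges are reflect-padded (odd reflection, three filter lengths) and the
  first and last 50 ms are excluded from detection as filter transients.
* **Median over all channels, including empty ones.** With few channels
  the across-channel median is appreciably correlated with each channel
  and biases the MAD noise scale low; at the chip-standard 60 electrodes
  the bias is negligible. Simulated validation scenarios therefore use
  30–60 channels, never a handful.

## Detection, sorting, curation

The noise scale per channel is the MAD-based sigma
`median(|x − median(x)|)/0.6745`; spikes are negative threshold crossings
at 4.5 sigma, aligned to the local trough, with a 1 ms dead time.
Snippets (0.6 ms before to 1.0 ms after the trough) are projected onto
three principal components and clustered with k-means (K ≤ 3 per
channel, mean-silhouette model selection with a 0.5 acceptance
threshold). Because trough alignment on a discrete grid jitters by one
sample, a genuine unit can fragment into shifted copies; clusters whose
mean templates match up to a ±3-sample shift (correlation ≥ 0.9,
amplitude ratio ≥ 0.6) are merged back. This per-channel design is
adequate at standard MEA electrode pitch, where a unit is visible on a
single electrode; it is not a general-purpose sorter.

Curation keeps units with ISI-violation rate ≤ 0.2 (fraction of ISIs
below 1.5 ms), template SNR ≥ 5 (trough-to-peak over MAD sigma), and at
least 5 spikes. The minimum spike count is a standard guard: a handful
of chance threshold crossings on an empty channel can otherwise average
into a template with SNR just above 5. With it, channels without a
planted unit yield zero curated units in ≥ 99% of simulated recordings —
the synthetic counterpart of an empty-channel noise control.

## Burst detection

Bursts are detected per unit with the five-parameter interval
(MaxInterval) algorithm: a burst opens at an ISI ≤ 20 ms, extends while
ISIs ≤ 100 ms, candidates closer than 100 ms are merged, and candidates
shorter than 20 ms or with fewer than 2 spikes are discarded — in that
order. The merge step is applied *before* the duration/count filters;
for the standard parameter set the merge is provably vacuous (any
inter-candidate gap is an ISI > 100 ms = the minimum inter-burst
interval), a property asserted over a thousand random trains, but the
ordering matters for non-standard parameters and is therefore fixed and
documented. The implementation is validated by exact agreement with an
independent brute-force oracle (enumerate maximal runs, merge, filter)
on 1000 random trains. A burst straddling a phase boundary is counted
once, in the window containing its start.

## Phases, margins, rate tables

A `phase_schedule` is an ordered set of labelled, non-overlapping
intervals with g-levels. Built-in presets:

| preset | phases | margins |
|---|---|---|
| `drop` | Baseline 600 s, Microgravity 4.7 s, Impact 5 s, Baseline 600 s | 150 ms |
| `centrifuge_6g` / `_4g` | Baseline 600 s, Ramp up 30 s, HyperG 300 s, Ramp down 30 s, Post 300 s | 2 s |

Safety margins are trimmed symmetrically from both ends of every phase
before any rate is computed, so no sample near a phase transition is
attributed to the wrong gravity condition. On the centrifuge the
hypergravity and post phases are analyzed as their first and last minute
(`hyperg1/2`, `post1/2`), probing adaptation, for seven analyzed windows
in total; the drop protocol yields four. All windows are half-open
`[start, end)`.

Units with zero spikes in *any* analyzed window are removed from the
entire analysis (an artifact guard); the burst-rate analysis is further
restricted to units with at least one burst in every window — in
simulated drop experiments roughly a third of units are burst-complete,
mirroring the much smaller burst-analysis cohorts typical of this kind
of data. Rates are log10-transformed for statistics, because firing and
bursting rates are lognormally distributed across units; the base is a
display choice only (any fixed base rescales all test statistics'
inputs linearly).

## Statistics

`rm_anova_gg()` is the classical within-subject decomposition
(`F = MS_condition/MS_error`, df `(k−1)` and `(k−1)(n−1)`), with the
Geisser–Greenhouse epsilon computed from the double-centered condition
covariance `C` as `tr(C)² / ((k−1)·tr(C²))`, bounded in `[1/(k−1), 1]`,
and the p-value taken at epsilon-scaled degrees of freedom. "Subjects"
are units pooled across runs, replicating the as-published analysis;
pooling ignores run-level clustering and is deliberately not extended to
a mixed model here. `tukey_pairwise()` uses the RM-ANOVA error term with
*uncorrected* error df (the sphericity correction applies to the omnibus
test only, matching common statistical-software behavior). Friedman's
test uses within-subject mid-ranks with the standard tie correction.
ROUT outlier screening is implemented for a location model (median,
RSDR = 68.27th percentile of absolute residuals with the `n/(n−1.5)`
small-sample correction, t-type p-values, Benjamini–Hochberg step-up at
rate Q), appropriate for scalar waveform parameters such as template
amplitude and half-width.

One calibration caveat is worth stating plainly: the phases have very
different durations (4.4 s of analyzed microgravity vs minutes of
baseline), so per-phase rate estimates have very different sampling
variance, and a pooled-error Tukey is not calibrated pair by pair. In
null simulations (600 simulated null experiments) the
baseline–microgravity pair is significant in ~9% of experiments rather
than the nominal 5% — the pooled error term underestimates that pair's
variance by more than Tukey's per-pair conservatism compensates — and
the probability that *some* pair is significant is ~19%. This is a
property of the as-published procedure on heteroscedastic phases,
reproduced faithfully rather than repaired; a per-pair paired test or a
heteroscedasticity-robust error term would fix it, at the cost of no
longer being the procedure under study.

# The synthetic generator

`synth_config()` describes what the simulator emulates:

* **Lognormal baseline rates**, median 3 Hz (`rate_lognormal_mu = log 3`,
  sigma 0.5 in log units). The sigma is a package choice (population
  spread of cultured-network unit rates); `exp(mu)` is exactly the
  distribution median, which the tests verify.
* **Spike trains** are a superposition of a tonic renewal process
  (refractory-shifted exponential ISIs, absolute refractory 2 ms) and a
  burst process: Poisson burst onsets, geometric burst lengths (mean 5
  spikes), intra-burst ISIs with mean 8 ms. `burst_fraction` (default
  0.15) sets the fraction of each unit's rate delivered in bursts. The
  value is a deliberate compromise fixed ahead of the validation runs: a
  pure burst process has count Fano factors near 9, which would swamp
  any few-second analysis window with clustering noise, while 0.15 keeps
  single-window rate estimates near Poisson precision (Fano ≈ 1.8) and
  still produces bursts that satisfy the MaxInterval criteria in every
  phase for about a third of units. No generative model for these
  spike trains is established in the literature this emulates; Poisson
  with burst episodes is a stand-in, and rate-fidelity checks quote
  Poisson-scale tolerances accordingly.
* **Waveforms** are biphasic 1.6 ms templates (0.3 ms trough lobe
  carrying 3/4 of the trough-to-peak amplitude, 0.5 ms rebound), with
  per-unit lognormal amplitudes of median 30.5 µV; electrode noise is
  Gaussian (4 µV), plus an optional sinusoidal common-mode artifact
  identical on all channels, the basis of the referencing test. One or
  two units per electrode; a configurable fraction of electrodes is
  empty (noise only). Samples must be int16-representable at the
  0.1 µV/LSB file calibration (±3276.7 µV, quantization far below
  noise).
* **Phase modulation** encodes the reported direction of gravity
  effects as per-subgroup multiplicative factors. Subgroups are
  baseline-rate terciles; under the drop preset all low/mid units gain
  ×4/3 in microgravity (the 3 → 4 Hz density-peak shift) while high
  units split ~50/50 in sign; the impact drives subgroups toward a
  bimodal 8/20 Hz profile; on the centrifuge the hypergravity onset
  suppresses low/mid units toward 2 Hz and ramps push rates toward
  8–13 Hz. Targets are converted to subgroup-wide factors
  (target / subgroup geometric mean) so the within-subgroup rate spread
  is preserved.
* **Determinism**: a single root seed; every sub-stream (rates,
  amplitudes, per-unit trains, noise) derives its own seed from it, so
  identical configuration and seed give bit-identical recordings and
  truth.

What the generator does *not* emulate: biophysical membrane dynamics,
synaptic connectivity and network bursts, local-field potentials,
electrode drift, cross-channel waveform spillover, non-stationary noise.
Passing tests therefore demonstrate that the pipeline is correct and
well-calibrated under the stated statistical structure — not that it is
robust to every pathology of real recordings.

# Problem sizes and numerical choices

The validation suite runs desk-scale versions of each experiment, chosen
as the package's own standard test conditions: time-compressed drop
protocols (`scale = 0.1`: 60 s baselines; the 4.7 s microgravity window
is never scaled — it is the scientific object), 10 kHz rendering at
30–60 channels for sorting checks, 20 seeds for recall/precision, 100
simulated recordings for the empty-channel control, 2000 null
simulations for ANOVA calibration, and 200 simulated experiments per arm
for end-to-end effect recovery. Statistical end-to-end checks run at the
spike-train level (generator truth into the rate-table and statistics
chain) rather than through voltage rendering, since sorting fidelity is
established separately.

Numerical details: windows are half-open everywhere; rank ties in
subgroup selection break by ascending unit id; density profiles use a
Gaussian kernel on a linear Hz grid with Scott's bandwidth
(`sd·n^{−1/5}`, floor 0.1 Hz for degenerate samples) renormalized over
the grid support; the ROUT scale has a machine-epsilon floor so a
degenerate (all-identical-but-one) sample still flags its outlier; the
GG epsilon is clamped to its theoretical bounds; filtering pads by odd
reflection.

# Known limitations

* End-to-end recovery of the planted microgravity effect is limited by
  physics, not implementation: with a 4.4 s analyzed window, a ×4/3
  effect on two-thirds of 63 units, log-rate attenuation of small
  counts, and a family-wise-corrected pairwise test, simulated power is
  ~45%, not the near-certain detection one might hope for. Equivalently:
  a single real experiment of this design detecting the effect is
  informative but not guaranteed to replicate. The acceptance report
  states the measured rate.
* The pooled-error Tukey on heteroscedastic phases (above) inflates the
  experiment-wise null rate; per-pair calibration for the
  baseline–microgravity comparison is nevertheless near-nominal.
* The sorter assumes one-electrode footprints and at most three units
  per channel; it is a transparent validation tool, not a replacement
  for a production spike sorter.
* Ramp phases use nominal scheduled durations; an accelerometer-trace
  segmentation is out of scope, and the schedule is authoritative.

# A worked example

```{r example, eval = FALSE}
sim <- simulate_experiment("drop", seed = 1, scale = 0.1)
analysis <- analyze_phases(sim$spikes, sim$schedule)
analysis
tidy(analysis$tukey_firing)
autoplot(analysis$table)
autoplot(density_profile(
  analysis$table$firing_rate[analysis$table$phase == "microgravity"]))
```
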