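# gravimea

Analysis of multi-electrode array (MEA) electrophysiology under altered
gravity — an end-to-end, fully testable R pipeline for experiments in
which cultured neural networks on 60-electrode MEA chips ride a drop
tower (seconds of microgravity, then a hard impact) or a centrifuge
(minutes of hypergravity with ramp phases), and the question is how
single-unit firing and bursting rates change between gravity phases.

It is written for electrophysiologists and gravitational biologists who
need the complete chain from raw extracellular voltage to phase-level
statistics, and for methodologists who want every stage of such a chain
verifiable against ground truth.

## What it does

* **Synthetic recordings with ground truth** — lognormal unit firing
  rates (median 3 Hz), burst-structured spike trains with an absolute
  refractory period, biphasic ~30 µV templates, Gaussian plus
  common-mode noise, empty electrodes, and per-subgroup phase
  modulation (e.g. the microgravity ×4/3 rate increase of low-firing
  units). Every downstream claim is tested against this truth.
* **Preprocessing** — zero-phase 2nd-order Butterworth high-pass
  (100 Hz) and common median referencing.
* **Spike detection, sorting, curation** — MAD-based noise scale
  `median(|x − median(x)|)/0.6745`, detection at 4.5 σ (negative
  crossings, trough-aligned, 1 ms dead time), per-channel PCA + k-means
  clustering with template-similarity merging, curation by ISI-violation
  rate ≤ 0.2, SNR ≥ 5, and a minimum spike count.
* **Burst detection** — the five-parameter interval (MaxInterval)
  algorithm: 20 ms max ISI to start, 100 ms max ISI to end, 100 ms
  minimum inter-burst interval, 20 ms minimum duration, ≥ 2 spikes;
  validated by exact agreement with a brute-force oracle.
* **Phase analysis** — protocol presets (drop tower; 4 g / 6 g
  centrifuge) with safety margins (150 ms / 2 s), first/last-minute
  sub-windows of long phases, unit × phase firing/burst rate tables,
  removal of units silent in any phase, log10 transform.
* **Statistics** — repeated-measures one-way ANOVA with the
  Geisser–Greenhouse correction

  `F = MS_cond / MS_err`,  `ε_GG = tr(C)² / ((k−1)·tr(C²))`,

  Tukey pairwise comparisons on the studentized range
  `q = |m_i − m_j| / √(MS_err/n)`, Friedman's test with tie correction,
  ROUT outlier screening (Q = 1%) for waveform metrics, kernel density
  profiles of firing rates, and paired low/mid/high subgroup deltas.
* **Tidy interfaces** — tables are tibbles, fitted objects have
  `tidy()`/`glance()` methods, result types have `autoplot()` methods,
  and a thin CLI (`exec/gravimea`) exposes
  `simulate | preprocess | sort | analyze | report`.

## Worked example

Simulate a time-compressed drop-tower experiment (60 s baselines, the
4.7 s microgravity window at full length) with the planted microgravity
effect, and run the phase analysis:

```r
library(gravimea)
sim <- simulate_experiment("drop", seed = 1, scale = 0.1)
analysis <- analyze_phases(sim$spikes, sim$schedule)
analysis
#> <gravity_analysis>
#>   units: 63 in, 63 firing analysis, 21 burst analysis
#>   firing-rate omnibus: Repeated-measures one-way ANOVA (n = 63 subjects, k = 4 conditions)
#>   F(3, 186) = 328.1, Geisser-Greenhouse epsilon = 0.6439
#>   p (GG-corrected) = 1.248e-48, p (uncorrected) = 5.144e-74

tidy(analysis$tukey_firing)
#> # A tibble: 6 × 5
#>   condition_1  condition_2  mean_diff      q    p_adj
#>   <chr>        <chr>            <dbl>  <dbl>    <dbl>
#> 1 baseline     microgravity   0.0765   5.23  1.63e- 3
#> 2 baseline     impact         0.549   37.5   4.33e-15
#> 3 baseline     post          -0.00590  0.403 9.92e- 1
#> 4 microgravity impact         0.472   32.2   4.33e-15
#> 5 microgravity post          -0.0824   5.63  5.67e- 4
#> 6 impact       post          -0.555   37.9   4.33e-15
```

Reading the output: 63 simulated units all remain active in every
phase; 21 of them burst in every phase and enter the burst-rate
analysis. The omnibus ANOVA detects phase differences; the Tukey table
shows the planted structure — a small significant log10 rate increase
from baseline to microgravity (`mean_diff` 0.077 ≈ the ×4/3 effect on
two-thirds of units, adjusted p = 0.0016), a large impact response, and
a post-drop baseline indistinguishable from the pre-drop baseline
(p = 0.99, the recovery control). Per-unit subgroup behavior:

```r
d <- subgroup_deltas(analysis$table, "baseline", "microgravity", k = 10)
sum(d$sign[d$subgroup == "low"] > 0)
#> [1] 8   # 8 of the 10 lowest-firing units measured higher in microgravity
plot_subgroup_deltas(d)     # paired-lines panel, low/mid/high
autoplot(analysis$table)    # log-rate violins per phase
```

(The planted truth raises *all* low units; with ~13 expected spikes in
the 4.4 s analyzed microgravity window, counting noise flips the
measured sign of a couple of them.)

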