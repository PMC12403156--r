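---
title: "Methods: two-state smFRET analysis of four-way junction biosensors"
author: "hjfret"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-state smFRET analysis of four-way junction biosensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hjfret)
```

## The measurement this package models

A four-way (Holliday) DNA junction carrying a Cy3/Cy5 FRET pair is
completed by hybridization of a nucleic-acid target. Once complete, the
junction interconverts continuously between its two stacked conformers
(iso-I, high FRET; iso-II, low FRET), so a target-bound molecule shows
anticorrelated donor/acceptor switching between a sensor-specific pair of
FRET levels, while an incomplete, target-free junction sits at a single
static level. Detection is therefore *digital*: count the molecules that
switch. Four junctions with distance-tuned FRET pairs
(HJ1 0.2↔0.4, HJ2 0.2↔0.6, HJ3 0.3↔0.7, HJ4 0.4↔0.9; static levels
0.2/0.3/0.4/0.6) can be multiplexed on one slide and told apart by their
fitted FRET-state pair.

The package implements the full analysis chain on top of a synthetic-data
module that emulates the TIRF measurement:

1. `simulate_state_path()` / `emit_trace()` / `simulate_cohort()` —
   two-state continuous-time Markov switching rendered into camera-level
   donor/acceptor traces;
2. `render_movie()` / `detect_spots()` / `pair_channels()` /
   `extract_traces()` — the movie-to-trace stage;
3. `compute_fret()` / `classify_dynamic()` / `percent_dynamic()` — FRET
   efficiency, molecule QC and the dynamic/static digital call;
4. `truncate_and_stitch()` / `fit_hmm2()` / `extract_dwells()` /
   `estimate_rates()` — two-state hidden Markov kinetics;
5. `build_tdp()` / `locate_peaks()` — transition density plots;
6. `multiplex_cohort()` / `summarize_mixture()` / `omission_test()` —
   multiplexed assignment and specificity;
7. `simulate_dose_response()` / `tabulate_dose_response()` /
   `fit_calibration()` / `call_lod()` — calibration and limit of
   detection.

## The synthetic-data generator and what it does (not) emulate

Dynamic molecules follow an exact continuous-time Markov chain with
exponential dwells at per-junction rates `k_lh` (low→high, the field's
k₂→₁) and `k_hl` (high→low, k₁→₂); the initial state is drawn from the
stationary distribution `P(high) = k_lh/(k_lh + k_hl)`. Emission
integrates state occupancy *within* each 100 ms frame, so kinetics faster
than the frame rate (HJ3's 6 s⁻¹) produce the partially averaged,
amplitude-attenuated frames a real camera records — this is deliberate,
because the known biases of the downstream analysis live exactly there.

Camera counts are not specified by the source experiments, so the
generator uses a declared, configurable model: total intensity 1000
counts, per-channel Gaussian noise of 60 counts and background 100 counts,
chosen so the FRET-efficiency noise is ≈0.05 s.d. — two states 0.2 apart
are separated by ≈4 s.d., matching what "visually separable" smFRET data
look like. Photobleaching is exponential (Cy3 mean 150 s, Cy5 300 s,
configurable; `Inf` disables), and from frame 1000 a red-laser segment
excites the acceptor directly, emulating the end-of-movie verification of
an active Cy5. The generator does **not** model triplet blinking, spectral
crosstalk, the detection gamma factor, diffusion or surface-density
effects; passing tests therefore validate the *analysis chain* under
realistic noise, bleaching and aliasing, not instrument-specific
photophysics.

## FRET efficiency, QC and the digital call

`E = I_A/(I_A + I_D)` is computed after background subtraction; frames
with non-positive total are undefined and excluded (never imputed), and E
is never clamped. The analysis window of a molecule is
`[0, min(donor bleach, acceptor bleach, red-laser start))` (0-based,
half-open). Bleach changepoints maximize the two-segment mean-shift
statistic, accepted only when the drop exceeds 5 channel s.d.; the
acceptor changepoint must additionally land near background so that FRET
switching is never mistaken for a bleach. Two molecule-level QC rules
reject pathological traces: no verified acceptor in the red-laser segment,
and a median in-window total below `5·√2·noise` (the signature of a bleach
so early the changepoint search cannot see it).

A molecule is called **dynamic** when (i) the donor/acceptor Pearson
correlation over the window is ≤ `r_max` and (ii) a per-trace two-state
HMM finds ≥ 2 Viterbi transitions with state separation ≥ 0.15. The
defaults (`r_max = -0.1`, wide 5/95-percentile initialization of the
per-trace fit) were calibrated on simulated mixed cohorts: the
straightforward settings (−0.3, interquartile initialization) silently
drop a sixth of HJ3's molecules because frame integration attenuates both
their anticorrelation and their apparent state separation. At the
calibrated settings the truth agreement on mixed four-sensor cohorts is
96–98% with a false-dynamic rate of 0–2%; both properties are asserted in
the test suite. `percent_dynamic()` excludes rejected molecules from
numerator and denominator.

## Kinetics: truncate-and-stitch, HMM, dwells, rates

Following the acquisition protocol, the first 20 s (200 frames) of each
dynamic molecule's window are concatenated and fitted *globally* with one
two-state Gaussian-emission HMM (`fit_hmm2()`, Baum–Welch with scaled
forward–backward in C++). Every stitched segment is an independent
sequence: no transition probability, dwell or TDP transition is ever
accumulated across a seam. Initialization: state means at the 25th/75th
percentiles of E, σ at half the IQR (floored at 10⁻³), self-transition
0.95; convergence at Δloglik < 10⁻⁶ (≤500 iterations); EM monotonicity is
asserted per iteration in the tests, and the forward and Viterbi
recursions are verified against exhaustive path enumeration on short
series. States are labelled so state 1 is high FRET (the junction
convention); Viterbi ties break toward the previous state so a tie never
fabricates a transition.

Dwells are run-length-encoded Viterbi segments; a dwell touching a
segment edge is censored on that side. Rates come from the
censored-exponential maximum-likelihood estimator

> k(out of state) = (observed exits from the state) / (total time in the state),

which coincides with `1/mean(dwell)` when nothing is censored but remains
unbiased when a mean dwell is comparable to the 20 s window — HJ1's
high-state dwell is 1/0.06 ≈ 17 s, so excluding censored dwells would
truncate its dwell distribution at the window and inflate `k_hl`
several-fold. The reciprocal-mean estimator is available as
`method = "dwell"` and agrees with the MLE for fast-cycling junctions
(asserted in tests); `rates_from_matrix()` provides the per-frame
transition-matrix diagnostic `k = −ln(1 − a_ij)/dt`. Uncertainties are
bootstrap s.d. over dwells (1000 seeded resamples). `Keq = k_lh/k_hl`
identically.

Two biases are inherent and documented rather than corrected: Viterbi
misses dwells shorter than about a frame, which underestimates both rates
by ~5–15% at `k·dt ≈ 0.1` (the ratio Keq is much less affected), and for
`k·dt ≳ 0.5` (HJ3) the recovered rates underestimate the truth strongly —
the test suite pins the *direction* of that bias instead of a value,
mirroring how such fits are known to miss transitions.

## Transition density plots

TDP coordinates are the mean *raw* E over the dwell before and after each
within-segment transition — not the fitted state means — so TDP peaks are
an independent check on the HMM. The grid is fixed on [0,1]² with bin
width 0.02 (resolving the panel's smallest state gap of 0.2); grid total
equals the transition count by construction. `locate_peaks()` fits two
isotropic 2D Gaussians by least squares seeded at the two largest
well-separated maxima, falling back (flagged) to argmax bin centers; a
second component with amplitude < 2% of the first flags a single-cluster
TDP. For reversible two-state dynamics the per-trace imbalance between
up- and down-transitions is at most one, so `symmetry_score()` approaches
1 on cohorts.

## Multiplex assignment

A dynamic molecule's per-trace fitted pair `(mu_low, mu_high)` is
assigned to the nearest sensor centroid (Euclidean, in the FRET-pair
plane) if that distance is ≤ `max_dist = 0.16` *and* the second-nearest
centroid is ≥ 0.03 further; otherwise it stays unassigned rather than
guessed. The radius was widened from the naive half-spacing after
calibration: frame integration biases HJ3's fitted low state upward by
about 0.1, and 0.16 accommodates that while the margin rule keeps
cross-assignment at zero in the calibration cohorts (measured accuracy
97.8–98.7%). Mixture percentages are reported over all analyzed molecules
by default — consistent with experiments whose four type percentages sum
to less than 100 because static molecules share the denominator — with
`denominator = "dynamic"` as the alternative. `omission_test()` runs the
specificity design: one sensor's junctions present but target-free, and
the analysis must produce zero dynamic calls of that type.

## Dose–response and limit of detection

The generator's binding model is a Hill curve
`f(c) = f_max·cʰ/(cʰ + c₅₀ʰ)` (the saturating empirical shape, with
configurable parameters; each molecule's bound state is an independent
Bernoulli draw). Per-concentration uncertainty follows the 3-group
protocol: molecules are randomly split into three near-equal groups
(static and dynamic alike) and the s.d. of the three group percentages is
reported. The calibration fit is an auxiliary Hill least-squares fit on
the percentage–concentration points (the points remain the primary
output); the linear range is where the local log–log slope is at least
half its maximum. The LOD is deliberately operationalized as
*presence/absence*: the lowest tested concentration with ≥1 dynamic
molecule, valid only when the zero-target blank is clean — a contaminated
blank is an error, not a baseline. This differs from 3σ-style LOD
conventions and is stated here because digital counting with a clean
blank supports it.

## Reproducibility and problem sizes

Every stochastic function takes a seed; cohort simulation is
bit-reproducible and `run_pipeline()` derives per-stage seeds from one
global seed by stage-name hashing, so stages can be rerun in isolation
and a rerun with the same config is byte-identical (asserted via file
checksums). The package's own validation uses simulation scales chosen
for statistical resolution at interactive runtimes: mixed-cohort
classification properties at 250–400 molecules; kinetic recovery at
250 traces × 2000 frames for HJ2/HJ4; and 800 traces for HJ1, whose 3.2 s
relaxation time against 20 s windows makes the realized equilibrium the
dominant noise source (at 200 windows the realized Keq has s.d. ≈ 0.5; at
~500 windows ≈ 0.3).

## Known limitations

* Rates for junctions switching faster than roughly half the frame rate
  are biased low; only the bias direction is guaranteed.
* Censoring is handled by the occupancy-time MLE, not by survival
  modelling of the dwell distribution; dwell *histograms* from
  `extract_dwells()` are window-truncated.
* Channel registration is a pure translation; real two-channel optics
  need a calibrated map before `pair_channels()`.
* No gamma/crosstalk correction: E values are apparent FRET, adequate for
  state separation and classification, not for absolute distances.
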