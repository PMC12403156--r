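# hjfret

Single-molecule FRET (smFRET) analysis of four-way (Holliday) DNA
junction biosensors, from fluorescence movies or donor/acceptor intensity
traces to transition kinetics, digital molecule counting and multiplexed
target identification — together with a synthetic-data module that
emulates the TIRF measurement, so the entire chain is testable without
microscope data.

## Who this is for and what it does

A DNA four-way junction completed by hybridization of its nucleic-acid
target interconverts continuously between two stacked conformers,
producing anticorrelated Cy3/Cy5 switching between a sensor-specific pair
of FRET levels; the incomplete junction is static. Counting switching
("dynamic") molecules is a digital, amplification-free readout of target
binding, and four junctions with distance-tuned FRET pairs
(HJ1 0.2↔0.4, HJ2 0.2↔0.6, HJ3 0.3↔0.7, HJ4 0.4↔0.9) can be read out
simultaneously on one slide.

The analysis core, in the field's standard notation:

* **FRET efficiency** per frame: `E = I_A / (I_A + I_D)` after background
  subtraction, over the pre-bleach, pre-red-laser window of each
  molecule; a direct red-laser excitation segment verifies the acceptor.
* **Digital counting**: `% dynamic = 100 · N_dynamic / N_total`, with
  per-concentration uncertainty from a random 3-group split and the LOD
  defined as the lowest concentration still yielding dynamic molecules
  over a clean blank.
* **Two-state kinetics**: the first 200 frames (20 s) of ~200 dynamic
  molecules are stitched and fitted globally with a two-state
  Gaussian-emission hidden Markov model (Baum–Welch/Viterbi); dwell
  times give the conformer rates k₂→₁ (low→high) and k₁→₂ (high→low) and
  the equilibrium constant **K_eq = k₂→₁ / k₁→₂**.
* **Transition density plots**: 2D histograms of (E before, E after)
  each transition, with 2D-Gaussian peak localization — an independent
  check on the fitted FRET states.
* **Multiplexing**: each dynamic molecule's fitted FRET pair
  `(mu_low, mu_high)` is assigned to the nearest sensor centroid with a
  distance-and-margin rule; an omission design verifies specificity.

## Worked example

Characterize HJ2 (target: DNA mimic of miR-342-3p) from pure simulation —
100 dynamic molecules at its published switching rates, analyzed by the
same pipeline a real experiment would use:

```r
library(hjfret)
res <- characterize_sensor(hj_sensor_panel()$HJ2,
                           n_traces = 100, n_frames = 1200, seed = 11)
res$fit
#> Two-state Gaussian HMM (converged, 14 EM iterations)
#>   FRET states: low 0.205 (sd 0.057), high 0.594 (sd 0.051)
#>   per-frame transition prob: low->high 0.0610, high->low 0.0692
#>   log-likelihood: 15527.42 over 12400 frames (62 segments)
res$rates
#> Transition rates (mle estimator)
#>   k(2->1, low->high)  = 0.606 +/- 0.029 /s
#>   k(1->2, high->low)  = 0.689 +/- 0.031 /s
#>   transitions (N) = 799;  Keq = k21/k12 = 0.879
locate_peaks(res$tdp)[, 1:2]
#>   e_initial   e_final
#> 1 0.5921132 0.2077392
#> 2 0.2069888 0.5921346
```

The fitted states land on HJ2's 0.2↔0.6 pair, the recovered rates sit
near the generating 0.7/0.8 s⁻¹ (slightly low, because Viterbi decoding
misses dwells shorter than a frame), Keq ≈ 0.88, and the TDP shows the
two symmetric transition clusters of a reversible two-state system.

A multiplexed cohort (all four sensors, saturating target) is analyzed
blind and summarized into types:

```r
co <- simulate_cohort(hj_sensor_panel(), 200, fraction_dynamic = 0.87,
                      n_frames = 1000, seed = 11)
summarize_mixture(multiplex_cohort(co))
#> Mixture of 196 analyzed molecules (151 dynamic, 45 static, 4 rejected)
#>   HJ1: 22 (11.2% of all)
#>   HJ2: 51 (26.0% of all)
#>   HJ3: 33 (16.8% of all)
#>   HJ4: 42 (21.4% of all)
#>   unassigned dynamic: 3
```

An end-to-end run with provenance-stamped outputs:

```r
run_pipeline(system.file("extdata", "demo-config.yaml", package = "hjfret"),
             out_dir = "demo_run")
```

A thin command-line dispatcher over the same functions ships at
`inst/cli/hjfret.R` (subcommands `simulate`, `render`, `extract`, `fret`,
`classify`, `fit-hmm`, `tdp`, `multiplex`, `dose`, `run`).

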