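# clonefate

Clone-level analysis of dual-reporter T helper cell differentiation
dynamics in micro-well arrays.

## The problem

Naive CD4⁺ T cells activated under Th17 or Treg-inducing conditions can
commit to the RORγt⁺ (Th17) lineage, the Foxp3⁺ (Treg) lineage, or a
double-positive (DP) RORγt⁺Foxp3⁺ state. With a dual fluorescence
reporter (RORγt→GFP, Foxp3→RFP), time-lapse imaging of micro-wells each
seeded with a single naive cell turns lineage commitment into a
quantitative, clone-resolved measurement. This package implements the
full downstream analysis for such experiments — and a synthetic-data
generator that emulates the imaging, flow-cytometry and bulk-expression
inputs so every stage is testable without the original data.

The quantitative core:

- **Response threshold & rise time.** Per channel, the threshold is
  calibrated from naive t = 0 signals as `mean + k·sd` (default k = 3).
  The rise time is the first frame opening a run of ≥ 2 frames above
  threshold; clones are classified SPR / SPF / DP / DN by which channels
  rise by the end of imaging (52 hr, 30-min frames). Group means of rise
  times account for right-censoring by the imaging window via a censored
  Gaussian MLE (`survival::survreg`).
- **Phase-space trajectories.** Median total-fluorescence traces per
  fate group are drawn in the (Foxp3, RORγt) plane. The *extrapolated*
  trajectory pairs the SPF group's Foxp3 median with the SPR group's
  RORγt median at each time point; agreement with the observed DP
  trajectory is scored as a normalized RMSD,
  `d = RMS(‖obs − exp‖) / RMS(‖exp‖)`, compared against a split-half
  bootstrap null.
- **Pixel-angle heterogeneity.** Each above-background pixel maps to an
  angle `θ = atan2(GFP, RFP)` ∈ [0°, 90°] (0° pure Foxp3, 90° pure
  RORγt, ~45° co-expression). Angles pooled over the last 5 frames are
  histogrammed (3° bins), Gaussian-smoothed (σ = 2 bins, reflecting
  boundaries), and local maxima counted with a prominence ≥ 10 % of the
  density maximum and ≥ 15° separation: ≥ 2 peaks flags a heterogeneous
  clone. Validation composes artificial heterogeneous clones as pixel
  unions of SPR × SPF well pairs.
- **Similarity index.** For each differentially expressed gene (fold
  change ≥ 2, Welch p < 0.05 in any of the three population pairs), the
  DP mean is placed on the SPR–SPF axis in log2 space:
  `s = 2·(DP − SPF)/(SPR − SPF) − 1`, so s = 1 means SPR-like and
  s = −1 SPF-like, binned at ±0.5 / ±1.5.
- **Transition frequencies.** Dye-labeled co-culture flow tables are
  quadrant-gated against naive-calibrated thresholds; per origin, the
  fraction gated into each destination state with binomial standard
  errors, and a chi-square homogeneity test across mixture ratios.

## Worked example

The `analysis/` scripts run the whole study on synthetic data
(`01_simulate.R` → `06_transitions.R`, writing tables under `results/`).
A condensed session:

```r
library(clonefate)

pop <- simulate_population(population_spec("Th17", n_clones = 300), seed = 1)
res <- classify_population(pop$traces)
round(prop.table(table(res$calls$fate)), 3)
#>    DN    DP   SPR
#> 0.171 0.205 0.624
```

With the default Th17 fractions (57 % SPR, 22 % DP, 21 % DN) the
end-of-experiment classification recovers the generating mix. Rise-time
summaries on a DP population (`summarize_rise_times(..., censored_at =
52)`) recover the onset distributions — e.g. RORγt 21.87 hr and Foxp3
38.61 hr (MLE means, `scripts/acceptance.R --seed 1`) against generating
means of 21.8 and 39.3 hr — and the Welch tests between SP and DP clones are
non-significant (p ≈ 0.24 and 0.81 in `analysis/02_classify.R`),
reproducing the independence of the two factors' timescales. The
trajectory stage prints a DP-versus-extrapolation normalized RMSD of
0.144 against a split-half null 95th percentile of 0.241 (the DP path is
indistinguishable from the single-positive extrapolation), the
heterogeneity stage finds 0 % multi-peak wells among homogeneous clones
with 100 % sensitivity on composed SPR × SPF pairs, and the transition
stage recovers SPR→DP ≈ 21–22 % and DP→SPR ≈ 14–16 % with no dependence
on the mixture ratio (chi-square p ≈ 0.3).

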