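---
title: "Models and methods behind clonefate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind clonefate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonefate)
```

`clonefate` analyses dual-reporter (RORγt→GFP, Foxp3→RFP) micro-well
time-lapse experiments at the clone level. This vignette documents the
models, the tunable parameters and their defaults, the numerical choices,
and what the synthetic-data generator does and does not emulate.

## The clone trace model

Each micro-well holds one founder cell and is imaged for 52 hr at 30-min
intervals (105 frames). Per channel `c`, the generator renders total well
fluorescence

    F_c(t) = baseline + amplitude_c · growth(t) · logistic((t − t50_c)/w) + ε_t,

with additive Gaussian trace noise `ε_t ~ N(0, noise_sd²)` and clipping at
zero. Three choices deserve comment.

**Onset parameterisation.** The clone parameter `onset_time_c` is defined
on the observable scale: it is the time at which the noise-free trace
reaches the naive-background detection level `baseline + 3·noise_sd`, and
the logistic midpoint `t50_c` is derived from it. The rise-time statistics
this field reports are threshold-crossing times, so the generator
parameter must be the same observable — otherwise every recovery check
would carry an amplitude- and noise-dependent offset that has nothing to
do with estimator quality. With `noise_sd = 0` the convention falls back
to the half-maximum, i.e. the onset is the sigmoid midpoint.

**Growth.** Cell divisions double a clone's signal capacity. `growth(t) =
2^d(t)` with `d(t)` piecewise-linear, reaching `k` at the k-th division
time and constant after the last one. The continuous form encodes two
facts at once: fluorescence is conserved when a cell splits between
daughters (no jump at the division itself), and total signal has doubled
by each division. One first-division time per clone is drawn by default
(`N(38.8, 5²)` hr under Th17, `N(36, 5²)` under Treg — the study reports
the medians and their standard errors; the 5-hr population sd is our
choice of a realistic spread). Division draws are *not* truncated at the
imaging end: they model manual-tracking annotations, not image-derived
quantities.

**Onset distributions.** Defaults are `N(21.8, 9.4²)` hr for RORγt and
`N(39.3, 8.2²)` hr for Foxp3, truncated at zero. Draws landing beyond the
imaging window simply never rise — end-of-experiment censoring, exactly
as in a real 52-hr experiment. The literature also quotes the same onset
means with standard errors (±0.06 / ±0.07 hr); the generator exposes the
distributions as plain `(mean, sd)` arguments so either reading can be
configured, and the sd interpretation is the default since it is the one
accompanied by a two-sample test.

## Threshold, rise time, classification

The response threshold is `mean + k·sd` of the t = 0 signals of filtered
wells (default `k = 3`; at least 10 wells). Wells enter the analysis only
if seeded with exactly one cell, at least one activation bead, and no
above-threshold fluorescence at t = 0. The rise time is the time of the
first frame opening a run of at least `persistence_frames = 2` frames
strictly above threshold — the persistence rule suppresses single-frame
noise crossings, and "first crossing" (rather than a fitted midpoint) is
used because the readout of interest is when expression becomes
detectable. Fates follow from which channels rise by the final frame:
both → DP, GFP only → SPR, RFP only → SPF, neither → DN. Endpoint MFI is
the mean total over the last 5 frames, matching the endpoint window used
by the pixel-angle analysis.

**Censoring-aware group means.** A 52-hr window right-censors late
risers: ~7 % of `N(39.3, 8.2²)` onsets fall beyond the last detectable
frame, so the plain mean of observed Foxp3 rise times systematically
underestimates the population mean by about 1 hr. `summarize_rise_times(
..., censored_at = 52)` therefore also fits a right-censored Gaussian by
maximum likelihood (`survival::survreg`), treating clones without an
observed rise as censored at the experiment end; its `mle_mean` is the
unbiased group summary and is what the recovery analyses report. The
observed-only mean/sd/median columns remain, as they are the quantities a
plain reading of endpoint data would give.

## Phase-space trajectories

Pointwise medians (± sd) of total fluorescence per fate group define the
group's path in the (Foxp3, RORγt) plane. The extrapolated trajectory
takes, at each time point, the SPF group's Foxp3 median as x and the SPR
group's RORγt median as y — the path a DP clone would follow if each
factor obeyed its single-positive dynamics independently. Agreement is
scored as

    d = RMS over t of ‖obs(t) − exp(t)‖  /  RMS over t of ‖exp(t)‖,

a dimensionless quantity, zero for identical paths and invariant to joint
rescaling. Because group medians at finite n are noisy, `d` is compared
against a split-half bootstrap null: the DP set is repeatedly halved and
the distance between half-medians recorded; a DP-versus-extrapolation
distance inside the null's 95th percentile is indistinguishable from
sampling noise. The absolute default threshold of 0.1 is retained as a
configurable convenience, but the null comparison is the statistically
meaningful readout. No time warping is applied — trajectories share the
acquisition grid by construction, and the question is precisely whether
the *timing* matches. Channels are not normalised before plotting; the
score's scale invariance makes this immaterial for the comparison.

## Pixel-angle heterogeneity

A well classified DP could contain true co-expressing cells or a mixture
of single-positive cells. Pixel angles distinguish the two: each pixel
above background maps to `θ = atan2(G, R)` in degrees (0° pure Foxp3,
90° pure RORγt, 45° balanced co-expression; pixels at exactly (0, 0)
are excluded rather than assigned an angle; angles are invariant to joint
positive rescaling of the two channels). Angles are pooled over the last
5 frames, histogrammed in 3° bins *centred* on 0°, 3°, …, 90° — so the
three anchor angles sit at bin centres — smoothed with a Gaussian kernel
(σ = 2 bins) with reflecting boundaries at 0° and 90°, and local maxima
counted. A peak must have topographic prominence at least 10 % of the
density maximum and lie at least 15° from any higher accepted peak
(greedy, highest first). Two or more peaks flag a heterogeneous clone;
counts are reported in 0 / 1 / 2+ categories.

Parameter notes, all config-exposed:

- **Intensity floor** (default 2·√2·pixel-background-sd of the combined
  channels): angles of near-background pixels are noise-dominated.
- **`min_pixels` = 20**: wells retaining fewer pooled pixels are flagged
  empty with zero peaks — a distribution cannot be assessed from a
  handful of noise pixels, and this guard prevents dark (DN) wells from
  producing spurious multi-peak calls.
- **Prominence 10 %**: calibrated on synthetic wells so that slow angle
  drift *within* the pooled endpoint window — a homogeneous clone whose
  second channel is still rising during the last 2.5 hr shifts its whole
  distribution — does not register as a second peak (such drift shoulders
  reach ~10 % prominence; genuinely mixed wells produce secondary modes
  of comparable mass, far above the cut). At this setting the false
  multi-peak rate on 400 homogeneous wells is below 1 % and sensitivity
  on composed SPR × SPF pairs is above 90 %.
- Histogram counts are unweighted; intensity weighting would couple peak
  shape to brightness differences between the mixed populations.

Artificial heterogeneous clones are framewise pixel unions of well pairs
from different fate classes. Pairs are composed only from wells that
individually retain ≥ 100 pixels — the analogue of pairing classified,
i.e. expressing, wells; a union whose dim partner contributes a handful
of pixels is not a meaningful two-population composite.

## Similarity index

On log2 expression with ≥ 2 replicates per population, genes
differentially expressed between any pair of SPR / DP / SPF (|mean
difference| ≥ log2(2), Welch p < 0.05, raw p by design — the selection
rule is a fold-change cut, not an FDR procedure) enter the index

    s = 2·(mean_DP − mean_SPF)/(mean_SPR − mean_SPF) − 1,

the linear placement of the DP mean on the SPR–SPF axis: s = 1 at SPR,
s = −1 at SPF, with bins [−1.5, −0.5) SPF-like, [−0.5, 0.5) intermediate,
[0.5, 1.5] SPR-like and beyond ±1.5 distinct. The index is undefined when
|SPR − SPF| < 0.25 log2 units (`denominator_floor`), where it would blow
up; such genes are binned "undefined". The index is invariant to adding a
constant to all three means and antisymmetric under swapping the SPR/SPF
labels. Genes with zero variance across both groups of a pair are handled
explicitly: identical means are excluded (p undefined), distinct
noise-free means separate perfectly. The t-test operates on the provided
expression matrix; count-based DE modelling upstream of that matrix is
out of scope.

## Transitions

Flow events are quadrant-gated against thresholds calibrated like the
imaging threshold (`mean + 3·sd` of a declared negative population).
Transition frequencies are per-origin destination fractions with binomial
standard errors `√(p(1−p)/n)`; origins are traced through a
proliferation-stable dye whose mapping to a population is a configuration
declaration, not hard-coded. Homogeneity across co-culture mixture ratios
is tested with a chi-square test plus the maximum absolute frequency
difference. Origin groups under 20 events are flagged low-confidence.

## What the generator does and does not emulate

It emulates: sigmoidal per-channel onset with population-specific onset
distributions, clone growth with division annotations, abstract per-well
pixel sets with independent Gaussian pixel noise, background pixels,
dye-labeled flow event tables with configurable transition probabilities,
and three-population expression tables with per-gene similarity classes
(defaults ~48 % SPR-like, ~30 % intermediate, ~20 % distinct, anchored at
s = 1 / 0 / −1 / ±2).

It does not emulate: spatial pixel layout (no downstream computation uses
it), cell death, asymmetric division, migration between wells, optical
artefacts (bleaching, focus drift, spectral bleed-through), flow
compensation or doublets, or count-level RNA-seq noise. Passing tests
therefore demonstrate that the estimators recover known parameters under
the stated noise model — not that they are robust to every artefact of
real microscopy data.

## Problem sizes and determinism

The standard analyses use 200–1000 clones per recovery question, 400
wells for detector specificity, 100 composed pairs for sensitivity,
250–400 clones per group for trajectory comparisons, 1500-gene expression
tables, and 4000–5000-event flow tables; each runs in seconds on one CPU.
All randomness flows from a single seed fanned out to per-stage child
seeds (`stage_seed()`), and identical seeds give bitwise-identical
outputs, including the pipeline's summary files.

## Known limitations

- The censored-Gaussian rise-time MLE assumes the latent onset
  distribution is Gaussian; heavy-tailed onset distributions would need a
  different parametric family.
- The peak detector's drift robustness is calibrated for the default
  steepness and endpoint window; much slower risers would warrant a wider
  window or time-resolved angle analysis.
- Trajectory comparison assumes a shared acquisition grid; experiments
  with dropped frames require resampling upstream.
- Treg-condition DP clones with low RORγt are not split into a separate
  class; a secondary "high" gate can be emulated by raising `k`.
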