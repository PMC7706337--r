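---
title: "Drought-stress phenotyping with an in-planta biosensor: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drought-stress phenotyping with an in-planta biosensor: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytosense)
```

This vignette documents the models, parameters and design choices behind the
package: what each pipeline stage computes, what the synthetic-data
generator does and does not emulate, and where the numerically delicate
decisions lie. It states no empirical result beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## Experimental designs

Two preset designs encode the emulated greenhouse trials, with day 0 at
bioristor implantation and all timestamps in minutes since implantation:

- **PILOT** (cv. Red Setter, 16 h photoperiod): 3 d settling, 14 d drought,
  2 d rewatering, 6 d second drought (25 d).
- **MAIN** (cv. Ikram, 12 h photoperiod): 1 d settling, 16 d drought with a
  single 50 cm³ limited irrigation, 7 d rewatering (24 d); imaging and
  physiology every 2 d.

The limited-irrigation day defaults to day 8. The published account is
ambiguous about its exact placement (a later passage associates the bump
with days 10–16), so it is a configurable schedule entry rather than a
constant. The drought window is the union of WITHHELD and LIMITED days; the
emergency irrigation does not terminate the stress block.

Phase labels derive from the schedule: PI before the first drought day, PII
from stress start, PIII from rewatering, PIV for a second drought block. DA
(the transient "drought avoidance" rebound) is a sub-window of PII whose
bounds only segmentation can fix.

## Sensor model and pipeline

**Response.** R = (I~ds~ − I~ds0~)/I~ds0~ per sample; samples with
|I~ds0~| < 10⁻³ µA are dropped and counted (the floor is arbitrary but
logged and configurable). R is invariant to common rescaling of both
currents, so drift of the baseline current cancels to first order.

**Daily means and NR.** Each 24 h window of the implantation clock is
averaged per plant (windows with under half the expected samples are flagged
and excluded); the day boundary is midnight of the implantation clock, a
convention the source account leaves open. NR is the ratio of stressed-group
to control-group mean daily R — a ratio of group means rather than a mean of
per-pair ratios, because no plant pairing is defined and group means are
robust to unequal group sizes. Days with a near-zero control mean are
masked, not extrapolated.

**Phase segmentation.** A continuous piecewise-linear model is fitted to NR
versus day; for each breakpoint count k (0–5) the optimal integer-day
breakpoints are found by exhaustive search (minimum residual sum of squares,
minimum segment length 2 d), and k is selected by BIC with 2k + 2
parameters (slopes, intercept and the break locations). Exhaustive search is
exact and affordable at daily resolution; the residual floor of 10⁻¹⁰ keeps
BIC finite on noiseless input, and ties resolve to the smallest k. Segments
are labelled by the design template phase containing their midpoint; a
segment with slope > 0.01 NR/day strictly inside the drought window is
relabelled DA. The slope threshold separates a genuine rebound from plateau
jitter.

**Onset detection.** The sub-daily NR series (stressed/control group mean
response per timestamp — the diurnal modulation is common to both groups
and cancels in the ratio) is scanned from stress start: at each grid time
the slope over the trailing 12 h window is tested one-sided against zero,
with the slope's standard error built from the pre-stress residual standard
deviation (up to 72 h of pre-stress data). Because the scan tests one window
per sample over a 72 h horizon, `alpha` is interpreted as a family-wise
level and Bonferroni-split over the number of grid points. This is
conservative for overlapping windows, which is the behaviour we want from an
early-warning test: the companion calibration (200 seeded replicates in the
acceptance suite) shows ≥ 90% of detections inside [30, 48] h under the
default effect size and ≤ 5% false detections under a null generator. A
per-window (uncorrected) reading of alpha would flag essentially every null
run within 72 h.

**Recovery deficit.** Mean NR over the PIII plateau (PIII minus its first
2 d of rewatering transient) divided by mean NR over PI. Values below 1
quantify irreversible damage. When the fitted segments absorb the 1-day PI
of the MAIN design into a longer first segment, the template windows are
used instead.

## Image rendering and analysis

The generator renders a parametric plant — a vertical stem with six
elliptical leaves of graded size (side views) and an eight-petal rosette
with a central crown disk (top view) — on a uniform mid-blue background,
8-bit, three views × RGB/NIR. The latent state maps to images as:

- side-view plant pixel count tracks projected biomass;
- vertical extent equals the latent height (the stressed height trajectory
  carries the full programmed deficit, wilting included — turgor drives
  leaf droop and the top-view spread, not the height, so the deficit is not
  double-counted);
- leaf droop angle grows as turgor falls, shrinking the top-view radial
  reach and thereby raising compactness;
- a fraction of plant pixels equal to the chlorosis state is coloured in
  the yellow hue band (lowest rows first, emulating older leaves);
- NIR leaf intensity is affine in hydration: 40 + 180·h on the 8-bit scale.

Segmentation keeps pixels whose hue lies in a configurable vegetation
window (default 20–180°, covering green, yellow and brown) with saturation
above 0.25 (RGB), or pixels brighter than the declared uniform background
(NIR), then retains the largest connected component (EBImage), which
removes salt noise. The synthetic background is deliberately unambiguous;
real phenotyping backgrounds (pot rims, soil, frames) are out of scope.

Index definitions and their numerical choices:

- **Biovolume** (A₀ + A₉₀ + log₁₀A~top~)/3. The published expression's
  third subscript omits the view angle; this implementation takes it as the
  top view, consistent with the cited three-view method, and the choice is
  configurable. A zero top area sets the log term to 0 and flags the value.
- **Height**: occupied row extent per side view (row 0 at image top), mean
  over available views; reported in pixel rows (no mm calibration exists).
- **Compactness**: pixel area over the convex-hull area of the polygon
  union of pixel squares (each pixel contributes its four corners), so a
  filled convex region scores exactly 1 — a hull over pixel centers would
  not. Computed on the top view by default ("how much of the hull area is
  covered by leaves" describes canopy closure); configurable.
- **Green index**: fraction of plant pixels with hue in [60°, 180°]. The
  greenness literature defines several fractions; the window is a config
  constant.
- **NIR index**: plant-pixel intensities histogrammed into 128 bins over
  [0, 256), bin-center weighted mean; equal to the plain mean within half a
  bin width (1 intensity unit).

## Physiology

RWC = 100·(FW − DW)/(TW − DW); fresh weights outside [DW, TW] are flagged
as measurement errors but still returned. "Relative SPAD" is interpreted as
the plant mean over the same-day control-group mean (the source does not
define the reference; normalization to day 0 is available by passing a
different reference). The SC fold change is control mean over stressed mean
per day. The generator synthesizes weights by fixing DW = 1 g and TW = 5 g
and inverting the RWC formula for FW — so the pipeline's RWC recovers the
programmed drop by construction plus replicate noise.

## Synthetic generator: what it emulates, and what not

One latent daily state per plant (projected biomass, height, hydration,
chlorosis, turgor, sap ion concentration) drives sensor, images and
physiology together, so cross-modal correlations such as R-vs-SC and
R-vs-biovolume are *emergent* from the shared latent state, never imposed
on the outputs.

Defaults encode the emulated study's conditions: 4 plants per group,
15 min sampling, baseline R = −0.5 with 15% diurnal modulation (sinusoid
clipped to the photoperiod; day samples more negative, night samples
higher), 30 h onset lag, NR decline of 0.12/day, a 2 d drought-avoidance
rebound regaining half the preceding decline starting stress day 4, an NR
plateau at 0.5 with a 0.05 bump at the limited-irrigation day, 70%
post-rewatering recovery, 15% height deficit reached by stress day 5,
4.5-fold SC reduction (the middle of the reported 4–5-fold range) during
stress days 7–14, 23% RWC drop at peak stress with full restoration, +5
SPAD units under stress, and Gaussian noise on currents and replicates (no
noise model is published; additive Gaussian is the neutral choice). The
ion response g(c) ∝ log₁₀(1 + c/c₀) is saturating and monotone — the
device is only reported to respond to all tested cations, so any monotone
map suffices — and the stressed ion trajectory is obtained by inverting g
at the programmed NR target, with fixed per-plant multiplicative effects
(size, ion level, hydration offset, baseline current) providing
between-plant variation. The unreported rebound amplitude defaults to 50%
of the preceding decline, configurable.

Not emulated: photorealistic canopies, 3-D structure and self-occlusion,
soil-water balance, device drift beyond a slow baseline trend, non-uniform
illumination, or real segmentation backgrounds. Passing tests therefore
demonstrate that the *pipeline* recovers known effects from data with the
right statistical structure — not that it would segment or calibrate real
platform imagery.

## Integrative statistics

The feature table holds one row per plant × imaging day with the six
variables C, GI, SC, R, NI, DB. R enters as the magnitude of the per-plant
daily mean response: the raw response is negative (a current-polarity
convention) and shrinks in magnitude under stress, and the published
positive associations with conductance and biovolume correspond to the
magnitude scale. SC joins from the nearest physiology day (≤ 1 d), R from
the nearest sensor day. Rows are restricted to imaging days from stress
start onward — for the MAIN design the 11 stress-period imaging days —
since pre-stress rows carry no treatment contrast; rows with missing values
are excluded and counted.

Correlations are pairwise-complete Pearson with t-based p values
(`stats::cor.test`). PCA standardizes the variables (correlation-matrix
PCA; the six variables have incommensurate units) via `stats::prcomp`;
variance explained sums to 100% and loadings are orthonormal. Per-timepoint
tests are equal-variance two-sample t or one-way ANOVA (identical for two
groups: F = t²), reported unadjusted as in the emulated study, with an
optional Benjamini–Hochberg switch. The star map defaults to the
conventional thresholds (∗ 0.05, ∗∗ 0.01, ∗∗∗ 0.001, ∗∗∗∗ 0.0001); an
inverted legacy map (∗∗ 0.05, ∗ 0.01) is available as a preset for
comparison with figure legends that use it. Cells with zero within-group
variance (possible under the null generator with noise switched off) yield
statistic 0 when the groups coincide, infinite when they are separated
point masses.

## Problem sizes and determinism

The test suite and the acceptance script run the MAIN design at its native
size: 8 plants, 24 d, 15 min sampling (18 432 sensor samples), 12 imaging
days × 6 images at 128 px, and 200 seeded replicates per arm for the onset
power/false-positive calibration; segmentation oracles use series of 10–20
days. Every stochastic step draws from a seed derived from the single
run seed (latent states, trace noise and physiology use fixed offsets of
it), and rendering is deterministic given the state, so identical seeds
give byte-identical CSVs, JSONs and PNGs; this is asserted in the tests.

## Known limitations

- Integer-day breakpoints: sub-daily phase boundaries are quantized; the
  onset detector, not the segmentation, is the sub-daily instrument.
- The Bonferroni onset correction is conservative; a sequential test (e.g.
  CUSUM-style) could detect marginally earlier at equal false-alarm rate.
- Compactness on small masks is grid-sensitive (the hull of few pixel
  squares is polygonal); values are exact but not rotation-invariant.
- The renderer's pixel-count-to-biomass proportionality degrades below
  ~100 px of leaf area per leaf (rasterization error is checked at ±5%
  under similarity scaling in the tests).
- With 4 plants per group the per-day tests are low-powered for subtle
  effects (GI early in stress); this mirrors the emulated experiment's
  size rather than a pipeline limit.
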