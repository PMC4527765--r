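---
title: "Methods: disentangling cell migration from membrane dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disentangling cell migration from membrane dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A migrating mesenchymal cell translocates by coordinating membrane
protrusion at its front with retraction at its rear, so cell speed and
overall membrane activity are strongly coupled. That coupling makes it hard
to tell whether a molecular feature — say, the paxillin content of adhesion
complexes, or an F-actin intensity statistic — tracks *migration* or
*membrane dynamics*, because any correlate of one is usually a correlate of
the other. `cmdyn` implements a statistical route around this problem that
needs no perturbation experiments: it quantifies both processes per cell
per time point, removes the linear dependence between them, and then asks
which features follow which residual axis.

## Membrane dynamics from mask series

The unit of input is a time series of binary segmentation masks of one
cell (default calibration 0.21 µm/pixel, 5 min/frame). Each pixel of the
focal frame is classified by its membership in the previous and next
frames, at actual positions — deliberately without aligning cell centres,
so that the regions reflect the motion of subcellular domains rather than
shape change alone:

| in previous | in next | label |
|---|---|---|
| yes | yes | stable |
| no  | yes | protrusion |
| yes | no  | retraction |
| no  | no  | short-lived |

The verbal definitions of protrusion ("absent in the previous frame") and
retraction ("absent in the next") overlap for pixels absent in both; the
membership-*pair* definition above resolves this by giving short-lived
pixels their own class, which forces the four categories to partition the
cell area exactly — a property the test suite asserts on every input, along
with its mirror image: reversing time swaps protrusion and retraction
labels and leaves the other two classes unchanged. Regions are plain pixel
sets; no connected-component filtering or minimum size is applied.

From the partition follow the per-frame process measures:

* **Dynamic Cell Area (DCA)** = protrusion + retraction + short-lived area
  (µm²);
* **ΔCell Area** = protrusion − retraction area, the net growth of the
  cell at that frame;
* **Cell Speed** = distance between the centres of area (unweighted
  foreground centroids — the masks are binary, so uniform weighting is the
  only defensible choice) of consecutive frames, divided by the frame
  interval (µm/min).

Because the three-frame comparison is undefined at sequence ends, the
first and last frame of every trace are excluded, as are frames adjacent
to segmentation gaps. `parse_validity()` applies the same rule to
already-tabulated observations.

## Corrected Membrane Dynamics

DCA and speed are strongly and approximately linearly coupled. A single
ordinary least squares line is fitted on all valid observations pooled
across cells (one global line, not per-cell fits — the relationship is a
population-level calibration):

$$\mathrm{DCA} = k \cdot \mathrm{speed} + m, \qquad
  \mathrm{CMD} = \mathrm{DCA} - k \cdot \mathrm{speed} - m.$$

CMD — Corrected Membrane Dynamics — is the residual: how much more (or
less) membrane a cell displaces than expected for its current speed. By
the OLS normal equations CMD has exactly zero mean and zero Pearson
correlation with speed, which the tests assert to 1e−10 relative; the more
interesting empirical property, also asserted, is that CMD *quintiles*
show no rank association with speed, so stratifying by CMD does not
smuggle speed back in. The fit is computed after the parsing exclusions,
since excluded frames have no defined DCA.

Two kinematic couplings complete the picture. ΔCell Area correlates
negatively with speed (slow cells tend to grow slightly; fast cells shrink
sharply), and the per-cell mean speed-autocorrelation coefficient
correlates negatively with mean speed (fast movement is transient).
Autocorrelation is computed per trajectory: missing speeds are replaced by
the trajectory mean, the series is mean-centred, and the lag-ℓ
autocovariance sum is divided by the lag-0 sum — the biased "coefficient"
normalization, chosen to match the convention of the common
cross-covariance routines; an unbiased per-lag-count variant is available
via `unbiased = TRUE`. The summary statistic averages lags 1–12 (one hour
at 5 min/frame); lag 0 is excluded because its value is 1 by construction
and would only shift, never reorder, cells. Trajectories shorter than
`max_lag + 1` frames or with zero variance are excluded with a warning;
the length threshold is exposed because no principled universal value
exists.

## Archetypes: the structure of feature-process relationships

For each process (speed, CMD) the valid observations are ranked into five
equal-count quintiles (ties broken by stable original order). Each of the
150 features is compared between quintiles 1 vs 3, 3 vs 5 and 1 vs 5 with
the two-sided Wilcoxon rank-sum test — exact enumeration for tiny tie-free
groups, otherwise the normal approximation with tie and continuity
correction. Raw p-values are Bonferroni-multiplied by the family size and
compared to 0.001. The family defaults to 3 × 150 = 450 *per process*,
matching the printed arithmetic of the procedure this package
operationalizes; a joint 2 × 450 family across both processes is available
through the `family` argument for sensitivity analysis.

The resulting significance triple maps to one of seven archetype
categories (plus "none"): all pairs distinct (a fully progressive,
near-linear response), plateau-early (1v3 and 1v5), plateau-late (3v5 and
1v5), extremes-only (1v5 alone — a weak but global trend), early-only,
late-only (each a single local contrast), and nonmonotone (1v3 and 3v5
significant but the extremes indistinguishable). The category captures
*where* differences arise; the sign of the response is reported
separately as the median-difference sign per pair.

## Two-step feature selection

Archetype testing is deliberately sensitive; the selection stage is
deliberately stringent, and asks which features are *specifically* related
to each process:

1. **Kruskal–Wallis** across quintiles 1/3/5 per feature (tie-corrected H,
   χ² with 2 df), Bonferroni family = 150 per process, adjusted P < 0.001.
2. **Canonical variate analysis (CVA)** of the same three groups over the
   full feature matrix. CVA solves the generalized eigenproblem
   $Bv = \lambda Wv$ with $B$ the between-group scatter and $W$ the pooled
   within-group scatter, via Cholesky reduction of $W$; at most two
   canonical vectors exist for three groups. Each feature's score is its
   sum of squared loads over the canonical vectors, and only the top half
   (75 of 150, inclusive at boundary ties) survives. This multivariate
   filter demotes features that are merely collinear passengers of a few
   strong axes.

A feature related to a process must pass both steps; the pass pattern over
the two processes classifies it as speed-only, CMD-only, both, or neither.

Two conventions in step 2 are genuinely open and are therefore explicit
options with documented defaults. Features are centred and scaled to unit
variance before CVA (`standardize = TRUE`): loads of raw features with
units as different as µm², minutes and dimensionless ratios are not
comparable, and ranking their squared sums would be meaningless without a
common scale. "Load" means the coefficient of the standardized feature in
the canonical vector; structure coefficients could be substituted by
post-processing the returned model, but coefficients are the default
because they are what defines the variate. When $W$ is not invertible
(possible on synthetic inputs with more features than observations) a
ridge of 1e−8 × mean diagonal is added with a warning.

## Cohort descriptors and standardization

Adhesion-complex (CMAC) features arrive as per-object records and are
summarized per cohort — the objects of one cell at one time point — by
quartile statistics: QD = (q₃ − q₁)/2 (semi-interquartile range),
QS = (q₂ − (q₁ + q₃)/2)/QD (Bowley skewness standardized by QD), and
CoV = QD/q₂, plus cohort sums and the mean object lifetime. The printed
source formulas for QD and QS are dimensionally inconsistent with their
own prose descriptions ("absolute variability", "asymmetry"); the standard
statistics above are what the prose describes, and a `literal = TRUE`
switch preserves the alternative operator placement for sensitivity
analysis. Quartiles interpolate linearly between order statistics
(`type = 7`, the common scientific default) — the convention matters only
for small cohorts and is configurable.

Intensities are made comparable across experimental repeats by dividing
each experiment's values by the median intensity of its smallest objects
(smallest 3 area-percentiles, the 0.15–0.2 µm² range in the original
data). Division rather than subtraction keeps ratio-type descriptors
coherent, and makes the operation idempotent: after one pass the reference
median is 1.

## The synthetic generator

Every stage is validated against data with known ground truth, generated
by two simulators.

**Mask movies** render a star-shaped cell (radius profile over 180 angular
bins) that translates at a nominal speed while persistent boundary bumps
appear at calibrated protrusion/retraction pixel rates, relax back toward
the resting radius, and a non-persistent smooth roughness term creates
short-lived pixels. A radial blob is the simplest shape family whose
protrusion and retraction pixel counts can be dialled independently while
guaranteeing a simply-connected mask. With all rates zero the cell is
rigid, so integer speeds yield exact mask translation — giving exact
expected values for speed and region tests.

**Observation tables** draw two independent latent processes. Latent speed
is heavy-tailed and positive: cell-level lognormal means (meanlog
log 0.15, sd 0.35) with within-cell AR(1) fluctuations on the log scale
(stationary sd 0.45), and AR persistence decreasing with the cell's mean
speed — so the generator reproduces, qualitatively, the observed
skewed speed distribution and the transience of fast migration. Latent CMD
is Gaussian (sd 50 µm²) and independent of speed by construction. Dynamic
Cell Area is k·speed + m + latent CMD with k = 400 µm² per µm/min and
m = 150 µm², chosen to give a speed–DCA correlation in the 0.6–0.7 range
typical of this kind of data; protrusion/retraction pixel counts split the
dynamic area with a noisy speed-dependent imbalance (protrusion fraction
0.55 falling to 0.37 across the speed range, observation noise sd 0.12),
so slow cells grow and fast cells shrink. Planted features apply archetype
response curves on the latent variable's quantile scale — linear ramps,
plateaus saturating at the 40%/60% boundaries, a symmetric triangular bump
for the non-monotone shape — scaled in units of the feature noise sd.

What the generator does *not* emulate: spatial structure of features,
inter-feature correlation beyond shared latents, measurement
heteroscedasticity, segmentation error, and the unknown true
distributional forms of real features (nothing is published about them).
Passing the recovery tests therefore demonstrates that the statistical
machinery is correct and well calibrated, not that real data satisfies its
assumptions.

## Problem sizes and numerical choices

The test-suite and analysis drivers use 100 cells × 50 frames (5000
observations) with 150 features, of which 5 speed-linked, 5 CMD-linked and
5 dual-linked at 5 sd effect — sizes at which the end-to-end class counts
are recovered exactly in ≥ 90% of seeded replicates, and comparable to the
scale of the original dataset (6419 observations). Property tests run
1000 random mask triples and 1000-replicate null calibrations of the rank
tests. All randomness flows from explicit integer seeds; fixed seed and
configuration give byte-identical pipeline reports.

Degenerate inputs are handled explicitly rather than silently: empty focal
masks, dimension mismatches and all-identical quintile variables are
errors; zero-variance trajectories and degenerate cohorts (QD = 0, q₂ = 0)
are flagged or excluded with warnings; an identically zero ΔCell Area
series (rigid translation) reports an undefined correlation rather than a
spurious one.

## Limitations

* Cell and adhesion segmentation/tracking are out of scope; masks and
  observation tables are consumed as produced upstream.
* The original imaging dataset is not redistributed here, so the
  published-data checks in the acceptance suite require the user to supply
  that table; all other validation is synthetic.
* Associations found by this pipeline are correlative by design; the
  method trades causal claims for freedom from perturbation artifacts.
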