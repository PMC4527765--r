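# cmdyn

Disentangling cell migration from membrane dynamics in live-cell imaging
data.

A migrating cell's speed and its overall membrane activity (protrusion and
retraction) are tightly coupled, so almost any molecular feature that
correlates with one also correlates with the other. `cmdyn` is for cell
biologists and image analysts who have per-cell, per-time-point
measurements — segmented cell masks and/or feature tables derived from
them — and want to know which features are *specifically* associated with
migration, which with membrane dynamics, and which with both.

## What it computes

**Membrane dynamics from binary masks.** Each pixel of a frame is
classified by its membership in the previous and next frames (at actual
positions, no centre alignment): stable (present in both), protrusion
(new, persists), retraction (old, disappears), or short-lived (present in
this frame only). The four classes partition the cell area exactly. From
them: Dynamic Cell Area (DCA, the non-stable area, µm²), ΔCell Area
(protrusion − retraction), and Cell Speed (centroid displacement per
frame, µm/min).

**Corrected Membrane Dynamics (CMD).** DCA depends approximately linearly
on speed. One pooled OLS fit

    DCA = k · speed + m,        CMD = DCA − k · speed − m

defines CMD as the residual — a speed-independent measure of how much
membrane a cell displaces relative to expectation for its speed (zero mean
and zero speed correlation by construction).

**Relationship structure (archetypes).** Observations are stratified into
quintiles of speed or of CMD; each feature is compared between quintiles
1 vs 3, 3 vs 5 and 1 vs 5 by two-sided Wilcoxon rank-sum tests with
Bonferroni correction (family 3 × 150 per process, adjusted P < 0.001).
The significance triple assigns each feature to one of seven archetypes —
fully progressive, plateauing early/late, extremes-only, single local
contrasts, or non-monotone.

**Specificity (two-step selection).** Per process, a feature must (1) pass
a Bonferroni-corrected Kruskal–Wallis test across quintiles 1/3/5 and
(2) fall in the top half of features ranked by sum of squared canonical
variate analysis (CVA) loads for the same groups. The pass pattern
classifies it as speed-only, CMD-only, both, or neither.

**Synthetic ground truth.** A mask-movie simulator (translating,
deforming radial blob with controllable protrusion/retraction pixel rates)
and an observation-table simulator (independent latent speed and CMD
processes with planted linear/plateau/non-monotone feature responses) make
every stage testable end to end.

## Worked example

```r
library(cmdyn)

plan <- default_archetype_plan(150, n_speed = 5, n_cmd = 5, n_both = 5,
                               effect = 5)
spec <- table_sim_spec(n_cells = 100, frames_per_cell = 50,
                       archetype_plan = plan, seed = 42)
report <- run_pipeline(list(table_spec = spec))
report
#> <run_report> 5000 observations (5000 valid), 150 features
#>   DCA = 390.49 * speed + 151.36  (r = 0.644)
#>   delta-area~speed r = -0.440; autocorr~speed r = -0.196
#>   related features: speed 10, cmd 10
#>   selection:  speed_only=5 cmd_only=5 both=5 neither=135
```

The fitted slope and intercept recover the generator's k = 400, m = 150;
the negative ΔArea–speed correlation says slow cells grow while fast cells
shrink; the negative autocorrelation–speed correlation says fast migration
is transient. The archetype stage finds exactly the 10 features planted on
each process (5 exclusive + 5 shared), and the two-step selection
classifies all 150 features without error (`report$confusion` holds the
ground-truth confusion table).

Mask movies work the same way:

```r
seq <- generate_mask_sequence(
  mask_sim_spec(n_frames = 10, grid_size = 96, speed_px_per_frame = 2,
                seed = 1))
d <- sequence_dynamics(seq)
round(d$speed[d$valid], 4)
#> [1] 0.084 0.084 0.084 0.084 0.084 0.084 0.084 0.084
```

— a rigid 2 px/frame translation at 0.21 µm/px and 5 min/frame is
0.084 µm/min, recovered exactly.

The `analysis/` directory contains the same workflow as numbered driver
scripts (`01_simulate.R` … `05_feature_selection.R`), each writing its
tables under `results/`.

## Documentation

The methods vignette
(`vignettes/membrane-dynamics-methods.Rmd`) describes the models, the
statistical conventions and their alternatives (Bonferroni family sizes,
quartile interpolation, CVA standardization and load definition,
autocovariance normalization), the synthetic generator's assumptions, and
known limitations.
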