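---
title: "Methods: behavioral phenotyping from home-cage and maze tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: behavioral phenotyping from home-cage and maze tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

phenocage implements the computational core of deep behavioral phenotyping
in mice: turning continuous position tracking from automated home cages and
standard maze tests into behavioral events, per-animal parameter registries,
task metrics and group statistics. The setting it targets is the comparison
of mouse models of Duchenne muscular dystrophy lacking one, several or all
brain dystrophin isoforms against wild-type littermates, but every operation
is generic over cohorts of tracked animals.

## Event model

A home-cage recording is a uniformly sampled (nominally 20 samples/s)
position trace over several days, starting at lights-off. Three event
layers are derived per animal:

* **shelter layer** — maximal runs of the body center inside the shelter
  zone;
* **locomotor layer** — outside the shelter, *movements* are runs with
  frame speed above `v_move` sustained for at least `min_move_dur`,
  bridged across sub-threshold gaps up to `merge_gap`; *arrests* are the
  complement;
* **activity layer** — movements merged across gaps up to
  `activity_merge_gap` form *activity bouts*.

Event times are end-exclusive on the frame grid, which makes the layers
exactly conservative: shelter time plus non-shelter time equals the trace
duration, and movement plus arrest time equals the non-shelter time. The
displacement of the final frame of a non-shelter span (which either
crosses into the shelter or is undefined at the trace end) is not counted
as locomotion; this is what keeps segmentation exact at low sample rates,
at the cost of at most a one-frame bias at shelter entries.

The speed and duration thresholds used by commercial tracking software are
not published, so all thresholds here are explicit configuration
(`segmentation_config()`), with conventional defaults: `v_move` = 2 cm/s,
`v_freeze` = 1 cm/s, `min_move_dur` = 0.5 s, `min_freeze_dur` = 1 s,
`merge_gap` = 0.5 s, `activity_merge_gap` = 5 s, proximity radius 2 cm,
keypoint confidence floor 0.6. Every downstream guarantee is either
threshold-agnostic or stated at these defaults. Tracking gaps up to 1 s
are linearly interpolated; longer gaps are reported by QC and split events.

## Mixture-derived behavioral thresholds

Sheltering and movement statistics are heavy-tailed mixtures of short and
long events, so per-animal thresholds are derived from Gaussian mixtures
fitted to log2-transformed values:

* shelter-visit durations (log2 s): 3 components; the **short-visit
  threshold** is the 90th percentile of the first (lowest-mean) component,
  `mu_1 + z_0.9 sigma_1`; the **long-visit threshold** is the crossing
  point of the weighted densities of the second and third components;
* movement distances (log2 cm): 2 components; the **long-movement
  threshold** is their crossing point;
* arrest durations: no mixture — the **long-arrest threshold** is the
  90th percentile of the raw durations (seconds, no log transform),
  using the nearest-rank convention for determinism and exact scale
  equivariance.

The fitting method behind the "curves fitted over a frequency plot"
description is not pinned down by the field's protocols; we use maximum
likelihood via EM on the raw log2 values (not a histogram least-squares
fit), with 10 seeded random restarts and a relative log-likelihood
tolerance of 1e-8, keeping the best restart. EM on the raw values is the
statistically standard estimator and yields the same intersections as any
curve drawn over the correctly normalized frequency plot. Components are
always reordered by ascending mean, so "first/second/third curve" is
well defined. The crossing point solves a quadratic on the log-density
scale; when no root falls between the two means (extreme weight
imbalance), the weight-weighted mean of the component means is returned
with a warning flag rather than an arbitrary root outside the bracket.
Fits on fewer than 30 events, or on degenerate (constant) input, return a
missing-flagged result instead of an error so that the registry can carry
the flag.

Whether mixtures should be fitted on day-3 events only or on all days is
genuinely open; the default pools all days per animal (more events for a
3-component EM at realistic visit counts) and is switchable
(`phenotype_config(pool_days = FALSE)`). Count, total, and switch
parameters are scoped to day 3, minimizing novel-environment effects.

## The 20-parameter registry

`compute_phenotype_vector()` always emits exactly 20 named parameters per
animal; inputs that cannot support a parameter (too few events for a
mixture, unobserved phases) yield a missing flag, never a dropped row.
The registry covers activity (total dark/light activity, mean bout
duration, habituation index, dark-light activity index), light-switch
reactivity (anticipation/response deltas for both switch directions),
sheltering (visit counts, both mixture thresholds, cumulative short- and
long-visit durations, shelter-time fraction) and movement/arrest patterns
(movement threshold, long-movement fraction, arrest threshold, mean
long-arrest duration, long-arrest count). The deep-phenotyping literature
names roughly 14 of these explicitly; the remainder complete the
conventional count of 20 and are flagged `registry_completed` in the
output so downstream analyses can distinguish them.

Two derived indices deserve their definitions spelled out:

* **habituation index** = total dark-phase-3 activity / total
  dark-phase-1 activity; 1 means no habituation, below 1 means less
  activity on the third night;
* **switch deltas** = mean hourly activity in the 2-h window before
  (anticipation) or after (response) a light switch, minus the baseline
  of the original phase, defined as the mean of its hours 8, 9 and 10.

## Task metrics

Recognition and sociability tests reduce to the discrimination index
DI = novel / (novel + familiar) interaction time, with chance 0.5;
probe trials in quadrant-divided arenas report relative path length and
time per quadrant with chance 0.25, plus the cumulative path length to
the first target entry (the standard replacement for latency when groups
differ in locomotion speed). Interaction is scored from pose keypoints as
the nose being within a proximity radius of the object or hole boundary;
frames below the confidence floor are excluded from both numerator and
denominator. Quadrants are half-open at the axes so the four quadrants
exactly partition the arena and relative distances sum to exactly 1.

The cognition-wall task is scored per entry, not per time: entries are
classified against the daily target as correct, perseverative (the
previous day's target — undefined on the first day and while the target
repeats, in which case errors are neutral) or neutral, and fractions are
reported in consecutive non-overlapping 50-entry bins, with the trailing
partial bin carrying its own size. Group-average curves honor the
convention of displaying only bins where more than 3 animals still
contribute. The pellet replay dispenses one pellet per five cumulative
(not necessarily consecutive) correct entries; the counter resets at
each daily target switch by default, since rewards are tied to the day's
target entrance, with carry-over available as an option.

## The statistical ladder

Group comparisons follow a normality-gated ladder: Shapiro-Wilk per group
at alpha = 0.05; one log10 attempt when any group fails (the data are not
otherwise transformed — the gate only chooses the path); then either
one-way ANOVA with Tukey post-hoc, or Kruskal-Wallis followed — only on a
significant omnibus — by pairwise Mann-Whitney tests, reported unadjusted
to match the described procedure (BH adjustment is available as an
option). With a designated control group, the pairwise set follows the
pooling design of littermate-control studies: every model is compared
against the pooled control, and model-vs-model comparisons are included
only when at least one model differs from control. Chance-level tests are
one-sample t or Wilcoxon signed-rank against the chance constant;
alternation counts use the uncorrected Pearson chi-square; the
spontaneous-behavior family is FDR-corrected with Benjamini-Hochberg
(the specific FDR variant used by practitioners varies; BH is the
documented default here, not a claim about any particular study).

The **WT-pooling consistency filter** guards against false positives that
exist only by virtue of pooling heterogeneous wild-type subgroups: a
parameter is excluded exactly when the WT subgroups differ among
themselves, some model is significant against the pooled WT, and no such
model is significant against its own littermate WTs.

Time-course analyses (behavior over time bins) are deliberately not
re-implemented: the package exports tidy per-bin tables, and linear mixed
models belong to an established backend (`lme4`/`lmerTest`).

## The synthetic-behavior generator

No public per-animal tracking data exist for this kind of study, so the
package carries a first-class generator whose output has exact ground
truth. Its structure mirrors what the analysis assumes:

* the animal alternates shelter visits (durations from the 3-component
  log2 mixture; default weights 0.3/0.4/0.3, means 4/7/11 log2-s, sds
  0.5) with out-of-shelter periods (exponential, phase-dependent entry
  rate — a field the generator needs but the phenotyping protocol does
  not state; defaults 4/h dark, 7/h light);
* activity bouts arrive within out-periods as a Poisson process with
  phase-dependent rate (defaults 16/h dark, 5/h light), multiplicatively
  modulated in the 2-h anticipation/response windows around switches;
* a bout is a run of movements (distances from the 2-component log2
  mixture, defaults means 2.5/5.5 log2-cm) separated by short uniform
  arrests whose range sits strictly between the merge gap and the
  activity merge gap, so bouts reassemble exactly;
* movements are correlated random walks whose every frame step is exactly
  `distance / frames`, bounded away from walls and the shelter, keeping
  the per-frame speed constant and above the detection threshold
  (requiring `sample_rate >= 2` at default thresholds).

These distributional families (Poisson arrivals, lognormal bout
durations, uniform intra-bout gaps) are modeling choices — real mouse
behavior does not come with published true distributions — and the
defaults were picked once as field-plausible values yielding realistic
event counts (roughly 60 shelter visits and several hundred movements per
simulated day). Everything is driven by explicit integer seeds with no
global RNG state, so identical specs reproduce bit-identical cohorts.
What passing tests on generator output demonstrate is therefore internal
correctness (exact event recovery, threshold recovery, calibrated error
rates), not fidelity to any particular real dataset: the generator has no
positional jitter by default, no identity switches, no grooming-like
micro-movements, and its shelter transitions are instantaneous.

Probe trials are simulated as isotropic correlated random walks with a
reflective circular boundary started at the center, making the expected
relative path length per quadrant exactly the chance level 0.25 by
symmetry.

## Numerical choices and degenerate inputs

* Zone membership is decided on point positions; zones are closed
  (boundary counts as inside), except between quadrants, which are
  half-open so they partition the arena.
* Displacements are attributed to the zone of their starting sample.
* Nearest-rank percentiles; EM restarts seeded from a deterministic
  child-seed scheme; component order fixed by ascending mean.
* Constant data in a statistical test yields a flagged degenerate result
  with p = 1 rather than an error; all-equal mixture input and undersized
  samples yield missing flags.
* Recordings shorter than three dark phases flag the habituation and
  unavailable switch parameters as missing and scope day-bound parameters
  to the last fully observed day, so the registry always has 20 rows.

## Problem sizes

The shipped test-suite and reproduction script run at desk scale by
design: synthetic home-cage traces at 2-5 samples/s over 1-3 days
(segmentation and conservation are rate-independent properties), mixture
recovery on 50 animals of 1,000 visits each, ladder calibration on 2,000
replicates of 4 x 15 animals, and 500 probe trials of 60 s at
20 samples/s. These sizes were chosen so each property is measured with
comfortable statistical margin.

## Known limitations

* The package consumes keypoint tables; it does not do pose estimation,
  video processing or multi-animal tracking.
* Correlations against human scorers cannot be reproduced without the
  original videos; interaction scoring is validated against scripted
  synthetic sessions instead.
* The exact thresholds inside commercial tracking software are unknown;
  analyses that depend on them should treat `segmentation_config()` as
  part of the experiment definition.
* Statistical comparison of whole learning curves between groups is not
  prescribed here; the per-bin tables are exported for whichever
  curve-level test the analyst prefers.
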