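# phenocage

Deep behavioral phenotyping of mice from automated tracking data.

Behavioral characterization of mouse disease models — the motivating case
is models of Duchenne muscular dystrophy missing one, several or all brain
dystrophin isoforms — increasingly relies on continuous home-cage tracking
and batteries of maze tests. The raw material is always the same: uniformly
sampled position traces, pose keypoints, and entry logs. phenocage turns
those into the quantities such studies report, for anyone analyzing
PhenoTyper-style home-cage recordings or standard maze tests in R:

* **event segmentation** — movements, arrests, shelter visits and activity
  bouts from a position trace, with exact time conservation across layers;
  freezing percentages in 60-s bins.
* **mixture-derived thresholds** — per-animal behavioral thresholds from
  Gaussian mixtures on log2-transformed statistics: the short
  shelter-visit threshold (90th percentile of the first of three fitted
  components, μ₁ + z₀.₉σ₁), the long shelter-visit threshold (crossing
  point of the second and third weighted component densities), the long
  movement threshold (crossing of a two-component fit), and a
  nearest-rank 90th-percentile arrest threshold.
* **a 20-parameter spontaneous-behavior registry** per animal: activity
  totals, the habituation index (dark-phase-3 / dark-phase-1 activity),
  anticipation/response activity deltas around light switches (2-h
  windows minus the hours-8–10 baseline of the original phase),
  sheltering and movement/arrest parameters.
* **task metrics** — discrimination indices DI = novel/(novel+familiar)
  with chance 0.5, T-maze alternation, probe-trial quadrant metrics with
  chance 0.25, distance-to-first-target-entry, keypoint-proximity
  interaction scoring, and per-50-entry learning curves
  (correct/perseverative/neutral) with the 5-correct-entries pellet
  replay for the cognition-wall task.
* **the statistics ladder** — Shapiro-gated ANOVA+Tukey vs
  Kruskal–Wallis+Mann–Whitney with a control-pairing rule, chance-level
  tests, chi-square on alternation, Benjamini–Hochberg FDR, and the
  wild-type-pooling consistency filter.
* **a synthetic-behavior generator** with exact ground truth (event logs,
  mixture components, agent parameters), making every stage verifiable
  without raw videos.

See `vignettes/phenocage-methods.Rmd` for the model and all numerical
choices.

## Worked example

Simulate one animal's 3-day home-cage recording, compute its phenotype
registry, and score a probe-trial cohort against chance:

```r
library(phenocage)

spec <- homecage_sim_spec(duration_days = 3, sample_rate = 5, seed = 11)
events <- simulate_homecage_events(spec)
pv <- compute_phenotype_vector(events)
pv[c(4, 11, 12, 14, 16), ]
#> # A tibble: 5 × 6
#>   parameter                  value units   phase missing registry_completed
#>   <chr>                      <dbl> <chr>   <chr> <lgl>   <lgl>
#> 1 habituation_index_dark      1.08 ratio   dark  FALSE   FALSE
#> 2 short_shelter_threshold     4.70 log2_s  both  FALSE   FALSE
#> 3 long_shelter_threshold      9.04 log2_s  both  FALSE   FALSE
#> 4 cum_long_visit_duration 39096.   s       both  FALSE   FALSE
#> 5 long_movement_threshold     3.73 log2_cm both  FALSE   FALSE

discrimination_index(novel_seconds = 62, familiar_seconds = 38)$di
#> [1] 0.62

trials <- simulate_probe_trials(100, seed = 2)
rel <- vapply(trials, function(tr) {
  qm <- zone_metrics(tr)
  qm$relative_distance[qm$zone == "NE"]
}, numeric(1))
chance_test(rel, chance = 0.25)$p
#> [1] 0.1745
```

The habituation index of 1.08 says this simulated animal was about as
active on its third night as its first (no habituation, as expected under
the generator's stationary rates). The shelter thresholds are on the log2
scale: visits longer than 2^9.04 s ≈ 8.8 min count as long visits, and
this animal accumulated ~39,100 s of them on day 3. The unbiased probe
cohort does not differ from the 0.25 chance share of the target quadrant
(p = 0.17), as it must for an isotropic walk.

A full cohort run — traces on disk, a YAML config, phenotype + learning +
statistics tables — is two calls (or the bundled
`inst/scripts/phenocage` CLI):

```r
cfg <- generate_fixtures("cohort_dir", seed = 1)   # 4 groups x 4 animals
report <- run_pipeline(cfg)
write_report(report, "cohort_dir/report")
```

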