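# shoalnoise

Quantifying how anthropogenic underwater noise changes the structure and
dynamics of fish shoals.

Playback experiments of this design film a small group of fish (here,
four juvenile European sea bass in a 105 cm octagonal arena) for two
consecutive periods: a silent first half and a second half during which a
sound — either ambient coastal noise as a control, or impulsive
pile-driving noise — is played back. Video tracking yields each fish's
(x, y) position per frame, and the scientific questions are whether the
playback makes shoals **less cohesive**, **less directionally ordered**,
and **less coordinated**, and whether pile-driving does so more than the
ambient control.

`shoalnoise` implements that analysis end to end for researchers in
collective animal behaviour and bioacoustics:

* **Trajectory handling** — CSV input (`frame,fish_id,x,y`), pixel→cm
  conversion, validation against the trial design, repair of short
  tracking gaps by linear interpolation, and segmentation into the two
  trial halves.
* **Kinematics** — per-fish speed and unit-heading series by central
  differences on boxcar-smoothed positions.
* **Shoal structure** — distance to the shoal centroid, modal
  nearest-neighbour distance (NND), bearing angle to the nearest
  neighbour (0° = dead ahead, 90° = beside, 180° = dead behind, split
  front/behind), absolute perpendicular and parallel neighbour offsets,
  heading difference (0° = aligned … 180° = opposed), and the
  Gaussian-smoothed relative neighbour-position density map.
* **Movement dynamics** — speed and direction cross-correlations between
  a fish and its modal nearest neighbour over each half:
  `C_speed(τ) = cor(v_i(t), v_j(t+τ))` and
  `C_dir(τ) = ⟨ĥ_i(t)·ĥ_j(t+τ)⟩`, with the peak correlation and the time
  delay at the peak (positive delay: fish *j* follows fish *i*).
* **Synthetic shoals** — a zonal (repulsion / alignment / attraction
  shells) agent-based simulator with individual and group heterogeneity,
  a designated follower with a known time lag, and a parameterised
  playback disruption, so every stage can be tested against ground truth.
* **Inference** — per-fish-per-half responses analysed with
  treatment × trial-half mixed models: LMMs (log10 for distances,
  log10(1−r) for correlations, untransformed speed and delay) and
  negative-binomial GLMMs (variance μ(1 + μ/k)) for the right-skewed
  angle/offset measures; random intercepts for trial, trial-half and
  fish-within-trial; an exact split-plot F test for the interaction;
  the interaction-pruning rule; Pearson-dispersion checks (pass when
  between 0.5 and 2); speed-covariate refits; and Cohen's-d effect sizes
  of the playback-induced change computed at trial level.

## Worked example

```r
library(shoalnoise)

# one simulated trial: 4 fish, 60 s silence then 60 s pile-driving playback
cfg <- sim_config(seed = 42, disruption = pile_driving_disruption(),
                  treatment = "pile_driving")
trial <- simulate_trial(cfg)
responses <- fish_half_summaries(trial$dataset)
responses[, c("fish", "half", "modal_nnd", "mean_heading_diff",
              "median_speed", "max_dir_corr")]
```

```
  fish   half modal_nnd mean_heading_diff median_speed max_dir_corr
1    1  first      6.25              13.9        14.68        0.945
2    2  first      5.75              11.8        11.16        0.956
3    3  first      5.75              10.9        13.24        0.964
4    4  first      6.25              14.9        15.29        0.945
5    1 second      8.75              45.5         6.90        0.656
6    2 second      8.25              41.4         5.03        0.726
7    3 second      8.25              36.5         6.65        0.726
8    4 second      8.25              44.3         7.53        0.615
```

During the playback half this shoal spreads out (modal NND rises from
about 6 to 8.5 cm), loses directional order (mean heading difference
rises from about 13° to 42°), slows to half its speed, and its
nearest-neighbour direction correlations fall from about 0.95 to 0.68 —
the pattern a strong disruption should produce.

The numbered drivers under `analysis/` run the whole study:
`01_simulate.R` (30 trials, paired random blocks), `02_metrics.R`
(response table + relative-position map), `03_models.R` (mixed models,
pruning, dispersion, effect sizes), `04_calibration.R` (type-I error and
ground-truth recovery). Each writes its tables under `results/`.

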