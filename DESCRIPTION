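Package: shoalnoise
Title: Shoal Structure and Dynamics Under Sound-Playback Treatments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the spatial and directional organisation and the
    movement dynamics of small fish shoals from 2-D video-tracking
    trajectories, and tests how these measures change when a sound playback
    starts. Provides trajectory reading, gap repair and trial-half
    segmentation; per-fish speed and heading series; cohesion and alignment
    metrics (centroid distance, modal nearest-neighbour distance, bearing
    angles, perpendicular/parallel offsets, heading differences, relative
    neighbour-position maps); nearest-neighbour speed and direction
    cross-correlations with peak and time delay; a zonal shoal simulator
    with a playback-disruption phase and known ground truth; and nested
    mixed-model inference (linear mixed models and negative-binomial
    generalized linear mixed models) on per-fish-per-half summaries with
    the transformation, interaction-pruning, dispersion-check and
    effect-size-of-change procedures used in playback experiments.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    lme4,
    lmerTest,
    glmmTMB,
    MASS,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
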