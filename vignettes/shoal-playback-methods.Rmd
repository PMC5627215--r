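---
title: "Measuring shoal structure and dynamics under sound playback: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring shoal structure and dynamics under sound playback}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shoalnoise)
```

## The experimental design this package analyses

A group of four fish swims in an octagonal arena (narrowest width
105 cm). Each trial has two consecutive halves: a first half with no
playback, then a second half during which a sound is played — ambient
coastal noise (control) or impulsive pile-driving noise. Fifteen groups
receive each treatment, assigned in paired random blocks (every
consecutive pair of trials contains one of each treatment in random
order), and every fish is tested once. Video tracking provides per-frame
(x, y) positions per fish.

Treatment is therefore a *between-group* factor, trial half a
*within-group* factor, and the scientific effect of interest is their
interaction: did the playback change the shoal more under pile-driving
than under the ambient control?

## Response measures

For every fish in every half the package computes:

*Cohesion* — mean distance to the shoal centroid (the arithmetic mean
position of the tracked fish per frame; frames with fewer than two
tracked fish are skipped and counted), and the modal nearest-neighbour
distance: the centre of the maximal bin of a fixed-width histogram
(default 0.5 cm, ties to the smaller distance). A histogram mode was
chosen over a kernel density because its tie rule and bin placement are
exactly reproducible.

*Structure* — the bearing angle from the focal fish's heading to its
nearest neighbour, folded to [0°, 180°] (left–right symmetry assumed)
and split at 90° into neighbours in front (`bearing < 90`) and behind;
absolute perpendicular and parallel offsets of the neighbour across and
along the focal heading (their signed means vanish by symmetry, so
absolute values carry the information; note `perp² + para² = nnd²`); and
the unsigned heading difference between the pair. Nearest neighbours are
re-assigned every frame, with ties going to the lower fish id. The
pooled relative neighbour-position map is a 2-D histogram in the
focal-centred, heading-aligned frame (default 1 cm cells, ±30 cm),
normalised to a probability mass function and smoothed with a Gaussian
filter of σ = 6 cells; the truncated convolution is renormalised so the
total mass is preserved.

*Dynamics* — speed and heading come from central differences of
boxcar-smoothed positions (window 5 frames; at 15 fps and above, raw
pixel jitter otherwise dominates heading estimates), with one-sided
differences at endpoints and next to tracking gaps. Headings are only
defined where speed reaches 0.5 cm/s — below that the travel direction
is jitter. Cross-correlations are computed once per half against the
*modal* (most frequent) nearest neighbour, so each fish contributes one
uninterrupted pair series per half rather than fragments from per-frame
re-pairing: Pearson correlation per lag for speeds, mean dot product of
unit headings per lag for direction, over a ±2 s window with at least
100 overlapping frames per lag. The peak is the maximum of the curve
(not the maximum absolute value) and the delay is the lag at the peak;
ties go to the smallest absolute delay, negative before positive. A
positive delay means the partner follows the focal fish. Speed delays
are computed but excluded from inference — speeds are strongly
correlated at near-zero delay, so their delays carry no signal — while
direction delays are analysed.

## The synthetic-shoal generator

No public trajectory data accompany this experimental design, so the
package ships a zonal agent-based simulator that reproduces the design's
statistical structure with known ground truth. Each fish reacts to
groupmates through three disjoint shells: hard repulsion inside 6 cm
(about one body length — fish do not overlap), alignment with neighbours
between 6 and 20 cm, and attraction towards the centroid of neighbours
between 20 and 40 cm. The disjoint-shell form matters: if attraction
also acted on close neighbours it would compete with alignment inside a
tight shoal, making cohesion and polarization antagonistic, which is the
opposite of how disturbed shoals behave. The steering blend also
contains a heading-persistence (inertia) term with weight 0.5; it gives
the social weights an absolute scale (a normalised blend would cancel
the alignment weight whenever alignment is the only active term).

Speeds are an AR(1) deviation (persistence 0.9 per frame, innovation
1.5 cm/s) around a preferred speed of 10 cm/s (≈1 body length/s for a
10 cm juvenile), with each fish's deviation pulled towards its
groupmates' (coupling 0.5) — this is what gives nearest-neighbour speed
*correlations* that a disruption can degrade. One designated fish (the
follower, id 4 by default) reads the group's headings with a 3-frame
delay, planting a known time lag for the direction cross-correlation to
recover.

Real shoals are heterogeneous, and the mixed models' random intercepts
exist precisely to absorb that heterogeneity, so the generator includes
it explicitly: per-fish preferred speeds (log-normal CV 0.15), a shared
per-trial speed factor (CV 0.10), a shared per-trial noisiness factor
(CV 0.30), per-trial characteristic spacing (CV 0.20 on the repulsion
radius), and slow per-fish behavioural-activity states (log AR(1),
correlation time 20 s, CV 0.30) that modulate the noise terms within a
trial. Without the between-unit terms every fish is statistically
identical, the random-effect variances are all zero and the
negative-binomial family degenerates; without the within-fish activity
states the half-to-half variation of per-fish summaries falls below what
any count model allows.

Trials run at desk scale by default — 15 fps and 60 s halves, after a
10 s acclimation burn-in that is simulated and discarded (mirroring the
acclimation period of the live protocol; without it the initial
transient makes the two halves distinguishable even with no playback) —
and the full-scale design (59 fps, 300 s halves) is available by
configuration. The arena boundary deflects the desired heading towards
the arena centre inside an 8 cm buffer; deflection rather than
reflection avoids speed artefacts at walls that would contaminate the
speed correlations.

During the playback half a `disruption_spec` multiplies the preferred
speed, the alignment weight (and speed coupling), the attraction weight,
and the noise scales. Falling cohesion also enlarges the personal-space
radius (`r_rep / sqrt(attraction_mult)`): disturbed fish keep larger
inter-individual distances, and this is what moves the *modal*
nearest-neighbour distance, which tracks typical spacing and is nearly
insensitive to attraction and noise alone. The default calibrations are

* ambient: speed ×0.9, alignment ×0.95, attraction ×0.95, noise ×1.1 —
  a mild, control-sized perturbation;
* pile-driving: speed ×0.6, alignment ×0.3, attraction ×0.4, noise ×1.8
  — chosen once from a response-surface probe of the half-2 minus half-1
  deltas so that the playback half shows the joint pattern disturbed
  shoals show (spacing and heading difference up, speed and both
  cross-correlations down), clearly stronger than the ambient control.

The simulator uses R's RNG throughout (including inside the compiled
core), so a seed makes whole experiments bit-reproducible.

## Statistical models

Each response is analysed with treatment (between), trial half (within)
and their interaction as fixed effects. Distance measures are log10
transformed; the maximum speed and direction correlations are
transformed as log10(1 − r); median speed and the direction delay are
untransformed. The right-skewed angle and offset measures use
negative-binomial GLMMs (log link, variance μ(1 + μ/k)) after
integerisation — degrees for angles, millimetres for offsets — since a
count family needs counts; the unit is recorded in the fit.

Random effects are intercepts for trial, for trial-half, and for fish
within trial. The trial-half term is the classical split-plot
"whole-plot error": the four fish of a trial share group-level
fluctuations between halves, and omitting it referred the interaction
test to the wrong stratum (pilot null simulations showed rejection rates
up to 0.42 at nominal 0.05). The interaction *test* itself is the exact
balanced split-plot F: trial-mean half-differences compared between
treatments (F with 1 and n_trials − 2 df), which remains exact even
where fish changes are *negatively* correlated within trials — true for
centroid distance, whose per-fish values are deviations from the
group's own mean and must balance; no variance-components model can
express that, and Satterthwaite tests there were conservative to the
point of never rejecting. The df method is recorded in every fit. With
the speed covariate requested, the trial-mean speed change joins the
whole-plot regression, and the fish-level median speed joins the LMM
fixed effects.

A non-significant interaction (p ≥ 0.05) is pruned and the model refit
with main effects only; reported fixed effects then come from the
refit. For the NB GLMMs the interaction is a likelihood-ratio χ² between
the nested fits. Underdispersed responses push the NB shape to its
k → ∞ (Poisson) boundary where the Hessian degenerates — bearing angles
are scale-free geometry and sit there under any generator — in which
case both nested models are refit with the shape pinned at a large value
and flagged `shape_boundary`; a converged fit whose Hessian is non-PD
because a variance component sits on its zero boundary is flagged
`singular`, the GLMM analogue of a singular LMM fit, rather than
erroring. The dispersion check refits the fixed-effects-only NB GLM and
reports Pearson χ²/df, passing between 0.5 and 2.

Effect sizes of the playback-induced change are Cohen's d between
treatments on the change score (half 2 minus half 1), aggregated to
trial means first because fish within a trial are not independent;
positive d means pile-driving increased the response more than ambient.
No multiplicity correction is applied across responses.

## Numerical choices and degenerate inputs

Tracking gaps up to 30 frames (≈0.5 s at 59 fps) are linearly
interpolated; longer or edge gaps stay missing and every metric skips
missing frames pairwise. Correlation lags whose overlap is shorter than
the minimum, or where a series is constant, are dropped; if all lags
drop, the pair errors. Bearing ties at exactly 90° go to "behind"
(front is the half-open [0°, 90°)); modal-NND bin ties go to the
smaller distance; cross-correlation peak ties go to the smallest |lag|,
negative first. Trajectory CSVs are written with 17 significant digits
so a read–write–read round trip is bit-exact.

## Problem sizes used by the checks

The test suite and the acceptance script run the full 15 + 15-group
design at desk scale (15 fps, 60 s halves): null-calibration checks use
200 replicate experiments, the qualitative-pattern check 25 replicates,
ground-truth recovery 20 seeds, and oracle-equivalence checks 50 random
series pairs. These sizes give binomial standard errors of ~1.5% on
rejection rates while keeping a full run in minutes.

## What passing tests do and do not show

The simulator emulates the *statistical structure* of the design —
group sizes, halves, block randomisation, heterogeneity between fish and
groups, a known follower lag, and treatment-dependent disruption — not
the sensory physiology of fish hearing, the acoustic field of the arena,
hydrodynamic interactions, or tracking-identity errors. Passing tests
show that the measures, the estimators and the inference machinery do
what they claim on data with known ground truth and that the whole
pipeline recovers planted effects in the right direction at the right
error rates; they do not validate any biological claim about real sea
bass, and analyses of real trajectories inherit whatever tracking errors
(notably identity swaps, which the package does not attempt to correct)
survive upstream.

## Known limitations

Velocity bearing stands in for body orientation, since only centroid
tracks are available; at near-zero speeds direction is undefined and
those frames are excluded from direction-based metrics. The NB family on
integerised continuous summaries follows the field's practice but is
approximate, and for scale-free angle measures it reduces to its Poisson
boundary. Arithmetic (not circular) means summarise folded angles,
which is adequate away from the 0°/180° boundaries. The simulator's
disruption calibration is a free parameter of the generator, not an
estimate from data: only the signs and the ordering of effects between
treatments are meaningful.
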