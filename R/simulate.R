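#' Playback-disruption specification
#'
#' Multipliers applied to the simulator during the playback (second) half
#' of a trial: preferred speed, alignment weight (and speed coupling),
#' attraction weight, and the turning/speed noise scales. The identity
#' spec (all 1) leaves the second half statistically identical to the
#' first.
#'
#' @param speed_mult,alignment_mult,attraction_mult,noise_mult Positive
#'   scalars.
#' @return A `disruption_spec`.
#' @export
disruption_spec <- function(speed_mult = 1, alignment_mult = 1,
                            attraction_mult = 1, noise_mult = 1) {
  v <- c(speed_mult = speed_mult, alignment_mult = alignment_mult,
         attraction_mult = attraction_mult, noise_mult = noise_mult)
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop("all disruption multipliers must be positive")
  }
  structure(as.list(v), class = "disruption_spec")
}

#' Default ambient-playback disruption
#'
#' Mild disruption: playback of familiar coastal sound still perturbs the
#' shoal, but weakly.
#' @export
ambient_disruption <- function() {
  disruption_spec(speed_mult = 0.9, alignment_mult = 0.95,
                  attraction_mult = 0.95, noise_mult = 1.1)
}

#' Default pile-driving disruption
#'
#' Strong disruption: impulsive noise slows the fish and degrades both
#' cohesion and coordination much more than the ambient control.
#' @export
pile_driving_disruption <- function() {
  disruption_spec(speed_mult = 0.6, alignment_mult = 0.3,
                  attraction_mult = 0.4, noise_mult = 1.8)
}

#' Shoal-simulation configuration
#'
#' Zonal shoaling model of a small group in a convex arena. Defaults give
#' the desk-scale version of the experimental design: 4 fish, two 60 s
#' halves at 15 fps in a 105 cm octagon (the full-scale design - two
#' 300 s halves at 59 fps - is available by changing `fps` and
#' `half_duration`).
#'
#' @param n_fish Group size (default 4).
#' @param fps Frame rate, Hz (default 15).
#' @param half_duration Duration of each trial half in seconds (default 60).
#' @param arena An [arena_spec()]; default [octagon_arena()] of 105 cm.
#' @param r_repulsion,r_alignment,r_attraction Zone radii in cm
#'   (repulsion < alignment < attraction).
#' @param w_alignment,w_attraction Dimensionless social weights.
#' @param w_persistence Weight of the fish's own previous heading in the
#'   steering blend (inertia); sets the absolute scale against which the
#'   social weights act (default 0.5).
#' @param preferred_speed Cruising speed, cm/s (default 10, about one body
#'   length per second for a 10 cm juvenile).
#' @param speed_noise Speed innovation scale, cm/s.
#' @param heading_noise Per-step turning noise, radians.
#' @param speed_coupling Weight pulling a fish's speed deviation towards
#'   its groupmates' (0-1).
#' @param speed_persistence AR(1) persistence of speed deviations (0-1).
#' @param fish_speed_cv Log-normal coefficient of variation of individual
#'   preferred speeds around the group value (default 0.15).
#' @param trial_speed_cv Log-normal CV of the shared group speed factor
#'   (default 0.10).
#' @param trial_noise_cv Log-normal CV of the shared group noisiness
#'   factor, scaling both turning and speed noise (default 0.30). These
#'   three give the between-individual and between-group heterogeneity
#'   real shoals show, which the random-intercept terms of the statistical
#'   models are there to absorb.
#' @param spacing_cv Log-normal CV of the per-trial repulsion radius:
#'   groups differ in their characteristic spacing (default 0.20).
#' @param activity_tau Correlation time (s) of each fish's slow
#'   behavioural-activity state (default 20).
#' @param activity_cv Stationary log-scale SD of the activity state, which
#'   multiplies the turning and speed noise; fish alternate between
#'   quieter and more active bouts (default 0.30).
#' @param follower 1-based index of the designated follower fish, or 0 for
#'   none.
#' @param follower_lag Frames of delay in the follower's alignment input.
#' @param wall_buffer Width of the wall-deflection buffer, cm.
#' @param burn_in Acclimation period in seconds simulated and discarded
#'   before recording starts (default 10).
#' @param disruption A [disruption_spec()] applied during the second half.
#' @param treatment Treatment label for the emitted dataset.
#' @param trial_id Trial identifier.
#' @param seed Integer seed; identical seeds give bit-identical
#'   trajectories. `NULL` uses the current RNG state.
#' @return A `sim_config`.
#' @export
sim_config <- function(n_fish = 4, fps = 15, half_duration = 60,
                       arena = octagon_arena(105),
                       r_repulsion = 6, r_alignment = 20, r_attraction = 40,
                       w_alignment = 1, w_attraction = 0.5,
                       w_persistence = 0.5,
                       preferred_speed = 10, speed_noise = 1.5,
                       heading_noise = 0.35,
                       speed_coupling = 0.5, speed_persistence = 0.9,
                       fish_speed_cv = 0.15, trial_speed_cv = 0.10,
                       trial_noise_cv = 0.30, spacing_cv = 0.20,
                       activity_tau = 20, activity_cv = 0.30,
                       follower = 4, follower_lag = 3,
                       wall_buffer = 8, burn_in = 10,
                       disruption = disruption_spec(),
                       treatment = "ambient", trial_id = "T01",
                       seed = NULL) {
  stopifnot(n_fish >= 2, fps > 0, half_duration > 0,
            inherits(arena, "arena_spec"),
            inherits(disruption, "disruption_spec"),
            speed_noise >= 0, heading_noise >= 0,
            speed_coupling >= 0, speed_coupling <= 1,
            speed_persistence >= 0, speed_persistence < 1,
            fish_speed_cv >= 0, trial_speed_cv >= 0, trial_noise_cv >= 0,
            spacing_cv >= 0, activity_tau > 0, activity_cv >= 0,
            follower >= 0, follower <= n_fish, follower_lag >= 0,
            burn_in >= 0)
  if (!(r_repulsion < r_alignment && r_alignment < r_attraction)) {
    stop("zone radii must satisfy repulsion < alignment < attraction")
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate one trial
#'
#' Runs the zonal model for two consecutive halves (no playback, then
#' playback with the configured disruption) after a discarded burn-in, and
#' returns the resulting trajectory dataset together with the ground
#' truth.
#'
#' @param cfg A [sim_config()].
#' @return List with `dataset` (a [trajectory_dataset()]) and `truth`
#'   (follower id, follower lag, disruption multipliers, seed).
#' @export
simulate_trial <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n_half <- as.integer(round(cfg$half_duration * cfg$fps))
  n_burn <- as.integer(round(cfg$burn_in * cfg$fps))
  n_total <- n_burn + 2L * n_half
  # start clustered near the centre, headings random
  pos0 <- cbind(runif(cfg$n_fish, -10, 10), runif(cfg$n_fish, -10, 10))
  theta0 <- runif(cfg$n_fish, 0, 2 * pi)
  # between-group and between-individual heterogeneity
  trial_speed <- exp(rnorm(1, 0, cfg$trial_speed_cv))
  trial_noise <- exp(rnorm(1, 0, cfg$trial_noise_cv))
  fish_speed <- cfg$preferred_speed * trial_speed *
    exp(rnorm(cfg$n_fish, 0, cfg$fish_speed_cv))
  r_rep <- min(cfg$r_repulsion * exp(rnorm(1, 0, cfg$spacing_cv)),
               0.9 * cfg$r_alignment)
  out <- sim_zonal_cpp(
    n_frames = n_total, half_boundary = n_burn + n_half,
    pos0 = pos0, theta0 = theta0,
    edge_n = cfg$arena$normals, edge_b = cfg$arena$offsets,
    cx = cfg$arena$centroid[1], cy = cfg$arena$centroid[2],
    dt = 1 / cfg$fps,
    r_rep = r_rep, r_ali = cfg$r_alignment,
    r_att = cfg$r_attraction,
    w_ali = cfg$w_alignment, w_att = cfg$w_attraction,
    w_prev = cfg$w_persistence,
    pref_speed = fish_speed,
    speed_noise = rep(cfg$speed_noise * trial_noise, cfg$n_fish),
    heading_noise = rep(cfg$heading_noise * trial_noise, cfg$n_fish),
    speed_coupling = cfg$speed_coupling,
    speed_persistence = cfg$speed_persistence,
    activity_rho = exp(-1 / (cfg$fps * cfg$activity_tau)),
    activity_sd = cfg$activity_cv,
    follower = cfg$follower - 1L, follower_lag = cfg$follower_lag,
    wall_buffer = cfg$wall_buffer,
    disr = unlist(cfg$disruption)
  )
  keep <- (n_burn + 1L):n_total
  n_frames <- length(keep)
  d <- data.frame(
    frame = rep(0:(n_frames - 1L), times = cfg$n_fish),
    fish_id = rep(seq_len(cfg$n_fish), each = n_frames),
    x = as.vector(out$x[keep, ]),
    y = as.vector(out$y[keep, ])
  )
  ds <- trajectory_dataset(d, cfg$trial_id, cfg$treatment, cfg$fps,
                           cfg$arena, half_boundary = n_half)
  list(
    dataset = ds,
    truth = list(follower = cfg$follower, follower_lag = cfg$follower_lag,
                 disruption = cfg$disruption, seed = cfg$seed,
                 fish_speed = fish_speed, trial_speed = trial_speed,
                 trial_noise = trial_noise, r_repulsion = r_rep)
  )
}

#' Generate a full playback experiment
#'
#' Simulates `2 * n_groups_per_treatment` trials in paired random blocks
#' (each consecutive pair of trials contains one trial of each treatment,
#' in random order within the pair), with per-trial seeds derived
#' reproducibly from `master_seed`. Ambient trials receive `ambient_spec`
#' during the playback half and pile-driving trials `pile_spec`.
#'
#' @param n_groups_per_treatment Groups per treatment (default 15).
#' @param ambient_spec,pile_spec [disruption_spec()]s for the two
#'   treatments.
#' @param base_cfg A [sim_config()] providing everything except treatment,
#'   disruption, trial id and seed.
#' @param master_seed Integer master seed.
#' @return A `shoal_experiment`: list with `trials` (list of
#'   [trajectory_dataset()]s), `truth` (per-trial ground truth) and
#'   `design` (data frame: trial, block, treatment, seed and the applied
#'   multipliers).
#' @export
generate_experiment <- function(n_groups_per_treatment = 15,
                                ambient_spec = ambient_disruption(),
                                pile_spec = pile_driving_disruption(),
                                base_cfg = sim_config(),
                                master_seed = 1) {
  stopifnot(n_groups_per_treatment >= 1)
  set.seed(master_seed)
  n_trials <- 2L * n_groups_per_treatment
  seeds <- sample.int(.Machine$integer.max, n_trials)
  treatments <- unlist(lapply(seq_len(n_groups_per_treatment), function(b) {
    sample(c("ambient", "pile_driving"))
  }))
  trials <- vector("list", n_trials)
  truth <- vector("list", n_trials)
  rows <- vector("list", n_trials)
  for (k in seq_len(n_trials)) {
    spec <- if (treatments[k] == "ambient") ambient_spec else pile_spec
    cfg <- base_cfg
    cfg$treatment <- treatments[k]
    cfg$disruption <- spec
    cfg$trial_id <- sprintf("T%02d", k)
    cfg$seed <- seeds[k]
    sim <- simulate_trial(cfg)
    trials[[k]] <- sim$dataset
    truth[[k]] <- sim$truth
    rows[[k]] <- data.frame(
      trial = cfg$trial_id, block = (k + 1L) %/% 2L,
      treatment = treatments[k], seed = seeds[k],
      speed_mult = spec$speed_mult, alignment_mult = spec$alignment_mult,
      attraction_mult = spec$attraction_mult, noise_mult = spec$noise_mult
    )
  }
  structure(
    list(trials = trials, truth = truth, design = do.call(rbind, rows)),
    class = "shoal_experiment"
  )
}

#' @export
print.shoal_experiment <- function(x, ...) {
  cat(sprintf("<shoal_experiment> %d trials (%s)\n", length(x$trials),
              paste(names(table(x$design$treatment)),
                    table(x$design$treatment),
                    sep = ": ", collapse = ", ")))
  invisible(x)
}
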