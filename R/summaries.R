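#' Metric parameters
#'
#' The tunable parameters of the per-half metric computations, collected
#' in one place so the pipeline, tests and scripts agree on defaults.
#'
#' @param smoothing_window Boxcar position-smoothing width, frames (odd).
#' @param heading_threshold Minimum speed for a defined heading, cm/s.
#' @param nnd_bin Modal-NND histogram bin width, cm.
#' @param modal_min_frames Minimum valid frames for the modal NND.
#' @param max_lag Cross-correlation window half-width, s.
#' @param min_overlap Minimum overlapping frames per correlation lag.
#' @param map_bin,map_extent,map_sigma Relative-position map cell size
#'   (cm), half-extent (cm) and Gaussian smoothing sigma (cells).
#' @return A list of class `metric_params`.
#' @export
metric_params <- function(smoothing_window = 5, heading_threshold = 0.5,
                          nnd_bin = 0.5, modal_min_frames = 50,
                          max_lag = 2, min_overlap = 100,
                          map_bin = 1, map_extent = 30, map_sigma = 6) {
  structure(as.list(environment()), class = "metric_params")
}

#' Per-fish per-half response summaries for one trial
#'
#' Splits the trial at its half boundary and computes, for every fish in
#' each half, the full set of response measures: mean centroid distance,
#' modal nearest-neighbour distance, mean absolute perpendicular and
#' parallel nearest-neighbour offsets, mean bearing to the neighbour in
#' front and behind, mean heading difference, median speed, maximum speed
#' and direction cross-correlations with the modal nearest neighbour, and
#' the direction time delay (the speed delay is carried along but flagged
#' excluded from inference).
#'
#' @param ds A `trajectory_dataset` with `half_boundary` set.
#' @param params A [metric_params()].
#' @return Data frame with one row per fish per half (columns `trial`,
#'   `fish`, `treatment`, `half`, then the measures).
#' @export
fish_half_summaries <- function(ds, params = metric_params()) {
  stopifnot(inherits(ds, "trajectory_dataset"),
            inherits(params, "metric_params"))
  halves <- split_halves(ds)
  out <- list()
  for (label in c("first", "second")) {
    h <- halves[[label]]
    ks <- compute_kinematics(h, params$smoothing_window,
                             params$heading_threshold)
    pg <- nearest_neighbour_geometry(h, ks)
    cd <- centroid_distance(h)
    dyn <- pair_dynamics_summary(h, ks, pg, params$max_lag,
                                 params$min_overlap)
    for (f in fish_ids(h)) {
      key <- as.character(f)
      g <- pg[[key]]
      front <- g$bearing[!is.na(g$side) & g$side == "front"]
      behind <- g$bearing[!is.na(g$side) & g$side == "behind"]
      drow <- dyn[dyn$fish == f, ]
      out[[paste(label, key)]] <- data.frame(
        trial = ds$trial_id,
        fish = f,
        treatment = ds$treatment,
        half = label,
        mean_centroid_dist = unname(cd$per_fish_mean[key]),
        modal_nnd = modal_nnd(g$nnd, params$nnd_bin,
                              params$modal_min_frames),
        mean_perp = mean(g$perp_offset, na.rm = TRUE),
        mean_para = mean(g$para_offset, na.rm = TRUE),
        mean_bearing_front = if (length(front)) mean(front) else NA_real_,
        mean_bearing_behind = if (length(behind)) mean(behind) else NA_real_,
        mean_heading_diff = heading_difference_summary(g),
        median_speed = median_speed(ks[[key]]),
        max_speed_corr = drow$max_speed_corr,
        max_dir_corr = drow$max_dir_corr,
        dir_delay_s = drow$dir_delay_s,
        speed_delay_s_excluded = drow$speed_delay_s_excluded
      )
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Response table for a whole experiment
#'
#' Applies [fish_half_summaries()] to every trial of a
#' [generate_experiment()] result (or a plain list of datasets) and binds
#' the rows into the tidy per-fish-per-half response table the statistical
#' models consume.
#'
#' @param experiment A `shoal_experiment`, or a list of
#'   `trajectory_dataset`s.
#' @param params A [metric_params()].
#' @return Data frame of per-fish-per-half responses.
#' @export
experiment_responses <- function(experiment, params = metric_params()) {
  trials <- if (inherits(experiment, "shoal_experiment")) {
    experiment$trials
  } else {
    experiment
  }
  do.call(rbind, lapply(trials, fish_half_summaries, params = params))
}

# sanity checks on a per-fish-per-half response table
validate_fish_half <- function(data) {
  need <- c("trial", "fish", "treatment", "half")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("response table missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!all(data$half %in% c("first", "second"))) {
    stop("half must be 'first' or 'second'")
  }
  key <- paste(data$trial, data$fish)
  tab <- table(key, data$half)
  if (any(tab != 1L)) {
    stop("unbalanced halves: every (trial, fish) needs exactly one row ",
         "per half")
  }
  invisible(data)
}
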