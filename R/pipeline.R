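#' Pipeline configuration
#'
#' One structured object drives an end-to-end run: either simulate an
#' experiment (`mode = "simulate"`) or read previously written trajectory
#' CSVs and a design table (`mode = "from_files"`), compute the response
#' table, fit all models, and write tidy outputs plus a manifest.
#'
#' @param mode `"simulate"` or `"from_files"`.
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed for simulate mode.
#' @param n_groups_per_treatment Groups per treatment (simulate mode).
#' @param sim A [sim_config()] used as the base configuration.
#' @param ambient_spec,pile_spec Treatment [disruption_spec()]s.
#' @param input_dir Directory holding `design.csv` and `trajectories/`
#'   (from_files mode, as written by [write_experiment()]).
#' @param params A [metric_params()].
#' @param alpha_prune Interaction-pruning level.
#' @param max_gap Gap-repair limit in frames (from_files mode).
#' @param cm_per_pixel Pixel-to-cm factor (from_files mode).
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("simulate", "from_files"),
                            out_dir, seed = 1,
                            n_groups_per_treatment = 15,
                            sim = sim_config(),
                            ambient_spec = ambient_disruption(),
                            pile_spec = pile_driving_disruption(),
                            input_dir = NULL,
                            params = metric_params(),
                            alpha_prune = 0.05,
                            max_gap = 30,
                            cm_per_pixel = 1) {
  mode <- match.arg(mode)
  if (mode == "from_files" && is.null(input_dir)) {
    stop("from_files mode needs input_dir")
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Write an experiment to disk
#'
#' Emits `design.csv` plus one trajectory CSV per trial under
#' `trajectories/`, in the format [read_trajectories()] reads, with full
#' double precision.
#'
#' @param experiment A `shoal_experiment`.
#' @param dir Output directory.
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "shoal_experiment"))
  dir.create(file.path(dir, "trajectories"), recursive = TRUE,
             showWarnings = FALSE)
  design <- experiment$design
  design$fps <- vapply(experiment$trials, function(t) t$fps, numeric(1))
  design$half_boundary <- vapply(experiment$trials,
                                 function(t) t$half_boundary, numeric(1))
  design$arena_width <- vapply(experiment$trials,
                               function(t) t$arena$narrowest_width,
                               numeric(1))
  utils::write.csv(design, file.path(dir, "design.csv"), row.names = FALSE)
  for (ds in experiment$trials) {
    write_trajectories(ds, file.path(dir, "trajectories",
                                     paste0(ds$trial_id, ".csv")))
  }
  invisible(dir)
}

#' Read an experiment written by [write_experiment()]
#'
#' @param dir Directory holding `design.csv` and `trajectories/`.
#' @param cm_per_pixel Pixel-to-cm conversion applied to every file.
#' @param max_gap Gap-repair limit passed to [interpolate_gaps()].
#' @return A `shoal_experiment` (without ground truth).
#' @export
read_experiment <- function(dir, cm_per_pixel = 1, max_gap = 30) {
  design <- utils::read.csv(file.path(dir, "design.csv"),
                            stringsAsFactors = FALSE)
  trials <- vector("list", nrow(design))
  for (k in seq_len(nrow(design))) {
    row <- design[k, ]
    path <- file.path(dir, "trajectories", paste0(row$trial, ".csv"))
    ds <- tryCatch(
      read_trajectories(path, design = list(
        trial_id = row$trial, treatment = row$treatment, fps = row$fps,
        half_boundary = row$half_boundary,
        arena = octagon_arena(row$arena_width)
      ), cm_per_pixel = cm_per_pixel),
      error = function(e) {
        stop("trial ", row$trial, ": ", conditionMessage(e), call. = FALSE)
      }
    )
    trials[[k]] <- interpolate_gaps(ds, max_gap = max_gap)
  }
  structure(list(trials = trials, truth = NULL, design = design),
            class = "shoal_experiment")
}

#' Run the full pipeline
#'
#' simulate (or load) -> per-fish-per-half metrics -> mixed models and
#' effect sizes -> tidy CSV outputs. Writes `responses.csv`,
#' `model_summary.csv`, `effect_sizes.csv`, `relative_position_map.txt`
#' (with a JSON sidecar) and `manifest.json` under the configured output
#' directory. Identical config and seed give byte-identical response and
#' summary CSVs.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with `responses`, `models`, `map`,
#'   `manifest`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  timings <- list()

  experiment <- if (cfg$mode == "simulate") {
    generate_experiment(cfg$n_groups_per_treatment, cfg$ambient_spec,
                        cfg$pile_spec, cfg$sim, master_seed = cfg$seed)
  } else {
    read_experiment(cfg$input_dir, cfg$cm_per_pixel, cfg$max_gap)
  }
  timings$input <- proc.time()[["elapsed"]] - t0

  t1 <- proc.time()[["elapsed"]]
  responses <- experiment_responses(experiment, cfg$params)
  # relative neighbour-position map pooled over all trials and halves
  pgs <- list()
  skipped_frames <- 0L
  for (ds in experiment$trials) {
    ks <- compute_kinematics(ds, cfg$params$smoothing_window,
                             cfg$params$heading_threshold)
    pg <- nearest_neighbour_geometry(ds, ks)
    skipped_frames <- skipped_frames + centroid_distance(ds)$n_skipped
    pgs <- c(pgs, pg)
  }
  map <- relative_position_map(pgs, cfg$params$map_bin,
                               cfg$params$map_extent, cfg$params$map_sigma)
  timings$metrics <- proc.time()[["elapsed"]] - t1

  t2 <- proc.time()[["elapsed"]]
  models <- fit_all_models(responses, alpha_prune = cfg$alpha_prune)
  timings$models <- proc.time()[["elapsed"]] - t2

  utils::write.csv(responses, file.path(cfg$out_dir, "responses.csv"),
                   row.names = FALSE)
  utils::write.csv(models$summary,
                   file.path(cfg$out_dir, "model_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(models$effect_sizes,
                   file.path(cfg$out_dir, "effect_sizes.csv"),
                   row.names = FALSE)
  utils::write.table(map$density,
                     file.path(cfg$out_dir, "relative_position_map.txt"),
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(bin_size = map$bin_size, extent = max(map$centers),
         sigma = map$sigma, n_frames = map$n_frames,
         n_outside = map$n_outside),
    file.path(cfg$out_dir, "relative_position_map.json"),
    auto_unbox = TRUE
  )
  manifest <- list(
    package_version = as.character(utils::packageVersion("shoalnoise")),
    mode = cfg$mode,
    seed = cfg$seed,
    n_trials = length(experiment$trials),
    params = unclass(cfg$params),
    alpha_prune = cfg$alpha_prune,
    skipped_frames = skipped_frames,
    pruned_interactions =
      models$summary$response[models$summary$pruning ==
                                "interaction_dropped"],
    timings_s = lapply(timings, round, 2)
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(responses = responses, models = models, map = map,
                 manifest = manifest))
}
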