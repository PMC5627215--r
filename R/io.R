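#' Read a trajectory file
#'
#' Reads the plain CSV export of a video-tracking run (header
#' `frame,fish_id,x,y`, one row per fish per frame, positions in pixels),
#' converts to cm, validates against the trial design, and attaches
#' per-fish gap statistics.
#'
#' @param path CSV file path.
#' @param design List with fields `trial_id`, `treatment`, `fps`,
#'   `half_boundary`, `arena` (an [arena_spec()]) and optionally `n_fish`
#'   (expected fish count).
#' @param cm_per_pixel Positive scalar pixel-to-cm conversion.
#' @return A [trajectory_dataset()] with attribute `"gap_stats"` (see
#'   [gap_statistics()]).
#' @export
read_trajectories <- function(path, design, cm_per_pixel = 1) {
  stopifnot(is.numeric(cm_per_pixel), length(cm_per_pixel) == 1L,
            cm_per_pixel > 0)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "fish_id", "x", "y")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("trajectory file ", path, " missing column(s): ",
         paste(miss, collapse = ", "))
  }
  if (anyDuplicated(raw[, c("fish_id", "frame")])) {
    stop("duplicate (fish_id, frame) rows in ", path)
  }
  raw$x <- raw$x * cm_per_pixel
  raw$y <- raw$y * cm_per_pixel
  if (!is.null(design$n_fish) &&
      length(unique(raw$fish_id)) != design$n_fish) {
    stop("design mismatch: file has ", length(unique(raw$fish_id)),
         " fish, design expects ", design$n_fish)
  }
  ds <- trajectory_dataset(raw, design$trial_id, design$treatment,
                           design$fps, design$arena,
                           half_boundary = design$half_boundary)
  attr(ds, "gap_stats") <- gap_statistics(ds)
  ds
}

#' Write a trajectory dataset to CSV
#'
#' Inverse of [read_trajectories()] (at `cm_per_pixel = 1`): writes the
#' tracked rows (untracked frames are omitted) with full double precision
#' so that a read/write/read round trip is bit-exact.
#'
#' @param ds A `trajectory_dataset`.
#' @param path Output CSV path.
#' @export
write_trajectories <- function(ds, path) {
  d <- ds$data[!is.na(ds$data$x) & !is.na(ds$data$y), ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("frame,fish_id,x,y", con)
  writeLines(sprintf("%d,%s,%.17g,%.17g", d$frame, as.character(d$fish_id),
                     d$x, d$y), con)
  invisible(path)
}

#' Per-fish tracking-gap statistics
#'
#' A gap is a maximal run of untracked frames strictly inside a fish's
#' frame range; runs touching the start or end of the range are reported
#' separately as edge gaps (they cannot be interpolated).
#'
#' @param ds A `trajectory_dataset`.
#' @return Data frame with one row per gap: `fish_id`, `start`, `length`,
#'   `edge` (logical). Zero rows when tracking is complete.
#' @export
gap_statistics <- function(ds) {
  out <- list()
  for (f in fish_ids(ds)) {
    d <- ds$data[ds$data$fish_id == f, ]
    missing <- is.na(d$x) | is.na(d$y)
    if (!any(missing)) next
    r <- rle(missing)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      out[[length(out) + 1L]] <- data.frame(
        fish_id = f,
        start = d$frame[starts[k]],
        length = r$lengths[k],
        edge = starts[k] == 1L || ends[k] == nrow(d)
      )
    }
  }
  if (!length(out)) {
    return(data.frame(fish_id = character(0), start = integer(0),
                      length = integer(0), edge = logical(0)))
  }
  do.call(rbind, out)
}

#' Repair short tracking gaps by linear interpolation
#'
#' Fills interior gaps of at most `max_gap` frames per coordinate by linear
#' interpolation between the flanking tracked positions. Longer gaps and
#' gaps at the start or end of a fish's record are left missing (no
#' extrapolation) and propagate as `NA` that downstream metrics skip
#' pairwise.
#'
#' @param ds A `trajectory_dataset`.
#' @param max_gap Maximum gap length (frames) to fill; 0 leaves the data
#'   unchanged. Default 30 frames (about 0.5 s at 59 fps).
#' @return The repaired dataset, with attribute `"n_interpolated"` giving
#'   the number of filled frames.
#' @export
interpolate_gaps <- function(ds, max_gap = 30) {
  stopifnot(inherits(ds, "trajectory_dataset"), max_gap >= 0)
  d <- ds$data
  n_filled <- 0L
  if (max_gap > 0) {
    for (f in unique(d$fish_id)) {
      idx <- which(d$fish_id == f)
      x <- d$x[idx]; y <- d$y[idx]
      missing <- is.na(x) | is.na(y)
      if (!any(missing) || all(missing)) next
      r <- rle(missing)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        if (starts[k] == 1L || ends[k] == length(x)) next  # edge: no extrapolation
        if (r$lengths[k] > max_gap) next
        i0 <- starts[k] - 1L; i1 <- ends[k] + 1L
        t <- (starts[k]:ends[k] - i0) / (i1 - i0)
        fill <- starts[k]:ends[k]
        x[fill] <- x[i0] + t * (x[i1] - x[i0])
        y[fill] <- y[i0] + t * (y[i1] - y[i0])
        n_filled <- n_filled + r$lengths[k]
      }
      d$x[idx] <- x; d$y[idx] <- y
    }
  }
  out <- trajectory_dataset(d, ds$trial_id, ds$treatment, ds$fps, ds$arena,
                            ds$half_boundary, ds$half)
  attr(out, "n_interpolated") <- n_filled
  attr(out, "gap_stats") <- gap_statistics(out)
  out
}
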