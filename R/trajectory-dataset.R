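#' Trajectory dataset
#'
#' Container for one trial's tracked positions: a complete (fish x frame)
#' grid in cm with `NA` for frames a fish was not tracked, plus the trial
#' metadata (frame rate, arena geometry, treatment, and the frame index
#' separating the two trial halves). Frame indices are 0-based and halves
#' are the half-open intervals `[start, boundary)` and `[boundary, end]`.
#'
#' @param data Data frame with columns `frame`, `fish_id`, `x`, `y`
#'   (positions already in cm, origin at the arena centroid).
#' @param trial_id Trial identifier.
#' @param treatment One of `"ambient"`, `"pile_driving"`.
#' @param fps Frame rate in Hz.
#' @param arena An [arena_spec()].
#' @param half_boundary Frame index at which the playback half starts;
#'   `NA` for an already-split half.
#' @param half `NA`, `"first"` or `"second"` (set by [split_halves()]).
#' @return An object of class `trajectory_dataset`.
#' @export
trajectory_dataset <- function(data, trial_id, treatment, fps, arena,
                               half_boundary = NA_integer_,
                               half = NA_character_) {
  stopifnot(is.data.frame(data))
  need <- c("frame", "fish_id", "x", "y")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("trajectory data missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0) {
    stop("fps must be a positive scalar")
  }
  treatment <- match.arg(treatment, c("ambient", "pile_driving"))
  stopifnot(inherits(arena, "arena_spec"))
  if (any(data$frame < 0) || any(data$frame != round(data$frame))) {
    stop("frames must be non-negative integers")
  }
  if (anyDuplicated(data[, c("fish_id", "frame")])) {
    stop("duplicate (fish_id, frame) rows: trajectory integrity error")
  }
  fish <- sort(unique(data$fish_id))
  if (length(fish) < 2L) stop("need at least 2 fish")
  frames <- seq(min(data$frame), max(data$frame))
  if (!is.na(half_boundary)) {
    if (half_boundary <= frames[1] || half_boundary > frames[length(frames)]) {
      stop("half_boundary must lie strictly inside the frame range")
    }
  }
  # complete grid: every fish gets every frame, NA positions where untracked
  nfr <- length(frames)
  full <- data.frame(
    frame = rep(frames, times = length(fish)),
    fish_id = rep(fish, each = nfr),
    x = NA_real_, y = NA_real_
  )
  slot <- (match(data$fish_id, fish) - 1L) * nfr +
    (data$frame - frames[1] + 1L)
  full$x[slot] <- data$x
  full$y[slot] <- data$y
  ok <- !is.na(full$x) & !is.na(full$y)
  if (any(ok)) {
    inside <- in_arena(arena, full$x[ok], full$y[ok], tol = 1e-6)
    if (!all(inside)) {
      stop(sum(!inside), " position(s) fall outside the arena polygon")
    }
  }
  structure(
    list(
      trial_id = trial_id,
      treatment = treatment,
      fps = fps,
      arena = arena,
      half_boundary = half_boundary,
      half = half,
      data = full
    ),
    class = "trajectory_dataset"
  )
}

#' @export
print.trajectory_dataset <- function(x, ...) {
  cat(sprintf(
    "<trajectory_dataset> trial %s (%s): %d fish x %d frames at %g fps%s\n",
    x$trial_id, x$treatment, n_fish(x), length(frames_of(x)), x$fps,
    if (!is.na(x$half)) paste0(", half = ", x$half) else ""
  ))
  invisible(x)
}

#' Number of fish in a dataset
#' @param ds A `trajectory_dataset`.
#' @export
n_fish <- function(ds) length(unique(ds$data$fish_id))

#' Frame index vector of a dataset
#' @param ds A `trajectory_dataset`.
#' @export
frames_of <- function(ds) sort(unique(ds$data$frame))

fish_ids <- function(ds) sort(unique(ds$data$fish_id))

# frames x fish coordinate matrices (columns ordered by sorted fish id)
position_arrays <- function(ds) {
  fish <- fish_ids(ds)
  frames <- frames_of(ds)
  nf <- length(frames)
  d <- ds$data  # already sorted (fish_id, frame) on the complete grid
  X <- matrix(d$x, nrow = nf, ncol = length(fish))
  Y <- matrix(d$y, nrow = nf, ncol = length(fish))
  colnames(X) <- colnames(Y) <- as.character(fish)
  list(frames = frames, fish = fish, X = X, Y = Y)
}

#' Split a trial into its two halves
#'
#' Partitions the frame range at `half_boundary` into the no-playback first
#' half `[start, boundary)` and the playback second half `[boundary, end]`.
#'
#' @param ds A `trajectory_dataset` with `half_boundary` set.
#' @return List with elements `first` and `second`, each a
#'   `trajectory_dataset` labelled with its half.
#' @export
split_halves <- function(ds) {
  stopifnot(inherits(ds, "trajectory_dataset"))
  b <- ds$half_boundary
  if (is.na(b)) stop("half_boundary is not set")
  mk <- function(rows, label) {
    trajectory_dataset(ds$data[rows, , drop = FALSE], ds$trial_id,
                       ds$treatment, ds$fps, ds$arena,
                       half_boundary = NA_integer_, half = label)
  }
  list(
    first = mk(ds$data$frame < b, "first"),
    second = mk(ds$data$frame >= b, "second")
  )
}

# rescale all lengths (positions + arena) by a factor; used for the
# unit-conversion linearity property
scale_dataset <- function(ds, factor) {
  d <- ds$data
  d$x <- d$x * factor
  d$y <- d$y * factor
  trajectory_dataset(d, ds$trial_id, ds$treatment, ds$fps,
                     scale_arena(ds$arena, factor),
                     ds$half_boundary, ds$half)
}
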