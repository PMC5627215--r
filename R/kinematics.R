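#' Per-fish speed and heading series
#'
#' Differentiates (optionally boxcar-smoothed) positions by central
#' differences scaled by the frame rate; endpoints and frames adjacent to
#' tracking gaps fall back to one-sided differences. Speed is the velocity
#' norm (cm/s); heading is the velocity unit vector and is only considered
#' defined (`valid`) where speed reaches `heading_threshold` — below that
#' the travel direction is dominated by tracking jitter.
#'
#' @param ds A `trajectory_dataset`.
#' @param smoothing_window Odd boxcar width in frames applied to positions
#'   before differentiation (1 = no smoothing). Default 5.
#' @param heading_threshold Minimum speed (cm/s) for a defined heading.
#' @return A named list (one element per fish) of `kinematic_series`
#'   objects with fields `fish_id`, `frame`, `speed`, `hx`, `hy`, `valid`.
#' @export
compute_kinematics <- function(ds, smoothing_window = 5,
                               heading_threshold = 0.5) {
  stopifnot(inherits(ds, "trajectory_dataset"))
  if (ds$fps <= 0) stop("fps must be positive")
  w <- as.integer(smoothing_window)
  if (w < 1L || w %% 2L == 0L) stop("smoothing_window must be odd and >= 1")
  pa <- position_arrays(ds)
  out <- list()
  for (i in seq_along(pa$fish)) {
    x <- pa$X[, i]; y <- pa$Y[, i]
    if (sum(!is.na(x) & !is.na(y)) < 3L) {
      stop("fish ", pa$fish[i], ": fewer than 3 tracked frames")
    }
    xs <- boxcar_smooth(x, w)
    ys <- boxcar_smooth(y, w)
    vx <- finite_difference(xs) * ds$fps
    vy <- finite_difference(ys) * ds$fps
    speed <- sqrt(vx^2 + vy^2)
    valid <- !is.na(speed) & speed >= heading_threshold
    hx <- ifelse(valid, vx / speed, NA_real_)
    hy <- ifelse(valid, vy / speed, NA_real_)
    out[[as.character(pa$fish[i])]] <- structure(
      list(fish_id = pa$fish[i], frame = pa$frames, speed = speed,
           hx = hx, hy = hy, valid = valid, fps = ds$fps),
      class = "kinematic_series"
    )
  }
  out
}

# NA-aware centered moving average with shrinking windows at the edges;
# frames with no observed position stay NA
boxcar_smooth <- function(x, w) {
  if (w == 1L) return(x)
  n <- length(x)
  half <- (w - 1L) %/% 2L
  obs <- !is.na(x)
  cs <- cumsum(ifelse(obs, x, 0))
  cn <- cumsum(as.numeric(obs))
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  s <- cs[hi] - c(0, cs)[lo]
  m <- cn[hi] - c(0, cn)[lo]
  out <- ifelse(m > 0, s / m, NA_real_)
  out[!obs] <- NA_real_  # don't invent positions for untracked frames
  out
}

# per-frame derivative: central where both neighbours exist, else one-sided
finite_difference <- function(x) {
  n <- length(x)
  d <- rep(NA_real_, n)
  xm <- c(NA, x[-n])   # x[t-1]
  xp <- c(x[-1], NA)   # x[t+1]
  central <- !is.na(xm) & !is.na(xp)
  d[central] <- (xp[central] - xm[central]) / 2
  fwd <- !central & !is.na(x) & !is.na(xp)
  d[fwd] <- xp[fwd] - x[fwd]
  bwd <- !central & !fwd & !is.na(x) & !is.na(xm)
  d[bwd] <- x[bwd] - xm[bwd]
  d
}

#' Median speed of a fish
#'
#' @param ks A `kinematic_series`.
#' @return Median speed (cm/s) over frames with a defined speed.
#' @export
median_speed <- function(ks) {
  s <- ks$speed[!is.na(ks$speed)]
  if (!length(s)) stop("no valid speed frames")
  stats::median(s)
}

#' @export
print.kinematic_series <- function(x, ...) {
  cat(sprintf("<kinematic_series> fish %s: %d frames, %d valid headings\n",
              as.character(x$fish_id), length(x$frame), sum(x$valid)))
  invisible(x)
}
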