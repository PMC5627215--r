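#' Distance of each fish to the shoal centroid
#'
#' The centroid at a frame is the arithmetic mean position of the fish
#' tracked at that frame; frames with fewer than two tracked fish are
#' skipped and counted.
#'
#' @param ds A `trajectory_dataset`.
#' @return List with `per_frame` (frames x fish matrix of distances, cm),
#'   `per_fish_mean` (named vector), and `n_skipped` frames.
#' @export
centroid_distance <- function(ds) {
  pa <- position_arrays(ds)
  present <- !is.na(pa$X) & !is.na(pa$Y)
  n_present <- rowSums(present)
  usable <- n_present >= 2L
  cx <- rowSums(pa$X, na.rm = TRUE) / n_present
  cy <- rowSums(pa$Y, na.rm = TRUE) / n_present
  d <- sqrt((pa$X - cx)^2 + (pa$Y - cy)^2)
  d[!usable, ] <- NA_real_
  colnames(d) <- as.character(pa$fish)
  list(
    per_frame = d,
    per_fish_mean = colMeans(d, na.rm = TRUE),
    n_skipped = sum(!usable)
  )
}

#' Per-frame nearest-neighbour geometry
#'
#' For every fish and frame: the nearest neighbour by Euclidean distance
#' (ties broken towards the lower fish id), the distance to it (`nnd`), the
#' unsigned bearing angle from the focal heading to the neighbour (0 =
#' dead ahead, 90 = directly beside, 180 = dead behind), whether the
#' neighbour is in front (`bearing < 90`) or behind, the absolute
#' perpendicular and parallel offsets of the neighbour across/along the
#' focal heading, and the unsigned heading difference between the pair.
#' Signed components of the neighbour position in the focal frame
#' (`right_offset`, `ahead_offset`) are kept for the relative-position
#' map. Frames without a defined focal heading keep `nnd` but have `NA`
#' angles and offsets.
#'
#' @param ds A `trajectory_dataset`.
#' @param ks Kinematics from [compute_kinematics()] on the same dataset.
#' @return Named list (per fish) of data frames with columns `frame`,
#'   `neighbour_id`, `nnd`, `bearing`, `side`, `perp_offset`,
#'   `para_offset`, `heading_diff`, `right_offset`, `ahead_offset`.
#' @export
nearest_neighbour_geometry <- function(ds, ks) {
  pa <- position_arrays(ds)
  nf <- length(pa$frames)
  nfish <- length(pa$fish)
  if (nfish < 2L) stop("need at least 2 fish")
  out <- list()
  for (i in seq_len(nfish)) {
    dx <- pa$X - pa$X[, i]
    dy <- pa$Y - pa$Y[, i]
    dist <- sqrt(dx^2 + dy^2)
    dist[, i] <- Inf
    dist[is.na(dist)] <- Inf
    focal_missing <- is.na(pa$X[, i]) | is.na(pa$Y[, i])
    nn <- max.col(-dist, ties.method = "first")  # first = lowest fish id
    none <- focal_missing | !is.finite(dist[cbind(seq_len(nf), nn)])
    nn[none] <- NA_integer_
    sel <- cbind(seq_len(nf), nn)
    nnd <- rep(NA_real_, nf)
    rx <- ry <- rep(NA_real_, nf)
    okn <- !is.na(nn)
    nnd[okn] <- dist[sel[okn, , drop = FALSE]]
    rx[okn] <- dx[sel[okn, , drop = FALSE]]
    ry[okn] <- dy[sel[okn, , drop = FALSE]]
    k <- ks[[as.character(pa$fish[i])]]
    hx <- k$hx; hy <- k$hy
    ahead <- rx * hx + ry * hy          # along the focal heading
    right <- rx * hy - ry * hx          # to the focal fish's right
    cosb <- pmin(1, pmax(-1, ahead / nnd))
    bearing <- acos(cosb) * 180 / pi
    side <- ifelse(is.na(bearing), NA_character_,
                   ifelse(bearing < 90, "front", "behind"))
    # neighbour heading for the pair's alignment
    nhx <- nhy <- rep(NA_real_, nf)
    for (j in seq_len(nfish)) {
      rows <- which(nn == j)
      if (length(rows)) {
        kj <- ks[[as.character(pa$fish[j])]]
        nhx[rows] <- kj$hx[rows]
        nhy[rows] <- kj$hy[rows]
      }
    }
    cosh_ <- pmin(1, pmax(-1, hx * nhx + hy * nhy))
    heading_diff <- acos(cosh_) * 180 / pi
    out[[as.character(pa$fish[i])]] <- data.frame(
      frame = pa$frames,
      neighbour_id = ifelse(is.na(nn), NA, pa$fish[nn]),
      nnd = nnd,
      bearing = bearing,
      side = side,
      perp_offset = abs(right),
      para_offset = abs(ahead),
      heading_diff = heading_diff,
      right_offset = right,
      ahead_offset = ahead
    )
  }
  out
}

#' Modal nearest-neighbour distance
#'
#' The most commonly observed nearest-neighbour distance, estimated as the
#' centre of the maximal bin of a fixed-width histogram starting at zero;
#' ties go to the smallest distance bin.
#'
#' @param nnd Numeric vector of per-frame nearest-neighbour distances (cm).
#' @param bin_width Histogram bin width in cm (default 0.5).
#' @param min_frames Minimum number of valid frames required (default 50).
#' @return Modal distance in cm (a bin centre).
#' @export
modal_nnd <- function(nnd, bin_width = 0.5, min_frames = 50) {
  stopifnot(bin_width > 0)
  x <- nnd[!is.na(nnd)]
  if (!length(x)) stop("empty nearest-neighbour distance series")
  if (length(x) < min_frames) {
    stop("only ", length(x), " valid frames (min_frames = ", min_frames, ")")
  }
  bin <- pmin(findInterval(x, seq(0, max(x) + bin_width, by = bin_width)),
              ceiling(max(x) / bin_width) + 1L)
  counts <- tabulate(bin)
  (which.max(counts) - 0.5) * bin_width  # which.max takes the first maximum
}

#' Mean heading difference with the nearest neighbour
#'
#' @param pg A per-fish geometry data frame from
#'   [nearest_neighbour_geometry()].
#' @return Mean unsigned heading difference in degrees over frames where
#'   both headings are defined.
#' @export
heading_difference_summary <- function(pg) {
  h <- pg$heading_diff[!is.na(pg$heading_diff)]
  if (!length(h)) stop("no frames with both headings defined")
  mean(h)
}

#' Relative neighbour-position density map
#'
#' 2-D histogram of nearest-neighbour positions in the focal-centred,
#' heading-aligned frame (x = to the focal fish's right, y = ahead),
#' pooled over the supplied fish, normalised to a probability mass
#' function and then smoothed with a Gaussian filter. Total mass is
#' preserved by the smoothing.
#'
#' @param pg_list List of geometry data frames from
#'   [nearest_neighbour_geometry()] (one or more fish).
#' @param bin_size Cell size in cm (default 1).
#' @param extent Half-width of the map in cm (default 30).
#' @param sigma Gaussian smoothing standard deviation in grid cells
#'   (default 6).
#' @return Object of class `relative_position_map`: list with `density`
#'   (smoothed), `raw` (pre-smoothing pmf), `centers` (cell centres, cm),
#'   `bin_size`, `sigma`, `n_frames` used, `n_outside` offsets beyond the
#'   extent.
#' @export
relative_position_map <- function(pg_list, bin_size = 1, extent = 30,
                                  sigma = 6) {
  if (is.data.frame(pg_list)) pg_list <- list(pg_list)
  rx <- unlist(lapply(pg_list, function(p) p$right_offset))
  ry <- unlist(lapply(pg_list, function(p) p$ahead_offset))
  ok <- !is.na(rx) & !is.na(ry)
  rx <- rx[ok]; ry <- ry[ok]
  if (!length(rx)) stop("no frames with a defined focal heading")
  centers <- seq(-extent, extent, by = bin_size)
  breaks <- c(centers - bin_size / 2, extent + bin_size / 2)
  inside <- rx >= breaks[1] & rx <= breaks[length(breaks)] &
    ry >= breaks[1] & ry <= breaks[length(breaks)]
  ix <- findInterval(rx[inside], breaks, rightmost.closed = TRUE)
  iy <- findInterval(ry[inside], breaks, rightmost.closed = TRUE)
  n <- length(centers)
  counts <- tabulate(iy + (ix - 1L) * n, nbins = n * n)
  grid <- matrix(counts, n, n)
  raw <- grid / sum(grid)
  structure(
    list(density = gaussian_smooth_2d(raw, sigma), raw = raw,
         centers = centers, bin_size = bin_size, sigma = sigma,
         n_frames = sum(inside), n_outside = sum(!inside)),
    class = "relative_position_map"
  )
}

# separable truncated-Gaussian convolution, renormalised so edge
# truncation does not leak mass
gaussian_smooth_2d <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- ceiling(4 * sigma)
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  pad_conv <- function(v) {
    n <- length(v)
    out <- stats::convolve(c(rep(0, r), v, rep(0, r)), rev(k), type = "open")
    out[(2 * r + 1):(2 * r + n)]
  }
  sm <- apply(m, 2, pad_conv)
  sm <- t(apply(sm, 1, pad_conv))
  tot <- sum(sm)
  if (tot > 0) sm * (sum(m) / tot) else sm
}

#' @export
print.relative_position_map <- function(x, ...) {
  cat(sprintf(
    "<relative_position_map> %dx%d cells of %.1f cm, sigma %.1f, %d frames\n",
    nrow(x$density), ncol(x$density), x$bin_size, x$sigma, x$n_frames))
  invisible(x)
}
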