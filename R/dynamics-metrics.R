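#' Speed cross-correlation between two fish
#'
#' For each integer lag tau in a symmetric window, the Pearson correlation
#' between `speed_i(t)` and `speed_j(t + tau)` over the tracked overlap.
#' A positive delay at the peak means fish j's speed follows fish i's.
#' Lags whose overlap is shorter than `min_overlap`, or where either
#' series is constant over the overlap (correlation undefined), are
#' dropped.
#'
#' @param speed_i,speed_j Numeric per-frame speed series on a shared frame
#'   index (`NA` = untracked), or `kinematic_series` objects.
#' @param max_lag Window half-width in seconds (default 2).
#' @param fps Frame rate (Hz); taken from the series when they are
#'   `kinematic_series`.
#' @param min_overlap Minimum overlapping frames per lag (default 100).
#' @return A `crosscorr_result`: list with `lags` (frames), `lag_s`,
#'   `curve`, `n_overlap`, `peak`, `delay_s`, `delay_frames`.
#' @export
speed_crosscorr <- function(speed_i, speed_j, max_lag = 2, fps = NULL,
                            min_overlap = 100) {
  if (inherits(speed_i, "kinematic_series")) {
    if (is.null(fps)) fps <- speed_i$fps
    speed_i <- speed_i$speed
  }
  if (inherits(speed_j, "kinematic_series")) speed_j <- speed_j$speed
  if (is.null(fps) || fps <= 0) stop("fps must be supplied and positive")
  if (length(speed_i) != length(speed_j)) {
    stop("series must share a frame index")
  }
  L <- max(1L, as.integer(round(max_lag * fps)))
  lags <- -L:L
  cc <- pearson_lag_curve_cpp(as.numeric(speed_i), as.numeric(speed_j),
                              lags)
  finish_curve(lags, cc$curve, cc$n_overlap, fps, min_overlap)
}

#' Direction cross-correlation between two fish
#'
#' Nagy-style directional correlation: for each lag tau, the mean dot
#' product of the two fish's unit headings, `mean_t heading_i(t) .
#' heading_j(t + tau)`, over frames where both headings are defined. Peak
#' ties are broken by smallest absolute delay, then negative before
#' positive.
#'
#' @param ks_i,ks_j `kinematic_series` objects, or two-column matrices of
#'   unit headings (hx, hy) on a shared frame index.
#' @inheritParams speed_crosscorr
#' @return A `crosscorr_result` (see [speed_crosscorr()]).
#' @export
direction_crosscorr <- function(ks_i, ks_j, max_lag = 2, fps = NULL,
                                min_overlap = 100) {
  as_h <- function(k) {
    if (inherits(k, "kinematic_series")) cbind(k$hx, k$hy) else as.matrix(k)
  }
  if (inherits(ks_i, "kinematic_series") && is.null(fps)) fps <- ks_i$fps
  hi <- as_h(ks_i); hj <- as_h(ks_j)
  if (is.null(fps) || fps <= 0) stop("fps must be supplied and positive")
  if (nrow(hi) != nrow(hj)) stop("series must share a frame index")
  L <- max(1L, as.integer(round(max_lag * fps)))
  lags <- -L:L
  cc <- dot_lag_curve_cpp(hi[, 1], hi[, 2], hj[, 1], hj[, 2], lags)
  finish_curve(lags, cc$curve, cc$n_overlap, fps, min_overlap)
}

finish_curve <- function(lags, curve, n_ov, fps, min_overlap) {
  curve[!is.na(n_ov) & n_ov < min_overlap] <- NA_real_
  if (all(is.na(curve))) {
    stop("correlation undefined at every lag (constant series or too ",
         "little overlap)")
  }
  peak <- max(curve, na.rm = TRUE)
  cand <- which(curve == peak)
  cand <- cand[order(abs(lags[cand]), lags[cand])]  # |delay| then neg first
  best <- cand[1]
  structure(
    list(lags = lags, lag_s = lags / fps, curve = curve, n_overlap = n_ov,
         peak = peak, delay_frames = lags[best], delay_s = lags[best] / fps),
    class = "crosscorr_result"
  )
}

#' @export
print.crosscorr_result <- function(x, ...) {
  cat(sprintf("<crosscorr_result> peak %.3f at delay %+g s (%+d frames)\n",
              x$peak, x$delay_s, x$delay_frames))
  invisible(x)
}

#' Per-fish nearest-neighbour dynamics summary
#'
#' For each fish, cross-correlations of speed and direction against its
#' modal (most frequent) nearest neighbour over the period, yielding the
#' maximum speed correlation, maximum direction correlation, and the
#' direction time delay. The speed delay is computed but flagged as
#' excluded from inference (speeds are strongly correlated at near-zero
#' delay, so their delays carry no signal).
#'
#' @param ds A `trajectory_dataset` (one trial half).
#' @param ks Kinematics from [compute_kinematics()].
#' @param pg Geometry from [nearest_neighbour_geometry()].
#' @param max_lag Window half-width in seconds.
#' @param min_overlap Minimum overlapping frames per lag.
#' @return Data frame with one row per fish: `fish`, `partner`,
#'   `max_speed_corr`, `max_dir_corr`, `dir_delay_s`,
#'   `speed_delay_s_excluded`. Fish with no computable pair get `NA`
#'   values; their ids are recorded in attribute `"failed"`.
#' @export
pair_dynamics_summary <- function(ds, ks, pg, max_lag = 2,
                                  min_overlap = 100) {
  fish <- fish_ids(ds)
  rows <- list()
  failed <- character(0)
  for (f in fish) {
    key <- as.character(f)
    nbr <- pg[[key]]$neighbour_id
    nbr <- nbr[!is.na(nbr)]
    row <- data.frame(fish = f, partner = NA, max_speed_corr = NA_real_,
                      max_dir_corr = NA_real_, dir_delay_s = NA_real_,
                      speed_delay_s_excluded = NA_real_)
    if (length(nbr)) {
      tab <- table(nbr)
      top <- names(tab)[tab == max(tab)]
      topv <- suppressWarnings(as.numeric(top))
      partner <- if (!anyNA(topv)) top[order(topv)][1] else sort(top)[1]  # tie -> lower id
      sc <- try(speed_crosscorr(ks[[key]], ks[[partner]], max_lag = max_lag,
                                min_overlap = min_overlap), silent = TRUE)
      dc <- try(direction_crosscorr(ks[[key]], ks[[partner]],
                                    max_lag = max_lag,
                                    min_overlap = min_overlap),
                silent = TRUE)
      if (!inherits(sc, "try-error") && !inherits(dc, "try-error")) {
        row$partner <- partner
        row$max_speed_corr <- sc$peak
        row$speed_delay_s_excluded <- sc$delay_s
        row$max_dir_corr <- dc$peak
        row$dir_delay_s <- dc$delay_s
      } else {
        failed <- c(failed, key)
      }
    } else {
      failed <- c(failed, key)
    }
    rows[[key]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "failed") <- failed
  out
}
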