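# Independent brute-force oracles and fixture builders used across the
# suite. These deliberately avoid the package's own implementations.

# naive per-lag Pearson cross-correlation: cor(a(t), b(t+lag))
oracle_pearson_curve <- function(a, b, lags) {
  vapply(lags, function(lag) {
    n <- length(a)
    if (lag >= 0) {
      ia <- seq_len(n - lag); ib <- ia + lag
    } else {
      ib <- seq_len(n + lag); ia <- ib - lag
    }
    av <- a[ia]; bv <- b[ib]
    ok <- !is.na(av) & !is.na(bv)
    av <- av[ok]; bv <- bv[ok]
    if (length(av) < 2 || sd(av) == 0 || sd(bv) == 0) return(NA_real_)
    cor(av, bv)
  }, numeric(1))
}

# naive per-lag mean heading dot product
oracle_dot_curve <- function(hi, hj, lags) {
  vapply(lags, function(lag) {
    n <- nrow(hi)
    if (lag >= 0) {
      ia <- seq_len(n - lag); ib <- ia + lag
    } else {
      ib <- seq_len(n + lag); ia <- ib - lag
    }
    d <- hi[ia, 1] * hj[ib, 1] + hi[ia, 2] * hj[ib, 2]
    d <- d[!is.na(d)]
    if (!length(d)) return(NA_real_) else mean(d)
  }, numeric(1))
}

# a large square arena so geometric fixtures never hit the walls
big_arena <- function(half = 1000) {
  arena_spec(cbind(c(-half, half, half, -half), c(-half, -half, half, half)))
}

# build a dataset from per-fish position matrices (n_frames x 2 each)
make_ds <- function(..., fps = 10, arena = big_arena(), treatment = "ambient",
                    half_boundary = NA_integer_) {
  paths <- list(...)
  rows <- do.call(rbind, lapply(seq_along(paths), function(i) {
    p <- paths[[i]]
    data.frame(frame = seq_len(nrow(p)) - 1L, fish_id = i,
               x = p[, 1], y = p[, 2])
  }))
  trajectory_dataset(rows, trial_id = "fix", treatment = treatment,
                     fps = fps, arena = arena,
                     half_boundary = half_boundary)
}

# straight-line path: start + t * step, for n frames
line_path <- function(n, start = c(0, 0), step = c(1, 0)) {
  cbind(start[1] + (seq_len(n) - 1) * step[1],
        start[2] + (seq_len(n) - 1) * step[2])
}

# smooth autocorrelated positive series (AR(1) around a mean), for
# cross-correlation fixtures
ar_series <- function(n, mean = 10, phi = 0.95, sd_innov = 1) {
  x <- numeric(n)
  x[1] <- rnorm(1)
  for (t in 2:n) x[t] <- phi * x[t - 1] + rnorm(1, sd = sd_innov)
  mean + x
}

# unit-heading matrix of a smoothly turning trajectory
turning_headings <- function(n, rate = 0.05) {
  ang <- cumsum(rnorm(n, sd = rate))
  cbind(cos(ang), sin(ang))
}

rigid_motion <- function(p, theta, shift) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  sweep(p %*% t(R), 2, -shift)
}

# tidy per-fish-per-half response table with known structure, for the
# statistics module; `effects` is a function(treatment, half) giving the
# cell mean
make_response_table <- function(n_trials_per_treatment = 15, n_fish = 4,
                                effects = function(tr, h) 0,
                                fish_sd = 0, trial_sd = 0, resid_sd = 0,
                                response = "y") {
  rows <- list()
  k <- 0
  for (tr in c("ambient", "pile_driving")) {
    for (g in seq_len(n_trials_per_treatment)) {
      k <- k + 1
      trial <- sprintf("T%02d", k)
      trial_eff <- rnorm(1, 0, trial_sd)
      for (f in seq_len(n_fish)) {
        fish_eff <- rnorm(1, 0, fish_sd)
        for (h in c("first", "second")) {
          rows[[length(rows) + 1]] <- data.frame(
            trial = trial, fish = f, treatment = tr, half = h,
            value = effects(tr, h) + trial_eff + fish_eff +
              rnorm(1, 0, resid_sd),
            median_speed = rnorm(1, 10, 1)
          )
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  names(out)[names(out) == "value"] <- response
  out
}

make_ds_from_rows <- function(rows, fps = 10, arena = big_arena(),
                              half_boundary = NA_integer_) {
  trajectory_dataset(rows, trial_id = "fix", treatment = "ambient",
                     fps = fps, arena = arena,
                     half_boundary = half_boundary)
}
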