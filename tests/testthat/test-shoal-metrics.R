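test_that("unit-square corners sit sqrt(2)/2 from the centroid", {
  n <- 5
  corners <- list(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  paths <- lapply(corners, function(cc) matrix(rep(cc, each = n), n, 2))
  ds <- do.call(make_ds, paths)
  cd <- centroid_distance(ds)
  expect_equal(unname(cd$per_fish_mean), rep(sqrt(2) / 2, 4),
               tolerance = 1e-12)
  # coincident fish: distance zero
  ds0 <- make_ds(paths[[1]], paths[[1]] + 1e-15)
  expect_equal(max(centroid_distance(ds0)$per_fish_mean), 0,
               tolerance = 1e-12)
})

test_that("centroid distances match a direct recomputation oracle", {
  set.seed(5)
  for (rep in 1:5) {
    paths <- replicate(4, matrix(rnorm(20 * 2, sd = 10), 20, 2),
                       simplify = FALSE)
    ds <- do.call(make_ds, paths)
    cd <- centroid_distance(ds)
    for (fr in c(1, 7, 20)) {
      pos <- t(vapply(paths, function(p) p[fr, ], numeric(2)))
      cen <- colMeans(pos)
      oracle <- sqrt(rowSums(sweep(pos, 2, cen)^2))
      expect_equal(unname(cd$per_frame[fr, ]), oracle, tolerance = 1e-12)
    }
  }
})

test_that("bearing, side and offsets follow the stated conventions", {
  n <- 40
  focal <- line_path(n, step = c(0, 5))  # heading (0, 1), speed 50 cm/s
  geom_for <- function(offset) {
    ds <- make_ds(focal, sweep(focal, 2, -offset))
    ks <- compute_kinematics(ds, smoothing_window = 1)
    nearest_neighbour_geometry(ds, ks)[["1"]]
  }
  mid <- 10  # any interior frame
  ahead <- geom_for(c(0, 5))
  expect_equal(ahead$bearing[mid], 0, tolerance = 1e-9)
  expect_equal(ahead$side[mid], "front")
  expect_equal(ahead$perp_offset[mid], 0, tolerance = 1e-9)
  expect_equal(ahead$para_offset[mid], 5, tolerance = 1e-9)

  beside <- geom_for(c(3, 0))
  expect_equal(beside$bearing[mid], 90, tolerance = 1e-9)
  expect_equal(beside$side[mid], "behind")  # 90 degrees is not in front
  expect_equal(beside$perp_offset[mid], 3, tolerance = 1e-9)
  expect_equal(beside$para_offset[mid], 0, tolerance = 1e-9)

  # the lattice angle the shoals favour: neighbour 43 degrees off the bow
  lattice <- geom_for(5 * c(sin(43 * pi / 180), cos(43 * pi / 180)))
  expect_equal(lattice$bearing[mid], 43, tolerance = 1e-9)
  expect_equal(lattice$side[mid], "front")
  expect_equal(lattice$nnd[mid], 5, tolerance = 1e-9)
})

test_that("perp^2 + para^2 = nnd^2 on random configurations", {
  set.seed(31)
  paths <- replicate(4, apply(matrix(rnorm(60 * 2, sd = 3), 60, 2), 2,
                              cumsum), simplify = FALSE)
  ds <- do.call(make_ds, paths)
  ks <- compute_kinematics(ds)
  pg <- nearest_neighbour_geometry(ds, ks)
  for (g in pg) {
    ok <- !is.na(g$perp_offset)
    expect_true(all(abs(g$perp_offset[ok]^2 + g$para_offset[ok]^2 -
                          g$nnd[ok]^2) < 1e-6))
  }
})

test_that("geometry is invariant under global rigid motions", {
  set.seed(41)
  paths <- replicate(4, apply(matrix(rnorm(60 * 2, sd = 3), 60, 2), 2,
                              cumsum), simplify = FALSE)
  moved <- lapply(paths, rigid_motion, theta = 1.1, shift = c(40, -7))
  ds <- do.call(make_ds, paths)
  dsm <- do.call(make_ds, moved)
  pg <- nearest_neighbour_geometry(ds, compute_kinematics(ds))
  pgm <- nearest_neighbour_geometry(dsm, compute_kinematics(dsm))
  cd <- centroid_distance(ds); cdm <- centroid_distance(dsm)
  expect_equal(cdm$per_fish_mean, cd$per_fish_mean, tolerance = 1e-9)
  for (f in names(pg)) {
    expect_equal(pgm[[f]]$nnd, pg[[f]]$nnd, tolerance = 1e-9)
    expect_equal(pgm[[f]]$bearing, pg[[f]]$bearing, tolerance = 1e-9)
    expect_equal(pgm[[f]]$perp_offset, pg[[f]]$perp_offset,
                 tolerance = 1e-9)
    expect_equal(pgm[[f]]$para_offset, pg[[f]]$para_offset,
                 tolerance = 1e-9)
    expect_equal(pgm[[f]]$heading_diff, pg[[f]]$heading_diff,
                 tolerance = 1e-9)
  }
})

test_that("nnd and heading difference are symmetric in the pair", {
  n <- 50
  p1 <- line_path(n, step = c(2, 1))
  p2 <- line_path(n, start = c(4, -3), step = c(2, 1))
  ds <- make_ds(p1, p2)
  pg <- nearest_neighbour_geometry(ds, compute_kinematics(ds))
  expect_equal(pg[["1"]]$nnd, pg[["2"]]$nnd, tolerance = 1e-12)
  expect_equal(pg[["1"]]$heading_diff, pg[["2"]]$heading_diff,
               tolerance = 1e-9)
})

test_that("modal NND picks the dominant histogram bin", {
  expect_true(abs(modal_nnd(rep(5, 100), bin_width = 0.5) - 5) <= 0.25)
  m <- modal_nnd(c(rep(2, 10), rep(8, 3)), bin_width = 1, min_frames = 1)
  expect_true(2 >= m - 0.5 && 2 <= m + 0.5)  # the bin holding 2.0 wins
  # ties go to the smallest distance bin
  tie <- modal_nnd(c(rep(1.2, 5), rep(9.2, 5)), bin_width = 1,
                   min_frames = 1)
  expect_lt(tie, 2)
  expect_error(modal_nnd(numeric(0)), "empty")
  expect_error(modal_nnd(rep(3, 10), min_frames = 50), "min_frames")
})

test_that("modal NND recovers the dominant mode of a large mixture", {
  set.seed(77)
  x <- abs(c(rnorm(7e4, 4, 0.6), rnorm(3e4, 9, 1.2)))
  expect_true(abs(modal_nnd(x, bin_width = 0.5) - 4) <= 0.5)
})

test_that("heading difference summarises alignment correctly", {
  n <- 40
  fwd <- line_path(n, step = c(0, 3))
  bwd <- line_path(n, start = c(5, 200), step = c(0, -3))
  dsp <- make_ds(fwd, sweep(fwd, 2, c(-5, 0)))
  pgp <- nearest_neighbour_geometry(dsp, compute_kinematics(dsp))
  expect_equal(heading_difference_summary(pgp[["1"]]), 0, tolerance = 1e-7)
  dsa <- make_ds(fwd, bwd)
  pga <- nearest_neighbour_geometry(dsa, compute_kinematics(dsa))
  expect_equal(heading_difference_summary(pga[["1"]]), 180,
               tolerance = 1e-7)
  # independent uniform headings: mean tends to 90 degrees
  set.seed(13)
  nmc <- 4000
  mc <- data.frame(heading_diff = acos(pmin(1, pmax(-1,
    cos(runif(nmc, 0, 2 * pi) - runif(nmc, 0, 2 * pi))))) * 180 / pi)
  se <- sd(mc$heading_diff) / sqrt(nmc)
  expect_lt(abs(heading_difference_summary(mc) - 90), 3 * se + 1e-9)
})

test_that("relative position map concentrates, mirrors and conserves mass", {
  n <- 60
  focal <- line_path(n, step = c(0, 5))
  ds <- make_ds(focal, sweep(focal, 2, c(0, -5)))  # neighbour dead ahead, 5 cm
  pg <- nearest_neighbour_geometry(ds, compute_kinematics(ds,
                                                          smoothing_window = 1))
  m <- relative_position_map(pg[["1"]], bin_size = 1, extent = 30,
                             sigma = 0)
  ix <- which(m$centers == 0); iy <- which(m$centers == 5)
  expect_equal(m$raw[iy, ix], 1)
  expect_equal(sum(m$raw), 1, tolerance = 1e-12)

  # mirror-symmetric input: one neighbour left, one right
  dsl <- make_ds(focal, sweep(focal, 2, c(3, 0)))
  dsr <- make_ds(focal, sweep(focal, 2, c(-3, 0)))
  pgl <- nearest_neighbour_geometry(dsl, compute_kinematics(dsl,
                                                            smoothing_window = 1))
  pgr <- nearest_neighbour_geometry(dsr, compute_kinematics(dsr,
                                                            smoothing_window = 1))
  ms <- relative_position_map(list(pgl[["1"]], pgr[["1"]]), sigma = 0)
  expect_equal(ms$raw, ms$raw[, rev(seq_len(ncol(ms$raw)))],
               tolerance = 1e-12)

  # Gaussian smoothing preserves total mass
  set.seed(3)
  paths <- replicate(4, apply(matrix(rnorm(400 * 2, sd = 2), 400, 2), 2,
                              cumsum), simplify = FALSE)
  dsr2 <- do.call(make_ds, paths)
  pgs <- nearest_neighbour_geometry(dsr2, compute_kinematics(dsr2))
  sm <- relative_position_map(pgs, sigma = 6)
  expect_equal(sum(sm$density), sum(sm$raw), tolerance = 1e-9)
  expect_equal(sum(sm$raw), 1, tolerance = 1e-12)
})
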