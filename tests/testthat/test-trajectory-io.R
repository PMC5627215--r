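design_for <- function(n_fish = 4, fps = 10, half_boundary = 5L,
                       arena = big_arena()) {
  list(trial_id = "T01", treatment = "ambient", fps = fps,
       half_boundary = half_boundary, arena = arena, n_fish = n_fish)
}

write_fixture_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  path
}

well_formed_rows <- function(n_fish = 4, n_frames = 10) {
  do.call(rbind, lapply(seq_len(n_fish), function(f) {
    data.frame(frame = 0:(n_frames - 1), fish_id = f,
               x = f * 10 + 0:(n_frames - 1), y = f * 5 + 0.5)
  }))
}

test_that("a well-formed file reads into a complete validated dataset", {
  path <- write_fixture_csv(well_formed_rows())
  ds <- read_trajectories(path, design_for())
  expect_s3_class(ds, "trajectory_dataset")
  expect_equal(nrow(ds$data), 40L)
  expect_equal(n_fish(ds), 4L)
  expect_equal(nrow(attr(ds, "gap_stats")), 0L)
})

test_that("read -> write -> read reproduces positions bit-exactly", {
  rows <- well_formed_rows()
  rows$x <- rows$x + pi * 1e-3   # non-representable decimals
  rows$y <- rows$y + sqrt(2)
  path <- write_fixture_csv(rows)
  ds1 <- read_trajectories(path, design_for())
  out <- tempfile(fileext = ".csv")
  write_trajectories(ds1, out)
  ds2 <- read_trajectories(out, design_for())
  expect_identical(ds2$data$x, ds1$data$x)
  expect_identical(ds2$data$y, ds1$data$y)
})

test_that("format, integrity and design violations raise named errors", {
  rows <- well_formed_rows()
  expect_error(
    read_trajectories(write_fixture_csv(rows[, c("frame", "fish_id", "y")]),
                      design_for()),
    "x")
  expect_error(
    read_trajectories(write_fixture_csv(rbind(rows, rows[1, ])),
                      design_for()),
    "duplicate")
  expect_error(read_trajectories(write_fixture_csv(rows),
                                 design_for(n_fish = 5)),
               "design mismatch")
})

test_that("a missing frame is reported as one gap of length one", {
  rows <- well_formed_rows()
  rows <- rows[!(rows$fish_id == 2 & rows$frame == 5), ]
  ds <- read_trajectories(write_fixture_csv(rows), design_for())
  gs <- attr(ds, "gap_stats")
  expect_equal(nrow(gs), 1L)
  expect_equal(gs$fish_id, 2)
  expect_equal(gs$start, 5)
  expect_equal(gs$length, 1L)
  expect_false(gs$edge)
})

test_that("gap interpolation fills short interior gaps linearly", {
  rows <- data.frame(frame = c(1, 3, 1, 2, 3), fish_id = c(1, 1, 2, 2, 2),
                     x = c(0, 2, 5, 5, 5), y = c(0, 2, 5, 5, 5))
  ds <- make_ds_from_rows(rows)
  fixed <- interpolate_gaps(ds, max_gap = 1)
  d <- fixed$data
  expect_equal(d$x[d$fish_id == 1 & d$frame == 2], 1)  # linear midpoint
  expect_equal(d$y[d$fish_id == 1 & d$frame == 2], 1)
  expect_equal(attr(fixed, "n_interpolated"), 1L)
})

test_that("long gaps are kept missing and max_gap = 0 changes nothing", {
  rows <- data.frame(frame = c(0, 6:9, 0:9), fish_id = c(rep(1, 5), rep(2, 10)),
                     x = c(0, 6:9, 0:9), y = 0)
  ds <- make_ds_from_rows(rows)
  kept <- interpolate_gaps(ds, max_gap = 2)   # 5-frame gap > max_gap
  expect_true(all(is.na(kept$data$x[kept$data$fish_id == 1 &
                                      kept$data$frame %in% 1:5])))
  same <- interpolate_gaps(ds, max_gap = 0)
  expect_identical(same$data, ds$data)
})

test_that("edge gaps are never extrapolated", {
  rows <- data.frame(frame = c(2:9, 0:9), fish_id = c(rep(1, 8), rep(2, 10)),
                     x = 1, y = 1)
  ds <- make_ds_from_rows(rows)
  fixed <- interpolate_gaps(ds, max_gap = 10)
  expect_true(all(is.na(fixed$data$x[fixed$data$fish_id == 1 &
                                       fixed$data$frame < 2])))
  gs <- gap_statistics(ds)
  expect_true(all(gs$edge[gs$fish_id == 1]))
})

test_that("split_halves partitions the frame range exactly", {
  p <- line_path(600)
  ds <- make_ds(p, p + 5, half_boundary = 300L)
  h <- split_halves(ds)
  expect_equal(length(frames_of(h$first)), 300L)
  expect_equal(length(frames_of(h$second)), 300L)
  expect_length(intersect(frames_of(h$first), frames_of(h$second)), 0L)
  expect_equal(sort(c(frames_of(h$first), frames_of(h$second))),
               frames_of(ds))
  expect_equal(h$first$half, "first")
  expect_equal(h$second$half, "second")
})

test_that("degenerate half boundaries are rejected", {
  p <- line_path(10)
  expect_error(make_ds(p, p + 5, half_boundary = 0L), "strictly inside")
  ds <- make_ds(p, p + 5)
  expect_error(split_halves(ds), "not set")
})

test_that("unit conversion is linear: length metrics scale by the factor", {
  set.seed(99)
  p1 <- apply(matrix(rnorm(100 * 2), 100, 2), 2, cumsum)
  p2 <- p1 + matrix(rnorm(100 * 2, sd = 2), 100, 2)
  ds <- make_ds(p1, p2)
  ds3 <- shoalnoise:::scale_dataset(ds, 3)
  cd1 <- centroid_distance(ds)$per_fish_mean
  cd3 <- centroid_distance(ds3)$per_fish_mean
  expect_equal(cd3, 3 * cd1, tolerance = 1e-12)
  # the heading threshold is an absolute speed, so it scales with length
  ks1 <- compute_kinematics(ds, heading_threshold = 0.5)
  ks3 <- compute_kinematics(ds3, heading_threshold = 1.5)
  g1 <- nearest_neighbour_geometry(ds, ks1)[["1"]]
  g3 <- nearest_neighbour_geometry(ds3, ks3)[["1"]]
  expect_equal(g3$nnd, 3 * g1$nnd, tolerance = 1e-12)
  expect_equal(g3$bearing, g1$bearing, tolerance = 1e-9)
})
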