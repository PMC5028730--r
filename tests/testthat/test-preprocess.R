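test_that("joint selection yields the 42-column matrix in fixed order", {
  rec <- make_test_record(n = 10L, seed = 2L)
  m <- select_joints(rec)
  expect_equal(dim(m$values), c(10L, 42L))
  expect_identical(colnames(m$values), motion_columns())
  expect_identical(m$stage, "selected")
  # a joint's coordinates land in its own columns
  rec$coords[4, c("AnkleL_x", "AnkleL_y", "AnkleL_z")] <- c(1, 2, 3)
  m <- select_joints(rec)
  expect_equal(unname(m$values[4, c("AnkleL_x", "AnkleL_y", "AnkleL_z")]),
               c(1, 2, 3))
  # camera-frame SpineBase track is carried for segmentation
  expect_equal(m$spinebase_track,
               rec$coords[, c("SpineBase_x", "SpineBase_y", "SpineBase_z")])
})

test_that("body-frame transform zeroes SpineBase and is translation invariant", {
  rec <- make_test_record(n = 8L, seed = 4L)
  rec$coords[1, c("SpineBase_x", "SpineBase_y", "SpineBase_z")] <- c(1, 1, 1)
  rec$coords[1, c("Neck_x", "Neck_y", "Neck_z")] <- c(1, 1.6, 1)
  b <- to_body_frame(select_joints(rec))
  expect_identical(b$stage, "body_frame")
  expect_equal(unname(b$values[1, c("Neck_x", "Neck_y", "Neck_z")]),
               c(0, 0.6, 0))
  expect_true(all(b$values[, c("SpineBase_x", "SpineBase_y", "SpineBase_z")] == 0))

  # rigid translation of the whole scene leaves the body frame unchanged
  shifted <- rec
  shifted$coords <- rec$coords +
    matrix(rep(c(2.5, -1.0, 7.3), 25), nrow(rec$coords), 75, byrow = TRUE)
  b2 <- to_body_frame(select_joints(shifted))
  expect_equal(b2$values, b$values)
})

test_that("all joints coincident with SpineBase give an all-zero body frame", {
  set.seed(8)
  base <- matrix(rnorm(15), 5, 3)
  coords <- base[, rep(1:3, 25)]
  colnames(coords) <- emogait:::coord_columns(kinect_joints())
  rec <- gait_record(coords, "S01", "neutral")
  b <- to_body_frame(select_joints(rec))
  expect_true(all(b$values == 0))
})

test_that("smoothing reproduces the 5-tap kernel impulse response exactly", {
  kernel <- c(1, 4, 6, 4, 1) / 16
  rec <- make_test_record(n = 7L)
  m <- select_joints(rec)
  m$values[] <- 0
  m$values[4, ] <- 1 # interior unit impulse in every channel
  s <- gauss_smooth(m, kernel)
  expect_identical(s$stage, "smoothed")
  expect_equal(unname(s$values[, 1]),
               c(0, 1 / 16, 4 / 16, 6 / 16, 4 / 16, 1 / 16, 0))
  # constant signals pass through unchanged (kernel mass 1)
  m$values[] <- 5
  expect_equal(gauss_smooth(m, kernel)$values, m$values)
})

test_that("smoothing matches direct convolution and reduces noise variance", {
  kernel <- c(1, 4, 6, 4, 1) / 16
  set.seed(11)
  rec <- make_test_record(n = 200L, seed = 11L)
  m <- select_joints(rec)
  s <- gauss_smooth(m, kernel)
  for (j in c(1L, 17L, 42L))
    expect_equal(s$values[, j], oracle_conv5(m$values[, j], kernel))
  expect_lt(var(s$values[, 1]), var(m$values[, 1]))
})

test_that("smoothing rejects too-short input and bad kernels", {
  m <- select_joints(make_test_record(n = 4L))
  expect_error(gauss_smooth(m), "at least 5")
  m5 <- select_joints(make_test_record(n = 5L))
  expect_error(gauss_smooth(m5, c(1, 1, 1, 1, 1)), "sum")
  expect_error(pipeline_config(kernel = c(1, 2, 3, 2, 1) / 10), "sum")
  expect_error(pipeline_config(min_segment_frames = 1), ">= 2")
})

test_that("differencing is the discrete derivative with cumulative-sum inverse", {
  rec <- make_test_record(n = 20L, seed = 6L)
  m <- gauss_smooth(select_joints(rec))
  ramp <- m
  ramp$values[] <- matrix(0:19, 20, 42)
  d <- differentiate(ramp)
  expect_identical(d$stage, "differenced")
  expect_equal(nrow(d$values), 19L)
  expect_true(all(d$values == 1))
  const <- m
  const$values[] <- 3.3
  expect_true(all(differentiate(const)$values == 0))
  # cumulative sum of the output prepended with row 0 reproduces the input
  d <- differentiate(m)
  rebuilt <- apply(rbind(m$values[1, ], d$values), 2L, cumsum)
  expect_equal(unname(rebuilt), unname(m$values))
})

test_that("a monotone depth track yields one full-length oriented segment", {
  # oracle: run-length scan of the sign of the smoothed depth change
  z <- seq(6, by = -0.04, length.out = 100) # strictly decreasing: approaching
  m <- matrix_from_track(z)
  segs <- segment_record(m)
  expect_length(segs, 1L)
  expect_identical(segs[[1]]$orientation, "front")
  expect_gte(nrow(segs[[1]]$values), 96L)

  z_back <- seq(1, by = 0.04, length.out = 100)
  segs <- segment_record(matrix_from_track(z_back))
  expect_length(segs, 1L)
  expect_identical(segs[[1]]$orientation, "back")
})

test_that("segments shorter than the 40-frame floor are discarded", {
  # two straight runs separated by a standstill; only the longer survives
  cfg <- pipeline_config(turn_trim_frames = 0L)
  z0 <- 6 - 35 * 0.04
  z <- c(seq(6, by = -0.04, length.out = 36),        # 35 usable diffs: too few
         rep(z0, 30),                                # standstill (dead band)
         seq(z0, by = 0.04, length.out = 46))        # 45 usable diffs: kept
  segs <- segment_record(matrix_from_track(z), config = cfg)
  expect_length(segs, 1L)
  expect_identical(segs[[1]]$orientation, "back")
  expect_gte(nrow(segs[[1]]$values), cfg$min_segment_frames)
})

test_that("segmentation drops turn neighborhoods and never overlaps", {
  z <- c(seq(7.5, by = -1 / 30, length.out = 180),
         rep(7.5 - 179 / 30, 60),
         seq(7.5 - 179 / 30, by = 1 / 30, length.out = 180))
  m <- matrix_from_track(z)
  cfg <- pipeline_config()
  segs <- segment_record(m, config = cfg)
  expect_length(segs, 2L)
  expect_identical(vapply(segs, `[[`, "", "orientation"), c("front", "back"))
  # disjoint, ordered, all >= 40 frames, and trimmed around the turn
  expect_true(segs[[1]]$stop <= segs[[2]]$start)
  for (s in segs) expect_gte(nrow(s$values), cfg$min_segment_frames)
  covered <- unlist(lapply(segs, function(s) s$start:(s$stop - 1L)))
  expect_false(anyDuplicated(covered) > 0)
  expect_true(all(covered >= 1L & covered <= nrow(m$values)))
  # identical input and config give byte-identical segments
  expect_identical(segs, segment_record(m, config = cfg))
})

test_that("stage order is enforced", {
  rec <- make_test_record(n = 10L)
  m <- select_joints(rec)
  expect_error(differentiate(m), "smoothed")
  expect_error(segment_record(m), "differenced")
  s <- gauss_smooth(to_body_frame(m))
  expect_error(to_body_frame(s), "selected")
})
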