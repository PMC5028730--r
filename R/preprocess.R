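#' Pipeline configuration
#'
#' Bundles the preprocessing parameters: the 5-tap smoothing kernel, the
#' minimum straight-walking segment length, the number of frames trimmed on
#' each side of a detected turn, and the walking-direction dead band.
#'
#' @param kernel Five non-negative smoothing weights summing to 1. Default is
#'   the binomial low-pass kernel `c(1, 4, 6, 4, 1) / 16`.
#' @param min_segment_frames Minimum frames per retained segment (default 40,
#'   chosen so every segment spans at least one stride at 30 Hz).
#' @param turn_trim_frames Frames removed on each side of a walking-direction
#'   change (default 15, about 0.5 s at 30 Hz).
#' @param turn_epsilon Dead band on the smoothed per-frame depth change of
#'   SpineBase, in meters per frame; frames with |dz| below it count as
#'   turning/standing (default 0.002).
#' @param frame_rate Sampling rate in Hz (default 30).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(kernel = c(1, 4, 6, 4, 1) / 16,
                            min_segment_frames = 40L,
                            turn_trim_frames = 15L,
                            turn_epsilon = 0.002,
                            frame_rate = 30) {
  kernel <- as.numeric(kernel)
  if (length(kernel) != 5L || any(!is.finite(kernel)))
    stop("kernel must be 5 finite weights", call. = FALSE)
  if (abs(sum(kernel) - 1) > 1e-12)
    stop("kernel weights must sum to 1 (within 1e-12)", call. = FALSE)
  min_segment_frames <- as.integer(min_segment_frames)
  if (min_segment_frames < 2L)
    stop("min_segment_frames must be >= 2", call. = FALSE)
  if (turn_trim_frames < 0L) stop("turn_trim_frames must be >= 0", call. = FALSE)
  if (turn_epsilon < 0) stop("turn_epsilon must be >= 0", call. = FALSE)
  if (frame_rate <= 0) stop("frame_rate must be positive", call. = FALSE)
  structure(list(kernel = kernel,
                 min_segment_frames = min_segment_frames,
                 turn_trim_frames = as.integer(turn_trim_frames),
                 turn_epsilon = turn_epsilon,
                 frame_rate = as.numeric(frame_rate)),
            class = "pipeline_config")
}

new_motion_matrix <- function(values, stage, frame_rate, spinebase_track) {
  structure(list(values = values, stage = stage, frame_rate = frame_rate,
                 spinebase_track = spinebase_track),
            class = "motion_matrix")
}

#' @export
print.motion_matrix <- function(x, ...) {
  cat(sprintf("<motion_matrix> %d x %d, stage=%s, %g Hz\n",
              nrow(x$values), ncol(x$values), x$stage, x$frame_rate))
  invisible(x)
}

stage_order <- c("selected", "body_frame", "smoothed", "differenced")

check_stage <- function(m, expected) {
  if (!inherits(m, "motion_matrix"))
    stop("expected a motion_matrix", call. = FALSE)
  if (m$stage != expected)
    stop(sprintf("motion matrix is at stage '%s'; this step expects '%s'",
                 m$stage, expected), call. = FALSE)
}

#' Select the 14 analysis joints
#'
#' Reduces a 25-joint record to the T x 42 motion matrix of the 14 analysis
#' joints (x, y, z per joint, fixed joint-major column order). The raw
#' camera-frame SpineBase trajectory is retained alongside: it serves as the
#' walker's position on the footpath for the later segmentation step.
#'
#' @param record A [gait_record].
#' @return A `motion_matrix` at stage `"selected"` with columns
#'   [motion_columns()].
#' @export
select_joints <- function(record) {
  stopifnot(inherits(record, "gait_record"))
  if (nrow(record$coords) == 0L)
    stop("record has no frames", call. = FALSE)
  cols <- motion_columns()
  values <- record$coords[, cols, drop = FALSE]
  track <- record$coords[, paste0("SpineBase_", c("x", "y", "z")),
                         drop = FALSE]
  new_motion_matrix(values, "selected", record$frame_rate, track)
}

#' Transform to body-centered coordinates
#'
#' Re-expresses every joint relative to the same frame's SpineBase position,
#' removing the walker's translation along the footpath so that records taken
#' at different positions relative to the camera become comparable. The
#' SpineBase columns become identically zero; the untouched camera-frame
#' SpineBase track is kept for segmentation.
#'
#' @param matrix A `motion_matrix` at stage `"selected"`.
#' @param spinebase_track Optional T x 3 camera-frame SpineBase positions;
#'   defaults to the track carried by `matrix`.
#' @return A `motion_matrix` at stage `"body_frame"`.
#' @export
to_body_frame <- function(matrix, spinebase_track = matrix$spinebase_track) {
  check_stage(matrix, "selected")
  spinebase_track <- as.matrix(spinebase_track)
  if (nrow(spinebase_track) != nrow(matrix$values) ||
      ncol(spinebase_track) != 3L)
    stop("spinebase_track must be T x 3 matching the motion matrix",
         call. = FALSE)
  # subtract the per-frame SpineBase position from every joint's x/y/z
  offset <- spinebase_track[, rep(1:3, times = 14L), drop = FALSE]
  new_motion_matrix(matrix$values - offset, "body_frame",
                    matrix$frame_rate, spinebase_track)
}

# 5-tap convolution with 2-frame mirror (reflect) padding; length-preserving.
convolve5 <- function(x, kernel) {
  n <- length(x)
  pad <- x[c(3L, 2L, seq_len(n), n - 1L, n - 2L)]
  kernel[1] * pad[1:n] + kernel[2] * pad[2:(n + 1)] +
    kernel[3] * pad[3:(n + 2)] + kernel[4] * pad[4:(n + 3)] +
    kernel[5] * pad[5:(n + 4)]
}

#' Sliding-window Gaussian smoothing
#'
#' Convolves each coordinate channel with the 5-tap low-pass kernel
#' `c(1, 4, 6, 4, 1) / 16`, suppressing sensor noise and tracking burrs.
#' Edges are mirror-padded by two frames so the output keeps T rows.
#'
#' @param matrix A `motion_matrix` at stage `"body_frame"` (a `"selected"`
#'   matrix is also accepted when smoothing is wanted without the coordinate
#'   transform).
#' @param kernel Five weights summing to 1.
#' @return A `motion_matrix` at stage `"smoothed"`.
#' @export
gauss_smooth <- function(matrix, kernel = c(1, 4, 6, 4, 1) / 16) {
  if (!inherits(matrix, "motion_matrix"))
    stop("expected a motion_matrix", call. = FALSE)
  if (!matrix$stage %in% c("selected", "body_frame"))
    stop(sprintf("cannot smooth a matrix at stage '%s'", matrix$stage),
         call. = FALSE)
  kernel <- as.numeric(kernel)
  if (length(kernel) != 5L || abs(sum(kernel) - 1) > 1e-12)
    stop("kernel must be 5 weights summing to 1", call. = FALSE)
  n <- nrow(matrix$values)
  if (n < 5L)
    stop("need at least 5 frames to smooth, got ", n, call. = FALSE)
  pad_idx <- c(3L, 2L, seq_len(n), n - 1L, n - 2L)
  pad <- matrix$values[pad_idx, , drop = FALSE]
  sm <- kernel[1] * pad[1:n, , drop = FALSE] +
    kernel[2] * pad[2:(n + 1), , drop = FALSE] +
    kernel[3] * pad[3:(n + 2), , drop = FALSE] +
    kernel[4] * pad[4:(n + 3), , drop = FALSE] +
    kernel[5] * pad[5:(n + 4), , drop = FALSE]
  new_motion_matrix(sm, "smoothed", matrix$frame_rate, matrix$spinebase_track)
}

#' Frame-to-frame differencing
#'
#' Replaces positions by their change between consecutive frames, which
#' carries the dynamic part of the gait and removes slow postural offsets.
#' Output row t is input row t+1 minus input row t, so a T-frame matrix
#' yields T-1 rows.
#'
#' @param matrix A `motion_matrix` at stage `"smoothed"`.
#' @return A `motion_matrix` at stage `"differenced"` with T-1 rows.
#' @export
differentiate <- function(matrix) {
  check_stage(matrix, "smoothed")
  n <- nrow(matrix$values)
  if (n < 2L) stop("need at least 2 frames to difference", call. = FALSE)
  d <- matrix$values[-1L, , drop = FALSE] - matrix$values[-n, , drop = FALSE]
  new_motion_matrix(d, "differenced", matrix$frame_rate,
                    matrix$spinebase_track)
}

new_segment <- function(values, start, stop, orientation, frame_rate) {
  structure(list(values = values, start = start, stop = stop,
                 orientation = orientation, frame_rate = frame_rate),
            class = "gait_segment")
}

#' @export
print.gait_segment <- function(x, ...) {
  cat(sprintf("<gait_segment> rows [%d, %d), orientation=%s, %d frames\n",
              x$start, x$stop, x$orientation, nrow(x$values)))
  invisible(x)
}

#' Split a record into straight-walking segments
#'
#' Joint tracking is unreliable while the walker turns at the footpath ends,
#' so turning frames are dropped and the record is cut into straight-walking
#' stretches. Walking direction is read from the camera-frame SpineBase depth
#' track: the per-frame depth change is smoothed with the same 5-tap kernel,
#' frames whose |dz| falls inside the dead band count as turning/standing,
#' and `turn_trim_frames` extra frames are removed on each side of every
#' direction change. Runs shorter than `min_segment_frames` are discarded.
#' Segments where depth decreases (walker approaching the camera) are tagged
#' `"front"`; depth-increasing runs are tagged `"back"`.
#'
#' @param matrix A `motion_matrix` at stage `"differenced"`.
#' @param spinebase_track Camera-frame SpineBase positions covering the
#'   undifferenced frame range (T x 3); defaults to the carried track.
#' @param config A [pipeline_config()].
#' @return List of `gait_segment` objects, ordered and disjoint; empty when
#'   no run qualifies. `start`/`stop` are 1-based row indices into the
#'   differenced matrix, `stop` exclusive.
#' @export
segment_record <- function(matrix, spinebase_track = matrix$spinebase_track,
                           config = pipeline_config()) {
  check_stage(matrix, "differenced")
  spinebase_track <- as.matrix(spinebase_track)
  n <- nrow(matrix$values)
  if (nrow(spinebase_track) < n + 1L)
    stop("spinebase_track must cover the undifferenced frame range",
         call. = FALSE)
  dz <- diff(spinebase_track[, 3L])[seq_len(n)]
  dzs <- if (n >= 5L) convolve5(dz, config$kernel) else dz
  lab <- integer(n)
  lab[dzs > config$turn_epsilon] <- 1L    # depth increasing: walking away
  lab[dzs < -config$turn_epsilon] <- -1L  # depth decreasing: approaching
  runs <- rle(lab)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  segs <- list()
  for (i in seq_along(runs$values)) {
    if (runs$values[i] == 0L) next
    s <- starts[i]
    e <- ends[i]
    # trim only at boundaries adjacent to a direction change or dead band,
    # not at the record ends
    if (s > 1L) s <- s + config$turn_trim_frames
    if (e < n) e <- e - config$turn_trim_frames
    if (e - s + 1L < config$min_segment_frames) next
    orientation <- if (runs$values[i] < 0L) "front" else "back"
    segs[[length(segs) + 1L]] <-
      new_segment(matrix$values[s:e, , drop = FALSE],
                  start = s, stop = e + 1L, orientation = orientation,
                  frame_rate = matrix$frame_rate)
  }
  segs
}

#' Run the full preprocessing chain
#'
#' Convenience wrapper: joint selection, body-centered transform, Gaussian
#' smoothing, differencing and segmentation in the documented stage order.
#'
#' @param record A [gait_record].
#' @param config A [pipeline_config()].
#' @return List of `gait_segment` objects.
#' @export
preprocess_record <- function(record, config = pipeline_config()) {
  m <- select_joints(record)
  m <- to_body_frame(m)
  m <- gauss_smooth(m, config$kernel)
  m <- differentiate(m)
  segment_record(m, config = config)
}
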