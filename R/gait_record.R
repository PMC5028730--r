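#' Construct a gait record
#'
#' A `gait_record` is one uninterrupted walking recording: an ordered set of
#' frames, each holding the 3D camera-coordinate positions (meters) of the 25
#' Kinect-v2 joints, plus subject / condition / camera metadata. Coordinates
#' follow the Kinect SDK convention: x lateral, y vertical, z depth from the
#' camera.
#'
#' @param coords Numeric matrix, frames x 75, with columns named
#'   `<Joint>_<axis>` in the canonical order `coord_columns(kinect_joints())`.
#' @param subject_id Subject identifier (string).
#' @param condition Class label for the recording, e.g. `"angry"` or
#'   `"neutral_pre_anger"`. Free-form; the four study labels are typical.
#' @param camera_id Camera identifier; recordings from different cameras are
#'   analyzed independently.
#' @param frame_rate Sampling rate in Hz (default 30).
#' @param frame_index Optional integer vector of frame indices, strictly
#'   increasing; defaults to `0:(T-1)`.
#' @return An object of class `gait_record`.
#' @export
gait_record <- function(coords, subject_id, condition, camera_id = "K1",
                        frame_rate = 30, frame_index = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  expected <- coord_columns(kinect_joints())
  if (nrow(coords) < 1L)
    stop("gait_record needs at least one frame", call. = FALSE)
  if (ncol(coords) != 75L)
    stop("coords must have 75 columns (25 joints x 3 axes), got ",
         ncol(coords), call. = FALSE)
  if (is.null(colnames(coords))) {
    colnames(coords) <- expected
  } else if (!identical(colnames(coords), expected)) {
    missing <- setdiff(expected, colnames(coords))
    if (length(missing))
      stop("missing joint coordinate column(s): ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    coords <- coords[, expected, drop = FALSE]
  }
  if (!all(is.finite(coords)))
    stop("all joint coordinates must be finite", call. = FALSE)
  if (is.null(frame_index)) frame_index <- seq_len(nrow(coords)) - 1L
  frame_index <- as.integer(frame_index)
  if (length(frame_index) != nrow(coords) || any(diff(frame_index) <= 0L) ||
      any(frame_index < 0L))
    stop("frame_index must be non-negative and strictly increasing, one per frame",
         call. = FALSE)
  if (!is.numeric(frame_rate) || frame_rate <= 0)
    stop("frame_rate must be a positive number of Hz", call. = FALSE)
  structure(
    list(coords = coords, frame_index = frame_index,
         subject_id = as.character(subject_id),
         condition = as.character(condition),
         camera_id = as.character(camera_id),
         frame_rate = as.numeric(frame_rate)),
    class = "gait_record")
}

#' @export
print.gait_record <- function(x, ...) {
  cat(sprintf("<gait_record> subject=%s condition=%s camera=%s\n",
              x$subject_id, x$condition, x$camera_id))
  cat(sprintf("  %d frames @ %g Hz (%.1f s), 25 joints\n",
              nrow(x$coords), x$frame_rate, nrow(x$coords) / x$frame_rate))
  invisible(x)
}

#' Number of frames in a gait record
#' @param record A `gait_record`.
#' @return Integer frame count.
#' @export
n_frames <- function(record) nrow(record$coords)
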