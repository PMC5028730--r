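#' Dominant frequency and phase of one channel
#'
#' Runs the discrete Fourier transform of one coordinate channel and returns
#' the frequency of the largest-magnitude bin among k = 1 ... floor(N/2)
#' (the DC bin is excluded; after differencing the mean is ~0 anyway and the
#' fundamental stride frequency is the physically meaningful peak), together
#' with the complex argument at that bin. Ties break toward the lowest bin.
#' A constant (including all-zero) signal returns (0, 0) by convention.
#'
#' @param signal Numeric vector of N >= 2 samples.
#' @param frame_rate Sampling rate in Hz.
#' @param window `"none"` (default, raw samples) or `"hann"` to taper the
#'   signal before the transform.
#' @return Named numeric vector `c(freq = Hz, phase = radians)`, phase in
#'   (-pi, pi].
#' @export
main_frequency_and_phase <- function(signal, frame_rate,
                                     window = c("none", "hann")) {
  window <- match.arg(window)
  n <- length(signal)
  if (n < 2L) stop("need at least 2 samples, got ", n, call. = FALSE)
  if (any(!is.finite(signal)))
    stop("signal must be finite", call. = FALSE)
  if (all(signal == signal[1])) return(c(freq = 0, phase = 0))
  x <- signal
  if (window == "hann")
    x <- x * (0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L)))
  spec <- stats::fft(x)
  half <- n %/% 2L
  mags <- Mod(spec[2:(half + 1L)])
  k <- which.max(mags)   # first maximum: ties go to the lowest bin
  c(freq = k * frame_rate / n, phase = Arg(spec[k + 1L]))
}

#' Fourier features of one segment
#'
#' Applies [main_frequency_and_phase()] to each of the 42 coordinate
#' channels of a straight-walking segment, yielding 42 main frequencies and
#' their 42 phases; the segment's front/back orientation is carried through.
#'
#' @param segment A `gait_segment` (at least 2 frames; segments from
#'   [segment_record()] span at least one stride by construction).
#' @param frame_rate Sampling rate in Hz; defaults to the segment's own.
#' @param window Passed to [main_frequency_and_phase()].
#' @return A `segment_features` list with `main_freqs`, `phases` (length-42
#'   named vectors) and `orientation`.
#' @export
segment_features <- function(segment, frame_rate = segment$frame_rate,
                             window = "none") {
  stopifnot(inherits(segment, "gait_segment"))
  fp <- apply(segment$values, 2L, main_frequency_and_phase,
              frame_rate = frame_rate, window = window)
  structure(list(main_freqs = fp["freq", ], phases = fp["phase", ],
                 orientation = segment$orientation),
            class = "segment_features")
}

circular_mean <- function(theta) atan2(mean(sin(theta)), mean(cos(theta)))

#' Aggregate segment features into the 168-value record descriptor
#'
#' Front and back views of the same gait look different, so segment features
#' are averaged within each orientation group and concatenated in the fixed
#' layout front main-frequencies (42), front phases (42), back
#' main-frequencies (42), back phases (42) - 168 values per record.
#'
#' @param features List of `segment_features` for one record.
#' @param phase_mean `"arithmetic"` (plain element-wise mean, the default) or
#'   `"circular"` (angular mean, robust to wrap-around).
#' @param record_id Identifier used in error messages.
#' @return Named numeric vector of length 168 with attributes `n_front` and
#'   `n_back` (segment counts averaged).
#' @export
aggregate_record <- function(features, phase_mean = c("arithmetic", "circular"),
                             record_id = "record") {
  phase_mean <- match.arg(phase_mean)
  stopifnot(length(features) > 0L)
  orient <- vapply(features, function(f) f$orientation, character(1))
  out <- numeric(0)
  counts <- c(front = 0L, back = 0L)
  for (side in c("front", "back")) {
    grp <- features[orient == side]
    if (length(grp) == 0L) {
      cond <- structure(
        class = c("emogait_missing_orientation", "error", "condition"),
        list(message = sprintf("%s has no %s segments; cannot build a 168-feature descriptor",
                               record_id, side),
             call = NULL))
      stop(cond)
    }
    counts[side] <- length(grp)
    freqs <- rowMeans(vapply(grp, `[[`, numeric(42), "main_freqs"))
    ph <- vapply(grp, `[[`, numeric(42), "phases")
    phases <- if (phase_mean == "circular") apply(ph, 1L, circular_mean)
              else rowMeans(ph)
    names(freqs) <- paste0(side, "_freq_", motion_columns())
    names(phases) <- paste0(side, "_phase_", motion_columns())
    out <- c(out, freqs, phases)
  }
  attr(out, "n_front") <- counts[["front"]]
  attr(out, "n_back") <- counts[["back"]]
  out
}

#' Feature names of the 168-value record descriptor
#' @return Character vector of length 168 in the fixed layout order.
#' @export
record_feature_names <- function() {
  unlist(lapply(c("front", "back"), function(side)
    c(paste0(side, "_freq_", motion_columns()),
      paste0(side, "_phase_", motion_columns()))))
}

#' Extract the 168-feature descriptor of one record
#'
#' Full per-record chain: preprocessing ([preprocess_record()]), per-segment
#' Fourier features and orientation-wise aggregation.
#'
#' @param record A [gait_record].
#' @param config A [pipeline_config()].
#' @param phase_mean,window Passed through to aggregation / the DFT.
#' @return Named 168-vector with `n_front`/`n_back` attributes.
#' @export
extract_record_features <- function(record, config = pipeline_config(),
                                    phase_mean = "arithmetic",
                                    window = "none") {
  segs <- preprocess_record(record, config)
  rid <- sprintf("%s/%s/%s", record$subject_id, record$condition,
                 record$camera_id)
  if (length(segs) == 0L) {
    cond <- structure(
      class = c("emogait_missing_orientation", "error", "condition"),
      list(message = sprintf("%s yielded no usable straight-walking segments", rid),
           call = NULL))
    stop(cond)
  }
  feats <- lapply(segs, segment_features, window = window)
  aggregate_record(feats, phase_mean = phase_mean, record_id = rid)
}

#' Build a feature table from many records
#'
#' Runs [extract_record_features()] over a list of records and assembles the
#' instances x 168 [feature_table()]. Records missing either orientation (no
#' front or no back straight-walking segment) are dropped with a warning, the
#' default policy for incomplete recordings.
#'
#' @param records List of [gait_record] objects.
#' @param config,phase_mean,window Passed through.
#' @return A [feature_table] labeled by each record's condition, with
#'   attribute `dropped` (character vector of dropped record ids) and
#'   `n_segments` (total segments used).
#' @export
build_feature_table <- function(records, config = pipeline_config(),
                                phase_mean = "arithmetic", window = "none") {
  stopifnot(length(records) > 0L)
  rows <- list()
  ids <- list()
  dropped <- character()
  n_segments <- 0L
  for (rec in records) {
    rid <- sprintf("%s/%s/%s", rec$subject_id, rec$condition, rec$camera_id)
    fv <- tryCatch(extract_record_features(rec, config, phase_mean, window),
                   emogait_missing_orientation = function(e) {
                     warning("dropping ", rid, ": ", conditionMessage(e),
                             call. = FALSE)
                     NULL
                   })
    if (is.null(fv)) {
      dropped <- c(dropped, rid)
      next
    }
    n_segments <- n_segments + attr(fv, "n_front") + attr(fv, "n_back")
    rows[[length(rows) + 1L]] <- as.numeric(fv)
    ids[[length(ids) + 1L]] <- data.frame(subject_id = rec$subject_id,
                                          condition = rec$condition,
                                          camera_id = rec$camera_id,
                                          stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    stop("no record yielded a complete feature vector", call. = FALSE)
  values <- do.call(rbind, rows)
  colnames(values) <- record_feature_names()
  tab <- feature_table(values, do.call(rbind, ids))
  attr(tab, "dropped") <- dropped
  attr(tab, "n_segments") <- n_segments
  tab
}

#' Z-score normalization
#'
#' Feature scales differ by orders of magnitude (Hz vs radians), so features
#' are standardized column-wise before PCA and model fitting. `zscore_fit`
#' estimates per-feature means and standard deviations; `zscore_apply`
#' transforms a table with them. Zero-variance columns map to 0.
#'
#' @param table A [feature_table] with >= 2 instances (for fitting).
#' @param stats A list `list(mean =, sd =)` from `zscore_fit`.
#' @return `zscore_fit`: the stats list; `zscore_apply`: a transformed
#'   [feature_table].
#' @export
zscore_fit <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (nrow(table$values) < 2L)
    stop("need at least 2 instances to fit normalization", call. = FALSE)
  list(mean = colMeans(table$values),
       sd = apply(table$values, 2L, stats::sd))
}

#' @rdname zscore_fit
#' @export
zscore_apply <- function(table, stats) {
  stopifnot(inherits(table, "feature_table"))
  sds <- ifelse(stats$sd > 0, stats$sd, 1)
  z <- sweep(sweep(table$values, 2L, stats$mean), 2L, sds, "/")
  z[, stats$sd == 0] <- 0
  feature_table(z, table$ids, table$labels)
}

#' Principal component reduction
#'
#' Fits PCA on a normalized feature table and keeps the minimal number of
#' leading components whose cumulative explained variance reaches
#' `variance_threshold`; `pca_apply` projects instances onto the retained
#' components. Used to compress the 168 Fourier features before classifier
#' training, where instances are few relative to features.
#'
#' @param table A normalized [feature_table].
#' @param variance_threshold Fraction in (0, 1]; default 0.95.
#' @param model A `pca_model` from `pca_fit`.
#' @return `pca_fit`: a `pca_model` with orthonormal loading matrix
#'   `components` (features x k) and non-increasing `explained_var`
#'   fractions; `pca_apply`: the projected [feature_table] with columns
#'   `PC1...PCk`.
#' @export
pca_fit <- function(table, variance_threshold = 0.95) {
  stopifnot(inherits(table, "feature_table"))
  if (!is.numeric(variance_threshold) || variance_threshold <= 0 ||
      variance_threshold > 1)
    stop("variance_threshold must be in (0, 1]", call. = FALSE)
  p <- stats::prcomp(table$values, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2
  total <- sum(ev)
  if (total <= 0) stop("feature table has no variance", call. = FALSE)
  frac <- ev / total
  k <- which(cumsum(frac) >= variance_threshold - 1e-12)[1L]
  structure(list(center = p$center,
                 components = p$rotation[, seq_len(k), drop = FALSE],
                 explained_var = frac[seq_len(k)],
                 variance_threshold = variance_threshold),
            class = "pca_model")
}

#' @rdname pca_fit
#' @export
pca_apply <- function(table, model) {
  stopifnot(inherits(table, "feature_table"), inherits(model, "pca_model"))
  x <- sweep(table$values, 2L, model$center)
  proj <- x %*% model$components
  colnames(proj) <- paste0("PC", seq_len(ncol(proj)))
  feature_table(proj, table$ids, table$labels)
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d components (threshold %.2f, cum. var %.3f)\n",
              ncol(x$components), x$variance_threshold,
              sum(x$explained_var)))
  invisible(x)
}
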