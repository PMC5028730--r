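#' Read a skeleton recording from CSV
#'
#' The skeleton CSV dialect is wide: one row per frame, a `frame_index`
#' column followed by the 75 coordinate columns `Head_x, Head_y, Head_z, ...`
#' in the canonical 25-joint order (meters, camera coordinates). Metadata
#' (subject, condition, camera, frame rate) is carried in a leading comment
#' line of the form `# subject=S01 condition=angry camera=K1 frame_rate=30`;
#' metadata missing from the file can be supplied through the arguments.
#'
#' @param path Path to a skeleton CSV file.
#' @param subject_id,condition,camera_id,frame_rate Fallback metadata used
#'   when the file carries no comment header (file values win).
#' @return A validated [gait_record].
#' @seealso [write_skeleton_csv()]
#' @export
read_skeleton_csv <- function(path, subject_id = "unknown",
                              condition = "unknown", camera_id = "K1",
                              frame_rate = 30) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || all(!nzchar(trimws(lines))))
    stop("empty skeleton file: ", path, call. = FALSE)
  meta <- list(subject = subject_id, condition = condition,
               camera = camera_id, frame_rate = frame_rate)
  comment <- grep("^#", lines, value = TRUE)
  if (length(comment)) {
    for (kv in regmatches(comment[1],
                          gregexpr("[A-Za-z_]+=[^[:space:]]+", comment[1]))[[1]]) {
      key <- sub("=.*$", "", kv)
      val <- sub("^[^=]*=", "", kv)
      if (key %in% names(meta)) meta[[key]] <- val
    }
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L)
    stop("skeleton file has no data rows: ", path, call. = FALSE)
  header <- strsplit(body[1], ",", fixed = TRUE)[[1]]
  expected <- c("frame_index", coord_columns(kinect_joints()))
  missing <- setdiff(expected, header)
  if (length(missing))
    stop("skeleton CSV is missing required column(s): ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (and %d more)", length(missing) - 5),
         call. = FALSE)
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        check.names = FALSE, colClasses = "character")
  df <- df[, expected, drop = FALSE]
  num <- matrix(NA_real_, nrow(df), ncol(df), dimnames = list(NULL, expected))
  for (j in seq_along(expected)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) & !is.na(df[[j]]))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' in column %s, data row %d",
                   df[[j]][bad[1]], expected[j], bad[1]), call. = FALSE)
    num[, j] <- v
  }
  gait_record(num[, -1, drop = FALSE],
              subject_id = meta$subject, condition = meta$condition,
              camera_id = meta$camera,
              frame_rate = as.numeric(meta$frame_rate),
              frame_index = num[, 1])
}

#' Write a skeleton recording to CSV
#'
#' Emits the wide dialect accepted by [read_skeleton_csv()]: a metadata
#' comment line, a header, then one row per frame in a fixed column order.
#' Floating-point values are written with 17 significant digits so that a
#' read/write round trip reproduces coordinates bit-exactly.
#'
#' @param record A [gait_record].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_skeleton_csv <- function(record, path) {
  stopifnot(inherits(record, "gait_record"))
  cols <- coord_columns(kinect_joints())
  header <- sprintf("# subject=%s condition=%s camera=%s frame_rate=%s",
                    record$subject_id, record$condition, record$camera_id,
                    format(record$frame_rate, digits = 17))
  vals <- matrix(sprintf("%.17g", record$coords), nrow = nrow(record$coords))
  rows <- paste(record$frame_index, apply(vals, 1, paste, collapse = ","),
                sep = ",")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, paste(c("frame_index", cols), collapse = ","), rows),
             con)
  invisible(path)
}

#' Construct a feature table
#'
#' A feature table is the instances-by-features matrix fed to normalization,
#' PCA and cross-validation, with per-instance identity (subject, condition,
#' camera) and a class label.
#'
#' @param values Numeric matrix, instances x features, with unique column
#'   names.
#' @param ids Data frame with columns `subject_id`, `condition`, `camera_id`,
#'   one row per instance.
#' @param labels Character vector of class labels, one per instance; defaults
#'   to `ids$condition`.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(values, ids, labels = ids$condition) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colnames(values)))
    colnames(values) <- paste0("f", seq_len(ncol(values)))
  if (anyDuplicated(colnames(values)))
    stop("feature names must be unique", call. = FALSE)
  ids <- as.data.frame(ids, stringsAsFactors = FALSE)
  need <- c("subject_id", "condition", "camera_id")
  if (!all(need %in% names(ids)))
    stop("ids must have columns subject_id, condition, camera_id", call. = FALSE)
  if (nrow(ids) != nrow(values) || length(labels) != nrow(values))
    stop("ids, labels and values must agree on instance count", call. = FALSE)
  structure(list(values = values, ids = ids[, need, drop = FALSE],
                 labels = as.character(labels)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d instances x %d features\n",
              nrow(x$values), ncol(x$values)))
  if (nrow(x$values)) {
    tab <- table(x$labels)
    cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Write / read a feature table CSV
#'
#' Lossless CSV round trip: identity columns (`subject_id`, `condition`,
#' `camera_id`, `label`) followed by the feature columns, values at 17
#' significant digits. An empty table writes a header-only file.
#'
#' @param table A [feature_table].
#' @param path File path.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` returns a [feature_table].
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  id_cols <- c("subject_id", "condition", "camera_id", "label")
  header <- paste(c(id_cols, colnames(table$values)), collapse = ",")
  if (nrow(table$values)) {
    vals <- matrix(sprintf("%.17g", table$values), nrow = nrow(table$values))
    rows <- paste(table$ids$subject_id, table$ids$condition,
                  table$ids$camera_id, table$labels,
                  apply(vals, 1, paste, collapse = ","), sep = ",")
  } else rows <- character()
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character")
  id_cols <- c("subject_id", "condition", "camera_id", "label")
  if (!all(id_cols %in% names(df)))
    stop("feature table CSV must start with columns ",
         paste(id_cols, collapse = ", "), call. = FALSE)
  feat_cols <- setdiff(names(df), id_cols)
  if (anyDuplicated(feat_cols))
    stop("duplicate feature names in ", path, call. = FALSE)
  values <- matrix(0, nrow(df), length(feat_cols),
                   dimnames = list(NULL, feat_cols))
  if (nrow(df))
    for (j in seq_along(feat_cols))
      values[, j] <- as.numeric(df[[feat_cols[j]]])
  feature_table(values,
                data.frame(subject_id = df$subject_id,
                           condition = df$condition,
                           camera_id = df$camera_id,
                           stringsAsFactors = FALSE),
                labels = df$label)
}
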