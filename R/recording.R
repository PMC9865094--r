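#' Activity label dictionary
#'
#' The five gait activities and their integer codes as used in the label
#' channel of a recording: 1 = resting (standing still), 2 = walking,
#' 3 = running, 4 = ascending stairs, 5 = descending stairs.
#'
#' @return A data.frame with columns `code` and `name`.
#' @export
#' @examples
#' activity_labels()
activity_labels <- function() {
  data.frame(
    code = 1:5,
    name = c("resting", "walking", "running", "ascending_stairs",
             "descending_stairs"),
    stringsAsFactors = FALSE
  )
}

#' Sensor channel layout
#'
#' The canonical ordering of the 20 sensor channels of a recording:
#' 6 complementary-filter (CF) angles, 6 accelerometer (ACC), 6 gyroscope
#' (GYRO) and 2 strain-gauge (SG) channels, each tagged with its sensor
#' group and body side. A stored record row appends one label column, so a
#' full row carries 21 values.
#'
#' @return A data.frame with columns `channel`, `group`
#'   (one of CF/ACC/GYRO/SG) and `side` (left/right), in canonical order.
#' @export
#' @examples
#' sensor_layout()
sensor_layout <- function() {
  axes <- c("X", "Y", "Z")
  nm <- c(paste0("CF_LEFT_", axes),   paste0("CF_RIGHT_", axes),
          paste0("ACC_LEFT_", axes),  paste0("ACC_RIGHT_", axes),
          paste0("GYRO_LEFT_", axes), paste0("GYRO_RIGHT_", axes),
          "STRAIN_GAUGE_LEFT_X", "STRAIN_GAUGE_RIGHT_X")
  data.frame(
    channel = nm,
    group = c(rep("CF", 6), rep("ACC", 6), rep("GYRO", 6), rep("SG", 2)),
    side = c(rep(c("left", "left", "left", "right", "right", "right"), 3),
             "left", "right"),
    stringsAsFactors = FALSE
  )
}

sensor_groups <- function() c("CF", "ACC", "GYRO", "SG")

label_column_name <- function() "LABEL"

valid_label_codes <- function(label_mode) {
  switch(label_mode,
         activity5 = 1:5,
         fog_binary = 0:1,
         stop("unknown label_mode: ", label_mode, call. = FALSE))
}

#' Construct a gait recording
#'
#' A gait recording is the unit of all I/O in this package: a fixed-rate
#' multichannel time series (rows are samples, columns are sensor channels
#' in the canonical [sensor_layout()] order) together with a per-sample
#' label sequence. In `activity5` mode labels are the codes of
#' [activity_labels()]; in `fog_binary` mode they are 0/1 with 1 marking a
#' freezing-of-gait episode.
#'
#' @param data Numeric matrix, one row per sample; column names must be a
#'   subset of the canonical channel names, in canonical order.
#' @param labels Integer vector, one label per row of `data`.
#' @param sample_rate_hz Sampling rate in Hz (default 40; period
#'   `1000 / sample_rate_hz` ms).
#' @param subject_id Free-text identifier.
#' @param label_mode `"activity5"` or `"fog_binary"`.
#' @return An object of class `gait_recording`.
#' @export
gait_recording <- function(data, labels, sample_rate_hz = 40,
                           subject_id = "", label_mode = "activity5") {
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric matrix", call. = FALSE)
  layout <- sensor_layout()
  if (is.null(colnames(data)))
    stop("`data` must have channel column names", call. = FALSE)
  unknown <- setdiff(colnames(data), layout$channel)
  if (length(unknown))
    stop("unknown channels: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  canon <- layout$channel[layout$channel %in% colnames(data)]
  data <- data[, canon, drop = FALSE]
  labels <- as.integer(labels)
  if (nrow(data) != length(labels))
    stop("row count of `data` (", nrow(data),
         ") does not equal length of `labels` (", length(labels), ")",
         call. = FALSE)
  if (anyNA(data) || any(!is.finite(data)))
    stop("recording contains missing or non-finite sensor values",
         call. = FALSE)
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1 ||
      sample_rate_hz <= 0)
    stop("`sample_rate_hz` must be a positive number", call. = FALSE)
  label_mode <- match.arg(label_mode, c("activity5", "fog_binary"))
  ok <- valid_label_codes(label_mode)
  bad <- setdiff(unique(labels), ok)
  if (length(bad))
    stop("labels outside the allowed set {",
         paste(ok, collapse = ","), "}: ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(
    list(data = data, labels = labels, sample_rate_hz = sample_rate_hz,
         subject_id = subject_id, label_mode = label_mode),
    class = "gait_recording"
  )
}

#' @export
print.gait_recording <- function(x, ...) {
  grp <- table(factor(sensor_layout()$group[
    match(colnames(x$data), sensor_layout()$channel)],
    levels = sensor_groups()))
  cat(sprintf("<gait_recording> %d samples x %d channels @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$sample_rate_hz,
              nrow(x$data) / x$sample_rate_hz))
  cat("  channels:", paste(sprintf("%s=%d", names(grp), grp),
                           collapse = " "), "\n")
  cat("  label mode:", x$label_mode, "| labels:",
      paste(sprintf("%s:%d", names(table(x$labels)), table(x$labels)),
            collapse = " "), "\n")
  if (nzchar(x$subject_id)) cat("  subject:", x$subject_id, "\n")
  invisible(x)
}

#' Read a gait recording from delimited text
#'
#' Reads one recording from a comma-separated file with a mandatory header
#' row naming the sensor channels plus a final `LABEL` column (21 columns
#' for a full recording). Column order is coerced to the canonical
#' [sensor_layout()] order.
#'
#' @param path File path.
#' @param label_mode `"activity5"` or `"fog_binary"`.
#' @param sample_rate_hz Sampling rate of the stored recording (Hz).
#' @param subject_id Optional subject identifier to attach.
#' @param allow_subset Accept files holding only a subset of the 20
#'   canonical channels (e.g. written after [select_channels()]); the
#'   default requires all 20.
#' @return A [gait_recording()].
#' @export
read_recording <- function(path, label_mode = "activity5",
                           sample_rate_hz = 40, subject_id = "",
                           allow_subset = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = ",", header = TRUE,
                          data.table = FALSE, colClasses = "character")
  layout <- sensor_layout()
  cols <- colnames(dt)
  unknown <- setdiff(cols, c(layout$channel, label_column_name()))
  if (length(unknown))
    stop("schema error: unknown columns: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (!label_column_name() %in% cols)
    stop("schema error: missing columns: ", label_column_name(),
         call. = FALSE)
  missing <- setdiff(layout$channel, cols)
  if (length(missing) && !allow_subset)
    stop("schema error: missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  chan <- setdiff(cols, label_column_name())
  body <- suppressWarnings(
    vapply(dt[, c(chan, label_column_name()), drop = FALSE], as.numeric,
           numeric(nrow(dt))))
  if (nrow(dt) == 1L) body <- matrix(body, nrow = 1,
                                     dimnames = list(NULL, c(chan, label_column_name())))
  if (nrow(dt) > 0 && anyNA(body)) {
    bad <- which(rowSums(is.na(body)) > 0)[1]
    stop("parse error: non-numeric cell in data row ", bad, call. = FALSE)
  }
  labels <- if (nrow(dt)) as.integer(body[, label_column_name()]) else integer(0)
  data <- body[, chan, drop = FALSE]
  if (nrow(dt) == 0) {
    data <- matrix(numeric(0), nrow = 0, ncol = length(chan),
                   dimnames = list(NULL, chan))
  }
  gait_recording(data, labels, sample_rate_hz = sample_rate_hz,
                 subject_id = subject_id, label_mode = label_mode)
}

#' Write a gait recording to delimited text
#'
#' Writes the recording as comma-separated text with a header row naming
#' the channels plus `LABEL`, using enough digits for a lossless
#' read/write round trip of finite doubles.
#'
#' @param rec A [gait_recording()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "gait_recording"))
  if (nrow(rec$data) == 0) {
    header <- paste(c(colnames(rec$data), label_column_name()),
                    collapse = ",")
    ok <- tryCatch({
      writeLines(header, path)
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok))
      stop("I/O error writing ", path, ": ", conditionMessage(ok),
           call. = FALSE)
    return(invisible(path))
  }
  txt <- matrix(formatC(rec$data, format = "g", digits = 17),
                nrow = nrow(rec$data),
                dimnames = list(NULL, colnames(rec$data)))
  df <- as.data.frame(txt, stringsAsFactors = FALSE)
  df[[label_column_name()]] <- rec$labels
  ok <- tryCatch({
    data.table::fwrite(df, path, sep = ",", quote = FALSE, eol = "\n")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("I/O error writing ", path, ": ", conditionMessage(ok),
         call. = FALSE)
  invisible(path)
}

#' Split a recording into equal contiguous segments
#'
#' Used by the leave-one-segment-out protocol: a 30-minute, 72,000-sample
#' recording split into 10 segments yields ten 3-minute segments of 7,200
#' samples each.
#'
#' @param rec A [gait_recording()].
#' @param n_segments Number of segments; the sample count must be exactly
#'   divisible (truncate the recording first if not).
#' @return A list of `n_segments` recordings, in temporal order.
#' @export
slice_segments <- function(rec, n_segments) {
  stopifnot(inherits(rec, "gait_recording"))
  n_segments <- as.integer(n_segments)
  if (length(n_segments) != 1 || is.na(n_segments) || n_segments < 1)
    stop("`n_segments` must be a positive integer", call. = FALSE)
  T <- nrow(rec$data)
  if (T %% n_segments != 0)
    stop("recording length ", T, " is not divisible by ", n_segments,
         " segments; truncate the recording to a multiple of ", n_segments,
         " samples first (no samples are dropped silently)", call. = FALSE)
  len <- T %/% n_segments
  lapply(seq_len(n_segments), function(k) {
    idx <- ((k - 1) * len + 1):(k * len)
    gait_recording(rec$data[idx, , drop = FALSE], rec$labels[idx],
                   sample_rate_hz = rec$sample_rate_hz,
                   subject_id = rec$subject_id, label_mode = rec$label_mode)
  })
}

#' Restrict a recording to selected sensor groups
#'
#' Keeps only the channels belonging to the requested sensor groups
#' (CF, ACC, GYRO, SG), preserving canonical order and labels. This is the
#' primitive behind the sensor-importance ablations.
#'
#' @param rec A [gait_recording()].
#' @param groups Non-empty character vector, subset of
#'   `c("CF","ACC","GYRO","SG")`.
#' @return A [gait_recording()] with the restricted channel set.
#' @export
select_channels <- function(rec, groups) {
  stopifnot(inherits(rec, "gait_recording"))
  if (length(groups) == 0)
    stop("`groups` must be a non-empty subset of {CF, ACC, GYRO, SG}",
         call. = FALSE)
  groups <- unique(as.character(groups))
  bad <- setdiff(groups, sensor_groups())
  if (length(bad))
    stop("invalid sensor group(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  layout <- sensor_layout()
  keep <- layout$channel[layout$group %in% groups]
  keep <- intersect(keep, colnames(rec$data))
  if (length(keep) == 0)
    stop("selected groups match no channels present in the recording",
         call. = FALSE)
  gait_recording(rec$data[, keep, drop = FALSE], rec$labels,
                 sample_rate_hz = rec$sample_rate_hz,
                 subject_id = rec$subject_id, label_mode = rec$label_mode)
}
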