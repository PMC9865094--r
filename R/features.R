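#' Assemble a per-sample feature matrix from a recording
#'
#' In `raw` mode the features are the sensor channels themselves (20
#' columns for a full recording). In `cwt` mode every channel is expanded
#' into its per-sample CWT magnitudes and the blocks are concatenated in
#' canonical channel order (20 x 27 = 540 columns with the default
#' [cwt_config()]); feature names are `"<channel>@<freq>Hz"`. Rows stay
#' aligned 1:1 with the recording samples and labels are carried through.
#'
#' Values are returned unscaled; evaluation protocols fit a
#' [fit_normalizer()] on their training rows only and apply it to the rest,
#' so normalization never leaks test data. Call [apply_normalizer()]
#' directly when a standalone normalized matrix is wanted.
#'
#' @param rec A [gait_recording()].
#' @param mode `"raw"` or `"cwt"`.
#' @param cwt Optional [cwt_config()] used in `cwt` mode.
#' @return An object of class `gait_features`: list with `values` (T x F
#'   matrix), `mode`, `feature_names`, `labels`, `label_mode`,
#'   `sample_rate_hz`.
#' @export
assemble_features <- function(rec, mode = c("raw", "cwt"),
                              cwt = cwt_config()) {
  stopifnot(inherits(rec, "gait_recording"))
  mode <- match.arg(mode)
  if (mode == "raw") {
    values <- rec$data
  } else {
    blocks <- lapply(colnames(rec$data), function(ch) {
      b <- cwt_featureize(rec$data[, ch], cwt, rec$sample_rate_hz)
      colnames(b) <- paste0(ch, "@", colnames(b))
      b
    })
    values <- do.call(cbind, blocks)
  }
  structure(
    list(values = values, mode = mode, feature_names = colnames(values),
         labels = rec$labels, label_mode = rec$label_mode,
         sample_rate_hz = rec$sample_rate_hz),
    class = "gait_features"
  )
}

#' @export
print.gait_features <- function(x, ...) {
  cat(sprintf("<gait_features> %d samples x %d features (%s mode)\n",
              nrow(x$values), ncol(x$values), x$mode))
  invisible(x)
}

#' @export
dim.gait_features <- function(x) dim(x$values)

#' Subset a feature matrix by row indices
#'
#' Keeps the selected sample rows and their labels, e.g. to carve a
#' training segment out of a full recording's features.
#'
#' @param fm A `gait_features` object.
#' @param idx Integer (or logical) row index vector.
#' @return The subsetted `gait_features`.
#' @export
subset_features <- function(fm, idx) {
  stopifnot(inherits(fm, "gait_features"))
  fm$values <- fm$values[idx, , drop = FALSE]
  fm$labels <- fm$labels[idx]
  fm
}
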