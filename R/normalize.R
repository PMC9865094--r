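#' Fit per-feature min-max normalization statistics
#'
#' Records the per-feature minimum and maximum of the training rows.
#' Normalization is fit on training data only and then applied unchanged
#' to test data, so the test set never leaks into the scaling. Per-feature
#' (not global) scaling ensures small-amplitude channels, such as the
#' complementary-filter angles, are not dominated by louder sensors.
#'
#' @param x Numeric matrix (rows = samples) or a feature matrix from
#'   [assemble_features()].
#' @return An object of class `gait_norm_stats` with fields `min`, `max`,
#'   `target_lo = 0`, `target_hi = 5`.
#' @export
fit_normalizer <- function(x) {
  v <- feature_values(x)
  if (nrow(v) < 1) stop("cannot fit normalizer on empty input",
                        call. = FALSE)
  structure(
    list(min = apply(v, 2, min), max = apply(v, 2, max),
         target_lo = 0, target_hi = 5, n_features = ncol(v),
         feature_names = colnames(v)),
    class = "gait_norm_stats"
  )
}

#' Apply min-max normalization to the interval [0, 5]
#'
#' Rescales each feature with `5 * (x - min) / (max - min)` using the
#' fitted training statistics. A degenerate feature (`max == min`) maps to
#' 0; test-time values outside the fitted range are clipped to `[0, 5]`.
#'
#' @param x Numeric matrix or feature matrix whose columns match `stats`.
#' @param stats A `gait_norm_stats` from [fit_normalizer()].
#' @return Object of the same kind as `x`, with values in `[0, 5]`.
#' @export
apply_normalizer <- function(x, stats) {
  stopifnot(inherits(stats, "gait_norm_stats"))
  v <- feature_values(x)
  if (ncol(v) != stats$n_features)
    stop("feature count (", ncol(v), ") does not match fitted stats (",
         stats$n_features, ")", call. = FALSE)
  rng <- stats$max - stats$min
  scale <- ifelse(rng > 0, (stats$target_hi - stats$target_lo) / rng, 0)
  y <- sweep(v, 2, stats$min, "-")
  y <- sweep(y, 2, scale, "*")
  y[y < stats$target_lo] <- stats$target_lo
  y[y > stats$target_hi] <- stats$target_hi
  replace_feature_values(x, y)
}

# accepts either a bare matrix or a gait_features object
feature_values <- function(x) {
  if (inherits(x, "gait_features")) return(x$values)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop("expected a numeric matrix or gait_features object",
         call. = FALSE)
  x
}

replace_feature_values <- function(x, v) {
  if (inherits(x, "gait_features")) {
    x$values <- v
    x
  } else v
}
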