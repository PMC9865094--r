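#' Accelerometer inclination angles
#'
#' Converts a 3-axis accelerometer sequence into per-axis inclination
#' angles against gravity, in degrees, using the standard tilt convention:
#' the X and Y angles are the elevation of that axis out of the horizontal
#' plane, `atan2(a_axis, sqrt(sum of squares of the other two))`, and the
#' Z angle is the tilt away from vertical,
#' `atan2(sqrt(a_x^2 + a_y^2), a_z)`. A device lying with Z along gravity
#' therefore reads (0, 0, 0).
#'
#' @param acc_xyz Numeric matrix with 3 columns (x, y, z), one row per
#'   sample; every row must have non-zero magnitude.
#' @return A matrix of the same shape with angles in degrees.
#' @export
#' @examples
#' accel_inclination(rbind(c(0, 0, 1), c(1, 0, 1)))
accel_inclination <- function(acc_xyz) {
  if (is.null(dim(acc_xyz))) acc_xyz <- matrix(acc_xyz, nrow = 1)
  if (ncol(acc_xyz) != 3)
    stop("`acc_xyz` must have exactly 3 columns (x, y, z)", call. = FALSE)
  if (anyNA(acc_xyz)) stop("NaN/NA in accelerometer input", call. = FALSE)
  mag <- sqrt(rowSums(acc_xyz^2))
  if (any(mag == 0))
    stop("zero-magnitude accelerometer sample at row ",
         which(mag == 0)[1], call. = FALSE)
  r2d <- 180 / pi
  ax <- acc_xyz[, 1]; ay <- acc_xyz[, 2]; az <- acc_xyz[, 3]
  out <- cbind(
    atan2(ax, sqrt(ay^2 + az^2)) * r2d,
    atan2(ay, sqrt(ax^2 + az^2)) * r2d,
    atan2(sqrt(ax^2 + ay^2), az) * r2d
  )
  colnames(out) <- c("x", "y", "z")
  out
}

#' Complementary-filter sensor fusion
#'
#' Fuses a gyroscope rate sequence with an accelerometer-derived
#' inclination sequence into a drift-free angle estimate via the causal
#' recurrence
#' \deqn{\theta_t = \alpha (\theta_{t-1} + \omega_t \, dt) +
#'       (1-\alpha) a_t, \qquad \theta_0 = a_0,}
#' evaluated sample by sample. The gyroscope path dominates in the short
#' term (it is precise but drifts); the accelerometer path anchors the
#' long-term mean (noisy but drift-free). `alpha = 1` is pure gyro
#' integration, `alpha = 0` passes the accelerometer angle through.
#'
#' @param acc_angle Accelerometer inclination sequence (degrees).
#' @param gyro_rate Gyroscope angular-rate sequence (degrees/s), same
#'   length.
#' @param alpha Gyro-path weight in `[0, 1]` (default 0.98, standard
#'   complementary-filter practice).
#' @param dt_s Sampling period in seconds (1/40 at the default 40 Hz).
#' @return Fused angle sequence of the same length.
#' @export
#' @examples
#' complementary_filter(c(0, 0, 1, 1), c(0, 2, 2, 0),
#'                      alpha = 0.98, dt_s = 0.025)
complementary_filter <- function(acc_angle, gyro_rate, alpha = 0.98,
                                 dt_s = 1 / 40) {
  if (length(acc_angle) != length(gyro_rate))
    stop("`acc_angle` and `gyro_rate` must have equal length",
         call. = FALSE)
  if (anyNA(acc_angle) || anyNA(gyro_rate))
    stop("NaN/NA in filter input", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0 || alpha > 1)
    stop("`alpha` must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(dt_s) || dt_s <= 0)
    stop("`dt_s` must be positive", call. = FALSE)
  n <- length(acc_angle)
  if (n == 0) return(numeric(0))
  u <- alpha * gyro_rate * dt_s + (1 - alpha) * acc_angle
  theta1 <- acc_angle[1]
  if (n == 1) return(theta1)
  rest <- stats::filter(u[-1], filter = alpha, method = "recursive",
                        init = theta1)
  c(theta1, as.numeric(rest))
}
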