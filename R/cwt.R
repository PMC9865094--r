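#' Continuous-wavelet-transform configuration
#'
#' Human gait energy lives roughly between 0.5 and 10 Hz; the analysis
#' band 0.2--20 Hz brackets it with margin. Frequency bins are log-spaced
#' at `voices_per_octave` bins per octave, giving
#' `floor(voices_per_octave * log2(f_max/f_min)) + 1` bins -- 27 with the
#' defaults -- so each of the 20 sensor channels expands into 27 per-sample
#' frequency features (540 in total).
#'
#' @param f_min_hz Lowest analysis frequency (Hz).
#' @param f_max_hz Highest analysis frequency (Hz). The default equals the
#'   Nyquist frequency at 40 Hz sampling; the top bin is attenuated but
#'   retained.
#' @param voices_per_octave Bins per frequency octave (default 4).
#' @param omega0 Centre frequency (rad) of the analytic Morlet wavelet.
#' @return An object of class `gait_cwt_config`.
#' @export
cwt_config <- function(f_min_hz = 0.2, f_max_hz = 20,
                       voices_per_octave = 4, omega0 = 6) {
  if (f_min_hz <= 0 || f_max_hz <= f_min_hz)
    stop("need 0 < f_min_hz < f_max_hz", call. = FALSE)
  if (voices_per_octave < 1)
    stop("`voices_per_octave` must be >= 1", call. = FALSE)
  n_bins <- floor(voices_per_octave * log2(f_max_hz / f_min_hz)) + 1
  structure(
    list(f_min_hz = f_min_hz, f_max_hz = f_max_hz,
         voices_per_octave = voices_per_octave, omega0 = omega0,
         n_bins = as.integer(n_bins)),
    class = "gait_cwt_config"
  )
}

#' Centre frequencies of the CWT bins
#'
#' @param cfg A [cwt_config()].
#' @return Strictly increasing vector of `cfg$n_bins` frequencies in Hz,
#'   log-spaced from `f_min_hz` upwards, all within the analysis band.
#' @export
cwt_frequencies <- function(cfg = cwt_config()) {
  stopifnot(inherits(cfg, "gait_cwt_config"))
  cfg$f_min_hz * 2^((seq_len(cfg$n_bins) - 1) / cfg$voices_per_octave)
}

# half-support (samples) of the widest (lowest-frequency) wavelet atom;
# the Gaussian envelope has std `scale` samples, truncated where it falls
# below ~1e-3 of its peak
cwt_half_support <- function(cfg, fs_hz) {
  max_scale <- cfg$omega0 * fs_hz / (2 * pi * cfg$f_min_hz)
  ceiling(sqrt(2 * log(1000)) * max_scale)
}

#' Per-sample CWT magnitude features for one channel
#'
#' Computes the magnitude of the analytic Morlet continuous wavelet
#' transform of a single signal at each configured frequency bin, aligned
#' 1:1 with the input samples (no decimation). Amplitudes are normalized
#' so a unit-amplitude sinusoid at a bin's centre frequency yields a
#' magnitude near 1 in that bin. The transform is computed over the whole
#' signal in the frequency domain (offline workflow) with reflection
#' padding of half the longest wavelet support at both ends.
#'
#' @param signal Numeric vector.
#' @param cfg A [cwt_config()].
#' @param fs_hz Sampling rate in Hz.
#' @return A `length(signal) x n_bins` matrix of magnitudes; columns are
#'   named by bin frequency.
#' @export
cwt_featureize <- function(signal, cfg = cwt_config(), fs_hz = 40) {
  stopifnot(inherits(cfg, "gait_cwt_config"))
  signal <- as.numeric(signal)
  if (anyNA(signal)) stop("NaN/NA in signal", call. = FALSE)
  n <- length(signal)
  pad <- cwt_half_support(cfg, fs_hz)
  if (n < 2 || n < pad)
    stop("signal too short for the lowest analysis frequency: need at ",
         "least ", pad, " samples (", sprintf("%.1f", pad / fs_hz),
         " s at ", fs_hz, " Hz), got ", n, call. = FALSE)
  # reflection padding, then round up to an FFT-friendly length
  left <- signal[pmax(pmin(seq(pad + 1, 2), n), 1)]
  right <- signal[pmax(pmin(seq(n - 1, n - pad), n), 1)]
  x <- c(left, signal, right)
  nfft <- stats::nextn(length(x), c(2, 3, 5))
  x <- c(x, numeric(nfft - length(x)))
  X <- stats::fft(x)
  w <- 2 * pi * fs_hz * c(0:(nfft %/% 2),
                          -((nfft - nfft %/% 2 - 1):1)) / nfft
  freqs <- cwt_frequencies(cfg)
  out <- matrix(0, n, cfg$n_bins)
  keep <- (pad + 1):(pad + n)
  pos <- w > 0
  for (k in seq_len(cfg$n_bins)) {
    scale <- cfg$omega0 / (2 * pi * freqs[k])    # seconds
    psi <- numeric(nfft)
    psi[pos] <- 2 * exp(-(scale * w[pos] - cfg$omega0)^2 / 2)
    coef <- stats::fft(X * psi, inverse = TRUE) / nfft
    out[, k] <- Mod(coef[keep])
  }
  colnames(out) <- sprintf("%.4gHz", freqs)
  out
}
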