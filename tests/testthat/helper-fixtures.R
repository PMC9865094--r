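# Shared fixtures and independent oracles for the test suite.
# Everything is generated in code; no stored data.

# small valid recording with arbitrary but finite values
tiny_recording <- function(T = 12, seed = 7, label_mode = "activity5") {
  set.seed(seed)
  data <- matrix(rnorm(T * 20), T, 20,
                 dimnames = list(NULL, sensor_layout()$channel))
  labels <- if (label_mode == "activity5")
    rep(1:5, length.out = T) else rep(0:1, length.out = T)
  gait_recording(data, labels, label_mode = label_mode)
}

# short synthetic recording used across classifier tests (cached per run)
short_rec <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_recording(
        sim_config(total_duration_s = 240, seed = 11,
                   schedule_block_s = 60))
    cache
  }
})

# brute-force one-vs-rest metric oracle: recounts TP/FP/FN/TN directly
# from the label vectors, never via a confusion matrix
oracle_metrics <- function(pred, truth, cls) {
  tp <- sum(truth == cls & pred == cls)
  fp <- sum(truth != cls & pred == cls)
  fn <- sum(truth == cls & pred != cls)
  tn <- sum(truth != cls & pred != cls)
  total <- length(truth)
  sdiv <- function(a, b) if (b == 0) 0 else a / b
  precision <- sdiv(tp, tp + fp)
  sensitivity <- sdiv(tp, tp + fn)
  c(accuracy = (tp + tn) / total,
    precision = precision,
    sensitivity = sensitivity,
    specificity = sdiv(tn, tn + fp),
    f1 = sdiv(2 * precision * sensitivity, precision + sensitivity))
}

# brute-force analytic-Morlet magnitude via direct time-domain inner
# products (independent of the FFT implementation path)
oracle_morlet_mag <- function(signal, freq, fs, t_index, omega0 = 6) {
  scale <- omega0 / (2 * pi * freq) * fs     # samples
  halfw <- ceiling(sqrt(2 * log(1000)) * scale)
  k <- -halfw:halfw
  atom <- exp(1i * omega0 * k / scale) * exp(-(k / scale)^2 / 2)
  # L1-type normalization matching a unit response to a matched sinusoid
  atom <- 2 * atom / (scale * sqrt(2 * pi))
  idx <- t_index + k
  x <- signal[pmin(pmax(idx, 1), length(signal))]
  Mod(sum(x * Conj(atom)))
}
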