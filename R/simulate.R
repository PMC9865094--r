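#' Activity waveform profile
#'
#' Generative parameters of one activity's quasi-periodic limb
#' oscillation. Locomotor activities oscillate at a fundamental stride
#' frequency inside the 0.5--10 Hz band that carries human gait energy;
#' resting has zero stride frequency and near-noise-floor amplitudes.
#' Stair ascent and descent are separated from level walking by stride
#' frequency and by an opposite-signed left/right amplitude asymmetry.
#'
#' @param activity Activity name (see [activity_labels()]).
#' @param stride_freq_hz Fundamental limb-oscillation frequency (Hz); 0
#'   for resting, otherwise within 0.5--10.
#' @param acc_amp,gyro_amp,sg_amp Per-sensor-group amplitude scalars
#'   (accelerometer amplitudes are in g-like units around a unit gravity
#'   baseline on the Z axes).
#' @param harmonic_weights Relative amplitudes of harmonics 1..H.
#' @param left_right_phase_deg Phase offset of the right leg relative to
#'   the left (legs are anti-phase in normal gait).
#' @param asymmetry Left/right amplitude asymmetry: the left-side
#'   amplitude is scaled by `1 + asymmetry/2` and the right by
#'   `1 - asymmetry/2`.
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @return An object of class `gait_activity_profile`.
#' @export
activity_profile <- function(activity, stride_freq_hz, acc_amp = 1,
                             gyro_amp = 1, sg_amp = 0.8,
                             harmonic_weights = c(1, 0.4, 0.15),
                             left_right_phase_deg = 180, asymmetry = 0,
                             noise_sd = 0.05) {
  labs <- activity_labels()
  if (!activity %in% labs$name)
    stop("unknown activity: ", activity, call. = FALSE)
  if (stride_freq_hz < 0 ||
      (stride_freq_hz > 0 && (stride_freq_hz < 0.5 || stride_freq_hz > 10)))
    stop("`stride_freq_hz` must be 0 (resting) or within 0.5-10 Hz",
         call. = FALSE)
  structure(
    list(activity = activity, code = labs$code[labs$name == activity],
         stride_freq_hz = stride_freq_hz, acc_amp = acc_amp,
         gyro_amp = gyro_amp, sg_amp = sg_amp,
         harmonic_weights = harmonic_weights,
         left_right_phase_deg = left_right_phase_deg,
         asymmetry = asymmetry, noise_sd = noise_sd),
    class = "gait_activity_profile"
  )
}

#' Default activity profiles
#'
#' Plausible, mutually separable waveform profiles for the five
#' activities: resting (no oscillation, amplitude 0.05), walking at
#' 1.8 Hz, running at 2.8 Hz with doubled amplitudes, stair ascent at
#' 1.4 Hz with +30% left/right asymmetry and stair descent at 1.6 Hz
#' with -30% asymmetry; three harmonics with weights (1, 0.4, 0.15) and
#' anti-phase legs throughout.
#'
#' @return A named list of [activity_profile()]s, one per activity.
#' @export
default_profiles <- function() {
  list(
    resting = activity_profile("resting", 0, acc_amp = 0.05,
                               gyro_amp = 0.05, sg_amp = 0.05),
    walking = activity_profile("walking", 1.8),
    running = activity_profile("running", 2.8, acc_amp = 2, gyro_amp = 2,
                               sg_amp = 1.6),
    ascending_stairs = activity_profile("ascending_stairs", 1.4,
                                        asymmetry = 0.3),
    descending_stairs = activity_profile("descending_stairs", 1.6,
                                         asymmetry = -0.3)
  )
}

#' Reference activity distributions
#'
#' Per-subject activity-time fractions of the five-subject gait study
#' (resting, walking, running, ascending stairs, descending stairs),
#' returned as fractions summing to 1. Walking dominates every subject
#' (51--62%) and running is the sparsest activity.
#'
#' @param subject_index 1 to 5, or `"mean"` for the across-subject mean
#'   row.
#' @return Named numeric vector of 5 fractions.
#' @export
#' @examples
#' default_table2_distribution("mean")
default_table2_distribution <- function(subject_index = "mean") {
  rows <- rbind(
    `1` = c(12.2, 51.4, 9.6, 14.4, 12.4),
    `2` = c(9.5, 60.5, 5.9, 13.3, 10.8),
    `3` = c(7.3, 61.5, 6.3, 13.7, 11.2),
    `4` = c(10.4, 58.9, 6.2, 13.5, 11.0),
    `5` = c(8.0, 61.8, 5.9, 13.4, 10.9),
    mean = c(9.5, 58.8, 6.8, 13.6, 11.3)
  )
  key <- as.character(subject_index)
  if (!key %in% rownames(rows))
    stop("`subject_index` must be 1..5 or \"mean\"", call. = FALSE)
  out <- rows[key, ] / 100
  names(out) <- activity_labels()$name
  out
}

#' Simulation configuration
#'
#' @param sample_rate_hz Sampling rate (default 40 Hz).
#' @param total_duration_s Total recording duration in seconds (default
#'   1800 s = 30 min = 72,000 samples at 40 Hz).
#' @param activity_schedule Optional explicit schedule: a data.frame with
#'   columns `activity` and `duration_s` whose durations sum to
#'   `total_duration_s`. When omitted, a schedule is built from
#'   `target_distribution`.
#' @param target_distribution Fractions per activity summing to 1
#'   (default: the mean reference distribution,
#'   [default_table2_distribution()]).
#' @param seed Integer seed; all randomness of the generator flows
#'   through it.
#' @param gyro_drift_sd Per-sample step standard deviation of the slow
#'   random-walk bias added to gyroscope channels (gyroscopes drift over
#'   time; default 0.001).
#' @param crossfade_s Linear amplitude cross-fade at bout transitions
#'   (default 0.5 s); labels switch at the cross-fade midpoint.
#' @param schedule_block_s Scheduling block length: the target fractions
#'   are realized inside every block of this many seconds, so each
#'   3-minute block contains all five activities (default 180 s).
#' @param fog Optional [fog_config()] for binary freezing-of-gait
#'   recordings.
#' @return An object of class `gait_sim_config`.
#' @export
sim_config <- function(sample_rate_hz = 40, total_duration_s = 1800,
                       activity_schedule = NULL,
                       target_distribution = default_table2_distribution("mean"),
                       seed = 1, gyro_drift_sd = 0.001, crossfade_s = 0.5,
                       schedule_block_s = 180, fog = NULL) {
  if (sample_rate_hz <= 0 || total_duration_s <= 0)
    stop("sample rate and duration must be positive", call. = FALSE)
  if (!is.null(activity_schedule)) {
    if (!all(c("activity", "duration_s") %in% names(activity_schedule)))
      stop("`activity_schedule` needs columns activity, duration_s",
           call. = FALSE)
    bad <- setdiff(activity_schedule$activity, activity_labels()$name)
    if (length(bad))
      stop("unknown activity in schedule: ", paste(bad, collapse = ", "),
           call. = FALSE)
    if (abs(sum(activity_schedule$duration_s) - total_duration_s) > 1e-6)
      stop("schedule durations must sum to total_duration_s",
           call. = FALSE)
  } else {
    if (length(target_distribution) != 5)
      stop("`target_distribution` must have 5 entries", call. = FALSE)
    if (abs(sum(target_distribution) - 1) > 1e-9)
      stop("`target_distribution` must sum to 1 (got ",
           sum(target_distribution), ")", call. = FALSE)
    if (is.null(names(target_distribution)))
      names(target_distribution) <- activity_labels()$name
  }
  structure(
    list(sample_rate_hz = sample_rate_hz,
         total_duration_s = total_duration_s,
         activity_schedule = activity_schedule,
         target_distribution = target_distribution,
         seed = as.integer(seed), gyro_drift_sd = gyro_drift_sd,
         crossfade_s = crossfade_s, schedule_block_s = schedule_block_s,
         fog = fog),
    class = "gait_sim_config"
  )
}

#' Freezing-of-gait episode configuration
#'
#' FOG episodes are rare, brief (1--20 s) events during which the lower
#' limbs tremble at 3--8 Hz despite the intent to move. Two scenarios are
#' modelled: gait-initiation freezes (over a resting background; IMU
#' amplitudes stay low while the strain-gauge channels carry the muscle
#' tremble) and during-walking freezes (elevated trembling on the IMU
#' channels as well). The strain-gauge channels tremble in both.
#'
#' @param n_episodes Number of episodes (default 13).
#' @param episode_duration_s Length-2 range of episode durations in
#'   seconds, inside `[1, 20]`.
#' @param tremble_freq_hz Length-2 range of tremble frequencies (Hz).
#' @param scenario_mix Fraction of episodes that are gait-initiation
#'   freezes (the rest occur during walking).
#' @param target_fraction Fraction of all samples labelled FOG (default
#'   0.082).
#' @return An object of class `gait_fog_config`.
#' @export
fog_config <- function(n_episodes = 13, episode_duration_s = c(2, 18),
                       tremble_freq_hz = c(3, 8), scenario_mix = 0.5,
                       target_fraction = 0.082) {
  if (episode_duration_s[1] < 1 || episode_duration_s[2] > 20 ||
      episode_duration_s[1] > episode_duration_s[2])
    stop("`episode_duration_s` must be an increasing range within [1, 20]",
         call. = FALSE)
  if (target_fraction < 0 || target_fraction >= 1)
    stop("`target_fraction` must be in [0, 1)", call. = FALSE)
  structure(
    list(n_episodes = as.integer(n_episodes),
         episode_duration_s = episode_duration_s,
         tremble_freq_hz = tremble_freq_hz, scenario_mix = scenario_mix,
         target_fraction = target_fraction),
    class = "gait_fog_config"
  )
}

# ---- internal synthesis machinery -------------------------------------

# per-block bout schedule realizing the target fractions; returns a
# data.frame(code, n_samples). the largest-quota activity in each block is
# split into two bouts so blocks have ~6 bouts and ~5 transitions.
build_schedule <- function(T, fs, dist, block_samples) {
  codes <- activity_labels()$code
  dist <- dist / sum(dist)
  n_blocks <- max(1L, floor(T / block_samples))
  sizes <- rep(T %/% n_blocks, n_blocks)
  sizes[n_blocks] <- sizes[n_blocks] + T - sum(sizes)
  out <- list()
  for (b in seq_len(n_blocks)) {
    quota <- round(dist * sizes[b])
    quota[which.max(quota)] <- quota[which.max(quota)] +
      sizes[b] - sum(quota)
    big <- which.max(quota)
    half <- quota[big] %/% 2
    bouts <- data.frame(code = c(codes, codes[big]),
                        n = c(quota, quota[big] - half))
    bouts$n[big] <- half
    bouts <- bouts[bouts$n > 0, , drop = FALSE]
    bouts <- bouts[sample.int(nrow(bouts)), , drop = FALSE]
    # avoid back-to-back bouts of the same activity across the split
    while (any(diff(bouts$code) == 0) && nrow(bouts) > 2)
      bouts <- bouts[sample.int(nrow(bouts)), , drop = FALSE]
    out[[b]] <- bouts
  }
  res <- do.call(rbind, out)
  names(res) <- c("code", "n_samples")
  res
}

# centred moving average turning per-bout step traces into linear
# cross-fades of width `w` samples (labels stay sharp; signal blends)
smooth_trace <- function(x, w) {
  if (w <= 1) return(x)
  if (w %% 2 == 0) w <- w + 1
  n <- length(x)
  xp <- c(rep(x[1], w %/% 2), x, rep(x[n], w %/% 2))
  as.numeric(stats::filter(xp, rep(1 / w, w), sides = 2))[
    (w %/% 2 + 1):(w %/% 2 + n)]
}

# raw accelerometer / gyroscope / strain-gauge synthesis (no CF yet)
synth_raw_channels <- function(labels, profiles, fs, gyro_drift_sd,
                               crossfade_s) {
  T <- length(labels)
  dt <- 1 / fs
  w <- round(crossfade_s * fs)
  prof_of <- function(code) {
    for (p in profiles) if (p$code == code) return(p)
    stop("config error: no profile for activity code ", code,
         call. = FALSE)
  }
  by_code <- lapply(sort(unique(labels)), prof_of)
  names(by_code) <- vapply(by_code, function(p) as.character(p$code), "")
  getp <- function(field) {
    v <- vapply(by_code, function(p) p[[field]], numeric(1))
    v[as.character(labels)]
  }
  f_t <- smooth_trace(getp("stride_freq_hz"), w)
  noise_t <- smooth_trace(getp("noise_sd"), w)
  asym_t <- smooth_trace(getp("asymmetry"), w)
  amp <- list(ACC = smooth_trace(getp("acc_amp"), w),
              GYRO = smooth_trace(getp("gyro_amp"), w),
              SG = smooth_trace(getp("sg_amp"), w))
  hw <- profiles[[1]]$harmonic_weights
  lr <- profiles[[1]]$left_right_phase_deg * pi / 180
  phase <- cumsum(2 * pi * f_t * dt)
  osc <- function(shift, fun = sin) {
    v <- 0
    for (h in seq_along(hw)) v <- v + hw[h] * fun(h * phase + shift)
    v
  }
  side_amp <- function(base, side)
    if (side == "left") base * (1 + asym_t / 2) else base * (1 - asym_t / 2)
  ax_shift <- c(X = 0, Y = 2 * pi / 3, Z = 4 * pi / 3)
  noise <- function() stats::rnorm(T, 0, 1) * noise_t
  acc <- gyro <- matrix(0, T, 6)
  k <- 0
  for (side in c("left", "right")) {
    sshift <- if (side == "left") 0 else lr
    for (ax in c("X", "Y", "Z")) {
      k <- k + 1
      base <- osc(ax_shift[[ax]] + sshift)
      acc[, k] <- side_amp(amp$ACC, side) * base +
        (if (ax == "Z") 1 else 0) + noise()
      drift <- cumsum(stats::rnorm(T, 0, gyro_drift_sd))
      gyro[, k] <- side_amp(amp$GYRO, side) *
        osc(ax_shift[[ax]] + sshift, cos) + drift + noise()
    }
  }
  sg <- cbind(
    side_amp(amp$SG, "left") * (0.2 + abs(osc(0))) + noise(),
    side_amp(amp$SG, "right") * (0.2 + abs(osc(lr))) + noise()
  )
  list(acc = acc, gyro = gyro, sg = sg)
}

# complementary-filter channels derived from the synthetic IMU channels,
# reproducing the real pipeline where CF is computed from ACC + GYRO
derive_cf <- function(acc, gyro, fs, alpha = 0.98) {
  cf <- matrix(0, nrow(acc), 6)
  for (side in 0:1) {
    cols <- side * 3 + 1:3
    inc <- accel_inclination(acc[, cols, drop = FALSE])
    for (ax in 1:3)
      cf[, side * 3 + ax] <- complementary_filter(
        inc[, ax], gyro[, cols[ax]], alpha = alpha, dt_s = 1 / fs)
  }
  cf
}

assemble_channels <- function(cf, acc, gyro, sg) {
  data <- cbind(cf, acc, gyro, sg)
  colnames(data) <- sensor_layout()$channel
  data
}

#' Generate a synthetic labelled gait recording
#'
#' Produces a 40 Hz, 20-channel recording with activity-specific
#' quasi-periodic structure: every channel is a sum of harmonics at the
#' activity's stride frequency (per-group amplitudes, legs anti-phase,
#' left/right asymmetry for stair activities), plus Gaussian noise and a
#' slow random-walk gyroscope drift. Bout transitions are cross-faded
#' linearly over `crossfade_s`; labels switch at the cross-fade midpoint.
#' The complementary-filter channels are not synthesized independently:
#' they are derived by running [complementary_filter()] on the synthetic
#' accelerometer and gyroscope channels, as in the real pipeline. The
#' result is reproducible bit-exactly from `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @param profiles Named list of [activity_profile()]s covering all
#'   scheduled activities (default [default_profiles()]).
#' @return A [gait_recording()] with
#'   `round(total_duration_s * sample_rate_hz)` rows; the realized bout
#'   schedule is attached as attribute `"schedule"`.
#' @export
generate_recording <- function(cfg, profiles = default_profiles()) {
  stopifnot(inherits(cfg, "gait_sim_config"))
  fs <- cfg$sample_rate_hz
  T <- round(cfg$total_duration_s * fs)
  withr::with_seed(cfg$seed, {
    if (!is.null(cfg$activity_schedule)) {
      codes <- activity_labels()$code[
        match(cfg$activity_schedule$activity, activity_labels()$name)]
      sched <- data.frame(code = codes,
                          n_samples = round(cfg$activity_schedule$duration_s * fs))
      sched$n_samples[nrow(sched)] <- sched$n_samples[nrow(sched)] +
        T - sum(sched$n_samples)
    } else {
      sched <- build_schedule(T, fs, cfg$target_distribution,
                              round(cfg$schedule_block_s * fs))
    }
    labels <- rep(sched$code, sched$n_samples)
    have <- vapply(profiles, function(p) p$code, numeric(1))
    miss <- setdiff(unique(labels), have)
    if (length(miss))
      stop("config error: schedule uses activities without profiles: ",
           paste(activity_labels()$name[miss], collapse = ", "),
           call. = FALSE)
    raw <- synth_raw_channels(labels, profiles, fs, cfg$gyro_drift_sd,
                              cfg$crossfade_s)
    cf <- derive_cf(raw$acc, raw$gyro, fs)
    rec <- gait_recording(assemble_channels(cf, raw$acc, raw$gyro, raw$sg),
                          labels, sample_rate_hz = fs,
                          subject_id = "synthetic",
                          label_mode = "activity5")
    attr(rec, "schedule") <- sched
    rec
  })
}

#' Generate a synthetic freezing-of-gait recording
#'
#' Builds a resting/walking background recording and inserts
#' [fog_config()] tremble episodes with binary labels (1 inside an
#' episode, 0 elsewhere). Episode durations are drawn from the configured
#' range and rescaled so the achieved FOG fraction lands within one
#' percentage point of `target_fraction`; episodes are disjoint, placed
#' inside background bouts matching their scenario, and their label
#' transitions fall exactly at the inserted boundaries. The
#' complementary-filter channels are derived after the tremble overlay,
#' so they too carry the episode signature.
#'
#' @param cfg A [sim_config()] whose `fog` field is a [fog_config()];
#'   default: 24 minutes with 13 episodes covering ~8.2% of samples.
#' @param profiles Activity profiles for the background (default
#'   [default_profiles()]).
#' @return A [gait_recording()] in `fog_binary` mode; the episode
#'   registry (start/end sample, scenario, tremble frequency) is attached
#'   as attribute `"fog_episodes"`.
#' @export
generate_fog_recording <- function(cfg = sim_config(total_duration_s = 1440,
                                                    fog = fog_config()),
                                   profiles = default_profiles()) {
  stopifnot(inherits(cfg, "gait_sim_config"))
  if (is.null(cfg$fog))
    stop("config error: `cfg$fog` must be a fog_config()", call. = FALSE)
  fc <- cfg$fog
  fs <- cfg$sample_rate_hz
  T <- round(cfg$total_duration_s * fs)
  lo <- max(1, fc$episode_duration_s[1]) * fs
  hi <- min(20, fc$episode_duration_s[2]) * fs
  total_fog <- round(fc$target_fraction * T)
  if (fc$n_episodes > 0 &&
      (total_fog < fc$n_episodes * lo || total_fog > fc$n_episodes * hi))
    stop("config error: target_fraction ", fc$target_fraction,
         " is not reachable with ", fc$n_episodes,
         " episodes of ", fc$episode_duration_s[1], "-",
         fc$episode_duration_s[2], " s", call. = FALSE)
  withr::with_seed(cfg$seed, {
    # resting/walking background with ~1 min scheduling blocks
    bg_dist <- c(resting = 0.35, walking = 0.65, running = 0,
                 ascending_stairs = 0, descending_stairs = 0)
    sched <- build_schedule(T, fs, bg_dist, round(60 * fs))
    bg_labels <- rep(sched$code, sched$n_samples)
    raw <- synth_raw_channels(bg_labels, profiles, fs, cfg$gyro_drift_sd,
                              cfg$crossfade_s)
    labels <- integer(T)
    registry <- NULL
    if (fc$n_episodes > 0) {
      durs <- stats::runif(fc$n_episodes, lo, hi)
      durs <- pmin(pmax(round(durs * total_fog / sum(durs)), lo), hi)
      adj <- total_fog - sum(durs)
      durs[which.max(durs)] <- min(hi, max(lo, durs[which.max(durs)] + adj))
      scen <- ifelse(stats::runif(fc$n_episodes) < fc$scenario_mix,
                     "gait_initiation", "during_walking")
      tfreq <- stats::runif(fc$n_episodes, fc$tremble_freq_hz[1],
                            fc$tremble_freq_hz[2])
      # free intervals inside background bouts, 1 s margin at both ends
      ends <- cumsum(sched$n_samples)
      free <- data.frame(start = c(1, head(ends, -1) + 1) + fs,
                         end = ends - fs, code = sched$code)
      free <- free[free$end > free$start, ]
      # episodes spread over the whole session: episode e aims at the
      # centre of the e-th of n equal time strata, so both parts of a
      # chronological split see episodes
      target_pos <- round((seq_len(fc$n_episodes) - 0.5) /
                            fc$n_episodes * T)
      eps <- list()
      for (e in seq_len(fc$n_episodes)) {
        want <- if (scen[e] == "gait_initiation") 1L else 2L
        cand <- which(free$code == want & free$end - free$start + 1 >= durs[e])
        if (!length(cand))
          cand <- which(free$end - free$start + 1 >= durs[e])
        if (!length(cand))
          stop("config error: could not place all FOG episodes; lower ",
               "n_episodes or target_fraction", call. = FALSE)
        mid <- (free$start[cand] + free$end[cand]) / 2
        i <- cand[which.min(abs(mid - target_pos[e]))]
        s0 <- free$start[i] +
          floor(stats::runif(1) * (free$end[i] - free$start[i] + 1 - durs[e]))
        e0 <- s0 + durs[e] - 1
        # split the used free interval
        free <- rbind(free[-i, ],
                      data.frame(start = free$start[i], end = s0 - fs,
                                 code = free$code[i]),
                      data.frame(start = e0 + fs, end = free$end[i],
                                 code = free$code[i]))
        free <- free[free$end > free$start, ]
        eps[[length(eps) + 1]] <- data.frame(
          start = s0, end = e0, scenario = scen[e],
          tremble_freq_hz = tfreq[e])
      }
      registry <- do.call(rbind, eps)
      registry <- registry[order(registry$start), ]
      rownames(registry) <- NULL
      for (r in seq_len(nrow(registry))) {
        idx <- registry$start[r]:registry$end[r]
        labels[idx] <- 1L
        tt <- (idx - idx[1]) / fs
        env <- pmin(1, pmin(tt, rev(tt)) / 0.1)  # 0.1 s onset/offset ramp
        trem <- sin(2 * pi * registry$tremble_freq_hz[r] * tt +
                    stats::runif(1, 0, 2 * pi)) * env
        raw$sg[idx, ] <- raw$sg[idx, ] + 1.5 * trem
        if (registry$scenario[r] == "during_walking") {
          raw$acc[idx, ] <- raw$acc[idx, ] + 1.2 * trem
          raw$gyro[idx, ] <- raw$gyro[idx, ] + 1.2 * trem
        }
      }
    }
    cf <- derive_cf(raw$acc, raw$gyro, fs)
    rec <- gait_recording(assemble_channels(cf, raw$acc, raw$gyro, raw$sg),
                          labels, sample_rate_hz = fs,
                          subject_id = "synthetic-fog",
                          label_mode = "fog_binary")
    attr(rec, "fog_episodes") <- registry
    rec
  })
}

#' Shift a recording's labels in time
#'
#' Delays (`k > 0`) or advances (`k < 0`) the label sequence by `k`
#' samples, padding the opened edge with the first/last label. Useful as
#' a fixture with a known ground-truth detection delay.
#'
#' @param rec A [gait_recording()].
#' @param k Integer shift in samples, `|k| < T`.
#' @return The recording with shifted labels.
#' @export
shift_labels <- function(rec, k) {
  stopifnot(inherits(rec, "gait_recording"))
  k <- as.integer(k)
  T <- length(rec$labels)
  if (abs(k) >= T)
    stop("|k| must be smaller than the recording length ", T,
         call. = FALSE)
  if (k == 0) return(rec)
  lab <- rec$labels
  rec$labels <- if (k > 0)
    c(rep(lab[1], k), lab[seq_len(T - k)])
  else
    c(lab[(-k + 1):T], rep(lab[T], -k))
  rec
}
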