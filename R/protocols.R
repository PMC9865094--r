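#' Sensor-group combinations in ablation order
#'
#' All 15 non-empty subsets of the four sensor groups, in the order used
#' by the sensor-importance tables: the four single groups, the six
#' pairs, the four triples, then the full set.
#'
#' @return List of character vectors.
#' @export
sensor_combinations <- function() {
  list(c("CF"), c("ACC"), c("GYRO"), c("SG"),
       c("ACC", "GYRO"), c("ACC", "CF"), c("ACC", "SG"),
       c("GYRO", "CF"), c("GYRO", "SG"), c("CF", "SG"),
       c("CF", "SG", "GYRO"), c("CF", "SG", "ACC"),
       c("SG", "ACC", "GYRO"), c("CF", "ACC", "GYRO"),
       c("CF", "ACC", "GYRO", "SG"))
}

#' Leave-one-segment-out cross-validation
#'
#' The recording is split into `n_segments` equal contiguous segments
#' (ten 3-minute segments for the default 30-minute recording). In fold
#' k the classifier -- including its normalizer -- is fitted on segment k
#' alone and evaluated on all remaining samples, so each fold trains on
#' 3 minutes and tests on 27. Folds whose training segment does not
#' contain every class are skipped with a warning. Fold scores are
#' aggregated as the mean and the n-1 standard deviation
#' ([std_eq7()]).
#'
#' @param rec A [gait_recording()].
#' @param spec A [classifier_spec()].
#' @param n_segments Number of folds (default 10).
#' @param mode Feature mode, `"raw"` or `"cwt"`.
#' @param cwt [cwt_config()] for `cwt` mode.
#' @param epochs Optional epoch-count override for the gradient-trained
#'   kinds.
#' @param verbose Print per-fold progress.
#' @return An object of class `gait_cv_result`: `fold_reports` (list of
#'   [macro_report()]s), `mean_report` and `std_report` (named vectors
#'   over the five macro scores and `overall_accuracy`), `folds_used`,
#'   `skipped_folds`, `learn_time_s`, `classify_time_s`.
#' @export
segment_cv <- function(rec, spec, n_segments = 10,
                       mode = c("raw", "cwt"), cwt = cwt_config(),
                       epochs = NULL, verbose = FALSE) {
  stopifnot(inherits(rec, "gait_recording"))
  mode <- match.arg(mode)
  T <- nrow(rec$data)
  if (T %% n_segments != 0)
    stop("recording length ", T, " is not divisible into ", n_segments,
         " segments", call. = FALSE)
  feats <- assemble_features(rec, mode, cwt)
  codes <- expected_codes(rec$label_mode, spec$n_classes)
  len <- T %/% n_segments
  fold_reports <- list()
  skipped <- integer(0)
  learn_t <- classify_t <- 0
  for (k in seq_len(n_segments)) {
    idx <- ((k - 1) * len + 1):(k * len)
    if (length(setdiff(codes, unique(rec$labels[idx])))) {
      warning("fold ", k, " skipped: training segment lacks class(es) ",
              paste(setdiff(codes, unique(rec$labels[idx])),
                    collapse = ", "), call. = FALSE)
      skipped <- c(skipped, k)
      next
    }
    t0 <- proc.time()[["elapsed"]]
    model <- train_classifier(spec, subset_features(feats, idx),
                              epochs = epochs)
    t1 <- proc.time()[["elapsed"]]
    pr <- predict(model, feats)
    t2 <- proc.time()[["elapsed"]]
    learn_t <- learn_t + (t1 - t0)
    classify_t <- classify_t + (t2 - t1)
    test <- setdiff(seq_len(T), idx)
    cm <- confusion(pr$labels[test], rec$labels[test], codes)
    rep <- macro_report(cm)
    fold_reports[[length(fold_reports) + 1]] <- rep
    if (verbose)
      message(sprintf("fold %d: macro F1 %.4f, overall acc %.4f",
                      k, rep$macro[["f1"]], rep$overall_accuracy))
  }
  if (!length(fold_reports))
    stop("no valid fold: no training segment contained all classes",
         call. = FALSE)
  score_mat <- t(vapply(fold_reports, function(r)
    c(r$macro[metric_names()], overall_accuracy = r$overall_accuracy),
    numeric(6)))
  mean_report <- colMeans(score_mat)
  std_report <- if (nrow(score_mat) >= 2) apply(score_mat, 2, std_eq7)
                else rep(NA_real_, 6)
  names(std_report) <- colnames(score_mat)
  structure(
    list(fold_reports = fold_reports, mean_report = mean_report,
         std_report = std_report,
         folds_used = setdiff(seq_len(n_segments), skipped),
         skipped_folds = skipped, learn_time_s = learn_t,
         classify_time_s = classify_t),
    class = "gait_cv_result"
  )
}

#' @export
print.gait_cv_result <- function(x, digits = 4, ...) {
  cat(sprintf("<gait_cv_result> %d folds (%d skipped)\n",
              length(x$fold_reports), length(x$skipped_folds)))
  tab <- rbind(mean = x$mean_report, `std (n-1)` = x$std_report)
  print(round(tab, digits))
  cat(sprintf("learn %.1f s, classify %.1f s (informational)\n",
              x$learn_time_s, x$classify_time_s))
  invisible(x)
}

#' Mean detection delay of label transitions
#'
#' For every transition in the ground-truth labels, the delay is the
#' number of samples until the first subsequent transition of the
#' predicted labels into the same class, searched within a 2-second
#' horizon; transitions with no matching predicted transition are
#' excluded from the mean and counted. A prediction that is simply the
#' truth delayed by k samples therefore yields exactly k.
#'
#' @param pred,truth Equal-length label sequences; `truth` must contain
#'   at least one transition.
#' @param fs_hz Sampling rate used to convert samples to milliseconds.
#' @param horizon_s Search horizon after each true transition (default
#'   2 s).
#' @return List with `mean_delay_samples`, `mean_delay_ms`, `n_matched`,
#'   `n_unmatched` and a `transitions` data.frame.
#' @export
detection_delay <- function(pred, truth, fs_hz = 40, horizon_s = 2) {
  if (length(pred) != length(truth))
    stop("`pred` and `truth` must have equal length", call. = FALSE)
  tr_t <- which(diff(truth) != 0) + 1L
  if (!length(tr_t))
    stop("no label transitions in `truth`", call. = FALSE)
  tr_p <- which(diff(pred) != 0) + 1L
  horizon <- round(horizon_s * fs_hz)
  delays <- rep(NA_real_, length(tr_t))
  for (i in seq_along(tr_t)) {
    target <- truth[tr_t[i]]
    cand <- tr_p[tr_p >= tr_t[i] & tr_p <= tr_t[i] + horizon &
                 pred[tr_p] == target]
    # a prediction already in the target class at the transition instant
    # counts as an immediate (zero-delay) detection
    if (pred[tr_t[i]] == target) {
      delays[i] <- 0
    } else if (length(cand)) {
      delays[i] <- cand[1] - tr_t[i]
    }
  }
  matched <- !is.na(delays)
  if (!any(matched))
    stop("no true transition was matched by a predicted transition ",
         "within the horizon", call. = FALSE)
  data <- data.frame(index = tr_t, class = truth[tr_t],
                     delay_samples = delays)
  list(mean_delay_samples = mean(delays[matched]),
       mean_delay_ms = mean(delays[matched]) * 1000 / fs_hz,
       n_matched = sum(matched), n_unmatched = sum(!matched),
       transitions = data)
}

#' Sensor-importance ablation
#'
#' Re-runs an evaluation protocol on every requested sensor-group subset
#' of the recording: the channels are restricted with
#' [select_channels()], the feature matrix (and hence the CWT width, 27
#' bins per remaining channel) is re-derived, and the protocol is run
#' unchanged. One result row per combination, in the given order.
#'
#' @param rec A [gait_recording()].
#' @param spec A [classifier_spec()].
#' @param combinations List of sensor-group subsets (default: all 15,
#'   [sensor_combinations()]).
#' @param protocol `"cv"` ([segment_cv()]) or `"fog"` ([fog_protocol()]).
#' @param mode Feature mode.
#' @param ... Passed to the protocol (e.g. `epochs`, `n_segments`).
#' @return A data.frame with one row per combination: the combination
#'   label, the five macro scores and `overall_accuracy` (for `cv`, fold
#'   means).
#' @export
ablate_sensors <- function(rec, spec, combinations = sensor_combinations(),
                           protocol = c("cv", "fog"),
                           mode = c("raw", "cwt"), ...) {
  protocol <- match.arg(protocol)
  mode <- match.arg(mode)
  if (!length(combinations))
    stop("`combinations` must be non-empty", call. = FALSE)
  rows <- lapply(combinations, function(groups) {
    sub <- select_channels(rec, groups)
    scores <- if (protocol == "cv") {
      segment_cv(sub, spec, mode = mode, ...)$mean_report
    } else {
      r <- fog_protocol(sub, spec, mode = mode, ...)
      c(r$macro[metric_names()], overall_accuracy = r$overall_accuracy)
    }
    data.frame(combination = paste(groups, collapse = ", "),
               t(scores), check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Chronological 60/40 freezing-of-gait protocol
#'
#' Splits a binary-labelled recording chronologically (never shuffled)
#' at `floor(0.6 T)`: the first 60% trains the classifier, the
#' remaining 40% is scored. Both parts must contain both classes. The returned
#' report's positive-class row (class 1 = FOG) carries the
#' accuracy/precision/sensitivity/F1 scores of episode detection.
#'
#' @param rec A [gait_recording()] in `fog_binary` mode.
#' @param spec A [classifier_spec()] with `n_classes = 2`.
#' @param mode Feature mode (`"cwt"` detects the trembling signature
#'   best).
#' @param cwt [cwt_config()] for `cwt` mode.
#' @param train_fraction Chronological split point (default 0.6).
#' @param epochs Optional epoch-count override.
#' @return A [macro_report()] with the extra fields `positive` (named
#'   scores of class 1) and `split_index`.
#' @export
fog_protocol <- function(rec, spec, mode = c("cwt", "raw"),
                         cwt = cwt_config(), train_fraction = 0.6,
                         epochs = NULL) {
  stopifnot(inherits(rec, "gait_recording"))
  mode <- match.arg(mode)
  if (rec$label_mode != "fog_binary")
    stop("`rec` must be a fog_binary recording", call. = FALSE)
  T <- nrow(rec$data)
  split <- floor(train_fraction * T)
  train_idx <- seq_len(split)
  test_idx <- (split + 1):T
  for (part in list(c("train", 1, split), c("test", split + 1, T))) {
    lab <- rec$labels[as.integer(part[2]):as.integer(part[3])]
    miss <- setdiff(0:1, unique(lab))
    if (length(miss))
      stop("class ", miss[1], " missing from the ", part[1],
           " part of the chronological split", call. = FALSE)
  }
  feats <- assemble_features(rec, mode, cwt)
  model <- train_classifier(spec, subset_features(feats, train_idx),
                            epochs = epochs)
  pr <- predict(model, feats)
  cm <- confusion(pr$labels[test_idx], rec$labels[test_idx], 0:1)
  rep <- macro_report(cm)
  pos <- per_class_metrics(cm, 1)
  rep$positive <- unlist(pos[metric_names()])
  rep$split_index <- split
  rep
}
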