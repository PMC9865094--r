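#' Numerically stable softmax
#'
#' Maps a real vector to a probability vector via
#' \eqn{\sigma_i = e^{z_i} / \sum_j e^{z_j}}, computed with
#' max-subtraction so large inputs do not overflow. Adding a constant to
#' every entry leaves the output unchanged.
#'
#' @param z Finite numeric vector.
#' @return Probability vector summing to 1.
#' @export
#' @examples
#' softmax(c(0, log(2)))  # (1/3, 2/3)
softmax <- function(z) {
  if (length(z) == 0) stop("`z` must be non-empty", call. = FALSE)
  if (!all(is.finite(z))) stop("`z` must be finite", call. = FALSE)
  e <- exp(z - max(z))
  e / sum(e)
}

#' Classifier specification
#'
#' Declarative description of one of the nine classifier kinds behind the
#' common train/predict contract. `classifier_zoo()` seeds the
#' kind-specific hyper-parameter table with the study defaults
#' (epoch counts, learning rates, bottleneck sizes, tree limits, five
#' parallel attention streams, ...); entries passed in `hyper` override
#' them.
#'
#' @param kind One of `"ann"`, `"dt"`, `"svm"`, `"nb"`, `"lstm"`,
#'   `"ae_softmax"`, `"ae_bilstm"`, `"cnn_rnn"`, `"cnna_rnn"` (plus the
#'   internal `"oracle"` stub used to test evaluation protocols).
#' @param n_classes 2 (binary FOG) or 5 (activities).
#' @param hyper Named list of hyper-parameter overrides.
#' @param window_len Temporal context per prediction, in samples
#'   (default 64 = 1.6 s at 40 Hz), used by the windowed sequence kinds.
#' @param seed Integer seed governing initialization and batching.
#' @return An object of class `gait_classifier_spec`.
#' @export
classifier_spec <- function(kind, n_classes = 5, hyper = list(),
                            window_len = 64, seed = 1) {
  base <- classifier_zoo(kind)
  if (!n_classes %in% c(2L, 5L))
    stop("`n_classes` must be 2 or 5", call. = FALSE)
  h <- utils::modifyList(base$hyper, hyper)
  structure(
    list(kind = kind, n_classes = as.integer(n_classes), hyper = h,
         window_len = as.integer(window_len), seed = as.integer(seed)),
    class = "gait_classifier_spec"
  )
}

#' Default hyper-parameters per classifier kind
#'
#' @param kind Classifier kind name.
#' @return List with elements `kind`, `description` and `hyper` (the
#'   seeded defaults).
#' @export
classifier_zoo <- function(kind) {
  zoo <- list(
    ann = list(description = "feed-forward neural network (nnet backend)",
               hyper = list(hidden = 18, max_epoch = 50,
                            learn_rate = 0.01)),
    dt = list(description = "decision tree (rpart backend)",
              hyper = list(max_epoch = 50, max_splits = 10,
                           min_parent = 2, min_leaf = 1)),
    svm = list(description = paste0("support vector machine, radial ",
                                    "basis kernel, one-vs-one (e1071 ",
                                    "backend)"),
               hyper = list(max_epoch = 7, cost = 1)),
    nb = list(description = "naive Bayes, Gaussian class-conditionals",
              hyper = list(distribution = "gaussian", kfold = 10)),
    lstm = list(description = "unidirectional LSTM sequence classifier",
                hyper = list(max_epoch = 60, learn_rate = 0.003,
                             hidden = 32, balance_classes = TRUE)),
    ae_softmax = list(description = paste0("autoencoder bottleneck + ",
                                           "softmax classification layer"),
                      hyper = list(bottleneck = NA, encoder_max_epoch = 400,
                                   softmax_max_epoch = 400,
                                   learn_rate = 0.01)),
    ae_bilstm = list(description = paste0("autoencoder bottleneck + ",
                                          "bidirectional LSTM"),
                     hyper = list(bottleneck = NA, encoder_max_epoch = 400,
                                  max_epoch = 75, learn_rate = 0.003,
                                  hidden = 80, balance_classes = TRUE)),
    cnn_rnn = list(description = paste0("three causal 1-D convolution ",
                                        "layers -> LSTM -> two fully ",
                                        "connected layers -> softmax"),
                   hyper = list(max_epoch = 50, learn_rate = 0.003,
                                filters = c(20, 20, 20), kernel = 5,
                                rnn_hidden = 32, fc_hidden = 24,
                                balance_classes = TRUE)),
    cnna_rnn = list(description = paste0("five parallel convolution ",
                                         "streams merged by learnable ",
                                         "additive attention weights, ",
                                         "then the LSTM + fully ",
                                         "connected tail"),
                    hyper = list(n_streams = 5, max_epoch = 50,
                                 learn_rate = 0.003,
                                 filters = c(20, 20, 20), kernel = 5,
                                 rnn_hidden = 32, fc_hidden = 24,
                                 balance_classes = TRUE)),
    oracle = list(description = "label-echo stub for protocol testing",
                  hyper = list())
  )
  if (!kind %in% names(zoo))
    stop("unknown classifier kind \"", kind, "\"; valid kinds: ",
         paste(setdiff(names(zoo), "oracle"), collapse = ", "),
         call. = FALSE)
  c(list(kind = kind), zoo[[kind]])
}

# bottleneck default rule: 12 neurons on narrow (raw-like) inputs,
# 100 on wide (CWT-like) inputs
default_bottleneck <- function(n_features) if (n_features >= 100) 100L else 12L

#' Build an untrained CNN+RNN skeleton
#'
#' Three causal 1-D convolution layers over the input window, a single
#' LSTM layer, then two fully connected layers ending in a per-sample
#' softmax head. With the default sizing on 20 raw channels the network
#' has roughly 14k learnable parameters.
#'
#' @param spec A [classifier_spec()] of kind `"cnn_rnn"` (or
#'   `"cnna_rnn"`, from which the single-stream sizing is taken).
#' @param n_features Input feature width (20 raw, 540 CWT).
#' @return An object of class `gait_network`: list with `cfg`, `params`
#'   and `param_count`.
#' @export
build_cnn_rnn <- function(spec, n_features) {
  stopifnot(inherits(spec, "gait_classifier_spec"))
  h <- spec$hyper
  cfg <- seqnet_config(n_in = n_features, n_classes = spec$n_classes,
                       streams = 1, filters = h$filters,
                       kernel = h$kernel, rnn = "lstm",
                       rnn_hidden = h$rnn_hidden, fc_hidden = h$fc_hidden,
                       window_len = spec$window_len)
  params <- withr::with_seed(spec$seed, seqnet_init(cfg))
  structure(list(cfg = cfg, params = params,
                 param_count = seqnet_param_count(params)),
            class = "gait_network")
}

#' Build an untrained attention CNNA+RNN skeleton
#'
#' `n_streams` independent copies of the CNN+RNN convolution stack whose
#' feature maps are merged by an additive attention block -- one learnable
#' scalar weight `aw` per stream (initialized to `1/n_streams`, learned
#' jointly by backpropagation), merged map `sum_s aw_s * F_s` with the
#' same shape as any single stream's map -- followed by the same LSTM and
#' fully connected tail.
#'
#' @param spec A [classifier_spec()] of kind `"cnna_rnn"` with
#'   `n_streams >= 2`.
#' @param n_features Input feature width.
#' @return A `gait_network` skeleton.
#' @export
build_cnna_rnn <- function(spec, n_features) {
  stopifnot(inherits(spec, "gait_classifier_spec"))
  h <- spec$hyper
  if (is.null(h$n_streams) || h$n_streams < 2)
    stop("`n_streams` must be >= 2 (a single stream collapses to ",
         "cnn_rnn)", call. = FALSE)
  cfg <- seqnet_config(n_in = n_features, n_classes = spec$n_classes,
                       streams = h$n_streams, filters = h$filters,
                       kernel = h$kernel, rnn = "lstm",
                       rnn_hidden = h$rnn_hidden, fc_hidden = h$fc_hidden,
                       window_len = spec$window_len)
  params <- withr::with_seed(spec$seed, seqnet_init(cfg))
  structure(list(cfg = cfg, params = params,
                 param_count = seqnet_param_count(params)),
            class = "gait_network")
}

#' Number of learnable parameters
#'
#' @param x A `gait_network` skeleton or a trained `gait_model`.
#' @return Integer parameter count.
#' @export
param_count <- function(x) {
  if (inherits(x, "gait_network")) return(x$param_count)
  if (inherits(x, "gait_model")) return(x$param_count)
  stop("no parameter count for this object", call. = FALSE)
}

#' Train an autoencoder for feature reduction
#'
#' A three-part network -- encoder, bottleneck, decoder -- trained to
#' reconstruct its input under mean-squared loss with Adam. After
#' training, only the encoder/bottleneck half is needed to compress
#' features (12 bottleneck neurons on raw inputs, 100 on CWT inputs by
#' default).
#'
#' @param x Numeric matrix or `gait_features` (rows = samples). Train on
#'   normalized features.
#' @param bottleneck Bottleneck width; must be smaller than the feature
#'   count. Default: 12 if fewer than 100 features, else 100.
#' @param max_epoch Training epochs (default 400).
#' @param learn_rate Adam learning rate.
#' @param activation Hidden activation: `"tanh"` (default) or
#'   `"linear"` (a linear bottleneck spans the principal subspace).
#' @param seed Integer seed.
#' @return An object of class `gait_autoencoder` with fields `layers`,
#'   `bottleneck`, `loss_log`, `param_count`. Use
#'   `predict(ae, x, type = "encode")` or `type = "reconstruct"`.
#' @export
train_autoencoder <- function(x, bottleneck = NULL, max_epoch = 400,
                              learn_rate = 0.01, activation = "tanh",
                              seed = 1) {
  v <- feature_values(x)
  F <- ncol(v)
  if (is.null(bottleneck) || is.na(bottleneck))
    bottleneck <- default_bottleneck(F)
  bottleneck <- as.integer(bottleneck)
  if (bottleneck >= F)
    stop("`bottleneck` (", bottleneck, ") must be smaller than the ",
         "feature count (", F, ")", call. = FALSE)
  layers <- withr::with_seed(seed, dense_init(c(F, bottleneck, F)))
  tr <- train_dense(layers, v, v, epochs = max_epoch, lr = learn_rate,
                    seed = seed, act = activation, loss = "mse")
  structure(
    list(layers = tr$layers, bottleneck = bottleneck,
         activation = activation, loss_log = tr$loss_log,
         param_count = seqnet_param_count(tr$layers)),
    class = "gait_autoencoder"
  )
}

#' @export
predict.gait_autoencoder <- function(object, newdata,
                                     type = c("encode", "reconstruct"),
                                     ...) {
  type <- match.arg(type)
  v <- feature_values(newdata)
  acts <- dense_forward(object$layers, v, act = object$activation)
  if (type == "encode") acts[[2]] else acts[[3]]
}

# encode helper that keeps the activation of the trained encoder
ae_encode <- function(ae, v) {
  acts <- dense_forward(ae$layers, v, act = ae$activation)
  acts[[2]]
}

expected_codes <- function(label_mode, n_classes) {
  if (label_mode == "fog_binary" || n_classes == 2) 0:1 else 1:5
}

#' Train a classifier
#'
#' Fits one of the nine classifier kinds on a per-sample feature matrix.
#' Min-max normalization statistics are fitted on the training rows and
#' stored in the model, so prediction always applies the training-time
#' scaling (with clipping) to new data. Training is deterministic given
#' `spec$seed`. Every class of the label mode must be present in the
#' training data.
#'
#' @param spec A [classifier_spec()].
#' @param features A `gait_features` from [assemble_features()] (or any
#'   object with `values` and `labels`).
#' @param epochs Optional override of the kind's default epoch count, for
#'   scaled-down training runs.
#' @param normalize Fit-and-store a `[0, 5]` normalizer on the training
#'   rows (default TRUE).
#' @return An object of class `gait_model` with fields `spec`, `fit`,
#'   `classes`, `n_features`, `training_log` (per-epoch loss for the
#'   gradient-trained kinds), `param_count`, `norm_stats`.
#' @export
train_classifier <- function(spec, features, epochs = NULL,
                             normalize = TRUE) {
  stopifnot(inherits(spec, "gait_classifier_spec"))
  if (is.null(features$labels))
    stop("`features` carries no labels", call. = FALSE)
  codes <- expected_codes(features$label_mode %||% "activity5",
                          spec$n_classes)
  miss <- setdiff(codes, unique(features$labels))
  if (length(miss))
    stop("training data is missing class(es): ",
         paste(miss, collapse = ", "),
         " (every class must appear in the training segment)",
         call. = FALSE)
  stats <- if (normalize) fit_normalizer(features$values) else NULL
  X <- if (normalize) feature_values(apply_normalizer(features$values, stats))
       else feature_values(features$values)
  y_idx <- match(features$labels, codes)
  h <- spec$hyper
  fit <- NULL; log <- numeric(0); pc <- NA_integer_
  kind <- spec$kind
  center <- NULL
  if (kind %in% c("lstm", "cnn_rnn", "cnna_rnn", "ae_softmax",
                  "ae_bilstm")) {
    # the gradient-trained nets see zero-mean inputs: all-positive [0,5]
    # features saturate the gate nonlinearities and stall convergence
    center <- colMeans(X)
    X <- sweep(X, 2, center)
  }
  cls_w <- NULL
  if (isTRUE(h$balance_classes)) {
    # inverse-frequency per-sample weights (mean 1) so sparse activities
    # contribute equally to the loss despite the class imbalance
    freq <- tabulate(y_idx, nbins = length(codes)) / length(y_idx)
    cls_w <- (1 / (freq[y_idx] * length(codes)))
  }
  if (kind == "oracle") {
    fit <- list()
    pc <- 0L
  } else if (kind == "nb") {
    fit <- withr::with_seed(spec$seed,
      e1071::naiveBayes(as.data.frame(X),
                        factor(features$labels, levels = codes)))
    pc <- 2L * length(codes) * ncol(X)
  } else if (kind == "dt") {
    df <- data.frame(X)
    colnames(df) <- paste0("V", seq_len(ncol(X)))  # rpart-safe names
    df$.y <- factor(features$labels, levels = codes)
    ctl <- rpart::rpart.control(cp = 0, xval = 0, maxsurrogate = 0,
                                maxcompete = 0,
                                minsplit = h$min_parent,
                                minbucket = h$min_leaf)
    fit <- withr::with_seed(spec$seed,
      rpart::rpart(.y ~ ., data = df, method = "class", control = ctl))
    if (is.finite(h$max_splits)) {
      ct <- fit$cptable
      ok <- which(ct[, "nsplit"] <= h$max_splits)
      fit <- rpart::prune(fit, cp = ct[max(ok), "CP"])
    }
    pc <- 2L
  } else if (kind == "svm") {
    fit <- withr::with_seed(spec$seed,
      e1071::svm(X, factor(features$labels, levels = codes),
                 kernel = "radial", cost = h$cost, probability = TRUE))
    pc <- length(fit$coefs)
  } else if (kind == "ann") {
    ep <- epochs %||% h$max_epoch
    fit <- withr::with_seed(spec$seed,
      nnet::nnet(X, nnet::class.ind(factor(features$labels,
                                           levels = codes)),
                 size = h$hidden, softmax = TRUE, maxit = ep,
                 MaxNWts = 1e6, trace = FALSE))
    pc <- length(fit$wts)
  } else if (kind == "lstm") {
    cfg <- seqnet_config(n_in = ncol(X), n_classes = spec$n_classes,
                         streams = 0, rnn = "lstm",
                         rnn_hidden = h$hidden, fc_hidden = 0,
                         window_len = spec$window_len)
    params <- withr::with_seed(spec$seed, seqnet_init(cfg))
    tr <- train_seqnet(cfg, params, X, y_idx,
                       epochs = epochs %||% h$max_epoch,
                       lr = h$learn_rate, seed = spec$seed,
                       sample_weights = cls_w,
                       batch_samples = h$batch_samples %||% 512,
                       augment = h$augment %||% TRUE)
    fit <- list(cfg = cfg, params = tr$params)
    log <- tr$loss_log
    pc <- seqnet_param_count(tr$params)
  } else if (kind %in% c("cnn_rnn", "cnna_rnn")) {
    skel <- if (kind == "cnn_rnn") build_cnn_rnn(spec, ncol(X))
            else build_cnna_rnn(spec, ncol(X))
    tr <- train_seqnet(skel$cfg, skel$params, X, y_idx,
                       epochs = epochs %||% h$max_epoch,
                       lr = h$learn_rate, seed = spec$seed,
                       sample_weights = cls_w,
                       batch_samples = h$batch_samples %||% 512,
                       augment = h$augment %||% TRUE)
    fit <- list(cfg = skel$cfg, params = tr$params)
    log <- tr$loss_log
    pc <- skel$param_count
  } else if (kind == "ae_softmax") {
    bn <- if (is.na(h$bottleneck)) default_bottleneck(ncol(X))
          else h$bottleneck
    ae <- train_autoencoder(X, bottleneck = bn,
                            max_epoch = epochs %||% h$encoder_max_epoch,
                            learn_rate = h$learn_rate, seed = spec$seed)
    E <- ae_encode(ae, X)
    head_layers <- withr::with_seed(spec$seed + 1L,
      dense_init(c(bn, spec$n_classes)))
    tr <- train_dense(head_layers, E, y_idx,
                      epochs = epochs %||% h$softmax_max_epoch,
                      lr = h$learn_rate, seed = spec$seed,
                      loss = "xent")
    fit <- list(ae = ae, head = tr$layers)
    log <- tr$loss_log
    pc <- ae$param_count + seqnet_param_count(tr$layers)
  } else if (kind == "ae_bilstm") {
    bn <- if (is.na(h$bottleneck)) default_bottleneck(ncol(X))
          else h$bottleneck
    ae <- train_autoencoder(X, bottleneck = bn,
                            max_epoch = epochs %||% h$encoder_max_epoch,
                            learn_rate = 0.01, seed = spec$seed)
    E <- ae_encode(ae, X)
    cfg <- seqnet_config(n_in = bn, n_classes = spec$n_classes,
                         streams = 0, rnn = "bilstm",
                         rnn_hidden = h$hidden, fc_hidden = 0,
                         window_len = spec$window_len)
    params <- withr::with_seed(spec$seed, seqnet_init(cfg))
    tr <- train_seqnet(cfg, params, E, y_idx,
                       epochs = epochs %||% h$max_epoch,
                       lr = h$learn_rate, seed = spec$seed,
                       sample_weights = cls_w,
                       batch_samples = h$batch_samples %||% 512,
                       augment = h$augment %||% TRUE)
    fit <- list(ae = ae, cfg = cfg, params = tr$params)
    log <- tr$loss_log
    pc <- ae$param_count + seqnet_param_count(tr$params)
  } else {
    stop("unknown classifier kind: ", kind, call. = FALSE)
  }
  structure(
    list(spec = spec, fit = fit, classes = codes, n_features = ncol(X),
         feature_names = colnames(X), training_log = log,
         param_count = pc, norm_stats = stats, center = center),
    class = "gait_model"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict per-sample labels and class probabilities
#'
#' @param object A trained `gait_model`.
#' @param newdata A `gait_features` (or numeric matrix) with the same
#'   feature width as the training data.
#' @param ... Unused.
#' @return List with `labels` (length-T vector of class codes; argmax of
#'   the probability rows, ties resolved to the lowest class code) and
#'   `probs` (T x K matrix, rows summing to 1, columns named by class
#'   code).
#' @export
predict.gait_model <- function(object, newdata, ...) {
  v <- feature_values(newdata)
  if (ncol(v) != object$n_features)
    stop("feature count (", ncol(v), ") does not match the model (",
         object$n_features, ")", call. = FALSE)
  if (!is.null(object$norm_stats))
    v <- feature_values(apply_normalizer(v, object$norm_stats))
  if (!is.null(object$center)) v <- sweep(v, 2, object$center)
  codes <- object$classes
  kind <- object$spec$kind
  P <- if (kind == "oracle") {
    lab <- newdata$labels
    if (is.null(lab))
      stop("oracle stub needs labelled features", call. = FALSE)
    out <- matrix(0, nrow(v), length(codes))
    out[cbind(seq_len(nrow(v)), match(lab, codes))] <- 1
    out
  } else if (kind == "nb") {
    stats::predict(object$fit, as.data.frame(v), type = "raw")
  } else if (kind == "dt") {
    nd <- data.frame(v)
    colnames(nd) <- paste0("V", seq_len(ncol(v)))
    stats::predict(object$fit, nd, type = "prob")
  } else if (kind == "svm") {
    pr <- stats::predict(object$fit, v, probability = TRUE)
    pm <- attr(pr, "probabilities")
    pm[, match(as.character(codes), colnames(pm)), drop = FALSE]
  } else if (kind == "ann") {
    out <- stats::predict(object$fit, v, type = "raw")
    if (is.null(dim(out))) out <- cbind(1 - out, out)
    out
  } else if (kind %in% c("lstm", "cnn_rnn", "cnna_rnn")) {
    predict_seqnet(object$fit$cfg, object$fit$params, v)
  } else if (kind == "ae_softmax") {
    E <- ae_encode(object$fit$ae, v)
    logits <- dense_forward(object$fit$head, E, act = "linear")[[2]]
    t(apply(logits, 1, softmax))
  } else if (kind == "ae_bilstm") {
    E <- ae_encode(object$fit$ae, v)
    predict_seqnet(object$fit$cfg, object$fit$params, E)
  } else stop("unknown kind", call. = FALSE)
  P <- as.matrix(P)
  P <- P / rowSums(P)
  colnames(P) <- as.character(codes)
  list(labels = codes[max.col(P, ties.method = "first")], probs = P)
}

#' @export
print.gait_model <- function(x, ...) {
  cat(sprintf("<gait_model> kind=%s classes=%s features=%d params=%s\n",
              x$spec$kind, paste(x$classes, collapse = ","),
              x$n_features, format(x$param_count, big.mark = ",")))
  if (length(x$training_log))
    cat(sprintf("  final training loss: %.4g (%d epochs)\n",
                utils::tail(x$training_log, 1), length(x$training_log)))
  invisible(x)
}
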