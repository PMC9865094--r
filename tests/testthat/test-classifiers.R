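test_that("softmax is a stable, translation-invariant distribution", {
  expect_equal(softmax(c(0, log(2))), c(1 / 3, 2 / 3), tolerance = 1e-14)
  expect_equal(softmax(rep(3.7, 6)), rep(1 / 6, 6))
  set.seed(8)
  for (i in 1:20) {
    z <- rnorm(sample(2:8, 1), sd = 10)
    p <- softmax(z)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_equal(softmax(z + 123.45), p, tolerance = 1e-12)
  }
  # large magnitudes do not overflow
  expect_equal(sum(softmax(c(1e4, 1e4 - 1))), 1)
  expect_error(softmax(numeric(0)), "non-empty")
  expect_error(softmax(c(1, Inf)), "finite")
})

test_that("the classifier zoo seeds kind-specific defaults", {
  expect_equal(classifier_zoo("nb")$hyper$distribution, "gaussian")
  expect_equal(classifier_zoo("dt")$hyper$max_splits, 10)
  expect_equal(classifier_zoo("dt")$hyper$min_parent, 2)
  expect_equal(classifier_zoo("cnna_rnn")$hyper$n_streams, 5)
  expect_equal(classifier_zoo("ann")$hyper$max_epoch, 50)
  expect_equal(classifier_zoo("lstm")$hyper$max_epoch, 60)
  expect_equal(classifier_zoo("ae_bilstm")$hyper$max_epoch, 75)
  expect_equal(classifier_zoo("ae_softmax")$hyper$encoder_max_epoch, 400)
  expect_equal(classifier_zoo("svm")$hyper$max_epoch, 7)
  expect_match(classifier_zoo("lstm")$description, "LSTM")
  expect_error(classifier_zoo("xyz"), "valid kinds")
  # spec overrides merge over defaults
  sp <- classifier_spec("cnna_rnn", hyper = list(n_streams = 3))
  expect_equal(sp$hyper$n_streams, 3)
  expect_equal(sp$hyper$max_epoch, 50)
})

test_that("naive Bayes separates well-separated Gaussian blobs", {
  set.seed(12)
  n <- 300
  X <- rbind(matrix(rnorm(n * 3, 0), ncol = 3),
             matrix(rnorm(n * 3, 6), ncol = 3))
  colnames(X) <- c("a", "b", "c")
  feats <- structure(list(values = X,
                          labels = rep(0:1, each = n),
                          label_mode = "fog_binary"),
                     class = "gait_features")
  m <- train_classifier(classifier_spec("nb", n_classes = 2), feats)
  pr <- predict(m, feats)
  expect_gte(mean(pr$labels == feats$labels), 0.99)
  expect_equal(unname(rowSums(pr$probs)), rep(1, 2 * n),
               tolerance = 1e-9)
})

test_that("decision tree respects the split cap and can memorize when uncapped", {
  rec <- short_rec()
  feats <- assemble_features(rec, "raw")
  tr <- gaitrec:::subset_features(feats, 1:2400)
  m <- train_classifier(classifier_spec("dt"), tr)
  n_splits <- sum(m$fit$frame$var != "<leaf>")
  expect_lte(n_splits, 10)
  # unlimited variant memorizes a small distinct training set
  small <- gaitrec:::subset_features(feats, seq(1, 2400, by = 12))
  m2 <- train_classifier(classifier_spec("dt",
                                         hyper = list(max_splits = Inf)),
                         small)
  pr <- predict(m2, small)
  expect_gte(mean(pr$labels == small$labels), 0.999)
})

test_that("training requires every class in the training data", {
  rec <- short_rec()
  feats <- assemble_features(rec, "raw")
  only2 <- gaitrec:::subset_features(feats, which(feats$labels %in% c(1, 2)))
  expect_error(train_classifier(classifier_spec("nb"), only2),
               "missing class")
  expect_error(train_classifier(classifier_spec("nb"), list(values = 1)),
               "no labels")
})

test_that("network skeletons land in the intended size band and nest by stream count", {
  cnn <- build_cnn_rnn(classifier_spec("cnn_rnn"), n_features = 20)
  expect_gte(cnn$param_count, 10000)
  expect_lte(cnn$param_count, 20000)
  cnna <- build_cnna_rnn(classifier_spec("cnna_rnn"), n_features = 20)
  expect_gt(cnna$param_count, cnn$param_count)
  # ~5x the single-stream conv parameters + the shared tail
  conv1 <- sum(vapply(cnn$params$conv[[1]],
                      function(l) length(l$W) + length(l$b), 0))
  tail_n <- cnn$param_count - conv1
  expect_equal(cnna$param_count, 5 * conv1 + tail_n + 5)
  expect_error(build_cnna_rnn(classifier_spec("cnna_rnn",
                                              hyper = list(n_streams = 1)),
                              20),
               "n_streams")
  # window shorter than the receptive field is rejected
  expect_error(build_cnn_rnn(classifier_spec("cnn_rnn", window_len = 8),
                             20),
               "receptive field")
})

test_that("an idle network still emits finite normalized probabilities", {
  net <- build_cnn_rnn(classifier_spec("cnn_rnn"), n_features = 20)
  X <- matrix(0, 70, 20)
  P <- gaitrec:::predict_seqnet(net$cfg, net$params, X)
  expect_true(all(is.finite(P)))
  expect_equal(unname(rowSums(P)), rep(1, 70), tolerance = 1e-9)
  expect_equal(dim(P), c(70, 5))
})

test_that("a single active attention stream reproduces the plain CNN+RNN exactly", {
  spec_a <- classifier_spec("cnna_rnn", seed = 4)
  spec_c <- classifier_spec("cnn_rnn", seed = 4)
  cnna <- build_cnna_rnn(spec_a, n_features = 20)
  cnn <- build_cnn_rnn(spec_c, n_features = 20)
  # share the tail and copy the single conv stack into stream 1
  p <- cnna$params
  p$conv[[1]] <- cnn$params$conv[[1]]
  p$rnn <- cnn$params$rnn
  p$fc1 <- cnn$params$fc1
  p$fc2 <- cnn$params$fc2
  p$aw <- c(1, 0, 0, 0, 0)
  set.seed(3)
  X <- matrix(rnorm(200 * 20), 200, 20)
  Pa <- gaitrec:::predict_seqnet(cnna$cfg, p, X)
  Pc <- gaitrec:::predict_seqnet(cnn$cfg, cnn$params, X)
  expect_identical(Pa, Pc)
})

test_that("backpropagated gradients match finite differences on a tiny net", {
  set.seed(42)
  cfg <- gaitrec:::seqnet_config(n_in = 3, n_classes = 3, streams = 2,
                                 filters = c(4, 4, 3), kernel = 3,
                                 rnn = "lstm", rnn_hidden = 4,
                                 fc_hidden = 4, window_len = 16)
  p <- gaitrec:::seqnet_init(cfg)
  B <- 2; T <- 8
  X <- matrix(rnorm(B * T * 3), B * T, 3)
  y <- sample(1:3, B * T, replace = TRUE)
  fw <- gaitrec:::seqnet_forward(cfg, p, X, B, T, keep_cache = TRUE)
  ce <- gaitrec:::softmax_xent(fw$logits, y)
  g <- gaitrec:::seqnet_backward(cfg, p, fw$cache, ce$dlogits)
  fl <- unlist(p)
  gl <- unlist(g[names(p)])
  loss_at <- function(v) {
    fw <- gaitrec:::seqnet_forward(cfg, utils::relist(v, p), X, B, T,
                                   keep_cache = FALSE)
    gaitrec:::softmax_xent(fw$logits, y)$loss
  }
  ids <- sample(length(fl), 25)
  rel <- vapply(ids, function(i) {
    eps <- 1e-5
    up <- fl; up[i] <- up[i] + eps
    dn <- fl; dn[i] <- dn[i] - eps
    num <- (loss_at(up) - loss_at(dn)) / (2 * eps)
    abs(num - gl[i]) / max(1e-6, abs(num) + abs(gl[i]))
  }, 0)
  expect_lt(stats::median(rel), 1e-5)
  expect_lt(max(rel), 1e-2)  # isolated ReLU kinks
})

test_that("sequence kinds train deterministically under a fixed seed", {
  rec <- short_rec()
  feats <- assemble_features(rec, "raw")
  tr <- gaitrec:::subset_features(feats, 1:2400)
  spec <- classifier_spec("cnna_rnn", seed = 6,
                          hyper = list(n_streams = 2,
                                       filters = c(6, 6, 6),
                                       rnn_hidden = 8, fc_hidden = 8))
  m1 <- train_classifier(spec, tr, epochs = 2)
  m2 <- train_classifier(spec, tr, epochs = 2)
  expect_identical(m1$fit$params, m2$fit$params)
  p1 <- predict(m1, tr)
  p2 <- predict(m2, tr)
  expect_identical(p1$labels, p2$labels)
  # training loss trends downward (smoothed over epochs)
  m3 <- train_classifier(spec, tr, epochs = 8)
  log <- m3$training_log
  expect_lt(mean(utils::tail(log, 3)), mean(utils::head(log, 3)))
})

test_that("prediction contract: aligned rows, unit-sum probabilities, low-code ties", {
  rec <- short_rec()
  feats <- assemble_features(rec, "raw")
  tr <- gaitrec:::subset_features(feats, 1:2400)
  m <- train_classifier(classifier_spec("nb"), tr)
  pr <- predict(m, feats)
  expect_length(pr$labels, nrow(feats$values))
  expect_equal(dim(pr$probs), c(nrow(feats$values), 5))
  expect_equal(unname(rowSums(pr$probs)), rep(1, nrow(feats$values)),
               tolerance = 1e-9)
  expect_error(predict(m, feats$values[, 1:7]), "feature count")
  # argmax tie resolution picks the lowest class code
  P <- rbind(c(0.2, 0.4, 0.4, 0, 0), c(0.5, 0.5, 0, 0, 0))
  expect_equal(c(1:5)[max.col(P, ties.method = "first")][1], 2)
  expect_equal(c(1:5)[max.col(P, ties.method = "first")][2], 1)
})

test_that("autoencoder compresses, reconstructs, and spans low-rank data", {
  set.seed(77)
  # rank-2 data in 6 dimensions
  basis <- matrix(rnorm(12), 2, 6)
  X <- matrix(rnorm(400), 200, 2) %*% basis
  ae <- train_autoencoder(X, bottleneck = 5, max_epoch = 200,
                          activation = "linear", seed = 1)
  enc <- predict(ae, X, type = "encode")
  recon <- predict(ae, X, type = "reconstruct")
  expect_equal(dim(enc), c(200, 5))
  expect_equal(dim(recon), dim(X))
  # bottleneck >= rank: near-perfect reconstruction (principal subspace)
  rel_err <- mean((recon - X)^2) / mean(X^2)
  expect_lt(rel_err, 0.01)
  # training reduces the reconstruction loss by at least 10%
  expect_lt(utils::tail(ae$loss_log, 1), 0.9 * ae$loss_log[1])
  expect_error(train_autoencoder(X, bottleneck = 6), "smaller")
})

test_that("autoencoder-based and delegated kinds clear the majority baseline", {
  rec <- short_rec()
  feats <- assemble_features(rec, "raw")
  tr <- gaitrec:::subset_features(feats, 1:2400)
  test_idx <- 2401:9600
  truth <- feats$labels[test_idx]
  majority <- max(tabulate(truth, 5)) / length(truth)
  fast <- list(
    ann = list(spec = classifier_spec("ann"), epochs = 40),
    svm = list(spec = classifier_spec("svm"), epochs = NULL),
    ae_softmax = list(spec = classifier_spec("ae_softmax"), epochs = 60),
    ae_bilstm = list(spec = classifier_spec("ae_bilstm",
                                            hyper = list(hidden = 24)),
                     epochs = 12),
    lstm = list(spec = classifier_spec("lstm"), epochs = 6)
  )
  for (nm in names(fast)) {
    m <- train_classifier(fast[[nm]]$spec, tr, epochs = fast[[nm]]$epochs)
    pr <- predict(m, gaitrec:::subset_features(feats, test_idx))
    acc <- mean(pr$labels == truth)
    expect_gt(acc, majority)
  }
})

test_that("the bottleneck default follows the feature width", {
  expect_equal(gaitrec:::default_bottleneck(20), 12L)
  expect_equal(gaitrec:::default_bottleneck(540), 100L)
})

test_that("models survive a save/load round trip", {
  rec <- short_rec()
  feats <- assemble_features(rec, "raw")
  tr <- gaitrec:::subset_features(feats, 1:2400)
  m <- train_classifier(classifier_spec("nb"), tr)
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f)
  expect_identical(predict(m2, tr)$labels, predict(m, tr)$labels)
  expect_error(load_model(withr::local_tempfile()), "not found")
})
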