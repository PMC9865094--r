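# Internal sequence-network engine: causal 1-D convolution stacks
# (optionally several parallel streams merged by additive attention),
# an LSTM / biLSTM recurrent layer and fully connected layers with a
# per-sample softmax head. Everything is plain R on BLAS matrix products;
# gradients are exact backpropagation (checked against finite differences
# in the test suite) and optimization is Adam.
#
# Data layout: a batch of B sequences of common length T is stored as a
# flat (B*T) x C matrix, row r = (b-1)*T + t. Convolutions never bleed
# across sequence boundaries; causal left padding replicates each
# sequence's first sample.

sigm <- function(x) 1 / (1 + exp(-x))

seqnet_config <- function(n_in, n_classes, streams = 1,
                          filters = c(20, 20, 20), kernel = 5,
                          rnn = c("lstm", "bilstm"), rnn_hidden = 32,
                          fc_hidden = 24, window_len = 64) {
  rnn <- match.arg(rnn)
  rf <- length(filters) * (kernel - 1) + 1  # conv receptive field
  if (streams > 0 && window_len < rf)
    stop("window_len (", window_len, ") is smaller than the total ",
         "convolution receptive field (", rf, " samples)", call. = FALSE)
  list(n_in = n_in, n_classes = n_classes, streams = as.integer(streams),
       filters = filters, kernel = kernel, rnn = rnn,
       rnn_hidden = rnn_hidden, fc_hidden = fc_hidden,
       window_len = as.integer(window_len), receptive_field = rf)
}

# scaled uniform fan-in init; LSTM forget-gate bias starts at 1
seqnet_init <- function(cfg) {
  mk <- function(nr, nc) {
    s <- sqrt(1 / nr)
    matrix(stats::runif(nr * nc, -s, s), nr, nc)
  }
  lstm_par <- function(n_in, h) {
    b <- numeric(4 * h)
    b[(h + 1):(2 * h)] <- 1
    list(W = mk(n_in, 4 * h), U = mk(h, 4 * h), b = b)
  }
  p <- list()
  if (cfg$streams > 0) {
    p$conv <- lapply(seq_len(cfg$streams), function(s) {
      cin <- cfg$n_in
      lapply(cfg$filters, function(cout) {
        l <- list(W = mk(cfg$kernel * cin, cout), b = numeric(cout))
        cin <<- cout
        l
      })
    })
    if (cfg$streams > 1) p$aw <- rep(1 / cfg$streams, cfg$streams)
  }
  top <- if (cfg$streams > 0) utils::tail(cfg$filters, 1) else cfg$n_in
  if (cfg$rnn == "lstm") {
    p$rnn <- lstm_par(top, cfg$rnn_hidden)
    rnn_out <- cfg$rnn_hidden
  } else {
    p$rnn_f <- lstm_par(top, cfg$rnn_hidden)
    p$rnn_b <- lstm_par(top, cfg$rnn_hidden)
    rnn_out <- 2 * cfg$rnn_hidden
  }
  if (cfg$fc_hidden > 0) {
    p$fc1 <- list(W = mk(rnn_out, cfg$fc_hidden), b = numeric(cfg$fc_hidden))
    p$fc2 <- list(W = mk(cfg$fc_hidden, cfg$n_classes),
                  b = numeric(cfg$n_classes))
  } else {
    p$fc2 <- list(W = mk(rnn_out, cfg$n_classes),
                  b = numeric(cfg$n_classes))
  }
  p
}

seqnet_param_count <- function(p) {
  n <- 0
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk) else n <<- n + length(x)
    invisible(NULL)
  }
  walk(p)
  n
}

addb <- function(Y, b) Y + rep(b, each = nrow(Y))

# causal im2col gather indices for B sequences of length T, kernel k
im2col_idx <- function(B, T, k) {
  base <- rep((seq_len(B) - 1L) * T, each = T)
  tt <- rep(seq_len(T), B)
  idx <- matrix(0L, B * T, k)
  for (j in 0:(k - 1)) idx[, j + 1] <- base + pmax(tt - j, 1L)
  idx
}

im2col <- function(X, idx) {
  k <- ncol(idx)
  out <- matrix(0, nrow(idx), k * ncol(X))
  cw <- ncol(X)
  for (j in seq_len(k))
    out[, ((j - 1) * cw + 1):(j * cw)] <- X[idx[, j], , drop = FALSE]
  out
}

conv_forward <- function(X, idx, lay) {
  cols <- im2col(X, idx)
  Z <- addb(cols %*% lay$W, lay$b)
  list(Y = pmax(Z, 0), cols = cols, mask = Z > 0)
}

conv_backward <- function(dY, cache, lay, idx, cin, want_dX = TRUE) {
  dZ <- dY * cache$mask
  dW <- crossprod(cache$cols, dZ)
  db <- colSums(dZ)
  dX <- NULL
  if (want_dX) {
    dcols <- dZ %*% t(lay$W)
    dX <- matrix(0, nrow(dY), cin)
    for (j in seq_len(ncol(idx))) {
      blk <- dcols[, ((j - 1) * cin + 1):(j * cin), drop = FALSE]
      agg <- rowsum(blk, group = idx[, j])
      rows <- as.integer(rownames(agg))
      dX[rows, ] <- dX[rows, , drop = FALSE] + agg
    }
  }
  list(dX = dX, grad = list(W = dW, b = db))
}

lstm_forward <- function(X, B, T, p, reverse = FALSE, keep_cache = TRUE) {
  H <- ncol(p$U) / 4
  XW <- X %*% p$W
  h <- matrix(0, B, H)
  cc <- matrix(0, B, H)
  Hout <- matrix(0, B * T, H)
  ts <- if (reverse) rev(seq_len(T)) else seq_len(T)
  cache <- if (keep_cache) vector("list", T) else NULL
  for (t in ts) {
    rows <- (seq_len(B) - 1L) * T + t
    g <- XW[rows, , drop = FALSE] + h %*% p$U + rep(p$b, each = B)
    i <- sigm(g[, 1:H, drop = FALSE])
    f <- sigm(g[, (H + 1):(2 * H), drop = FALSE])
    gg <- tanh(g[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- sigm(g[, (3 * H + 1):(4 * H), drop = FALSE])
    c_prev <- cc
    h_prev <- h
    cc <- f * cc + i * gg
    tc <- tanh(cc)
    h <- o * tc
    Hout[rows, ] <- h
    if (keep_cache)
      cache[[t]] <- list(i = i, f = f, gg = gg, o = o, c_prev = c_prev,
                         h_prev = h_prev, tc = tc, rows = rows)
  }
  list(H = Hout, cache = cache, ts = ts)
}

lstm_backward <- function(dH, X, B, T, p, fwd) {
  H <- ncol(p$U) / 4
  dW <- matrix(0, nrow(p$W), 4 * H)
  dU <- matrix(0, H, 4 * H)
  db <- numeric(4 * H)
  dX <- matrix(0, B * T, nrow(p$W))
  dh_next <- matrix(0, B, H)
  dc_next <- matrix(0, B, H)
  tU <- t(p$U)
  tW <- t(p$W)
  for (t in rev(fwd$ts)) {
    cc <- fwd$cache[[t]]
    rows <- cc$rows
    dh <- dH[rows, , drop = FALSE] + dh_next
    do <- dh * cc$tc
    dc <- dc_next + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$gg
    dg <- dc * cc$i
    df <- dc * cc$c_prev
    dc_next <- dc * cc$f
    dgates <- cbind(di * cc$i * (1 - cc$i),
                    df * cc$f * (1 - cc$f),
                    dg * (1 - cc$gg^2),
                    do * cc$o * (1 - cc$o))
    dW <- dW + crossprod(X[rows, , drop = FALSE], dgates)
    dU <- dU + crossprod(cc$h_prev, dgates)
    db <- db + colSums(dgates)
    dh_next <- dgates %*% tU
    dX[rows, ] <- dgates %*% tW
  }
  list(dX = dX, grad = list(W = dW, U = dU, b = db))
}

seqnet_forward <- function(cfg, p, X, B, T, keep_cache = TRUE) {
  cache <- list(B = B, T = T)
  if (cfg$streams > 0) {
    idx <- im2col_idx(B, T, cfg$kernel)
    cache$idx <- idx
    cache$streams <- vector("list", cfg$streams)
    Ys <- vector("list", cfg$streams)
    for (s in seq_len(cfg$streams)) {
      cur <- X
      lays <- vector("list", length(cfg$filters))
      for (l in seq_along(cfg$filters)) {
        cv <- conv_forward(cur, idx, p$conv[[s]][[l]])
        lays[[l]] <- if (keep_cache)
          list(cols = cv$cols, mask = cv$mask, cin = ncol(cur)) else NULL
        cur <- cv$Y
      }
      Ys[[s]] <- cur
      cache$streams[[s]] <- lays
    }
    if (cfg$streams > 1) {
      M <- p$aw[1] * Ys[[1]]
      for (s in 2:cfg$streams) M <- M + p$aw[s] * Ys[[s]]
      if (keep_cache) cache$Ys <- Ys
    } else M <- Ys[[1]]
  } else M <- X
  cache$M <- M
  if (cfg$rnn == "lstm") {
    fwd <- lstm_forward(M, B, T, p$rnn, keep_cache = keep_cache)
    R <- fwd$H
    cache$rnn <- fwd
  } else {
    fwd_f <- lstm_forward(M, B, T, p$rnn_f, reverse = FALSE,
                          keep_cache = keep_cache)
    fwd_b <- lstm_forward(M, B, T, p$rnn_b, reverse = TRUE,
                          keep_cache = keep_cache)
    R <- cbind(fwd_f$H, fwd_b$H)
    cache$rnn_f <- fwd_f
    cache$rnn_b <- fwd_b
  }
  cache$R <- R
  if (cfg$fc_hidden > 0) {
    Z1 <- addb(R %*% p$fc1$W, p$fc1$b)
    A1 <- pmax(Z1, 0)
    cache$fc1_mask <- Z1 > 0
    cache$A1 <- A1
    logits <- addb(A1 %*% p$fc2$W, p$fc2$b)
  } else {
    logits <- addb(R %*% p$fc2$W, p$fc2$b)
  }
  list(logits = logits, cache = cache)
}

seqnet_backward <- function(cfg, p, cache, dlogits) {
  g <- list()
  if (cfg$fc_hidden > 0) {
    g$fc2 <- list(W = crossprod(cache$A1, dlogits), b = colSums(dlogits))
    dA1 <- dlogits %*% t(p$fc2$W)
    dZ1 <- dA1 * cache$fc1_mask
    g$fc1 <- list(W = crossprod(cache$R, dZ1), b = colSums(dZ1))
    dR <- dZ1 %*% t(p$fc1$W)
  } else {
    g$fc2 <- list(W = crossprod(cache$R, dlogits), b = colSums(dlogits))
    dR <- dlogits %*% t(p$fc2$W)
  }
  B <- cache$B; T <- cache$T
  if (cfg$rnn == "lstm") {
    bk <- lstm_backward(dR, cache$M, B, T, p$rnn, cache$rnn)
    g$rnn <- bk$grad
    dM <- bk$dX
  } else {
    h <- ncol(cache$rnn_f$H)
    bkf <- lstm_backward(dR[, 1:h, drop = FALSE], cache$M, B, T,
                         p$rnn_f, cache$rnn_f)
    bkb <- lstm_backward(dR[, (h + 1):(2 * h), drop = FALSE], cache$M,
                         B, T, p$rnn_b, cache$rnn_b)
    g$rnn_f <- bkf$grad
    g$rnn_b <- bkb$grad
    dM <- bkf$dX + bkb$dX
  }
  if (cfg$streams > 0) {
    nl <- length(cfg$filters)
    g$conv <- vector("list", cfg$streams)
    if (cfg$streams > 1) {
      g$aw <- vapply(seq_len(cfg$streams),
                     function(s) sum(dM * cache$Ys[[s]]), numeric(1))
    }
    for (s in seq_len(cfg$streams)) {
      dcur <- if (cfg$streams > 1) p$aw[s] * dM else dM
      glays <- vector("list", nl)
      for (l in nl:1) {
        cc <- cache$streams[[s]][[l]]
        bk <- conv_backward(dcur, cc, p$conv[[s]][[l]], cache$idx,
                            cc$cin, want_dX = (l > 1))
        glays[[l]] <- bk$grad
        dcur <- bk$dX
      }
      g$conv[[s]] <- glays
    }
  }
  g
}

# cross-entropy loss + gradient for per-sample softmax outputs;
# y is a 1-based class index vector, w optional per-sample weights
softmax_xent <- function(logits, y, w = NULL) {
  m <- apply(logits, 1, max)
  ez <- exp(logits - m)
  P <- ez / rowSums(ez)
  n <- nrow(logits)
  ii <- cbind(seq_len(n), y)
  dl <- P
  dl[ii] <- dl[ii] - 1
  if (is.null(w)) {
    loss <- -mean(log(pmax(P[ii], 1e-300)))
    dl <- dl / n
  } else {
    sw <- sum(w)
    loss <- -sum(w * log(pmax(P[ii], 1e-300))) / sw
    dl <- dl * (w / sw)
  }
  list(loss = loss, P = P, dlogits = dl)
}

# ---- Adam over nested parameter lists ---------------------------------

adam_state <- function(p) {
  zero <- function(x) if (is.list(x)) lapply(x, zero) else x * 0
  list(m = zero(p), v = zero(p), t = 0)
}

adam_step <- function(p, g, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1
  corr1 <- 1 - beta1^st$t
  corr2 <- 1 - beta2^st$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      keys <- if (is.null(names(p))) seq_along(p) else names(p)
      for (k in keys) {
        r <- upd(p[[k]], g[[k]], m[[k]], v[[k]])
        out_p[[k]] <- r$p; out_m[[k]] <- r$m; out_v[[k]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      p <- p - lr * (m / corr1) / (sqrt(v / corr2) + eps)
      list(p = p, m = m, v = v)
    }
  }
  r <- upd(p, g, st$m, st$v)
  list(p = r$p, state = list(m = r$m, v = r$v, t = st$t))
}

# ---- training and prediction over long sequences ----------------------

train_seqnet <- function(cfg, params, X, y_idx, epochs, lr,
                         batch_samples = 512, seed = 1,
                         sample_weights = NULL, augment = TRUE) {
  T <- nrow(X)
  W <- min(cfg$window_len, T)
  per_batch <- max(1L, floor(batch_samples / W))
  burn <- min(W %/% 4, 16L)
  burn_mask <- rep(1, W)
  if (burn > 0) burn_mask[seq_len(burn)] <- 0
  st <- adam_state(params)
  log <- numeric(epochs)
  best <- list(loss = Inf, params = params)
  withr::with_seed(seed, {
    for (ep in seq_len(epochs)) {
      # augmentation: a fresh random offset of the window grid each
      # epoch (so windows cut the signal at varying stride phases) and
      # a +-10% per-window amplitude jitter; both regularize the fit to
      # the single short training segment
      off <- if (augment && T > 2 * W) sample.int(W, 1) - 1L else 0L
      starts <- seq(1L + off, T - W + 1L, by = W)
      ord <- sample(starts)
      ep_loss <- 0
      n_b <- 0
      for (i0 in seq(1, length(ord), by = per_batch)) {
        ss <- ord[i0:min(i0 + per_batch - 1, length(ord))]
        B <- length(ss)
        rows <- as.integer(t(outer(ss, 0:(W - 1), "+")))
        Xb <- X[rows, , drop = FALSE]
        if (augment)
          Xb <- Xb * rep(stats::runif(B, 0.9, 1.1), each = W)
        yb <- y_idx[rows]
        wb <- if (is.null(sample_weights)) rep(1, length(rows))
              else sample_weights[rows]
        # burn-in: positions with almost no temporal context carry no
        # loss, so the net is never trained to guess from 1-2 samples
        wb <- wb * rep(burn_mask, B)
        fw <- seqnet_forward(cfg, params, Xb, B, W, keep_cache = TRUE)
        ce <- softmax_xent(fw$logits, yb, wb)
        g <- seqnet_backward(cfg, params, fw$cache, ce$dlogits)
        stp <- adam_step(params, g, st, lr)
        params <- stp$p
        st <- stp$state
        ep_loss <- ep_loss + ce$loss
        n_b <- n_b + 1
      }
      log[ep] <- ep_loss / n_b
      # keep the epoch with the lowest mean training loss: stochastic
      # training can drift away from a good region late in the run
      if (log[ep] < best$loss) best <- list(loss = log[ep], params = params)
    }
  })
  list(params = best$params, loss_log = log, final_params = params)
}

# per-sample class probabilities over a full recording, evaluated under
# exactly the training regime: fresh-state windows of window_len,
# stepped by half a window so every emitted output sits in the second
# half of its window (>= window_len/2 samples of causal context; the
# sequence head/tail are edge-replicated, which cannot leak future
# information into a causal LSTM). biLSTM nets extend the window half a
# window to the right so their backward pass also has context.
predict_seqnet <- function(cfg, params, X, max_chunks = 256L) {
  T <- nrow(X)
  W <- min(cfg$window_len, T)
  half <- max(1L, W %/% 2L)
  rctx <- if (cfg$rnn == "bilstm") half else 0L
  L <- W + rctx
  starts <- seq(1L - half, T - half, by = half)
  P <- matrix(0, T, cfg$n_classes)
  for (g0 in seq(1, length(starts), by = max_chunks)) {
    gs <- starts[g0:min(g0 + max_chunks - 1, length(starts))]
    B <- length(gs)
    rows <- integer(B * L)
    for (b in seq_len(B)) {
      span <- gs[b]:(gs[b] + L - 1L)
      rows[((b - 1) * L + 1):(b * L)] <- pmin(pmax(span, 1L), T)
    }
    fw <- seqnet_forward(cfg, params, X[rows, , drop = FALSE], B, L,
                         keep_cache = FALSE)
    m <- apply(fw$logits, 1, max)
    ez <- exp(fw$logits - m)
    Pb <- ez / rowSums(ez)
    for (b in seq_len(B)) {
      lo <- max(gs[b] + half, 1L)
      hi <- min(gs[b] + W - 1L, T)
      if (lo > hi) next
      keep <- lo:hi
      src <- ((b - 1) * L) + (keep - gs[b] + 1L)
      P[keep, ] <- Pb[src, , drop = FALSE]
    }
  }
  P
}

# ---- dense nets (autoencoder, softmax head) ---------------------------

dense_init <- function(sizes, seed = NULL) {
  mk <- function(nr, nc) {
    s <- sqrt(1 / nr)
    matrix(stats::runif(nr * nc, -s, s), nr, nc)
  }
  lapply(seq_len(length(sizes) - 1), function(l)
    list(W = mk(sizes[l], sizes[l + 1]), b = numeric(sizes[l + 1])))
}

dense_forward <- function(layers, X, act = "tanh", linear_out = TRUE) {
  acts <- list(X)
  n <- length(layers)
  for (l in seq_len(n)) {
    Z <- addb(acts[[l]] %*% layers[[l]]$W, layers[[l]]$b)
    A <- if (l < n || !linear_out) {
      switch(act, tanh = tanh(Z), relu = pmax(Z, 0), linear = Z)
    } else Z
    acts[[l + 1]] <- A
  }
  acts
}

dense_backward <- function(layers, acts, dOut, act = "tanh",
                           linear_out = TRUE) {
  n <- length(layers)
  g <- vector("list", n)
  d <- dOut
  for (l in n:1) {
    if (!(l == n && linear_out)) {
      A <- acts[[l + 1]]
      d <- switch(act,
                  tanh = d * (1 - A^2),
                  relu = d * (A > 0),
                  linear = d)
    }
    g[[l]] <- list(W = crossprod(acts[[l]], d), b = colSums(d))
    if (l > 1) d <- d %*% t(layers[[l]]$W)
  }
  g
}

train_dense <- function(layers, X, target, epochs, lr,
                        batch = 128, seed = 1, act = "tanh",
                        loss = c("mse", "xent")) {
  loss <- match.arg(loss)
  st <- adam_state(layers)
  log <- numeric(epochs)
  n <- nrow(X)
  withr::with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; nb <- 0
      for (i0 in seq(1, n, by = batch)) {
        ids <- ord[i0:min(i0 + batch - 1, n)]
        acts <- dense_forward(layers, X[ids, , drop = FALSE], act)
        out <- acts[[length(acts)]]
        if (loss == "mse") {
          diff <- out - target[ids, , drop = FALSE]
          l <- mean(diff^2)
          dOut <- 2 * diff / length(diff)
        } else {
          ce <- softmax_xent(out, target[ids])
          l <- ce$loss
          dOut <- ce$dlogits
        }
        g <- dense_backward(layers, acts, dOut, act)
        stp <- adam_step(layers, g, st, lr)
        layers <- stp$p
        st <- stp$state
        ep_loss <- ep_loss + l; nb <- nb + 1
      }
      log[ep] <- ep_loss / nb
    }
  })
  list(layers = layers, loss_log = log)
}
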