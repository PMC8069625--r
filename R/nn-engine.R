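# Compact neural-network training engine used by the mlp/cnn/rnn/crnn
# families: dense, 1-D convolution (same padding, im2col over BLAS matmul),
# max pooling, global average pooling and an LSTM, trained with binary
# cross-entropy and Adam. Everything is deterministic given a seed; the
# backward pass is verified against finite differences in the test suite.
#
# Array convention: sequence minibatches are (batch, length, channels);
# feature minibatches are (batch, features).

sigmoid_ <- function(x) 1 / (1 + exp(-x))

glorot_ <- function(nin, nout, n = nin * nout) {
  lim <- sqrt(6 / (nin + nout))
  stats::runif(n, -lim, lim)
}

nn_layer_dense <- function(nin, nout, act = c("relu", "linear")) {
  list(type = "dense", act = match.arg(act),
       W = matrix(glorot_(nin, nout), nin, nout), b = rep(0, nout))
}

nn_layer_conv <- function(cin, cout, kernel) {
  list(type = "conv", k = kernel, cin = cin, cout = cout,
       W = matrix(glorot_(kernel * cin, cout), kernel * cin, cout),
       b = rep(0, cout))
}

nn_layer_pool <- function(size) list(type = "pool", size = size)

nn_layer_gap <- function() list(type = "gap")

nn_layer_lstm <- function(cin, units) {
  b <- rep(0, 4L * units)
  b[(units + 1L):(2L * units)] <- 1          # forget-gate bias
  list(type = "lstm", cin = cin, H = units,
       W = matrix(glorot_(cin, units, cin * 4L * units), cin, 4L * units),
       U = matrix(glorot_(units, units, units * 4L * units), units, 4L * units),
       b = b)
}

slice_t <- function(X, t) {
  d <- dim(X)
  matrix(X[, t, , drop = FALSE], d[1L], d[3L])
}

# ---- forward ---------------------------------------------------------------

fw_dense <- function(layer, X) {
  Y <- X %*% layer$W
  Y <- sweep(Y, 2L, layer$b, `+`)
  if (layer$act == "relu") {
    mask <- Y > 0
    Y <- Y * mask
    list(out = Y, cache = list(X = X, mask = mask))
  } else list(out = Y, cache = list(X = X))
}

fw_conv <- function(layer, X) {
  d <- dim(X); B <- d[1L]; L <- d[2L]; C <- d[3L]; k <- layer$k
  padl <- (k - 1L) %/% 2L
  Xc <- cpp_im2col(X, B, L, C, k, padl)
  Y2 <- Xc %*% layer$W
  Y2 <- Y2 + rep(layer$b, each = nrow(Y2))
  mask <- Y2 > 0
  Y2 <- Y2 * mask
  list(out = array(Y2, c(B, L, layer$cout)),
       cache = list(Xc = Xc, mask = mask, B = B, L = L, C = C, padl = padl))
}

fw_pool <- function(layer, X) {
  d <- dim(X); B <- d[1L]; L <- d[2L]; C <- d[3L]; p <- layer$size
  if (L %% p != 0L)
    wd_contract_error(sprintf("pool size %d does not divide length %d", p, L))
  r <- cpp_maxpool_fw(X, B, L, C, p)
  list(out = r$out, cache = list(amax = r$amax, B = B, L = L, C = C, p = p))
}

fw_gap <- function(layer, X) {
  d <- dim(X); C <- d[3L]
  Y <- vapply(seq_len(C), function(c) rowSums(X[, , c, drop = FALSE]) / d[2L],
              numeric(d[1L]))
  if (is.null(dim(Y))) Y <- matrix(Y, d[1L], C)
  list(out = Y, cache = list(B = d[1L], L = d[2L], C = C))
}

fw_lstm <- function(layer, X) {
  d <- dim(X); B <- d[1L]; T <- d[2L]; H <- layer$H
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  Is <- Fs <- Gs <- Os <- Cs <- Hs <- array(0, c(B, T, H))
  ii <- 1:H; fi <- (H + 1L):(2L * H); gi <- (2L * H + 1L):(3L * H)
  oi <- (3L * H + 1L):(4L * H)
  for (t in seq_len(T)) {
    z <- slice_t(X, t) %*% layer$W + h %*% layer$U
    z <- sweep(z, 2L, layer$b, `+`)
    i <- sigmoid_(z[, ii, drop = FALSE]); f <- sigmoid_(z[, fi, drop = FALSE])
    g <- tanh(z[, gi, drop = FALSE]); o <- sigmoid_(z[, oi, drop = FALSE])
    cc <- f * cc + i * g
    h <- o * tanh(cc)
    Is[, t, ] <- i; Fs[, t, ] <- f; Gs[, t, ] <- g; Os[, t, ] <- o
    Cs[, t, ] <- cc; Hs[, t, ] <- h
  }
  list(out = h, cache = list(X = X, Is = Is, Fs = Fs, Gs = Gs, Os = Os,
                             Cs = Cs, Hs = Hs, B = B, T = T, H = H))
}

nn_forward <- function(net, X) {
  caches <- vector("list", length(net$layers))
  for (li in seq_along(net$layers)) {
    layer <- net$layers[[li]]
    r <- switch(layer$type,
                dense = fw_dense(layer, X),
                conv = fw_conv(layer, X),
                pool = fw_pool(layer, X),
                gap = fw_gap(layer, X),
                lstm = fw_lstm(layer, X))
    X <- r$out
    caches[[li]] <- r$cache
  }
  list(out = X, caches = caches)
}

# ---- backward --------------------------------------------------------------

bw_dense <- function(layer, cache, dY) {
  if (layer$act == "relu") dY <- dY * cache$mask
  list(dX = dY %*% t(layer$W),
       grads = list(W = t(cache$X) %*% dY, b = colSums(dY)))
}

bw_conv <- function(layer, cache, dY) {
  B <- cache$B; L <- cache$L; C <- cache$C; k <- layer$k
  dY2 <- matrix(dY, B * L, layer$cout) * cache$mask
  dW <- crossprod(cache$Xc, dY2)
  db <- colSums(dY2)
  dXc <- tcrossprod(dY2, layer$W)
  list(dX = cpp_col2im(dXc, B, L, C, k, cache$padl),
       grads = list(W = dW, b = db))
}

bw_pool <- function(layer, cache, dY) {
  list(dX = cpp_maxpool_bw(dY, cache$amax, cache$B, cache$L, cache$C,
                           cache$p),
       grads = NULL)
}

bw_gap <- function(layer, cache, dY) {
  dX <- array(0, c(cache$B, cache$L, cache$C))
  for (c in seq_len(cache$C))
    dX[, , c] <- matrix(dY[, c] / cache$L, cache$B, cache$L)
  list(dX = dX, grads = NULL)
}

bw_lstm <- function(layer, cache, dH) {
  B <- cache$B; T <- cache$T; H <- cache$H
  dW <- matrix(0, nrow(layer$W), ncol(layer$W))
  dU <- matrix(0, H, 4L * H)
  db <- rep(0, 4L * H)
  dX <- array(0, dim(cache$X))
  dh <- dH
  dc <- matrix(0, B, H)
  for (t in rev(seq_len(T))) {
    i <- matrix(cache$Is[, t, ], B, H); f <- matrix(cache$Fs[, t, ], B, H)
    g <- matrix(cache$Gs[, t, ], B, H); o <- matrix(cache$Os[, t, ], B, H)
    ct <- matrix(cache$Cs[, t, ], B, H)
    cprev <- if (t > 1L) matrix(cache$Cs[, t - 1L, ], B, H) else matrix(0, B, H)
    hprev <- if (t > 1L) matrix(cache$Hs[, t - 1L, ], B, H) else matrix(0, B, H)
    tc <- tanh(ct)
    do_ <- dh * tc
    dc <- dc + dh * o * (1 - tc^2)
    di <- dc * g; dg <- dc * i; df <- dc * cprev
    dc <- dc * f
    dz <- cbind(di * i * (1 - i), df * f * (1 - f),
                dg * (1 - g^2), do_ * o * (1 - o))
    xt <- slice_t(cache$X, t)
    dW <- dW + t(xt) %*% dz
    dU <- dU + t(hprev) %*% dz
    db <- db + colSums(dz)
    dX[, t, ] <- dz %*% t(layer$W)
    dh <- dz %*% t(layer$U)
  }
  list(dX = dX, grads = list(W = dW, U = dU, b = db))
}

nn_backward <- function(net, caches, dOut) {
  grads <- vector("list", length(net$layers))
  dX <- dOut
  for (li in rev(seq_along(net$layers))) {
    layer <- net$layers[[li]]
    r <- switch(layer$type,
                dense = bw_dense(layer, caches[[li]], dX),
                conv = bw_conv(layer, caches[[li]], dX),
                pool = bw_pool(layer, caches[[li]], dX),
                gap = bw_gap(layer, caches[[li]], dX),
                lstm = bw_lstm(layer, caches[[li]], dX))
    grads[li] <- list(r$grads)   # keep NULL entries for param-free layers
    dX <- r$dX
  }
  list(grads = grads, dX = dX)
}

# ---- optimizer and training loop ------------------------------------------

adam_init <- function(net) {
  list(t = 0L, state = lapply(net$layers, function(l) {
    ps <- intersect(c("W", "U", "b"), names(l))
    stats::setNames(lapply(ps, function(p)
      list(m = l[[p]] * 0, v = l[[p]] * 0)), ps)
  }))
}

adam_step <- function(net, adam, grads, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  adam$t <- adam$t + 1L
  c1 <- 1 - beta1^adam$t
  c2 <- 1 - beta2^adam$t
  for (li in seq_along(net$layers)) {
    g <- grads[[li]]
    if (is.null(g)) next
    for (p in names(g)) {
      st <- adam$state[[li]][[p]]
      st$m <- beta1 * st$m + (1 - beta1) * g[[p]]
      st$v <- beta2 * st$v + (1 - beta2) * g[[p]]^2
      net$layers[[li]][[p]] <- net$layers[[li]][[p]] -
        lr * (st$m / c1) / (sqrt(st$v / c2) + eps)
      adam$state[[li]][[p]] <- st
    }
  }
  list(net = net, adam = adam)
}

# Mean binary cross-entropy of logits against 0/1 targets, and its gradient.
bce_loss <- function(logits, y) {
  p <- pmin(pmax(sigmoid_(logits), 1e-12), 1 - 1e-12)
  list(loss = -mean(y * log(p) + (1 - y) * log(1 - p)),
       dlogits = matrix((sigmoid_(logits) - y) / length(y), length(y), 1L))
}

# Build the layer stack for one network family. `inputDim` is the feature
# count (mlp) or c(length, channels) for sequence inputs.
nn_build <- function(family, params, inputDim, seed) {
  with_seed(seed, {
    layers <- list()
    if (family == "mlp") {
      nin <- inputDim
      for (h in params$hidden) {
        layers <- c(layers, list(nn_layer_dense(nin, h, "relu")))
        nin <- h
      }
      layers <- c(layers, list(nn_layer_dense(nin, 1L, "linear")))
    } else {
      L <- inputDim[1L]; cin <- inputDim[2L]
      if (family %in% c("cnn", "crnn")) {
        for (bi in seq_along(params$filters)) {
          layers <- c(layers, list(nn_layer_conv(cin, params$filters[bi],
                                                 params$kernel),
                                   nn_layer_pool(params$pool[bi])))
          cin <- params$filters[bi]
          L <- L %/% params$pool[bi]
        }
      }
      if (family == "cnn") {
        layers <- c(layers, list(nn_layer_gap(),
                                 nn_layer_dense(cin, 1L, "linear")))
      } else {
        layers <- c(layers, list(nn_layer_lstm(cin, params$units),
                                 nn_layer_dense(params$units, 1L, "linear")))
      }
    }
    list(family = family, layers = layers)
  })
}

# Sequence length reaching the recurrent layer of a crnn stack.
nn_crnn_seq_length <- function(inputLength, pool) {
  for (p in pool) inputLength <- inputLength %/% p
  inputLength
}

nn_train <- function(net, X, y, epochs = 10L, batch = 32L, lr = 1e-3,
                     seed = 1L) {
  n <- if (length(dim(X)) == 3L) dim(X)[1L] else nrow(X)
  adam <- adam_init(net)
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- with_seed(derive_seed(seed, ep), sample.int(n))
    tot <- 0
    for (start in seq(1L, n, by = batch)) {
      idx <- ord[start:min(start + batch - 1L, n)]
      Xb <- if (length(dim(X)) == 3L) X[idx, , , drop = FALSE]
      else X[idx, , drop = FALSE]
      fwd <- nn_forward(net, Xb)
      loss <- bce_loss(drop(fwd$out), y[idx])
      if (!is.finite(loss$loss))
        wd_convergence_error(sprintf("non-finite training loss at epoch %d", ep))
      tot <- tot + loss$loss * length(idx)
      bwd <- nn_backward(net, fwd$caches, loss$dlogits)
      upd <- adam_step(net, adam, bwd$grads, lr = lr)
      net <- upd$net
      adam <- upd$adam
    }
    history[ep] <- tot / n
  }
  list(net = net, history = history)
}

nn_predict <- function(net, X, chunk = 512L) {
  n <- if (length(dim(X)) == 3L) dim(X)[1L] else nrow(X)
  out <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    Xb <- if (length(dim(X)) == 3L) X[idx, , , drop = FALSE]
    else X[idx, , drop = FALSE]
    out[idx] <- sigmoid_(drop(nn_forward(net, Xb)$out))
  }
  out
}
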