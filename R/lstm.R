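# Bidirectional LSTM internals: parameter initialisation, forward pass,
# backpropagation through time, and Adam-family optimizer updates. All
# operations are batched matrix products so training stays fast in plain R.
# Windows enter as an n_features x width x batch array; time steps are
# processed as batch x features matrices.

sigmoid <- function(x) 1 / (1 + exp(-x))

act_fun <- function(name) {
  switch(name,
    tanh = list(f = tanh, df = function(z, a) 1 - a^2),
    LeakyReLU = list(
      f = function(z) ifelse(z > 0, z, 0.01 * z),
      df = function(z, a) ifelse(z > 0, 1, 0.01)),
    stop(sprintf("unknown activation '%s'", name), call. = FALSE))
}

glorot <- function(nr, nc) {
  r <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -r, r), nr, nc)
}

# Flat named parameter list for a stacked bi-LSTM plus dense head.
# Layer inputs: n_features for layer 1, 2*hidden for deeper layers.
# Gate order in the 4H-wide weight blocks: input, forget, cell, output;
# forget-gate biases start at 1.
init_params <- function(n_features, hidden, layers, n_classes) {
  p <- list()
  for (l in seq_len(layers)) {
    din <- if (l == 1L) n_features else 2L * hidden
    for (dir in c("f", "b")) {
      b <- rep(0, 4 * hidden)
      b[(hidden + 1):(2 * hidden)] <- 1
      p[[sprintf("l%d_%s_Wx", l, dir)]] <- glorot(din, 4 * hidden)
      p[[sprintf("l%d_%s_Wh", l, dir)]] <- glorot(hidden, 4 * hidden)
      p[[sprintf("l%d_%s_b", l, dir)]] <- b
    }
  }
  p$dense_W1 <- glorot(2 * hidden, hidden)
  p$dense_b1 <- rep(0, hidden)
  p$dense_W2 <- glorot(hidden, n_classes)
  p$dense_b2 <- rep(0, n_classes)
  p
}

# One direction over a sequence. xs: list of B x Din matrices in pass order.
lstm_pass <- function(xs, Wx, Wh, b, hidden) {
  TT <- length(xs); B <- nrow(xs[[1]])
  h <- matrix(0, B, hidden); cc <- matrix(0, B, hidden)
  cache <- vector("list", TT)
  hs <- vector("list", TT)
  idx_i <- 1:hidden; idx_f <- hidden + idx_i
  idx_g <- 2 * hidden + idx_i; idx_o <- 3 * hidden + idx_i
  for (t in seq_len(TT)) {
    z <- xs[[t]] %*% Wx + h %*% Wh
    z <- sweep(z, 2, b, "+")
    gi <- sigmoid(z[, idx_i, drop = FALSE])
    gf <- sigmoid(z[, idx_f, drop = FALSE])
    gg <- tanh(z[, idx_g, drop = FALSE])
    go <- sigmoid(z[, idx_o, drop = FALSE])
    c_prev <- cc
    cc <- gf * c_prev + gi * gg
    tc <- tanh(cc)
    h_prev <- h
    h <- go * tc
    cache[[t]] <- list(x = xs[[t]], i = gi, f = gf, g = gg, o = go,
                       c = cc, tc = tc, c_prev = c_prev, h_prev = h_prev)
    hs[[t]] <- h
  }
  list(hs = hs, cache = cache)
}

# BPTT for one direction. dh_seq: list of B x H gradients w.r.t. each h_t
# (zeros allowed). Returns parameter gradients and gradients w.r.t. inputs.
lstm_pass_backward <- function(cache, Wx, Wh, dh_seq, hidden) {
  TT <- length(cache); B <- nrow(cache[[1]]$x)
  din <- ncol(cache[[1]]$x)
  dWx <- matrix(0, din, 4 * hidden)
  dWh <- matrix(0, hidden, 4 * hidden)
  db <- rep(0, 4 * hidden)
  dxs <- vector("list", TT)
  dh_next <- matrix(0, B, hidden)
  dc_next <- matrix(0, B, hidden)
  for (t in rev(seq_len(TT))) {
    cc <- cache[[t]]
    dh <- dh_seq[[t]] + dh_next
    do_ <- dh * cc$tc
    dct <- dh * cc$o * (1 - cc$tc^2) + dc_next
    di <- dct * cc$g
    df <- dct * cc$c_prev
    dg <- dct * cc$i
    dz <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do_ * cc$o * (1 - cc$o))
    dWx <- dWx + crossprod(cc$x, dz)
    dWh <- dWh + crossprod(cc$h_prev, dz)
    db <- db + colSums(dz)
    dxs[[t]] <- tcrossprod(dz, Wx)
    dh_next <- tcrossprod(dz, Wh)
    dc_next <- dct * cc$f
  }
  list(dWx = dWx, dWh = dWh, db = db, dxs = dxs)
}

# Full forward pass. X: n_features x width x B array. Returns class
# probabilities and (optionally) all caches for backprop. dropout_mask is an
# inverted-dropout mask on the recurrent output (B x 2H) or NULL.
bilstm_forward <- function(params, X, hidden, layers, activation,
                           dropout_mask = NULL, keep_cache = FALSE) {
  TT <- dim(X)[2]; B <- dim(X)[3]
  xs <- lapply(seq_len(TT), function(t) t(matrix(X[, t, ], dim(X)[1], B)))
  act <- act_fun(activation)
  caches <- vector("list", layers)
  for (l in seq_len(layers)) {
    fw <- lstm_pass(xs, params[[sprintf("l%d_f_Wx", l)]],
                    params[[sprintf("l%d_f_Wh", l)]],
                    params[[sprintf("l%d_f_b", l)]], hidden)
    bw <- lstm_pass(rev(xs), params[[sprintf("l%d_b_Wx", l)]],
                    params[[sprintf("l%d_b_Wh", l)]],
                    params[[sprintf("l%d_b_b", l)]], hidden)
    caches[[l]] <- list(fw = fw, bw = bw)
    if (l < layers) {
      xs <- lapply(seq_len(TT), function(t)
        cbind(fw$hs[[t]], bw$hs[[TT + 1L - t]]))
    } else {
      feat <- cbind(fw$hs[[TT]], bw$hs[[TT]])
    }
  }
  if (!is.null(dropout_mask)) feat <- feat * dropout_mask
  z1 <- sweep(feat %*% params$dense_W1, 2, params$dense_b1, "+")
  a1 <- act$f(z1)
  logits <- sweep(a1 %*% params$dense_W2, 2, params$dense_b2, "+")
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  probs <- e / rowSums(e)
  out <- list(probs = probs, logits = logits)
  if (keep_cache)
    out$cache <- list(caches = caches, feat = feat, z1 = z1, a1 = a1,
                      dropout_mask = dropout_mask, TT = TT, B = B)
  out
}

# Backward pass from dlogits (B x n_classes). Returns flat gradient list
# matching the parameter names.
bilstm_backward <- function(params, fwd, dlogits, hidden, layers, activation) {
  cache <- fwd$cache
  act <- act_fun(activation)
  TT <- cache$TT; B <- cache$B
  g <- list()
  g$dense_W2 <- crossprod(cache$a1, dlogits)
  g$dense_b2 <- colSums(dlogits)
  da1 <- tcrossprod(dlogits, params$dense_W2)
  dz1 <- da1 * act$df(cache$z1, cache$a1)
  g$dense_W1 <- crossprod(cache$feat, dz1)
  g$dense_b1 <- colSums(dz1)
  dfeat <- tcrossprod(dz1, params$dense_W1)
  if (!is.null(cache$dropout_mask)) dfeat <- dfeat * cache$dropout_mask

  zero <- matrix(0, B, hidden)
  dh_f <- rep(list(zero), TT)
  dh_b <- rep(list(zero), TT)
  dh_f[[TT]] <- dfeat[, 1:hidden, drop = FALSE]
  dh_b[[TT]] <- dfeat[, hidden + 1:hidden, drop = FALSE]

  for (l in rev(seq_len(layers))) {
    fw <- cache$caches[[l]]$fw; bw <- cache$caches[[l]]$bw
    gf <- lstm_pass_backward(fw$cache, params[[sprintf("l%d_f_Wx", l)]],
                             params[[sprintf("l%d_f_Wh", l)]], dh_f, hidden)
    gb <- lstm_pass_backward(bw$cache, params[[sprintf("l%d_b_Wx", l)]],
                             params[[sprintf("l%d_b_Wh", l)]], dh_b, hidden)
    g[[sprintf("l%d_f_Wx", l)]] <- gf$dWx
    g[[sprintf("l%d_f_Wh", l)]] <- gf$dWh
    g[[sprintf("l%d_f_b", l)]] <- gf$db
    g[[sprintf("l%d_b_Wx", l)]] <- gb$dWx
    g[[sprintf("l%d_b_Wh", l)]] <- gb$dWh
    g[[sprintf("l%d_b_b", l)]] <- gb$db
    if (l > 1L) {
      # input at fwd pass step t was cbind(h_f[t], h_b[TT+1-t]) of layer l-1
      dh_f <- vector("list", TT); dh_b <- vector("list", TT)
      for (t in seq_len(TT)) {
        dxt <- gf$dxs[[t]] + gb$dxs[[TT + 1L - t]]
        dh_f[[t]] <- dxt[, 1:hidden, drop = FALSE]
        dh_b[[TT + 1L - t]] <- dxt[, hidden + 1:hidden, drop = FALSE]
      }
    }
  }
  g
}

softmax_xent <- function(probs, y_onehot) {
  eps <- 1e-12
  loss <- -mean(rowSums(y_onehot * log(probs + eps)))
  dlogits <- (probs - y_onehot) / nrow(probs)
  list(loss = loss, dlogits = dlogits)
}

new_opt_state <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

# One update of the Adam family. kind: "Adam", "Nadam" (Nesterov momentum in
# the numerator) or "AdamW" (decoupled weight decay).
opt_step <- function(params, grads, state, lr, kind = "Adam",
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                     weight_decay = 0.004) {
  state$t <- state$t + 1L
  t <- state$t
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  for (nm in names(params)) {
    gr <- grads[[nm]]
    if (is.null(gr)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    num <- switch(kind,
      Adam = mhat,
      AdamW = mhat,
      Nadam = beta1 * mhat + (1 - beta1) * gr / bc1,
      stop(sprintf("unknown optimizer '%s'", kind), call. = FALSE))
    delta <- lr * num / (sqrt(vhat) + eps)
    if (kind == "AdamW") delta <- delta + lr * weight_decay * params[[nm]]
    params[[nm]] <- params[[nm]] - delta
  }
  list(params = params, state = state)
}
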