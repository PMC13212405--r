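# Compact recurrent-network engine: stacked LSTM or simple-RNN (sigmoid)
# layers over a fixed-length window, a rectified-linear dense layer and a
# scalar linear output, trained by backpropagation through time with Adam
# on the mean-squared error. Everything is plain R matrix algebra; all
# randomness (init, shuffling, validation split) comes from the caller's
# seed, so training is reproducible.

sigmoid <- function(z) 1 / (1 + exp(-z))

glorot <- function(nr, nc) {
  l <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -l, l), nr, nc)
}

# Parameter initialization. `spec$units` are the recurrent layer sizes,
# `spec$dense_units` the dense-layer width, `gates` 4 (LSTM) or 1 (RNN).
net_init <- function(spec, input_dim) {
  gates <- if (spec$family == "lstm") 4L else 1L
  params <- list()
  d <- input_dim
  for (l in seq_along(spec$units)) {
    H <- spec$units[l]
    b <- numeric(gates * H)
    if (spec$family == "lstm") b[(H + 1):(2 * H)] <- 1  # forget-gate bias
    params[[paste0("W", l)]] <- glorot(d, gates * H)
    params[[paste0("U", l)]] <- glorot(H, gates * H)
    params[[paste0("b", l)]] <- b
    d <- H
  }
  params$A1 <- glorot(d, spec$dense_units)
  params$c1 <- numeric(spec$dense_units)
  params$A2 <- glorot(spec$dense_units, 1L)
  params$c2 <- numeric(1L)
  params
}

# Forward pass of one recurrent layer over a list of step inputs
# (each B x d). Returns the hidden-state sequence and caches for BPTT.
layer_forward <- function(xs, W, U, b, family) {
  B <- nrow(xs[[1]]); H <- nrow(U); T_ <- length(xs)
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  hs <- vector("list", T_); cache <- vector("list", T_)
  for (t in seq_len(T_)) {
    Z <- xs[[t]] %*% W + h %*% U
    Z <- sweep(Z, 2, b, `+`)
    if (family == "lstm") {
      i <- sigmoid(Z[, 1:H, drop = FALSE])
      f <- sigmoid(Z[, (H + 1):(2 * H), drop = FALSE])
      o <- sigmoid(Z[, (2 * H + 1):(3 * H), drop = FALSE])
      g <- tanh(Z[, (3 * H + 1):(4 * H), drop = FALSE])
      c_prev <- cc
      cc <- f * c_prev + i * g
      tc <- tanh(cc)
      h_prev_cached <- if (t == 1) matrix(0, B, H) else hs[[t - 1]]
      h <- o * tc
      cache[[t]] <- list(i = i, f = f, o = o, g = g, c_prev = c_prev,
                         tc = tc, h_prev = h_prev_cached)
    } else {
      h_prev_cached <- if (t == 1) matrix(0, B, H) else hs[[t - 1]]
      h <- sigmoid(Z)
      cache[[t]] <- list(h = h, h_prev = h_prev_cached)
    }
    hs[[t]] <- h
  }
  list(hs = hs, cache = cache)
}

# Backward pass of one recurrent layer. `dhs` is a list of gradients on
# the layer's hidden outputs at every step (zero matrices where unused).
layer_backward <- function(xs, hs, cache, W, U, dhs, family) {
  B <- nrow(xs[[1]]); H <- nrow(U); T_ <- length(xs)
  dW <- W * 0; dU <- U * 0; db <- numeric(ncol(W))
  dxs <- vector("list", T_)
  dh_rec <- matrix(0, B, H); dc <- matrix(0, B, H)
  for (t in rev(seq_len(T_))) {
    dh <- dhs[[t]] + dh_rec
    if (family == "lstm") {
      cv <- cache[[t]]
      do_ <- dh * cv$tc
      dc <- dc + dh * cv$o * (1 - cv$tc^2)
      di <- dc * cv$g
      df <- dc * cv$c_prev
      dg <- dc * cv$i
      dZ <- cbind(di * cv$i * (1 - cv$i),
                  df * cv$f * (1 - cv$f),
                  do_ * cv$o * (1 - cv$o),
                  dg * (1 - cv$g^2))
      dc <- dc * cv$f
    } else {
      hcur <- cache[[t]]$h
      dZ <- dh * hcur * (1 - hcur)
    }
    dW <- dW + crossprod(xs[[t]], dZ)
    dU <- dU + crossprod(cache[[t]]$h_prev, dZ)
    db <- db + colSums(dZ)
    dxs[[t]] <- dZ %*% t(W)
    dh_rec <- dZ %*% t(U)
  }
  list(dW = dW, dU = dU, db = db, dxs = dxs)
}

# Full forward pass: x is an array B x T x d. Returns predictions (length
# B) and, if `keep` is TRUE, all intermediate states for the backward pass.
net_forward <- function(params, x, spec, keep = FALSE) {
  B <- dim(x)[1]; T_ <- dim(x)[2]; d <- dim(x)[3]
  xs <- lapply(seq_len(T_), function(t) matrix(x[, t, ], B, d))
  layer_out <- vector("list", length(spec$units))
  cur <- xs
  for (l in seq_along(spec$units)) {
    fw <- layer_forward(cur, params[[paste0("W", l)]],
                        params[[paste0("U", l)]], params[[paste0("b", l)]],
                        spec$family)
    layer_out[[l]] <- list(xs = cur, fw = fw)
    cur <- fw$hs
  }
  h_last <- cur[[T_]]
  Dpre <- sweep(h_last %*% params$A1, 2, params$c1, `+`)
  D <- pmax(Dpre, 0)
  pred <- as.numeric(sweep(D %*% params$A2, 2, params$c2, `+`))
  if (!keep) return(list(pred = pred))
  list(pred = pred, layer_out = layer_out, h_last = h_last,
       Dpre = Dpre, D = D, T_ = T_, B = B)
}

# Gradients of the mean-squared error w.r.t. every parameter.
net_backward <- function(params, fw, y, spec) {
  B <- fw$B; T_ <- fw$T_
  dpred <- matrix(2 * (fw$pred - y) / B, B, 1)
  grads <- list()
  grads$A2 <- crossprod(fw$D, dpred)
  grads$c2 <- sum(dpred)
  dD <- dpred %*% t(params$A2)
  dDpre <- dD * (fw$Dpre > 0)
  grads$A1 <- crossprod(fw$h_last, dDpre)
  grads$c1 <- colSums(dDpre)
  dh_last <- dDpre %*% t(params$A1)

  n_layers <- length(spec$units)
  # gradient on the top layer's outputs: only the last step is used
  dhs <- lapply(seq_len(T_), function(t)
    matrix(0, B, spec$units[n_layers]))
  dhs[[T_]] <- dh_last
  for (l in rev(seq_len(n_layers))) {
    lo <- fw$layer_out[[l]]
    bk <- layer_backward(lo$xs, lo$fw$hs, lo$fw$cache,
                         params[[paste0("W", l)]], params[[paste0("U", l)]],
                         dhs, spec$family)
    grads[[paste0("W", l)]] <- bk$dW
    grads[[paste0("U", l)]] <- bk$dU
    grads[[paste0("b", l)]] <- bk$db
    dhs <- bk$dxs
  }
  grads
}

adam_init <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Mean-squared error of the network on (x, y), computed in minibatches.
net_loss <- function(params, x, y, spec, batch = 512L) {
  n <- dim(x)[1]
  if (n == 0) return(NA_real_)
  sse <- 0
  for (s in seq(1, n, by = batch)) {
    e <- min(s + batch - 1, n)
    p <- net_forward(params, x[s:e, , , drop = FALSE], spec)$pred
    sse <- sse + sum((p - y[s:e])^2)
  }
  sse / n
}
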