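# Minimal neural-network primitives (forward + backward) in vectorised base
# R. Activations flow as 3D arrays [batch, time, channels]; dense stages as
# matrices [batch, units]. Backward passes return both parameter gradients
# and input gradients, which the attribution module reuses for exact
# input-space gradients.

nn_sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(nin, nout, dims = c(nin, nout)) {
  lim <- sqrt(6 / (nin + nout))
  array(runif(prod(dims), -lim, lim), dims)
}

# ---- 1D convolution (valid) via im2col -------------------------------------

im2col <- function(X, k) {
  d <- dim(X); B <- d[1]; T <- d[2]; C <- d[3]
  To <- T - k + 1L
  Xc <- matrix(0, B * To, k * C)
  for (o in seq_len(k) - 1L) {
    Xc[, (o * C + 1L):(o * C + C)] <- matrix(X[, (1L + o):(To + o), , drop = FALSE], B * To, C)
  }
  Xc
}

conv1d_forward <- function(X, W, b, k) {
  d <- dim(X); B <- d[1]; To <- d[2] - k + 1L
  Xc <- im2col(X, k)
  Y <- sweep(Xc %*% W, 2, b, "+")
  list(out = array(Y, c(B, To, ncol(W))), cache = list(Xc = Xc, dimX = d, k = k, W = W))
}

conv1d_backward <- function(dY, cache) {
  d <- cache$dimX; B <- d[1]; T <- d[2]; C <- d[3]; k <- cache$k
  To <- T - k + 1L
  F_ <- dim(dY)[3]
  dYm <- matrix(dY, B * To, F_)
  dW <- crossprod(cache$Xc, dYm)
  db <- colSums(dYm)
  dXc <- dYm %*% t(cache$W)
  dX <- array(0, d)
  for (o in seq_len(k) - 1L) {
    dX[, (1L + o):(To + o), ] <- dX[, (1L + o):(To + o), , drop = FALSE] +
      array(dXc[, (o * C + 1L):(o * C + C)], c(B, To, C))
  }
  list(dX = dX, dW = dW, db = db)
}

# ---- batch normalisation (per channel over batch x time) -------------------

bn_forward <- function(X, gamma, beta, state, training, momentum = 0.9, eps = 1e-5) {
  d <- dim(X); C <- d[3]
  Xm <- matrix(X, prod(d[1:2]), C)
  if (training) {
    mu <- colMeans(Xm)
    v <- colMeans(sweep(Xm, 2, mu)^2)
    state$mean <- momentum * state$mean + (1 - momentum) * mu
    state$var <- momentum * state$var + (1 - momentum) * v
  } else {
    mu <- state$mean
    v <- state$var
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(Xm, 2, mu), 2, inv, "*")
  Y <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(out = array(Y, d),
       cache = list(xhat = xhat, inv = inv, gamma = gamma, dimX = d, training = training),
       state = state)
}

bn_backward <- function(dY, cache) {
  d <- cache$dimX; C <- d[3]; N <- prod(d[1:2])
  dYm <- matrix(dY, N, C)
  dgamma <- colSums(dYm * cache$xhat)
  dbeta <- colSums(dYm)
  dxhat <- sweep(dYm, 2, cache$gamma, "*")
  if (cache$training) {
    # full batch-norm gradient
    t1 <- sweep(dxhat, 2, colMeans(dxhat))
    t2 <- sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), "*")
    dXm <- sweep(t1 - t2, 2, cache$inv, "*")
  } else {
    dXm <- sweep(dxhat, 2, cache$inv, "*")
  }
  list(dX = array(dXm, d), dgamma = dgamma, dbeta = dbeta)
}

# ---- activations, dropout, pooling -----------------------------------------

relu_forward <- function(X) list(out = pmax(X, 0), cache = X > 0)
relu_backward <- function(dY, cache) dY * cache

dropout_forward <- function(X, p, training) {
  if (!training || p <= 0) return(list(out = X, cache = NULL))
  keep <- array(rbinom(length(X), 1L, 1 - p), dim(X)) / (1 - p)
  list(out = X * keep, cache = keep)
}
dropout_backward <- function(dY, cache) if (is.null(cache)) dY else dY * cache

maxpool2_forward <- function(X) {
  d <- dim(X); To <- d[2] %/% 2L
  ia <- seq(1L, 2L * To, by = 2L); ib <- ia + 1L
  A <- X[, ia, , drop = FALSE]; Bm <- X[, ib, , drop = FALSE]
  take_a <- A >= Bm
  list(out = pmax(A, Bm), cache = list(take_a = take_a, dimX = d, ia = ia, ib = ib))
}
maxpool2_backward <- function(dY, cache) {
  dX <- array(0, cache$dimX)
  dX[, cache$ia, ] <- dY * cache$take_a
  dX[, cache$ib, ] <- dX[, cache$ib, , drop = FALSE] + dY * (!cache$take_a)
  dX
}

# ---- LSTM (returns last hidden state) --------------------------------------

lstm_init <- function(n_in, n_hidden) {
  b <- rep(0, 4 * n_hidden)
  b[(n_hidden + 1):(2 * n_hidden)] <- 1  # forget-gate bias
  list(Wx = glorot(n_in, 4 * n_hidden), Wh = glorot(n_hidden, 4 * n_hidden), b = b)
}

lstm_forward <- function(X, p) {
  d <- dim(X); B <- d[1]; T <- d[2]
  H <- nrow(p$Wh)
  h <- matrix(0, B, H); c_ <- matrix(0, B, H)
  steps <- vector("list", T)
  idx <- function(g) ((g - 1L) * H + 1L):(g * H)
  for (t in seq_len(T)) {
    Xt <- matrix(X[, t, , drop = FALSE], B, d[3])
    Z <- Xt %*% p$Wx + h %*% p$Wh
    Z <- sweep(Z, 2, p$b, "+")
    i <- nn_sigmoid(Z[, idx(1), drop = FALSE])
    f <- nn_sigmoid(Z[, idx(2), drop = FALSE])
    o <- nn_sigmoid(Z[, idx(3), drop = FALSE])
    g <- tanh(Z[, idx(4), drop = FALSE])
    c_prev <- c_
    c_ <- f * c_prev + i * g
    tc <- tanh(c_)
    h_prev <- h
    h <- o * tc
    steps[[t]] <- list(Xt = Xt, i = i, f = f, o = o, g = g,
                       c_prev = c_prev, tc = tc, h_prev = h_prev)
  }
  list(out = h, cache = list(steps = steps, dimX = d, H = H))
}

lstm_backward <- function(dh, p, cache) {
  d <- cache$dimX; B <- d[1]; T <- d[2]; H <- cache$H
  dWx <- p$Wx * 0; dWh <- p$Wh * 0; db <- p$b * 0
  dX <- array(0, d)
  dc <- matrix(0, B, H)
  for (t in rev(seq_len(T))) {
    s <- cache$steps[[t]]
    do_ <- dh * s$tc
    dc <- dc + dh * s$o * (1 - s$tc^2)
    di <- dc * s$g
    df <- dc * s$c_prev
    dg <- dc * s$i
    dZ <- cbind(di * s$i * (1 - s$i),
                df * s$f * (1 - s$f),
                do_ * s$o * (1 - s$o),
                dg * (1 - s$g^2))
    dWx <- dWx + crossprod(s$Xt, dZ)
    dWh <- dWh + crossprod(s$h_prev, dZ)
    db <- db + colSums(dZ)
    dX[, t, ] <- dZ %*% t(p$Wx)
    dh <- dZ %*% t(p$Wh)
    dc <- dc * s$f
  }
  list(dX = dX, dWx = dWx, dWh = dWh, db = db)
}

# ---- dense -----------------------------------------------------------------

dense_forward <- function(X, W, b) {
  list(out = sweep(X %*% W, 2, b, "+"), cache = list(X = X, W = W))
}
dense_backward <- function(dY, cache) {
  list(dX = dY %*% t(cache$W), dW = crossprod(cache$X, dY), db = colSums(dY))
}

# ---- optimisers ------------------------------------------------------------

optimizer_init <- function(params, kind) {
  kind <- match.arg(kind, c("adam", "rmsprop", "sgd"))
  zeros <- lapply(params, function(p) p * 0)
  list(kind = kind, t = 0L, m = zeros, v = zeros)
}

optimizer_step <- function(opt, params, grads, lr) {
  opt$t <- opt$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (opt$kind == "adam") {
      b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
      opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * g
      opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * g^2
      mhat <- opt$m[[nm]] / (1 - b1^opt$t)
      vhat <- opt$v[[nm]] / (1 - b2^opt$t)
      params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    } else if (opt$kind == "rmsprop") {
      opt$v[[nm]] <- 0.9 * opt$v[[nm]] + 0.1 * g^2
      params[[nm]] <- params[[nm]] - lr * g / (sqrt(opt$v[[nm]]) + 1e-8)
    } else {
      opt$m[[nm]] <- 0.9 * opt$m[[nm]] + g
      params[[nm]] <- params[[nm]] - lr * opt$m[[nm]]
    }
  }
  list(opt = opt, params = params)
}
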