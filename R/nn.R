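# Minimal neural-network engine for 1-D spectral models: channel batch
# normalization, kernel-2 stride-2 convolutions, average pooling, dropout,
# an LSTM layer trained by backpropagation through time, dense layers and
# Adam. Tensors are 3-D arrays (batch x channels x positions); dense
# activations are matrices (batch x features). Everything is vectorized over
# the batch; only the time loop of the LSTM iterates.

sigmoid <- function(x) 1 / (1 + exp(-x))

# broadcast a per-channel vector over a (n, C, T) array: rep(v, each = n)
# recycles exactly along the channel axis
chan_mul <- function(x, v) x * rep(v, each = dim(x)[1])
chan_add <- function(x, v) x + rep(v, each = dim(x)[1])
chan_stat <- function(x, f) {
  # per-channel sums over batch and positions via one colSums pass
  d <- dim(x)
  s <- colSums(matrix(f(x), d[1], d[2] * d[3]))
  rowSums(matrix(s, d[2], d[3]))
}

glorot <- function(fan_in, fan_out, n) {
  lim <- sqrt(6 / (fan_in + fan_out))
  runif(n, -lim, lim)
}

# ---- layer constructors -----------------------------------------------------

layer_bn <- function(channels) {
  list(type = "bn", C = channels,
       params = list(gamma = rep(1, channels), beta = rep(0, channels)),
       buffers = list(run_mean = rep(0, channels), run_var = rep(1, channels)),
       momentum = 0.1, eps = 1e-5)
}

layer_conv <- function(c_in, c_out) {
  list(type = "conv", c_in = c_in, c_out = c_out,
       params = list(
         W = matrix(glorot(2 * c_in, c_out, 2 * c_in * c_out), 2 * c_in, c_out),
         b = rep(0, c_out)
       ))
}

layer_relu <- function() list(type = "relu", params = list())
layer_pool <- function() list(type = "pool", params = list())
layer_dropout <- function(p) list(type = "dropout", p = p, params = list())
layer_flatten <- function() list(type = "flatten", params = list())

layer_dense <- function(d_in, d_out) {
  list(type = "dense", d_in = d_in, d_out = d_out,
       params = list(
         W = matrix(glorot(d_in, d_out, d_in * d_out), d_in, d_out),
         b = rep(0, d_out)
       ))
}

layer_tanh <- function() list(type = "tanh", params = list())

layer_lstm <- function(d_in, hidden) {
  # combined gate weights, column blocks f | i | g | o, input rows [h, x]
  W <- matrix(glorot(d_in + hidden, hidden, (d_in + hidden) * 4 * hidden),
              d_in + hidden, 4 * hidden)
  b <- rep(0, 4 * hidden)
  b[seq_len(hidden)] <- 1  # forget-gate bias init
  list(type = "lstm", d_in = d_in, hidden = hidden, params = list(W = W, b = b))
}

# ---- forward / backward -----------------------------------------------------

# kernel-2 stride-2 convolution; odd trailing position is dropped, except a
# length-1 sequence which is zero-padded to length 2 so the stack stays
# defined for the smallest admissible inputs.
conv_forward <- function(layer, x) {
  d <- dim(x)
  n <- d[1]; C <- d[2]; T_in <- d[3]
  padded <- FALSE
  if (T_in == 1L) {
    x <- array(c(x, array(0, dim = c(n, C, 1))), dim = c(n, C, 2))
    T_in <- 2L
    padded <- TRUE
  }
  T_out <- T_in %/% 2L
  x1 <- x[, , seq(1L, 2L * T_out, by = 2L), drop = FALSE]
  x2 <- x[, , seq(2L, 2L * T_out, by = 2L), drop = FALSE]
  M <- cbind(
    matrix(aperm(x1, c(1, 3, 2)), n * T_out, C),
    matrix(aperm(x2, c(1, 3, 2)), n * T_out, C)
  )
  Yf <- M %*% layer$params$W
  Yf <- Yf + rep(layer$params$b, each = nrow(Yf))
  y <- aperm(array(Yf, dim = c(n, T_out, layer$c_out)), c(1, 3, 2))
  list(out = y, cache = list(M = M, n = n, C = C, T_in = T_in, T_out = T_out,
                             padded = padded))
}

conv_backward <- function(layer, cache, dy) {
  n <- cache$n; C <- cache$C; T_out <- cache$T_out
  dYf <- matrix(aperm(dy, c(1, 3, 2)), n * T_out, layer$c_out)
  dW <- crossprod(cache$M, dYf)
  db <- colSums(dYf)
  dM <- dYf %*% t(layer$params$W)
  dx1 <- aperm(array(dM[, seq_len(C), drop = FALSE], dim = c(n, T_out, C)), c(1, 3, 2))
  dx2 <- aperm(array(dM[, C + seq_len(C), drop = FALSE], dim = c(n, T_out, C)), c(1, 3, 2))
  dx <- array(0, dim = c(n, C, cache$T_in))
  dx[, , seq(1L, 2L * T_out, by = 2L)] <- dx1
  dx[, , seq(2L, 2L * T_out, by = 2L)] <- dx2
  if (cache$padded) dx <- dx[, , 1L, drop = FALSE]
  list(dx = dx, grads = list(W = dW, b = db))
}

bn_forward <- function(layer, x, training) {
  d <- dim(x)
  m <- d[1] * d[3]
  if (training) {
    mu <- chan_stat(x, identity) / m
    v <- chan_stat(x, function(z) z^2) / m - mu^2
    v <- pmax(v, 0)
    layer$buffers$run_mean <- (1 - layer$momentum) * layer$buffers$run_mean +
      layer$momentum * mu
    layer$buffers$run_var <- (1 - layer$momentum) * layer$buffers$run_var +
      layer$momentum * v
  } else {
    mu <- layer$buffers$run_mean
    v <- layer$buffers$run_var
  }
  sd_c <- sqrt(v + layer$eps)
  xhat <- chan_mul(chan_add(x, -mu), 1 / sd_c)
  y <- chan_add(chan_mul(xhat, layer$params$gamma), layer$params$beta)
  list(out = y, cache = list(xhat = xhat, sd_c = sd_c, m = m),
       layer = layer)
}

bn_backward <- function(layer, cache, dy) {
  g <- layer$params$gamma
  m <- cache$m
  dgamma <- chan_stat(dy * cache$xhat, identity)
  dbeta <- chan_stat(dy, identity)
  dxhat <- chan_mul(dy, g)
  sum_dxhat <- chan_stat(dxhat, identity)
  sum_dxhat_xhat <- chan_stat(dxhat * cache$xhat, identity)
  t1 <- chan_add(dxhat, -sum_dxhat / m)
  t2 <- chan_mul(cache$xhat, sum_dxhat_xhat / m)
  dx <- chan_mul(t1 - t2, 1 / cache$sd_c)
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

pool_forward <- function(layer, x) {
  T_in <- dim(x)[3]
  if (T_in < 2L) return(list(out = x, cache = list(identity = TRUE, T_in = T_in)))
  T_out <- T_in %/% 2L
  x1 <- x[, , seq(1L, 2L * T_out, by = 2L), drop = FALSE]
  x2 <- x[, , seq(2L, 2L * T_out, by = 2L), drop = FALSE]
  list(out = (x1 + x2) / 2,
       cache = list(identity = FALSE, T_in = T_in, T_out = T_out,
                    dims = dim(x)))
}

pool_backward <- function(layer, cache, dy) {
  if (cache$identity) return(list(dx = dy, grads = list()))
  dx <- array(0, dim = cache$dims)
  half <- dy / 2
  dx[, , seq(1L, 2L * cache$T_out, by = 2L)] <- half
  dx[, , seq(2L, 2L * cache$T_out, by = 2L)] <- half
  list(dx = dx, grads = list())
}

lstm_forward <- function(layer, x) {
  d <- dim(x)
  n <- d[1]; C <- d[2]; T_steps <- d[3]
  H <- layer$hidden
  W <- layer$params$W
  b <- layer$params$b
  h <- matrix(0, n, H)
  cs <- matrix(0, n, H)
  caches <- vector("list", T_steps)
  brep <- rep(b, each = n)
  for (t in seq_len(T_steps)) {
    A <- cbind(h, matrix(x[, , t], n, C))
    Z <- A %*% W + brep
    f <- sigmoid(Z[, seq_len(H), drop = FALSE])
    i <- sigmoid(Z[, H + seq_len(H), drop = FALSE])
    g <- tanh(Z[, 2 * H + seq_len(H), drop = FALSE])
    o <- sigmoid(Z[, 3 * H + seq_len(H), drop = FALSE])
    c_prev <- cs
    cs <- f * c_prev + i * g
    tc <- tanh(cs)
    h <- o * tc
    caches[[t]] <- list(A = A, f = f, i = i, g = g, o = o,
                        c_prev = c_prev, c = cs, tc = tc)
  }
  list(out = h, cache = list(steps = caches, n = n, C = C, T_steps = T_steps))
}

lstm_backward <- function(layer, cache, dh_out) {
  H <- layer$hidden
  C <- cache$C
  n <- cache$n
  T_steps <- cache$T_steps
  W <- layer$params$W
  tW <- t(W)
  dh <- dh_out
  dc <- matrix(0, n, H)
  dx <- array(0, dim = c(n, C, T_steps))
  # stack per-step activations and gate grads, then one big crossprod for dW
  A_all <- matrix(0, n * T_steps, H + C)
  dZ_all <- matrix(0, n * T_steps, 4 * H)
  for (t in seq(T_steps, 1L)) {
    st <- cache$steps[[t]]
    do <- dh * st$tc * st$o * (1 - st$o)
    dc <- dc + dh * st$o * (1 - st$tc^2)
    df <- dc * st$c_prev * st$f * (1 - st$f)
    di <- dc * st$g * st$i * (1 - st$i)
    dg <- dc * st$i * (1 - st$g^2)
    dZ <- cbind(df, di, dg, do)
    rows <- (t - 1L) * n + seq_len(n)
    A_all[rows, ] <- st$A
    dZ_all[rows, ] <- dZ
    dA <- dZ %*% tW
    dh <- dA[, seq_len(H), drop = FALSE]
    dx[, , t] <- dA[, H + seq_len(C), drop = FALSE]
    dc <- dc * st$f
  }
  list(dx = dx, grads = list(W = crossprod(A_all, dZ_all), b = colSums(dZ_all)))
}

layer_forward <- function(layer, x, training) {
  switch(layer$type,
    bn = bn_forward(layer, x, training),
    conv = conv_forward(layer, x),
    relu = list(out = pmax(x, 0), cache = list(mask = x > 0)),
    pool = pool_forward(layer, x),
    dropout = {
      if (training && layer$p > 0) {
        keep <- array(runif(length(x)) >= layer$p, dim = dim(x))
        list(out = x * keep / (1 - layer$p), cache = list(keep = keep))
      } else {
        list(out = x, cache = list(keep = NULL))
      }
    },
    flatten = {
      d <- dim(x)
      list(out = matrix(x, d[1], d[2] * d[3]), cache = list(dims = d))
    },
    dense = {
      out <- x %*% layer$params$W
      list(out = out + rep(layer$params$b, each = nrow(out)),
           cache = list(x = x))
    },
    tanh = {
      y <- tanh(x)
      list(out = y, cache = list(y = y))
    },
    lstm = lstm_forward(layer, x),
    abort(paste0("Unknown layer type ", layer$type))
  )
}

layer_backward <- function(layer, cache, dy) {
  switch(layer$type,
    bn = bn_backward(layer, cache, dy),
    conv = conv_backward(layer, cache, dy),
    relu = list(dx = dy * cache$mask, grads = list()),
    pool = pool_backward(layer, cache, dy),
    dropout = {
      if (is.null(cache$keep)) list(dx = dy, grads = list())
      else list(dx = dy * cache$keep / (1 - layer$p), grads = list())
    },
    flatten = list(dx = array(dy, dim = cache$dims), grads = list()),
    dense = list(
      dx = dy %*% t(layer$params$W),
      grads = list(W = crossprod(cache$x, dy), b = colSums(dy))
    ),
    tanh = list(dx = dy * (1 - cache$y^2), grads = list()),
    lstm = lstm_backward(layer, cache, dy)
  )
}

net_forward <- function(layers, x, training) {
  caches <- vector("list", length(layers))
  for (l in seq_along(layers)) {
    res <- layer_forward(layers[[l]], x, training)
    if (training && layers[[l]]$type == "bn") layers[[l]] <- res$layer
    caches[[l]] <- res$cache
    x <- res$out
  }
  list(out = x, caches = caches, layers = layers)
}

net_backward <- function(layers, caches, dy) {
  grads <- vector("list", length(layers))
  for (l in seq(length(layers), 1L)) {
    res <- layer_backward(layers[[l]], caches[[l]], dy)
    grads[[l]] <- res$grads
    dy <- res$dx
  }
  grads
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(layers) {
  purrr::map(layers, function(layer) {
    purrr::map(layer$params, function(p) {
      list(m = p * 0, v = p * 0)
    })
  })
}

adam_step <- function(layers, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (l in seq_along(layers)) {
    for (nm in names(grads[[l]])) {
      g <- grads[[l]][[nm]]
      st <- state[[l]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      layers[[l]]$params[[nm]] <- layers[[l]]$params[[nm]] -
        lr * mhat / (sqrt(vhat) + eps)
      state[[l]][[nm]] <- st
    }
  }
  list(layers = layers, state = state)
}

# ---- losses -----------------------------------------------------------------

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# returns list(loss, dlogits)
loss_grad <- function(logits, target, task) {
  n <- nrow(logits)
  if (task == "classification") {
    p <- softmax_rows(logits)
    idx <- cbind(seq_len(n), target)
    loss <- -mean(log(pmax(p[idx], 1e-12)))
    dz <- p
    dz[idx] <- dz[idx] - 1
    list(loss = loss, dlogits = dz / n)
  } else {
    r <- logits[, 1] - target
    list(loss = mean(r^2), dlogits = matrix(2 * r / n, ncol = 1))
  }
}
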