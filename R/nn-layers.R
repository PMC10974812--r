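# Minimal neural-network engine: layer constructors, shape inference,
# parameter initialization, forward and backward passes. Dense, dropout,
# 1-D/2-D convolution (stride 1), max pooling, global average pooling,
# residual 2-D blocks and bidirectional LSTM layers; enough to express every
# architecture family of the pipeline. All shapes are batch-first:
# [n, d], [n, T, C] or [n, H, W, C].

#' @name nn-layers
#' @title Layer constructors for the built-in neural engine
#' @description Declarative layer descriptions consumed by [nn_model()].
#'   Shapes are inferred and parameters initialized (Glorot uniform) when
#'   the model is built.
#' @param units,filters Output width / number of convolution filters.
#' @param activation One of `"relu"`, `"swish"`, `"linear"`, `"softmax"`.
#' @param rate Dropout rate in `[0, 1)`.
#' @param kernel_size Kernel length (1-D) or side (2-D, square).
#' @param pool_size Pooling factor (stride equals the pool size).
#' @param padding `"valid"` or `"same"` (2-D convolution only).
#' @param return_sequences Emit the full output sequence (`TRUE`) or only
#'   the final state (`FALSE`).
#' @return A layer description list.
NULL

#' @rdname nn-layers
#' @export
layer_dense <- function(units, activation = "relu") {
  list(type = "dense", units = as.integer(units), activation = activation)
}

#' @rdname nn-layers
#' @export
layer_dropout <- function(rate) {
  stopifnot(rate >= 0, rate < 1)
  list(type = "dropout", rate = rate)
}

#' @rdname nn-layers
#' @export
layer_flatten <- function() list(type = "flatten")

#' @rdname nn-layers
#' @export
layer_conv1d <- function(filters, kernel_size, activation = "relu") {
  list(type = "conv1d", filters = as.integer(filters),
       kernel_size = as.integer(kernel_size), activation = activation)
}

#' @rdname nn-layers
#' @export
layer_maxpool1d <- function(pool_size = 2) {
  list(type = "maxpool1d", pool_size = as.integer(pool_size))
}

#' @rdname nn-layers
#' @export
layer_conv2d <- function(filters, kernel_size, activation = "relu",
                         padding = "valid") {
  list(type = "conv2d", filters = as.integer(filters),
       kernel_size = as.integer(kernel_size), activation = activation,
       padding = padding)
}

#' @rdname nn-layers
#' @export
layer_maxpool2d <- function(pool_size = 2) {
  list(type = "maxpool2d", pool_size = as.integer(pool_size))
}

#' @rdname nn-layers
#' @export
layer_global_avg_pool2d <- function() list(type = "gap2d")

#' @rdname nn-layers
#' @export
layer_residual2d <- function(filters, kernel_size = 3) {
  list(type = "residual2d", filters = as.integer(filters),
       kernel_size = as.integer(kernel_size))
}

#' @rdname nn-layers
#' @export
layer_bilstm <- function(units, return_sequences = FALSE) {
  list(type = "bilstm", units = as.integer(units),
       return_sequences = isTRUE(return_sequences))
}

glorot <- function(fan_in, fan_out, dims = c(fan_in, fan_out)) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

act_forward <- function(z, kind) {
  switch(kind,
         linear = z,
         relu = pmax(z, 0),
         swish = z * stats::plogis(z),
         softmax = {
           zm <- z - apply(z, 1L, max)
           e <- exp(zm)
           e / rowSums(e)
         },
         stop("unknown activation: ", kind))
}

# Gradient of the activation given pre-activation z (softmax is never
# differentiated here: its gradient is fused with the cross-entropy loss).
act_backward <- function(dout, z, kind) {
  switch(kind,
         linear = dout,
         relu = dout * (z > 0),
         swish = {
           s <- stats::plogis(z)
           dout * (s + z * s * (1 - s))
         },
         stop("cannot differentiate activation: ", kind))
}

# ---- shape inference & initialization ------------------------------------

layer_init <- function(layer, in_shape) {
  t <- layer$type
  if (t == "dense") {
    stopifnot(length(in_shape) == 1L)
    layer$params <- list(W = glorot(in_shape, layer$units),
                         b = numeric(layer$units))
    layer$out_shape <- layer$units
  } else if (t == "dropout") {
    layer$out_shape <- in_shape
  } else if (t == "flatten") {
    layer$out_shape <- prod(in_shape)
  } else if (t == "conv1d") {
    stopifnot(length(in_shape) == 2L)
    k <- layer$kernel_size; C <- in_shape[2]; F_ <- layer$filters
    layer$params <- list(W = glorot(k * C, F_), b = numeric(F_))
    layer$in_channels <- C
    layer$out_shape <- c(in_shape[1] - k + 1L, F_)
  } else if (t == "maxpool1d") {
    stopifnot(length(in_shape) == 2L)
    layer$out_shape <- c(in_shape[1] %/% layer$pool_size, in_shape[2])
  } else if (t == "conv2d") {
    stopifnot(length(in_shape) == 3L)
    k <- layer$kernel_size; C <- in_shape[3]; F_ <- layer$filters
    layer$params <- list(W = glorot(k * k * C, F_), b = numeric(F_))
    layer$in_channels <- C
    out_hw <- if (layer$padding == "same") in_shape[1:2] else in_shape[1:2] - k + 1L
    layer$out_shape <- c(out_hw, F_)
  } else if (t == "maxpool2d") {
    stopifnot(length(in_shape) == 3L)
    p <- layer$pool_size
    layer$out_shape <- c(in_shape[1] %/% p, in_shape[2] %/% p, in_shape[3])
  } else if (t == "gap2d") {
    stopifnot(length(in_shape) == 3L)
    layer$out_shape <- in_shape[3]
  } else if (t == "residual2d") {
    stopifnot(length(in_shape) == 3L)
    k <- layer$kernel_size; C <- in_shape[3]; F_ <- layer$filters
    layer$params <- list(W1 = glorot(k * k * C, F_), b1 = numeric(F_),
                         W2 = glorot(k * k * F_, F_), b2 = numeric(F_))
    layer$project <- C != F_
    if (layer$project) {
      layer$params$Wp <- glorot(C, F_)
      layer$params$bp <- numeric(F_)
    }
    layer$in_channels <- C
    layer$out_shape <- c(in_shape[1:2], F_)
  } else if (t == "bilstm") {
    stopifnot(length(in_shape) == 2L)
    d <- in_shape[2]; u <- layer$units
    mk <- function() {
      b <- numeric(4 * u)
      b[(u + 1L):(2L * u)] <- 1          # forget-gate bias
      list(Wx = glorot(d, 4 * u, c(d, 4 * u)),
           Wh = glorot(u, 4 * u, c(u, 4 * u)), b = b)
    }
    layer$params <- c(stats::setNames(mk(), c("Wx_f", "Wh_f", "b_f")),
                      stats::setNames(mk(), c("Wx_b", "Wh_b", "b_b")))
    layer$in_dim <- d
    layer$out_shape <- if (layer$return_sequences) {
      c(in_shape[1], 2L * u)
    } else {
      2L * u
    }
  } else {
    stop("unknown layer type: ", t)
  }
  layer
}

# ---- conv helpers (im2col) -----------------------------------------------

im2col_1d <- function(x, k) {
  d <- dim(x)                              # [n, T, C]
  t_out <- d[2] - k + 1L
  cols <- vector("list", k)
  for (j in seq_len(k)) {
    cols[[j]] <- matrix(x[, j:(j + t_out - 1L), , drop = FALSE],
                        d[1] * t_out, d[3])
  }
  do.call(cbind, cols)                     # [n*t_out, k*C]
}

col2im_1d <- function(dcol, dims, k) {
  n <- dims[1]; T_ <- dims[2]; C <- dims[3]
  t_out <- T_ - k + 1L
  dx <- array(0, dims)
  for (j in seq_len(k)) {
    block <- array(dcol[, ((j - 1L) * C + 1L):(j * C), drop = FALSE],
                   c(n, t_out, C))
    dx[, j:(j + t_out - 1L), ] <- dx[, j:(j + t_out - 1L), , drop = FALSE] + block
  }
  dx
}

pad2d <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1], d[2] + 2L * p, d[3] + 2L * p, d[4]))
  out[, (p + 1L):(p + d[2]), (p + 1L):(p + d[3]), ] <- x
  out
}

im2col_2d <- function(x, k) {
  d <- dim(x)                              # [n, H, W, C]
  h_out <- d[2] - k + 1L; w_out <- d[3] - k + 1L
  cols <- vector("list", k * k)
  idx <- 1L
  for (di in seq_len(k)) {
    for (dj in seq_len(k)) {
      cols[[idx]] <- matrix(x[, di:(di + h_out - 1L),
                              dj:(dj + w_out - 1L), , drop = FALSE],
                            d[1] * h_out * w_out, d[4])
      idx <- idx + 1L
    }
  }
  do.call(cbind, cols)                     # [n*h_out*w_out, k*k*C]
}

col2im_2d <- function(dcol, dims, k) {
  n <- dims[1]; H <- dims[2]; W <- dims[3]; C <- dims[4]
  h_out <- H - k + 1L; w_out <- W - k + 1L
  dx <- array(0, dims)
  idx <- 1L
  for (di in seq_len(k)) {
    for (dj in seq_len(k)) {
      block <- array(dcol[, ((idx - 1L) * C + 1L):(idx * C), drop = FALSE],
                     c(n, h_out, w_out, C))
      dx[, di:(di + h_out - 1L), dj:(dj + w_out - 1L), ] <-
        dx[, di:(di + h_out - 1L), dj:(dj + w_out - 1L), , drop = FALSE] + block
      idx <- idx + 1L
    }
  }
  dx
}

conv2d_raw <- function(x, W, b, k, pad_same) {
  p <- if (pad_same) (k - 1L) %/% 2L else 0L
  xp <- pad2d(x, p)
  d <- dim(xp)
  xcol <- im2col_2d(xp, k)
  z <- sweep(xcol %*% W, 2L, b, "+")
  h_out <- d[2] - k + 1L; w_out <- d[3] - k + 1L
  list(z = array(z, c(d[1], h_out, w_out, length(b))), xcol = xcol,
       xp_dims = d, p = p)
}

conv2d_raw_backward <- function(dz, cache, W, k) {
  dzm <- matrix(dz, nrow(cache$xcol), dim(dz)[4])
  dW <- crossprod(cache$xcol, dzm)
  db <- colSums(dzm)
  dxp <- col2im_2d(dzm %*% t(W), cache$xp_dims, k)
  p <- cache$p
  dx <- if (p > 0L) {
    d <- cache$xp_dims
    dxp[, (p + 1L):(d[2] - p), (p + 1L):(d[3] - p), , drop = FALSE]
  } else {
    dxp
  }
  list(dx = dx, dW = dW, db = db)
}

# ---- LSTM ----------------------------------------------------------------

lstm_forward_dir <- function(x, Wx, Wh, b, u) {
  d <- dim(x)                              # [n, T, din]
  n <- d[1]; T_ <- d[2]
  h <- matrix(0, n, u); c_ <- matrix(0, n, u)
  H <- array(0, c(n, T_, u))
  cache <- vector("list", T_)
  for (t in seq_len(T_)) {
    xt <- matrix(x[, t, , drop = FALSE], n, d[3])
    z <- sweep(xt %*% Wx + h %*% Wh, 2L, b, "+")
    i <- stats::plogis(z[, 1:u, drop = FALSE])
    f <- stats::plogis(z[, (u + 1):(2 * u), drop = FALSE])
    g <- tanh(z[, (2 * u + 1):(3 * u), drop = FALSE])
    o <- stats::plogis(z[, (3 * u + 1):(4 * u), drop = FALSE])
    c_prev <- c_
    c_ <- f * c_prev + i * g
    tc <- tanh(c_)
    h_prev_cache <- h
    h <- o * tc
    H[, t, ] <- h
    cache[[t]] <- list(xt = xt, i = i, f = f, g = g, o = o,
                       c_prev = c_prev, tc = tc, h_prev = h_prev_cache)
  }
  list(H = H, cache = cache)
}

lstm_backward_dir <- function(dH, dh_last, fwd, x_dims, Wx, Wh, u) {
  n <- x_dims[1]; T_ <- x_dims[2]; din <- x_dims[3]
  dWx <- matrix(0, din, 4 * u); dWh <- matrix(0, u, 4 * u)
  db <- numeric(4 * u)
  dx <- array(0, x_dims)
  dh_next <- if (is.null(dh_last)) matrix(0, n, u) else dh_last
  dc_next <- matrix(0, n, u)
  for (t in rev(seq_len(T_))) {
    cc <- fwd$cache[[t]]
    dh <- dh_next
    if (!is.null(dH)) dh <- dh + matrix(dH[, t, , drop = FALSE], n, u)
    do_ <- dh * cc$tc
    dc <- dc_next + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g
    dg <- dc * cc$i
    df <- dc * cc$c_prev
    dc_next <- dc * cc$f
    dz <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do_ * cc$o * (1 - cc$o))
    dWx <- dWx + crossprod(cc$xt, dz)
    dWh <- dWh + crossprod(cc$h_prev, dz)
    db <- db + colSums(dz)
    dx[, t, ] <- dz %*% t(Wx)
    dh_next <- dz %*% t(Wh)
  }
  list(dx = dx, dWx = dWx, dWh = dWh, db = db)
}

reverse_time <- function(x) {
  x[, rev(seq_len(dim(x)[2])), , drop = FALSE]
}

# ---- forward / backward dispatch -----------------------------------------

layer_forward <- function(layer, x, training = FALSE) {
  t <- layer$type
  if (t == "dense") {
    z <- sweep(x %*% layer$params$W, 2L, layer$params$b, "+")
    list(out = act_forward(z, layer$activation), cache = list(x = x, z = z))
  } else if (t == "dropout") {
    if (training && layer$rate > 0) {
      mask <- array(stats::rbinom(length(x), 1L, 1 - layer$rate),
                    dim(x) %||% length(x)) / (1 - layer$rate)
      list(out = x * mask, cache = list(mask = mask))
    } else {
      list(out = x, cache = list(mask = NULL))
    }
  } else if (t == "flatten") {
    d <- dim(x)
    list(out = matrix(x, d[1], prod(d[-1])), cache = list(dims = d))
  } else if (t == "conv1d") {
    k <- layer$kernel_size
    xcol <- im2col_1d(x, k)
    z <- sweep(xcol %*% layer$params$W, 2L, layer$params$b, "+")
    d <- dim(x)
    za <- array(z, c(d[1], d[2] - k + 1L, layer$filters))
    list(out = act_forward(za, layer$activation),
         cache = list(xcol = xcol, z = za, dims = d))
  } else if (t == "maxpool1d") {
    p <- layer$pool_size
    d <- dim(x)
    t_out <- d[2] %/% p
    best <- array(-Inf, c(d[1], t_out, d[3]))
    bestj <- array(1L, c(d[1], t_out, d[3]))
    for (j in seq_len(p)) {
      slice <- x[, seq(j, p * t_out, by = p), , drop = FALSE]
      upd <- slice > best
      best[upd] <- slice[upd]
      bestj[upd] <- j
    }
    list(out = best, cache = list(bestj = bestj, dims = d, t_out = t_out))
  } else if (t == "conv2d") {
    k <- layer$kernel_size
    cv <- conv2d_raw(x, layer$params$W, layer$params$b, k,
                     layer$padding == "same")
    list(out = act_forward(cv$z, layer$activation),
         cache = list(cv = cv, z = cv$z, x_dims = dim(x)))
  } else if (t == "maxpool2d") {
    p <- layer$pool_size
    d <- dim(x)
    h_out <- d[2] %/% p; w_out <- d[3] %/% p
    best <- array(-Inf, c(d[1], h_out, w_out, d[4]))
    bestij <- array(1L, c(d[1], h_out, w_out, d[4]))
    idx <- 1L
    for (di in seq_len(p)) {
      for (dj in seq_len(p)) {
        slice <- x[, seq(di, p * h_out, by = p), seq(dj, p * w_out, by = p),
                   , drop = FALSE]
        upd <- slice > best
        best[upd] <- slice[upd]
        bestij[upd] <- idx
        idx <- idx + 1L
      }
    }
    list(out = best, cache = list(bestij = bestij, dims = d,
                                  h_out = h_out, w_out = w_out))
  } else if (t == "gap2d") {
    d <- dim(x)
    out <- apply(x, c(1L, 4L), mean)
    list(out = matrix(out, d[1], d[4]), cache = list(dims = d))
  } else if (t == "residual2d") {
    k <- layer$kernel_size
    cv1 <- conv2d_raw(x, layer$params$W1, layer$params$b1, k, TRUE)
    a1 <- act_forward(cv1$z, "relu")
    cv2 <- conv2d_raw(a1, layer$params$W2, layer$params$b2, k, TRUE)
    if (layer$project) {
      d <- dim(x)
      xm <- matrix(x, prod(d[1:3]), d[4])
      skip <- array(sweep(xm %*% layer$params$Wp, 2L, layer$params$bp, "+"),
                    c(d[1:3], layer$filters))
    } else {
      skip <- x
      xm <- NULL
    }
    z <- cv2$z + skip
    list(out = act_forward(z, "relu"),
         cache = list(cv1 = cv1, a1 = a1, cv2 = cv2, z = z, xm = xm,
                      x_dims = dim(x)))
  } else if (t == "bilstm") {
    u <- layer$units
    p <- layer$params
    fwd <- lstm_forward_dir(x, p$Wx_f, p$Wh_f, p$b_f, u)
    xr <- reverse_time(x)
    bwd <- lstm_forward_dir(xr, p$Wx_b, p$Wh_b, p$b_b, u)
    d <- dim(x)
    if (layer$return_sequences) {
      out <- array(0, c(d[1], d[2], 2L * u))
      out[, , 1:u] <- fwd$H
      out[, , (u + 1):(2 * u)] <- reverse_time(bwd$H)
    } else {
      out <- cbind(matrix(fwd$H[, d[2], , drop = FALSE], d[1], u),
                   matrix(bwd$H[, d[2], , drop = FALSE], d[1], u))
    }
    list(out = out, cache = list(fwd = fwd, bwd = bwd, dims = d))
  } else {
    stop("unknown layer type: ", t)
  }
}

# `dout_is_dz = TRUE` (final dense under cross-entropy) means dout is already
# the pre-activation gradient.
layer_backward <- function(layer, cache, dout, dout_is_dz = FALSE) {
  t <- layer$type
  if (t == "dense") {
    dz <- if (dout_is_dz) dout else act_backward(dout, cache$z, layer$activation)
    list(dx = dz %*% t(layer$params$W),
         grads = list(W = crossprod(cache$x, dz), b = colSums(dz)))
  } else if (t == "dropout") {
    if (is.null(cache$mask)) list(dx = dout, grads = NULL)
    else list(dx = dout * cache$mask, grads = NULL)
  } else if (t == "flatten") {
    list(dx = array(dout, cache$dims), grads = NULL)
  } else if (t == "conv1d") {
    dz <- act_backward(dout, cache$z, layer$activation)
    dzm <- matrix(dz, nrow(cache$xcol), layer$filters)
    dW <- crossprod(cache$xcol, dzm)
    db <- colSums(dzm)
    dx <- col2im_1d(dzm %*% t(layer$params$W), cache$dims, layer$kernel_size)
    list(dx = dx, grads = list(W = dW, b = db))
  } else if (t == "maxpool1d") {
    p <- layer$pool_size
    d <- cache$dims
    dx <- array(0, d)
    for (j in seq_len(p)) {
      sel <- cache$bestj == j
      block <- array(0, dim(dout))
      block[sel] <- dout[sel]
      dx[, seq(j, p * cache$t_out, by = p), ] <-
        dx[, seq(j, p * cache$t_out, by = p), , drop = FALSE] + block
    }
    list(dx = dx, grads = NULL)
  } else if (t == "conv2d") {
    dz <- act_backward(dout, cache$z, layer$activation)
    bk <- conv2d_raw_backward(dz, cache$cv, layer$params$W,
                              layer$kernel_size)
    list(dx = bk$dx, grads = list(W = bk$dW, b = bk$db))
  } else if (t == "maxpool2d") {
    p <- layer$pool_size
    d <- cache$dims
    dx <- array(0, d)
    idx <- 1L
    for (di in seq_len(p)) {
      for (dj in seq_len(p)) {
        sel <- cache$bestij == idx
        block <- array(0, dim(dout))
        block[sel] <- dout[sel]
        dx[, seq(di, p * cache$h_out, by = p), seq(dj, p * cache$w_out, by = p), ] <-
          dx[, seq(di, p * cache$h_out, by = p),
             seq(dj, p * cache$w_out, by = p), , drop = FALSE] + block
        idx <- idx + 1L
      }
    }
    list(dx = dx, grads = NULL)
  } else if (t == "gap2d") {
    d <- cache$dims
    per <- d[2] * d[3]
    dx <- array(0, d)
    for (c_ in seq_len(d[4])) {
      dx[, , , c_] <- array(rep(dout[, c_] / per, per), d[1:3])
    }
    list(dx = dx, grads = NULL)
  } else if (t == "residual2d") {
    k <- layer$kernel_size
    dz <- act_backward(dout, cache$z, "relu")
    bk2 <- conv2d_raw_backward(dz, cache$cv2, layer$params$W2, k)
    da1 <- act_backward(bk2$dx, cache$cv1$z, "relu")
    bk1 <- conv2d_raw_backward(da1, cache$cv1, layer$params$W1, k)
    grads <- list(W1 = bk1$dW, b1 = bk1$db, W2 = bk2$dW, b2 = bk2$db)
    if (layer$project) {
      d <- cache$x_dims
      dzm <- matrix(dz, prod(d[1:3]), layer$filters)
      grads$Wp <- crossprod(cache$xm, dzm)
      grads$bp <- colSums(dzm)
      dskip <- array(dzm %*% t(layer$params$Wp), d)
    } else {
      dskip <- dz
    }
    list(dx = bk1$dx + dskip, grads = grads)
  } else if (t == "bilstm") {
    u <- layer$units
    p <- layer$params
    d <- cache$dims
    if (layer$return_sequences) {
      dH_f <- dout[, , 1:u, drop = FALSE]
      dH_b <- reverse_time(dout[, , (u + 1):(2 * u), drop = FALSE])
      gf <- lstm_backward_dir(dH_f, NULL, cache$fwd, c(d[1], d[2], layer$in_dim),
                              p$Wx_f, p$Wh_f, u)
      gb <- lstm_backward_dir(dH_b, NULL, cache$bwd, c(d[1], d[2], layer$in_dim),
                              p$Wx_b, p$Wh_b, u)
    } else {
      gf <- lstm_backward_dir(NULL, dout[, 1:u, drop = FALSE], cache$fwd,
                              c(d[1], d[2], layer$in_dim), p$Wx_f, p$Wh_f, u)
      gb <- lstm_backward_dir(NULL, dout[, (u + 1):(2 * u), drop = FALSE],
                              cache$bwd, c(d[1], d[2], layer$in_dim),
                              p$Wx_b, p$Wh_b, u)
    }
    list(dx = gf$dx + reverse_time(gb$dx),
         grads = list(Wx_f = gf$dWx, Wh_f = gf$dWh, b_f = gf$db,
                      Wx_b = gb$dWx, Wh_b = gb$dWh, b_b = gb$db))
  } else {
    stop("unknown layer type: ", t)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
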