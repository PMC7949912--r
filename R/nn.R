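# Minimal CPU neural-network layer library used by the slice regressors.
#
# Internal activation layout is channel-first: arrays (C, H, W, N) between
# convolutional layers and matrices (features, N) after global average
# pooling. With this layout a convolution is im2col + one matrix multiply
# whose output reshapes to the next activation with no permutation, and
# batch-norm statistics are plain row operations. Gather indices are
# precomputed per input geometry and cached. Everything is plain R so
# training is bit-reproducible under a fixed seed.

.conv_cache <- new.env(parent = emptyenv())

# im2col gather indices for a (C, H, W, N) batch with virtual zero padding.
# idx (k*k*C, Ho*Wo) holds 1-based source indices into the unpadded image,
# or 0 where the (padded) source is outside — gathers read a guard zero,
# scatters drop those gradients. `full` is the batch-expanded gather vector
# (guard index per*N + 1 for invalid), `rows` the per-patch-element scatter
# indices. Cached per geometry and batch size. Patch-row order: channel
# fastest, then kernel row, then kernel column, matching the weight layout.
conv_operator <- function(C, H, W, k, stride, pad, N) {
  key <- paste(C, H, W, k, stride, pad, N, sep = "_")
  hit <- .conv_cache[[key]]
  if (!is.null(hit)) return(hit)
  Ho <- (H + 2 * pad - k) %/% stride + 1L
  Wo <- (W + 2 * pad - k) %/% stride + 1L
  kkC <- k * k * C
  P <- Ho * Wo
  per <- C * H * W
  ch <- rep(0:(C - 1), times = k * k)
  dr <- rep(rep(0:(k - 1), each = C), times = k)
  dc <- rep(0:(k - 1), each = C * k)
  r0 <- rep((0:(Ho - 1)) * stride, times = Wo) - pad
  c0 <- rep((0:(Wo - 1)) * stride, each = Ho) - pad
  ri <- outer(dr, r0, `+`)
  ci <- outer(dc, c0, `+`)
  valid <- ri >= 0 & ri < H & ci >= 0 & ci < W
  idx <- ch + C * ri + C * H * ci + 1L
  guard <- as.integer(per * N + 1L)
  idxN <- matrix(guard, kkC, P)
  idxN[valid] <- as.integer(idx[valid])
  boff <- rep.int(as.integer((0:(N - 1)) * per), rep.int(kkC * P, N))
  full <- rep.int(as.vector(idxN), N)
  inval <- full == guard
  full <- full + boff
  full[inval] <- guard
  # per patch-element scatter rows (valid entries only), batch-expanded
  rows <- lapply(seq_len(kkC), function(j) {
    v <- which(valid[j, ])
    src <- as.integer(idx[j, v])
    list(
      ind = rep.int(src, N) + rep.int(as.integer((0:(N - 1)) * per), rep.int(length(v), N)),
      cols = rep.int(v, N) + rep.int(as.integer((0:(N - 1)) * P), rep.int(length(v), N)),
      all_valid = length(v) == P
    )
  })
  out <- list(
    full = full, rows = rows, Ho = Ho, Wo = Wo, kkC = kkC, P = P,
    per = per, guard = guard
  )
  .conv_cache[[key]] <- out
  out
}

# zero-pad the spatial dims of a (C, H, W, N) array
pad_hw <- function(x, p) {
  if (p == 0) return(x)
  d <- dim(x)
  out <- array(0, c(d[1], d[2] + 2 * p, d[3] + 2 * p, d[4]))
  out[, (p + 1):(p + d[2]), (p + 1):(p + d[3]), ] <- x
  out
}

unpad_hw <- function(x, p, d) {
  if (p == 0) {
    dim(x) <- d
    return(x)
  }
  out <- x[, (p + 1):(p + d[2]), (p + 1):(p + d[3]), , drop = FALSE]
  dim(out) <- d
  out
}

# ---- layer constructors ----------------------------------------------------

nn_conv <- function(in_ch, out_ch, k = 3L, stride = 1L, pad = 1L) {
  fan_in <- k * k * in_ch
  list(
    type = "conv", k = k, stride = stride, pad = pad,
    in_ch = in_ch, out_ch = out_ch,
    params = list(
      W = matrix(rnorm(fan_in * out_ch, 0, sqrt(2 / fan_in)), fan_in, out_ch),
      b = numeric(out_ch)
    )
  )
}

nn_bn <- function(ch, momentum = 0.1, eps = 1e-5) {
  list(
    type = "bn", ch = ch, momentum = momentum, eps = eps,
    params = list(gamma = rep(1, ch), beta = numeric(ch)),
    state = list(mean = numeric(ch), var = rep(1, ch))
  )
}

nn_relu <- function() list(type = "relu", params = list())

nn_maxpool <- function(k = 3L, stride = 2L, pad = 1L) {
  list(type = "maxpool", k = k, stride = stride, pad = pad, params = list())
}

nn_gap <- function() list(type = "gap", params = list())

nn_linear <- function(in_f, out_f) {
  list(
    type = "linear", in_f = in_f, out_f = out_f,
    params = list(
      W = matrix(rnorm(in_f * out_f, 0, sqrt(2 / in_f)), in_f, out_f),
      b = numeric(out_f)
    )
  )
}

nn_resblock <- function(in_ch, out_ch, stride = 1L) {
  main <- list(
    nn_conv(in_ch, out_ch, 3L, stride, 1L), nn_bn(out_ch), nn_relu(),
    nn_conv(out_ch, out_ch, 3L, 1L, 1L), nn_bn(out_ch)
  )
  shortcut <- if (stride != 1L || in_ch != out_ch) {
    list(nn_conv(in_ch, out_ch, 1L, stride, 0L), nn_bn(out_ch))
  } else {
    list()
  }
  list(type = "resblock", main = main, shortcut = shortcut, params = list())
}

# ---- forward / backward ----------------------------------------------------

conv_forward <- function(layer, x) {
  d <- dim(x)
  op <- conv_operator(d[1], d[2], d[3], layer$k, layer$stride, layer$pad, d[4])
  xv <- c(x, 0) # guard zero at index per*N + 1 for virtual padding
  X <- matrix(xv[op$full], op$kkC)
  Y <- crossprod(layer$params$W, X) + layer$params$b
  dim(Y) <- c(layer$out_ch, op$Ho, op$Wo, d[4])
  list(out = Y, cache = list(X = X, op = op, dim_x = d))
}

conv_backward <- function(layer, dout, cache) {
  op <- cache$op
  dY <- matrix(dout, layer$out_ch)
  dW <- tcrossprod(cache$X, dY)
  db <- rowSums(dY)
  dX <- layer$params$W %*% dY
  dx <- numeric(prod(cache$dim_x))
  # for a fixed patch element the source voxels are distinct, so each row
  # scatters with a plain indexed add
  for (j in seq_len(op$kkC)) {
    r <- op$rows[[j]]
    ind <- r$ind
    dx[ind] <- dx[ind] + if (r$all_valid) dX[j, ] else dX[j, r$cols]
  }
  dim(dx) <- cache$dim_x
  list(dx = dx, grads = list(W = dW, b = db))
}

bn_forward <- function(layer, x, training) {
  d <- dim(x)
  M <- matrix(x, layer$ch) # channels x (H*W*N)
  if (training) {
    mu <- rowMeans(M)
    xc <- M - mu
    v <- rowMeans(xc * xc)
  } else {
    mu <- layer$state$mean
    v <- layer$state$var
    xc <- M - mu
  }
  invstd <- 1 / sqrt(v + layer$eps)
  xhat <- xc * invstd
  y <- xhat * layer$params$gamma + layer$params$beta
  dim(y) <- d
  state <- layer$state
  if (training) {
    m <- layer$momentum
    state$mean <- (1 - m) * state$mean + m * mu
    state$var <- (1 - m) * state$var + m * v
  }
  list(out = y, cache = list(xhat = xhat, invstd = invstd, dim = d), state = state)
}

bn_backward <- function(layer, dout, cache) {
  dy <- matrix(dout, layer$ch)
  n <- ncol(dy)
  dgamma <- rowSums(dy * cache$xhat)
  dbeta <- rowSums(dy)
  dx <- (layer$params$gamma * cache$invstd) *
    (dy - dbeta / n - cache$xhat * (dgamma / n))
  dim(dx) <- cache$dim
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

maxpool_forward <- function(layer, x) {
  d <- dim(x)
  xp <- pad_hw(x, layer$pad)
  dp <- dim(xp)
  C <- dp[1]
  # per-channel pooling: kernel offsets for one channel, expanded over
  # channels (stride 1 in the channel dimension) and images
  k <- layer$k
  dr <- rep(0:(k - 1), times = k)
  dc <- rep(0:(k - 1), each = k)
  patch_off <- C * dr + C * dp[2] * dc
  Ho <- (dp[2] - k) %/% layer$stride + 1L
  Wo <- (dp[3] - k) %/% layer$stride + 1L
  r0 <- rep((0:(Ho - 1)) * layer$stride, times = Wo)
  c0 <- rep((0:(Wo - 1)) * layer$stride, each = Ho)
  base <- C * r0 + C * dp[2] * c0
  per <- prod(dp[1:3])
  offs <- outer(0:(C - 1), c(outer(base, (0:(dp[4] - 1)) * per, `+`)), `+`)
  full <- outer(as.integer(patch_off), as.integer(offs), `+`) + 1L
  X <- matrix(xp[full], k * k)
  am <- max.col(t(X), ties.method = "first")
  sel <- (seq_len(ncol(X)) - 1L) * nrow(X) + am
  vals <- X[sel]
  # column order is (channel, position, image): reorder to (C, Ho, Wo, N)
  out <- array(vals, c(C, Ho, Wo, dp[4]))
  src <- full[sel]
  list(out = out, cache = list(src = src, dp = dp, d = d))
}

maxpool_backward <- function(layer, dout, cache) {
  dxp <- numeric(prod(cache$dp))
  acc <- rowsum(as.vector(dout), cache$src)
  dxp[as.integer(rownames(acc))] <- acc[, 1]
  dim(dxp) <- cache$dp
  list(dx = unpad_hw(dxp, layer$pad, cache$d), grads = list())
}

gap_forward <- function(x) {
  d <- dim(x)
  out <- matrix(0, d[1], d[4])
  for (n in seq_len(d[4])) {
    out[, n] <- rowMeans(matrix(x[, , , n], d[1]))
  }
  list(out = out, cache = list(d = d))
}

gap_backward <- function(dout, cache) {
  d <- cache$d
  hw <- d[2] * d[3]
  dx <- array(0, d)
  for (n in seq_len(d[4])) {
    dx[, , , n] <- dout[, n] / hw # recycles channel-first
  }
  list(dx = dx, grads = list())
}

layer_forward <- function(layer, x, training) {
  switch(layer$type,
    conv = c(conv_forward(layer, x), list(state = NULL)),
    bn = bn_forward(layer, x, training),
    relu = list(out = pmax(x, 0), cache = list(mask = x > 0), state = NULL),
    maxpool = c(maxpool_forward(layer, x), list(state = NULL)),
    gap = c(gap_forward(x), list(state = NULL)),
    linear = list(
      out = crossprod(layer$params$W, x) + layer$params$b,
      cache = list(x = x), state = NULL
    ),
    resblock = {
      fm <- seq_forward(layer$main, x, training)
      fs <- if (length(layer$shortcut)) {
        seq_forward(layer$shortcut, x, training)
      } else {
        list(out = x, caches = NULL, states = NULL)
      }
      pre <- fm$out + fs$out
      list(
        out = pmax(pre, 0),
        cache = list(main = fm$caches, shortcut = fs$caches, mask = pre > 0),
        state = list(main = fm$states, shortcut = fs$states)
      )
    },
    abort(paste0("unknown layer type: ", layer$type))
  )
}

layer_backward <- function(layer, dout, cache) {
  switch(layer$type,
    conv = conv_backward(layer, dout, cache),
    bn = bn_backward(layer, dout, cache),
    relu = {
      dx <- dout
      dx[!cache$mask] <- 0
      list(dx = dx, grads = list())
    },
    maxpool = maxpool_backward(layer, dout, cache),
    gap = gap_backward(dout, cache),
    linear = list(
      dx = layer$params$W %*% dout,
      grads = list(W = tcrossprod(cache$x, dout), b = rowSums(dout))
    ),
    resblock = {
      dpre <- dout
      dpre[!cache$mask] <- 0
      bm <- seq_backward(layer$main, dpre, cache$main)
      if (length(layer$shortcut)) {
        bs <- seq_backward(layer$shortcut, dpre, cache$shortcut)
        dx <- bm$dx + bs$dx
        grads <- list(main = bm$grads, shortcut = bs$grads)
      } else {
        dx <- bm$dx + dpre
        grads <- list(main = bm$grads, shortcut = list())
      }
      list(dx = dx, grads = grads)
    }
  )
}

seq_forward <- function(layers, x, training) {
  caches <- vector("list", length(layers))
  states <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    f <- layer_forward(layers[[i]], x, training)
    x <- f$out
    caches[i] <- list(f$cache)
    states[i] <- list(f$state)
  }
  list(out = x, caches = caches, states = states)
}

seq_backward <- function(layers, dout, caches) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    b <- layer_backward(layers[[i]], dout, caches[[i]])
    dout <- b$dx
    grads[i] <- list(b$grads)
  }
  list(dx = dout, grads = grads)
}

# Recalibrate batch-norm running statistics with a cumulative average of
# clean-batch statistics (the training-time running average is computed on
# augmented batches, whose intensity shifts bias it relative to clean
# evaluation input). Momentum-1 forwards give raw batch stats per layer;
# they are averaged across batches and written back.
set_bn_momentum <- function(layers, m) {
  for (i in seq_along(layers)) {
    if (layers[[i]]$type == "bn") {
      layers[[i]]$momentum <- m
    } else if (layers[[i]]$type == "resblock") {
      layers[[i]]$main <- set_bn_momentum(layers[[i]]$main, m)
      layers[[i]]$shortcut <- set_bn_momentum(layers[[i]]$shortcut, m)
    }
  }
  layers
}

accumulate_states <- function(acc, states, k) {
  for (i in seq_along(states)) {
    st <- states[[i]]
    if (is.null(st)) next
    if (!is.null(st$mean)) { # bn state
      if (is.null(acc[[i]])) {
        acc[[i]] <- st
      } else {
        acc[[i]]$mean <- acc[[i]]$mean + (st$mean - acc[[i]]$mean) / k
        acc[[i]]$var <- acc[[i]]$var + (st$var - acc[[i]]$var) / k
      }
    } else { # resblock
      if (is.null(acc[[i]])) acc[[i]] <- list(main = NULL, shortcut = NULL)
      acc[[i]]$main <- accumulate_states(acc[[i]]$main %||% vector("list", length(st$main)), st$main, k)
      acc[[i]]$shortcut <- accumulate_states(acc[[i]]$shortcut %||% vector("list", length(st$shortcut)), st$shortcut, k)
    }
  }
  acc
}

refresh_bn <- function(layers, data, batch = 64L) {
  layers1 <- set_bn_momentum(layers, 1)
  N <- dim(data)[4]
  acc <- vector("list", length(layers1))
  i <- 1L
  k <- 0L
  while (i <= N) {
    j <- min(i + batch - 1L, N)
    if (j - i < 1L) break # batch stats need >= 2 samples
    xb <- aperm(data[, , , i:j, drop = FALSE], c(3, 1, 2, 4))
    f <- seq_forward(layers1, xb, training = TRUE)
    acc <- accumulate_states(acc, f$states, (k <- k + 1L))
    i <- j + 1L
  }
  if (k > 0L) layers <- apply_states(layers, acc)
  layers
}

# fold updated BN running stats back into the layer list
apply_states <- function(layers, states) {
  for (i in seq_along(layers)) {
    st <- states[[i]]
    if (is.null(st)) next
    if (layers[[i]]$type == "bn") {
      layers[[i]]$state <- st
    } else if (layers[[i]]$type == "resblock") {
      layers[[i]]$main <- apply_states(layers[[i]]$main, st$main)
      if (length(layers[[i]]$shortcut)) {
        layers[[i]]$shortcut <- apply_states(layers[[i]]$shortcut, st$shortcut)
      }
    }
  }
  layers
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(layers) {
  lapply(layers, function(l) {
    if (l$type == "resblock") {
      list(main = adam_init(l$main), shortcut = adam_init(l$shortcut))
    } else {
      lapply(l$params, function(p) list(m = p * 0, v = p * 0))
    }
  })
}

adam_update <- function(layers, grads, state, lr, wd, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "resblock") {
      up_m <- adam_update(l$main, grads[[i]]$main, state[[i]]$main, lr, wd, t)
      l$main <- up_m$layers
      state[[i]]$main <- up_m$state
      if (length(l$shortcut)) {
        up_s <- adam_update(l$shortcut, grads[[i]]$shortcut, state[[i]]$shortcut, lr, wd, t)
        l$shortcut <- up_s$layers
        state[[i]]$shortcut <- up_s$state
      }
      layers[[i]] <- l
      next
    }
    if (!length(l$params)) next
    for (nm in names(l$params)) {
      g <- grads[[i]][[nm]]
      if (is.null(g)) next
      # classic Adam L2: decay folded into the gradient
      g <- g + wd * l$params[[nm]]
      st <- state[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      l$params[[nm]] <- l$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      state[[i]][[nm]] <- st
    }
    layers[[i]] <- l
  }
  list(layers = layers, state = state)
}

count_params <- function(layers) {
  sum(vapply(layers, function(l) {
    if (l$type == "resblock") {
      count_params(l$main) + count_params(l$shortcut)
    } else {
      sum(vapply(l$params, length, numeric(1)))
    }
  }, numeric(1)))
}
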