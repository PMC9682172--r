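# ---------------------------------------------------------------------------
# Minimal deterministic neural-network engine.
#
# Tensors are column-major arrays [maps, rows, time, batch] for convolutional
# stages and [units, batch] matrices for dense stages.  Convolution is im2col
# + GEMM with 'same' padding along the time axis and 'valid' along the
# channel-row axis.  All randomness (init, validation split, shuffling,
# dropout, RReLU slopes) flows through the R RNG, so a seed fixes a run
# bit-exactly.  Layers carry a `trainable` flag: frozen layers are skipped by
# the optimizer, and frozen batch-norm layers run with their inference
# statistics even during training, so their state is bit-identical across a
# training run.
# ---------------------------------------------------------------------------

new_layer <- function(type, ..., trainable = TRUE) {
  c(list(type = type, trainable = trainable), list(...))
}

init_conv <- function(c_in, c_out, kh, kw) {
  fan_in <- c_in * kh * kw
  list(W = matrix(stats::rnorm(fan_in * c_out, 0, sqrt(2 / fan_in)), fan_in, c_out),
       b = numeric(c_out))
}

init_dense <- function(n_in, n_out) {
  list(W = matrix(stats::rnorm(n_out * n_in, 0, sqrt(2 / n_in)), n_out, n_in),
       b = numeric(n_out))
}

layer_conv <- function(c_in, c_out, kh, kw) {
  p <- init_conv(c_in, c_out, kh, kw)
  new_layer("conv", c_in = c_in, c_out = c_out, kh = kh, kw = kw,
            pad_w = (kw - 1L) %/% 2L, W = p$W, b = p$b)
}

layer_bn <- function(n) {
  new_layer("bn", n = n, gamma = rep(1, n), beta = numeric(n),
            run_mean = numeric(n), run_var = rep(1, n),
            momentum = 0.1, eps = 1e-5)
}

layer_rrelu <- function(lower = 1 / 8, upper = 1 / 3) {
  if (!(lower > 0 && lower <= upper && upper < 1)) {
    stopf("RReLU bounds must satisfy 0 < lower <= upper < 1")
  }
  new_layer("rrelu", lower = lower, upper = upper)
}

layer_pool <- function(p) new_layer("pool", p = as.integer(p))
layer_dropout <- function(p = 0.3) new_layer("dropout", p = p)
layer_flatten <- function() new_layer("flatten")
layer_dense <- function(n_in, n_out) {
  p <- init_dense(n_in, n_out)
  new_layer("dense", n_in = n_in, n_out = n_out, W = p$W, b = p$b)
}
layer_tanh <- function() new_layer("tanh")
layer_parallel <- function(branches) new_layer("parallel", branches = branches)

#' Randomized rectified linear unit
#'
#' Identity for non-negative inputs.  Negative inputs are scaled by a random
#' slope drawn uniformly from `[lower, upper]` in training mode, and by the
#' deterministic mean slope `(lower + upper) / 2` in evaluation mode.
#'
#' @param x Numeric vector/array.
#' @param lower,upper Slope bounds (defaults 1/8 and 1/3).
#' @param mode `"train"` or `"eval"`.
#' @return Array of the same shape as `x`.
#' @export
rrelu <- function(x, lower = 1 / 8, upper = 1 / 3, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  if (!(lower > 0 && lower <= upper && upper < 1)) {
    stopf("RReLU bounds must satisfy 0 < lower <= upper < 1")
  }
  y <- x
  neg <- x < 0
  if (mode == "eval") {
    y[neg] <- x[neg] * (lower + upper) / 2
  } else {
    y[neg] <- x[neg] * stats::runif(sum(neg), lower, upper)
  }
  y
}

# ---- forward/backward -----------------------------------------------------

# Per-tap gather/scatter index vectors for im2col, cached per shape (they
# are reused every batch).  Within one kernel tap the target positions are
# unique, so scatter-adds in the backward pass need no deduplication.
conv_index_cache <- new.env(parent = emptyenv())

conv_indices <- function(C, H, Wp, N, kh, kw) {
  key <- paste(C, H, Wp, N, kh, kw, sep = "_")
  hit <- conv_index_cache[[key]]
  if (!is.null(hit)) return(hit)
  H_out <- H - kh + 1L
  W_out <- Wp - kw + 1L  # == original W for 'same' time padding
  # 0-based offsets of output cols (h0 fastest, then w0, then n)
  base <- rep(0:(H_out - 1L), times = W_out * N) +
    H * (rep(rep(0:(W_out - 1L), each = H_out), times = N) +
         Wp * rep(0:(N - 1L), each = H_out * W_out))
  tgts <- vector("list", kh * kw)
  t <- 0L
  for (dw in 0:(kw - 1L)) for (dh in 0:(kh - 1L)) {
    # row-block order must match the weight layout: c fastest, then dh, dw
    t <- t + 1L
    off <- dh + H * dw
    tgts[[t]] <- rep(C * (base + off), each = C) + seq_len(C)
  }
  # reorder blocks to (dh fastest, dw slowest) as enumerated above: the loop
  # above already emits dh fastest within dw; block t corresponds to
  # (dh, dw) = ((t-1) %% kh, (t-1) %/% kh), matching the weight rows.
  val <- list(tgts = tgts, H_out = H_out, W_out = W_out, ncol = H_out * W_out * N)
  conv_index_cache[[key]] <- val
  val
}

fwd_conv <- function(layer, x) {
  d <- dim(x)  # [c_in, H, W, N]
  C <- d[1L]; H <- d[2L]; W <- d[3L]; N <- d[4L]
  kh <- layer$kh; kw <- layer$kw; pw <- layer$pad_w
  if (H - kh + 1L < 1L) stopf("conv kernel height %d exceeds input rows %d", kh, H)
  Wp <- W + 2L * pw
  xp <- array(0, c(C, H, Wp, N))
  xp[, , (pw + 1L):(pw + W), ] <- x
  ci <- conv_indices(C, H, Wp, N, kh, kw)
  R <- C * kh * kw
  M <- matrix(0, R, ci$ncol)
  for (t in seq_len(kh * kw)) {
    M[((t - 1L) * C + 1L):(t * C), ] <- xp[ci$tgts[[t]]]
  }
  out <- crossprod(layer$W, M) + layer$b
  dim(out) <- c(layer$c_out, ci$H_out, W, N)
  list(out = out, cache = list(M = M, in_dim = d, ci = ci))
}

bwd_conv <- function(layer, cache, dy) {
  d <- cache$in_dim
  C <- d[1L]; H <- d[2L]; W <- d[3L]; N <- d[4L]
  kh <- layer$kh; kw <- layer$kw; pw <- layer$pad_w
  ci <- cache$ci
  dim(dy) <- c(layer$c_out, ci$ncol)
  grads <- list(W = tcrossprod(cache$M, dy), b = rowSums(dy))
  dM <- layer$W %*% dy
  dxp <- numeric(C * H * (W + 2L * pw) * N)
  for (t in seq_len(kh * kw)) {
    tg <- ci$tgts[[t]]
    dxp[tg] <- dxp[tg] + dM[((t - 1L) * C + 1L):(t * C), ]
  }
  dim(dxp) <- c(C, H, W + 2L * pw, N)
  dx <- dxp[, , (pw + 1L):(pw + W), , drop = FALSE]
  list(dx = dx, grads = grads)
}

fwd_bn <- function(layer, x, mode) {
  d <- dim(x)
  xm <- x
  dim(xm) <- c(layer$n, length(x) / layer$n)
  m <- ncol(xm)
  use_batch <- (mode == "train") && layer$trainable && m > 1L
  if (use_batch) {
    mu <- rowMeans(xm)
    v <- rowMeans(xm^2) - mu^2
    layer$run_mean <- (1 - layer$momentum) * layer$run_mean + layer$momentum * mu
    layer$run_var <- (1 - layer$momentum) * layer$run_var + layer$momentum * v
  } else {
    mu <- layer$run_mean
    v <- layer$run_var
  }
  invstd <- 1 / sqrt(v + layer$eps)
  xhat <- (xm - mu) * invstd
  out <- layer$gamma * xhat + layer$beta
  dim(out) <- d
  list(out = out, cache = list(xhat = xhat, invstd = invstd, d = d, m = m),
       layer = layer)
}

bwd_bn <- function(layer, cache, dy) {
  dim(dy) <- c(layer$n, cache$m)
  xhat <- cache$xhat
  grads <- list(gamma = rowSums(dy * xhat), beta = rowSums(dy))
  dxhat <- dy * layer$gamma
  m <- cache$m
  dx <- (cache$invstd / m) * (m * dxhat - rowSums(dxhat) - xhat * rowSums(dxhat * xhat))
  dim(dx) <- cache$d
  list(dx = dx, grads = grads)
}

fwd_rrelu <- function(layer, x, mode) {
  s <- array(1, dim(x) %||% length(x))
  neg <- x < 0
  if (mode == "train") {
    s[neg] <- stats::runif(sum(neg), layer$lower, layer$upper)
  } else {
    s[neg] <- (layer$lower + layer$upper) / 2
  }
  list(out = x * s, cache = list(s = s))
}

fwd_pool <- function(layer, x) {
  d <- dim(x)
  p <- layer$p
  W_out <- d[3L] %/% p
  if (W_out < 1L) stopf("pool size %d reduces time axis %d below 1", p, d[3L])
  xr <- x[, , seq_len(W_out * p), , drop = FALSE]
  dim(xr) <- c(d[1L], d[2L], p, W_out, d[4L])
  mx <- xr[, , 1L, , , drop = FALSE]
  dim(mx) <- c(d[1L], d[2L], W_out, d[4L])
  am <- array(1L, dim(mx))
  if (p > 1L) for (i in 2:p) {
    v <- xr[, , i, , , drop = FALSE]
    dim(v) <- dim(mx)
    upd <- v > mx
    mx[upd] <- v[upd]
    am[upd] <- i
  }
  list(out = mx, cache = list(am = am, in_dim = d, W_out = W_out))
}

bwd_pool <- function(layer, cache, dy) {
  d <- cache$in_dim
  p <- layer$p
  W_out <- cache$W_out
  dxr <- array(0, c(d[1L], d[2L], p, W_out, d[4L]))
  for (i in seq_len(p)) {
    sl <- array(0, dim(cache$am))
    hit <- cache$am == i
    sl[hit] <- dy[hit]
    dxr[, , i, , ] <- sl
  }
  dx <- array(0, d)
  dx[, , seq_len(W_out * p), ] <- dxr
  list(dx = dx, grads = NULL)
}

fwd_dropout <- function(layer, x, mode) {
  if (mode != "train" || layer$p <= 0) {
    return(list(out = x, cache = list(mask = NULL)))
  }
  mask <- (stats::runif(length(x)) >= layer$p) / (1 - layer$p)
  dim(mask) <- dim(x)
  list(out = x * mask, cache = list(mask = mask))
}

fwd_dense <- function(layer, x) {
  list(out = layer$W %*% x + layer$b, cache = list(x = x))
}

bwd_dense <- function(layer, cache, dy) {
  list(dx = crossprod(layer$W, dy),
       grads = list(W = tcrossprod(dy, cache$x), b = rowSums(dy)))
}

# Forward through a layer list.  Returns output, per-layer caches, and the
# (possibly updated, for BN running stats) layers.
forward_layers <- function(layers, x, mode) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    r <- switch(l$type,
      conv = fwd_conv(l, x),
      bn = fwd_bn(l, x, mode),
      rrelu = fwd_rrelu(l, x, mode),
      pool = fwd_pool(l, x),
      dropout = fwd_dropout(l, x, mode),
      flatten = {
        d <- dim(x)
        y <- x
        dim(y) <- c(prod(d[-length(d)]), d[length(d)])
        list(out = y, cache = list(d = d))
      },
      dense = fwd_dense(l, x),
      tanh = { y <- tanh(x); list(out = y, cache = list(y = y)) },
      parallel = {
        outs <- vector("list", length(l$branches))
        bcaches <- vector("list", length(l$branches))
        for (bi in seq_along(l$branches)) {
          br <- forward_layers(l$branches[[bi]], x, mode)
          outs[[bi]] <- br$out
          bcaches[[bi]] <- br$caches
          l$branches[[bi]] <- br$layers
        }
        list(out = do.call(rbind, outs), cache = list(bcaches = bcaches,
             widths = vapply(outs, nrow, 1L)), layer = l)
      },
      stopf("unknown layer type '%s'", l$type))
    if (!is.null(r$layer)) layers[[i]] <- r$layer
    caches[[i]] <- r$cache
    x <- r$out
  }
  list(out = x, caches = caches, layers = layers)
}

# Backward through a layer list from the gradient at its output.  Gradients
# are accumulated for trainable layers only; `stop_at` (index) prunes the
# sweep below the earliest trainable layer.
backward_layers <- function(layers, caches, dy, stop_at = 1L) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    r <- switch(l$type,
      conv = bwd_conv(l, caches[[i]], dy),
      bn = bwd_bn(l, caches[[i]], dy),
      rrelu = list(dx = dy * caches[[i]]$s, grads = NULL),
      pool = bwd_pool(l, caches[[i]], dy),
      dropout = {
        m <- caches[[i]]$mask
        list(dx = if (is.null(m)) dy else dy * m, grads = NULL)
      },
      flatten = { dim(dy) <- caches[[i]]$d; list(dx = dy, grads = NULL) },
      dense = bwd_dense(l, caches[[i]], dy),
      tanh = list(dx = dy * (1 - caches[[i]]$y^2), grads = NULL),
      parallel = {
        w <- caches[[i]]$widths
        offs <- cumsum(c(0L, w))
        bgrads <- vector("list", length(l$branches))
        dx <- NULL
        for (bi in seq_along(l$branches)) {
          dyb <- dy[(offs[bi] + 1L):offs[bi + 1L], , drop = FALSE]
          br <- backward_layers(l$branches[[bi]], caches[[i]]$bcaches[[bi]], dyb)
          bgrads[[bi]] <- br$grads
          dx <- if (is.null(dx)) br$dx else dx + br$dx
        }
        list(dx = dx, grads = bgrads)
      },
      stopf("unknown layer type '%s'", l$type))
    if ((l$trainable || l$type == "parallel") && !is.null(r$grads)) {
      grads[[i]] <- r$grads
    }
    if (i <= stop_at) break
    dy <- r$dx
  }
  list(grads = grads, dx = r$dx)
}

# ---- parameter plumbing ---------------------------------------------------

param_names <- function(l) {
  switch(l$type, conv = c("W", "b"), dense = c("W", "b"),
         bn = c("gamma", "beta"), character())
}

# Apply fn(layer, path) over every layer in a (possibly nested) layer list.
walk_layers <- function(layers, fn) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "parallel") {
      for (bi in seq_along(l$branches)) {
        l$branches[[bi]] <- walk_layers(l$branches[[bi]], fn)
      }
      layers[[i]] <- fn(l)
    } else {
      layers[[i]] <- fn(l)
    }
  }
  layers
}

count_trainable_layers <- function(layers) {
  total <- 0L
  for (l in layers) {
    if (l$type == "parallel") {
      total <- total + sum(vapply(l$branches, count_trainable_layers, 0L))
    } else if (l$trainable) {
      total <- total + sum(vapply(param_names(l), function(p) length(l[[p]]), 0L))
    }
  }
  total
}

#' Count trainable parameters of a model
#'
#' Sums weight, bias, and batch-norm scale/shift parameters over layers whose
#' freeze mask marks them trainable.  Batch-norm running statistics are
#' buffers, not parameters, and are never counted.
#'
#' @param model An `emg_net`, PFCnet, Siamese, or FTnet model.
#' @return Integer parameter count.
#' @export
count_trainable <- function(model) {
  if (inherits(model, "emg_siamese")) {
    return(length(model$w) + 1L)
  }
  stopifnot(inherits(model, "emg_net"))
  count_trainable_layers(model$layers)
}

snapshot_params <- function(layers) {
  lapply(layers, function(l) {
    if (l$type == "parallel") {
      list(branches = lapply(l$branches, snapshot_params))
    } else {
      keep <- c(param_names(l), if (l$type == "bn") c("run_mean", "run_var"))
      l[keep]
    }
  })
}

restore_params <- function(layers, snap) {
  for (i in seq_along(layers)) {
    if (layers[[i]]$type == "parallel") {
      for (bi in seq_along(layers[[i]]$branches)) {
        layers[[i]]$branches[[bi]] <-
          restore_params(layers[[i]]$branches[[bi]], snap[[i]]$branches[[bi]])
      }
    } else {
      for (nm in names(snap[[i]])) layers[[i]][[nm]] <- snap[[i]][[nm]]
    }
  }
  layers
}

# Adam update over a nested layer list; `state` mirrors the layer structure.
adam_step <- function(layers, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  if (is.null(state)) state <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "parallel") {
      if (is.null(state[[i]])) state[[i]] <- vector("list", length(l$branches))
      for (bi in seq_along(l$branches)) {
        if (is.null(grads[[i]][[bi]])) next
        r <- adam_step(l$branches[[bi]], grads[[i]][[bi]], state[[i]][[bi]],
                       lr, t, beta1, beta2, eps)
        layers[[i]]$branches[[bi]] <- r$layers
        state[[i]][[bi]] <- r$state
      }
      next
    }
    if (!l$trainable || is.null(grads[[i]])) next
    if (is.null(state[[i]])) state[[i]] <- list()
    for (nm in names(grads[[i]])) {
      g <- grads[[i]][[nm]]
      st <- state[[i]][[nm]] %||% list(m = g * 0, v = g * 0)
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      layers[[i]][[nm]] <- layers[[i]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
      state[[i]][[nm]] <- st
    }
  }
  list(layers = layers, state = state)
}

# Earliest trainable layer index at the top level (parallel counts as
# trainable if any branch layer is).
first_trainable_index <- function(layers) {
  has_trainable <- function(ls) {
    any(vapply(ls, function(l) {
      if (l$type == "parallel") any(vapply(l$branches, has_trainable, TRUE))
      else l$trainable && length(param_names(l)) > 0L
    }, TRUE))
  }
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    hit <- if (l$type == "parallel") any(vapply(l$branches, has_trainable, TRUE))
           else l$trainable && length(param_names(l)) > 0L
    if (hit) return(i)
  }
  length(layers)
}

# ---- input plumbing and inference -----------------------------------------

# Windows [n, channels, len] -> engine input [1, channels, len, n].
windows_to_input <- function(ws) {
  if (inherits(ws, "emg_windows")) ws <- ws$windows
  d <- dim(ws)
  x <- aperm(ws, c(2L, 3L, 1L))
  dim(x) <- c(1L, d[2L], d[3L], d[1L])
  x
}

softmax_cols <- function(z) {
  z <- sweep(z, 2L, apply(z, 2L, max))
  e <- exp(z)
  sweep(e, 2L, colSums(e), "/")
}

net_logits <- function(net, x, mode = "eval", upto = NULL) {
  layers <- if (is.null(upto)) net$layers else net$layers[seq_len(upto)]
  forward_layers(layers, x, mode)$out
}

#' Class-probability and label prediction for a trained network
#'
#' Runs the network in evaluation mode (no dropout, deterministic RReLU
#' slope, batch-norm inference statistics).  Probability rows are
#' non-negative and sum to one for softmax heads; sigmoid heads return
#' per-unit activations.  `predict_label()` takes the per-row argmax with
#' lowest-index tie-break.
#'
#' @param net A trained `emg_net`.
#' @param ws An [emg_windows()] set (or a `[n, channels, len]` array).
#' @param batch_size Inference batch size.
#' @return `predict_proba()`: matrix `[n_windows x n_classes]` with class
#'   columns; `predict_label()`: character vector of predicted class tokens.
#' @export
predict_proba <- function(net, ws, batch_size = 256L) {
  stopifnot(inherits(net, "emg_net"))
  x <- windows_to_input(ws)
  d <- dim(x)
  if (!identical(d[1:3], net$input_shape)) {
    stopf("input shape [%s] does not match model input [%s]",
          paste(d[1:3], collapse = "x"), paste(net$input_shape, collapse = "x"))
  }
  n <- d[4L]
  out <- matrix(0, n, length(net$classes), dimnames = list(NULL, net$classes))
  for (at in seq(1L, n, by = batch_size)) {
    idx <- at:min(at + batch_size - 1L, n)
    z <- net_logits(net, x[, , , idx, drop = FALSE], mode = "eval")
    p <- if (net$out_act == "softmax") softmax_cols(z) else 1 / (1 + exp(-z))
    out[idx, ] <- t(p)
  }
  out
}

#' @rdname predict_proba
#' @export
predict_label <- function(net, ws, batch_size = 256L) {
  p <- predict_proba(net, ws, batch_size)
  net$classes[apply(p, 1L, which.max)]
}

# ---- training -------------------------------------------------------------

#' Training configuration for the network engine
#'
#' @param epochs Maximum epochs.
#' @param batch_size Minibatch size.
#' @param lr Initial learning rate (Adam).
#' @param lr_end Final learning rate for an exponential per-epoch decay, or
#'   `NULL` for a constant rate.
#' @param val_fraction Fraction of the training windows held out (randomly,
#'   seeded) for validation-loss checkpointing.
#' @param patience Early-stopping patience in epochs (`Inf` disables).
#' @param seed Seed fixing validation split, shuffling, dropout and RReLU.
#' @return A list of class `"emg_train_config"`.
#' @export
emg_train_config <- function(epochs = 30L, batch_size = 128L, lr = 0.001,
                             lr_end = NULL, val_fraction = 0.2,
                             patience = Inf, seed = 1L) {
  stopifnot(epochs >= 1L, batch_size >= 1L, val_fraction >= 0, val_fraction < 1)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, lr_end = lr_end, val_fraction = val_fraction,
                 patience = patience, seed = seed),
            class = "emg_train_config")
}

# Loss and logit-gradient for softmax cross-entropy or per-unit sigmoid
# binary cross-entropy against one-hot targets.  Both share the gradient
# (p - y) / batch at the logits.
loss_and_grad <- function(z, Y, out_act) {
  n <- ncol(z)
  if (out_act == "softmax") {
    p <- softmax_cols(z)
    loss <- -mean(log(pmax(colSums(p * Y), 1e-12)))
  } else {
    p <- 1 / (1 + exp(-z))
    loss <- -mean(Y * log(pmax(p, 1e-12)) + (1 - Y) * log(pmax(1 - p, 1e-12)))
  }
  list(loss = loss, dz = (p - Y) / n)
}

take_batch <- function(x, idx) {
  if (length(dim(x)) == 4L) x[, , , idx, drop = FALSE] else x[, idx, drop = FALSE]
}

any_trainable_params <- function(layers) {
  any(vapply(layers, function(l) {
    if (l$type == "parallel") any(vapply(l$branches, any_trainable_params, TRUE))
    else l$trainable && length(param_names(l)) > 0L
  }, TRUE))
}

eval_loss_layers <- function(layers, out_act, x, Y, batch_size = 256L) {
  d <- dim(x)
  n <- d[length(d)]
  tot <- 0
  for (at in seq(1L, n, by = batch_size)) {
    idx <- at:min(at + batch_size - 1L, n)
    z <- forward_layers(layers, take_batch(x, idx), "eval")$out
    tot <- tot + loss_and_grad(z, Y[, idx, drop = FALSE], out_act)$loss * length(idx)
  }
  tot / n
}

# Eval-mode activations of a frozen layer prefix, computed in batches.
forward_frozen_prefix <- function(layers, x, batch_size = 256L) {
  d <- dim(x)
  n <- d[length(d)]
  out <- NULL
  for (at in seq(1L, n, by = batch_size)) {
    idx <- at:min(at + batch_size - 1L, n)
    z <- forward_layers(layers, take_batch(x, idx), "eval")$out
    if (is.null(out)) {
      dz <- dim(z)
      dz[length(dz)] <- n
      out <- array(0, dz)
    }
    if (length(dim(out)) == 4L) out[, , , idx] <- z else out[, idx] <- z
  }
  out
}

#' Train a network with Adam, validation checkpointing and early stopping
#'
#' Holds out `val_fraction` of the training windows (random, seeded) as a
#' validation set, minimizes cross-entropy (softmax head) or per-unit binary
#' cross-entropy (sigmoid head) with Adam, records per-epoch train and
#' validation loss, keeps the weights of the minimum-validation-loss epoch,
#' and stops early when validation loss has not improved for `patience`
#' epochs.  Frozen layers are untouched by the optimizer.
#'
#' @param net An `emg_net` (see [build_cnet()]).
#' @param ws Training [emg_windows()]; labels must cover >= 2 classes unless
#'   the net was built with an explicit class set.
#' @param cfg An [emg_train_config()].
#' @return The trained `emg_net`, with `history` (data frame of epoch losses)
#'   and `best_epoch` fields.
#' @export
train_model <- function(net, ws, cfg = emg_train_config()) {
  stopifnot(inherits(net, "emg_net"))
  if (n_windows(ws) == 0L) stopf("empty training set")
  if (is.null(net$classes)) stopf("net has no class set")
  if (length(unique(ws$labels)) < 2L) stopf("training data has a single class")
  if (!all(ws$labels %in% net$classes)) stopf("training labels outside the model's class set")
  x <- windows_to_input(ws)
  Y <- matrix(0, length(net$classes), n_windows(ws))
  Y[cbind(match(ws$labels, net$classes), seq_len(ncol(Y)))] <- 1
  # A fully frozen layer prefix below the earliest trainable layer is a
  # deterministic feature map (frozen layers run in eval mode), so its
  # activations are computed once instead of every epoch.  This is what
  # makes the staged fine-tuning schedules cheap.
  stop_full <- first_trainable_index(net$layers)
  prefix <- seq_len(stop_full - 1L)
  frozen_prefix <- length(prefix) > 0L && !any_trainable_params(net$layers[prefix])
  if (frozen_prefix) {
    x <- forward_frozen_prefix(net$layers[prefix], x)
    layers <- net$layers[-prefix]
  } else {
    layers <- net$layers
  }
  with_seed(cfg$seed, {
    n <- ncol(Y)
    n_val <- floor(cfg$val_fraction * n)
    val_idx <- if (n_val > 0L) sample.int(n, n_val) else integer()
    tr_idx <- setdiff(seq_len(n), val_idx)
    xv <- take_batch(x, val_idx); Yv <- Y[, val_idx, drop = FALSE]
    stop_at <- first_trainable_index(layers)
    state <- vector("list", length(layers))
    best <- list(loss = Inf, epoch = 0L, snap = snapshot_params(layers))
    history <- data.frame(epoch = integer(), train_loss = double(),
                          val_loss = double())
    t_adam <- 0L
    for (ep in seq_len(cfg$epochs)) {
      lr <- if (is.null(cfg$lr_end) || cfg$epochs == 1L) cfg$lr else {
        cfg$lr * (cfg$lr_end / cfg$lr)^((ep - 1) / (cfg$epochs - 1))
      }
      ord <- tr_idx[sample.int(length(tr_idx))]
      ep_loss <- 0
      for (at in seq(1L, length(ord), by = cfg$batch_size)) {
        idx <- ord[at:min(at + cfg$batch_size - 1L, length(ord))]
        fw <- forward_layers(layers, take_batch(x, idx), "train")
        layers <- fw$layers  # BN running-stat updates
        lg <- loss_and_grad(fw$out, Y[, idx, drop = FALSE], net$out_act)
        ep_loss <- ep_loss + lg$loss * length(idx)
        bw <- backward_layers(layers, fw$caches, lg$dz, stop_at)
        t_adam <- t_adam + 1L
        up <- adam_step(layers, bw$grads, state, lr, t_adam)
        layers <- up$layers
        state <- up$state
      }
      ep_loss <- ep_loss / length(ord)
      vl <- if (n_val > 0L) eval_loss_layers(layers, net$out_act, xv, Yv) else ep_loss
      history <- rbind(history, data.frame(epoch = ep, train_loss = ep_loss,
                                           val_loss = vl))
      if (vl < best$loss - 1e-12) {
        best <- list(loss = vl, epoch = ep, snap = snapshot_params(layers))
      } else if (ep - best$epoch >= cfg$patience) {
        break
      }
    }
    layers <- restore_params(layers, best$snap)
    if (frozen_prefix) {
      net$layers[-prefix] <- layers
    } else {
      net$layers <- layers
    }
    net$history <- history
    net$best_epoch <- best$epoch
  })
  net
}
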