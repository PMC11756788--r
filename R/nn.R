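# Minimal differentiable network substrate for 1-D sequence models.
#
# Batches of one-hot sequences are arrays of shape (channels, length, batch);
# after flattening/pooling, activations are (features, batch) matrices.
# Convolutions are computed as BLAS matrix products via im2col. Every layer
# implements an explicit backward pass, which both drives training and
# provides the input gradients required by integrated-gradients attribution.

#' Convolutional layer (1-D, stride 1)
#'
#' @param in_ch,out_ch channel counts.
#' @param kernel kernel width.
#' @param dilation dilation rate.
#' @param pad `"same"` (zero-padded, length-preserving) or `"valid"`.
#' @return a layer object; weights use seeded He-uniform initialisation drawn
#'   from the current RNG state.
#' @export
layer_conv1d <- function(in_ch, out_ch, kernel, dilation = 1L, pad = "same") {
  fan_in <- in_ch * kernel
  lim <- sqrt(6 / fan_in)
  list(type = "conv1d", in_ch = in_ch, out_ch = out_ch, k = as.integer(kernel),
       dilation = as.integer(dilation), pad = match.arg(pad, c("same", "valid")),
       frozen = FALSE,
       params = list(
         W = matrix(stats::runif(out_ch * fan_in, -lim, lim), out_ch, fan_in),
         b = numeric(out_ch)))
}

#' Batch normalisation over channels
#' @param ch channel count.
#' @return a layer object.
#' @export
layer_batchnorm <- function(ch) {
  list(type = "batchnorm", ch = ch, eps = 1e-5, momentum = 0.1, frozen = FALSE,
       params = list(gamma = rep(1, ch), beta = numeric(ch)),
       state = list(mean = numeric(ch), var = rep(1, ch)))
}

#' @rdname layer_conv1d
#' @export
layer_relu <- function() list(type = "relu", frozen = FALSE, params = NULL)

#' @rdname layer_conv1d
#' @export
layer_gelu <- function() list(type = "gelu", frozen = FALSE, params = NULL)

#' Max pooling (non-overlapping windows)
#' @param width pool width; the incoming length must be divisible by it.
#' @return a layer object.
#' @export
layer_maxpool <- function(width) {
  list(type = "maxpool", width = as.integer(width), frozen = FALSE, params = NULL)
}

#' Attention pooling over positions
#'
#' A learned linear map gives one scalar score per position; a softmax over
#' positions turns scores into weights; the output is the score-weighted sum
#' of per-position feature vectors (as used for sequence-to-vector pooling in
#' attention-based genomics architectures).
#'
#' @param in_ch incoming channel count.
#' @return a layer object.
#' @export
layer_attention_pool <- function(in_ch) {
  lim <- sqrt(6 / (in_ch + 1))
  list(type = "attention_pool", in_ch = in_ch, frozen = FALSE,
       params = list(wa = stats::runif(in_ch, -lim, lim), ba = 0))
}

#' @rdname layer_attention_pool
#' @export
layer_mean_pool <- function() list(type = "mean_pool", frozen = FALSE, params = NULL)

#' @rdname layer_conv1d
#' @export
layer_flatten <- function() list(type = "flatten", frozen = FALSE, params = NULL)

#' Fully connected layer
#' @param in_dim,out_dim feature dimensions.
#' @return a layer object; seeded Glorot-uniform initialisation.
#' @export
layer_dense <- function(in_dim, out_dim) {
  lim <- sqrt(6 / (in_dim + out_dim))
  list(type = "dense", in_dim = in_dim, out_dim = out_dim, frozen = FALSE,
       params = list(
         W = matrix(stats::runif(out_dim * in_dim, -lim, lim), out_dim, in_dim),
         b = numeric(out_dim)))
}

#' @rdname layer_conv1d
#' @export
layer_sigmoid <- function() list(type = "sigmoid", frozen = FALSE, params = NULL)

#' Residual block: output = input + sublayers(input)
#' @param layers list of layer objects whose composition preserves shape.
#' @return a layer object.
#' @export
layer_residual <- function(layers) {
  list(type = "residual", frozen = FALSE, params = NULL, sub = layers)
}

#' Assemble a network
#'
#' Verifies shape compatibility by symbolic propagation and records metadata:
#' parameter count, total downsampling factor and receptive field of the
#' convolutional prefix.
#'
#' @param layers list of layer objects.
#' @param input_shape `c(channels, length)` of one one-hot sample, or a
#'   single feature count for flat-vector inputs (e.g. targets matrices).
#' @return an `nn_model`.
#' @export
nn_model <- function(layers, input_shape) {
  shp <- if (length(input_shape) == 1L) {
    list(mode = "vec", C = input_shape[1], L = 1L)
  } else {
    list(mode = "seq", C = input_shape[1], L = input_shape[2])
  }
  down <- 1L; rf <- 1L
  infer <- function(shp, layer) {
    switch(layer$type,
      conv1d = {
        stopifnot(shp$mode == "seq")
        if (shp$C != layer$in_ch) stop("conv1d channel mismatch", call. = FALSE)
        span <- (layer$k - 1L) * layer$dilation
        rf <<- rf + span * down
        if (layer$pad == "valid") {
          if (shp$L - span < 1) stop("input length incompatible with conv", call. = FALSE)
          shp$L <- shp$L - span
        }
        shp$C <- layer$out_ch
      },
      batchnorm = stopifnot(shp$mode == "seq", shp$C == layer$ch),
      maxpool = {
        stopifnot(shp$mode == "seq")
        if (shp$L %% layer$width != 0) {
          stop("input length incompatible with pooling factors", call. = FALSE)
        }
        shp$L <- shp$L %/% layer$width
        down <<- down * layer$width
      },
      attention_pool = {
        stopifnot(shp$mode == "seq")
        if (shp$C != layer$in_ch) stop("attention_pool channel mismatch", call. = FALSE)
        shp <- list(mode = "vec", C = shp$C, L = 1L)
      },
      mean_pool = {
        stopifnot(shp$mode == "seq")
        shp <- list(mode = "vec", C = shp$C, L = 1L)
      },
      flatten = {
        stopifnot(shp$mode == "seq")
        shp <- list(mode = "vec", C = shp$C * shp$L, L = 1L)
      },
      dense = {
        stopifnot(shp$mode == "vec")
        if (shp$C != layer$in_dim) {
          stop(sprintf("dense expects %d features, got %d", layer$in_dim, shp$C),
               call. = FALSE)
        }
        shp$C <- layer$out_dim
      },
      relu = , gelu = , sigmoid = NULL,
      residual = {
        shp0 <- shp
        for (sl in layer$sub) shp <- infer(shp, sl)
        if (!identical(shp0[c("mode", "C", "L")], shp[c("mode", "C", "L")])) {
          stop("residual sublayers must preserve shape", call. = FALSE)
        }
      },
      stop("unknown layer type: ", layer$type, call. = FALSE)
    )
    shp
  }
  for (layer in layers) shp <- infer(shp, layer)
  model <- structure(list(layers = layers, input_shape = input_shape,
                          input_mode = if (length(input_shape) == 1L) "vec" else "seq",
                          output_shape = c(shp$C, shp$L),
                          output_mode = shp$mode),
                     class = "nn_model")
  model$meta <- list(n_params = nn_n_params(model), downsample = down,
                     receptive_field = rf)
  model
}

#' @export
print.nn_model <- function(x, ...) {
  cat(sprintf("<nn_model: %d layers, %d parameters, input %s>\n",
              length(x$layers), x$meta$n_params,
              paste(x$input_shape, collapse = "x")))
  invisible(x)
}

count_params <- function(layers) {
  sum(vapply(layers, function(l) {
    n <- sum(vapply(l$params, length, numeric(1))) %||% 0
    if (!is.null(l$sub)) n <- n + count_params(l$sub)
    n
  }, numeric(1)))
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

#' Total trainable parameter count
#' @param model an `nn_model`.
#' @return integer count.
#' @export
nn_n_params <- function(model) as.integer(count_params(model$layers))

# ---- forward ---------------------------------------------------------------

conv_forward <- function(layer, x) {
  d <- dim(x); C <- d[1]; L <- d[2]; B <- d[3]
  k <- layer$k; dil <- layer$dilation
  span <- (k - 1L) * dil
  if (layer$pad == "same") {
    pl <- span %/% 2L
    xp <- array(0, c(C, L + span, B))
    xp[, (pl + 1L):(pl + L), ] <- x
    Lout <- L
  } else {
    xp <- x
    pl <- 0L
    Lout <- L - span
  }
  col <- array(0, c(C * k, Lout, B))
  for (j in seq_len(k)) {
    off <- (j - 1L) * dil
    col[((j - 1L) * C + 1L):(j * C), , ] <- xp[, (off + 1L):(off + Lout), , drop = FALSE]
  }
  dim(col) <- c(C * k, Lout * B)
  out <- layer$params$W %*% col + layer$params$b
  dim(out) <- c(layer$out_ch, Lout, B)
  list(out = out, cache = list(col = col, C = C, L = L, B = B, Lout = Lout,
                               pl = pl, span = span))
}

conv_backward <- function(layer, dout, cache, need_dx = TRUE) {
  C <- cache$C; L <- cache$L; B <- cache$B; Lout <- cache$Lout
  k <- layer$k; dil <- layer$dilation
  dim(dout) <- c(layer$out_ch, Lout * B)
  dW <- tcrossprod(dout, cache$col)
  db <- rowSums(dout)
  if (!need_dx) {
    return(list(dx = NULL, grads = list(W = dW, b = db)))
  }
  dcol <- crossprod(layer$params$W, dout)
  dim(dcol) <- c(C * k, Lout, B)
  dxp <- array(0, c(C, L + cache$span, B))
  for (j in seq_len(k)) {
    off <- (j - 1L) * dil
    idx <- (off + 1L):(off + Lout)
    dxp[, idx, ] <- dxp[, idx, , drop = FALSE] +
      dcol[((j - 1L) * C + 1L):(j * C), , , drop = FALSE]
  }
  dx <- dxp[, (cache$pl + 1L):(cache$pl + L), , drop = FALSE]
  list(dx = dx, grads = list(W = dW, b = db))
}

bn_forward <- function(layer, x, train) {
  if (train && isTRUE(layer$frozen)) train <- FALSE  # frozen layers keep their stats
  if (train) {
    m <- rowMeans(x, dims = 1)
    v <- rowMeans(x * x, dims = 1) - m * m
    layer$state$mean <- (1 - layer$momentum) * layer$state$mean + layer$momentum * m
    layer$state$var <- (1 - layer$momentum) * layer$state$var + layer$momentum * v
  } else {
    m <- layer$state$mean
    v <- layer$state$var
  }
  invstd <- 1 / sqrt(v + layer$eps)
  xhat <- (x - m) * invstd  # recycles along channel (first) dim
  out <- layer$params$gamma * xhat + layer$params$beta
  list(out = out, cache = list(xhat = xhat, invstd = invstd, train = train),
       layer = layer)
}

bn_backward <- function(layer, dout, cache) {
  xhat <- cache$xhat
  dgamma <- rowSums(dout * xhat, dims = 1)
  dbeta <- rowSums(dout, dims = 1)
  dxhat <- dout * layer$params$gamma
  if (cache$train) {
    N <- prod(dim(dout)[-1])
    dx <- (cache$invstd / N) *
      (N * dxhat - rowSums(dxhat, dims = 1) - xhat * rowSums(dxhat * xhat, dims = 1))
  } else {
    dx <- dxhat * cache$invstd
  }
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

maxpool_forward <- function(layer, x) {
  d <- dim(x); C <- d[1]; L <- d[2]; B <- d[3]
  p <- layer$width
  if (L %% p != 0) stop("input length incompatible with pooling factors", call. = FALSE)
  Q <- L %/% p
  r <- x
  dim(r) <- c(C, p, Q, B)
  mx <- r[, 1, , , drop = TRUE]
  dim(mx) <- c(C, Q, B)
  arg <- array(1L, c(C, Q, B))
  if (p > 1) {
    for (j in 2:p) {
      s <- r[, j, , , drop = TRUE]
      dim(s) <- c(C, Q, B)
      upd <- s > mx
      mx[upd] <- s[upd]
      arg[upd] <- j
    }
  }
  list(out = mx, cache = list(arg = arg, C = C, L = L, B = B, p = p, Q = Q))
}

maxpool_backward <- function(layer, dout, cache) {
  C <- cache$C; Q <- cache$Q; B <- cache$B; p <- cache$p
  dr <- numeric(C * cache$L * B)
  ci <- rep.int(seq_len(C), Q * B)
  qi <- rep.int(rep(seq_len(Q), each = C), B)
  bi <- rep(seq_len(B), each = C * Q)
  lin <- ci + C * ((cache$arg - 1L) + p * ((qi - 1L) + Q * (bi - 1L)))
  dr[lin] <- dout
  dim(dr) <- c(C, cache$L, B)
  list(dx = dr, grads = NULL)
}

attn_forward <- function(layer, x) {
  d <- dim(x); C <- d[1]; L <- d[2]; B <- d[3]
  s <- crossprod(matrix(x, C, L * B), layer$params$wa) + layer$params$ba
  dim(s) <- c(L, B)
  a <- exp(sweep(s, 2, apply(s, 2, max)))
  a <- sweep(a, 2, colSums(a), "/")
  out <- matrix(0, C, B)
  for (b in seq_len(B)) out[, b] <- x[, , b] %*% a[, b]
  list(out = out, cache = list(x = x, a = a, C = C, L = L, B = B))
}

attn_backward <- function(layer, dout, cache) {
  C <- cache$C; L <- cache$L; B <- cache$B
  dx <- array(0, c(C, L, B))
  dwa <- numeric(C); dba <- 0
  wa <- layer$params$wa
  for (b in seq_len(B)) {
    Fb <- cache$x[, , b, drop = TRUE]
    dim(Fb) <- c(C, L)
    ab <- cache$a[, b]
    da <- drop(crossprod(Fb, dout[, b]))
    ds <- ab * (da - sum(ab * da))
    dx[, , b] <- outer(dout[, b], ab) + outer(wa, ds)
    dwa <- dwa + drop(Fb %*% ds)
    dba <- dba + sum(ds)
  }
  list(dx = dx, grads = list(wa = dwa, ba = dba))
}

meanpool_forward <- function(layer, x) {
  d <- dim(x); C <- d[1]; L <- d[2]; B <- d[3]
  out <- matrix(0, C, B)
  for (b in seq_len(B)) out[, b] <- rowMeans(matrix(x[, , b], C, L))
  list(out = out, cache = list(C = C, L = L, B = B))
}

meanpool_backward <- function(layer, dout, cache) {
  dx <- aperm(array(dout / cache$L, c(cache$C, cache$B, cache$L)), c(1, 3, 2))
  list(dx = dx, grads = NULL)
}

layer_forward <- function(layer, x, train) {
  switch(layer$type,
    conv1d = conv_forward(layer, x),
    batchnorm = bn_forward(layer, x, train),
    relu = list(out = pmax(x, 0), cache = list(mask = x > 0)),
    gelu = {
      ph <- stats::pnorm(x)
      list(out = x * ph, cache = list(x = x, ph = ph))
    },
    maxpool = maxpool_forward(layer, x),
    attention_pool = attn_forward(layer, x),
    mean_pool = meanpool_forward(layer, x),
    flatten = {
      d <- dim(x)
      list(out = matrix(x, d[1] * d[2], d[3]), cache = list(d = d))
    },
    dense = list(out = layer$params$W %*% x + layer$params$b, cache = list(x = x)),
    sigmoid = {
      p <- 1 / (1 + exp(-x))
      list(out = p, cache = list(p = p))
    },
    residual = {
      caches <- vector("list", length(layer$sub))
      h <- x
      upd <- layer
      for (i in seq_along(layer$sub)) {
        r <- layer_forward(layer$sub[[i]], h, train)
        if (!is.null(r$layer)) upd$sub[[i]] <- r$layer
        caches[[i]] <- r$cache
        h <- r$out
      }
      list(out = x + h, cache = list(sub = caches), layer = upd)
    },
    stop("unknown layer type", call. = FALSE)
  )
}

layer_backward <- function(layer, dout, cache, need_dx = TRUE) {
  switch(layer$type,
    conv1d = conv_backward(layer, dout, cache, need_dx),
    batchnorm = bn_backward(layer, dout, cache),
    relu = list(dx = dout * cache$mask, grads = NULL),
    gelu = list(dx = dout * (cache$ph + cache$x * stats::dnorm(cache$x)), grads = NULL),
    maxpool = maxpool_backward(layer, dout, cache),
    attention_pool = attn_backward(layer, dout, cache),
    mean_pool = meanpool_backward(layer, dout, cache),
    flatten = {
      dim(dout) <- cache$d
      list(dx = dout, grads = NULL)
    },
    dense = list(dx = crossprod(layer$params$W, dout),
                 grads = list(W = tcrossprod(dout, cache$x), b = rowSums(dout))),
    sigmoid = list(dx = dout * cache$p * (1 - cache$p), grads = NULL),
    residual = {
      g <- vector("list", length(layer$sub))
      d <- dout
      for (i in rev(seq_along(layer$sub))) {
        r <- layer_backward(layer$sub[[i]], d, cache$sub[[i]])
        g[i] <- list(r$grads)  # keep NULL grads as placeholders
        d <- r$dx
      }
      list(dx = dout + d, grads = list(sub = g))
    }
  )
}

#' Forward pass through a network
#'
#' @param model an [nn_model()].
#' @param x input batch, array `(channels, length, batch)`.
#' @param train logical; training mode uses batch statistics in batch
#'   normalisation and updates its running statistics (the updated model is
#'   returned). Eval mode is fully deterministic.
#' @return list with `out` (final activations; for sigmoid-headed classifiers
#'   a `1 x batch` matrix of probabilities), `caches` (for
#'   [nn_backward_pass()]) and `model` (with updated normalisation state).
#' @export
nn_forward_pass <- function(model, x, train = FALSE) {
  if (model$input_mode == "seq" && length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  caches <- vector("list", length(model$layers))
  h <- x
  for (i in seq_along(model$layers)) {
    r <- layer_forward(model$layers[[i]], h, train)
    if (!is.null(r$layer)) model$layers[[i]] <- r$layer
    caches[[i]] <- r$cache
    h <- r$out
  }
  list(out = h, caches = caches, model = model)
}

#' Backward pass: gradients of a scalar objective
#'
#' @param model the model used in the forward pass.
#' @param caches caches returned by [nn_forward_pass()].
#' @param dout gradient of the objective with respect to the network output
#'   (same shape as `out`).
#' @param need_input_grad compute the gradient with respect to the input
#'   batch (required for attribution; during parameter training the first
#'   layer's input gradient is not needed and is skipped).
#' @return list with `dx` (gradient w.r.t. the input batch, or `NULL` when
#'   `need_input_grad = FALSE`) and `grads` (per-layer parameter gradients,
#'   parallel to `model$layers`).
#' @export
nn_backward_pass <- function(model, caches, dout, need_input_grad = TRUE) {
  grads <- vector("list", length(model$layers))
  d <- dout
  for (i in rev(seq_along(model$layers))) {
    r <- layer_backward(model$layers[[i]], d, caches[[i]],
                        need_dx = need_input_grad || i > 1L)
    grads[i] <- list(r$grads)  # keep NULL grads as placeholders
    d <- r$dx
  }
  list(dx = d, grads = grads)
}

#' Predicted probabilities for a batch of one-hot sequences
#'
#' Runs the model in eval mode, in chunks to bound memory.
#'
#' @param model a sigmoid-headed [nn_model()].
#' @param x array `(4, L, n)` (or a single `4 x L` matrix).
#' @param batch_size chunk size.
#' @return numeric vector of probabilities.
#' @export
nn_predict <- function(model, x, batch_size = 256L) {
  if (model$input_mode == "vec") {
    x <- as.matrix(x)
    n <- ncol(x)
    out <- numeric(n)
    for (s in seq(1L, n, by = batch_size)) {
      e <- min(s + batch_size - 1L, n)
      out[s:e] <- drop(nn_forward_pass(model, x[, s:e, drop = FALSE],
                                       train = FALSE)$out)
    }
    return(out)
  }
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  n <- dim(x)[3]
  out <- numeric(n)
  for (s in seq(1L, n, by = batch_size)) {
    e <- min(s + batch_size - 1L, n)
    out[s:e] <- drop(nn_forward_pass(model, x[, , s:e, drop = FALSE],
                                     train = FALSE)$out)
  }
  out
}

#' Gradient of the scalar network output with respect to the input
#'
#' Eval-mode forward then backward with unit output gradient for every sample
#' in the batch; samples are independent, so each slice of the result is that
#' sample's input gradient.
#'
#' @param model a scalar-output [nn_model()].
#' @param x input batch `(4, L, n)`.
#' @return array of input gradients, same shape as `x`.
#' @export
nn_input_gradient <- function(model, x) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  fwd <- nn_forward_pass(model, x, train = FALSE)
  dout <- fwd$out
  dout[] <- 1
  nn_backward_pass(fwd$model, fwd$caches, dout)$dx
}

#' Extract / restore all parameters of a model
#'
#' Used for best-epoch weight restoration and for freeze contracts.
#'
#' @param model an `nn_model`.
#' @return nested list of parameter arrays.
#' @export
nn_get_params <- function(model) {
  get1 <- function(layers) {
    lapply(layers, function(l) {
      out <- list(params = l$params)
      if (!is.null(l$sub)) out$sub <- get1(l$sub)
      out
    })
  }
  get1(model$layers)
}

#' @rdname nn_get_params
#' @param params a nested parameter list from [nn_get_params()].
#' @return the model with parameters replaced.
#' @export
nn_set_params <- function(model, params) {
  set1 <- function(layers, p) {
    for (i in seq_along(layers)) {
      layers[[i]]$params <- p[[i]]$params
      if (!is.null(layers[[i]]$sub)) layers[[i]]$sub <- set1(layers[[i]]$sub, p[[i]]$sub)
    }
    layers
  }
  model$layers <- set1(model$layers, params)
  model
}

#' Mark layers as frozen (excluded from optimiser updates)
#'
#' @param model an `nn_model`.
#' @param idx indices of top-level layers to (un)freeze; sub-layers of
#'   residual blocks inherit the flag.
#' @param frozen logical.
#' @return the modified model.
#' @export
nn_freeze <- function(model, idx, frozen = TRUE) {
  for (i in idx) {
    model$layers[[i]]$frozen <- frozen
    if (!is.null(model$layers[[i]]$sub)) {
      model$layers[[i]]$sub <- lapply(model$layers[[i]]$sub, function(l) {
        l$frozen <- frozen
        l
      })
    }
  }
  model
}
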