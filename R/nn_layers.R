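## Minimal CNN engine: layer forward/backward passes on dense arrays.
##
## Activations are 4-d arrays dim c(N, H, W, C) between image layers and
## N x D matrices after flattening. Convolution is im2col + BLAS matmul;
## reshapes rely on R's column-major layout, so an (N*H*W) x C matrix view
## of an (N,H,W,C) array indexes n fastest, then rows, then columns. All
## backward passes return the gradient w.r.t. the layer input, which also
## yields per-pixel input gradients for attribution.

## ---- im2col for 3x3 'same' convolution -----------------------------------

## x: (N,H,W,C) -> patches (N*H*W) x (9*C); column blocks ordered by the
## 9 kernel offsets, each block holding C channels.
.im2col3 <- function(x) {
  d <- dim(x); N <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  xp <- array(0, c(N, H + 2, W + 2, C))
  xp[, 2:(H + 1), 2:(W + 1), ] <- x
  cols <- vector("list", 9)
  b <- 0L
  for (dj in 0:2) for (di in 0:2) {
    b <- b + 1L
    sl <- xp[, (1 + di):(H + di), (1 + dj):(W + dj), , drop = FALSE]
    dim(sl) <- c(N * H * W, C)
    cols[[b]] <- sl
  }
  do.call(cbind, cols)
}

## Scatter-add inverse of .im2col3: dpatches (N*H*W) x (9*C) -> dx (N,H,W,C).
.col2im3 <- function(dpatches, N, H, W, C) {
  dxp <- array(0, c(N, H + 2, W + 2, C))
  b <- 0L
  for (dj in 0:2) for (di in 0:2) {
    blk <- dpatches[, b * C + seq_len(C), drop = FALSE]
    b <- b + 1L
    dim(blk) <- c(N, H, W, C)
    dxp[, (1 + di):(H + di), (1 + dj):(W + dj), ] <-
      dxp[, (1 + di):(H + di), (1 + dj):(W + dj), , drop = FALSE] + blk
  }
  dxp[, 2:(H + 1), 2:(W + 1), , drop = FALSE]
}

## ---- layers ---------------------------------------------------------------

.layer_conv <- function(c_in, filters, seed_scale = NULL) {
  fan_in <- 9 * c_in
  w <- matrix(rnorm(fan_in * filters, 0, sqrt(2 / fan_in)), fan_in, filters)
  list(type = "conv", W = w, b = numeric(filters), c_in = c_in, filters = filters)
}

.conv_forward <- function(layer, x) {
  d <- dim(x)
  patches <- .im2col3(x)
  out <- patches %*% layer$W
  out <- sweep(out, 2, layer$b, "+")
  dim(out) <- c(d[1], d[2], d[3], layer$filters)
  list(out = out, cache = list(patches = patches, dims = d))
}

.conv_backward <- function(layer, dout, cache) {
  d <- cache$dims
  dm <- dout; dim(dm) <- c(d[1] * d[2] * d[3], layer$filters)
  dW <- crossprod(cache$patches, dm)
  db <- colSums(dm)
  dx <- .col2im3(dm %*% t(layer$W), d[1], d[2], d[3], d[4])
  list(dx = dx, grads = list(W = dW, b = db))
}

.layer_bn <- function(channels, momentum = 0.9, eps = 1e-5) {
  list(type = "bn", gamma = rep(1, channels), beta = numeric(channels),
       run_mean = numeric(channels), run_var = rep(1, channels),
       momentum = momentum, eps = eps, channels = channels)
}

## Batch normalization over (N,H,W) per channel.
.bn_forward <- function(layer, x, training) {
  d <- dim(x); C <- d[4]
  xm <- x; dim(xm) <- c(prod(d[1:3]), C)
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(sweep(xm, 2, mu)^2)
  } else {
    mu <- layer$run_mean
    v <- layer$run_var
  }
  inv_sd <- 1 / sqrt(v + layer$eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, inv_sd, "*")
  out <- sweep(sweep(xhat, 2, layer$gamma, "*"), 2, layer$beta, "+")
  dim(out) <- d
  state <- NULL
  if (training)
    state <- list(run_mean = layer$momentum * layer$run_mean + (1 - layer$momentum) * mu,
                  run_var = layer$momentum * layer$run_var + (1 - layer$momentum) * v)
  list(out = out, cache = list(xhat = xhat, inv_sd = inv_sd, dims = d,
                               training = training),
       state = state)
}

.bn_backward <- function(layer, dout, cache) {
  d <- cache$dims; m <- prod(d[1:3])
  dm <- dout; dim(dm) <- c(m, d[4])
  dgamma <- colSums(dm * cache$xhat)
  dbeta <- colSums(dm)
  dxhat <- sweep(dm, 2, layer$gamma, "*")
  if (cache$training) {
    ## dx = inv_sd/m * (m*dxhat - sum(dxhat) - xhat * sum(dxhat*xhat))
    dx <- m * dxhat
    dx <- sweep(dx, 2, colSums(dxhat))
    dx <- dx - sweep(cache$xhat, 2, colSums(dxhat * cache$xhat), "*")
    dx <- sweep(dx, 2, cache$inv_sd / m, "*")
  } else {
    dx <- sweep(dxhat, 2, cache$inv_sd, "*")  # affine in eval mode
  }
  dim(dx) <- d
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

.relu_forward <- function(x) list(out = pmax(x, 0), cache = x > 0)
.relu_backward <- function(dout, cache) dout * cache

## 2x2 max pooling, stride 2, valid (odd trailing row/col dropped).
.pool_forward <- function(x) {
  d <- dim(x); H2 <- d[2] %/% 2L; W2 <- d[3] %/% 2L
  i1 <- seq_len(H2) * 2L - 1L; j1 <- seq_len(W2) * 2L - 1L
  a <- list(x[, i1, j1, , drop = FALSE], x[, i1 + 1L, j1, , drop = FALSE],
            x[, i1, j1 + 1L, , drop = FALSE], x[, i1 + 1L, j1 + 1L, , drop = FALSE])
  out <- pmax(a[[1]], a[[2]], a[[3]], a[[4]])
  ## first-match tie-break so gradient is routed to exactly one cell
  m1 <- a[[1]] == out
  m2 <- a[[2]] == out & !m1
  m3 <- a[[3]] == out & !m1 & !m2
  m4 <- !m1 & !m2 & !m3
  list(out = out, cache = list(masks = list(m1, m2, m3, m4), dims = d,
                               H2 = H2, W2 = W2))
}

.pool_backward <- function(dout, cache) {
  d <- cache$dims
  dx <- array(0, d)
  i1 <- seq_len(cache$H2) * 2L - 1L; j1 <- seq_len(cache$W2) * 2L - 1L
  ms <- cache$masks
  dx[, i1, j1, ] <- dout * ms[[1]]
  dx[, i1 + 1L, j1, ] <- dout * ms[[2]]
  dx[, i1, j1 + 1L, ] <- dout * ms[[3]]
  dx[, i1 + 1L, j1 + 1L, ] <- dout * ms[[4]]
  dx
}

.layer_dense <- function(d_in, d_out) {
  list(type = "dense",
       W = matrix(rnorm(d_in * d_out, 0, sqrt(2 / d_in)), d_in, d_out),
       b = numeric(d_out))
}

.dense_forward <- function(layer, x) {
  list(out = sweep(x %*% layer$W, 2, layer$b, "+"), cache = x)
}

.dense_backward <- function(layer, dout, cache) {
  list(dx = dout %*% t(layer$W),
       grads = list(W = crossprod(cache, dout), b = colSums(dout)))
}

.softmax <- function(logits) {
  e <- exp(logits - apply(logits, 1, max))
  e / rowSums(e)
}

## Categorical cross-entropy in nats: loss = -sum_i y_i log(p_i), averaged
## over the batch; gradient w.r.t. logits is (p - y)/N.
.softmax_ce <- function(logits, y_onehot) {
  p <- .softmax(logits)
  eps <- 1e-12
  loss <- -mean(rowSums(y_onehot * log(p + eps)))
  list(loss = loss, prob = p, dlogits = (p - y_onehot) / nrow(logits))
}

## ---- whole-network forward/backward --------------------------------------

## model$layers is an ordered list of layer descriptors; "relu", "pool"
## and "flatten" are stateless markers.
.net_forward <- function(model, x, training = FALSE) {
  caches <- vector("list", length(model$layers))
  states <- vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    r <- switch(l$type,
      conv = .conv_forward(l, x),
      bn = .bn_forward(l, x, training),
      relu = .relu_forward(x),
      pool = .pool_forward(x),
      flatten = {
        d <- dim(x)
        xm <- x; dim(xm) <- c(d[1], prod(d[-1]))
        list(out = xm, cache = d)
      },
      dense = .dense_forward(l, x)
    )
    x <- r$out
    caches[[i]] <- r$cache
    if (!is.null(r$state)) states[[i]] <- r$state
  }
  list(logits = x, caches = caches, states = states)
}

## Backward from dlogits; returns parameter grads per layer and dx at the
## input (for attribution).
.net_backward <- function(model, dlogits, caches) {
  grads <- vector("list", length(model$layers))
  dout <- dlogits
  for (i in rev(seq_along(model$layers))) {
    l <- model$layers[[i]]
    r <- switch(l$type,
      conv = .conv_backward(l, dout, caches[[i]]),
      bn = .bn_backward(l, dout, caches[[i]]),
      relu = list(dx = .relu_backward(dout, caches[[i]])),
      pool = list(dx = .pool_backward(dout, caches[[i]])),
      flatten = { d <- caches[[i]]; dm <- dout; dim(dm) <- d; list(dx = dm) },
      dense = .dense_backward(l, dout, caches[[i]])
    )
    dout <- r$dx
    grads[i] <- list(r$grads)  # [[<- would drop NULL slots
  }
  list(dx = dout, grads = grads)
}

## RMSprop with 1/(1 + decay * t) learning-rate decay.
.rmsprop_step <- function(model, grads, opt) {
  lr <- opt$lr / (1 + opt$decay * opt$t)
  eps <- 1e-8
  for (i in seq_along(model$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (nm in names(g)) {
      key <- paste0(i, ".", nm)
      cache <- opt$cache[[key]]
      if (is.null(cache)) cache <- g[[nm]] * 0
      cache <- opt$rho * cache + (1 - opt$rho) * g[[nm]]^2
      opt$cache[[key]] <- cache
      model$layers[[i]][[nm]] <- model$layers[[i]][[nm]] -
        lr * g[[nm]] / (sqrt(cache) + eps)
    }
  }
  opt$t <- opt$t + 1
  list(model = model, opt = opt)
}

.apply_bn_states <- function(model, states) {
  for (i in seq_along(states)) {
    if (!is.null(states[[i]])) {
      model$layers[[i]]$run_mean <- states[[i]]$run_mean
      model$layers[[i]]$run_var <- states[[i]]$run_var
    }
  }
  model
}
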