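# Minimal 1-D convolutional network machinery: im2col-based conv layers,
# ReLU, sigmoid + binary cross-entropy, reverse-mode gradients and Adam.
# All heavy lifting is BLAS matrix multiplication; arrays are (batch, length,
# channels). Deliberately self-contained: the package's quality model is a
# small strided conv encoder-decoder and needs nothing more.

nn_conv_layer <- function(cin, cout, k, stride, act = c("relu", "linear")) {
  act <- match.arg(act)
  list(W = matrix(stats::rnorm(k * cin * cout, 0, sqrt(2 / (k * cin))),
                  nrow = k * cin, ncol = cout),
       b = numeric(cout),
       k = k, stride = stride, pad = (k - 1L) %/% 2L,
       cin = cin, cout = cout, act = act)
}

nn_col_index <- function(lp, k, stride) {
  lout <- (lp - k) %/% stride + 1L
  outer(seq_len(k), (seq_len(lout) - 1L) * stride, `+`)  # (k, lout)
}

nn_conv_forward <- function(layer, x) {
  d <- dim(x); B <- d[1]; L <- d[2]; cin <- d[3]
  p <- layer$pad
  lp <- L + 2L * p
  xp <- array(0, c(B, lp, cin))
  xp[, (p + 1L):(p + L), ] <- x
  idx <- nn_col_index(lp, layer$k, layer$stride)
  lout <- ncol(idx)
  xs <- xp[, as.vector(idx), , drop = FALSE]          # (B, k*lout, cin)
  m <- aperm(array(xs, c(B, layer$k, lout, cin)), c(1, 3, 2, 4))
  dim(m) <- c(B * lout, layer$k * cin)
  z <- m %*% layer$W
  z <- sweep(z, 2, layer$b, `+`)
  a <- if (layer$act == "relu") pmax(z, 0) else z
  y <- array(a, c(B, lout, layer$cout))
  list(y = y, cache = list(m = m, z = z, dims = c(B, L, cin, lp, lout),
                           idx = idx))
}

nn_conv_backward <- function(layer, cache, dy) {
  B <- cache$dims[1]; L <- cache$dims[2]; cin <- cache$dims[3]
  lp <- cache$dims[4]; lout <- cache$dims[5]
  dym <- matrix(dy, nrow = B * lout, ncol = layer$cout)
  if (layer$act == "relu") dym <- dym * (cache$z > 0)
  dW <- crossprod(cache$m, dym)
  db <- colSums(dym)
  dm <- dym %*% t(layer$W)                             # (B*lout, k*cin)
  dmarr <- aperm(array(dm, c(B, lout, layer$k, cin)), c(1, 3, 2, 4))
  dxp <- array(0, c(B, lp, cin))
  for (j in seq_len(layer$k)) {
    cols <- cache$idx[j, ]
    dxp[, cols, ] <- dxp[, cols, ] + dmarr[, j, , ]
  }
  p <- layer$pad
  list(dW = dW, db = db, dx = dxp[, (p + 1L):(p + L), , drop = FALSE])
}

nn_forward <- function(layers, x, keep_cache = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    fw <- nn_conv_forward(layers[[i]], x)
    x <- fw$y
    if (keep_cache) caches[[i]] <- fw$cache
  }
  list(out = x, caches = caches)
}

nn_sigmoid <- function(z) 1 / (1 + exp(-z))

# mean binary cross-entropy on logits; NA labels are masked out
nn_bce <- function(logits, y) {
  mask <- !is.na(y)
  z <- logits[mask]; yy <- y[mask]
  # numerically stable: log(1+exp(-|z|)) + max(z,0) - z*y
  mean(pmax(z, 0) - z * yy + log1p(exp(-abs(z))))
}

nn_bce_grad <- function(logits, y) {
  mask <- !is.na(y)
  g <- nn_sigmoid(logits) - ifelse(mask, y, nn_sigmoid(logits))
  g[!mask] <- 0
  g / max(1L, sum(mask))
}

nn_adam_init <- function(layers) {
  lapply(layers, function(l) list(mW = l$W * 0, vW = l$W * 0,
                                  mb = l$b * 0, vb = l$b * 0))
}

nn_adam_step <- function(layers, grads, state, lr, t,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  for (i in seq_along(layers)) {
    s <- state[[i]]; g <- grads[[i]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$dW
    s$vW <- beta2 * s$vW + (1 - beta2) * g$dW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$db
    s$vb <- beta2 * s$vb + (1 - beta2) * g$db^2
    layers[[i]]$W <- layers[[i]]$W - lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + eps)
    layers[[i]]$b <- layers[[i]]$b - lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    state[[i]] <- s
  }
  list(layers = layers, state = state)
}

# one training step on a batch: forward, BCE, backward, Adam update
nn_train_step <- function(layers, x, y, state, lr, t) {
  fw <- nn_forward(layers, x, keep_cache = TRUE)
  logits <- matrix(fw$out, nrow = dim(x)[1])
  loss <- nn_bce(logits, y)
  dy <- array(nn_bce_grad(logits, y), dim(fw$out))
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    bk <- nn_conv_backward(layers[[i]], fw$caches[[i]], dy)
    grads[[i]] <- bk[c("dW", "db")]
    dy <- bk$dx
  }
  upd <- nn_adam_step(layers, grads, state, lr, t)
  list(layers = upd$layers, state = upd$state, loss = loss)
}

nn_n_params <- function(layers) {
  sum(vapply(layers, function(l) length(l$W) + length(l$b), numeric(1)))
}
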