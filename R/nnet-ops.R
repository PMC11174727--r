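# Differentiable layer primitives for the segmentation network.
#
# Tensors are plain H x W x C double arrays (column-major). Convolutions
# are computed as im2col + GEMM through the compiled kernels; every
# forward returns the cache its backward needs. Gradients flow to
# parameters and inputs only as far as the network needs them.

conv2d_fw <- function(x, W, b, stride = 1L, pad = 1L, dilation = 1L, k = 3L) {
  d <- dim(x)
  cols <- im2col_cpp(x, k, k, stride, pad, dilation)
  om <- W %*% cols + b  # b recycles down columns: rows are output channels
  oh <- (d[1] + 2 * pad - ((k - 1) * dilation + 1)) %/% stride + 1
  ow <- (d[2] + 2 * pad - ((k - 1) * dilation + 1)) %/% stride + 1
  out <- array(t(om), dim = c(oh, ow, nrow(W)))
  list(out = out, cols = cols, xdim = d,
       stride = stride, pad = pad, dilation = dilation, k = k)
}

conv2d_bw <- function(dout, W, cache) {
  d <- dim(dout)
  dm <- t(matrix(dout, d[1] * d[2], d[3]))
  dW <- dm %*% t(cache$cols)
  db <- rowSums(dm)
  dcols <- crossprod(W, dm)
  dx <- col2im_cpp(dcols, cache$xdim[1], cache$xdim[2], cache$xdim[3],
                   cache$k, cache$k, cache$stride, cache$pad, cache$dilation)
  list(dx = dx, dW = dW, db = db)
}

conv1x1_fw <- function(x, W, b) {
  d <- dim(x)
  xm <- matrix(x, d[1] * d[2], d[3])
  om <- xm %*% t(W)
  om <- sweep(om, 2, b, "+")
  list(out = array(om, dim = c(d[1], d[2], nrow(W))), xm = xm, xdim = d)
}

conv1x1_bw <- function(dout, W, cache) {
  d <- dim(dout)
  dm <- matrix(dout, d[1] * d[2], d[3])
  dW <- crossprod(dm, cache$xm)
  db <- colSums(dm)
  dx <- array(dm %*% W, dim = cache$xdim)
  list(dx = dx, dW = dW, db = db)
}

# Depthwise 3x3: one 9-tap filter per channel (rows of W).
dwconv_fw <- function(x, W, b, stride = 1L, pad = 1L) {
  d <- dim(x)
  oh <- (d[1] + 2 * pad - 3) %/% stride + 1
  ow <- (d[2] + 2 * pad - 3) %/% stride + 1
  out <- array(0, dim = c(oh, ow, d[3]))
  cols <- vector("list", d[3])
  for (c in seq_len(d[3])) {
    xc <- array(x[, , c], dim = c(d[1], d[2], 1))
    cols[[c]] <- im2col_cpp(xc, 3L, 3L, stride, pad, 1L)
    out[, , c] <- matrix(W[c, , drop = FALSE] %*% cols[[c]] + b[c], oh, ow)
  }
  list(out = out, cols = cols, xdim = d, stride = stride, pad = pad)
}

dwconv_bw <- function(dout, W, cache) {
  d <- cache$xdim
  od <- dim(dout)
  dW <- matrix(0, nrow(W), 9)
  db <- numeric(nrow(W))
  dx <- array(0, dim = d)
  for (c in seq_len(d[3])) {
    dm <- matrix(dout[, , c], 1, od[1] * od[2])
    dW[c, ] <- dm %*% t(cache$cols[[c]])
    db[c] <- sum(dm)
    dcols <- crossprod(W[c, , drop = FALSE], dm)
    dx[, , c] <- col2im_cpp(dcols, d[1], d[2], 1L, 3L, 3L,
                            cache$stride, cache$pad, 1L)[, , 1]
  }
  list(dx = dx, dW = dW, db = db)
}

relu_fw <- function(x) list(out = pmax(x, 0), mask = x > 0)
relu_bw <- function(dout, cache) dout * cache$mask

upsample2_fw <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , drop = FALSE]
}

upsample2_bw <- function(dout) {
  d <- dim(dout)
  o <- seq(1, d[1], by = 2); e <- seq(2, d[1], by = 2)
  oc <- seq(1, d[2], by = 2); ec <- seq(2, d[2], by = 2)
  dout[o, oc, , drop = FALSE] + dout[e, oc, , drop = FALSE] +
    dout[o, ec, , drop = FALSE] + dout[e, ec, , drop = FALSE]
}

# Image-level pooling branch: global average -> 1x1 projection -> ReLU ->
# broadcast back over the feature map.
gap_fw <- function(x, W, b) {
  d <- dim(x)
  v <- colMeans(matrix(x, d[1] * d[2], d[3]))
  pre <- as.numeric(W %*% v + b)
  act <- pmax(pre, 0)
  out <- array(rep(act, each = d[1] * d[2]), dim = c(d[1], d[2], length(act)))
  list(out = out, v = v, mask = pre > 0, xdim = d)
}

gap_bw <- function(dout, W, cache) {
  d <- cache$xdim
  dact <- colSums(matrix(dout, d[1] * d[2], dim(dout)[3]))
  dpre <- dact * cache$mask
  dW <- outer(dpre, cache$v)
  db <- dpre
  dv <- as.numeric(crossprod(W, dpre))
  dx <- array(rep(dv / (d[1] * d[2]), each = d[1] * d[2]), dim = d)
  list(dx = dx, dW = dW, db = db)
}

concat3 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  array(unlist(parts, use.names = FALSE),
        dim = c(d[1], d[2], sum(vapply(parts, function(p) dim(p)[3], numeric(1)))))
}

softmax3 <- function(x) {
  d <- dim(x)
  m <- matrix(x, d[1] * d[2], d[3])
  m <- m - apply(m, 1, max)
  e <- exp(m)
  array(e / rowSums(e), dim = d)
}

he_init <- function(nrow, ncol, fan_in) {
  matrix(rnorm(nrow * ncol, 0, sqrt(2 / fan_in)), nrow, ncol)
}

adam_step <- function(params, grads, state, lr, beta1, beta2, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

adam_init <- function(params) {
  zeros <- lapply(params, function(p) p * 0)  # keeps matrix/vector shapes
  list(m = zeros, v = zeros, t = 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
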