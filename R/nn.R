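# Small neural-network primitives shared by the classifier and the domain
# mapper. Tensors are R arrays in (H, W, C, N) layout; 3x3 convolutions with
# zero padding 1 are delegated to compiled im2col/BLAS kernels.

conv2d <- function(x, w, b) .conv2d_fwd(x, w, b)

conv2d_grad <- function(x, w, dy, need_dx = TRUE)
  .conv2d_bwd(x, w, dy, need_dx)

# leaky rectifier (slope 0.1 on the negative side): keeps narrow streams
# trainable by never fully silencing a unit
relu <- function(x) {
  neg <- x < 0
  x[neg] <- 0.1 * x[neg]
  x
}

relu_grad <- function(pre, dy) {
  neg <- pre <= 0
  dy[neg] <- 0.1 * dy[neg]
  dy
}

# 2x2 average pooling, stride 2; H and W must be even.
avgpool2 <- function(x) {
  d <- dim(x)
  H <- d[1]; W <- d[2]
  stopifnot(H %% 2 == 0, W %% 2 == 0)
  io <- seq(1, H, 2); jo <- seq(1, W, 2)
  (x[io, jo, , , drop = FALSE] + x[io + 1, jo, , , drop = FALSE] +
     x[io, jo + 1, , , drop = FALSE] + x[io + 1, jo + 1, , , drop = FALSE]) / 4
}

avgpool2_grad <- function(dy, in_dim) {
  dx <- array(0, in_dim)
  H <- in_dim[1]; W <- in_dim[2]
  io <- seq(1, H, 2); jo <- seq(1, W, 2)
  g <- dy / 4
  dx[io, jo, , ] <- g
  dx[io + 1, jo, , ] <- g
  dx[io, jo + 1, , ] <- g
  dx[io + 1, jo + 1, , ] <- g
  dx
}

# global average pooling: (H,W,C,N) -> (C,N)
gap <- function(x) {
  d <- dim(x)
  m <- matrix(x, d[1] * d[2], d[3] * d[4])
  matrix(colMeans(m), d[3], d[4])
}

# global max pooling: (H,W,C,N) -> (C,N) with argmax kept for backward
gmp <- function(x) {
  d <- dim(x)
  m <- matrix(x, d[1] * d[2], d[3] * d[4])
  idx <- max.col(t(m), ties.method = "first")
  f <- matrix(m[cbind(idx, seq_along(idx))], d[3], d[4])
  list(f = f, idx = idx)
}

gmp_grad <- function(df, idx, in_dim) {
  HW <- in_dim[1] * in_dim[2]
  dx <- numeric(prod(in_dim))
  cols <- seq_along(idx)
  dx[(cols - 1) * HW + idx] <- as.vector(df)
  array(dx, in_dim)
}

gap_grad <- function(df, in_dim) {
  # df: (C,N) -> broadcast back over H*W
  HW <- in_dim[1] * in_dim[2]
  array(rep(as.vector(df), each = HW) / HW, in_dim)
}

# dense layer on column-feature matrices: h (in x N), w (in x out), b (out)
dense <- function(h, w, b) crossprod(w, h) + b

dense_grad <- function(h, w, dy) {
  list(dh = w %*% dy, dw = h %*% t(dy), db = rowSums(dy))
}

# numerically stabilized softmax over rows of a (classes x N) matrix
softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}
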