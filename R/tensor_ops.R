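# Internal tensor primitives.
#
# Feature maps live in 4-D arrays with dim c(H, W, N, C): two spatial axes,
# then the batch axis, then channels. Column-major order means
# `matrix(x, H*W*N, C)` exposes channels as columns with zero copy cost,
# so every channel-mixing operation is a single BLAS matrix product.

ts_shape <- function(x) dim(x)

# flatten to (H*W*N) x C
ts_mat <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1L] * d[2L] * d[3L], d[4L])
  x
}

ts_unmat <- function(m, h, w, n) {
  dim(m) <- c(h, w, n, ncol(m))
  m
}

# y[i, j, , ] = x[i + di, j + dj, , ], zero outside the frame
ts_shift <- function(x, di, dj) {
  d <- dim(x)
  h <- d[1L]; w <- d[2L]
  out <- array(0, d)
  rlo <- max(1L, 1L - di); rhi <- min(h, h - di)
  clo <- max(1L, 1L - dj); chi <- min(w, w - dj)
  if (rlo <= rhi && clo <= chi) {
    ri <- rlo:rhi; rj <- clo:chi
    out[ri, rj, , ] <- x[ri + di, rj + dj, , , drop = FALSE]
  }
  out
}

## ---- same-padding convolution (odd kernel, stride 1) ----
# W: array (k, k, Cin, Cout); cross-correlation convention:
# y[i,j] = sum_{u,v} x[i+u, j+v] W[u,v]
# The hot path is compiled (im2col + GEMM, src/conv.cpp); the plain-R
# shift-and-multiply versions below are kept as reference implementations.

conv2d_fwd <- function(x, W, b = NULL) {
  .conv2d_same_fwd_cpp(x, W, b)
}

conv2d_bwd <- function(x, W, dy) {
  .conv2d_same_bwd_cpp(x, W, dy)
}

conv2d_fwd_ref <- function(x, W, b = NULL) {
  d <- dim(x); k <- dim(W)[1L]; r <- (k - 1L) %/% 2L
  cout <- dim(W)[4L]
  acc <- matrix(0, d[1L] * d[2L] * d[3L], cout)
  for (u in -r:r) for (v in -r:r) {
    xs <- if (u == 0L && v == 0L) x else ts_shift(x, u, v)
    acc <- acc + ts_mat(xs) %*% matrix(W[u + r + 1L, v + r + 1L, , ], dim(W)[3L], cout)
  }
  if (!is.null(b)) acc <- acc + rep(b, each = nrow(acc))
  ts_unmat(acc, d[1L], d[2L], d[3L])
}

conv2d_bwd_ref <- function(x, W, dy) {
  d <- dim(x); k <- dim(W)[1L]; r <- (k - 1L) %/% 2L
  cin <- dim(W)[3L]; cout <- dim(W)[4L]
  dym <- ts_mat(dy)
  dW <- array(0, dim(W))
  dx <- array(0, d)
  for (u in -r:r) for (v in -r:r) {
    xs <- if (u == 0L && v == 0L) x else ts_shift(x, u, v)
    dW[u + r + 1L, v + r + 1L, , ] <- crossprod(ts_mat(xs), dym)
    dxi <- ts_unmat(dym %*% t(matrix(W[u + r + 1L, v + r + 1L, , ], cin, cout)),
                    d[1L], d[2L], d[3L])
    dx <- dx + (if (u == 0L && v == 0L) dxi else ts_shift(dxi, -u, -v))
  }
  list(dx = dx, dW = dW, db = colSums(dym))
}

## ---- depthwise 3x3 convolution (one k x k filter per channel) ----
# W: array (k, k, C); compiled fast path for k = 3, R reference kept

dwconv2d_fwd <- function(x, W, b = NULL) {
  if (dim(W)[1L] == 3L) return(.dwconv3_fwd_cpp(x, W, b))
  dwconv2d_fwd_ref(x, W, b)
}

dwconv2d_bwd <- function(x, W, dy) {
  if (dim(W)[1L] == 3L) return(.dwconv3_bwd_cpp(x, W, dy))
  dwconv2d_bwd_ref(x, W, dy)
}

dwconv2d_fwd_ref <- function(x, W, b = NULL) {
  d <- dim(x); k <- dim(W)[1L]; r <- (k - 1L) %/% 2L
  acc <- array(0, d)
  for (u in -r:r) for (v in -r:r) {
    xs <- if (u == 0L && v == 0L) x else ts_shift(x, u, v)
    wuv <- W[u + r + 1L, v + r + 1L, ]
    acc <- acc + ts_unmat(ts_mat(xs) * rep(wuv, each = d[1L] * d[2L] * d[3L]),
                          d[1L], d[2L], d[3L])
  }
  if (!is.null(b)) acc <- acc + rep(b, each = d[1L] * d[2L] * d[3L])
  acc
}

dwconv2d_bwd_ref <- function(x, W, dy) {
  d <- dim(x); k <- dim(W)[1L]; r <- (k - 1L) %/% 2L
  rows <- d[1L] * d[2L] * d[3L]
  dym <- ts_mat(dy)
  dW <- array(0, dim(W))
  dx <- array(0, d)
  for (u in -r:r) for (v in -r:r) {
    xs <- if (u == 0L && v == 0L) x else ts_shift(x, u, v)
    dW[u + r + 1L, v + r + 1L, ] <- colSums(ts_mat(xs) * dym)
    wuv <- W[u + r + 1L, v + r + 1L, ]
    dxi <- ts_unmat(dym * rep(wuv, each = rows), d[1L], d[2L], d[3L])
    dx <- dx + (if (u == 0L && v == 0L) dxi else ts_shift(dxi, -u, -v))
  }
  list(dx = dx, dW = dW, db = colSums(dym))
}

## ---- patch embedding: k = stride = P ----
# W: array (P, P, Cin, C)

patchify_fwd <- function(x, W, b) {
  d <- dim(x); P <- dim(W)[1L]
  hp <- d[1L] %/% P; wp <- d[2L] %/% P
  cout <- dim(W)[4L]
  acc <- matrix(0, hp * wp * d[3L], cout)
  for (u in 0:(P - 1L)) for (v in 0:(P - 1L)) {
    xs <- x[seq.int(1L + u, d[1L], P), seq.int(1L + v, d[2L], P), , , drop = FALSE]
    acc <- acc + ts_mat(xs) %*% matrix(W[u + 1L, v + 1L, , ], dim(W)[3L], cout)
  }
  acc <- acc + rep(b, each = nrow(acc))
  ts_unmat(acc, hp, wp, d[3L])
}

patchify_bwd <- function(x, W, dy) {
  d <- dim(x); P <- dim(W)[1L]
  cin <- dim(W)[3L]; cout <- dim(W)[4L]
  dym <- ts_mat(dy)
  dW <- array(0, dim(W))
  dx <- array(0, d)
  for (u in 0:(P - 1L)) for (v in 0:(P - 1L)) {
    ridx <- seq.int(1L + u, d[1L], P); cidx <- seq.int(1L + v, d[2L], P)
    xs <- x[ridx, cidx, , , drop = FALSE]
    dW[u + 1L, v + 1L, , ] <- crossprod(ts_mat(xs), dym)
    dx[ridx, cidx, , ] <- ts_unmat(dym %*% t(matrix(W[u + 1L, v + 1L, , ], cin, cout)),
                                   length(ridx), length(cidx), d[3L])
  }
  list(dx = dx, dW = dW, db = colSums(dym))
}

## ---- 2x2 stride-2 transposed convolution ----
# W: array (2, 2, Cin, Cout); each input pixel paints a 2x2 output block.

tconv2_fwd <- function(x, W, b) {
  d <- dim(x); cout <- dim(W)[4L]
  xm <- ts_mat(x)
  out <- array(0, c(2L * d[1L], 2L * d[2L], d[3L], cout))
  for (u in 0:1) for (v in 0:1) {
    ym <- xm %*% matrix(W[u + 1L, v + 1L, , ], d[4L], cout)
    out[seq.int(1L + u, 2L * d[1L], 2L), seq.int(1L + v, 2L * d[2L], 2L), , ] <-
      ts_unmat(ym, d[1L], d[2L], d[3L])
  }
  out + rep(b, each = 4L * d[1L] * d[2L] * d[3L])
}

tconv2_bwd <- function(x, W, dy) {
  d <- dim(x); cin <- d[4L]; cout <- dim(W)[4L]
  xm <- ts_mat(x)
  dW <- array(0, dim(W))
  dxm <- matrix(0, nrow(xm), cin)
  db <- numeric(cout)
  for (u in 0:1) for (v in 0:1) {
    dys <- dy[seq.int(1L + u, 2L * d[1L], 2L), seq.int(1L + v, 2L * d[2L], 2L), , ,
              drop = FALSE]
    dysm <- ts_mat(dys)
    dW[u + 1L, v + 1L, , ] <- crossprod(xm, dysm)
    dxm <- dxm + dysm %*% t(matrix(W[u + 1L, v + 1L, , ], cin, cout))
    db <- db + colSums(dysm)
  }
  list(dx = ts_unmat(dxm, d[1L], d[2L], d[3L]), dW = dW, db = db)
}

## ---- 2x2 stride-2 max pooling (compiled; R reference kept) ----

maxpool2_fwd <- function(x) {
  .maxpool2_fwd_cpp(x)
}

maxpool2_bwd <- function(dy, sel, in_dim) {
  .maxpool2_bwd_cpp(dy, sel, as.integer(in_dim))
}

maxpool2_fwd_ref <- function(x) {
  d <- dim(x)
  ro <- seq.int(1L, d[1L], 2L); re <- ro + 1L
  co <- seq.int(1L, d[2L], 2L); ce <- co + 1L
  x11 <- x[ro, co, , , drop = FALSE]; x12 <- x[ro, ce, , , drop = FALSE]
  x21 <- x[re, co, , , drop = FALSE]; x22 <- x[re, ce, , , drop = FALSE]
  m <- pmax(x11, x12, x21, x22)
  w1 <- x11 == m
  w2 <- (x12 == m) & !w1
  w3 <- (x21 == m) & !(w1 | w2)
  w4 <- !(w1 | w2 | w3)
  list(y = m, sel = list(w1, w2, w3, w4))
}

maxpool2_bwd_ref <- function(dy, sel, in_dim) {
  dx <- array(0, in_dim)
  ro <- seq.int(1L, in_dim[1L], 2L); re <- ro + 1L
  co <- seq.int(1L, in_dim[2L], 2L); ce <- co + 1L
  dx[ro, co, , ] <- dy * sel[[1L]]
  dx[ro, ce, , ] <- dy * sel[[2L]]
  dx[re, co, , ] <- dy * sel[[3L]]
  dx[re, ce, , ] <- dy * sel[[4L]]
  dx
}

## ---- average pooling by integer factor f (used for attention token grids) ----

avgpoolf_fwd <- function(x, f) {
  if (f == 1L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1L] %/% f, d[2L] %/% f, d[3L], d[4L]))
  for (u in 0:(f - 1L)) for (v in 0:(f - 1L)) {
    out <- out + x[seq.int(1L + u, d[1L], f), seq.int(1L + v, d[2L], f), , ,
                   drop = FALSE]
  }
  out / (f * f)
}

avgpoolf_bwd <- function(dy, f) {
  if (f == 1L) return(dy)
  d <- dim(dy)
  up <- dy[rep(seq_len(d[1L]), each = f), rep(seq_len(d[2L]), each = f), , ,
           drop = FALSE]
  up / (f * f)
}

# nearest-neighbour broadcast of a pooled grid back to the full grid
nn_upsample_fwd <- function(x, f) {
  if (f == 1L) return(x)
  d <- dim(x)
  x[rep(seq_len(d[1L]), each = f), rep(seq_len(d[2L]), each = f), , , drop = FALSE]
}

nn_upsample_bwd <- function(dy, f) {
  if (f == 1L) return(dy)
  d <- dim(dy)
  out <- array(0, c(d[1L] %/% f, d[2L] %/% f, d[3L], d[4L]))
  for (u in 0:(f - 1L)) for (v in 0:(f - 1L)) {
    out <- out + dy[seq.int(1L + u, d[1L], f), seq.int(1L + v, d[2L], f), , ,
                    drop = FALSE]
  }
  out
}

## ---- count-normalised 3x3 box average and the local-contrast operator ----
# The window average divides by the number of in-frame neighbours so a
# spatially constant map is exactly its own average (no border halo).

box3_counts <- function(h, w) {
  rc <- rep(3, h); rc[1L] <- 2; rc[h] <- 2
  cc <- rep(3, w); cc[1L] <- 2; cc[w] <- 2
  if (h == 1L) rc[] <- 1
  if (w == 1L) cc[] <- 1
  outer(rc, cc)
}

avgbox3_fwd <- function(x) {
  d <- dim(x)
  .box3_sum_cpp(x) / as.vector(box3_counts(d[1L], d[2L]))
}

avgbox3_fwd_ref <- function(x) {
  d <- dim(x)
  s <- array(0, d)
  for (u in -1:1) for (v in -1:1) {
    s <- s + (if (u == 0L && v == 0L) x else ts_shift(x, u, v))
  }
  s / as.vector(box3_counts(d[1L], d[2L]))
}

# adjoint of avgbox3 (the operator is symmetric in neighbourhood pattern but
# has per-output normalisation, so normalise first, then scatter back)
avgbox3_bwd <- function(dy) {
  d <- dim(dy)
  .box3_sum_cpp(dy / as.vector(box3_counts(d[1L], d[2L])))
}

# centre-surround contrast: x minus its local box average
contrast_delta_fwd <- function(x) x - avgbox3_fwd(x)
contrast_delta_bwd <- function(dy) dy - avgbox3_bwd(dy)

## ---- bilinear upsampling via a cached sparse operator ----

.bilinear_cache <- new.env(parent = emptyenv())

bilinear_matrix <- function(in_h, in_w, out_h, out_w) {
  key <- paste(in_h, in_w, out_h, out_w, sep = "x")
  if (!is.null(.bilinear_cache[[key]])) return(.bilinear_cache[[key]])
  axis_weights <- function(n_in, n_out) {
    # half-pixel-centre convention, clamped at the frame
    src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
    src <- pmin(pmax(src, 0), n_in - 1)
    i0 <- pmin(floor(src), n_in - 1)
    i1 <- pmin(i0 + 1, n_in - 1)
    t <- src - i0
    list(i0 = i0 + 1, i1 = i1 + 1, w0 = 1 - t, w1 = t)
  }
  ay <- axis_weights(in_h, out_h)
  ax <- axis_weights(in_w, out_w)
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  out_idx <- seq_len(out_h)
  for (j in seq_len(out_w)) {
    for (cx in 1:2) {
      jc <- if (cx == 1L) ax$i0[j] else ax$i1[j]
      wx <- if (cx == 1L) ax$w0[j] else ax$w1[j]
      for (cy in 1:2) {
        ic <- if (cy == 1L) ay$i0 else ay$i1
        wy <- if (cy == 1L) ay$w0 else ay$w1
        rows <- c(rows, out_idx + (j - 1L) * out_h)
        cols <- c(cols, ic + (jc - 1L) * in_h)
        vals <- c(vals, wx * wy)
      }
    }
  }
  U <- Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                            dims = c(out_h * out_w, in_h * in_w))
  .bilinear_cache[[key]] <- U
  U
}

bilinear_upsample_fwd <- function(x, out_h, out_w) {
  .bilinear_fwd_cpp(x, as.integer(out_h), as.integer(out_w))
}

bilinear_upsample_bwd <- function(dy, in_h, in_w) {
  .bilinear_bwd_cpp(dy, as.integer(in_h), as.integer(in_w))
}

# sparse-operator reference implementation of the same resampling
bilinear_upsample_fwd_ref <- function(x, out_h, out_w) {
  d <- dim(x)
  U <- bilinear_matrix(d[1L], d[2L], out_h, out_w)
  xm <- x; dim(xm) <- c(d[1L] * d[2L], d[3L] * d[4L])
  ym <- as.matrix(U %*% xm)
  array(ym, c(out_h, out_w, d[3L], d[4L]))
}

bilinear_upsample_bwd_ref <- function(dy, in_h, in_w) {
  d <- dim(dy)
  U <- bilinear_matrix(in_h, in_w, d[1L], d[2L])
  dym <- dy; dim(dym) <- c(d[1L] * d[2L], d[3L] * d[4L])
  xm <- as.matrix(Matrix::crossprod(U, dym))
  array(xm, c(in_h, in_w, d[3L], d[4L]))
}

## ---- activations ----

relu_fwd <- function(x) x * (x > 0)
relu_bwd <- function(dy, x) dy * (x > 0)

leaky_relu_fwd <- function(x, slope) ifelse(x > 0, x, slope * x)
leaky_relu_bwd <- function(dy, x, slope) dy * ifelse(x > 0, 1, slope)

sigmoid_fwd <- function(x) 1 / (1 + exp(-x))
sigmoid_bwd <- function(dy, y) dy * y * (1 - y)
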