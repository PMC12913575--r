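# shared fixtures and independent brute-force oracles

ns <- asNamespace("dualseg")

tiny_vhunet <- function(seed = 3) {
  cfg <- vhunet_config(input_size = c(16L, 16L), in_channels = 1L,
                       stage_widths = c(2L, 4L, 6L, 8L), bridge_width = 8L,
                       attn_heads = 2L, hrnet_kernels = c(1L, 3L))
  vhunet_init(cfg, seed = seed)
}

tiny_pdn <- function(seed = 4) {
  cfg <- pdn_config(input_size = c(16L, 16L), in_channels = 1L,
                    stage_widths = c(2L, 4L, 6L, 8L), contrast_width = 8L,
                    border_width = 4L, pool_stages = 2L)
  pdn_init(cfg, seed = seed)
}

rand_tensor <- function(h, w, n, c, seed = 1) {
  set.seed(seed)
  array(rnorm(h * w * n * c), c(h, w, n, c))
}

rand_mask <- function(h, w, p = 0.4, seed = 1, nonempty = FALSE) {
  set.seed(seed)
  repeat {
    m <- matrix(as.integer(runif(h * w) < p), h, w)
    if (!nonempty || sum(m) > 0) return(m)
    seed <- seed + 1000
    set.seed(seed)
  }
}

# numerical gradient of a scalar-valued function
fd_grad <- function(f, x, eps = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

max_rel_err <- function(a, b) {
  max(abs(a - b)) / max(1e-8, max(abs(a)), max(abs(b)))
}

# O(n^2) all-pairs directed boundary distances (independent of the
# distance-transform implementation)
bf_boundary <- function(m) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0L, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (m[i, j] == 0) next
    nb <- c(if (i > 1) m[i - 1, j] else 0, if (i < h) m[i + 1, j] else 0,
            if (j > 1) m[i, j - 1] else 0, if (j < w) m[i, j + 1] else 0)
    if (any(nb == 0)) out[i, j] <- 1L
  }
  out
}

bf_directed_dists <- function(from_m, to_m) {
  fb <- which(bf_boundary(from_m) == 1, arr.ind = TRUE)
  tb <- which(bf_boundary(to_m) == 1, arr.ind = TRUE)
  vapply(seq_len(nrow(fb)), function(k) {
    sqrt(min((fb[k, 1] - tb[, 1])^2 + (fb[k, 2] - tb[, 2])^2))
  }, numeric(1))
}

bf_hd95 <- function(pred, gt) {
  as.numeric(quantile(c(bf_directed_dists(pred, gt),
                        bf_directed_dists(gt, pred)), 0.95, names = FALSE))
}

bf_assd <- function(pred, gt) {
  (mean(bf_directed_dists(pred, gt)) + mean(bf_directed_dists(gt, pred))) / 2
}

# loop-based pooling / contrast oracles on a single-channel matrix
bf_maxpool2 <- function(m) {
  h <- nrow(m) %/% 2; w <- ncol(m) %/% 2
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    out[i, j] <- max(m[2 * i - 1:0, 2 * j - 1:0])
  }
  out
}

bf_avgbox3 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    ri <- max(1, i - 1):min(h, i + 1)
    rj <- max(1, j - 1):min(w, j + 1)
    out[i, j] <- mean(m[ri, rj])
  }
  out
}

# histogram equalization oracle: direct cdf mapping through the empirical
# distribution (256 bins)
bf_hist_equalize <- function(x) {
  q <- pmin(pmax(as.integer(round(x)), 0L), 255L)
  counts <- tabulate(q + 1L, nbins = 256L)
  cdf <- cumsum(counts)
  cdf_min <- min(cdf[cdf > 0])
  out <- round((cdf[q + 1L] - cdf_min) / (length(q) - cdf_min) * 255)
  matrix(out, nrow(x), ncol(x))
}

bf_resize_nn <- function(m, oh, ow) {
  out <- matrix(0, oh, ow)
  for (i in seq_len(oh)) for (j in seq_len(ow)) {
    si <- min(max(ceiling((i - 0.5) * nrow(m) / oh), 1), nrow(m))
    sj <- min(max(ceiling((j - 0.5) * ncol(m) / ow), 1), ncol(m))
    out[i, j] <- m[si, sj]
  }
  out
}

small_phantoms <- function(n, seed = 777, ...) {
  generate_samples(n, phantom_spec(seed = seed, ...))
}
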