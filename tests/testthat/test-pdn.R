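test_that("the 256 configuration reproduces the published contrast ladder", {
  m <- pdn_init(pdn_preset("gray-256"), seed = 1)
  x <- array(runif(256 * 256), c(256, 256, 1, 1))
  st <- pdn_stem(x, m)
  expect_identical(dim(st), c(256L, 256L, 1L, 64L))
  expect_true(all(st >= 0))
  ct <- multiscale_contrast(st, m)
  expect_identical(dim(ct), c(16L, 16L, 1L, 1024L))
  bd <- boundary_refine(ct, m)
  expect_identical(dim(bd), c(16L, 16L, 1L, 512L))
  fused <- dualseg:::c_bind_channels(ct, bd)
  expect_identical(dim(fused), c(16L, 16L, 1L, 1536L))
  hd <- pdn_head(bd, ct, m)
  expect_identical(dim(hd$prob_coarse), c(16L, 16L, 1L, 1L))
  expect_identical(dim(hd$prob), c(256L, 256L, 1L, 1L))
  expect_true(all(hd$mask %in% c(0, 1)))
})

test_that("the stem is zero on a zero image and never negative", {
  m <- tiny_pdn()
  expect_true(all(pdn_stem(array(0, c(16, 16, 1, 1)), m) == 0))
  x <- rand_tensor(16, 16, 2, 1, seed = 2)
  expect_true(all(pdn_stem(x, m) >= 0))
})

test_that("the contrast operator annihilates spatially constant maps at every stage", {
  for (d in list(c(5, 7, 2, 2), c(16, 16, 1, 4), c(1, 9, 1, 1))) {
    cst <- array(3.25, d)
    expect_true(all(abs(dualseg:::contrast_delta_fwd(cst)) < 1e-12))
  }
  # through the staged ladder: a constant input leaves every stage's
  # post-pooling contrast map exactly zero
  m <- tiny_pdn()
  x <- array(0.7, c(16, 16, 2, 2))
  co <- dualseg:::contrast_fwd(m, x, keep_cache = TRUE)
  for (st in co$cache) expect_true(all(abs(st$dlt) < 1e-10))
})

test_that("pooling and contrast match brute-force oracles on small maps", {
  set.seed(5)
  for (rep in 1:10) {
    msmall <- matrix(rnorm(64), 8, 8)
    x <- array(msmall, c(8, 8, 1, 1))
    expect_lt(max_rel_err(dualseg:::maxpool2_fwd(x)$y[, , 1, 1],
                          bf_maxpool2(msmall)), 1e-12)
    expect_lt(max_rel_err(dualseg:::avgbox3_fwd(x)[, , 1, 1],
                          bf_avgbox3(msmall)), 1e-12)
    expect_lt(max_rel_err(dualseg:::contrast_delta_fwd(x)[, , 1, 1],
                          msmall - bf_avgbox3(msmall)), 1e-12)
  }
  # a single bright pixel responds only inside its pooled neighbourhood
  img <- matrix(0, 8, 8); img[3, 5] <- 1
  x <- array(img, c(8, 8, 1, 1))
  pooled <- dualseg:::maxpool2_fwd(x)$y
  dlt <- dualseg:::contrast_delta_fwd(pooled)[, , 1, 1]
  oracle <- bf_maxpool2(img) - bf_avgbox3(bf_maxpool2(img))
  expect_lt(max_rel_err(dlt, oracle), 1e-12)
  nz <- which(dlt != 0, arr.ind = TRUE)
  expect_true(all(abs(nz[, 1] - 2) <= 1 & abs(nz[, 2] - 3) <= 1))
})

test_that("separable convolution equals its explicit two-step composition", {
  set.seed(6)
  x <- rand_tensor(4, 4, 1, 2, seed = 6)
  dwW <- array(rnorm(9 * 2), c(3, 3, 2)); dwb <- rnorm(2)
  pwW <- matrix(rnorm(2 * 3), 2, 3); pwb <- rnorm(3)
  # oracle: loop-based depthwise, then per-pixel matrix product
  depth <- array(0, c(4, 4, 1, 2))
  for (c in 1:2) {
    for (i in 1:4) for (j in 1:4) {
      acc <- dwb[c]
      for (u in -1:1) for (v in -1:1) {
        si <- i + u; sj <- j + v
        if (si >= 1 && si <= 4 && sj >= 1 && sj <= 4) {
          acc <- acc + x[si, sj, 1, c] * dwW[u + 2, v + 2, c]
        }
      }
      depth[i, j, 1, c] <- acc
    }
  }
  oracle <- array(0, c(4, 4, 1, 3))
  for (i in 1:4) for (j in 1:4) {
    oracle[i, j, 1, ] <- as.numeric(depth[i, j, 1, ] %*% pwW) + pwb
  }
  dw <- dualseg:::dwconv2d_fwd(x, dwW, dwb)
  pw <- dualseg:::ts_mat(dw) %*% pwW + rep(pwb, each = 16)
  expect_lt(max_rel_err(array(pw, c(4, 4, 1, 3)), oracle), 1e-10)
})

test_that("boundary refinement applies the configured LeakyReLU slope", {
  expect_equal(dualseg:::leaky_relu_fwd(-1, 0.01), -0.01)
  expect_equal(dualseg:::leaky_relu_fwd(2, 0.01), 2)
  m <- tiny_pdn()
  ct <- multiscale_contrast(pdn_stem(rand_tensor(16, 16, 2, 1, seed = 7), m), m)
  bd <- boundary_refine(ct, m)
  expect_identical(dim(bd)[4], m$cfg$border_width)
  expect_identical(dim(bd)[1:2], dim(ct)[1:2])
})

test_that("the head is 0.5-constant under zero weights and empty at tau = 0.5", {
  m <- tiny_pdn()
  m$params$head$W[] <- 0; m$params$head$b <- 0
  fwd <- pdn_forward(m, rand_tensor(16, 16, 2, 1, seed = 8))
  expect_true(all(fwd$prob == 0.5))
  expect_true(all(fwd$mask == 0))  # strict > tie rule
})

test_that("raising the threshold never adds foreground", {
  m <- tiny_pdn()
  x <- rand_tensor(16, 16, 2, 1, seed = 9)
  fwd <- pdn_forward(m, x)
  taus <- c(0.3, 0.45, 0.5, 0.6, 0.8)
  masks <- lapply(taus, function(t) fwd$prob > t)
  for (k in seq_along(taus)[-1]) {
    expect_true(all(masks[[k]] <= masks[[k - 1]]))
  }
})

test_that("head inputs must share spatial dimensions", {
  m <- tiny_pdn()
  a <- rand_tensor(4, 4, 1, m$cfg$border_width, seed = 10)
  b <- rand_tensor(8, 8, 1, m$cfg$contrast_width, seed = 11)
  expect_error(pdn_head(a, b, m), "share spatial dims")
})
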