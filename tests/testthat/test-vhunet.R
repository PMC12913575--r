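test_that("the 224 preset reproduces every published feature-map shape", {
  m <- vhunet_init(vhunet_preset("rgb-224"), seed = 1)
  x <- array(runif(224 * 224 * 3), c(224, 224, 1, 3))
  emb <- patch_embed(x, m)
  expect_identical(dim(emb), c(112L, 112L, 1L, 64L))
  skips <- vhu_encode(x, m)
  shapes <- lapply(skips, function(s) dim(s)[c(1, 2, 4)])
  expect_identical(shapes,
                   list(c(112L, 112L, 64L), c(56L, 56L, 128L),
                        c(28L, 28L, 256L), c(14L, 14L, 512L)))
  br <- vhu_bridge(skips[[4]], m)
  expect_identical(dim(br), c(14L, 14L, 1L, 1024L))
  expect_true(all(br >= 0))  # ReLU range
  dec <- vhu_decode(br, skips, m)
  expect_identical(dim(dec), c(224L, 224L, 1L, 64L))
  prob <- organ_head(dec, m)
  expect_true(all(prob > 0 & prob < 1))
})

test_that("scaled configurations follow the same shape contract", {
  m <- vhunet_init(vhunet_preset("desk-64"), seed = 1)
  x <- array(runif(64 * 64), c(64, 64, 1, 1))
  skips <- vhu_encode(x, m)
  expect_identical(lapply(skips, function(s) dim(s)[c(1, 2, 4)]),
                   list(c(32L, 32L, 16L), c(16L, 16L, 32L),
                        c(8L, 8L, 64L), c(4L, 4L, 128L)))
  out <- vhunet_forward(m, x)
  expect_identical(dim(out$feat), c(64L, 64L, 1L, 16L))
  expect_identical(dim(out$prob), c(64L, 64L, 1L, 1L))

  g <- vhunet_init(vhunet_preset("gray-256"), seed = 1)
  xg <- array(runif(256 * 256), c(256, 256, 1, 1))
  sg <- vhu_encode(xg, g)
  expect_identical(dim(sg[[1]])[c(1, 2, 4)], c(128L, 128L, 16L))
  expect_identical(dim(sg[[4]])[c(1, 2, 4)], c(16L, 16L, 128L))

  widths <- vapply(skips, function(s) dim(s)[4], integer(1))
  expect_identical(widths[-1], 2L * widths[-4])  # channel doubling
})

test_that("indivisible inputs and mismatched skips raise informative errors", {
  m <- tiny_vhunet()
  expect_error(patch_embed(array(1, c(5, 5, 1, 1)), m), "divisible")
  expect_error(vhu_encode(array(1, c(8, 8, 1, 1)), m), "does not match")
  x <- array(runif(16 * 16), c(16, 16, 1, 1))
  skips <- vhu_encode(x, m)
  br <- vhu_bridge(skips[[4]], m)
  bad <- skips
  bad[[3]] <- bad[[3]][1, 1, , , drop = FALSE]
  expect_error(vhu_decode(br, bad, m), "decoder stage 1")
})

test_that("zeroed residual branches make stacked transformer blocks exact identities", {
  p <- vit_block_params(8, heads = 2, seed = 5)
  p$attn$Wo[] <- 0; p$attn$bo[] <- 0
  p$ffn$W2[] <- 0; p$ffn$b2[] <- 0
  x <- rand_tensor(4, 4, 2, 8, seed = 6)
  y <- x
  for (i in 1:3) y <- vit_block(y, p, heads = 2)
  expect_equal(y, x, tolerance = 1e-12)
})

test_that("transformer blocks are permutation-equivariant over tokens", {
  p <- vit_block_params(8, heads = 2, seed = 7)
  x <- rand_tensor(2, 2, 1, 8, seed = 8)
  perm <- c(3, 1, 4, 2)
  permute <- function(a) {
    m <- matrix(a, 4, 8)
    array(m[perm, ], dim(a))
  }
  y_then_perm <- permute(vit_block(x, p, heads = 2))
  perm_then_y <- vit_block(permute(x), p, heads = 2)
  expect_lt(max_rel_err(y_then_perm, perm_then_y), 1e-5)
})

test_that("a single-scale 1x1 multi-scale block is a pointwise convolution", {
  p <- hrnet_block_params(3, 4, kernels = 1L, seed = 9)
  x <- rand_tensor(5, 5, 2, 3, seed = 10)
  pre <- hrnet_block(x, p, normalize = FALSE, activation = FALSE)
  Wmat <- matrix(p$Ws[[1]], 3, 4)
  direct <- dualseg:::ts_mat(x) %*% Wmat + rep(p$b, each = 50)
  expect_lt(max_rel_err(pre, array(direct, dim(pre))), 1e-5)
})

test_that("zeroed multi-scale kernels give an identically zero pre-activation", {
  p <- hrnet_block_params(3, 4, seed = 11)
  for (i in seq_along(p$Ws)) p$Ws[[i]][] <- 0
  p$b[] <- 0
  x <- rand_tensor(6, 6, 2, 3, seed = 12)
  expect_true(all(hrnet_block(x, p, normalize = FALSE,
                              activation = FALSE) == 0))
  # shape contract at the published deepest stage width
  p2 <- hrnet_block_params(8, 8, seed = 13)
  expect_identical(dim(hrnet_block(rand_tensor(14, 14, 1, 8, seed = 14), p2)),
                   c(14L, 14L, 1L, 8L))
})

test_that("embedding and multi-scale blocks are homogeneous without bias", {
  m <- tiny_vhunet()
  m$params$emb$b[] <- 0
  m$params$emb$pos[] <- 0
  x <- rand_tensor(16, 16, 1, 1, seed = 15)
  e1 <- patch_embed(x, m)
  e3 <- patch_embed(3 * x, m)
  expect_lt(max_rel_err(e3, 3 * e1), 1e-5)

  p <- hrnet_block_params(2, 3, seed = 16)
  p$b[] <- 0
  f <- rand_tensor(6, 6, 1, 2, seed = 17)
  expect_lt(max_rel_err(hrnet_block(3 * f, p, normalize = FALSE,
                                    activation = FALSE),
                        3 * hrnet_block(f, p, normalize = FALSE,
                                        activation = FALSE)), 1e-5)
})

test_that("patch embedding matches an explicit patch-wise product", {
  ns <- asNamespace("dualseg")
  x <- rand_tensor(4, 4, 1, 1, seed = 18)
  set.seed(19)
  W <- array(rnorm(2 * 2 * 1 * 3), c(2, 2, 1, 3))
  b <- rnorm(3)
  out <- ns$patchify_fwd(x, W, b)
  expect_identical(dim(out), c(2L, 2L, 1L, 3L))
  for (i in 1:2) for (j in 1:2) for (c in 1:3) {
    patch <- x[2 * i - 1:0, 2 * j - 1:0, 1, 1]
    expect_equal(out[i, j, 1, c], sum(patch * W[, , 1, c]) + b[c],
                 tolerance = 1e-10)
  }
  # zero image, zero bias, zero positional table -> zero output
  m <- tiny_vhunet()
  m$params$emb$b[] <- 0; m$params$emb$pos[] <- 0
  expect_true(all(patch_embed(array(0, c(16, 16, 1, 1)), m) == 0))
})

test_that("organ head follows the sigmoid contract", {
  m <- tiny_vhunet()
  feat <- rand_tensor(16, 16, 2, 2, seed = 19)
  m$params$head$W[] <- 0; m$params$head$b <- 0
  expect_true(all(organ_head(feat, m) == 0.5))
  m$params$head$b <- 10
  expect_true(all(organ_head(feat, m) > 0.9999))
  m2 <- tiny_vhunet()
  p <- organ_head(feat, m2)
  expect_true(all(p > 0 & p < 1))
})

test_that("bridge clamps at zero and parameter counting is exact", {
  m <- tiny_vhunet()
  m$params$bridge$W[] <- 0; m$params$bridge$b[] <- -1
  f4 <- rand_tensor(2, 2, 1, 8, seed = 20)
  expect_true(all(vhu_bridge(f4, m) == 0))

  expect_identical(count_parameters(list()), 0)
  expect_identical(count_parameters(list(W = array(0, c(3, 3, 1, 8)),
                                         b = rep(0, 8))), 80)
  expect_identical(count_parameters(list(W = array(0, c(1, 1, 4, 4)))), 16)
})

test_that("fp32 model sizes reproduce the published footprints", {
  expect_identical(model_size_mib(32624261), 124.45)
  expect_identical(model_size_mib(7781761), 29.69)
  expect_identical(model_size_mib(3370000), 12.86)
  expect_identical(model_size_mib(196916), 0.75)
  expect_identical(model_size_mib(0), 0)
  expect_error(model_size_mib(-1), "non-negative")
})
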