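# The compiled kernels are checked against the plain-R reference
# implementations, and the reference backward passes against numerical
# differentiation, so each route is validated independently.

test_that("compiled convolution kernels match the reference implementation", {
  set.seed(5)
  x <- rand_tensor(7, 9, 3, 5, seed = 5)
  for (k in c(1L, 3L, 5L)) {
    W <- array(rnorm(k * k * 5 * 6), c(k, k, 5, 6))
    b <- rnorm(6)
    y_cpp <- dualseg:::conv2d_fwd(x, W, b)
    y_ref <- dualseg:::conv2d_fwd_ref(x, W, b)
    expect_lt(max_rel_err(y_cpp, y_ref), 1e-5)
    dy <- array(rnorm(length(y_cpp)), dim(y_cpp))
    b_cpp <- dualseg:::conv2d_bwd(x, W, dy)
    b_ref <- dualseg:::conv2d_bwd_ref(x, W, dy)
    expect_lt(max_rel_err(b_cpp$dx, b_ref$dx), 1e-5)
    expect_lt(max_rel_err(b_cpp$dW, b_ref$dW), 1e-5)
    expect_lt(max_rel_err(b_cpp$db, b_ref$db), 1e-5)
  }
})

test_that("compiled pooling/contrast/resampling kernels match references", {
  x <- rand_tensor(6, 8, 3, 5, seed = 8)
  a <- dualseg:::maxpool2_fwd(x)
  b <- dualseg:::maxpool2_fwd_ref(x)
  expect_identical(a$y, b$y)
  dy <- array(rnorm(length(a$y)), dim(a$y))
  expect_identical(dualseg:::maxpool2_bwd(dy, a$sel, dim(x)),
                   dualseg:::maxpool2_bwd_ref(dy, b$sel, dim(x)))

  expect_lt(max_rel_err(dualseg:::avgbox3_fwd(x),
                        dualseg:::avgbox3_fwd_ref(x)), 1e-12)

  W <- array(rnorm(9 * 5), c(3, 3, 5)); bb <- rnorm(5)
  expect_lt(max_rel_err(dualseg:::dwconv2d_fwd(x, W, bb),
                        dualseg:::dwconv2d_fwd_ref(x, W, bb)), 1e-12)
  dyd <- array(rnorm(length(x)), dim(x))
  c1 <- dualseg:::dwconv2d_bwd(x, W, dyd)
  c2 <- dualseg:::dwconv2d_bwd_ref(x, W, dyd)
  expect_lt(max_rel_err(c1$dx, c2$dx), 1e-12)
  expect_lt(max_rel_err(c1$dW, c2$dW), 1e-12)

  y1 <- dualseg:::bilinear_upsample_fwd(x, 13, 17)
  y2 <- dualseg:::bilinear_upsample_fwd_ref(x, 13, 17)
  expect_lt(max_rel_err(y1, y2), 1e-12)
  dyb <- array(rnorm(13 * 17 * 3 * 5), c(13, 17, 3, 5))
  expect_lt(max_rel_err(dualseg:::bilinear_upsample_bwd(dyb, 6, 8),
                        dualseg:::bilinear_upsample_bwd_ref(dyb, 6, 8)), 1e-12)
})

test_that("compiled attention matches the double-precision reference", {
  set.seed(3)
  p <- dualseg:::mhsa_init(8)
  x <- rand_tensor(4, 4, 3, 8, seed = 3)
  f1 <- dualseg:::mhsa_fwd(x, p, 4)
  f2 <- dualseg:::mhsa_fwd_ref(x, p, 4)
  expect_lt(max_rel_err(f1$y, f2$y), 1e-5)
  dy <- array(rnorm(length(x)), dim(x))
  b1 <- dualseg:::mhsa_bwd(dy, p, f1$cache)
  b2 <- dualseg:::mhsa_bwd_ref(dy, p, f2$cache)
  expect_lt(max_rel_err(b1$dx, b2$dx), 1e-5)
  expect_lt(max_rel_err(b1$grads$Wq, b2$grads$Wq), 1e-5)
  expect_lt(max_rel_err(b1$grads$Wo, b2$grads$Wo), 1e-5)
})

test_that("reference backward passes agree with numerical gradients", {
  ns <- asNamespace("dualseg")
  x <- rand_tensor(5, 6, 2, 3, seed = 42)

  W <- array(rnorm(3 * 3 * 3 * 4), c(3, 3, 3, 4)); b <- rnorm(4)
  dy <- rand_tensor(5, 6, 2, 4, seed = 43)
  bw <- ns$conv2d_bwd_ref(x, W, dy)
  expect_lt(max_rel_err(bw$dx, fd_grad(function(z)
    sum(ns$conv2d_fwd_ref(z, W, b) * dy), x)), 1e-6)
  expect_lt(max_rel_err(bw$dW, fd_grad(function(z)
    sum(ns$conv2d_fwd_ref(x, z, b) * dy), W)), 1e-6)

  Wp <- array(rnorm(2 * 2 * 3 * 5), c(2, 2, 3, 5)); bp <- rnorm(5)
  xp <- rand_tensor(6, 6, 2, 3, seed = 44)
  dyp <- rand_tensor(3, 3, 2, 5, seed = 45)
  pb <- ns$patchify_bwd(xp, Wp, dyp)
  expect_lt(max_rel_err(pb$dx, fd_grad(function(z)
    sum(ns$patchify_fwd(z, Wp, bp) * dyp), xp)), 1e-6)
  expect_lt(max_rel_err(pb$dW, fd_grad(function(z)
    sum(ns$patchify_fwd(xp, z, bp) * dyp), Wp)), 1e-6)

  Wt <- array(rnorm(2 * 2 * 3 * 4), c(2, 2, 3, 4)); bt <- rnorm(4)
  dyt <- rand_tensor(10, 12, 2, 4, seed = 46)
  tb <- ns$tconv2_bwd(x, Wt, dyt)
  expect_lt(max_rel_err(tb$dx, fd_grad(function(z)
    sum(ns$tconv2_fwd(z, Wt, bt) * dyt), x)), 1e-6)
  expect_lt(max_rel_err(tb$dW, fd_grad(function(z)
    sum(ns$tconv2_fwd(x, z, bt) * dyt), Wt)), 1e-6)

  dyd <- rand_tensor(5, 6, 2, 3, seed = 47)
  expect_lt(max_rel_err(ns$contrast_delta_bwd(dyd), fd_grad(function(z)
    sum(ns$contrast_delta_fwd(z) * dyd), x)), 1e-6)

  set.seed(48)
  pl <- ns$layernorm_init(3); pl$g <- rnorm(3) + 1; pl$b <- rnorm(3)
  dyl <- rand_tensor(5, 6, 2, 3, seed = 49)
  fl <- ns$layernorm_fwd(x, pl)
  bl <- ns$layernorm_bwd(dyl, pl, fl$cache)
  expect_lt(max_rel_err(bl$dx, fd_grad(function(z)
    sum(ns$layernorm_fwd(z, pl)$y * dyl), x)), 1e-5)
  expect_lt(max_rel_err(bl$grads$g, fd_grad(function(z) {
    pp <- pl; pp$g <- z
    sum(ns$layernorm_fwd(x, pp)$y * dyl)
  }, pl$g)), 1e-5)

  pb2 <- ns$batchnorm_init(3); pb2$g <- rnorm(3) + 1
  st <- ns$batchnorm_state(3)
  fb <- ns$batchnorm_fwd(x, pb2, st, TRUE)
  bb <- ns$batchnorm_bwd(dyl, pb2, fb$cache)
  expect_lt(max_rel_err(bb$dx, fd_grad(function(z)
    sum(ns$batchnorm_fwd(z, pb2, st, TRUE)$y * dyl), x)), 1e-5)

  pa <- ns$mhsa_init(4)
  xa <- rand_tensor(2, 2, 3, 4, seed = 50)
  dya <- rand_tensor(2, 2, 3, 4, seed = 51)
  fa <- ns$mhsa_fwd_ref(xa, pa, 2)
  ba <- ns$mhsa_bwd_ref(dya, pa, fa$cache)
  expect_lt(max_rel_err(ba$dx, fd_grad(function(z)
    sum(ns$mhsa_fwd_ref(z, pa, 2)$y * dya), xa)), 1e-5)

  pf <- ns$ffn_init(3, 2)
  ff <- ns$ffn_fwd(x, pf)
  bf <- ns$ffn_bwd(dyl, pf, ff$cache)
  expect_lt(max_rel_err(bf$dx, fd_grad(function(z)
    sum(ns$ffn_fwd(z, pf)$y * dyl), x)), 1e-6)
  expect_lt(max_rel_err(bf$grads$W1, fd_grad(function(z) {
    pp <- pf; pp$W1 <- z
    sum(ns$ffn_fwd(x, pp)$y * dyl)
  }, pf$W1)), 1e-6)
})

test_that("the Adam optimizer updates every learnable array", {
  m <- tiny_vhunet()
  set.seed(1)
  x <- rand_tensor(16, 16, 2, 1, seed = 12)
  gt <- (rand_tensor(16, 16, 2, 1, seed = 13) > 0) * 1
  fwd <- vhunet_forward(m, x, train = TRUE)
  g <- vhunet_backward(m, fwd, dualseg:::soft_dice_batch(fwd$prob, gt)$dprob)
  opt <- dualseg:::adam_new(m$params, lr = 1e-3)
  st <- dualseg:::adam_step(opt, m$params, g)
  moved <- function(a, b) {
    if (is.numeric(a)) return(any(a != b))
    any(mapply(moved, a, b))
  }
  # every top-level group moves, including the unnamed per-stage lists
  for (nm in names(m$params)) {
    expect_true(moved(m$params[[nm]], st$params[[nm]]), label = nm)
  }
})
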