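test_that("zero epochs leave parameters untouched with an empty history", {
  m <- tiny_vhunet()
  samples <- small_phantoms(4, image_size = c(16L, 16L),
                            organ_axes_range = c(3, 5),
                            mass_radius_range = c(1, 2))
  cfg <- train_config(seed = 1, epochs = 0)
  out <- train_model(m, samples, target = "mask", cfg = cfg, quiet = TRUE)
  expect_identical(out$model$params, m$params)
  expect_identical(nrow(out$history), 0L)
})

test_that("training on easy phantoms strictly decreases the loss", {
  samples <- small_phantoms(20, seed = 5, noise_sd = 0, texture_sd = 0)
  m <- vhunet_init(vhunet_preset("desk-64"), seed = 1)
  cfg <- train_config(seed = 1, epochs = 5, augment = FALSE)
  out <- train_model(m, samples, target = "mask", cfg = cfg, quiet = TRUE)
  expect_identical(nrow(out$history), 5L)
  expect_true(all(is.finite(as.matrix(out$history[-1]))))
  expect_lt(out$history$train_loss[5], out$history$train_loss[1])
})

test_that("one optimization step strictly decreases the Dice loss on a phantom", {
  ns <- asNamespace("dualseg")
  s <- small_phantoms(1, seed = 21)[[1]]
  bt <- ns$stack_batch(list(s), field = "mask")
  m <- vhunet_init(vhunet_preset("desk-64"), seed = 2)
  fwd <- vhunet_forward(m, bt$x, train = TRUE)
  l0 <- ns$soft_dice_batch(fwd$prob, bt$y)
  g <- vhunet_backward(m, fwd, l0$dprob)
  opt <- ns$adam_new(m$params, lr = 1e-3)
  st <- ns$adam_step(opt, m$params, g)
  m$params <- st$params
  fwd2 <- vhunet_forward(m, bt$x, train = TRUE)
  l1 <- ns$soft_dice_batch(fwd2$prob, bt$y)
  expect_lt(l1$loss, l0$loss)
})

test_that("training is deterministic under a fixed seed", {
  samples <- small_phantoms(8, seed = 6)
  run <- function() {
    m <- vhunet_init(vhunet_preset("desk-64"), seed = 3)
    cfg <- train_config(seed = 3, epochs = 2)
    train_model(m, samples, target = "mask", cfg = cfg,
                quiet = TRUE)$history$train_loss
  }
  expect_lt(abs(tail(run(), 1) - tail(run(), 1)), 1e-6)
})

test_that("missing mass targets are reported with guidance", {
  samples <- small_phantoms(4, seed = 7)
  samples <- lapply(samples, function(s) { s$mass_mask <- NULL; s })
  m <- pdn_init(pdn_preset("desk-64"), seed = 1)
  expect_error(train_model(m, samples, target = "mass_mask",
                           cfg = train_config(epochs = 1), quiet = TRUE),
               "mass_mask targets are missing")
  expect_error(run_dual_track(samples, train_config(epochs = 1)),
               "phantom")
})

test_that("an oracle predictor evaluates to a perfect score", {
  samples <- small_phantoms(4, seed = 8)
  gt_organ <- lapply(samples, `[[`, "mask")
  gt_mass <- lapply(samples, `[[`, "mass_mask")
  fused <- mapply(fuse_masks, gt_organ, gt_mass, SIMPLIFY = FALSE)
  layers <- lapply(fused, label_layers)
  ro <- evaluate_masks(lapply(layers, `[[`, "organ"), gt_organ)
  rm_ <- evaluate_masks(lapply(layers, `[[`, "mass"), gt_mass,
                        boundary = FALSE)
  expect_equal(ro$aggregates$dice$mean, 1)
  expect_equal(rm_$aggregates$dice$mean, 1)
})

test_that("checkpoints round-trip with a text summary", {
  m <- tiny_pdn()
  p <- tempfile(fileext = ".rds")
  save_checkpoint(m, p)
  m2 <- load_checkpoint(p)
  expect_identical(m2$params, m$params)
  summ <- readLines(paste0(p, ".txt"))
  expect_true(any(grepl(as.character(count_parameters(m)), summ)))
})

test_that("disk-based segmentation writes labeled masks and overlays", {
  samples <- small_phantoms(2, seed = 13)
  dir <- tempfile("imgs"); dir.create(dir)
  for (s in samples) {
    png::writePNG(round(s$image) / 255, file.path(dir, paste0(s$id, ".png")))
  }
  vhu <- vhunet_init(vhunet_preset("desk-64"), seed = 1)
  pdn <- pdn_init(pdn_preset("desk-64"), seed = 2)
  out <- tempfile("seg")
  res <- segment_images(dir, vhu, pdn, out)
  expect_identical(nrow(res), 2L)
  expect_true(all(file.exists(res$labels)))
  expect_true(all(file.exists(res$overlay)))
  lab <- load_labeled_mask(res$labels[1])
  expect_true(all(lab %in% 0:2))
  # determinism on repeated runs
  res2 <- segment_images(dir, vhu, pdn, tempfile("seg2"))
  expect_identical(tools::md5sum(res$labels[1])[[1]],
                   tools::md5sum(res2$labels[1])[[1]])
  # size mismatch is reported
  bad <- tempfile("bad"); dir.create(bad)
  png::writePNG(matrix(0.5, 32, 32), file.path(bad, "b.png"))
  expect_error(segment_images(bad, vhu, pdn, tempfile()), "expects")
})
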