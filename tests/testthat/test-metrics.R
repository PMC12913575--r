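test_that("overlap metrics follow their closed forms on constructed masks", {
  gt <- matrix(0L, 4, 4); gt[1:4, 1] <- 1L            # 4 pixels
  pred <- matrix(0L, 4, 4); pred[1:2, 1] <- 1L        # 2 inside
  cfg0 <- metric_config(epsilon = 1e-300)
  expect_equal(dice(pred, gt, cfg0), 2 * 2 / (2 + 4), tolerance = 1e-12)
  expect_equal(iou(pred, gt, cfg0), 2 / 4, tolerance = 1e-12)
  expect_equal(dice(gt, gt, cfg0), 1)
  e <- matrix(0L, 4, 4)
  expect_equal(dice(e, e), 1)  # epsilon-smoothed empty/empty convention
  expect_equal(iou(e, e), 1)
  disj <- matrix(0L, 4, 4); disj[1, 2] <- 1L
  expect_lt(iou(pred * 0 + disj, gt, cfg0), 1e-10)
  expect_error(dice(pred, matrix(0L, 3, 3)), "differ")
})

test_that("dice and iou satisfy the 2J/(1+J) identity, reproducing printed pairs", {
  cfg0 <- metric_config(epsilon = 1e-300)
  set.seed(1)
  for (k in 1:50) {
    a <- rand_mask(12, 12, p = runif(1, 0.2, 0.8), seed = k)
    b <- rand_mask(12, 12, p = runif(1, 0.2, 0.8), seed = k + 500)
    if (sum(a) + sum(b) == 0) next
    d <- dice(a, b, cfg0); j <- iou(a, b, cfg0)
    expect_lt(abs(d - 2 * j / (1 + j)), 1e-12)
    expect_equal(d, dice(b, a, cfg0))  # symmetry
    expect_equal(j, iou(b, a, cfg0))
  }
  expect_equal(round(2 * 0.9441 / (1 + 0.9441), 4), 0.9712)
  expect_equal(round(2 * 0.9285 / (1 + 0.9285), 4), 0.9629)
})

test_that("dice loss is one minus soft dice, exactly", {
  set.seed(2)
  gt <- rand_mask(8, 8, seed = 3)
  prob <- matrix(runif(64), 8, 8)
  cfg <- metric_config()
  soft_dice <- (2 * sum(prob * gt) + cfg$epsilon) /
    (sum(prob) + sum(gt) + cfg$epsilon)
  expect_equal(dice_loss(prob, gt, cfg) + soft_dice, 1, tolerance = 1e-15)
  expect_lt(dice_loss(gt * 1.0, gt, cfg), 1e-6)
  # the printed loss/dice pairs of the evaluated models
  expect_equal(1 - 0.9712, 0.0288, tolerance = 1e-12)
  expect_equal(1 - 0.9532, 0.0468, tolerance = 1e-12)
  expect_equal(1 - 0.9629, 0.0371, tolerance = 1e-12)
})

test_that("the batch soft-dice gradient matches numerical differentiation", {
  ns <- asNamespace("dualseg")
  set.seed(4)
  prob <- array(runif(6 * 6 * 2), c(6, 6, 2, 1))
  gt <- array(rbinom(72, 1, 0.4), c(6, 6, 2, 1))
  sd1 <- ns$soft_dice_batch(prob, gt)
  num <- fd_grad(function(p) ns$soft_dice_batch(p, gt)$loss, prob)
  expect_lt(max_rel_err(sd1$dprob, num), 1e-6)
})

test_that("boundary metrics match a brute-force all-pairs oracle", {
  cfg <- metric_config()
  m <- rand_mask(6, 6, seed = 1, nonempty = TRUE)
  expect_equal(hd95(m, m, cfg), 0)
  expect_equal(assd(m, m, cfg), 0)

  a <- matrix(0L, 7, 7); a[2, 2] <- 1L
  b <- matrix(0L, 7, 7); b[2, 5] <- 1L
  expect_equal(hd95(a, b, cfg), 3)
  expect_equal(assd(a, b, cfg), 3)

  set.seed(5)
  for (k in 1:40) {
    p <- rand_mask(12, 12, p = runif(1, 0.15, 0.7), seed = k, nonempty = TRUE)
    g <- rand_mask(12, 12, p = runif(1, 0.15, 0.7), seed = k + 900,
                   nonempty = TRUE)
    expect_equal(hd95(p, g, cfg), bf_hd95(p, g), tolerance = 1e-10)
    expect_equal(assd(p, g, cfg), bf_assd(p, g), tolerance = 1e-10)
    expect_equal(hd95(p, g, cfg), hd95(g, p, cfg))  # symmetry
    expect_equal(assd(p, g, cfg), assd(g, p, cfg))
  }
})

test_that("anisotropic pixel spacing scales boundary distances", {
  a <- matrix(0L, 5, 5); a[3, 2] <- 1L
  b <- matrix(0L, 5, 5); b[3, 4] <- 1L
  cfg <- metric_config(pixel_spacing = c(1, 2.5))
  expect_equal(hd95(a, b, cfg), 5)
})

test_that("empty masks are refused with an optional identical-empty sentinel", {
  e <- matrix(0L, 5, 5)
  m <- rand_mask(5, 5, seed = 6, nonempty = TRUE)
  expect_error(hd95(e, m), "non-empty")
  expect_error(assd(m, e), "non-empty")
  expect_equal(hd95(e, e, on_empty = "zero"), 0)
  expect_error(hd95(e, m, on_empty = "zero"), "non-empty")
})

test_that("confusion counts enumerate every pixel", {
  gt <- matrix(c(1L, 1L, 0L, 0L), 2, 2)
  pred <- matrix(c(1L, 0L, 0L, 0L), 2, 2)
  expect_identical(confusion_counts(pred, gt),
                   c(TP = 1L, FP = 0L, FN = 1L, TN = 2L))
  m <- rand_mask(9, 9, seed = 7)
  expect_identical(unname(sum(confusion_counts(m, m))), 81L)
  expect_identical(unname(confusion_counts(m, m)[c("FP", "FN")]), c(0L, 0L))
  comp <- 1L - m
  cc <- confusion_counts(comp, m)
  expect_identical(unname(cc[c("TP", "TN")]), c(0L, 0L))
})

test_that("aggregation reproduces the published confidence intervals", {
  # two symmetric values realize mean 0.9712, population sd 0.0088
  agg <- aggregate_report(c(0.9712 - 0.0088, 0.9712 + 0.0088))
  expect_equal(agg$mean, 0.9712)
  expect_equal(agg$sd, 0.0088)
  expect_equal(round(agg$ci_low, 5), 0.95395)
  expect_equal(round(agg$ci_high, 5), 0.98845)

  agg2 <- aggregate_report(c(0.9532 - 0.0134, 0.9532 + 0.0134))
  expect_equal(round(agg2$ci_low, 4), 0.9269)
  expect_equal(round(agg2$ci_high, 4), 0.9795)

  same <- aggregate_report(rep(0.5, 7))
  expect_equal(same$sd, 0)
  expect_equal(same$ci_high - same$ci_low, 0)
  expect_error(aggregate_report(numeric(0)), "at least one")
})

test_that("mask evaluation assembles per-sample rows, aggregates and confusion", {
  set.seed(8)
  gts <- lapply(1:4, function(k) rand_mask(10, 10, seed = k, nonempty = TRUE))
  preds <- gts
  rep1 <- evaluate_masks(preds, gts)
  expect_identical(nrow(rep1$per_sample), 4L)
  expect_true(all(rep1$per_sample$dice == 1))
  expect_true(all(rep1$per_sample$hd95 == 0))
  expect_identical(unname(rep1$confusion[c("FP", "FN")]), c(0, 0))
  csv <- tempfile(fileext = ".csv")
  txt <- tempfile(fileext = ".txt")
  write_metrics_report(rep1, csv, txt)
  expect_identical(nrow(read.csv(csv)), 4L)
  expect_true(any(grepl("dice", readLines(txt))))
})
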