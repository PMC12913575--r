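#' Metric configuration
#'
#' @param epsilon smoothing constant added to numerator and denominator of
#'   the overlap metrics (so two empty masks score 1).
#' @param hd_percentile percentile of the pooled boundary distances used by
#'   [hd95()].
#' @param pixel_spacing physical size of a pixel along (row, column); boundary
#'   distances are reported in these units.
#' @return a list of class \code{metric_config}.
#' @export
metric_config <- function(epsilon = 1e-6, hd_percentile = 95,
                          pixel_spacing = c(1, 1)) {
  stopifnot(epsilon > 0, hd_percentile > 0, hd_percentile <= 100,
            length(pixel_spacing) == 2L, all(pixel_spacing > 0))
  structure(list(epsilon = epsilon, hd_percentile = hd_percentile,
                 pixel_spacing = as.numeric(pixel_spacing)),
            class = "metric_config")
}

check_same_dims <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt))) {
    stop("mask dimensions differ: ", paste(dim(pred), collapse = "x"),
         " vs ", paste(dim(gt), collapse = "x"))
  }
}

#' Dice similarity coefficient
#'
#' \code{(2 |pred n gt| + eps) / (|pred| + |gt| + eps)}. Two empty masks
#' score 1 under the epsilon-smoothed formula.
#'
#' @param pred,gt binary masks (matrices over \{0, 1\}) of equal size.
#' @param cfg a [metric_config()].
#' @return Dice coefficient in \[0, 1\].
#' @export
dice <- function(pred, gt, cfg = metric_config()) {
  check_same_dims(pred, gt)
  i <- sum(pred * gt)
  (2 * i + cfg$epsilon) / (sum(pred) + sum(gt) + cfg$epsilon)
}

#' Soft Dice loss
#'
#' \code{1 - soft-Dice(pred_prob, gt)} with a real-valued intersection; the
#' quantity minimised during training. The printed loss/Dice pairs of the
#' evaluated models satisfy \code{loss + dice = 1} exactly, which fixes the
#' sign convention.
#'
#' @param pred_prob probability map in \[0, 1\].
#' @param gt binary mask.
#' @param cfg a [metric_config()].
#' @return loss in \[0, 1\].
#' @export
dice_loss <- function(pred_prob, gt, cfg = metric_config()) {
  check_same_dims(pred_prob, gt)
  i <- sum(pred_prob * gt)
  1 - (2 * i + cfg$epsilon) / (sum(pred_prob) + sum(gt) + cfg$epsilon)
}

# batch soft-dice loss (mean over samples) and its gradient
# prob, gt: arrays (H, W, N, 1)
soft_dice_batch <- function(prob, gt, eps = 1e-6) {
  n <- dim(prob)[3L]
  losses <- numeric(n)
  dprob <- array(0, dim(prob))
  for (k in seq_len(n)) {
    p <- prob[, , k, 1L]
    g <- gt[, , k, 1L]
    i <- sum(p * g)
    den <- sum(p) + sum(g) + eps
    num <- 2 * i + eps
    losses[k] <- 1 - num / den
    # d(1 - num/den)/dp = -(2 g den - num) / den^2
    dprob[, , k, 1L] <- -(2 * g * den - num) / den^2 / n
  }
  list(loss = mean(losses), dprob = dprob)
}

#' Intersection over union (Jaccard index)
#'
#' \code{(|pred n gt| + eps) / (|pred u gt| + eps)}; related to Dice by
#' \code{dice = 2 iou / (1 + iou)}.
#'
#' @inheritParams dice
#' @return IoU in \[0, 1\].
#' @export
iou <- function(pred, gt, cfg = metric_config()) {
  check_same_dims(pred, gt)
  i <- sum(pred * gt)
  u <- sum(pred) + sum(gt) - i
  (i + cfg$epsilon) / (u + cfg$epsilon)
}

# 4-connectivity erosion residue: boundary pixels of a binary mask
mask_boundary <- function(m) {
  m <- (m > 0) * 1L
  h <- nrow(m); w <- ncol(m)
  up <- rbind(0L, m[-h, , drop = FALSE])
  dn <- rbind(m[-1L, , drop = FALSE], 0L)
  lf <- cbind(0L, m[, -w, drop = FALSE])
  rt <- cbind(m[, -1L, drop = FALSE], 0L)
  eroded <- m & up & dn & lf & rt
  m & !eroded
}

boundary_distances <- function(from_b, to_b, spacing) {
  if (all(spacing == 1)) {
    # Euclidean distance transform: distance of every pixel to the nearest
    # boundary pixel of the target mask
    dt <- EBImage::distmap(1 - to_b, metric = "euclidean")
    as.numeric(dt[from_b == 1L])
  } else {
    fi <- which(from_b == 1L, arr.ind = TRUE)
    ti <- which(to_b == 1L, arr.ind = TRUE)
    fy <- fi[, 1L] * spacing[1L]; fx <- fi[, 2L] * spacing[2L]
    ty <- ti[, 1L] * spacing[1L]; tx <- ti[, 2L] * spacing[2L]
    vapply(seq_along(fy), function(k) {
      sqrt(min((fy[k] - ty)^2 + (fx[k] - tx)^2))
    }, numeric(1))
  }
}

prep_boundary_pair <- function(pred, gt, on_empty) {
  check_same_dims(pred, gt)
  if (sum(pred) == 0 || sum(gt) == 0) {
    if (on_empty == "zero" && sum(pred) == 0 && sum(gt) == 0) {
      return(NULL)  # identical-empty sentinel
    }
    stop("boundary metrics require non-empty masks (pred: ", sum(pred),
         " px, gt: ", sum(gt), " px)")
  }
  list(pb = mask_boundary(pred), gb = mask_boundary(gt))
}

#' 95th-percentile Hausdorff distance
#'
#' Percentile (default 95) of the pooled directed nearest boundary-to-boundary
#' distances in both directions; boundaries are 4-connectivity erosion
#' residues and distances are Euclidean, scaled by the pixel spacing.
#'
#' @inheritParams dice
#' @param on_empty \code{"error"} (default) or \code{"zero"}, which returns 0
#'   for an identical pair of empty masks instead of erroring.
#' @return distance \eqn{\ge 0}.
#' @export
hd95 <- function(pred, gt, cfg = metric_config(), on_empty = c("error", "zero")) {
  on_empty <- match.arg(on_empty)
  b <- prep_boundary_pair(pred, gt, on_empty)
  if (is.null(b)) return(0)
  d_pg <- boundary_distances(b$pb, b$gb, cfg$pixel_spacing)
  d_gp <- boundary_distances(b$gb, b$pb, cfg$pixel_spacing)
  as.numeric(stats::quantile(c(d_pg, d_gp), cfg$hd_percentile / 100,
                             names = FALSE))
}

#' Average symmetric surface distance
#'
#' Mean of the two directed average boundary distances.
#'
#' @inheritParams hd95
#' @return distance \eqn{\ge 0}.
#' @export
assd <- function(pred, gt, cfg = metric_config(), on_empty = c("error", "zero")) {
  on_empty <- match.arg(on_empty)
  b <- prep_boundary_pair(pred, gt, on_empty)
  if (is.null(b)) return(0)
  d_pg <- boundary_distances(b$pb, b$gb, cfg$pixel_spacing)
  d_gp <- boundary_distances(b$gb, b$pb, cfg$pixel_spacing)
  (mean(d_pg) + mean(d_gp)) / 2
}

#' Pixelwise confusion counts
#'
#' @inheritParams dice
#' @return named vector \code{c(TP, FP, FN, TN)} summing to the pixel count.
#' @export
confusion_counts <- function(pred, gt) {
  check_same_dims(pred, gt)
  tp <- sum(pred == 1 & gt == 1)
  fp <- sum(pred == 1 & gt == 0)
  fn <- sum(pred == 0 & gt == 1)
  tn <- sum(pred == 0 & gt == 0)
  c(TP = tp, FP = fp, FN = fn, TN = tn)
}

#' Aggregate per-sample metric values
#'
#' Mean, standard deviation (population formula; 0 for a single value) and a
#' normal-approximation 95% confidence interval \code{mean ± 1.96 sd}.
#'
#' @param values numeric vector of per-sample metric values.
#' @return named list \code{mean}, \code{sd}, \code{ci_low}, \code{ci_high}.
#' @export
aggregate_report <- function(values) {
  if (length(values) == 0L) stop("aggregate_report needs at least one value")
  m <- mean(values)
  s <- if (length(values) == 1L) 0 else sqrt(mean((values - m)^2))
  list(mean = m, sd = s, ci_low = m - 1.96 * s, ci_high = m + 1.96 * s)
}

#' Evaluate predicted masks against ground truth
#'
#' Computes per-sample Dice, IoU, HD95 and ASSD, their aggregates, and pooled
#' confusion counts.
#'
#' @param preds list of predicted binary masks.
#' @param gts list of ground-truth binary masks (same length and sizes).
#' @param ids optional sample ids.
#' @param cfg a [metric_config()].
#' @param boundary compute HD95/ASSD (requires non-empty masks; empty pairs
#'   are scored with the zero sentinel and one-sided empties as NA).
#' @return a \code{metrics_report}: list with \code{per_sample} (data.frame),
#'   \code{aggregates} (per metric: mean/sd/ci), \code{confusion}.
#' @export
evaluate_masks <- function(preds, gts, ids = NULL, cfg = metric_config(),
                           boundary = TRUE) {
  stopifnot(length(preds) == length(gts))
  n <- length(preds)
  if (is.null(ids)) ids <- sprintf("sample_%03d", seq_len(n))
  per <- data.frame(id = ids,
                    dice = numeric(n), iou = numeric(n),
                    hd95 = NA_real_, assd = NA_real_,
                    stringsAsFactors = FALSE)
  conf <- c(TP = 0, FP = 0, FN = 0, TN = 0)
  for (k in seq_len(n)) {
    p <- preds[[k]]; g <- gts[[k]]
    per$dice[k] <- dice(p, g, cfg)
    per$iou[k] <- iou(p, g, cfg)
    if (boundary) {
      ok <- sum(p) > 0 && sum(g) > 0
      both_empty <- sum(p) == 0 && sum(g) == 0
      if (ok || both_empty) {
        per$hd95[k] <- hd95(p, g, cfg, on_empty = "zero")
        per$assd[k] <- assd(p, g, cfg, on_empty = "zero")
      }
    }
    conf <- conf + confusion_counts(p, g)
  }
  aggregates <- lapply(c(dice = "dice", iou = "iou", hd95 = "hd95",
                         assd = "assd"), function(mname) {
    v <- per[[mname]]
    v <- v[!is.na(v)]
    if (length(v) == 0L) return(NULL)
    aggregate_report(v)
  })
  structure(list(per_sample = per, aggregates = aggregates, confusion = conf),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("metrics_report:", nrow(x$per_sample), "samples\n")
  for (m in names(x$aggregates)) {
    a <- x$aggregates[[m]]
    if (is.null(a)) next
    cat(sprintf("  %-5s %.4f +/- %.4f  [%.4f-%.4f]\n",
                m, a$mean, a$sd, max(0, a$ci_low), a$ci_high))
  }
  cat("  confusion: TP", x$confusion["TP"], "FP", x$confusion["FP"],
      "FN", x$confusion["FN"], "TN", x$confusion["TN"], "\n")
  invisible(x)
}

#' Write a metrics report to disk
#'
#' Per-sample values as CSV plus a plain-text aggregate summary.
#'
#' @param report a [evaluate_masks()] result.
#' @param csv_path path of the per-sample CSV.
#' @param summary_path optional path of the aggregate text summary.
#' @return invisibly, the report.
#' @export
write_metrics_report <- function(report, csv_path, summary_path = NULL) {
  utils::write.csv(report$per_sample, csv_path, row.names = FALSE)
  if (!is.null(summary_path)) {
    con <- file(summary_path, "w")
    on.exit(close(con))
    sink(con); on.exit(sink(), add = TRUE, after = FALSE)
    print(report)
  }
  invisible(report)
}
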