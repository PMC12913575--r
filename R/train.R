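#' Training configuration for the dual-track experiment
#'
#' Defaults follow the published training recipe: Adam, learning rate 0.001,
#' batch size 32, 35 epochs, Dice loss. (The text elsewhere states a learning
#' rate of 0.0001; that value is available as \code{lr_preset = "slow"}.)
#' The \code{"desk-64"} input preset trains 64 x 64 single-channel models
#' with \code{width_divisor = 4} and batch size 16 — small enough for a CPU
#' core — while \code{"rgb-224"} and \code{"gray-256"} keep the published
#' geometry.
#'
#' @param input_preset one of \code{"desk-64"}, \code{"rgb-224"},
#'   \code{"gray-256"}.
#' @param learning_rate Adam learning rate.
#' @param lr_preset \code{"table"} (0.001) or \code{"slow"} (0.0001); ignored
#'   when \code{learning_rate} is given explicitly.
#' @param batch_size minibatch size.
#' @param epochs training epochs (0 leaves parameters untouched).
#' @param seed global seed covering shuffling, augmentation and
#'   initialisation.
#' @param augment apply the paired augmentation stack during training
#'   (flips and rotation; the desk phantom pipeline skips intensity/elastic
#'   jitter, whose published parameters target 224-px clinical slices).
#' @param threshold organ/mass probability threshold.
#' @param r_val,r_test split fractions used by [run_dual_track()].
#' @return a list of class \code{train_config}.
#' @export
train_config <- function(input_preset = c("desk-64", "rgb-224", "gray-256"),
                         learning_rate = NULL,
                         lr_preset = c("table", "slow"),
                         batch_size = NULL, epochs = NULL,
                         seed = 1L, augment = TRUE, threshold = 0.5,
                         r_val = 0.04, r_test = 0.16) {
  input_preset <- match.arg(input_preset)
  lr_preset <- match.arg(lr_preset)
  if (is.null(learning_rate)) {
    learning_rate <- if (lr_preset == "table") 0.001 else 0.0001
  }
  desk <- input_preset == "desk-64"
  if (is.null(batch_size)) batch_size <- if (desk) 16L else 32L
  if (is.null(epochs)) epochs <- if (desk) 10L else 35L
  stopifnot(learning_rate > 0, batch_size >= 1L, epochs >= 0L)
  structure(list(input_preset = input_preset,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 seed = as.integer(seed), augment = isTRUE(augment),
                 threshold = threshold, r_val = r_val, r_test = r_test),
            class = "train_config")
}

# stack samples into a (H, W, N, C) tensor of [0,1] images and a mask tensor
stack_batch <- function(samples, field = "mask", input_field = "image") {
  n <- length(samples)
  im1 <- samples[[1L]][[input_field]]
  d <- dim(im1)
  ch <- if (length(d) == 3L) d[3L] else 1L
  x <- array(0, c(d[1L], d[2L], n, ch))
  y <- array(0, c(d[1L], d[2L], n, 1L))
  for (k in seq_len(n)) {
    im <- samples[[k]][[input_field]]
    if (length(dim(im)) == 3L) {
      for (c in seq_len(ch)) x[, , k, c] <- im[, , c]
    } else {
      x[, , k, 1L] <- im
    }
    tgt <- samples[[k]][[field]]
    if (!is.null(tgt)) y[, , k, 1L] <- tgt
  }
  list(x = x / 255, y = y)
}

model_forward <- function(model, x, train = FALSE) {
  if (model$type == "vhunet") vhunet_forward(model, x, train = train)
  else pdn_forward(model, x, train = train)
}

model_backward <- function(model, fwd, dprob) {
  if (model$type == "vhunet") vhunet_backward(model, fwd, dprob)
  else pdn_backward(model, fwd, dprob)
}

# batched evaluation loss/dice on a sample list
eval_model <- function(model, samples, target, batch_size = 16L) {
  losses <- numeric(0)
  dices <- numeric(0)
  ious <- numeric(0)
  for (b in split(seq_along(samples),
                  ceiling(seq_along(samples) / batch_size))) {
    bt <- stack_batch(samples[b], field = target)
    fwd <- model_forward(model, bt$x, train = FALSE)
    sd <- soft_dice_batch(fwd$prob, bt$y)
    losses <- c(losses, sd$loss)
    for (k in seq_along(b)) {
      pm <- (fwd$prob[, , k, 1L] > model$cfg$threshold %||% 0.5) * 1
      dices <- c(dices, dice(pm, bt$y[, , k, 1L]))
      ious <- c(ious, iou(pm, bt$y[, , k, 1L]))
    }
  }
  list(loss = mean(losses), dice = mean(dices), iou = mean(ious))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Train a segmentation model with Adam and Dice loss
#'
#' Minimises the soft Dice loss with Adam; per-epoch training and validation
#' loss, Dice and IoU are recorded, and the parameters of the best
#' validation-Dice epoch are restored at the end (and optionally
#' checkpointed). Fully deterministic given the seed.
#'
#' @param model a [vhunet_init()] or [pdn_init()] model.
#' @param dataset list of \code{sample_pair}s (images on \[0, 255\]).
#' @param target \code{"mask"} (organ) or \code{"mass_mask"}.
#' @param cfg a [train_config()].
#' @param val_dataset optional validation samples; defaults to evaluating on
#'   the training set.
#' @param augment_cfg an [augment_config()] used when \code{cfg$augment}.
#' @param checkpoint_path optional RDS path updated at each best epoch.
#' @param quiet suppress per-epoch console lines.
#' @return list with the trained \code{model} and a \code{history} data.frame
#'   (one row per epoch).
#' @export
train_model <- function(model, dataset, target = c("mask", "mass_mask"),
                        cfg = train_config(), val_dataset = NULL,
                        augment_cfg = augment_config(
                          p_brightness_contrast = 0, p_elastic = 0),
                        checkpoint_path = NULL, quiet = FALSE) {
  target <- match.arg(target)
  if (length(dataset) == 0L) stop("empty training dataset")
  if (target == "mass_mask" &&
      any(vapply(dataset, function(s) is.null(s$mass_mask), logical(1)))) {
    stop("mass_mask targets are missing; generate phantoms with a mass or ",
         "supply a mass_dir when loading pairs")
  }
  if (is.null(val_dataset)) val_dataset <- dataset
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        train_dice = numeric(0), train_iou = numeric(0),
                        val_loss = numeric(0), val_dice = numeric(0),
                        val_iou = numeric(0))
  if (cfg$epochs == 0L) return(list(model = model, history = history))
  opt <- adam_new(model$params, lr = cfg$learning_rate)
  best <- list(dice = -Inf, params = model$params, state = model$state)
  n <- length(dataset)
  for (ep in seq_len(cfg$epochs)) {
    ord <- with_seed(cfg$seed * 1000L + ep, sample(n))
    ep_losses <- numeric(0)
    ep_dice <- numeric(0)
    ep_iou <- numeric(0)
    for (b in split(ord, ceiling(seq_along(ord) / cfg$batch_size))) {
      batch <- dataset[b]
      if (cfg$augment) {
        batch <- lapply(seq_along(batch), function(k) {
          s <- batch[[k]]
          a <- augment_pair(s$image, s$mask, augment_cfg,
                            rng_state = cfg$seed * 100003L + ep * 1009L +
                              b[k],
                            mass_mask = s$mass_mask)
          s$image <- a$image
          s$mask <- a$mask
          if (!is.null(a$mass_mask)) s$mass_mask <- a$mass_mask
          s
        })
      }
      bt <- stack_batch(batch, field = target)
      fwd <- model_forward(model, bt$x, train = TRUE)
      model$state <- fwd$state
      sd <- soft_dice_batch(fwd$prob, bt$y)
      if (!is.finite(sd$loss)) stop("non-finite loss at epoch ", ep)
      grads <- model_backward(model, fwd, sd$dprob)
      st <- adam_step(opt, model$params, grads)
      opt <- st$opt
      model$params <- st$params
      ep_losses <- c(ep_losses, sd$loss)
      # running (keras-style) training metrics from the minibatch outputs
      thr <- model$cfg$threshold %||% 0.5
      for (k in seq_along(b)) {
        pm <- (fwd$prob[, , k, 1L] > thr) * 1
        ep_dice <- c(ep_dice, dice(pm, bt$y[, , k, 1L]))
        ep_iou <- c(ep_iou, iou(pm, bt$y[, , k, 1L]))
      }
    }
    va_eval <- eval_model(model, val_dataset, target, cfg$batch_size)
    history <- rbind(history,
                     data.frame(epoch = ep, train_loss = mean(ep_losses),
                                train_dice = mean(ep_dice),
                                train_iou = mean(ep_iou),
                                val_loss = va_eval$loss,
                                val_dice = va_eval$dice,
                                val_iou = va_eval$iou))
    if (!quiet) {
      message(sprintf("[%s] epoch %d/%d  loss %.4f  val dice %.4f",
                      model$type, ep, cfg$epochs, mean(ep_losses),
                      va_eval$dice))
    }
    if (va_eval$dice > best$dice) {
      best <- list(dice = va_eval$dice, params = model$params,
                   state = model$state)
      if (!is.null(checkpoint_path)) save_checkpoint(model, checkpoint_path)
    }
  }
  model$params <- best$params
  model$state <- best$state
  list(model = model, history = history)
}

#' Save / load a model checkpoint
#'
#' A checkpoint is the configuration plus all named parameter arrays and
#' normalisation state in one RDS file; a text summary with the parameter
#' count and fp32 size is written alongside.
#'
#' @param model a model object.
#' @param path RDS path.
#' @return invisibly, the path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  n <- count_parameters(model)
  writeLines(c(paste("type:", model$type),
               paste("parameters:", n),
               paste("fp32 size (MiB):", model_size_mib(n))),
             paste0(path, ".txt"))
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)

# deterministic inference: preprocessed [0,255] image -> organ mask
predict_organ <- function(model, samples, batch_size = 16L, threshold = 0.5) {
  out <- vector("list", length(samples))
  for (b in split(seq_along(samples),
                  ceiling(seq_along(samples) / batch_size))) {
    bt <- stack_batch(samples[b])
    fwd <- model_forward(model, bt$x, train = FALSE)
    for (k in seq_along(b)) {
      out[[b[k]]] <- (fwd$prob[, , k, 1L] > threshold) * 1L
    }
  }
  out
}

# no-leakage mass-track inference: consumes the image and the ORGAN TRACK's
# prediction only — ground-truth masks never enter this path
predict_mass <- function(pdn_model, vhu_model, samples, batch_size = 16L,
                         threshold = 0.5) {
  organ_masks <- predict_organ(vhu_model, samples, batch_size, threshold)
  masked <- lapply(seq_along(samples), function(k) {
    list(image = mask_organ_image(samples[[k]]$image, organ_masks[[k]]))
  })
  masses <- vector("list", length(samples))
  for (b in split(seq_along(masked),
                  ceiling(seq_along(masked) / batch_size))) {
    bt <- stack_batch(masked[b])
    fwd <- model_forward(pdn_model, bt$x, train = FALSE)
    for (k in seq_along(b)) {
      masses[[b[k]]] <- (fwd$prob[, , k, 1L] > pdn_model$cfg$threshold) * 1L
    }
  }
  list(organ = organ_masks, mass = masses)
}

#' Run the full dual-track experiment on a dataset
#'
#' Splits the dataset, trains the organ track on (image, organ mask), builds
#' organ-masked images from the *trained organ track's predictions* (the
#' no-leakage contract: ground-truth masks never feed the mass track's
#' inference input), trains the mass track on them, and evaluates the fused
#' three-label segmentation on the held-out test split.
#'
#' @param dataset list of \code{sample_pair}s with organ and mass masks.
#' @param cfg a [train_config()].
#' @param preprocess apply the deterministic contrast enhancement to every
#'   image before training/inference.
#' @param quiet suppress progress lines.
#' @return list with the two trained models, their histories, the test-set
#'   \code{report} (organ metrics), \code{mass_report} (fused mass metrics),
#'   \code{pdn_mass_report} (mass metrics before fusion), the fused labeled
#'   masks and the split.
#' @export
run_dual_track <- function(dataset, cfg = train_config(), preprocess = TRUE,
                           quiet = FALSE) {
  if (any(vapply(dataset, function(s) is.null(s$mass_mask), logical(1)))) {
    stop("dataset lacks mass masks; generate phantoms (see generate_samples)")
  }
  ids <- vapply(dataset, `[[`, character(1), "id")
  sp <- split_ids(ids, cfg$r_val, cfg$r_test, shuffle_seed = cfg$seed)
  if (preprocess) {
    pp <- preprocess_config(target_size = dim(dataset[[1L]]$mask))
    dataset <- lapply(dataset, function(s) {
      s$image <- enhance_contrast(s$image, pp)
      s
    })
  }
  by_id <- stats::setNames(dataset, ids)
  train_s <- by_id[sp$train]; val_s <- by_id[sp$val]; test_s <- by_id[sp$test]

  preset <- cfg$input_preset
  vhu <- vhunet_init(vhunet_preset(if (preset == "desk-64") "desk-64"
                                   else if (preset == "gray-256") "gray-256"
                                   else "rgb-224"), seed = cfg$seed)
  t1 <- train_model(vhu, train_s, target = "mask", cfg = cfg,
                    val_dataset = val_s, quiet = quiet)

  # sequential curriculum: the mass track trains on masked images built from
  # the already-trained organ track's predictions
  masked_inputs <- function(samples) {
    organ_pred <- predict_organ(t1$model, samples, cfg$batch_size,
                                cfg$threshold)
    lapply(seq_along(samples), function(k) {
      s <- samples[[k]]
      s$image <- mask_organ_image(s$image, organ_pred[[k]])
      s
    })
  }
  pdn <- pdn_init(pdn_preset(if (preset == "desk-64") "desk-64"
                             else "gray-256"), seed = cfg$seed + 1L)
  t2 <- train_model(pdn, masked_inputs(train_s), target = "mass_mask",
                    cfg = cfg, val_dataset = masked_inputs(val_s),
                    quiet = quiet)

  pred <- predict_mass(t2$model, t1$model, test_s, cfg$batch_size,
                       cfg$threshold)
  fused <- lapply(seq_along(test_s), function(k) {
    fuse_masks(pred$organ[[k]], pred$mass[[k]])
  })
  gt_organ <- lapply(test_s, `[[`, "mask")
  gt_mass <- lapply(test_s, `[[`, "mass_mask")
  fused_layers <- lapply(fused, label_layers)
  report <- evaluate_masks(lapply(fused_layers, `[[`, "organ"), gt_organ,
                           ids = sp$test)
  mass_report <- evaluate_masks(lapply(fused_layers, `[[`, "mass"), gt_mass,
                                ids = sp$test, boundary = FALSE)
  pdn_mass_report <- evaluate_masks(pred$mass, gt_mass, ids = sp$test,
                                    boundary = FALSE)
  list(vhu = t1$model, pdn = t2$model,
       history_vhu = t1$history, history_pdn = t2$history,
       report = report, mass_report = mass_report,
       pdn_mass_report = pdn_mass_report,
       fused = fused, split = sp)
}

#' Segment images on disk with trained checkpoints
#'
#' Loads PNGs, applies the deterministic contrast enhancement, runs both
#' tracks (the mass track on the organ-masked image from the organ track's
#' prediction), fuses, and writes a labeled PNG plus a colour overlay per
#' image. Deterministic for fixed checkpoints.
#'
#' @param input a directory of PNGs or a vector of PNG paths.
#' @param vhu,pdn trained models (or RDS checkpoint paths).
#' @param out_dir output directory.
#' @param threshold organ probability threshold.
#' @return invisibly, a data.frame of written paths.
#' @export
segment_images <- function(input, vhu, pdn, out_dir, threshold = 0.5) {
  if (is.character(vhu)) vhu <- load_checkpoint(vhu)
  if (is.character(pdn)) pdn <- load_checkpoint(pdn)
  paths <- if (length(input) == 1L && dir.exists(input)) {
    list.files(input, pattern = "\\.png$", full.names = TRUE)
  } else input
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  expect <- vhu$cfg$input_size
  rows <- lapply(paths, function(p) {
    img <- load_image(p)
    spd <- if (length(dim(img)) == 3L) dim(img)[1:2] else dim(img)
    if (!identical(as.integer(spd), expect)) {
      stop("image ", basename(p), " is ", paste(spd, collapse = "x"),
           " but the checkpoint expects ", paste(expect, collapse = "x"))
    }
    img <- enhance_contrast(img)
    s <- list(list(id = basename(p), image = img))
    pred <- predict_mass(pdn, vhu, s, threshold = threshold)
    labeled <- fuse_masks(pred$organ[[1L]], pred$mass[[1L]])
    stem <- sub("\\.png$", "", basename(p))
    mask_path <- file.path(out_dir, paste0(stem, "_labels.png"))
    overlay_path <- file.path(out_dir, paste0(stem, "_overlay.png"))
    save_labeled_mask(labeled, mask_path)
    gray <- if (length(dim(img)) == 3L) img[, , 1L] else img
    save_overlay(gray, labeled, overlay_path)
    data.frame(id = stem, labels = mask_path, overlay = overlay_path,
               stringsAsFactors = FALSE)
  })
  invisible(do.call(rbind, rows))
}
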