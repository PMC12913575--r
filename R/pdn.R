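#' Configuration for the contrast-driven protuberance detection track
#'
#' Track 2 receives the organ-masked image and segments the protuberant mass.
#' A convolutional stem is followed by \code{pool_stages} repetitions of
#' stride-2 max pooling, a centre-surround contrast operator (the feature map
#' minus its local 3x3 window average) and a widening convolution; the final
#' contrast features are refined by a depthwise-separable convolution with
#' batch normalisation and LeakyReLU, the two branches are concatenated, and
#' a 1x1 convolution + sigmoid gives a coarse probability map which is
#' bilinearly upsampled and thresholded.
#'
#' At the published 256 x 256 configuration the ladder prints
#' 16x16x1024 (contrast) -> 16x16x1536 (fused) -> 16x16x1 (probability).
#'
#' @param input_size integer pair (default 256 x 256).
#' @param in_channels image channels.
#' @param stage_widths stem width followed by the pooling-stage widths
#'   (before division by \code{width_divisor}).
#' @param contrast_width channel count of the final contrast features.
#' @param border_width channel count of the boundary-refined branch.
#' @param pool_stages number of stride-2 pooling stages.
#' @param leaky_slope negative slope of the LeakyReLU.
#' @param threshold probability threshold tau in (0, 1); the mask rule is
#'   strictly greater than tau.
#' @param width_divisor integer >= 1 desk-scale shrink.
#' @return a list of class \code{pdn_config}.
#' @export
pdn_config <- function(input_size = c(256L, 256L), in_channels = 1L,
                       stage_widths = c(64L, 128L, 256L, 512L),
                       contrast_width = 1024L, border_width = 512L,
                       pool_stages = 4L, leaky_slope = 0.01,
                       threshold = 0.5, width_divisor = 1L) {
  stopifnot(threshold > 0, threshold < 1, width_divisor >= 1L,
            pool_stages >= 1L)
  if (any(input_size %% 2L^pool_stages != 0L)) {
    stop("input_size must be divisible by 2^pool_stages = ", 2L^pool_stages)
  }
  widths <- as.integer(stage_widths %/% width_divisor)
  structure(list(input_size = as.integer(input_size),
                 in_channels = as.integer(in_channels),
                 stage_widths = widths,
                 contrast_width = as.integer(contrast_width %/% width_divisor),
                 border_width = as.integer(border_width %/% width_divisor),
                 pool_stages = as.integer(pool_stages),
                 leaky_slope = leaky_slope,
                 threshold = threshold,
                 width_divisor = as.integer(width_divisor)),
            class = "pdn_config")
}

#' Named configuration presets for the mass track
#'
#' \code{"gray-256"} is the published configuration (four pooling stages,
#' contrast width 1024, border width 512). \code{"desk-64"} uses 64 x 64
#' inputs, \code{width_divisor = 4} and three pooling stages, keeping the
#' coarse probability grid at 1/8 of the input so that masses a few pixels
#' across remain resolvable.
#'
#' @param name one of \code{"gray-256"}, \code{"desk-64"}.
#' @return a \code{pdn_config}.
#' @export
pdn_preset <- function(name = c("gray-256", "desk-64")) {
  name <- match.arg(name)
  switch(name,
    "gray-256" = pdn_config(),
    "desk-64" = pdn_config(input_size = c(64L, 64L), width_divisor = 4L,
                           pool_stages = 3L)
  )
}

# channel ladder of the pooling stages: widen through the tail of
# stage_widths and finish at contrast_width
.pdn_stage_channels <- function(cfg) {
  tail_w <- cfg$stage_widths[-1L]
  n <- cfg$pool_stages
  c(utils::head(tail_w, n - 1L), cfg$contrast_width)
}

#' Initialise mass-track network parameters
#'
#' @param cfg a [pdn_config()].
#' @param seed integer seed.
#' @return a model object: \code{list(cfg, params, state)}.
#' @export
pdn_init <- function(cfg, seed = 1L) {
  with_seed(seed, {
    w0 <- cfg$stage_widths[1L]
    chans <- .pdn_stage_channels(cfg)
    params <- list(
      stem = list(W = he_conv(3L, cfg$in_channels, w0), b = rep(0, w0),
                  bn = batchnorm_init(w0)),
      stages = {
        cin <- w0
        lapply(seq_len(cfg$pool_stages), function(s) {
          p <- list(W = he_conv(3L, cin, chans[s]), b = rep(0, chans[s]))
          cin <<- chans[s]
          p
        })
      },
      refine = list(dwW = array(stats::rnorm(9L * cfg$contrast_width,
                                             sd = sqrt(2 / 9)),
                                c(3L, 3L, cfg$contrast_width)),
                    dwb = rep(0, cfg$contrast_width),
                    pwW = glorot_mat(cfg$contrast_width, cfg$border_width),
                    pwb = rep(0, cfg$border_width),
                    bn = batchnorm_init(cfg$border_width)),
      head = list(W = glorot_mat(cfg$contrast_width + cfg$border_width, 1L),
                  b = 0)
    )
    state <- list(stem = batchnorm_state(w0),
                  refine = batchnorm_state(cfg$border_width))
    structure(list(cfg = cfg, params = params, state = state, type = "pdn"),
              class = "dualseg_model")
  })
}

## ---- module operations ----

#' Stem transform of the mass track
#'
#' 3x3 convolution, batch normalisation and ReLU; spatial size preserved,
#' channels = first stage width, all outputs non-negative.
#'
#' @param masked_image organ-masked image \code{(H, W, C)} or batch
#'   \code{(H, W, N, C)}, see [mask_organ_image()].
#' @param model a [pdn_init()] model.
#' @return stem feature map.
#' @export
pdn_stem <- function(masked_image, model) {
  x <- as_feature_batch(masked_image)
  x$restore(stem_fwd(model, x$x, train = FALSE, keep_cache = FALSE)$y)
}

stem_fwd <- function(model, x, train, keep_cache = TRUE) {
  p <- model$params$stem
  pre <- conv2d_fwd(x, p$W, p$b)
  bn <- batchnorm_fwd(pre, p$bn, model$state$stem, train)
  y <- relu_fwd(bn$y)
  list(y = y, state = bn$state,
       cache = if (keep_cache) list(x = x, bn = bn$cache, bny = bn$y) else NULL)
}

stem_bwd <- function(model, dy, cache) {
  dbn <- relu_bwd(dy, cache$bny)
  bnb <- batchnorm_bwd(dbn, model$params$stem$bn, cache$bn)
  cb <- conv2d_bwd(cache$x, model$params$stem$W, bnb$dx)
  list(dx = cb$dx, grads = list(W = cb$dW, b = cb$db, bn = bnb$grads))
}

#' Multiscale pooling and contrast stage ladder
#'
#' Each stage applies stride-2 max pooling, the centre-surround contrast
#' operator \code{x - boxavg3(x)} (count-normalised at borders so a constant
#' map maps to exactly zero), then a widening 3x3 convolution with ReLU.
#' After \code{pool_stages} stages the spatial size is
#' \code{input / 2^pool_stages} with \code{contrast_width} channels.
#'
#' @param f stem feature map.
#' @param model the model.
#' @return contrast feature map.
#' @export
multiscale_contrast <- function(f, model) {
  x <- as_feature_batch(f)
  x$restore(contrast_fwd(model, x$x, keep_cache = FALSE)$y)
}

contrast_fwd <- function(model, x, keep_cache = TRUE) {
  p <- model$params$stages
  caches <- vector("list", length(p))
  for (s in seq_along(p)) {
    if (any(dim(x)[1:2] %% 2L != 0L)) {
      stop("stage ", s, ": spatial dims ", paste(dim(x)[1:2], collapse = "x"),
           " not divisible by 2")
    }
    mp <- maxpool2_fwd(x)
    dlt <- contrast_delta_fwd(mp$y)
    pre <- conv2d_fwd(dlt, p[[s]]$W, p[[s]]$b)
    y <- relu_fwd(pre)
    caches[[s]] <- if (keep_cache) list(in_dim = dim(x), sel = mp$sel,
                                        dlt = dlt, pre = pre) else NULL
    x <- y
  }
  list(y = x, cache = caches)
}

contrast_bwd <- function(model, dy, cache) {
  p <- model$params$stages
  grads <- vector("list", length(p))
  for (s in rev(seq_along(p))) {
    ct <- cache[[s]]
    dpre <- relu_bwd(dy, ct$pre)
    cb <- conv2d_bwd(ct$dlt, p[[s]]$W, dpre)
    ddlt <- contrast_delta_bwd(cb$dx)
    dy <- maxpool2_bwd(ddlt, ct$sel, ct$in_dim)
    grads[[s]] <- list(W = cb$dW, b = cb$db)
  }
  list(dx = dy, grads = grads)
}

#' Boundary refinement of the contrast features
#'
#' Depthwise-separable convolution (3x3 depthwise, then 1x1 pointwise to the
#' border width), batch normalisation and LeakyReLU; spatial size preserved.
#'
#' @param contrast_f output of [multiscale_contrast()].
#' @param model the model.
#' @return border-refined feature map with \code{border_width} channels.
#' @export
boundary_refine <- function(contrast_f, model) {
  x <- as_feature_batch(contrast_f)
  x$restore(refine_fwd(model, x$x, train = FALSE, keep_cache = FALSE)$y)
}

refine_fwd <- function(model, x, train, keep_cache = TRUE) {
  p <- model$params$refine
  dw <- dwconv2d_fwd(x, p$dwW, p$dwb)
  d <- dim(dw)
  pw <- ts_unmat(sweep(ts_mat(dw) %*% p$pwW, 2L, p$pwb, `+`),
                 d[1L], d[2L], d[3L])
  bn <- batchnorm_fwd(pw, p$bn, model$state$refine, train)
  y <- leaky_relu_fwd(bn$y, model$cfg$leaky_slope)
  list(y = y, state = bn$state,
       cache = if (keep_cache) list(x = x, dw = dw, bn = bn$cache,
                                    bny = bn$y) else NULL)
}

refine_bwd <- function(model, dy, cache) {
  p <- model$params$refine
  dbn <- leaky_relu_bwd(dy, cache$bny, model$cfg$leaky_slope)
  bnb <- batchnorm_bwd(dbn, p$bn, cache$bn)
  dpwm <- ts_mat(bnb$dx)
  gpwW <- crossprod(ts_mat(cache$dw), dpwm)
  gpwb <- colSums(dpwm)
  d <- dim(cache$dw)
  ddw <- ts_unmat(dpwm %*% t(p$pwW), d[1L], d[2L], d[3L])
  dwb <- dwconv2d_bwd(cache$x, p$dwW, ddw)
  list(dx = dwb$dx,
       grads = list(dwW = dwb$dW, dwb = dwb$db, pwW = gpwW, pwb = gpwb,
                    bn = bnb$grads))
}

#' Fusion head of the mass track
#'
#' Concatenates the contrast and border branches along channels, applies a
#' 1x1 convolution to one channel and a sigmoid, bilinearly upsamples the
#' probability map to \code{out_size}, and thresholds strictly at tau.
#'
#' @param border_f border-refined feature map.
#' @param contrast_f contrast feature map (same spatial size).
#' @param model the model.
#' @param out_size integer pair, output mask size.
#' @return list with \code{prob} (upsampled probability map), \code{prob_coarse}
#'   (pre-upsampling map), and \code{mask} (binary mass mask, rule
#'   \code{prob > threshold}).
#' @export
pdn_head <- function(border_f, contrast_f, model, out_size = model$cfg$input_size) {
  b <- as_feature_batch(border_f)
  cf <- as_feature_batch(contrast_f)
  if (!identical(dim(b$x)[1:3], dim(cf$x)[1:3])) {
    stop("border (", paste(dim(b$x)[1:2], collapse = "x"), ") and contrast (",
         paste(dim(cf$x)[1:2], collapse = "x"), ") maps must share spatial dims")
  }
  hf <- pdn_head_fwd(model, cf$x, b$x, out_size)
  list(prob = b$restore(hf$prob),
       prob_coarse = b$restore(hf$coarse),
       mask = b$restore(hf$prob > model$cfg$threshold) * 1)
}

pdn_head_fwd <- function(model, contrast, border, out_size) {
  p <- model$params$head
  fused <- c_bind_channels(contrast, border)
  d <- dim(fused)
  z <- ts_mat(fused) %*% p$W + as.vector(p$b)
  coarse <- ts_unmat(1 / (1 + exp(-z)), d[1L], d[2L], d[3L])
  prob <- bilinear_upsample_fwd(coarse, out_size[1L], out_size[2L])
  list(fused = fused, coarse = coarse, prob = prob)
}

pdn_head_bwd <- function(model, dprob, cache) {
  dcoarse <- bilinear_upsample_bwd(dprob, dim(cache$coarse)[1L],
                                   dim(cache$coarse)[2L])
  dz <- ts_mat(dcoarse) * ts_mat(cache$coarse) * (1 - ts_mat(cache$coarse))
  p <- model$params$head
  dfused <- ts_unmat(dz %*% t(p$W), dim(cache$fused)[1L],
                     dim(cache$fused)[2L], dim(cache$fused)[3L])
  cw <- model$cfg$contrast_width
  list(dcontrast = dfused[, , , seq_len(cw), drop = FALSE],
       dborder = dfused[, , , -seq_len(cw), drop = FALSE],
       grads = list(W = crossprod(ts_mat(cache$fused), dz), b = sum(dz)))
}

c_bind_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1L], da[2L], da[3L], da[4L] + db[4L]))
  out[, , , seq_len(da[4L])] <- a
  out[, , , da[4L] + seq_len(db[4L])] <- b
  out
}

#' Full forward pass of the mass track
#'
#' @param model a [pdn_init()] model.
#' @param masked_image organ-masked image or batch.
#' @param train training mode (batch statistics + caches).
#' @return list with \code{prob} (full-resolution probability map),
#'   \code{mask} (thresholded binary mask), updated \code{state}, and a
#'   \code{cache} when training.
#' @export
pdn_forward <- function(model, masked_image, train = FALSE) {
  x <- as_feature_batch(masked_image)$x
  st <- stem_fwd(model, x, train, keep_cache = train)
  model$state$stem <- st$state
  co <- contrast_fwd(model, st$y, keep_cache = train)
  rf <- refine_fwd(model, co$y, train, keep_cache = train)
  model$state$refine <- rf$state
  hd <- pdn_head_fwd(model, co$y, rf$y, dim(x)[1:2])
  list(prob = hd$prob, mask = (hd$prob > model$cfg$threshold) * 1,
       state = model$state,
       cache = if (train) list(stem = st$cache, contrast = co$cache,
                               refine = rf$cache, head = hd) else NULL)
}

#' Backward pass of the mass track
#'
#' @param model the model used forward.
#' @param fwd result of \code{pdn_forward(..., train = TRUE)}.
#' @param dprob gradient w.r.t. the full-resolution probability map.
#' @return gradients mirroring \code{model$params}.
#' @export
pdn_backward <- function(model, fwd, dprob) {
  hb <- pdn_head_bwd(model, dprob, fwd$cache$head)
  rb <- refine_bwd(model, hb$dborder, fwd$cache$refine)
  dcontrast <- hb$dcontrast + rb$dx
  cb <- contrast_bwd(model, dcontrast, fwd$cache$contrast)
  sb <- stem_bwd(model, cb$dx, fwd$cache$stem)
  list(stem = sb$grads, stages = cb$grads, refine = rb$grads, head = hb$grads)
}
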