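#' Configuration for the transformer-enhanced U-Net organ track
#'
#' Builds the configuration for Track 1: a U-Net whose encoder interleaves
#' vision-transformer attention blocks with multi-scale (HRNet-style)
#' convolution blocks. The patch embedding performs the first spatial
#' halving (patch size \code{P = 2}), and three stride-2 max pools complete
#' the resolution ladder, e.g. 224 -> 112 -> 56 -> 28 -> 14 at the default
#' input size with stage widths 64/128/256/512 and a 1024-channel bridge.
#'
#' @param input_size integer pair, input height and width (default 224 x 224).
#' @param in_channels number of image channels.
#' @param patch_size patch embedding size/stride \code{P}.
#' @param stage_widths channel widths of the four encoder stages (before
#'   division by \code{width_divisor}).
#' @param bridge_width bridge (bottleneck) channel count before division.
#' @param embed_dim patch-embedding dimension; defaults to the first stage
#'   width after division.
#' @param attn_heads number of self-attention heads.
#' @param ffn_expansion expansion factor of the transformer feed-forward layer.
#' @param hrnet_kernels kernel sizes of the parallel multi-scale convolutions.
#' @param width_divisor integer >= 1; divides all widths for desk-scale runs.
#' @param attn_token_limit attention operates on a token grid average-pooled
#'   (by the smallest power-of-two factor) to at most this many tokens, with
#'   the attention output broadcast back to the full grid. Set
#'   \code{options(dualseg.verbose = TRUE)} to be notified when pooling is
#'   active.
#' @return a list of class \code{vhunet_config}.
#' @export
vhunet_config <- function(input_size = c(224L, 224L), in_channels = 3L,
                          patch_size = 2L,
                          stage_widths = c(64L, 128L, 256L, 512L),
                          bridge_width = 1024L,
                          embed_dim = NULL,
                          attn_heads = 4L, ffn_expansion = 2L,
                          hrnet_kernels = c(1L, 3L, 5L),
                          width_divisor = 1L,
                          attn_token_limit = 4096L) {
  stopifnot(width_divisor >= 1L, length(input_size) == 2L,
            length(stage_widths) == 4L)
  widths <- as.integer(stage_widths %/% width_divisor)
  bw <- as.integer(bridge_width %/% width_divisor)
  if (is.null(embed_dim)) embed_dim <- widths[1L]
  if (any(input_size %% (patch_size * 2L^(length(widths) - 1L)) != 0L)) {
    stop("input_size must be divisible by patch_size * 2^", length(widths) - 1L,
         " = ", patch_size * 2L^(length(widths) - 1L))
  }
  if (embed_dim %% attn_heads != 0L) {
    stop("embed_dim must be divisible by attn_heads")
  }
  structure(list(input_size = as.integer(input_size),
                 in_channels = as.integer(in_channels),
                 patch_size = as.integer(patch_size),
                 stage_widths = widths, bridge_width = bw,
                 embed_dim = as.integer(embed_dim),
                 attn_heads = as.integer(attn_heads),
                 ffn_expansion = as.integer(ffn_expansion),
                 hrnet_kernels = as.integer(hrnet_kernels),
                 width_divisor = as.integer(width_divisor),
                 attn_token_limit = as.integer(attn_token_limit)),
            class = "vhunet_config")
}

#' Named configuration presets for the organ track
#'
#' \code{"rgb-224"}: 224 x 224 x 3 input with full stage widths 64..512 and a
#' 1024-channel bridge. \code{"gray-256"}: 256 x 256 x 1 input with widths
#' 16..128 and a 128-channel bridge (the two published configurations are
#' contradictory; both are kept as presets). \code{"desk-64"}: 64 x 64 x 1
#' input, \code{width_divisor = 4}, attention token grids pooled to at most
#' 256 tokens — a configuration small enough to train on one CPU core.
#'
#' @param name one of \code{"rgb-224"}, \code{"gray-256"}, \code{"desk-64"}.
#' @return a \code{vhunet_config}.
#' @export
vhunet_preset <- function(name = c("rgb-224", "gray-256", "desk-64")) {
  name <- match.arg(name)
  switch(name,
    "rgb-224" = vhunet_config(),
    "gray-256" = vhunet_config(input_size = c(256L, 256L), in_channels = 1L,
                               stage_widths = c(16L, 32L, 64L, 128L),
                               bridge_width = 128L),
    "desk-64" = vhunet_config(input_size = c(64L, 64L), in_channels = 1L,
                              width_divisor = 4L, attn_token_limit = 256L)
  )
}

#' Initialise organ-track network parameters
#'
#' He-normal initialisation for convolution kernels, Glorot for attention and
#' feed-forward matrices, zero biases, zero positional table.
#'
#' @param cfg a [vhunet_config()].
#' @param seed integer seed for reproducible initialisation.
#' @return a model object: \code{list(cfg, params, state)}.
#' @export
vhunet_init <- function(cfg, seed = 1L) {
  with_seed(seed, {
    P <- cfg$patch_size
    hp <- cfg$input_size[1L] %/% P
    wp <- cfg$input_size[2L] %/% P
    E <- cfg$embed_dim
    w <- cfg$stage_widths
    params <- list(
      emb = list(W = he_conv(P, cfg$in_channels, E),
                 b = rep(0, E),
                 pos = array(0, c(hp, wp, 1L, E))),
      enc = lapply(seq_along(w), function(s) {
        cin <- if (s == 1L) E else w[s - 1L]
        list(vit = vit_block_params(cin, heads = cfg$attn_heads,
                                    expansion = cfg$ffn_expansion),
             hr = hrnet_block_params(cin, w[s], kernels = cfg$hrnet_kernels))
      }),
      bridge = list(W = he_conv(3L, w[4L], cfg$bridge_width),
                    b = rep(0, cfg$bridge_width)),
      dec = {
        cins <- c(cfg$bridge_width, w[3L], w[2L], w[1L])
        couts <- c(w[3L], w[2L], w[1L], E)
        skips <- c(w[3L], w[2L], w[1L], NA)
        lapply(1:4, function(t) {
          p <- list(tcW = array(stats::rnorm(4L * cins[t] * couts[t],
                                             sd = sqrt(2 / (4 * cins[t]))),
                                c(2L, 2L, cins[t], couts[t])),
                    tcb = rep(0, couts[t]),
                    convW = he_conv(3L, couts[t], couts[t]),
                    convb = rep(0, couts[t]))
          if (!is.na(skips[t])) {
            p$skipW <- glorot_mat(skips[t], couts[t])
            p$skipb <- rep(0, couts[t])
          }
          p
        })
      },
      head = list(W = glorot_mat(E, 1L), b = 0)
    )
    state <- list(enc = lapply(seq_along(w),
                               function(s) batchnorm_state(w[s])))
    structure(list(cfg = cfg, params = params, state = state, type = "vhunet"),
              class = "dualseg_model")
  })
}

## ---- exported building blocks ----

#' Parameters for a standalone vision-transformer block
#'
#' @param channels token channel count.
#' @param heads attention heads (channels must be divisible by heads).
#' @param expansion feed-forward expansion factor.
#' @param seed optional seed; when given, initialisation is reproducible.
#' @return nested parameter list (two layer norms, attention, feed-forward).
#' @export
vit_block_params <- function(channels, heads = 4L, expansion = 2L, seed = NULL) {
  stopifnot(channels %% heads == 0L)
  build <- function() list(ln1 = layernorm_init(channels),
                           attn = mhsa_init(channels),
                           ln2 = layernorm_init(channels),
                           ffn = ffn_init(channels, expansion))
  if (is.null(seed)) build() else with_seed(seed, build())
}

#' Parameters for a standalone multi-scale convolution block
#'
#' @param in_channels,out_channels channel contract of the block.
#' @param kernels kernel sizes of the parallel convolutions (summed).
#' @param seed optional seed.
#' @return list with per-scale kernels \code{Ws}, bias \code{b}, batch-norm
#'   weights \code{bn}.
#' @export
hrnet_block_params <- function(in_channels, out_channels, kernels = c(1L, 3L, 5L),
                               seed = NULL) {
  build <- function() list(
    Ws = lapply(kernels, function(k) he_conv(k, in_channels, out_channels)),
    b = rep(0, out_channels),
    bn = batchnorm_init(out_channels))
  if (is.null(seed)) build() else with_seed(seed, build())
}

.attn_pool_factor <- function(h, w, limit) {
  f <- 1L
  while ((h %/% f) * (w %/% f) > limit &&
         h %% (2L * f) == 0L && w %% (2L * f) == 0L) {
    f <- 2L * f
  }
  if (f > 1L && isTRUE(getOption("dualseg.verbose", FALSE))) {
    message("attention token grid pooled by factor ", f,
            " (", h, "x", w, " -> ", h %/% f, "x", w %/% f, ")")
  }
  f
}

vit_fwd <- function(x, p, heads, token_limit, keep_cache = TRUE) {
  d <- dim(x)
  f <- .attn_pool_factor(d[1L], d[2L], token_limit)
  ln1 <- layernorm_fwd(x, p$ln1)
  ap <- avgpoolf_fwd(ln1$y, f)
  at <- mhsa_fwd(ap, p$attn, heads, keep_cache = keep_cache)
  v <- x + nn_upsample_fwd(at$y, f)
  ln2 <- layernorm_fwd(v, p$ln2)
  ff <- ffn_fwd(ln2$y, p$ffn)
  y <- v + ff$y
  list(y = y,
       cache = if (keep_cache) list(ln1 = ln1$cache, attn = at$cache,
                                    ln2 = ln2$cache, ffn = ff$cache, f = f)
              else NULL)
}

vit_bwd <- function(dy, p, cache) {
  ffb <- ffn_bwd(dy, p$ffn, cache$ffn)
  ln2b <- layernorm_bwd(ffb$dx, p$ln2, cache$ln2)
  dv <- dy + ln2b$dx
  atb <- mhsa_bwd(nn_upsample_bwd(dv, cache$f), p$attn, cache$attn)
  ln1b <- layernorm_bwd(avgpoolf_bwd(atb$dx, cache$f), p$ln1, cache$ln1)
  list(dx = dv + ln1b$dx,
       grads = list(ln1 = ln1b$grads, attn = atb$grads,
                    ln2 = ln2b$grads, ffn = ffb$grads))
}

hr_fwd <- function(x, p, state, train, normalize = TRUE, keep_cache = TRUE) {
  pre <- NULL
  for (W in p$Ws) {
    y <- conv2d_fwd(x, W)
    pre <- if (is.null(pre)) y else pre + y
  }
  pre <- pre + rep(p$b, each = prod(dim(pre)[1:3]))
  if (normalize) {
    bn <- batchnorm_fwd(pre, p$bn, state, train)
    y <- relu_fwd(bn$y)
    list(y = y, state = bn$state,
         cache = if (keep_cache) list(x = x, pre = pre, bn = bn$cache,
                                      bny = bn$y) else NULL)
  } else {
    list(y = pre, state = state,
         cache = if (keep_cache) list(x = x, pre = pre) else NULL)
  }
}

hr_bwd <- function(dy, p, cache) {
  dbn <- relu_bwd(dy, cache$bny)
  bnb <- batchnorm_bwd(dbn, p$bn, cache$bn)
  dpre <- bnb$dx
  dWs <- vector("list", length(p$Ws))
  dx <- NULL
  for (i in seq_along(p$Ws)) {
    cb <- conv2d_bwd(cache$x, p$Ws[[i]], dpre)
    dWs[[i]] <- cb$dW
    dx <- if (is.null(dx)) cb$dx else dx + cb$dx
  }
  list(dx = dx,
       grads = list(Ws = dWs, b = colSums(ts_mat(dpre)), bn = bnb$grads))
}

#' Apply a vision-transformer block to a feature map
#'
#' Layer norm, multi-head self-attention and a residual add, then layer norm,
#' feed-forward and a second residual add. Shape preserving.
#'
#' @param f feature map, array \code{(H, W, N, C)} or \code{(H, W, C)} for a
#'   single sample.
#' @param params from [vit_block_params()].
#' @param heads attention heads.
#' @param attn_token_limit see [vhunet_config()].
#' @return feature map of the same shape as the input.
#' @export
vit_block <- function(f, params, heads = 4L, attn_token_limit = 4096L) {
  x <- as_feature_batch(f)
  y <- vit_fwd(x$x, params, heads, attn_token_limit, keep_cache = FALSE)$y
  x$restore(y)
}

#' Apply a multi-scale convolution block to a feature map
#'
#' Parallel same-padding convolutions at several kernel sizes are summed
#' (plus a bias), then optionally batch-normalised, then passed through ReLU.
#' With \code{normalize = FALSE} and \code{activation = FALSE} the raw summed
#' convolution (the block's pre-activation) is returned.
#'
#' @param f feature map as in [vit_block()].
#' @param params from [hrnet_block_params()].
#' @param normalize apply batch normalisation (batch statistics).
#' @param activation apply the ReLU nonlinearity.
#' @return feature map with the block's output channel count.
#' @export
hrnet_block <- function(f, params, normalize = TRUE, activation = TRUE) {
  x <- as_feature_batch(f)
  pre <- NULL
  for (W in params$Ws) {
    y <- conv2d_fwd(x$x, W)
    pre <- if (is.null(pre)) y else pre + y
  }
  pre <- pre + rep(params$b, each = prod(dim(pre)[1:3]))
  y <- pre
  if (normalize) {
    y <- batchnorm_fwd(y, params$bn, batchnorm_state(length(params$b)),
                       train = TRUE)$y
  }
  if (activation) y <- relu_fwd(y)
  x$restore(y)
}

# accept (H,W), (H,W,C) or (H,W,N,C); return batch + restorer.
# (H,W,C) -> (H,W,1,C) is a pure relabelling of dims: the column-major
# layouts coincide when N = 1.
as_feature_batch <- function(f) {
  d <- dim(f)
  if (is.null(d) || length(d) == 2L) {
    m <- as.matrix(f)
    x <- array(m, c(dim(m), 1L, 1L))
    restore <- function(y) if (dim(y)[4L] == 1L) y[, , 1L, 1L] else
      array(y, dim(y)[c(1L, 2L, 4L)])
  } else if (length(d) == 3L) {
    x <- array(f, c(d[1L], d[2L], 1L, d[3L]))
    restore <- function(y) array(y, dim(y)[c(1L, 2L, 4L)])
  } else {
    x <- f
    restore <- identity
  }
  list(x = x, restore = restore)
}

#' Patch embedding of an image batch
#'
#' Non-overlapping \code{P x P} patches are linearly projected to the
#' embedding dimension by a stride-\code{P} convolution and a learned additive
#' positional table is added; output spatial size is \code{input / P}.
#'
#' @param image array \code{(H, W, C)} or batch \code{(H, W, N, C)}, values on
#'   any scale (the network is trained on \code{[0, 1]}).
#' @param model a model from [vhunet_init()].
#' @return feature map \code{(H/P, W/P, N, embed_dim)}.
#' @export
patch_embed <- function(image, model) {
  x <- as_feature_batch(image)$x
  d <- dim(x)
  P <- model$cfg$patch_size
  if (any(d[1:2] %% P != 0L)) {
    stop("image spatial dims (", d[1L], "x", d[2L],
         ") must be divisible by the patch size P = ", P)
  }
  embed_fwd(x, model$params$emb)
}

embed_fwd <- function(x, p) {
  y <- patchify_fwd(x, p$W, p$b)
  n <- dim(y)[3L]
  y + p$pos[, , rep(1L, n), , drop = FALSE]
}

embed_bwd <- function(x, p, dy) {
  pb <- patchify_bwd(x, p$W, dy)
  n <- dim(dy)[3L]
  dpos <- dy
  if (n > 1L) {
    dpos <- array(rowSums(aperm(dy, c(1L, 2L, 4L, 3L)), dims = 3L),
                  c(dim(dy)[1L], dim(dy)[2L], 1L, dim(dy)[4L]))
  }
  list(dx = pb$dx, grads = list(W = pb$dW, b = pb$db, pos = dpos))
}

## ---- full network forward / backward ----

encode_fwd <- function(model, x, train = FALSE, keep_cache = TRUE) {
  cfg <- model$cfg
  p <- model$params
  st <- model$state
  caches <- list(emb_x = if (keep_cache) x else NULL)
  f <- embed_fwd(x, p$emb)
  skips <- vector("list", 4L)
  stage_caches <- vector("list", 4L)
  for (s in 1:4) {
    vb <- vit_fwd(f, p$enc[[s]]$vit, cfg$attn_heads, cfg$attn_token_limit,
                  keep_cache = keep_cache)
    hb <- hr_fwd(vb$y, p$enc[[s]]$hr, st$enc[[s]], train,
                 keep_cache = keep_cache)
    st$enc[[s]] <- hb$state
    skips[[s]] <- hb$y
    pool <- NULL
    if (s < 4L) {
      pool <- maxpool2_fwd(hb$y)
      f <- pool$y
    }
    stage_caches[[s]] <- list(vit = vb$cache, hr = hb$cache,
                              pool_sel = if (!is.null(pool)) pool$sel else NULL,
                              in_dim = dim(hb$y))
  }
  caches$stages <- stage_caches
  list(skips = skips, state = st, cache = if (keep_cache) caches else NULL)
}

encode_bwd <- function(model, cache, dskips, dtop) {
  # dtop: gradient flowing into the pooled output of stage 4 chain
  # dskips: list of gradients w.r.t. each stored skip output (may be NULL)
  p <- model$params
  grads_enc <- vector("list", 4L)
  dnext <- dtop  # gradient w.r.t. pooled feature entering stage s+1
  for (s in 4:1) {
    sc <- cache$stages[[s]]
    dy <- if (is.null(dskips[[s]])) array(0, sc$in_dim) else dskips[[s]]
    if (s < 4L && !is.null(dnext)) {
      dy <- dy + maxpool2_bwd(dnext, sc$pool_sel, sc$in_dim)
    }
    if (s == 4L && !is.null(dnext)) dy <- dy + dnext
    hb <- hr_bwd(dy, p$enc[[s]]$hr, sc$hr)
    vb <- vit_bwd(hb$dx, p$enc[[s]]$vit, sc$vit)
    grads_enc[[s]] <- list(vit = vb$grads, hr = hb$grads)
    dnext <- vb$dx
  }
  eb <- embed_bwd(cache$emb_x, p$emb, dnext)
  list(grads = list(emb = eb$grads, enc = grads_enc), dx = eb$dx)
}

bridge_fwd <- function(model, f4, keep_cache = TRUE) {
  p <- model$params$bridge
  pre <- conv2d_fwd(f4, p$W, p$b)
  list(y = relu_fwd(pre),
       cache = if (keep_cache) list(x = f4, pre = pre) else NULL)
}

bridge_bwd <- function(model, dy, cache) {
  dpre <- relu_bwd(dy, cache$pre)
  cb <- conv2d_bwd(cache$x, model$params$bridge$W, dpre)
  list(dx = cb$dx, grads = list(W = cb$dW, b = cb$db))
}

decode_fwd <- function(model, b, skips, train = FALSE, state = model$state,
                       keep_cache = TRUE) {
  p <- model$params$dec
  d <- b
  caches <- vector("list", 4L)
  for (t in 1:4) {
    pt <- p[[t]]
    u <- tconv2_fwd(d, pt$tcW, pt$tcb)
    s_in <- NULL
    if (!is.null(pt$skipW)) {
      s_in <- skips[[4L - t]]
      if (!identical(dim(u)[1:3], dim(s_in)[1:3])) {
        stop("decoder stage ", t, ": upsampled feature ",
             paste(dim(u)[1:2], collapse = "x"), " does not match skip ",
             paste(dim(s_in)[1:2], collapse = "x"))
      }
      spm <- ts_mat(s_in) %*% pt$skipW + rep(pt$skipb, each = prod(dim(u)[1:3]))
      u <- u + ts_unmat(spm, dim(u)[1L], dim(u)[2L], dim(u)[3L])
    }
    pre <- conv2d_fwd(u, pt$convW, pt$convb)
    y <- relu_fwd(pre)
    caches[[t]] <- if (keep_cache) list(d_in = d, u = u, s_in = s_in,
                                        pre = pre) else NULL
    d <- y
  }
  list(y = d, state = state, cache = caches)
}

decode_bwd <- function(model, dy, cache) {
  p <- model$params$dec
  grads <- vector("list", 4L)
  dskips <- vector("list", 4L)
  for (t in 4:1) {
    pt <- p[[t]]
    ct <- cache[[t]]
    dpre <- relu_bwd(dy, ct$pre)
    cb <- conv2d_bwd(ct$u, pt$convW, dpre)
    du <- cb$dx
    g <- list(tcW = NULL, tcb = NULL, convW = cb$dW, convb = cb$db)
    if (!is.null(pt$skipW)) {
      dum <- ts_mat(du)
      g$skipW <- crossprod(ts_mat(ct$s_in), dum)
      g$skipb <- colSums(dum)
      dsm <- dum %*% t(pt$skipW)
      dskips[[4L - t]] <- ts_unmat(dsm, dim(du)[1L], dim(du)[2L], dim(du)[3L])
    }
    tb <- tconv2_bwd(ct$d_in, pt$tcW, du)
    g$tcW <- tb$dW
    g$tcb <- tb$db
    grads[[t]] <- g
    dy <- tb$dx
  }
  list(dbridge = dy, dskips = dskips, grads = grads)
}

head_fwd <- function(model, feat) {
  p <- model$params$head
  z <- ts_mat(feat) %*% p$W + as.vector(p$b)
  y <- 1 / (1 + exp(-z))
  d <- dim(feat)
  list(y = ts_unmat(y, d[1L], d[2L], d[3L]))
}

head_bwd <- function(model, dy, feat, prob) {
  dz <- ts_mat(dy) * ts_mat(prob) * (1 - ts_mat(prob))
  p <- model$params$head
  d <- dim(feat)
  list(dx = ts_unmat(dz %*% t(p$W), d[1L], d[2L], d[3L]),
       grads = list(W = crossprod(ts_mat(feat), dz), b = sum(dz)))
}

#' Encoder forward pass returning the four stage features
#'
#' @param image image or batch (see [patch_embed()]).
#' @param model a [vhunet_init()] model.
#' @return list of four feature maps ordered shallow to deep, e.g.
#'   112x112x64, 56x56x128, 28x28x256, 14x14x512 for the default 224 preset.
#' @export
vhu_encode <- function(image, model) {
  x <- as_feature_batch(image)$x
  if (!identical(dim(x)[1:2], model$cfg$input_size)) {
    stop("image size ", paste(dim(x)[1:2], collapse = "x"),
         " does not match the configured input size ",
         paste(model$cfg$input_size, collapse = "x"))
  }
  encode_fwd(model, x, train = FALSE, keep_cache = FALSE)$skips
}

#' Bridge (bottleneck) convolution
#'
#' A 3x3 convolution widening the deepest encoder feature to the bridge
#' width, followed by ReLU; spatial size is preserved.
#'
#' @param f4 deepest encoder stage output.
#' @param model the model.
#' @return bridge feature map (e.g. 14x14x1024 at the 224 preset).
#' @export
vhu_bridge <- function(f4, model) {
  x <- as_feature_batch(f4)
  x$restore(bridge_fwd(model, x$x, keep_cache = FALSE)$y)
}

#' Decoder forward pass
#'
#' Four stages of transposed-convolution upsampling; the first three add a
#' 1x1-projected encoder skip at the matching resolution, and every stage
#' finishes with a 3x3 convolution and ReLU. Output is at the input
#' resolution with \code{embed_dim} channels.
#'
#' @param bridge_out the bridge feature map.
#' @param skips encoder stage features ordered shallow to deep, as returned
#'   by [vhu_encode()].
#' @param model the model.
#' @return decoded feature map, e.g. 224x224x64 at the default preset.
#' @export
vhu_decode <- function(bridge_out, skips, model) {
  b <- as_feature_batch(bridge_out)
  sk <- lapply(skips, function(s) as_feature_batch(s)$x)
  b$restore(decode_fwd(model, b$x, sk, keep_cache = FALSE)$y)
}

#' Per-pixel organ probability head
#'
#' A 1x1 convolution to one channel followed by a sigmoid; every output value
#' lies strictly in (0, 1).
#'
#' @param decoded decoder output feature map.
#' @param model the model.
#' @return probability map \code{(H, W, N, 1)} (or \code{(H, W)} for a single
#'   sample input).
#' @export
organ_head <- function(decoded, model) {
  x <- as_feature_batch(decoded)
  x$restore(head_fwd(model, x$x)$y)
}

#' Full forward pass of the organ track
#'
#' @param model a [vhunet_init()] model.
#' @param image image or batch.
#' @param train use batch statistics in the normalisation layers and keep the
#'   caches needed for a backward pass.
#' @return list with \code{prob} (probability map \code{(H, W, N, 1)}),
#'   \code{state} (updated running statistics) and, when \code{train = TRUE},
#'   a \code{cache} for [vhunet_backward()].
#' @export
vhunet_forward <- function(model, image, train = FALSE) {
  x <- as_feature_batch(image)$x
  enc <- encode_fwd(model, x, train = train, keep_cache = train)
  br <- bridge_fwd(model, enc$skips[[4L]], keep_cache = train)
  st <- enc$state
  st$dec <- model$state$dec
  dec <- decode_fwd(model, br$y, enc$skips, train = train, state = st,
                    keep_cache = train)
  hd <- head_fwd(model, dec$y)
  list(prob = hd$y, feat = dec$y, skips = enc$skips, state = dec$state,
       cache = if (train) list(enc = enc$cache, br = br$cache, dec = dec$cache,
                               feat = dec$y, skips4 = enc$skips[[4L]])
              else NULL)
}

#' Backward pass of the organ track
#'
#' @param model the model used in the forward pass.
#' @param fwd result of \code{vhunet_forward(..., train = TRUE)}.
#' @param dprob gradient of the loss with respect to the probability map.
#' @return gradients mirroring \code{model$params}.
#' @export
vhunet_backward <- function(model, fwd, dprob) {
  hb <- head_bwd(model, dprob, fwd$cache$feat, fwd$prob)
  db <- decode_bwd(model, hb$dx, fwd$cache$dec)
  bb <- bridge_bwd(model, db$dbridge, fwd$cache$br)
  dskips <- db$dskips
  dskips[[4L]] <- bb$dx
  eb <- encode_bwd(model, fwd$cache$enc, dskips, dtop = NULL)
  grads <- eb$grads
  grads$bridge <- bb$grads
  grads$dec <- db$grads
  grads$head <- hb$grads
  grads
}

#' Count learnable parameters of a model or parameter list
#'
#' Running batch-norm statistics are state, not parameters, and are excluded.
#'
#' @param model a model object or a (nested) parameter list.
#' @return integer parameter count.
#' @export
count_parameters <- function(model) {
  p <- if (!is.null(model$params)) model$params else model
  param_count(p)
}

#' Model size in MiB at a given parameter width
#'
#' \code{param_count * bytes_per_param / 2^20}, rounded half-up to two
#' decimals — the fp32 convention used when reporting model footprints.
#'
#' @param param_count non-negative parameter count.
#' @param bytes_per_param bytes per parameter (4 for fp32).
#' @return size in MiB with two decimals.
#' @export
model_size_mib <- function(param_count, bytes_per_param = 4L) {
  if (param_count < 0) stop("param_count must be non-negative")
  x <- param_count * bytes_per_param / 1048576
  floor(x * 100 + 0.5) / 100
}
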