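#' Preprocessing configuration
#'
#' @param clahe_clip_limit CLAHE clip limit (default 2.0).
#' @param clahe_tile_grid integer pair, CLAHE tile grid (default 8 x 8).
#' @param apply_clahe_prob probability of applying the contrast step inside a
#'   stochastic training stack; the deterministic inference path always
#'   applies it (probability 1).
#' @param target_size integer pair that [prepare_mask()] resizes to.
#' @param rescale_factor intensity rescale applied before the networks
#'   (default 1/255).
#' @return a list of class \code{preprocess_config}.
#' @export
preprocess_config <- function(clahe_clip_limit = 2.0,
                              clahe_tile_grid = c(8L, 8L),
                              apply_clahe_prob = 0.5,
                              target_size = c(224L, 224L),
                              rescale_factor = 1 / 255) {
  stopifnot(clahe_clip_limit > 0, all(clahe_tile_grid >= 1L),
            apply_clahe_prob >= 0, apply_clahe_prob <= 1)
  structure(list(clahe_clip_limit = clahe_clip_limit,
                 clahe_tile_grid = as.integer(clahe_tile_grid),
                 apply_clahe_prob = apply_clahe_prob,
                 target_size = as.integer(target_size),
                 rescale_factor = rescale_factor),
            class = "preprocess_config")
}

# global histogram equalization by cdf mapping on 256 bins; input/output
# on [0, 255]; monotone in intensity
hist_equalize <- function(x) {
  q <- pmin(pmax(as.integer(round(x)), 0L), 255L)
  h <- tabulate(q + 1L, nbins = 256L)
  cdf <- cumsum(h)
  cdf_min <- min(cdf[cdf > 0])
  n <- length(q)
  if (n == cdf_min) return(x * 0 + q[1L])  # single-level histogram
  map <- round((cdf - cdf_min) / (n - cdf_min) * 255)
  out <- map[q + 1L]
  out <- matrix(out, nrow(as.matrix(x)))
  dim(out) <- dim(x)
  out
}

#' Contrast enhancement: CLAHE followed by global histogram equalization
#'
#' Tile-wise contrast-limited adaptive histogram equalization, then a global
#' cdf-mapping equalization. Multi-channel images are enhanced on a luminance
#' channel and the channels rescaled proportionally; a constant image is
#' returned unchanged (degenerate histogram). Output stays within \[0, 255\]
#' and the global step is monotone in intensity.
#'
#' @param image matrix or H x W x C array on the raw \[0, 255\] scale.
#' @param cfg a [preprocess_config()].
#' @return enhanced image, same shape.
#' @export
enhance_contrast <- function(image, cfg = preprocess_config()) {
  if (any(!is.finite(image))) stop("image contains non-finite pixels")
  d <- dim(image)
  multi <- length(d) == 3L && d[3L] > 1L
  lum <- if (multi) {
    0.299 * image[, , 1L] + 0.587 * image[, , 2L] + 0.114 * image[, , 3L]
  } else if (length(d) == 3L) image[, , 1L] else image
  if (diff(range(lum)) == 0) return(image)
  cl <- EBImage::clahe(lum / 255, nx = cfg$clahe_tile_grid[1L],
                       ny = cfg$clahe_tile_grid[2L],
                       limit = cfg$clahe_clip_limit)
  cl <- pmin(pmax(as.numeric(cl), 0), 1)
  cl <- matrix(cl, nrow(lum), ncol(lum))
  he <- hist_equalize(cl * 255)
  if (!multi) {
    if (length(d) == 3L) return(array(he, d))
    return(he)
  }
  ratio <- he / pmax(lum, 1e-6)
  out <- image
  for (c in seq_len(d[3L])) out[, , c] <- pmin(pmax(image[, , c] * ratio, 0), 255)
  out
}

# nearest-neighbour resize with half-pixel centre alignment
resize_nn <- function(m, out_h, out_w) {
  h <- nrow(m); w <- ncol(m)
  ri <- pmin(pmax(ceiling((seq_len(out_h) - 0.5) * h / out_h), 1L), h)
  ci <- pmin(pmax(ceiling((seq_len(out_w) - 0.5) * w / out_w), 1L), w)
  m[ri, ci, drop = FALSE]
}

#' Prepare a mask: nearest-neighbour resize, no contrast operation
#'
#' Masks are carried through the preprocessing pipeline untouched except for
#' a nearest-neighbour resize to the target size; the output stays binary.
#'
#' @param mask binary matrix.
#' @param cfg a [preprocess_config()]; \code{cfg$target_size} is the output
#'   size.
#' @return binary matrix of the target size (bitwise-identical input when the
#'   size already matches).
#' @export
prepare_mask <- function(mask, cfg = preprocess_config()) {
  stopifnot(all(mask %in% c(0, 1)))
  if (identical(dim(mask), as.integer(cfg$target_size))) return(mask)
  resize_nn(mask, cfg$target_size[1L], cfg$target_size[2L])
}

#' Mask an image with a predicted organ mask
#'
#' Elementwise product; the mask is broadcast across image channels and
#' pixels where the mask is 0 become exactly 0. This is the no-leakage input
#' construction for the mass track: at inference the mask must come from the
#' organ track's prediction, never from ground truth.
#'
#' @param image matrix or H x W x C array.
#' @param predicted_mask binary matrix with the image's spatial dims.
#' @return masked image, same shape as the input.
#' @export
mask_organ_image <- function(image, predicted_mask) {
  d <- dim(image)
  sp <- if (length(d) == 3L) d[1:2] else d
  if (!identical(as.integer(sp), as.integer(dim(predicted_mask)))) {
    stop("image spatial dims ", paste(sp, collapse = "x"),
         " do not match mask dims ", paste(dim(predicted_mask), collapse = "x"))
  }
  if (length(d) == 3L) {
    out <- image
    for (c in seq_len(d[3L])) out[, , c] <- image[, , c] * predicted_mask
    out
  } else {
    image * predicted_mask
  }
}

#' Rescale an image from \[0, 255\] to \[0, 1\]
#'
#' @param image image on the raw scale.
#' @param cfg a [preprocess_config()] supplying the rescale factor.
#' @return rescaled image.
#' @export
rescale_image <- function(image, cfg = preprocess_config()) {
  image * cfg$rescale_factor
}
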