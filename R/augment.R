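#' Augmentation configuration
#'
#' Paired stochastic augmentation: horizontal/vertical flips, rotation within
#' a limit, brightness/contrast jitter (image only) and an elastic transform
#' (Gaussian-smoothed random displacement field plus a random affine jitter,
#' reflect border handling). The rotation limit defaults to 20 degrees, the
#' value the methodology states repeatedly; the alternative published value
#' of 15 degrees is reachable through this argument.
#'
#' @param p_hflip,p_vflip flip probabilities.
#' @param rotation_limit_degrees rotation drawn uniformly in +/- this limit.
#' @param p_rotate rotation probability.
#' @param p_brightness_contrast probability of intensity jitter.
#' @param brightness_limit,contrast_limit fractional jitter limits.
#' @param elastic_alpha displacement magnitude (pixels).
#' @param elastic_sigma Gaussian smoothing sigma of the displacement field.
#' @param elastic_alpha_affine corner jitter (pixels) of the random affine.
#' @param p_elastic elastic transform probability.
#' @param seed default rng state for [augment_pair()].
#' @return a list of class \code{augment_config}.
#' @export
augment_config <- function(p_hflip = 0.5, p_vflip = 0.5,
                           rotation_limit_degrees = 20, p_rotate = 0.5,
                           p_brightness_contrast = 0.3,
                           brightness_limit = 0.2, contrast_limit = 0.2,
                           elastic_alpha = 1, elastic_sigma = 50,
                           elastic_alpha_affine = 50, p_elastic = 0.3,
                           seed = 1L) {
  probs <- c(p_hflip, p_vflip, p_rotate, p_brightness_contrast, p_elastic)
  stopifnot(all(probs >= 0), all(probs <= 1), rotation_limit_degrees >= 0)
  structure(list(p_hflip = p_hflip, p_vflip = p_vflip,
                 rotation_limit_degrees = rotation_limit_degrees,
                 p_rotate = p_rotate,
                 p_brightness_contrast = p_brightness_contrast,
                 brightness_limit = brightness_limit,
                 contrast_limit = contrast_limit,
                 elastic_alpha = elastic_alpha,
                 elastic_sigma = elastic_sigma,
                 elastic_alpha_affine = elastic_alpha_affine,
                 p_elastic = p_elastic, seed = as.integer(seed)),
            class = "augment_config")
}

# sample an image at fractional source coordinates
# my, mx: matrices of source row/col coords; border: "zero" fills outside,
# "reflect" mirrors coordinates into the frame
warp_sample <- function(img, my, mx, method = c("bilinear", "nearest"),
                        border = c("zero", "reflect")) {
  method <- match.arg(method)
  border <- match.arg(border)
  h <- nrow(img); w <- ncol(img)
  if (border == "reflect") {
    reflect <- function(v, n) {
      v <- (v - 1) %% (2 * (n - 1))
      v <- ifelse(v > (n - 1), 2 * (n - 1) - v, v)
      v + 1
    }
    if (h > 1) my <- reflect(my, h) else my[] <- 1
    if (w > 1) mx <- reflect(mx, w) else mx[] <- 1
  }
  inside <- my >= 1 & my <= h & mx >= 1 & mx <= w
  myc <- pmin(pmax(my, 1), h)
  mxc <- pmin(pmax(mx, 1), w)
  if (method == "nearest") {
    out <- img[cbind(as.vector(round(myc)), as.vector(round(mxc)))]
  } else {
    y0 <- pmin(floor(myc), h - 1); x0 <- pmin(floor(mxc), w - 1)
    if (h == 1) y0[] <- 1
    if (w == 1) x0[] <- 1
    ty <- myc - y0; tx <- mxc - x0
    y1 <- pmin(y0 + 1, h); x1 <- pmin(x0 + 1, w)
    g <- function(yy, xx) img[cbind(as.vector(yy), as.vector(xx))]
    out <- (1 - ty) * (1 - tx) * g(y0, x0) + (1 - ty) * tx * g(y0, x1) +
           ty * (1 - tx) * g(y1, x0) + ty * tx * g(y1, x1)
  }
  out[!inside] <- 0
  matrix(out, h, w)
}

# realized geometric transform of one augmentation draw
sample_transform <- function(h, w, cfg) {
  tr <- list(hflip = stats::runif(1) < cfg$p_hflip,
             vflip = stats::runif(1) < cfg$p_vflip,
             angle = 0, bc = NULL, elastic = NULL)
  if (stats::runif(1) < cfg$p_rotate) {
    tr$angle <- stats::runif(1, -cfg$rotation_limit_degrees,
                             cfg$rotation_limit_degrees)
  }
  if (stats::runif(1) < cfg$p_brightness_contrast) {
    tr$bc <- c(brightness = stats::runif(1, -cfg$brightness_limit,
                                         cfg$brightness_limit),
               contrast = stats::runif(1, -cfg$contrast_limit,
                                       cfg$contrast_limit))
  }
  if (stats::runif(1) < cfg$p_elastic) {
    dy <- cfg$elastic_alpha * smooth_field(h, w, cfg$elastic_sigma / 8, 1)
    dx <- cfg$elastic_alpha * smooth_field(h, w, cfg$elastic_sigma / 8, 1)
    aa <- cfg$elastic_alpha_affine
    # random affine from jittered corner correspondences
    src <- rbind(c(h / 4, w / 4), c(h / 4, 3 * w / 4), c(3 * h / 4, w / 2))
    dst <- src + matrix(stats::runif(6, -aa, aa), 3, 2)
    A <- tryCatch(solve(cbind(src, 1), dst), error = function(e) NULL)
    tr$elastic <- list(dy = dy, dx = dx, A = A)
  }
  tr
}

# source-coordinate maps of the realized transform (output pixel -> input)
transform_coords <- function(h, w, tr) {
  my <- matrix(seq_len(h), h, w)
  mx <- matrix(seq_len(w), h, w, byrow = TRUE)
  if (!is.null(tr$elastic)) {
    if (!is.null(tr$elastic$A)) {
      P <- cbind(as.vector(my), as.vector(mx), 1) %*% tr$elastic$A
      my <- matrix(P[, 1L], h, w)
      mx <- matrix(P[, 2L], h, w)
    }
    my <- my + tr$elastic$dy
    mx <- mx + tr$elastic$dx
  }
  if (tr$angle != 0) {
    th <- tr$angle * pi / 180
    cy <- (h + 1) / 2; cx <- (w + 1) / 2
    y0 <- my - cy; x0 <- mx - cx
    my <- cy + cos(th) * y0 - sin(th) * x0
    mx <- cx + sin(th) * y0 + cos(th) * x0
  }
  if (tr$vflip) my <- (h + 1) - my
  if (tr$hflip) mx <- (w + 1) - mx
  list(my = my, mx = mx, elastic = !is.null(tr$elastic))
}

apply_transform <- function(m, tr, method) {
  co <- transform_coords(nrow(m), ncol(m), tr)
  border <- if (co$elastic) "reflect" else "zero"
  warp_sample(m, co$my, co$mx, method = method, border = border)
}

#' Paired stochastic augmentation of an image and its mask(s)
#'
#' One realized transform (flips, rotation, optional elastic warp) is applied
#' identically to the image (bilinear interpolation) and to every mask
#' (nearest neighbour, so outputs stay binary); brightness/contrast jitter
#' touches the image only. Given the same \code{rng_state} the output is
#' bitwise reproducible. The realized transform is attached as the
#' \code{"transform"} attribute.
#'
#' @param image matrix or H x W x C array on \[0, 255\].
#' @param mask binary matrix with the image's spatial dims.
#' @param cfg an [augment_config()].
#' @param rng_state integer seed of this draw (defaults to \code{cfg$seed}).
#' @param mass_mask optional second mask transformed identically.
#' @return list with \code{image}, \code{mask} and (when given) \code{mass_mask}.
#' @export
augment_pair <- function(image, mask, cfg = augment_config(),
                         rng_state = cfg$seed, mass_mask = NULL) {
  d <- dim(image)
  sp <- if (length(d) == 3L) d[1:2] else d
  stopifnot(identical(as.integer(sp), as.integer(dim(mask))))
  with_seed(rng_state, {
    tr <- sample_transform(sp[1L], sp[2L], cfg)
    warp_img <- function(m) apply_transform(m, tr, "bilinear")
    img <- if (length(d) == 3L) {
      out <- image
      for (c in seq_len(d[3L])) out[, , c] <- warp_img(image[, , c])
      out
    } else warp_img(image)
    if (!is.null(tr$bc)) {
      img <- pmin(pmax(img * (1 + tr$bc["contrast"]) +
                         tr$bc["brightness"] * 255, 0), 255)
    }
    out <- list(image = img,
                mask = apply_transform(mask, tr, "nearest"))
    if (!is.null(mass_mask)) {
      out$mass_mask <- apply_transform(mass_mask, tr, "nearest")
    }
    attr(out, "transform") <- tr
    out
  })
}
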