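#' Specification of the synthetic organ-with-mass phantom generator
#'
#' Each phantom is a grayscale slice containing a bright elliptical organ on
#' a dark background with a brighter disc-shaped mass attached, by default,
#' to the organ contour so that it protrudes — the geometry the protuberance
#' detector targets. The image is a piecewise-constant intensity map plus a
#' smooth Gaussian texture field plus independent Gaussian pixel noise,
#' clipped to \[0, 255\].
#'
#' @param image_size integer pair (default 64 x 64).
#' @param organ_axes_range range of the ellipse semi-axes in pixels.
#' @param mass_radius_range range of the mass disc radius in pixels (0
#'   allowed, giving an empty mass mask).
#' @param mass_on_boundary place the mass centre on the organ contour
#'   (default); otherwise strictly inside the organ.
#' @param intensity_bg,intensity_organ,intensity_mass mean intensities on
#'   \[0, 255\]; must be strictly increasing so mass-vs-organ contrast is
#'   learnable.
#' @param noise_sd standard deviation of the per-pixel Gaussian noise.
#' @param texture_sd standard deviation of the smooth texture field.
#' @param seed base seed; together with the sample index it fully determines
#'   each phantom.
#' @return a list of class \code{phantom_spec}.
#' @export
phantom_spec <- function(image_size = c(64L, 64L),
                         organ_axes_range = c(12, 20),
                         mass_radius_range = c(4, 9),
                         mass_on_boundary = TRUE,
                         intensity_bg = 30, intensity_organ = 110,
                         intensity_mass = 190,
                         noise_sd = 8, texture_sd = 5,
                         seed = 1L) {
  if (!(intensity_bg < intensity_organ && intensity_organ < intensity_mass)) {
    stop("intensities must satisfy bg < organ < mass")
  }
  if (max(mass_radius_range) >= min(organ_axes_range)) {
    stop("mass radius must stay below the smallest organ semi-axis")
  }
  structure(list(image_size = as.integer(image_size),
                 organ_axes_range = organ_axes_range,
                 mass_radius_range = mass_radius_range,
                 mass_on_boundary = isTRUE(mass_on_boundary),
                 intensity_bg = intensity_bg,
                 intensity_organ = intensity_organ,
                 intensity_mass = intensity_mass,
                 noise_sd = noise_sd, texture_sd = texture_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# smooth random field: iid normals blurred by a separable Gaussian
smooth_field <- function(h, w, sigma, sd) {
  if (sd <= 0) return(matrix(0, h, w))
  z <- matrix(stats::rnorm(h * w), h, w)
  r <- max(1L, ceiling(2 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  pad_filter <- function(m, kern) {
    # filter along rows with edge replication
    n <- nrow(m)
    idx <- pmin(pmax(outer(seq_len(n), seq(-r, r), `+`), 1L), n)
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(kern)) out <- out + kern[j] * m[idx[, j], , drop = FALSE]
    out
  }
  z <- pad_filter(z, k)
  z <- t(pad_filter(t(z), k))
  z * sd / stats::sd(as.numeric(z))
}

#' Generate one phantom sample
#'
#' Deterministic in \code{(spec$seed, index)}: organ ellipse with randomised
#' centre, semi-axes and rotation; mass disc centred on (or inside) the organ
#' contour, clamped to at most one radius beyond the organ body; the organ
#' mask is the ellipse united with the mass so that the mass is always
#' contained in the organ.
#'
#' @param spec a [phantom_spec()].
#' @param index positive sample index.
#' @return a \code{sample_pair}: list with \code{id}, \code{image} (matrix on
#'   \[0, 255\]), \code{mask} (organ) and \code{mass_mask}.
#' @export
generate_phantom <- function(spec, index) {
  stopifnot(inherits(spec, "phantom_spec"), index >= 1)
  h <- spec$image_size[1L]; w <- spec$image_size[2L]
  with_seed((spec$seed %% 65011) * 33013L + as.integer(index), {
    cy <- h / 2 + stats::runif(1, -0.1, 0.1) * h
    cx <- w / 2 + stats::runif(1, -0.1, 0.1) * w
    a <- stats::runif(1, spec$organ_axes_range[1L], spec$organ_axes_range[2L])
    b <- stats::runif(1, spec$organ_axes_range[1L], spec$organ_axes_range[2L])
    th <- stats::runif(1, 0, pi)
    yy <- matrix(seq_len(h), h, w) - cy
    xx <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
    u <- cos(th) * xx + sin(th) * yy
    v <- -sin(th) * xx + cos(th) * yy
    body <- ((u / a)^2 + (v / b)^2 <= 1) * 1L

    r <- stats::runif(1, spec$mass_radius_range[1L], spec$mass_radius_range[2L])
    mass <- matrix(0L, h, w)
    if (r > 0) {
      phi <- stats::runif(1, 0, 2 * pi)
      scale <- if (spec$mass_on_boundary) 1 else stats::runif(1, 0.2, 0.6)
      my <- cy + scale * (a * cos(phi) * sin(th) + b * sin(phi) * cos(th))
      mx <- cx + scale * (a * cos(phi) * cos(th) - b * sin(phi) * sin(th))
      disc <- ((matrix(seq_len(h), h, w) - my)^2 +
               (matrix(seq_len(w), h, w, byrow = TRUE) - mx)^2 <= r^2) * 1L
      # clamp the protrusion to at most one mass radius beyond the body
      dil <- EBImage::dilate(body, EBImage::makeBrush(2L * ceiling(r) + 1L,
                                                      shape = "disc"))
      mass <- disc * (dil > 0)
    }
    organ <- ((body + mass) > 0) * 1L

    img <- matrix(spec$intensity_bg, h, w)
    img[organ == 1L] <- spec$intensity_organ
    img[mass == 1L] <- spec$intensity_mass
    img <- img + smooth_field(h, w, sigma = 4, sd = spec$texture_sd)
    if (spec$noise_sd > 0) img <- img + matrix(stats::rnorm(h * w, sd = spec$noise_sd), h, w)
    img <- pmin(pmax(img, 0), 255)

    structure(list(id = sprintf("phantom_%04d", as.integer(index)),
                   image = img, mask = organ, mass_mask = mass),
              class = "sample_pair")
  })
}

#' Generate a phantom dataset on disk
#'
#' Writes \code{images/}, \code{masks/} and \code{mass_masks/} PNG triples,
#' a CSV manifest, and the generator spec (for provenance) into
#' \code{out_dir}; the layout is re-loadable with [load_pairs()].
#'
#' @param n number of samples.
#' @param spec a [phantom_spec()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, the manifest data.frame.
#' @export
generate_dataset <- function(n, spec, out_dir) {
  stopifnot(n >= 1)
  dirs <- file.path(out_dir, c("images", "masks", "mass_masks"))
  for (d in dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  ids <- character(n)
  for (k in seq_len(n)) {
    s <- generate_phantom(spec, k)
    ids[k] <- s$id
    png::writePNG(round(s$image) / 255, file.path(dirs[1L], paste0(s$id, ".png")))
    png::writePNG(s$mask * 1, file.path(dirs[2L], paste0(s$id, ".png")))
    png::writePNG(s$mass_mask * 1, file.path(dirs[3L], paste0(s$id, ".png")))
  }
  manifest <- data.frame(id = ids, stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  writeLines(utils::capture.output(utils::str(unclass(spec))),
             file.path(out_dir, "phantom_spec.txt"))
  invisible(manifest)
}

#' Generate an in-memory phantom dataset
#'
#' @param n number of samples.
#' @param spec a [phantom_spec()].
#' @return list of \code{sample_pair}s.
#' @export
generate_samples <- function(n, spec) {
  lapply(seq_len(n), function(k) generate_phantom(spec, k))
}
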