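#' Fuse organ and mass masks into a labeled segmentation
#'
#' Deterministic pixelwise overlay: label 2 (mass) where both masks are
#' foreground, label 1 (organ) where only the organ mask is, label 0
#' elsewhere. Mass pixels falling outside the organ are suppressed to
#' background, enforcing the mass-inside-organ constraint.
#'
#' @param organ binary organ mask (matrix over \{0, 1\}).
#' @param mass binary mass mask of the same size.
#' @return integer matrix over \{0, 1, 2\} of class \code{labeled_mask}.
#' @export
fuse_masks <- function(organ, mass) {
  if (!identical(dim(organ), dim(mass))) {
    stop("organ (", paste(dim(organ), collapse = "x"), ") and mass (",
         paste(dim(mass), collapse = "x"), ") masks must have equal dims")
  }
  labels <- (organ > 0) * 1L + (organ > 0 & mass > 0) * 1L
  structure(labels, class = c("labeled_mask", class(labels)))
}

#' Decompose a labeled mask into its organ and mass layers
#'
#' The organ layer is label >= 1 (the organ including the mass region); the
#' mass layer is label == 2. \code{fuse_masks(layers$organ, layers$mass)}
#' reproduces the labeled mask exactly.
#'
#' @param labeled a [fuse_masks()] result.
#' @return list with binary matrices \code{organ} and \code{mass}.
#' @export
label_layers <- function(labeled) {
  list(organ = (unclass(labeled) >= 1L) * 1L,
       mass = (unclass(labeled) == 2L) * 1L)
}

#' Save a labeled mask as an 8-bit PNG with values \{0, 1, 2\}
#'
#' @param labeled a labeled mask.
#' @param path output PNG path.
#' @return invisibly, the path.
#' @export
save_labeled_mask <- function(labeled, path) {
  png::writePNG(unclass(labeled) / 255, path)
  invisible(path)
}

#' Load a labeled mask written by [save_labeled_mask()]
#'
#' @param path PNG path.
#' @return integer matrix over \{0, 1, 2\}.
#' @export
load_labeled_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  labels <- matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
  structure(labels, class = c("labeled_mask", class(labels)))
}

#' Save a colour overlay of a labeled segmentation on an image
#'
#' The image is rendered in grayscale with the organ contour drawn in green
#' and the mass region filled in red.
#'
#' @param image grayscale image matrix on \[0, 255\].
#' @param labeled labeled mask of the same size.
#' @param path output PNG path.
#' @return invisibly, the path.
#' @export
save_overlay <- function(image, labeled, path) {
  g <- pmin(pmax(image / 255, 0), 1)
  layers <- label_layers(labeled)
  contour <- mask_boundary(layers$organ)
  rgb <- array(g, c(dim(g), 3L))
  rgb[, , 1L][layers$mass == 1L] <- 1
  rgb[, , 2L][layers$mass == 1L] <- 0.2
  rgb[, , 3L][layers$mass == 1L] <- 0.2
  rgb[, , 1L][contour == 1L] <- 0.1
  rgb[, , 2L][contour == 1L] <- 1
  rgb[, , 3L][contour == 1L] <- 0.1
  png::writePNG(rgb, path)
  invisible(path)
}
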