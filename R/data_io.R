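#' Load paired image/mask samples from mirrored directories
#'
#' Images and masks pair by shared filename stem; pairs are returned in
#' lexicographic id order. Images are returned on the raw \[0, 255\] scale
#' (grayscale matrix or H x W x C array); masks are binarised with the rule
#' value > 0. Orphan files (an image without a mask or vice versa) and pairs
#' with unequal dimensions are rejected with a diagnostic.
#'
#' @param image_dir directory of image PNGs.
#' @param mask_dir directory of organ-mask PNGs.
#' @param mass_dir optional directory of mass-mask PNGs.
#' @return list of \code{sample_pair}s.
#' @export
load_pairs <- function(image_dir, mask_dir, mass_dir = NULL) {
  for (d in c(image_dir, mask_dir, mass_dir)) {
    if (!dir.exists(d)) stop("directory does not exist: ", d)
  }
  stems <- function(d) sort(sub("\\.png$", "", list.files(d, pattern = "\\.png$")))
  si <- stems(image_dir); sm <- stems(mask_dir)
  orphans <- c(setdiff(si, sm), setdiff(sm, si))
  if (length(orphans) > 0L) {
    stop("unpaired ids (missing image or mask): ",
         paste(orphans, collapse = ", "))
  }
  lapply(si, function(id) {
    img <- load_image(file.path(image_dir, paste0(id, ".png")))
    msk <- load_mask(file.path(mask_dir, paste0(id, ".png")))
    if (!identical(dim(img)[1:2], dim(msk))) {
      stop("pair ", id, ": image ", paste(dim(img)[1:2], collapse = "x"),
           " and mask ", paste(dim(msk), collapse = "x"), " dims differ")
    }
    mm <- NULL
    if (!is.null(mass_dir)) {
      mp <- file.path(mass_dir, paste0(id, ".png"))
      if (file.exists(mp)) {
        mm <- load_mask(mp)
        if (!identical(dim(mm), dim(msk))) {
          stop("pair ", id, ": mass mask dims differ from the organ mask")
        }
      }
    }
    structure(list(id = id, image = img, mask = msk, mass_mask = mm),
              class = "sample_pair")
  })
}

#' Load an image PNG on the raw \[0, 255\] scale
#'
#' @param path PNG path.
#' @return matrix (grayscale) or H x W x C array.
#' @export
load_image <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L && dim(m)[3L] == 1L) m <- m[, , 1L]
  m * 255
}

#' Load a binary mask PNG (any value > 0 is foreground)
#'
#' @param path PNG path.
#' @return matrix over \{0, 1\}.
#' @export
load_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  (m > 0) * 1L
}

#' Save a binary mask as an 8-bit PNG (foreground stored as 255)
#'
#' @param mask matrix over \{0, 1\}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
save_mask <- function(mask, path) {
  png::writePNG((mask > 0) * 1, path)
  invisible(path)
}

#' Deterministic train/validation/test split counts
#'
#' \code{n_train = floor(n (1 - r_val - r_test))}; the remainder is split
#' proportionally, with floor on the validation share and the rest assigned
#' to test: \code{n_val = floor(remainder * r_val / (r_val + r_test))},
#' \code{n_test = remainder - n_val}. This is the unique simple rounding rule
#' consistent with the published partition tables (e.g. 1,169 -> 935/117/117
#' and 10,015 -> 8,012/1,001/1,002 at r_val = r_test = 0.1). The floor is
#' guarded against floating-point droop (10,015 x 0.8 is 8,011.999... in
#' double arithmetic).
#'
#' @param n total sample count (>= 3).
#' @param r_val,r_test validation and test fractions, each in (0, 1) with
#'   \code{r_val + r_test < 1}.
#' @return named integer vector \code{c(train, val, test)} summing to n.
#' @export
split_dataset <- function(n, r_val = 0.1, r_test = 0.1) {
  stopifnot(n >= 3, r_val > 0, r_test > 0, r_val + r_test < 1)
  safe_floor <- function(x) floor(round(x, 9))
  n_train <- safe_floor(n * (1 - r_val - r_test))
  rem <- n - n_train
  n_val <- safe_floor(rem * r_val / (r_val + r_test))
  n_test <- rem - n_val
  counts <- c(train = as.integer(n_train), val = as.integer(n_val),
              test = as.integer(n_test))
  if (any(counts == 0)) {
    bad <- names(counts)[counts == 0]
    stop("split produces an empty partition (", paste(bad, collapse = ", "),
         "); increase n or the corresponding ratio")
  }
  counts
}

#' Shuffle ids and assign them to train/validation/test
#'
#' Ids are shuffled with \code{shuffle_seed} before assignment; the partition
#' sizes follow [split_dataset()] and are independent of the shuffle. An
#' optional grouping key (e.g. a patient id per sample) makes the split
#' group-wise: groups are shuffled and assigned whole, approximating the
#' requested sample counts.
#'
#' @param ids character vector of sample ids.
#' @param r_val,r_test split fractions.
#' @param shuffle_seed integer seed.
#' @param group optional vector, same length as ids, of grouping keys.
#' @return list with character vectors \code{train}, \code{val}, \code{test}.
#' @export
split_ids <- function(ids, r_val = 0.1, r_test = 0.1, shuffle_seed = 1L,
                      group = NULL) {
  if (is.null(group)) {
    counts <- split_dataset(length(ids), r_val, r_test)
    perm <- with_seed(shuffle_seed, sample(ids))
    list(train = sort(perm[seq_len(counts["train"])]),
         val = sort(perm[counts["train"] + seq_len(counts["val"])]),
         test = sort(perm[counts["train"] + counts["val"] +
                            seq_len(counts["test"])]))
  } else {
    stopifnot(length(group) == length(ids))
    counts <- split_dataset(length(ids), r_val, r_test)
    groups <- with_seed(shuffle_seed, sample(unique(as.character(group))))
    sizes <- table(as.character(group))[groups]
    cum <- cumsum(as.numeric(sizes))
    g_train <- groups[cum <= counts["train"]]
    rest <- setdiff(groups, g_train)
    cum_rest <- cumsum(as.numeric(sizes[rest]))
    g_val <- rest[cum_rest <= counts["val"]]
    g_test <- setdiff(rest, g_val)
    gr <- as.character(group)
    list(train = sort(ids[gr %in% g_train]),
         val = sort(ids[gr %in% g_val]),
         test = sort(ids[gr %in% g_test]))
  }
}

#' Write a split manifest CSV (columns id, subset)
#'
#' @param split a [split_ids()] result.
#' @param path output CSV path.
#' @return invisibly, the manifest data.frame.
#' @export
write_split_manifest <- function(split, path) {
  manifest <- data.frame(
    id = c(split$train, split$val, split$test),
    subset = rep(c("train", "val", "test"),
                 c(length(split$train), length(split$val), length(split$test))),
    stringsAsFactors = FALSE)
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(manifest)
}

#' Slice a NIfTI volume into axial 2-D PNG images
#'
#' Optional adapter for volumetric inputs; each axial slice is min-max
#' rescaled to \[0, 255\] and written as an 8-bit PNG. Requires the RNifti
#' package.
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @param out_dir output directory.
#' @param prefix filename prefix.
#' @return invisibly, the written file paths.
#' @export
nifti_to_slices <- function(path, out_dir, prefix = "slice") {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("nifti_to_slices requires the RNifti package")
  }
  vol <- RNifti::readNifti(path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  nz <- dim(vol)[3L]
  paths <- character(nz)
  for (z in seq_len(nz)) {
    sl <- vol[, , z]
    rng <- range(sl)
    sl <- if (diff(rng) > 0) (sl - rng[1L]) / diff(rng) else sl * 0
    paths[z] <- file.path(out_dir, sprintf("%s_%04d.png", prefix, z))
    png::writePNG(sl, paths[z])
  }
  invisible(paths)
}
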