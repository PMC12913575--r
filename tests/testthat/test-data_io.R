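test_that("split counts reproduce the published partition tables exactly", {
  expect_identical(unname(split_dataset(1169, 0.1, 0.1)), c(935L, 117L, 117L))
  expect_identical(unname(split_dataset(10015, 0.1, 0.1)),
                   c(8012L, 1001L, 1002L))
  expect_identical(unname(split_dataset(10, 0.1, 0.1)), c(8L, 1L, 1L))
})

test_that("split counts are a partition for arbitrary n and ratios", {
  set.seed(42)
  for (k in 1:200) {
    n <- sample(3:5000, 1)
    rv <- runif(1, 0.02, 0.4)
    rt <- runif(1, 0.02, min(0.4, 0.95 - rv))
    counts <- tryCatch(split_dataset(n, rv, rt), error = function(e) NULL)
    if (is.null(counts)) next  # a ratio too small for this n
    expect_true(all(counts >= 0))
    expect_identical(sum(counts), as.integer(n))
  }
})

test_that("degenerate ratios raise an informative error", {
  expect_error(split_dataset(5, 0.01, 0.5), "empty partition")
  expect_error(split_dataset(2, 0.1, 0.1))
})

test_that("id assignment is a disjoint cover with shuffle-independent counts", {
  ids <- sprintf("s%03d", 1:57)
  a <- split_ids(ids, 0.1, 0.2, shuffle_seed = 1)
  b <- split_ids(ids, 0.1, 0.2, shuffle_seed = 99)
  expect_setequal(c(a$train, a$val, a$test), ids)
  expect_length(intersect(a$train, a$val), 0)
  expect_length(intersect(a$train, a$test), 0)
  expect_identical(lengths(a), lengths(b))
  expect_false(identical(a$train, b$train))
})

test_that("group-wise splitting keeps groups intact", {
  ids <- sprintf("s%02d", 1:40)
  grp <- rep(sprintf("p%02d", 1:10), each = 4)
  sp <- split_ids(ids, 0.2, 0.2, shuffle_seed = 3, group = grp)
  for (sub in sp) {
    g <- unique(grp[match(sub, ids)])
    expect_true(all(ids[grp %in% g] %in% sub))
  }
  expect_setequal(c(sp$train, sp$val, sp$test), ids)
})

test_that("masks survive a save/load round trip bitwise", {
  m <- rand_mask(13, 17, seed = 5)
  path <- tempfile(fileext = ".png")
  save_mask(m, path)
  expect_identical(load_mask(path), m)
})

test_that("generated datasets reload with pairing, order and binarization", {
  out <- tempfile("phantoms")
  generate_dataset(3, phantom_spec(seed = 5), out)
  pairs <- load_pairs(file.path(out, "images"), file.path(out, "masks"),
                      file.path(out, "mass_masks"))
  expect_length(pairs, 3)
  ids <- vapply(pairs, `[[`, character(1), "id")
  expect_identical(ids, sort(ids))
  for (p in pairs) {
    expect_true(all(p$mask %in% c(0L, 1L)))
    expect_identical(dim(p$image)[1:2], dim(p$mask))
    expect_identical(dim(p$mass_mask), dim(p$mask))
  }
  # orphan detection
  file.remove(file.path(out, "masks", paste0(ids[2], ".png")))
  expect_error(load_pairs(file.path(out, "images"), file.path(out, "masks")),
               "unpaired")
})

test_that("pairs with unequal dimensions are rejected with a diagnostic", {
  out <- tempfile("badpair")
  dir.create(file.path(out, "images"), recursive = TRUE)
  dir.create(file.path(out, "masks"), recursive = TRUE)
  png::writePNG(matrix(0.5, 8, 8), file.path(out, "images", "a.png"))
  png::writePNG(matrix(1, 4, 4), file.path(out, "masks", "a.png"))
  expect_error(load_pairs(file.path(out, "images"), file.path(out, "masks")),
               "dims differ")
})

test_that("empty directories load to an empty list", {
  out <- tempfile("empty")
  dir.create(file.path(out, "images"), recursive = TRUE)
  dir.create(file.path(out, "masks"), recursive = TRUE)
  expect_length(load_pairs(file.path(out, "images"), file.path(out, "masks")),
                0)
})

test_that("split manifests are written as id/subset CSV", {
  sp <- split_ids(sprintf("s%02d", 1:20), 0.2, 0.2, shuffle_seed = 1)
  path <- tempfile(fileext = ".csv")
  write_split_manifest(sp, path)
  man <- read.csv(path, stringsAsFactors = FALSE)
  expect_identical(names(man), c("id", "subset"))
  expect_identical(nrow(man), 20L)
  expect_setequal(unique(man$subset), c("train", "val", "test"))
})
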