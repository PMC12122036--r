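# Data pipeline: split protocol, pair loading, augmentation, binarisation.

test_that("split sizes follow the rounded 7:2:1 protocol", {
  ids <- function(n) sprintf("s%05d", seq_len(n))
  # published dataset totals reproduce the printed test-partition sizes
  expect_length(split_dataset(ids(2150))$test, 215)
  expect_length(split_dataset(ids(1279))$test, 128)
  expect_length(split_dataset(ids(670))$test, 67)
  # exact ratio at N = 10
  s <- split_dataset(ids(10))
  expect_equal(lengths(s)[c("train", "val", "test")],
               c(train = 7L, val = 2L, test = 1L))
  expect_error(split_dataset(ids(2)), "at least 3")
  expect_error(split_dataset(c("a", "a", "b")), "unique")
})

test_that("splits are exact partitions, reproducible, seed-sensitive", {
  ids <- sprintf("im%03d", 1:97)
  s1 <- split_dataset(ids, split_spec(seed = 4L))
  s2 <- split_dataset(ids, split_spec(seed = 4L))
  s3 <- split_dataset(ids, split_spec(seed = 5L))
  expect_identical(s1, s2)
  expect_false(identical(s1$test, s3$test))
  all_ids <- c(s1$train, s1$val, s1$test)
  expect_setequal(all_ids, ids)
  expect_equal(length(all_ids), length(unique(all_ids)))
})

test_that("pair loading binarises masks and validates dimensions", {
  d <- tempfile()
  dir.create(d)
  img <- array(runif(12 * 10 * 3), c(12, 10, 3))
  msk <- matrix(c(0, 40, 127, 128, 200, 255) / 255, 12, 10)
  png::writePNG(img, file.path(d, "case1.png"))
  png::writePNG(msk, file.path(d, "case1_mask.png"))
  s <- load_sample_pair(file.path(d, "case1.png"),
                        file.path(d, "case1_mask.png"))
  expect_identical(s$identifier, "case1")
  expect_identical(s$source, "disk")
  expect_true(all(s$mask %in% c(0, 1)))
  # 8-bit threshold at 127: values {0,40,127} -> 0, {128,200,255} -> 1
  expect_equal(unique(s$mask[matrix(msk * 255 <= 127, 12, 10)]), 0)
  expect_equal(unique(s$mask[matrix(msk * 255 > 127, 12, 10)]), 1)
  png::writePNG(matrix(0, 5, 5), file.path(d, "bad_mask.png"))
  expect_error(load_sample_pair(file.path(d, "case1.png"),
                                file.path(d, "bad_mask.png")),
               "12x10.*5x5")
  expect_error(load_sample_pair(file.path(d, "missing.png"),
                                file.path(d, "case1_mask.png")),
               "not found")
  unlink(d, recursive = TRUE)
})

test_that("flips are involutions and augmentation preserves the contract", {
  set.seed(71)
  s <- tiny_lesion_pairs(1)[[1]]
  flip_cfg <- augment_config(rotation = 0, hflip = 1, vflip = 0,
                             crop = c(1, 1))
  once <- augment_pair(s, flip_cfg)
  twice <- augment_pair(once, flip_cfg)
  expect_identical(twice$image, s$image)
  expect_identical(twice$mask, s$mask)
  # any draw: mask binary, same shape, aligned with image
  cfg <- augment_config(rotation = 25, crop = c(0.7, 1),
                        hair = list(count = c(1L, 3L)))
  for (rep in 1:5) {
    a <- augment_pair(s, cfg)
    expect_identical(dim(a$image), dim(s$image))
    expect_identical(dim(a$mask), dim(s$mask))
    expect_true(all(a$mask %in% c(0, 1)))
  }
})

test_that("rotating a coordinate grid moves image and mask together", {
  # paint the mask pattern into an image channel and check the augmented
  # image channel still matches the augmented mask where sampling is exact
  H <- 32L
  msk <- matrix(0, H, H)
  msk[10:20, 12:24] <- 1
  img <- array(0, c(H, H, 3))
  img[, , 1] <- msk * 255
  s <- dfn$new_sample_pair(img, msk, "grid", "synthetic")
  cfg <- augment_config(rotation = 30, hflip = 0.5, vflip = 0.5,
                        crop = c(1, 1))
  a <- augment_pair(s, cfg, seed = 72L)
  # nearest-neighbour mask and bilinear image agree away from the boundary
  interior <- a$image[, , 1] / 255
  agree <- mean((interior > 0.5) == (a$mask == 1))
  expect_gt(agree, 0.97)
})

test_that("augmentation is deterministic under a fixed seed", {
  s <- tiny_lesion_pairs(1)[[1]]
  cfg <- augment_config(rotation = 20, crop = c(0.8, 1),
                        hair = list(count = c(2L, 4L)))
  a1 <- augment_pair(s, cfg, seed = 73L)
  a2 <- augment_pair(s, cfg, seed = 73L)
  expect_identical(a1$image, a2$image)
  expect_identical(a1$mask, a2$mask)
  a3 <- augment_pair(s, cfg, seed = 74L)
  expect_false(identical(a3$image, a1$image))
})

test_that("hair noise darkens the image but never touches the mask", {
  s <- tiny_lesion_pairs(1, size = 48L)[[1]]
  # k = 0 is a no-op
  none <- add_hair_noise(s, augment_config(hair = NULL), seed = 75L)
  expect_identical(none$image, s$image)
  cfg <- augment_config(hair = list(count = c(5L, 5L),
                                    thickness = c(1L, 2L)))
  h <- add_hair_noise(s, cfg, seed = 76L)
  expect_identical(h$mask, s$mask)
  changed <- which(h$image != s$image, arr.ind = TRUE)
  npix <- length(unique(changed[, 1] + 1000 * changed[, 2]))
  expect_gt(npix, 0)
  # 5 strokes, max thickness 2, max length 0.8*48 plus disc overlap slack
  expect_lt(npix, 5 * 3 * ceiling(0.8 * 48) * 2)
  # strokes darken: no channel value may increase
  expect_true(all(h$image <= s$image))
})

test_that("prediction binarisation uses the >= tie-break", {
  p <- array(c(0.2, 0.5, 0.7, 0.49), c(2, 2, 1, 1))
  m <- binarize_prediction(p, 0.5)
  expect_equal(as.vector(m), c(0, 1, 1, 0))
  expect_identical(dim(m), dim(p))
  expect_equal(binarize_prediction(array(0, c(2, 2, 1, 1))),
               array(0, c(2, 2, 1, 1)))
  expect_error(binarize_prediction(p, 1.5), "threshold")
  # composition with the metrics on a perfect probability map
  g <- array(rbinom(16, 1, 0.5), c(4, 4, 1, 1))
  r <- segmentation_metrics(binarize_prediction(g * 0.9 + 0.05), g,
                            hausdorff = FALSE)$per_image
  expect_equal(r$iou, 1)
})
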