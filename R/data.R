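# Data pipeline: loading paired image/mask PNGs, the train/validation/test
# split protocol, geometric augmentation shared between image and mask, and
# synthetic body-hair noise.

#' Train/validation/test split specification
#'
#' @param ratio positive triple `(train, val, test)`; default `(7, 2, 1)`
#' @param seed integer seed for the assignment shuffle
#' @return a `split_spec` list
#' @export
split_spec <- function(ratio = c(7, 2, 1), seed = 1L) {
  if (length(ratio) != 3 || any(ratio <= 0))
    stop("invalid configuration: ratio must be three positive numbers")
  structure(list(ratio = ratio, seed = as.integer(seed)),
            class = "split_spec")
}

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Split identifiers into train/validation/test partitions
#'
#' The test partition gets `round(N * r_test / sum(ratio))` identifiers, the
#' validation partition `round(N * r_val / sum(ratio))` (capped so training
#' stays non-empty), and training the remainder.  Assignment is by a seeded
#' shuffle; the partition is exact (disjoint and covering).
#'
#' @param identifiers unique character vector, length >= 3
#' @param spec a [split_spec()]
#' @return list with `train`, `val` and `test` character vectors
#' @export
split_dataset <- function(identifiers, spec = split_spec()) {
  n <- length(identifiers)
  if (n < 3) stop("invalid input: need at least 3 identifiers")
  if (anyDuplicated(identifiers))
    stop("invalid input: identifiers must be unique")
  tot <- sum(spec$ratio)
  n_test <- round(n * spec$ratio[3] / tot)
  n_val <- round(n * spec$ratio[2] / tot)
  n_test <- max(1L, min(n_test, n - 2L))
  n_val <- max(1L, min(n_val, n - n_test - 1L))
  perm <- with_seed(spec$seed, sample(identifiers))
  list(train = sort(perm[seq_len(n - n_val - n_test)]),
       val = sort(perm[n - n_val - n_test + seq_len(n_val)]),
       test = sort(perm[n - n_test + seq_len(n_test)]))
}

# Sample pairs -----------------------------------------------------------

new_sample_pair <- function(image, mask, id, source) {
  stopifnot(identical(dim(image)[1:2], dim(mask)[1:2]))
  structure(list(image = image, mask = mask, identifier = id,
                 source = source), class = "sample_pair")
}

#' @export
print.sample_pair <- function(x, ...) {
  cat("<sample_pair", x$identifier, paste(dim(x$image)[1:2], collapse = "x"),
      "source:", x$source, "fg:", round(mean(x$mask), 3), ">\n")
  invisible(x)
}

read_png_any <- function(path) {
  if (!file.exists(path)) stop("I/O error: file not found: ", path)
  if (!grepl("\\.png$", path, ignore.case = TRUE))
    stop("I/O error: only PNG rasters are supported, got: ", path)
  png::readPNG(path)
}

#' Load an aligned image/mask pair from disk
#'
#' The image is returned as an `(H, W, 3)` integer array in 0-255; the mask
#' is binarised by thresholding the 8-bit values at 127.  Dimensions are
#' validated to be equal and the identifier is taken from the image file
#' stem.
#'
#' @param image_path PNG image path
#' @param mask_path PNG mask path (grayscale; colour masks are converted
#'   with a warning)
#' @return a `sample_pair`
#' @export
load_sample_pair <- function(image_path, mask_path) {
  img <- read_png_any(image_path)
  msk <- read_png_any(mask_path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  if (length(dim(msk)) == 3) {
    if (dim(msk)[3] > 1) {
      warning("mask ", mask_path, " is not grayscale; converting by mean")
      msk <- apply(msk[, , 1:min(3, dim(msk)[3]), drop = FALSE], c(1, 2), mean)
    } else msk <- msk[, , 1]
  }
  if (!identical(dim(img)[1:2], dim(msk)[1:2]))
    stop("invalid input: image ", paste(dim(img)[1:2], collapse = "x"),
         " and mask ", paste(dim(msk)[1:2], collapse = "x"),
         " dimensions differ")
  image <- round(img * 255)
  mask <- (round(msk * 255) > 127) * 1
  new_sample_pair(image, mask,
                  tools::file_path_sans_ext(basename(image_path)), "disk")
}

# Augmentation -----------------------------------------------------------

#' Augmentation configuration
#'
#' @param rotation maximum absolute rotation, degrees
#' @param hflip,vflip horizontal/vertical flip probabilities
#' @param crop `(min, max)` crop fraction range in `(0, 1]`
#' @param hair hair-noise parameter list (`count` range, `thickness` range
#'   in px, `darkness` range in `[0, 1]`, `curvature`) or `NULL` to disable
#' @param seed integer seed
#' @return an `augment_config` list
#' @export
augment_config <- function(rotation = 15, hflip = 0.5, vflip = 0.5,
                           crop = c(0.8, 1), hair = NULL, seed = 1L) {
  if (hflip < 0 || hflip > 1 || vflip < 0 || vflip > 1)
    stop("invalid configuration: flip probabilities must be in [0, 1]")
  if (any(crop <= 0) || any(crop > 1) || crop[1] > crop[2])
    stop("invalid configuration: crop fractions must be in (0, 1]")
  if (is.null(hair)) hair <- list(count = c(0L, 0L))
  hair <- utils::modifyList(list(count = c(2L, 6L), thickness = c(1L, 3L),
                                 darkness = c(0.5, 0.9), curvature = 0.3),
                            hair)
  structure(list(rotation = rotation, hflip = hflip, vflip = vflip,
                 crop = crop, hair = hair, seed = as.integer(seed)),
            class = "augment_config")
}

#' Apply a random geometric augmentation to an image/mask pair
#'
#' Draws one rotation, flip and crop configuration and applies the identical
#' geometric transform to image and mask; the mask is resampled
#' nearest-neighbour (staying binary) and output dimensions equal the input
#' dimensions.  Rotation fills image borders by reflection and mask borders
#' with zero.
#'
#' @param s a `sample_pair`
#' @param cfg an [augment_config()]
#' @param seed optional seed; when `NULL` the current RNG stream is used
#' @return augmented `sample_pair`
#' @export
augment_pair <- function(s, cfg = augment_config(), seed = NULL) {
  run <- function() {
    img <- s$image / 255
    msk <- s$mask
    H <- dim(msk)[1]; W <- dim(msk)[2]
    if (cfg$rotation > 0) {
      ang <- stats::runif(1, -cfg$rotation, cfg$rotation)
      img <- rotate_raster(img, ang, "bilinear", "reflect")
      msk <- rotate_raster(msk, ang, "nearest", "zero")
    }
    if (stats::runif(1) < cfg$hflip) {
      img <- img[, rev(seq_len(W)), , drop = FALSE]
      msk <- msk[, rev(seq_len(W)), drop = FALSE]
    }
    if (stats::runif(1) < cfg$vflip) {
      img <- img[rev(seq_len(H)), , , drop = FALSE]
      msk <- msk[rev(seq_len(H)), , drop = FALSE]
    }
    f <- stats::runif(1, cfg$crop[1], cfg$crop[2])
    hc <- max(1L, round(H * f)); wc <- max(1L, round(W * f))
    if (hc < H || wc < W) {
      y0 <- sample.int(H - hc + 1L, 1L)
      x0 <- sample.int(W - wc + 1L, 1L)
      img <- crop_raster(img, y0, x0, hc, wc)
      msk <- crop_raster(msk, y0, x0, hc, wc)
      img <- resize_image(img, H, W, "bilinear")
      msk <- resize_image(msk, H, W, "nearest")
    }
    out <- new_sample_pair(pmin(pmax(round(img * 255), 0), 255),
                           (msk > 0.5) * 1, s$identifier, s$source)
    if (cfg$hair$count[2] > 0) out <- add_hair_noise(out, cfg)
    out
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# draw one quadratic Bezier stroke into an (H, W, 3) [0,1] image
draw_stroke <- function(img, p0, p1, p2, thickness, shade) {
  H <- dim(img)[1]; W <- dim(img)[2]
  npts <- max(16L, 2L * round(sqrt(sum((p2 - p0)^2))))
  tt <- seq(0, 1, length.out = npts)
  pts <- outer((1 - tt)^2, p0) + outer(2 * tt * (1 - tt), p1) +
    outer(tt^2, p2)
  r <- (thickness - 1) / 2
  off <- expand.grid(dy = -ceiling(r):ceiling(r), dx = -ceiling(r):ceiling(r))
  off <- off[off$dy^2 + off$dx^2 <= max(r, 0.5)^2 + 1e-9, , drop = FALSE]
  ys <- round(rep(pts[, 1], each = nrow(off)) + off$dy)
  xs <- round(rep(pts[, 2], each = nrow(off)) + off$dx)
  keep <- ys >= 1 & ys <= H & xs >= 1 & xs <= W
  idx <- unique(cbind(ys[keep], xs[keep]))
  for (c in 1:3) {
    ch <- img[, , c]
    ch[idx] <- ch[idx] * (1 - shade)
    img[, , c] <- ch
  }
  img
}

#' Composite synthetic body-hair strokes onto an image
#'
#' Adds `k` thin dark quadratic-Bezier strokes (k drawn from the configured
#' count range) to the image only; the mask is returned untouched.
#'
#' @inheritParams augment_pair
#' @return `sample_pair` with modified image, identical mask
#' @export
add_hair_noise <- function(s, cfg = augment_config(hair = list()),
                           seed = NULL) {
  run <- function() {
    h <- cfg$hair
    k <- if (h$count[1] >= h$count[2]) h$count[1]
    else sample(h$count[1]:h$count[2], 1L)
    if (k == 0) return(s)
    img <- s$image / 255
    H <- dim(img)[1]; W <- dim(img)[2]
    for (i in seq_len(k)) {
      p0 <- c(stats::runif(1, 1, H), stats::runif(1, 1, W))
      len <- stats::runif(1, 0.3, 0.8) * min(H, W)
      th <- stats::runif(1, 0, 2 * pi)
      p2 <- p0 + len * c(cos(th), sin(th))
      mid <- (p0 + p2) / 2
      perp <- c(-sin(th), cos(th)) * len * h$curvature *
        stats::runif(1, -1, 1)
      p1 <- mid + perp
      thick <- sample(h$thickness[1]:h$thickness[2], 1L)
      shade <- stats::runif(1, h$darkness[1], h$darkness[2])
      img <- draw_stroke(img, p0, p1, p2, thick, shade)
    }
    new_sample_pair(pmin(pmax(round(img * 255), 0), 255), s$mask,
                    s$identifier, s$source)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Threshold a probability map into a binary mask
#'
#' Uses a `>=` comparison, so probabilities exactly at the threshold map to
#' foreground.
#'
#' @param p numeric array of probabilities in `[0, 1]`
#' @param threshold scalar in `(0, 1)`
#' @return binary array of the same shape
#' @export
binarize_prediction <- function(p, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1)
    stop("invalid configuration: threshold must be in (0, 1)")
  out <- (p >= threshold) * 1
  dim(out) <- dim(p)
  out
}

# Directory helpers ------------------------------------------------------

#' List matching image/mask pairs under a dataset directory
#'
#' Expects `images/` and `masks/` subdirectories with matching file stems.
#'
#' @param dir dataset root
#' @return data frame with `id`, `image`, `mask` columns
#' @export
list_pairs <- function(dir) {
  imgs <- list.files(file.path(dir, "images"), pattern = "\\.png$",
                     full.names = TRUE)
  if (!length(imgs)) stop("I/O error: no PNG images under ", dir)
  ids <- tools::file_path_sans_ext(basename(imgs))
  masks <- file.path(dir, "masks", paste0(ids, ".png"))
  ok <- file.exists(masks)
  if (!all(ok))
    stop("I/O error: missing masks for: ",
         paste(utils::head(ids[!ok], 5), collapse = ", "))
  data.frame(id = ids, image = imgs, mask = masks, stringsAsFactors = FALSE)
}
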