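# Synthetic image/mask generators for the two task regimes the network
# targets: a single large irregular skin lesion on a textured skin-tone
# background (optionally with hair strokes), and many small bright nucleus
# blobs on a dark field.  Every sample is fully determined by (seed, index).

#' Synthetic dataset specification
#'
#' @param mode `"lesion"` (one large star-convex lesion per image) or
#'   `"nuclei"` (many small bright blobs)
#' @param image_size `(H, W)` in pixels
#' @param count number of samples in a generated dataset
#' @param seed integer master seed; sample `i` uses a stream derived from
#'   `(seed, i)`
#' @param lesion parameter list: `center_jitter` (fraction of the image the
#'   lesion centre may wander from the middle), `radius_frac` (mean radius
#'   as a fraction of the short side, in `(0, 0.5)`), `irregularity`
#'   (radial-modulation amplitude), `harmonics` (number of sinusoidal
#'   harmonics of the boundary), `blur_sigma` (px), `noise_sd` (additive
#'   Gaussian pixel noise, on 0-1 intensities), `hair_prob` (probability a
#'   sample receives hair strokes)
#' @param nuclei parameter list: `count` blob-count range, `radius` radius
#'   range in px, `min_sep` minimum centre separation beyond the sum of
#'   radii, in px
#' @return a `synthetic_spec` list
#' @export
synthetic_spec <- function(mode = c("lesion", "nuclei"),
                           image_size = c(128L, 128L),
                           count = 16L, seed = 1L,
                           lesion = list(), nuclei = list()) {
  mode <- match.arg(mode)
  lesion <- utils::modifyList(
    list(center_jitter = 0.08, radius_frac = 0.28, irregularity = 0.22,
         harmonics = 5L, blur_sigma = 1.2, noise_sd = 0.02,
         hair_prob = 0.3), lesion)
  nuclei <- utils::modifyList(
    list(count = c(5L, 15L), radius = c(3, 8), min_sep = 2), nuclei)
  if (lesion$radius_frac <= 0 || lesion$radius_frac >= 0.5)
    stop("invalid configuration: radius_frac must lie in (0, 0.5)")
  if (nuclei$radius[1] < 1)
    stop("invalid configuration: blob radii must be >= 1 px")
  if (count < 1) stop("invalid configuration: count must be >= 1")
  structure(list(mode = mode, image_size = as.integer(image_size),
                 count = as.integer(count), seed = as.integer(seed),
                 lesion = lesion, nuclei = nuclei),
            class = "synthetic_spec")
}

sample_seed <- function(seed, index) {
  (as.numeric(seed) * 10007 + as.numeric(index) * 7919) %% 2147483647
}

# smooth random background texture: blurred white noise, rescaled
texture_field <- function(H, W, sigma = 6, amplitude = 0.05) {
  f <- blur_matrix(matrix(stats::rnorm(H * W), H, W), sigma)
  rng <- max(abs(f))
  if (rng == 0) return(matrix(0, H, W))
  f / rng * amplitude
}

#' Generate one synthetic lesion sample
#'
#' The mask is a filled star-convex region with radial boundary
#' `r(theta) = r0 * (1 + sum_k a_k sin(k theta + phi_k))`; the image is a
#' skin-tone background with low-frequency texture, a darker fill inside the
#' lesion, Gaussian blur, pixel noise and optional hair strokes.
#'
#' @param spec a [synthetic_spec()] with `mode = "lesion"`
#' @param index sample index (>= 1); output is deterministic in
#'   `(spec$seed, index)`
#' @return a `sample_pair` with `source = "synthetic"`
#' @export
generate_lesion_sample <- function(spec, index) {
  stopifnot(spec$mode == "lesion")
  with_seed(sample_seed(spec$seed, index), {
    P <- spec$lesion
    H <- spec$image_size[1]; W <- spec$image_size[2]
    cy <- H / 2 + stats::runif(1, -1, 1) * P$center_jitter * H
    cx <- W / 2 + stats::runif(1, -1, 1) * P$center_jitter * W
    r0 <- P$radius_frac * min(H, W) * stats::runif(1, 0.85, 1.15)
    for (attempt in 1:8) {
      amp <- P$irregularity / if (attempt > 1) 2^(attempt - 1) else 1
      a <- stats::runif(P$harmonics, 0, amp) / seq_len(P$harmonics)
      phi <- stats::runif(P$harmonics, 0, 2 * pi)
      radial <- function(theta) {
        m <- rep(1, length(theta))
        for (k in seq_len(P$harmonics))
          m <- m + a[k] * sin(k * theta + phi[k])
        r0 * m
      }
      probe <- radial(seq(0, 2 * pi, length.out = 256))
      if (all(probe > 1)) break # non-degenerate boundary
    }
    g <- dest_grid(H, W)
    dy <- g$y - cy; dx <- g$x - cx
    theta <- atan2(dx, dy)
    fg <- sqrt(dy^2 + dx^2) <= radial(theta)
    mask <- matrix(as.numeric(fg), H, W)

    base <- c(stats::runif(1, 0.75, 0.9), stats::runif(1, 0.55, 0.7),
              stats::runif(1, 0.45, 0.6)) # skin tone RGB
    lesion_col <- base * stats::runif(1, 0.35, 0.55)
    img <- array(0, c(H, W, 3))
    soft <- blur_matrix(mask, P$blur_sigma)
    for (c in 1:3) {
      tex <- texture_field(H, W)
      img[, , c] <- base[c] * (1 + tex) * (1 - soft) + lesion_col[c] * soft
    }
    img <- blur_image(img, P$blur_sigma / 2)
    img <- img + array(stats::rnorm(H * W * 3, 0, P$noise_sd), c(H, W, 3))
    s <- new_sample_pair(pmin(pmax(round(img * 255), 0), 255), mask,
                         sprintf("lesion_%04d", index), "synthetic")
    if (stats::runif(1) < P$hair_prob)
      s <- add_hair_noise(s, augment_config(hair = list(count = c(2L, 5L))))
    s
  })
}

#' Generate one synthetic nuclei sample
#'
#' The mask is a union of `k` ellipses placed by rejection sampling so that
#' centres are at least `min_sep` px apart beyond the sum of radii; the
#' image is a dark field with bright blobs plus noise.
#'
#' @param spec a [synthetic_spec()] with `mode = "nuclei"`
#' @param index sample index (>= 1)
#' @return a `sample_pair`; if placement fails after the retry cap the
#'   sample carries fewer blobs and a warning is raised
#' @export
generate_nuclei_sample <- function(spec, index) {
  stopifnot(spec$mode == "nuclei")
  with_seed(sample_seed(spec$seed, index), {
    P <- spec$nuclei
    H <- spec$image_size[1]; W <- spec$image_size[2]
    k <- if (P$count[1] >= P$count[2]) P$count[1]
    else sample(P$count[1]:P$count[2], 1L)
    centers <- matrix(0, 0, 2)
    radii <- numeric(0)
    tries <- 0L
    while (nrow(centers) < k && tries < 200L * k) {
      tries <- tries + 1L
      r <- stats::runif(1, P$radius[1], P$radius[2])
      cy <- stats::runif(1, r + 1, H - r)
      cx <- stats::runif(1, r + 1, W - r)
      if (nrow(centers)) {
        d <- sqrt((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2)
        if (any(d < radii + r + P$min_sep)) next
      }
      centers <- rbind(centers, c(cy, cx))
      radii <- c(radii, r)
    }
    if (nrow(centers) < k)
      warning("nuclei placement: only ", nrow(centers), " of ", k,
              " blobs placed")
    g <- dest_grid(H, W)
    mask <- matrix(0, H, W)
    for (i in seq_len(nrow(centers))) {
      ecc <- stats::runif(1, 0.7, 1)
      ang <- stats::runif(1, 0, pi)
      dy <- g$y - centers[i, 1]; dx <- g$x - centers[i, 2]
      u <- cos(ang) * dy + sin(ang) * dx
      v <- -sin(ang) * dy + cos(ang) * dx
      inside <- (u / radii[i])^2 + (v / (radii[i] * ecc))^2 <= 1
      mask[inside] <- 1
    }
    bg <- stats::runif(1, 0.05, 0.15)
    soft <- blur_matrix(mask, 0.8)
    img <- array(0, c(H, W, 3))
    tint <- c(stats::runif(1, 0.7, 0.9), stats::runif(1, 0.7, 0.9),
              stats::runif(1, 0.8, 1))
    for (c in 1:3)
      img[, , c] <- bg * (1 + texture_field(H, W)) +
        (tint[c] - bg) * soft +
        stats::rnorm(H * W, 0, 0.02)
    new_sample_pair(pmin(pmax(round(img * 255), 0), 255), mask,
                    sprintf("nuclei_%04d", index), "synthetic")
  })
}

#' Generate one synthetic sample of the configured mode
#' @inheritParams generate_lesion_sample
#' @export
generate_sample <- function(spec, index) {
  if (spec$mode == "lesion") generate_lesion_sample(spec, index)
  else generate_nuclei_sample(spec, index)
}

#' Generate and write a synthetic dataset
#'
#' Writes `images/` and `masks/` PNG trees with `spec$count` pairs plus a
#' tab-separated manifest; the written pairs round-trip losslessly through
#' [load_sample_pair()].
#'
#' @param spec a [synthetic_spec()]
#' @param out_dir writable output directory
#' @return the manifest data frame (invisibly written to
#'   `manifest.tsv`)
#' @export
generate_dataset <- function(spec, out_dir) {
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE,
             showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("I/O error: cannot create ", out_dir)
  rows <- lapply(seq_len(spec$count), function(i) {
    s <- generate_sample(spec, i)
    png::writePNG(s$image / 255,
                  file.path(out_dir, "images", paste0(s$identifier, ".png")))
    png::writePNG(s$mask, file.path(out_dir, "masks",
                                    paste0(s$identifier, ".png")))
    data.frame(id = s$identifier, mode = spec$mode, seed = spec$seed,
               index = i, foreground_fraction = round(mean(s$mask), 5),
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest
}

#' Generate an in-memory list of synthetic sample pairs
#' @inheritParams generate_dataset
#' @export
generate_pairs <- function(spec) {
  lapply(seq_len(spec$count), function(i) generate_sample(spec, i))
}
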