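# Low-level raster helpers: bilinear/nearest sampling with configurable
# border handling, geometric transforms shared between image and mask, and
# a small separable Gaussian blur.  Images are (H, W) matrices or (H, W, C)
# arrays of doubles.

# reflect an index vector into [1, n] (mirror without repeating the edge)
reflect_index <- function(i, n) {
  if (n == 1) return(rep(1, length(i)))
  p <- 2 * (n - 1)
  j <- (i - 1) %% p
  j <- ifelse(j < 0, j + p, j)
  ifelse(j >= n, p - j, j) + 1
}

clamp_index <- function(i, n) pmin(pmax(i, 1), n)

# sample a single-channel matrix at fractional coordinates (ys, xs)
sample_channel <- function(m, ys, xs, method = c("bilinear", "nearest"),
                           border = c("reflect", "zero")) {
  method <- match.arg(method)
  border <- match.arg(border)
  H <- nrow(m); W <- ncol(m)
  fetch <- function(iy, ix) {
    if (border == "reflect") {
      iy2 <- reflect_index(iy, H); ix2 <- reflect_index(ix, W)
      m[cbind(iy2, ix2)]
    } else {
      inside <- iy >= 1 & iy <= H & ix >= 1 & ix <= W
      v <- numeric(length(iy))
      v[inside] <- m[cbind(iy[inside], ix[inside])]
      v
    }
  }
  if (method == "nearest") return(fetch(round(ys), round(xs)))
  y0 <- floor(ys); x0 <- floor(xs)
  ty <- ys - y0; tx <- xs - x0
  (1 - ty) * (1 - tx) * fetch(y0, x0) +
    (1 - ty) * tx * fetch(y0, x0 + 1) +
    ty * (1 - tx) * fetch(y0 + 1, x0) +
    ty * tx * fetch(y0 + 1, x0 + 1)
}

sample_image <- function(img, ys, xs, H, W, method, border) {
  if (length(dim(img)) == 2) {
    out <- sample_channel(img, ys, xs, method, border)
    dim(out) <- c(H, W)
    return(out)
  }
  C <- dim(img)[3]
  out <- array(0, c(H, W, C))
  for (c in seq_len(C))
    out[, , c] <- sample_channel(img[, , c], ys, xs, method, border)
  out
}

# destination grid as flat coordinate vectors (row index varies fastest)
dest_grid <- function(H, W) {
  list(y = rep(seq_len(H), times = W), x = rep(seq_len(W), each = H))
}

#' Resize a raster to a target size
#'
#' @param img `(H, W)` matrix or `(H, W, C)` array
#' @param h,w target size
#' @param method `"bilinear"` (images) or `"nearest"` (masks)
#' @return resized raster
#' @export
resize_image <- function(img, h, w, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  d <- dim(img)
  g <- dest_grid(h, w)
  ys <- (g$y - 0.5) * d[1] / h + 0.5
  xs <- (g$x - 0.5) * d[2] / w + 0.5
  sample_image(img, ys, xs, h, w, method, "reflect")
}

# rotate about the centre by `angle` degrees; image gets bilinear sampling
# with reflected borders, mask gets nearest with zero fill
rotate_raster <- function(img, angle, method, border) {
  d <- dim(img)
  H <- d[1]; W <- d[2]
  th <- angle * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  g <- dest_grid(H, W)
  dy <- g$y - cy; dx <- g$x - cx
  ys <- cos(th) * dy - sin(th) * dx + cy
  xs <- sin(th) * dy + cos(th) * dx + cx
  sample_image(img, ys, xs, H, W, method, border)
}

crop_raster <- function(img, y0, x0, hc, wc) {
  d <- dim(img)
  if (length(d) == 2) img[y0:(y0 + hc - 1), x0:(x0 + wc - 1)]
  else img[y0:(y0 + hc - 1), x0:(x0 + wc - 1), , drop = FALSE]
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k / sum(k)
}

# separable Gaussian blur with replicated borders
blur_matrix <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- gaussian_kernel(sigma)
  r <- (length(k) - 1L) %/% 2L
  H <- nrow(m); W <- ncol(m)
  # rows
  out <- matrix(0, H, W)
  for (j in seq_along(k)) {
    sh <- j - r - 1L
    idx <- clamp_index(seq_len(H) + sh, H)
    out <- out + k[j] * m[idx, , drop = FALSE]
  }
  m2 <- out
  out <- matrix(0, H, W)
  for (j in seq_along(k)) {
    sh <- j - r - 1L
    idx <- clamp_index(seq_len(W) + sh, W)
    out <- out + k[j] * m2[, idx, drop = FALSE]
  }
  out
}

blur_image <- function(img, sigma) {
  if (length(dim(img)) == 2) return(blur_matrix(img, sigma))
  for (c in seq_len(dim(img)[3])) img[, , c] <- blur_matrix(img[, , c], sigma)
  img
}
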