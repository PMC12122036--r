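# Combined BCE-Dice training objective.  The plain-array functions below are
# the reference implementations used for reporting; t_combined_loss builds
# the same quantity on the autodiff tape for training.

#' Loss weights for the combined BCE-Dice objective
#'
#' @param alpha weight of the Dice term, in `[0, 1]`
#' @param beta weight of the binary cross-entropy term, in `[0, 1]`
#' @return a `loss_weights` list
#' @export
loss_weights <- function(alpha = 0.7, beta = 0.3) {
  if (alpha < 0 || alpha > 1 || beta < 0 || beta > 1)
    stop("invalid configuration: loss weights must lie in [0, 1]")
  structure(list(alpha = alpha, beta = beta), class = "loss_weights")
}

check_loss_shapes <- function(p, g) {
  if (!identical(dim(p), dim(g)) || length(p) != length(g))
    stop("invalid input: prediction and ground-truth shapes differ (",
         paste(dim(p), collapse = "x"), " vs ", paste(dim(g), collapse = "x"),
         ")")
}

#' Soft Dice loss
#'
#' `1 - 2 * sum(p g) / (sum(p^2) + sum(g^2) + eps)` over all pixels.
#'
#' @param p predicted probabilities in `[0, 1]`
#' @param g binary ground truth of the same shape
#' @param eps denominator stabiliser
#' @return non-negative scalar
#' @export
dice_loss <- function(p, g, eps = 1e-6) {
  check_loss_shapes(p, g)
  1 - 2 * sum(p * g) / (sum(p^2) + sum(g^2) + eps)
}

#' Binary cross-entropy loss
#'
#' Pixel mean of `-(g log p + (1 - g) log(1 - p))` with probabilities
#' clamped to `[eps, 1 - eps]`.
#'
#' @inheritParams dice_loss
#' @export
bce_loss <- function(p, g, eps = 1e-6) {
  check_loss_shapes(p, g)
  pc <- pmin(pmax(p, eps), 1 - eps)
  -mean(g * log(pc) + (1 - g) * log(1 - pc))
}

#' Combined BCE-Dice loss
#'
#' `alpha * dice_loss + beta * bce_loss`, defaulting to the (0.7, 0.3)
#' weighting under which the network is trained.
#'
#' @inheritParams dice_loss
#' @param w a [loss_weights()]
#' @export
combined_loss <- function(p, g, w = loss_weights(), eps = 1e-6) {
  w$alpha * dice_loss(p, g, eps) + w$beta * bce_loss(p, g, eps)
}

# tape versions ----------------------------------------------------------

t_dice_loss <- function(p, g, eps = 1e-6) {
  pv <- p$value
  spg <- sum(pv * g)
  den <- sum(pv^2) + sum(g^2) + eps
  new_tensor(1 - 2 * spg / den, list(p), function(dy) {
    list(dy * (-2) * (g * den - spg * 2 * pv) / den^2)
  })
}

t_bce_loss <- function(p, g, eps = 1e-6) {
  pc <- pmin(pmax(p$value, eps), 1 - eps)
  n <- length(pc)
  new_tensor(-mean(g * log(pc) + (1 - g) * log(1 - pc)), list(p),
             function(dy) {
               inside <- p$value > eps & p$value < 1 - eps
               list(dy * inside * (-g / pc + (1 - g) / (1 - pc)) / n)
             })
}

t_combined_loss <- function(p, g, w = loss_weights(), eps = 1e-6) {
  dl <- t_dice_loss(p, g, eps)
  bl <- t_bce_loss(p, g, eps)
  new_tensor(w$alpha * dl$value + w$beta * bl$value, list(dl, bl),
             function(dy) list(dy * w$alpha, dy * w$beta))
}
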