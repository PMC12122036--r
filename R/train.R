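# Training and inference: Adam optimiser, mini-batch fitting with the
# combined BCE-Dice loss, plateau learning-rate decay, best-by-validation
# checkpointing, and batch prediction/evaluation helpers.

adam_new <- function(params, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$params <- params
  st$lr <- lr
  st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st$t <- 0
  st$m <- lapply(params, function(p) p$value * 0)
  st$v <- lapply(params, function(p) p$value * 0)
  st
}

adam_step <- function(st) {
  st$t <- st$t + 1
  bc1 <- 1 - st$beta1^st$t
  bc2 <- 1 - st$beta2^st$t
  for (i in seq_along(st$params)) {
    p <- st$params[[i]]
    g <- p$grad
    if (is.null(g)) next
    st$m[[i]] <- st$beta1 * st$m[[i]] + (1 - st$beta1) * g
    st$v[[i]] <- st$beta2 * st$v[[i]] + (1 - st$beta2) * g^2
    p$value <- p$value - st$lr * (st$m[[i]] / bc1) /
      (sqrt(st$v[[i]] / bc2) + st$eps)
    p$grad <- NULL
  }
  invisible(st)
}

# stack a list of sample pairs into model input/target arrays at the given
# resolution; images are scaled to [0, 1]
stack_pairs <- function(pairs, size) {
  B <- length(pairs)
  x <- array(0, c(size[1], size[2], 3, B))
  y <- array(0, c(size[1], size[2], 1, B))
  for (b in seq_len(B)) {
    img <- pairs[[b]]$image / 255
    msk <- pairs[[b]]$mask
    if (!identical(dim(img)[1:2], as.integer(size))) {
      img <- resize_image(img, size[1], size[2], "bilinear")
      msk <- resize_image(msk, size[1], size[2], "nearest")
    }
    x[, , , b] <- img
    y[, , 1, b] <- (msk > 0.5) * 1
  }
  list(x = x, y = y)
}

batch_dsc <- function(p, g, threshold = 0.5) {
  pm <- binarize_prediction(p, threshold)
  rep <- segmentation_metrics(pm, g, hausdorff = FALSE)
  mean(rep$per_image$dsc)
}

#' Fit a network on sample pairs with the combined BCE-Dice loss
#'
#' Trains with Adam, optional online augmentation, per-epoch validation
#' metrics, best-by-validation-DSC weight tracking and plateau learning-rate
#' decay (halved after `patience` epochs without improvement of the
#' monitored loss).
#'
#' @param net a `defif_net` (modified in place; also returned)
#' @param train_pairs list of `sample_pair`s
#' @param val_pairs optional validation list; when `NULL` the training loss
#'   is monitored instead
#' @param epochs number of epochs
#' @param batch_size mini-batch size
#' @param lr initial Adam learning rate
#' @param weights a [loss_weights()]
#' @param augment optional [augment_config()] applied online per epoch
#' @param size training resolution `(H, W)`; defaults to the model input
#' @param seed seed for shuffling/augmentation
#' @param decay_factor learning-rate decay multiplier on plateau
#' @param patience plateau patience in epochs
#' @param dsc_stop optional early-stop target for the training-batch DSC
#' @param verbose print per-epoch progress
#' @return list with `net`, `history` (one row per epoch), `best` (epoch,
#'   val_dsc, params snapshot)
#' @export
fit_network <- function(net, train_pairs, val_pairs = NULL, epochs = 10L,
                        batch_size = 8L, lr = 1e-4,
                        weights = loss_weights(), augment = NULL,
                        size = NULL, seed = 1L, decay_factor = 0.5,
                        patience = 10L, dsc_stop = NULL, verbose = FALSE) {
  if (is.null(size)) size <- net$config$input_size
  params <- collect_params(net$state)
  opt <- adam_new(params, lr)
  set.seed(seed)
  val <- if (!is.null(val_pairs)) stack_pairs(val_pairs, size)
  n <- length(train_pairs)
  hist <- vector("list", epochs)
  best <- list(epoch = 0L, val_dsc = -Inf, params = NULL, bn = NULL)
  monitor_best <- Inf
  stale <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    ep_dsc <- 0
    nb <- 0L
    for (b0 in seq(1L, n, by = batch_size)) {
      idx <- ord[b0:min(b0 + batch_size - 1L, n)]
      pairs <- train_pairs[idx]
      if (!is.null(augment))
        pairs <- lapply(pairs, augment_pair, cfg = augment)
      batch <- stack_pairs(pairs, size)
      p <- defifnet_forward(net, t_const(batch$x), training = TRUE)
      loss <- t_combined_loss(p, batch$y, weights)
      if (!is.finite(loss$value))
        stop("numeric failure: non-finite loss at epoch ", ep,
             ", batch starting at sample ", b0)
      backward(loss)
      adam_step(opt)
      ep_loss <- ep_loss + loss$value * length(idx)
      ep_dsc <- ep_dsc + batch_dsc(p$value, batch$y) * length(idx)
      nb <- nb + length(idx)
    }
    train_loss <- ep_loss / nb
    train_dsc <- ep_dsc / nb
    val_loss <- NA_real_
    val_dsc <- NA_real_
    if (!is.null(val)) {
      pv <- defifnet_forward(net, val$x, training = FALSE)
      val_loss <- combined_loss(pv, val$y, weights)
      val_dsc <- batch_dsc(pv, val$y)
      if (val_dsc > best$val_dsc) {
        best <- list(epoch = ep, val_dsc = val_dsc,
                     params = lapply(params, function(p) p$value),
                     bn = lapply(collect_bn_states(net$state),
                                 function(e) list(mean = e$mean,
                                                  var = e$var)))
      }
    }
    monitor <- if (!is.null(val)) val_loss else train_loss
    if (monitor < monitor_best - 1e-6) {
      monitor_best <- monitor
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= patience) {
        opt$lr <- opt$lr * decay_factor
        stale <- 0L
        if (verbose) message("  lr decayed to ", opt$lr)
      }
    }
    hist[[ep]] <- data.frame(epoch = ep, train_loss = train_loss,
                             train_dsc = train_dsc, val_loss = val_loss,
                             val_dsc = val_dsc, lr = opt$lr)
    if (verbose)
      message(sprintf("epoch %3d loss %.4f dsc %.3f val_dsc %.3f", ep,
                      train_loss, train_dsc, val_dsc))
    if (!is.null(dsc_stop) && train_dsc >= dsc_stop) break
  }
  history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
  if (!is.null(best$params)) {
    # restore the best-by-validation weights
    for (nm in names(params)) params[[nm]]$value <- best$params[[nm]]
    bns <- collect_bn_states(net$state)
    for (nm in names(bns)) {
      bns[[nm]]$mean <- best$bn[[nm]]$mean
      bns[[nm]]$var <- best$bn[[nm]]$var
    }
  }
  list(net = net, history = history,
       best = best[c("epoch", "val_dsc")])
}

#' Predict probability maps for a batch of images
#'
#' @param net a `defif_net`
#' @param images `(H, W, 3, B)` array in `[0, 1]`, or a list of
#'   `sample_pair`s / `(H, W, 3)` arrays (0-255 integer pairs are rescaled)
#' @param size inference resolution; defaults to the model input size
#' @return `(size, size, 1, B)` array of probabilities
#' @export
predict_probabilities <- function(net, images, size = NULL) {
  if (is.null(size)) size <- net$config$input_size
  if (is.list(images)) {
    B <- length(images)
    x <- array(0, c(size[1], size[2], 3, B))
    for (b in seq_len(B)) {
      img <- images[[b]]
      if (inherits(img, "sample_pair")) img <- img$image
      if (max(img) > 1) img <- img / 255
      if (!identical(dim(img)[1:2], as.integer(size)))
        img <- resize_image(img, size[1], size[2], "bilinear")
      x[, , , b] <- img
    }
  } else x <- images
  defifnet_forward(net, x, training = FALSE)
}

#' Evaluate a network on sample pairs
#'
#' @param net a `defif_net`
#' @param pairs list of `sample_pair`s
#' @param threshold binarisation threshold
#' @param size evaluation resolution
#' @return a `metric_report`
#' @export
evaluate_network <- function(net, pairs, threshold = 0.5, size = NULL) {
  if (is.null(size)) size <- net$config$input_size
  d <- stack_pairs(pairs, size)
  p <- defifnet_forward(net, d$x, training = FALSE)
  segmentation_metrics(binarize_prediction(p, threshold), d$y,
                       ids = vapply(pairs, function(s) s$identifier,
                                    character(1)))
}
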