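# Full network assembly: dual encoder (local 3x3 stream + global-dependency
# 7x7 stream fused per level by FIFConv), CFRM skip connections, a
# bottleneck of two 3x3 convolutions plus an MBGM, residual
# feature-enhancement decoder levels, and a 1x1 segmentation head.

#' Model configuration
#'
#' @param depth number of encoder levels L (default 4)
#' @param channels per-level channel widths `c_1..c_L`; all must be even.
#'   The default doubling schedule is fixed by the calibration script in
#'   `scripts/calibrate_channels.R`, which selects the schedule whose
#'   parameter and multiply-accumulate totals best match the published
#'   compute budget of the architecture (0.24 M parameters, 0.33 GMACs at
#'   256x256).
#' @param bottleneck_width channel width of the bottleneck stage
#' @param input_size `(height, width)` in pixels, each divisible by `2^depth`
#' @param in_channels input image channels (3 for RGB)
#' @param num_classes output classes; 1 gives a sigmoid head, >1 softmax
#' @param seed integer seed for weight initialisation
#' @return a `defif_config` list
#' @export
model_config <- function(depth = 4L,
                         channels = c(4L, 8L, 16L, 32L),
                         bottleneck_width = 32L,
                         input_size = c(256L, 256L),
                         in_channels = 3L,
                         num_classes = 1L,
                         seed = 42L) {
  depth <- as.integer(depth)
  channels <- as.integer(channels)
  if (depth < 1L) stop("invalid configuration: depth must be >= 1")
  if (length(channels) != depth)
    stop("invalid configuration: need one channel width per level")
  if (any(channels %% 2L != 0L))
    stop("invalid configuration: channel widths must be even")
  if (any(input_size %% 2L^depth != 0L))
    stop("invalid configuration: input size must be divisible by 2^depth")
  structure(list(depth = depth, channels = channels,
                 bottleneck_width = as.integer(bottleneck_width),
                 input_size = as.integer(input_size),
                 in_channels = as.integer(in_channels),
                 num_classes = as.integer(num_classes),
                 seed = as.integer(seed)),
            class = "defif_config")
}

#' Build a network from a configuration
#'
#' @param config a [model_config()]
#' @return a `defif_net` object holding the configuration and all parameter
#'   tensors, keyed by level
#' @export
build_network <- function(config = model_config()) {
  stopifnot(inherits(config, "defif_config"))
  set.seed(config$seed)
  L <- config$depth
  ch <- config$channels
  bw <- config$bottleneck_width
  enc <- vector("list", L)
  dec <- vector("list", L)
  for (i in seq_len(L)) {
    cin <- if (i == 1L) config$in_channels else ch[i - 1L]
    enc[[i]] <- list(
      conv1 = new_cbr(3L, cin, ch[i]),
      conv2 = new_cbr(3L, ch[i], ch[i]),
      gdf = new_cbr(7L, cin, ch[i]),
      fif = fifconv_params(ch[i]),
      cfrm = cfrm_params(ch[i]))
  }
  bottleneck <- list(conv1 = new_cbr(3L, ch[L], bw),
                     conv2 = new_cbr(3L, bw, bw),
                     mbgm = mbgm_params(bw, bw, bw))
  for (i in seq_len(L)) {
    cdeep <- if (i == L) bw else ch[i + 1L]
    dec[[i]] <- list(
      up = new_conv(1L, cdeep, ch[i]),
      conv1 = new_cbr(3L, 2L * ch[i], ch[i]),
      conv2 = new_cbr(3L, ch[i], ch[i]),
      fif = fifconv_params(ch[i]))
  }
  head <- new_conv(1L, ch[1L], config$num_classes)
  structure(list(config = config,
                 state = list(encoder = enc, bottleneck = bottleneck,
                              decoder = dec, head = head)),
            class = "defif_net")
}

#' @export
print.defif_net <- function(x, ...) {
  cfg <- x$config
  cat("DEFIF-Net: depth", cfg$depth,
      "channels [", paste(cfg$channels, collapse = ", "), "]",
      "bottleneck", cfg$bottleneck_width, "\n")
  cat("  input", paste(cfg$input_size, collapse = "x"),
      "x", cfg$in_channels, " classes", cfg$num_classes, "\n")
  cat("  trainable parameters:", count_parameters(x), "\n")
  invisible(x)
}

check_finite <- function(t, where) {
  if (!all(is.finite(t$value)))
    stop("numeric failure: non-finite activations at ", where)
  t
}

#' One dual-encoder level
#'
#' Runs the local stream (two 3x3 conv-BN-ReLU layers) and the
#' global-dependency stream (7x7 conv-BN-ReLU), fuses them by elementwise
#' addition refined by FIFConv.
#'
#' @param left_in local-stream input (array or tensor)
#' @param gdf_in global-dependency-stream input
#' @param level encoder level index
#' @param net a `defif_net`
#' @param training logical, batch-norm mode
#' @return list with `left_out` (pre-pooling local features) and `fused`
#'   (the FIFConv-fused map routed to the skip connection and, after
#'   pooling, to the next global-dependency level)
#' @export
encoder_level_forward <- function(left_in, gdf_in, level, net,
                                  training = FALSE) {
  lev <- net$state$encoder[[level]]
  arr_in <- !is_tensor(left_in)
  li <- as_tensor(left_in)
  gi <- as_tensor(gdf_in)
  lo <- cbr_fw(lev$conv2, cbr_fw(lev$conv1, li, training), training)
  gf <- cbr_fw(lev$gdf, gi, training)
  fused <- fifconv_forward(t_add(lo, gf), lev$fif)
  if (arr_in) list(left_out = lo$value, fused = fused$value)
  else list(left_out = lo, fused = fused)
}

#' One residual feature-enhancement decoder level
#'
#' Bilinearly upsamples the deep map, adjusts channels with a 1x1
#' convolution, concatenates with the skip map, reduces with two 3x3
#' conv-BN-ReLU layers to F1, refines with FIFConv to F2, and returns the
#' residual sum F2 + F1.
#'
#' @param deep deeper feature map (half the skip's spatial resolution)
#' @param skip same-level skip feature map
#' @param level decoder level index
#' @param net a `defif_net`
#' @param training logical, batch-norm mode
#' @return feature map of the skip's shape
#' @export
rfe_decoder_level_forward <- function(deep, skip, level, net,
                                      training = FALSE) {
  lev <- net$state$decoder[[level]]
  arr_in <- !is_tensor(deep)
  dt <- as_tensor(deep)
  st <- as_tensor(skip)
  dd <- fm_dims(dt$value)
  ds <- fm_dims(st$value)
  if (!all(2L * dd[1:2] == ds[1:2]))
    stop("invalid input: deep map ", dd[1], "x", dd[2],
         " does not upsample to skip size ", ds[1], "x", ds[2])
  u <- conv_fw(lev$up, t_upsample2(dt))
  f0 <- t_concat_c(u, st)
  f1 <- cbr_fw(lev$conv2, cbr_fw(lev$conv1, f0, training), training)
  f2 <- fifconv_forward(f1, lev$fif)
  out <- t_add(f2, f1)
  if (arr_in) out$value else out
}

#' Full forward pass
#'
#' @param net a `defif_net`
#' @param image `(H, W, in_channels, B)` array or tensor with H, W divisible
#'   by `2^depth`
#' @param training logical, batch-norm mode
#' @return `(H, W, num_classes, B)` map of probabilities in `[0, 1]`
#' @export
defifnet_forward <- function(net, image, training = FALSE) {
  cfg <- net$config
  L <- cfg$depth
  d <- fm_dims(tensor_value(image))
  if (any(d[1:2] %% 2L^L != 0L))
    stop("invalid input: spatial size ", d[1], "x", d[2],
         " not divisible by 2^", L)
  if (d[3] != cfg$in_channels)
    stop("invalid input: expected ", cfg$in_channels, " channels, got ", d[3])
  arr_in <- !is_tensor(image)
  left <- as_tensor(image)
  gdf <- left
  skips <- vector("list", L)
  for (i in seq_len(L)) {
    prof_tag(paste0("encoder_", i))
    r <- encoder_level_forward(left, gdf, i, net, training)
    check_finite(r$fused, paste0("encoder level ", i))
    skips[[i]] <- r$fused
    left <- t_maxpool2(r$left_out)
    gdf <- t_maxpool2(r$fused)
  }
  prof_tag("bottleneck")
  z <- t_add(left, gdf) # merge the two encoder streams
  bn <- net$state$bottleneck
  z <- cbr_fw(bn$conv2, cbr_fw(bn$conv1, z, training), training)
  z <- mbgm_forward(z, bn$mbgm, training)
  check_finite(z, "bottleneck")
  for (i in rev(seq_len(L))) {
    prof_tag(paste0("decoder_", i))
    s <- cfrm_forward(skips[[i]], net$state$encoder[[i]]$cfrm)
    z <- rfe_decoder_level_forward(z, s, i, net, training)
    check_finite(z, paste0("decoder level ", i))
  }
  prof_tag("head")
  logits <- conv_fw(net$state$head, z)
  out <- if (cfg$num_classes == 1L) t_sigmoid(logits) else t_softmax_c(logits)
  prof_tag("untagged")
  if (arr_in) out$value else out
}

# Counters ---------------------------------------------------------------

#' Count trainable parameters
#'
#' Counts every trainable scalar: convolution kernels and biases, batch-norm
#' affine terms, and the CFRM scale/shift vectors.
#'
#' @param net a `defif_net` (or any nested list of parameter tensors)
#' @return integer-valued total
#' @export
count_parameters <- function(net) {
  ps <- collect_params(if (inherits(net, "defif_net")) net$state else net)
  sum(vapply(ps, function(p) length(p$value), numeric(1)))
}

#' Count forward-pass multiply-accumulate operations
#'
#' Runs a profiled forward pass on a zero batch of one image.  Convolutions
#' contribute `k^2 * C_in / groups * C_out * H_out * W_out`; elementwise,
#' normalisation, pooling and resampling stages contribute one (or two, for
#' affine normalisations) operation per output element.
#'
#' @param net a `defif_net`
#' @param input_size `(H, W)`; defaults to the configured input size
#' @return total multiply-accumulate count (numeric)
#' @export
count_macs <- function(net, input_size = net$config$input_size) {
  x <- array(0, c(input_size[1], input_size[2], net$config$in_channels, 1L))
  prof_start()
  on.exit(if (!is.null(.dfn$prof)) prof_stop())
  invisible(defifnet_forward(net, x, training = FALSE))
  p <- prof_stop()
  on.exit()
  sum(p$macs)
}

# per-stage breakdown used by the summary report
macs_by_stage <- function(net, input_size = net$config$input_size) {
  x <- array(0, c(input_size[1], input_size[2], net$config$in_channels, 1L))
  prof_start()
  on.exit(if (!is.null(.dfn$prof)) prof_stop())
  invisible(defifnet_forward(net, x, training = FALSE))
  p <- prof_stop()
  on.exit()
  p$macs
}

params_by_stage <- function(net) {
  st <- net$state
  parts <- c(
    stats::setNames(lapply(seq_along(st$encoder),
                           function(i) st$encoder[[i]]),
                    paste0("encoder_", seq_along(st$encoder))),
    list(bottleneck = st$bottleneck),
    stats::setNames(lapply(seq_along(st$decoder),
                           function(i) st$decoder[[i]]),
                    paste0("decoder_", seq_along(st$decoder))),
    list(head = st$head))
  vapply(parts, count_parameters, numeric(1))
}

#' Model size and compute summary
#'
#' @param net a `defif_net`
#' @param input_size `(H, W)` resolution for the MAC count
#' @return a `defif_summary` list with totals, per-stage breakdowns, and the
#'   counting convention
#' @export
network_summary <- function(net, input_size = net$config$input_size) {
  pars <- count_parameters(net)
  macs <- macs_by_stage(net, input_size)
  structure(list(
    parameters = pars,
    parameters_m = round(pars / 1e6, 2),
    macs = sum(macs),
    macs_g = round(sum(macs) / 1e9, 2),
    input_size = input_size,
    params_by_stage = params_by_stage(net),
    macs_by_stage = macs,
    convention = paste("convolutions: k^2 * C_in/groups * C_out * H_out *",
                       "W_out multiply-accumulates; elementwise, pooling and",
                       "resampling ops counted once per output element")),
    class = "defif_summary")
}

#' @export
print.defif_summary <- function(x, ...) {
  cat(sprintf("Trainable parameters: %d (%.2f M)\n", x$parameters,
              x$parameters / 1e6))
  cat(sprintf("MACs at %dx%d: %.0f (%.2f G)\n", x$input_size[1],
              x$input_size[2], x$macs, x$macs / 1e9))
  cat("Per-stage breakdown (params | MACs):\n")
  for (nm in names(x$params_by_stage)) {
    m <- x$macs_by_stage[nm]
    cat(sprintf("  %-12s %8d | %12.0f\n", nm, x$params_by_stage[nm],
                if (is.na(m)) 0 else m))
  }
  cat(x$convention, "\n")
  invisible(x)
}

# Checkpoints ------------------------------------------------------------

#' Save network weights and configuration to a single file
#'
#' @param net a `defif_net`
#' @param path file path (`.rds`)
#' @export
save_checkpoint <- function(net, path) {
  ps <- collect_params(net$state)
  bns <- collect_bn_states(net$state)
  obj <- list(format = "defifnet-checkpoint-1",
              config = unclass(net$config),
              params = lapply(ps, function(p) p$value),
              bn = lapply(bns, function(e) list(mean = e$mean, var = e$var)))
  saveRDS(obj, path)
  invisible(path)
}

#' Load a network from a checkpoint file
#'
#' @param path file written by [save_checkpoint()]
#' @return a `defif_net` with restored weights and batch-norm statistics
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "defifnet-checkpoint-1"))
    stop("invalid input: not a recognised checkpoint file")
  cfg <- do.call(model_config, obj$config)
  net <- build_network(cfg)
  ps <- collect_params(net$state)
  if (!identical(names(ps), names(obj$params)))
    stop("checkpoint mismatch: parameter structure differs in fields: ",
         paste(setdiff(union(names(ps), names(obj$params)),
                       intersect(names(ps), names(obj$params))),
               collapse = ", "))
  for (nm in names(ps)) {
    v <- obj$params[[nm]]
    dim(v) <- dim(ps[[nm]]$value)
    ps[[nm]]$value <- v
  }
  bns <- collect_bn_states(net$state)
  for (nm in names(bns)) {
    bns[[nm]]$mean <- obj$bn[[nm]]$mean
    bns[[nm]]$var <- obj$bn[[nm]]$var
  }
  net
}
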