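# Reverse-mode automatic differentiation on 4-d feature maps.
#
# A tensor is an environment holding a value (an R array, matrix, vector or
# scalar), an optional backward closure, and references to its parents.  The
# graph is built eagerly; backward() walks nodes in reverse creation order,
# which is a valid topological order for an eagerly built graph.
#
# Feature maps use the layout (H, W, C, B): column-major, so per-channel
# broadcasting can be done with rep(v, each = H*W) recycling over batches.

.dfn <- new.env(parent = emptyenv())
.dfn$nid <- 0
.dfn$prof <- NULL # when non-NULL: env with $macs (named numeric) and $tag

new_tensor <- function(value, parents = list(), backward = NULL,
                       requires_grad = FALSE) {
  t <- new.env(parent = emptyenv())
  .dfn$nid <- .dfn$nid + 1
  t$nid <- .dfn$nid
  t$value <- value
  t$parents <- parents
  t$backward <- backward
  t$requires_grad <- requires_grad ||
    any(vapply(parents, function(p) p$requires_grad, logical(1)))
  t$grad <- NULL
  class(t) <- "dfn_tensor"
  t
}

#' Wrap a numeric array as a trainable parameter tensor
#' @param value numeric array/vector of initial values
#' @keywords internal
t_param <- function(value) new_tensor(value, requires_grad = TRUE)

t_const <- function(value) new_tensor(value)

is_tensor <- function(x) inherits(x, "dfn_tensor")

as_tensor <- function(x) if (is_tensor(x)) x else t_const(x)

tensor_value <- function(x) if (is_tensor(x)) x$value else x

#' @export
print.dfn_tensor <- function(x, ...) {
  d <- dim(x$value)
  cat("<tensor", if (is.null(d)) paste0("len=", length(x$value))
      else paste(d, collapse = "x"),
      if (x$requires_grad) "grad" else "", ">\n")
  invisible(x)
}

# MAC profiling ---------------------------------------------------------

prof_start <- function() {
  .dfn$prof <- new.env(parent = emptyenv())
  .dfn$prof$macs <- numeric(0)
  .dfn$prof$tag <- "untagged"
}

prof_stop <- function() {
  p <- .dfn$prof
  .dfn$prof <- NULL
  p
}

prof_tag <- function(tag) {
  if (!is.null(.dfn$prof)) .dfn$prof$tag <- tag
  invisible(NULL)
}

prof_add <- function(n) {
  p <- .dfn$prof
  if (is.null(p)) return(invisible(NULL))
  cur <- p$macs[p$tag]
  p$macs[p$tag] <- if (is.na(cur)) n else cur + n
  invisible(NULL)
}

# Backward pass ---------------------------------------------------------

#' Run reverse-mode differentiation from a scalar loss tensor
#'
#' Accumulates gradients into the `grad` field of every reachable parameter
#' tensor (gradients from previous calls are overwritten, not accumulated).
#'
#' @param loss scalar output tensor
#' @keywords internal
backward <- function(loss) {
  stopifnot(is_tensor(loss), length(loss$value) == 1)
  # collect reachable grad-requiring nodes
  nodes <- vector("list", 256L)
  nn <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(loss)
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(nd$nid)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    nn <- nn + 1L
    if (nn > length(nodes)) nodes <- c(nodes, vector("list", length(nodes)))
    nodes[[nn]] <- nd
    for (p in nd$parents) if (p$requires_grad) stack[[length(stack) + 1L]] <- p
  }
  nodes <- nodes[seq_len(nn)]
  ord <- order(vapply(nodes, function(n) n$nid, numeric(1)), decreasing = TRUE)
  nodes <- nodes[ord]

  grads <- new.env(parent = emptyenv())
  grads[[as.character(loss$nid)]] <- 1
  for (nd in nodes) {
    g <- grads[[as.character(nd$nid)]]
    if (is.null(g)) next
    if (is.null(nd$backward)) {
      if (nd$requires_grad) nd$grad <- g # leaf parameter
      next
    }
    pg <- nd$backward(g)
    ps <- nd$parents
    for (i in seq_along(ps)) {
      p <- ps[[i]]
      if (!p$requires_grad || is.null(pg[[i]])) next
      key <- as.character(p$nid)
      cur <- grads[[key]]
      grads[[key]] <- if (is.null(cur)) pg[[i]] else cur + pg[[i]]
    }
  }
  invisible(loss)
}

# Shape helpers ---------------------------------------------------------

fm_dims <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) != 4)
    stop("invalid input: expected a 4-d (H, W, C, B) feature map")
  d
}

# broadcast a length-C vector over an (H, W, C, B) array
bc_channel <- function(v, d) rep(v, each = d[1] * d[2])

# broadcast a (C, B) matrix over an (H, W, C, B) array
bc_cb <- function(m, d) rep(as.vector(m), each = d[1] * d[2])

# per-channel sum of an (H, W, C, B) array -> length-C vector
channel_sum <- function(a, d) {
  rowSums(matrix(colSums(matrix(a, nrow = d[1] * d[2])), d[3], d[4]))
}

# per-(channel, batch) sum -> (C, B) matrix
cb_sum <- function(a, d) {
  matrix(colSums(matrix(a, nrow = d[1] * d[2])), d[3], d[4])
}

# Elementwise primitives -------------------------------------------------

t_add <- function(a, b) {
  stopifnot(identical(dim(a$value), dim(b$value)))
  prof_add(length(a$value))
  new_tensor(a$value + b$value, list(a, b),
             function(dy) list(dy, dy))
}

t_mul <- function(a, b) {
  stopifnot(identical(dim(a$value), dim(b$value)))
  av <- a$value; bv <- b$value
  prof_add(length(av))
  new_tensor(av * bv, list(a, b),
             function(dy) list(dy * bv, dy * av))
}

t_relu <- function(x) {
  v <- x$value
  pos <- v > 0
  y <- v * pos
  prof_add(length(v))
  new_tensor(y, list(x), function(dy) list(dy * pos))
}

t_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$value))
  prof_add(length(s))
  new_tensor(s, list(x), function(dy) list(dy * s * (1 - s)))
}

# Structural primitives --------------------------------------------------

t_concat_c <- function(a, b) {
  da <- fm_dims(a$value); db <- fm_dims(b$value)
  stopifnot(all(da[c(1, 2, 4)] == db[c(1, 2, 4)]))
  y <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  y[, , seq_len(da[3]), ] <- a$value
  y[, , da[3] + seq_len(db[3]), ] <- b$value
  ca <- da[3]
  new_tensor(y, list(a, b), function(dy) {
    list(dy[, , seq_len(ca), , drop = FALSE],
         dy[, , ca + seq_len(dim(dy)[3] - ca), , drop = FALSE])
  })
}

t_split_c <- function(x, from, to) {
  d <- fm_dims(x$value)
  y <- x$value[, , from:to, , drop = FALSE]
  new_tensor(y, list(x), function(dy) {
    dx <- array(0, d)
    dx[, , from:to, ] <- dy
    list(dx)
  })
}

t_permute_c <- function(x, perm) {
  d <- fm_dims(x$value)
  stopifnot(length(perm) == d[3])
  inv <- order(perm)
  new_tensor(x$value[, , perm, , drop = FALSE], list(x),
             function(dy) list(dy[, , inv, , drop = FALSE]))
}

# Channel-wise scaling / affine ops --------------------------------------

# scale each (H, W) plane by a per-(channel, batch) scalar gate g: (C, B)
t_channel_scale <- function(x, g) {
  d <- fm_dims(x$value)
  gv <- bc_cb(g$value, d)
  xv <- x$value
  prof_add(length(xv))
  new_tensor(xv * gv, list(x, g), function(dy) {
    list(dy * gv, cb_sum(dy * xv, d))
  })
}

# y = x * w[c] + b[c] with w, b length-C parameter tensors
t_channel_affine <- function(x, w, b) {
  d <- fm_dims(x$value)
  wv <- bc_channel(w$value, d)
  xv <- x$value
  y <- xv * wv + bc_channel(b$value, d)
  dim(y) <- d
  prof_add(2 * length(xv))
  new_tensor(y, list(x, w, b), function(dy) {
    list(dy * wv, channel_sum(dy * xv, d), channel_sum(dy, d))
  })
}

# global average pooling: (H, W, C, B) -> (C, B)
t_gap <- function(x) {
  d <- fm_dims(x$value)
  hw <- d[1] * d[2]
  y <- matrix(colMeans(matrix(x$value, nrow = hw)), d[3], d[4])
  prof_add(length(x$value))
  new_tensor(y, list(x), function(dy) {
    dx <- bc_cb(dy / hw, d)
    dim(dx) <- d
    list(dx)
  })
}

# affine on a (C, B) matrix with length-C parameters: y = m * w + b
t_cb_affine <- function(m, w, b) {
  dm <- dim(m$value)
  mv <- m$value
  y <- mv * w$value + b$value # length-C vectors recycle down columns
  prof_add(2 * length(mv))
  new_tensor(y, list(m, w, b), function(dy) {
    list(dy * w$value, rowSums(dy * mv), rowSums(dy))
  })
}

# Convolution / pooling / resampling -------------------------------------

t_conv2d <- function(x, w, b, pad, groups = 1L) {
  xv <- x$value
  wv <- w$value
  y <- conv2d_fw_cpp(xv, wv, b$value, pad, groups)
  d <- dim(y)
  wd <- dim(wv)
  prof_add(as.numeric(wd[1]) * wd[2] * wd[3] * wd[4] * d[1] * d[2] * d[4])
  new_tensor(y, list(x, w, b), function(dy) {
    r <- conv2d_bw_cpp(xv, wv, dy, pad, groups)
    list(r$dx, r$dw, r$db)
  })
}

t_maxpool2 <- function(x) {
  d <- fm_dims(x$value)
  r <- maxpool2_fw_cpp(x$value)
  prof_add(length(r$y))
  new_tensor(r$y, list(x), function(dy) {
    list(maxpool2_bw_cpp(r$idx, dy, d[1], d[2]))
  })
}

t_upsample2 <- function(x) {
  d <- fm_dims(x$value)
  y <- upsample2_fw_cpp(x$value)
  prof_add(length(y))
  new_tensor(y, list(x), function(dy) {
    list(upsample2_bw_cpp(dy, d[1], d[2]))
  })
}

# Normalisation ----------------------------------------------------------

# batch normalisation over (H, W, B) per channel; running statistics live in
# the plain environment `st` ($mean, $var).
t_batchnorm <- function(x, gamma, beta, st, training,
                        momentum = 0.1, eps = 1e-5) {
  d <- fm_dims(x$value)
  m <- d[1] * d[2] * d[4]
  if (training) {
    mu <- channel_sum(x$value, d) / m
    ex2 <- channel_sum(x$value^2, d) / m
    va <- pmax(ex2 - mu^2, 0)
    st$mean <- (1 - momentum) * st$mean + momentum * mu
    st$var <- (1 - momentum) * st$var + momentum * va * m / max(m - 1, 1)
  } else {
    mu <- st$mean
    va <- st$var
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- (x$value - bc_channel(mu, d)) * bc_channel(istd, d)
  dim(xhat) <- d
  y <- xhat * bc_channel(gamma$value, d) + bc_channel(beta$value, d)
  dim(y) <- d
  prof_add(2 * length(y))
  new_tensor(y, list(x, gamma, beta), function(dy) {
    gB <- bc_channel(gamma$value, d)
    dgamma <- channel_sum(dy * xhat, d)
    dbeta <- channel_sum(dy, d)
    if (training) {
      dxhat <- dy * gB
      s1 <- bc_channel(channel_sum(dxhat, d) / m, d)
      s2 <- bc_channel(channel_sum(dxhat * xhat, d) / m, d)
      dx <- (dxhat - s1 - xhat * s2) * bc_channel(istd, d)
    } else {
      dx <- dy * gB * bc_channel(istd, d)
    }
    dim(dx) <- d
    list(dx, dgamma, dbeta)
  })
}

# group normalisation (no affine): channels partitioned into `groups`
# contiguous groups, normalised per (group, batch) over channels x space
t_groupnorm <- function(x, groups, eps = 1e-5) {
  d <- fm_dims(x$value)
  if (d[3] %% groups != 0)
    stop("invalid configuration: group count ", groups,
         " does not divide channel count ", d[3])
  n <- d[1] * d[2] * d[3] / groups # elements per normalisation set
  m <- matrix(x$value, nrow = n)   # columns = (group, batch)
  mu <- colMeans(m)
  va <- pmax(colMeans(m^2) - mu^2, 0)
  istd <- 1 / sqrt(va + eps)
  xhat <- (m - rep(mu, each = n)) * rep(istd, each = n)
  y <- xhat
  dim(y) <- d
  prof_add(2 * length(y))
  new_tensor(y, list(x), function(dy) {
    dym <- matrix(dy, nrow = n)
    s1 <- rep(colMeans(dym), each = n)
    s2 <- rep(colMeans(dym * xhat), each = n)
    dx <- (dym - s1 - xhat * s2) * rep(istd, each = n)
    dim(dx) <- d
    list(dx)
  })
}

# per-pixel softmax over channels, for multi-class heads
t_softmax_c <- function(x) {
  d <- fm_dims(x$value)
  a <- matrix(aperm(x$value, c(3, 1, 2, 4)), nrow = d[3])
  a <- exp(sweep(a, 2, apply(a, 2, max)))
  s <- sweep(a, 2, colSums(a), "/")
  y <- aperm(array(s, c(d[3], d[1], d[2], d[4])), c(2, 3, 1, 4))
  prof_add(2 * length(y))
  new_tensor(y, list(x), function(dy) {
    dm <- matrix(aperm(dy, c(3, 1, 2, 4)), nrow = d[3])
    ds <- s * sweep(dm, 2, colSums(s * dm))
    dx <- aperm(array(ds, c(d[3], d[1], d[2], d[4])), c(2, 3, 1, 4))
    list(dx)
  })
}
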