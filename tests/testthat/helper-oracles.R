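# Independent straight-line oracles used to validate the package's block
# implementations.  Everything here is deliberately naive plain R (nested
# loops, explicit index arithmetic) and shares no code with the package's
# compiled/taped forward path.

dfn <- asNamespace("defifnet")

# direct convolution by sextuple loop
naive_conv <- function(x, w, b, pad = NULL, groups = 1) {
  d <- dim(x)
  wd <- dim(w)
  kh <- wd[1]; kw <- wd[2]; cing <- wd[3]; cout <- wd[4]
  if (is.null(pad)) pad <- (kh - 1) / 2
  Ho <- d[1] + 2 * pad - kh + 1
  Wo <- d[2] + 2 * pad - kw + 1
  coutg <- cout / groups
  y <- array(0, c(Ho, Wo, cout, d[4]))
  for (bi in seq_len(d[4])) for (oc in seq_len(cout)) {
    g <- ceiling(oc / coutg)
    c0 <- (g - 1) * cing
    for (ho in seq_len(Ho)) for (wo in seq_len(Wo)) {
      s <- b[oc]
      for (ci in seq_len(cing)) for (ki in seq_len(kh)) for (kj in seq_len(kw)) {
        hi <- ho + ki - 1 - pad
        wi <- wo + kj - 1 - pad
        if (hi >= 1 && hi <= d[1] && wi >= 1 && wi <= d[2])
          s <- s + x[hi, wi, c0 + ci, bi] * w[ki, kj, ci, oc]
      }
      y[ho, wo, oc, bi] <- s
    }
  }
  y
}

cv <- function(layer) layer$w$value  # kernel of a conv parameter list
cb <- function(layer) layer$b$value

sigm <- function(z) 1 / (1 + exp(-z))

cat_c <- function(a, b) {
  da <- dim(a); db <- dim(b)
  y <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  y[, , seq_len(da[3]), ] <- a
  y[, , da[3] + seq_len(db[3]), ] <- b
  y
}

# FIFConv evaluated equation by equation
fif_oracle <- function(x, p) {
  C <- dim(x)[3]; h <- C / 2
  x1 <- x[, , 1:h, , drop = FALSE]                       # split
  x2 <- x[, , (h + 1):C, , drop = FALSE]
  x1 <- naive_conv(x1, cv(p$conv1_left), cb(p$conv1_left))     # 1x1 lifts
  x2 <- naive_conv(x2, cv(p$conv1_right), cb(p$conv1_right))
  x1 <- naive_conv(x1, cv(p$group_conv), cb(p$group_conv), groups = 2) +
    naive_conv(x1, cv(p$inner_conv1_left), cb(p$inner_conv1_left))
  x2 <- x2 + naive_conv(x2, cv(p$inner_conv1_right), cb(p$inner_conv1_right))
  y <- cat_c(x1, x2)
  d <- dim(y)
  gate <- apply(y, c(3, 4), mean)                        # global average pool
  gate <- sigm(gate)
  for (c in seq_len(d[3])) for (bi in seq_len(d[4]))
    y[, , c, bi] <- y[, , c, bi] * gate[c, bi]
  y[, , 1:C, , drop = FALSE] + y[, , (C + 1):(2 * C), , drop = FALSE]
}

fif_oracle_gate <- function(x, p) {
  C <- dim(x)[3]; h <- C / 2
  x1 <- naive_conv(x[, , 1:h, , drop = FALSE], cv(p$conv1_left),
                   cb(p$conv1_left))
  x2 <- naive_conv(x[, , (h + 1):C, , drop = FALSE], cv(p$conv1_right),
                   cb(p$conv1_right))
  x1 <- naive_conv(x1, cv(p$group_conv), cb(p$group_conv), groups = 2) +
    naive_conv(x1, cv(p$inner_conv1_left), cb(p$inner_conv1_left))
  x2 <- x2 + naive_conv(x2, cv(p$inner_conv1_right), cb(p$inner_conv1_right))
  sigm(apply(cat_c(x1, x2), c(3, 4), mean))
}

# group normalisation, naive per (group, batch)
naive_gn <- function(x, groups, eps = 1e-5) {
  d <- dim(x)
  cg <- d[3] / groups
  y <- x
  for (bi in seq_len(d[4])) for (g in seq_len(groups)) {
    ch <- (g - 1) * cg + seq_len(cg)
    v <- x[, , ch, bi]
    mu <- mean(v)
    va <- mean((v - mu)^2)
    y[, , ch, bi] <- (v - mu) / sqrt(va + eps)
  }
  y
}

# the 2-group shuffle destination map derived from first principles:
# output slot i takes input channel (i-1) %% 2 * (C/2) + ceiling(i/2)
shuffle_oracle_perm <- function(C) {
  vapply(seq_len(C), function(i) ((i - 1) %% 2) * (C / 2) + ceiling(i / 2),
         numeric(1))
}

cfrm_oracle <- function(x, p) {
  C <- dim(x)[3]; h <- C / 2
  x1 <- x[, , 1:h, , drop = FALSE]
  x2 <- x[, , (h + 1):C, , drop = FALSE]
  gate1 <- sigm(apply(x1, c(3, 4), mean) * p$w_gap$value + p$b_gap$value)
  y1 <- x1
  for (c in seq_len(h)) for (bi in seq_len(dim(x)[4]))
    y1[, , c, bi] <- x1[, , c, bi] * gate1[c, bi]
  gn <- naive_gn(x2, p$gn_groups)
  gate2 <- gn
  for (c in seq_len(h))
    gate2[, , c, ] <- sigm(gn[, , c, , drop = FALSE] * p$w_gn$value[c] +
                             p$b_gn$value[c])
  y2 <- naive_conv(x2, cv(p$branch2_conv), cb(p$branch2_conv),
                   groups = p$branch2_conv$groups) * gate2
  y <- cat_c(y1, y2)
  y[, , shuffle_oracle_perm(C), , drop = FALSE]
}

# eval-mode batch norm with fresh running stats (mean 0, var 1) + ReLU
bnrelu0 <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x)
  y <- x
  for (c in seq_len(d[3]))
    y[, , c, ] <- x[, , c, , drop = FALSE] / sqrt(1 + eps) * gamma[c] + beta[c]
  pmax(y, 0)
}

cbr_oracle <- function(x, l) {
  bnrelu0(naive_conv(x, cv(l$conv), cb(l$conv), groups = l$conv$groups),
          l$bn$gamma$value, l$bn$beta$value)
}

mbgm_oracle <- function(x, p) {
  y <- cbr_oracle(x, p$entry_conv)
  pr <- cbr_oracle(y, p$primary_conv1)
  q <- cbr_oracle(pr, p$secondary_conv1)
  r <- cbr_oracle(pr, p$branch_conv3)
  cbr_oracle(cat_c(q, pr + r), p$exit_conv)
}

# brute-force average Hausdorff over foreground coordinates
hausdorff_oracle <- function(a, b) {
  pa <- which(a == 1, arr.ind = TRUE)
  pb <- which(b == 1, arr.ind = TRUE)
  dmin <- function(p, q) {
    vapply(seq_len(nrow(p)), function(i)
      min(sqrt((p[i, 1] - q[, 1])^2 + (p[i, 2] - q[, 2])^2)), numeric(1))
  }
  (mean(dmin(pa, pb)) + mean(dmin(pb, pa))) / 2
}

# 4-connected component count by flood fill
count_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nlab <- 0L
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (mask[i, j] == 1 && lab[i, j] == 0L) {
      nlab <- nlab + 1L
      queue <- list(c(i, j))
      lab[i, j] <- nlab
      while (length(queue)) {
        p <- queue[[length(queue)]]
        queue[[length(queue)]] <- NULL
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          y <- p[1] + d[1]; x <- p[2] + d[2]
          if (y >= 1 && y <= H && x >= 1 && x <= W &&
              mask[y, x] == 1 && lab[y, x] == 0L) {
            lab[y, x] <- nlab
            queue[[length(queue) + 1L]] <- c(y, x)
          }
        }
      }
    }
  }
  nlab
}

# build a tiny lesion-style pair list quickly
tiny_lesion_pairs <- function(n = 4, size = 32L, seed = 5L) {
  generate_pairs(synthetic_spec("lesion", image_size = c(size, size),
                                count = n, seed = seed))
}
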