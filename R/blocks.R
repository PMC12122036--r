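# The three bespoke layers of the network: the feature interaction fusion
# convolution (FIFConv), the channel feature reconstruction module (CFRM)
# and the multi-branch ghost module (MBGM), plus the channel shuffle.
#
# All forward functions accept either a plain (H, W, C, B) array (returning
# an array) or an autodiff tensor (returning a tensor), so the blocks can be
# used standalone or inside the assembled network.

block_io <- function(x, f) {
  if (is_tensor(x)) return(f(x))
  d <- dim(x)
  if (is.null(d) || length(d) != 4)
    stop("invalid input: expected a 4-d (H, W, C, B) array")
  f(t_const(x))$value
}

check_spatial <- function(x) {
  d <- fm_dims(tensor_value(x))
  if (d[1] < 1 || d[2] < 1) stop("invalid input: empty spatial dimensions")
  d
}

# FIFConv ---------------------------------------------------------------

#' Create parameters for a feature interaction fusion convolution
#'
#' FIFConv splits its C input channels into halves, lifts each half to C
#' channels with a 1x1 convolution, refines the first with a 2-group 3x3
#' convolution plus a parallel 1x1 path and the second with an identity
#' residual plus a 1x1 path, gates the concatenated 2C-channel map with a
#' sigmoid of its global average pool, then re-splits and sums the halves
#' back to C channels.  Convolutions are plain kernel + bias (no
#' normalisation or activation).
#'
#' @param channels even number of input (= output) channels
#' @return parameter list usable with [fifconv_forward()]
#' @export
fifconv_params <- function(channels) {
  C <- as.integer(channels)
  if (C < 2L || C %% 2L != 0L)
    stop("invalid configuration: FIFConv needs an even channel count >= 2, got ", C)
  list(conv1_left = new_conv(1L, C %/% 2L, C),
       conv1_right = new_conv(1L, C %/% 2L, C),
       group_conv = new_conv(3L, C, C, groups = 2L),
       inner_conv1_left = new_conv(1L, C, C),
       inner_conv1_right = new_conv(1L, C, C),
       channels = C)
}

#' Apply a feature interaction fusion convolution
#'
#' @param x `(H, W, C, B)` array or tensor with `C == p$channels`
#' @param p parameters from [fifconv_params()]
#' @return feature map of the same shape as `x`
#' @export
fifconv_forward <- function(x, p) {
  d <- check_spatial(x)
  if (d[3] != p$channels)
    stop("invalid configuration: FIFConv built for ", p$channels,
         " channels, input has ", d[3])
  C <- p$channels
  block_io(x, function(xt) {
    h <- C %/% 2L
    x1 <- t_split_c(xt, 1L, h)                       # tearing
    x2 <- t_split_c(xt, h + 1L, C)
    x1 <- conv_fw(p$conv1_left, x1)                  # lift to C channels
    x2 <- conv_fw(p$conv1_right, x2)
    x1 <- t_add(conv_fw(p$group_conv, x1),           # grouped 3x3 + 1x1
                conv_fw(p$inner_conv1_left, x1))
    x2 <- t_add(x2, conv_fw(p$inner_conv1_right, x2)) # identity residual + 1x1
    y <- t_concat_c(x1, x2)                          # 2C channels
    gate <- t_sigmoid(t_gap(y))                      # per-channel scalar gate
    y <- t_channel_scale(y, gate)
    t_add(t_split_c(y, 1L, C), t_split_c(y, C + 1L, 2L * C)) # re-split + sum
  })
}

# channel shuffle --------------------------------------------------------

shuffle_perm <- function(C, groups) {
  # view channels as `groups` contiguous blocks, then interleave across
  # blocks: column-major reading of the block-by-position matrix
  as.vector(matrix(seq_len(C), nrow = groups, byrow = TRUE))
}

#' Channel shuffle
#'
#' Interleaves channels across `groups` contiguous groups, the fixed
#' permutation that restores cross-group information flow after grouped
#' operations.  Values are unchanged.
#'
#' @param x `(H, W, C, B)` array or tensor
#' @param groups positive integer dividing C
#' @return feature map with permuted channels
#' @export
channel_shuffle <- function(x, groups) {
  d <- fm_dims(tensor_value(x))
  groups <- as.integer(groups)
  if (groups < 1L || d[3] %% groups != 0L)
    stop("invalid configuration: groups (", groups,
         ") must divide channel count (", d[3], ")")
  perm <- shuffle_perm(d[3], groups)
  block_io(x, function(xt) t_permute_c(xt, perm))
}

# CFRM -------------------------------------------------------------------

#' Create parameters for a channel feature reconstruction module
#'
#' CFRM splits the C channels into halves.  The first half is gated by
#' `sigmoid(gap * w_gap + b_gap)` where `gap` is its global average pool;
#' the second half passes through a grouped 3x3 convolution gated by
#' `sigmoid(GroupNorm(x2) * w_gn + b_gn)`.  The halves are concatenated and
#' a 2-group channel shuffle is applied.  The learnable scales initialise to
#' zero and the shifts to one, so a fresh module gates by `sigmoid(1)`.
#'
#' @param channels even channel count C
#' @param gn_groups group-normalisation groups (must divide C/2); defaults
#'   to 2 when C/2 is even, otherwise 1
#' @param conv_groups groups of the 3x3 convolution on the second half;
#'   same default rule
#' @return parameter list usable with [cfrm_forward()]
#' @export
cfrm_params <- function(channels, gn_groups = NULL, conv_groups = NULL) {
  C <- as.integer(channels)
  if (C < 2L || C %% 2L != 0L)
    stop("invalid configuration: CFRM needs an even channel count >= 2, got ", C)
  h <- C %/% 2L
  if (is.null(gn_groups)) gn_groups <- if (h %% 2L == 0L) 2L else 1L
  if (is.null(conv_groups)) conv_groups <- if (h %% 2L == 0L) 2L else 1L
  gn_groups <- as.integer(gn_groups)
  if (h %% gn_groups != 0L)
    stop("invalid configuration: gn_groups (", gn_groups,
         ") must divide C/2 (", h, ")")
  list(w_gap = t_param(numeric(h)), b_gap = t_param(rep(1, h)),
       w_gn = t_param(numeric(h)), b_gn = t_param(rep(1, h)),
       branch2_conv = new_conv(3L, h, h, groups = as.integer(conv_groups)),
       gn_groups = gn_groups, channels = C)
}

#' Apply a channel feature reconstruction module
#'
#' @param x `(H, W, C, B)` array or tensor with `C == p$channels`
#' @param p parameters from [cfrm_params()]
#' @return feature map of the same shape as `x`
#' @export
cfrm_forward <- function(x, p) {
  d <- check_spatial(x)
  if (d[3] != p$channels)
    stop("invalid configuration: CFRM built for ", p$channels,
         " channels, input has ", d[3])
  C <- p$channels
  block_io(x, function(xt) {
    h <- C %/% 2L
    x1 <- t_split_c(xt, 1L, h)
    x2 <- t_split_c(xt, h + 1L, C)
    # branch 1: globally pooled gate
    g1 <- t_sigmoid(t_cb_affine(t_gap(x1), p$w_gap, p$b_gap))
    y1 <- t_channel_scale(x1, g1)
    # branch 2: grouped conv gated by normalised map
    g2 <- t_sigmoid(t_channel_affine(t_groupnorm(x2, p$gn_groups),
                                     p$w_gn, p$b_gn))
    y2 <- t_mul(conv_fw(p$branch2_conv, x2), g2)
    y <- t_concat_c(y1, y2)
    t_permute_c(y, shuffle_perm(C, 2L))
  })
}

# MBGM -------------------------------------------------------------------

#' Create parameters for a multi-branch ghost module
#'
#' The module lifts the input with a 3x3 convolution, then runs a ghost-style
#' primary 1x1 path P, a cheap secondary 1x1 path Q = conv1(P), and an extra
#' 3x3 branch R = conv3(P).  The output is a 3x3 convolution of the
#' concatenation of Q with the residual fusion P + R.  Every convolution is
#' followed by batch normalisation and ReLU.
#'
#' @param in_channels input channel count
#' @param branch_channels internal width C_b (defaults to `in_channels`)
#' @param out_channels output channel count (defaults to `in_channels`)
#' @return parameter list usable with [mbgm_forward()]
#' @export
mbgm_params <- function(in_channels, branch_channels = in_channels,
                        out_channels = in_channels) {
  list(entry_conv = new_cbr(3L, in_channels, branch_channels),
       primary_conv1 = new_cbr(1L, branch_channels, branch_channels),
       secondary_conv1 = new_cbr(1L, branch_channels, branch_channels),
       branch_conv3 = new_cbr(3L, branch_channels, branch_channels),
       exit_conv = new_cbr(3L, 2L * branch_channels, out_channels),
       in_channels = as.integer(in_channels),
       out_channels = as.integer(out_channels))
}

#' Apply a multi-branch ghost module
#'
#' @param x `(H, W, C_in, B)` array or tensor
#' @param p parameters from [mbgm_params()]
#' @param training logical; use batch statistics (TRUE) or running
#'   statistics (FALSE) in the batch-norm layers
#' @return feature map with `p$out_channels` channels, same spatial size
#' @export
mbgm_forward <- function(x, p, training = FALSE) {
  d <- check_spatial(x)
  if (d[3] != p$in_channels)
    stop("invalid configuration: MBGM built for ", p$in_channels,
         " input channels, input has ", d[3])
  block_io(x, function(xt) {
    y <- cbr_fw(p$entry_conv, xt, training)
    pr <- cbr_fw(p$primary_conv1, y, training)
    q <- cbr_fw(p$secondary_conv1, pr, training)
    r <- cbr_fw(p$branch_conv3, pr, training)
    cbr_fw(p$exit_conv, t_concat_c(q, t_add(pr, r)), training)
  })
}
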