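# Bespoke layer blocks: FIFConv, channel shuffle, CFRM, MBGM.

test_that("FIFConv preserves shape, maps zero to zero, rejects bad inputs", {
  set.seed(1)
  for (C in c(2L, 4L, 8L, 16L, 32L)) {
    p <- fifconv_params(C)
    x <- array(rnorm(6 * 5 * C * 2), c(6, 5, C, 2))
    y <- fifconv_forward(x, p)
    expect_identical(dim(y), dim(x))
    expect_true(all(is.finite(y)))
  }
  # zero fixed point: all branches map 0 -> 0 and the sigmoid(0)=0.5 gate
  # preserves zero
  p <- fifconv_params(8L)
  z <- fifconv_forward(array(0, c(4, 4, 8, 1)), p)
  expect_equal(max(abs(z)), 0)
  expect_error(fifconv_params(5L), "even")
  p4 <- fifconv_params(4L)
  expect_error(fifconv_forward(array(0, c(4, 4, 6, 1)), p4),
               "invalid configuration")
})

test_that("FIFConv equals the straight-line per-equation oracle", {
  set.seed(42)
  for (rep in 1:20) {
    C <- sample(c(4L, 6L, 8L), 1)
    H <- sample(3:6, 1); W <- sample(3:6, 1); B <- sample(1:2, 1)
    p <- fifconv_params(C)
    x <- array(rnorm(H * W * C * B), c(H, W, C, B))
    expect_equal(fifconv_forward(x, p), fif_oracle(x, p), tolerance = 1e-5)
    gate <- fif_oracle_gate(x, p)
    expect_true(all(gate > 0 & gate < 1)) # strict boundedness of the gate
  }
})

test_that("FIFConv reproduces a hand-set unit-kernel evaluation", {
  # small integer input, hand-set kernels: every 1x1 kernel averages its
  # inputs, grouped conv is a centre-tap identity within groups
  p <- fifconv_params(4L)
  unit1 <- function(l) {
    l$w$value[] <- 1 / dim(l$w$value)[3]
    l$b$value[] <- 0
  }
  unit1(p$conv1_left); unit1(p$conv1_right)
  unit1(p$inner_conv1_left); unit1(p$inner_conv1_right)
  p$group_conv$w$value[] <- 0
  for (oc in 1:4) p$group_conv$w$value[2, 2, (oc - 1) %% 2 + 1, oc] <- 1
  p$group_conv$b$value[] <- 0
  x <- array(rep(1:4, each = 4), c(2, 2, 4, 1))
  expect_equal(fifconv_forward(x, p), fif_oracle(x, p), tolerance = 1e-12)
})

test_that("channel shuffle is the documented permutation with an inverse", {
  # identity for one group
  x <- array(rnorm(3 * 3 * 6), c(3, 3, 6, 1))
  expect_identical(channel_shuffle(x, 1L), x)
  # C=6, groups=2: channels [0..5] -> [0,3,1,4,2,5]
  lab <- array(0, c(1, 1, 6, 1)); lab[1, 1, , 1] <- 0:5
  expect_equal(as.vector(channel_shuffle(lab, 2L)), c(0, 3, 1, 4, 2, 5))
  # C=4: [a,b,c,d] -> [a,c,b,d]
  lab4 <- array(0, c(1, 1, 4, 1)); lab4[1, 1, , 1] <- 1:4
  expect_equal(as.vector(channel_shuffle(lab4, 2L)), c(1, 3, 2, 4))
  # multiset of channel slices preserved; inverse restores input
  for (g in c(2L, 3L)) {
    y <- channel_shuffle(x, g)
    expect_equal(sort(apply(y, 3, sum)), sort(apply(x, 3, sum)))
    perm <- dfn$shuffle_perm(6L, g)
    inv <- order(perm)
    expect_identical(y[, , inv, , drop = FALSE], x)
  }
  expect_error(channel_shuffle(x, 4L), "divide")
})

test_that("CFRM matches its oracle and honours the pinned initialisation", {
  set.seed(7)
  for (rep in 1:20) {
    C <- sample(c(4L, 8L, 12L), 1)
    H <- sample(3:6, 1); W <- sample(3:6, 1); B <- sample(1:2, 1)
    p <- cfrm_params(C)
    # randomise the learnable gates away from the init for a stronger check
    p$w_gap$value[] <- rnorm(C / 2, 0, 0.5)
    p$b_gap$value[] <- rnorm(C / 2, 1, 0.5)
    p$w_gn$value[] <- rnorm(C / 2, 0, 0.5)
    p$b_gn$value[] <- rnorm(C / 2, 1, 0.5)
    x <- array(rnorm(H * W * C * B), c(H, W, C, B))
    y <- cfrm_forward(x, p)
    expect_identical(dim(y), dim(x))
    expect_equal(y, cfrm_oracle(x, p), tolerance = 1e-5)
  }
  expect_error(cfrm_params(6L, gn_groups = 2L), "divide")
  expect_error(cfrm_params(5L), "even")
})

test_that("freshly initialised CFRM gates branch 1 by sigmoid(1)", {
  set.seed(8)
  C <- 8L
  p <- cfrm_params(C)
  expect_equal(p$w_gap$value, numeric(C / 2)) # zeros/ones initialisers
  expect_equal(p$b_gap$value, rep(1, C / 2))
  # identity branch-2 convolution so only the gates act
  p$branch2_conv$w$value[] <- 0
  cg <- (C / 2) / p$branch2_conv$groups
  for (oc in seq_len(C / 2))
    p$branch2_conv$w$value[2, 2, (oc - 1) %% cg + 1, oc] <- 1
  x <- array(rnorm(5 * 5 * C * 2), c(5, 5, C, 2))
  y <- cfrm_forward(x, p)
  # branch-1 channels land on the odd output slots after the 2-group shuffle
  expect_equal(y[, , seq(1, C, by = 2), , drop = FALSE],
               x[, , seq_len(C / 2), , drop = FALSE] * (1 / (1 + exp(-1))),
               tolerance = 1e-12)
})

test_that("MBGM matches its oracle, preserves shape and the zero point", {
  set.seed(9)
  p <- mbgm_params(32L)
  x <- array(rnorm(8 * 8 * 32), c(8, 8, 32, 1))
  expect_identical(dim(mbgm_forward(x, p)), c(8L, 8L, 32L, 1L))
  # zero fixed point with ReLU when biases and BN shifts are zero
  expect_equal(max(abs(mbgm_forward(array(0, c(4, 4, 32, 1)), p))), 0)
  for (rep in 1:20) {
    cin <- sample(c(2L, 4L), 1); cb <- sample(c(2L, 4L), 1)
    cout <- sample(c(2L, 4L), 1)
    p <- mbgm_params(cin, cb, cout)
    # randomise BN affine away from identity
    for (nm in c("entry_conv", "primary_conv1", "secondary_conv1",
                 "branch_conv3", "exit_conv")) {
      p[[nm]]$bn$gamma$value[] <- runif(length(p[[nm]]$bn$gamma$value), .5, 1.5)
      p[[nm]]$bn$beta$value[] <- rnorm(length(p[[nm]]$bn$beta$value), 0, .3)
    }
    H <- sample(3:5, 1)
    x <- array(rnorm(H * H * cin * 2), c(H, H, cin, 2))
    expect_equal(mbgm_forward(x, p), mbgm_oracle(x, p), tolerance = 1e-5)
  }
  p2 <- mbgm_params(4L)
  expect_error(mbgm_forward(array(0, c(4, 4, 6, 1)), p2),
               "invalid configuration")
})

test_that("MBGM with hand-set kernels follows the two-stage composition", {
  # integer input, small hand-set kernels, BN in identity mode up to the
  # 1/sqrt(1+eps) running-variance factor; intermediates named as in the
  # two defining equations
  p <- mbgm_params(2L, 2L, 2L)
  setk <- function(l, val) { l$conv$w$value[] <- val; l$conv$b$value[] <- 0 }
  setk(p$entry_conv, 0.1)
  setk(p$primary_conv1, 0.25)
  setk(p$secondary_conv1, 0.5)
  setk(p$branch_conv3, 0.05)
  setk(p$exit_conv, 0.02)
  x <- array(rep(c(1, 2), each = 9), c(3, 3, 2, 1))
  s0 <- 1 / sqrt(1 + 1e-5)
  relu <- function(a) pmax(a, 0)
  Y <- relu(naive_conv(x, p$entry_conv$conv$w$value, rep(0, 2)) * s0)
  P <- relu(naive_conv(Y, p$primary_conv1$conv$w$value, rep(0, 2)) * s0)
  Q <- relu(naive_conv(P, p$secondary_conv1$conv$w$value, rep(0, 2)) * s0)
  R <- relu(naive_conv(P, p$branch_conv3$conv$w$value, rep(0, 2)) * s0)
  Z <- relu(naive_conv(cat_c(Q, P + R), p$exit_conv$conv$w$value,
                       rep(0, 2)) * s0)
  expect_equal(mbgm_forward(x, p), Z, tolerance = 1e-10)
})
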