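# Network assembly: encoder/decoder levels, full forward contracts, and the
# parameter / multiply-accumulate counters.

small_net <- function(size = 16L, seed = 31L) {
  build_network(model_config(depth = 2L, channels = c(4L, 8L),
                             bottleneck_width = 8L,
                             input_size = c(size, size), seed = seed))
}

test_that("encoder level fuses the two streams through FIFConv", {
  set.seed(32)
  net <- small_net()
  x <- array(runif(16 * 16 * 3), c(16, 16, 3, 1))
  r <- encoder_level_forward(x, x, 1L, net)
  expect_identical(dim(r$left_out), c(16L, 16L, 4L, 1L))
  expect_identical(dim(r$fused), c(16L, 16L, 4L, 1L))
  # compositional check: fused equals FIFConv of the branch sum evaluated
  # separately
  lev <- net$state$encoder[[1]]
  lo <- dfn$cbr_fw(lev$conv2, dfn$cbr_fw(lev$conv1, dfn$t_const(x)))$value
  gf <- dfn$cbr_fw(lev$gdf, dfn$t_const(x))$value
  expect_equal(r$fused, fifconv_forward(lo + gf, lev$fif), tolerance = 1e-12)
  # zeroed 7x7 kernel: the global-dependency stream contributes only its
  # (BN-shifted) constant; with bias and beta zero it vanishes entirely
  lev$gdf$conv$w$value[] <- 0
  lev$gdf$conv$b$value[] <- 0
  lev$gdf$bn$beta$value[] <- 0
  r2 <- encoder_level_forward(x, x, 1L, net)
  expect_equal(r2$fused, fifconv_forward(r2$left_out, lev$fif),
               tolerance = 1e-12)
})

test_that("decoder level implements upsample-concat-reduce-refine-residual", {
  set.seed(33)
  net <- small_net()
  deep <- array(rnorm(8 * 8 * 8), c(8, 8, 8, 1))
  skip <- array(rnorm(16 * 16 * 4), c(16, 16, 4, 1))
  out <- rfe_decoder_level_forward(deep, skip, 1L, net)
  expect_identical(dim(out), dim(skip))
  # straight-line oracle of the five named steps
  lev <- net$state$decoder[[1]]
  u <- naive_conv(dfn$upsample2_fw_cpp(deep), cv(lev$up), cb(lev$up))
  f0 <- cat_c(u, skip)
  f1 <- cbr_oracle(cbr_oracle(f0, lev$conv1), lev$conv2)
  f2 <- fif_oracle(f1, lev$fif)
  expect_equal(out, f2 + f1, tolerance = 1e-5)
  # residual identity: output minus F1 equals FIFConv(F1) exactly
  f1_pkg <- dfn$cbr_fw(lev$conv2, dfn$cbr_fw(
    lev$conv1, dfn$t_concat_c(
      dfn$conv_fw(lev$up, dfn$t_upsample2(dfn$t_const(deep))),
      dfn$t_const(skip))))$value
  expect_equal(out - f1_pkg, fifconv_forward(f1_pkg, lev$fif),
               tolerance = 1e-12)
  # resolution mismatch is rejected
  expect_error(rfe_decoder_level_forward(deep, skip[1:8, 1:8, , ,
                                                    drop = FALSE], 1L, net),
               "invalid input")
})

test_that("full forward keeps spatial size and probability range", {
  for (size in c(64L, 128L)) {
    net <- build_network(model_config(input_size = c(size, size), seed = 41L))
    x <- array(runif(size * size * 3 * 1), c(size, size, 3, 1))
    p <- defifnet_forward(net, x)
    expect_identical(dim(p), c(size, size, 1L, 1L))
    expect_true(all(p >= 0 & p <= 1))
  }
  # determinism in eval mode: identical batches give identical outputs
  net <- small_net()
  x <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  expect_identical(defifnet_forward(net, x), defifnet_forward(net, x))
  expect_error(defifnet_forward(net, array(0, c(10, 10, 3, 1))),
               "divisible")
})

test_that("multi-class head produces a per-pixel simplex", {
  net <- build_network(model_config(depth = 2L, channels = c(4L, 8L),
                                    bottleneck_width = 8L,
                                    input_size = c(16L, 16L),
                                    num_classes = 3L, seed = 42L))
  x <- array(runif(16 * 16 * 3), c(16, 16, 3, 1))
  p <- defifnet_forward(net, x)
  expect_identical(dim(p), c(16L, 16L, 3L, 1L))
  sums <- apply(p, c(1, 2, 4), sum)
  expect_true(all(abs(sums - 1) < 1e-6))
})

test_that("parameter counter matches hand-computed single-layer totals", {
  set.seed(43)
  expect_equal(count_parameters(list(dfn$new_conv(1L, 4L, 4L))), 20)
  expect_equal(count_parameters(list(dfn$new_conv(3L, 3L, 8L))), 224)
  # additivity over composition
  a <- dfn$new_conv(3L, 3L, 8L)
  b <- dfn$new_conv(1L, 8L, 2L)
  expect_equal(count_parameters(list(a, b)),
               count_parameters(list(a)) + count_parameters(list(b)))
  # grouped convolution divides kernel parameters by the group count
  expect_equal(count_parameters(list(dfn$new_conv(3L, 8L, 8L, groups = 2L))),
               3 * 3 * 4 * 8 + 8)
})

test_that("MAC counter matches hand-computed values and scales quadratically", {
  set.seed(44)
  x <- dfn$t_const(array(0, c(8, 8, 4, 1)))
  l <- dfn$new_conv(1L, 4L, 4L)
  dfn$prof_start()
  invisible(dfn$conv_fw(l, x))
  p <- dfn$prof_stop()
  expect_equal(sum(p$macs), 4 * 4 * 64) # 1024
  # halving all channel widths divides convolution MACs by ~4
  net1 <- build_network(model_config(depth = 2L, channels = c(8L, 16L),
                                     bottleneck_width = 16L,
                                     input_size = c(32L, 32L), seed = 45L))
  net2 <- build_network(model_config(depth = 2L, channels = c(4L, 8L),
                                     bottleneck_width = 8L,
                                     input_size = c(32L, 32L), seed = 45L))
  r <- count_macs(net1) / count_macs(net2)
  expect_gt(r, 3.2)
  expect_lt(r, 4.2)
})

test_that("summary, checkpoint save/load round-trip preserve behaviour", {
  set.seed(46)
  net <- small_net()
  s <- network_summary(net)
  expect_equal(s$parameters, count_parameters(net))
  expect_equal(s$macs, count_macs(net))
  expect_equal(sum(s$params_by_stage), s$parameters)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3, 1))
  p1 <- defifnet_forward(net, x)
  f <- tempfile(fileext = ".rds")
  save_checkpoint(net, f)
  net2 <- load_checkpoint(f)
  expect_equal(defifnet_forward(net2, x), p1, tolerance = 1e-12)
  unlink(f)
})
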