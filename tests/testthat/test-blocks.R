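bypass_cfg <- function(width, ...) {
  block_config(width, ..., bn_identity = TRUE,
               cbam = cbam_config(enabled = FALSE))
}

test_that("identity-configured residual block reproduces its input exactly", {
  set.seed(31)
  blk <- identity_cbres(3)
  x <- array(rnorm(5 * 5 * 3 * 2), c(5, 5, 3, 2))   # signed input
  expect_equal(block_forward(blk, x), x, tolerance = 1e-14)
})

test_that("blocks project any input depth to the configured width", {
  set.seed(32)
  x <- array(rnorm(16 * 16 * 8), c(16, 16, 8, 1))
  for (ctor in list(cbres_block,
                    function(c, cfg) dual_dilate_cb_block(c, block_config(
                      12, dilation_rates = c(1, 2))),
                    function(c, cfg) tridilation_block(c, block_config(
                      12, dilation_rates = c(1, 2, 3))),
                    function(c, cfg) splitfusion_block(c, block_config(12)))) {
    blk <- ctor(8L, block_config(12))
    expect_equal(dim(block_forward(blk, x)), c(16L, 16L, 12L, 1L))
  }
  mb <- mu_block(8L, mu_block_config(12))
  expect_equal(dim(block_forward(mb, x)), c(16L, 16L, 12L, 1L))
})

test_that("residual block equals the two-convolution-plus-shortcut oracle", {
  set.seed(33)
  blk <- cbres_block(1L, bypass_cfg(1, activation = "linear"))
  x <- array(rnorm(25), c(5, 5, 1, 1))
  ka <- array(rnorm(9), c(3, 3, 1, 1))
  kb <- array(rnorm(9), c(3, 3, 1, 1))
  ks <- array(rnorm(1), c(1, 1, 1, 1))
  blk$children$conv_a$params$w <- ka; blk$children$conv_a$params$b[] <- 0
  blk$children$conv_b$params$w <- kb; blk$children$conv_b$params$b[] <- 0
  blk$children$conv_s$params$w <- ks; blk$children$conv_s$params$b[] <- 0
  got <- block_forward(blk, x)
  want <- brute_conv(brute_conv(x, ka), kb) + brute_conv(x, ks)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("zero-configured dilated blocks output zero", {
  x <- array(rnorm(11 * 11 * 4 * 2), c(11, 11, 4, 2))
  dd <- dual_dilate_cb_block(4L, bypass_cfg(6, dilation_rates = c(1, 2)))
  munetseg:::block_zero_weights(dd)
  expect_true(all(block_forward(dd, x) == 0))
  expect_equal(dim(block_forward(dd, x)), c(11L, 11L, 6L, 2L))

  td <- tridilation_block(4L, bypass_cfg(6, dilation_rates = c(1, 2, 3)))
  munetseg:::block_zero_weights(td)
  expect_true(all(block_forward(td, x) == 0))
})

test_that("dilation-rate preconditions are enforced", {
  expect_error(dual_dilate_cb_block(3, block_config(4, dilation_rates = 1)),
               "dilation_rates")
  expect_error(tridilation_block(3, block_config(4, dilation_rates = c(1, 2))),
               "dilation_rates")
  expect_error(cbam_config(spatial_kernel = 4), "odd")
})

impulse_support <- function(block) {
  # all-ones kernels, identity BN, bypassed attention, single impulse
  for (m in munetseg:::nn_modules(block))
    for (nm in names(m$params)) m$params[[nm]][] <- 1
  for (m in munetseg:::nn_modules(block))
    if (m$kind == "conv") m$params$b[] <- 0
  x <- array(0, c(15, 15, 1, 1)); x[8, 8, 1, 1] <- 1
  y <- block_forward(block, x)
  nz <- which(y[, , 1, 1] != 0, arr.ind = TRUE)
  c(diff(range(nz[, 1])) + 1L, diff(range(nz[, 2])) + 1L)
}

test_that("stacked dilated convolutions have the predicted receptive fields", {
  dd <- dual_dilate_cb_block(1L, bypass_cfg(1, dilation_rates = c(1, 2)))
  expect_equal(impulse_support(dd), c(7L, 7L))
  td <- tridilation_block(1L, bypass_cfg(1, dilation_rates = c(1, 2, 3)))
  expect_equal(impulse_support(td), c(13L, 13L))
})

test_that("split block composes to the separable full kernel", {
  set.seed(34)
  u <- rnorm(3)   # 1x3 horizontal kernel
  v <- rnorm(3)   # 3x1 vertical kernel
  blk <- splitfusion_block(1L, bypass_cfg(1, split_n = 3))
  blk$children$conv_h$params$w <- array(u, c(1, 3, 1, 1))
  blk$children$conv_h$params$b[] <- 0
  blk$children$conv_v$params$w <- array(v, c(3, 1, 1, 1))
  blk$children$conv_v$params$b[] <- 0
  x <- array(rnorm(8 * 8), c(8, 8, 1, 1))
  got <- block_forward(blk, x)
  want <- brute_conv(x, array(outer(v, u), c(3, 3, 1, 1)))
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("split block with N = 1 identity kernels passes input through", {
  blk <- splitfusion_block(2L, bypass_cfg(2, split_n = 1))
  munetseg:::block_zero_weights(blk)
  for (i in 1:2) {
    blk$children$conv_h$params$w[1, 1, i, i] <- 1
    blk$children$conv_v$params$w[1, 1, i, i] <- 1
  }
  x <- array(rnorm(7 * 9 * 2), c(7, 9, 2, 1))
  expect_equal(block_forward(blk, x), x, tolerance = 1e-14)
})

test_that("mu-block has six fusion branches and a single-live-branch identity", {
  mb <- mu_block(3L, mu_block_config(3, fusion = "sum", bn_identity = TRUE,
                                     cbam = cbam_config(enabled = FALSE)))
  expect_equal(mb$n_branches, 6L)
  munetseg:::block_zero_weights(mb)
  # revive only the first residual branch as an identity
  for (i in 1:3) mb$children$cbres1$children$conv_s$params$w[1, 1, i, i] <- 1
  set.seed(35)
  x <- array(rnorm(6 * 6 * 3 * 2), c(6, 6, 3, 2))
  expect_equal(block_forward(mb, x), x, tolerance = 1e-14)
})

test_that("averaging projection reproduces the mean of the six branches", {
  set.seed(36)
  mb <- mu_block(4L, mu_block_config(4, fusion = "concat", bn_identity = TRUE,
                                     cbam = cbam_config(enabled = FALSE)))
  munetseg:::mu_block_set_avg_projection(mb)
  x <- array(rnorm(8 * 8 * 4), c(8, 8, 4, 1))
  ch <- mb$children
  t1 <- block_forward(ch$tdau, x)
  t2 <- block_forward(ch$dd, x)
  y1 <- block_forward(ch$cbres1, x)
  y2 <- block_forward(ch$cbres2, y1)
  y3 <- block_forward(ch$cbres3, y2)
  t6 <- block_forward(ch$sf, x)
  want <- (t1 + t2 + y1 + y2 + y3 + t6) / 6
  expect_equal(block_forward(mb, x), want, tolerance = 1e-10)
})

test_that("block parameter counts are identical across rebuilds", {
  n1 <- munetseg:::n_params(mu_block(8L, mu_block_config(16)))
  n2 <- munetseg:::n_params(mu_block(8L, mu_block_config(16)))
  expect_identical(n1, n2)
  expect_gt(n1, 0)
})

test_that("every block preserves spatial dimensions on random sizes", {
  set.seed(37)
  for (i in 1:5) {
    h <- sample(5:14, 1); w <- sample(5:14, 1); cin <- sample(1:5, 1)
    x <- array(rnorm(h * w * cin), c(h, w, cin, 1))
    blk <- mu_block(cin, mu_block_config(sample(2:6, 1)))
    expect_equal(dim(block_forward(blk, x))[1:2], c(h, w))
  }
})
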