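#' Block configuration
#'
#' Shared settings for the bespoke network blocks.  `width` is the output
#' channel count; every block projects its input to `width` channels
#' regardless of the input depth and preserves spatial dimensions exactly
#' (same-padding).
#'
#' @param width positive integer, output channels.
#' @param dilation_rates ordered dilation rates; `c(1, 2)` for the
#'   dual-dilated block, `c(1, 2, 3)` for the tri-dilated block.
#' @param split_n kernel length N of the `1xN` / `Nx1` split block.
#' @param cbam a [cbam_config()].
#' @param activation `"relu"` inserts a ReLU between internal
#'   convolution-BN stages; `"linear"` composes them without a pointwise
#'   nonlinearity, as in the block equations.  The residual block defaults
#'   to `"relu"` (its stages are Convolution-BatchNorm-ReLU units); the
#'   dilated and split blocks default to `"linear"`.
#' @param bn_identity freeze every batch-norm in the block to a
#'   pass-through (test hook for the exact arithmetic oracles).
#' @return an object of class `block_config`.
#' @export
block_config <- function(width, dilation_rates = 1L, split_n = 3L,
                         cbam = cbam_config(), activation = NULL,
                         bn_identity = FALSE) {
  width <- as.integer(width)
  if (is.na(width) || width < 1L) stop("width must be >= 1", call. = FALSE)
  if (length(dilation_rates) < 1L || any(dilation_rates < 1L))
    stop("dilation_rates must be positive", call. = FALSE)
  split_n <- as.integer(split_n)
  if (is.na(split_n) || split_n < 1L) stop("split_n must be >= 1", call. = FALSE)
  stopifnot(inherits(cbam, "cbam_config"))
  structure(list(width = width, dilation_rates = as.integer(dilation_rates),
                 split_n = split_n, cbam = cbam, activation = activation,
                 bn_identity = isTRUE(bn_identity)),
            class = "block_config")
}

bcfg_act <- function(cfg, default) {
  a <- cfg$activation %||% default
  if (!a %in% c("relu", "linear"))
    stop("activation must be 'relu' or 'linear'", call. = FALSE)
  a
}

mk_bn <- function(ch, cfg, name) nn_bn(ch, identity = cfg$bn_identity, name = name)

apply_act <- function(mod, x, ctx, act)
  if (act == "relu") nn_forward(mod, x, ctx) else x

apply_act_bw <- function(mod, dy, ctx, act)
  if (act == "relu") nn_backward(mod, dy, ctx) else dy

#' Residual convolution-attention block (CBRes)
#'
#' `Y = CBAM( BN(conv1x1(X)) + BN(conv3x3(ReLU(BN(conv3x3(BN(X)))))) )`.
#' The `1x1` path is the residual shortcut and carries the channel
#' projection to `width`.
#'
#' @param in_ch input channel count.
#' @param cfg a [block_config()].
#' @return a block module; run it with [block_forward()].
#' @export
cbres_block <- function(in_ch, cfg) {
  w <- cfg$width
  m <- new_mod("cbres", name = "cbres", cfg = cfg,
               act = bcfg_act(cfg, "relu"))
  m$children <- list(
    bn_in = mk_bn(in_ch, cfg, "bn_in"),
    conv_a = nn_conv(in_ch, w, 3L, name = "conv_a"),
    bn_a = mk_bn(w, cfg, "bn_a"),
    relu_a = nn_relu("relu_a"),
    conv_b = nn_conv(w, w, 3L, name = "conv_b"),
    bn_b = mk_bn(w, cfg, "bn_b"),
    conv_s = nn_conv(in_ch, w, 1L, name = "conv_s"),
    bn_s = mk_bn(w, cfg, "bn_s"),
    cbam = new_cbam(w, cfg$cbam))
  m
}

nn_fw.nn_cbres <- function(mod, x, ctx) {
  ch <- mod$children
  xm <- nn_forward(ch$bn_in, x, ctx)
  m <- nn_forward(ch$conv_a, xm, ctx)
  m <- nn_forward(ch$bn_a, m, ctx)
  m <- apply_act(ch$relu_a, m, ctx, mod$act)
  m <- nn_forward(ch$conv_b, m, ctx)
  m <- nn_forward(ch$bn_b, m, ctx)
  s <- nn_forward(ch$conv_s, x, ctx)
  s <- nn_forward(ch$bn_s, s, ctx)
  nn_forward(ch$cbam, s + m, ctx)
}

nn_bw.nn_cbres <- function(mod, dy, ctx) {
  ch <- mod$children
  dsum <- nn_backward(ch$cbam, dy, ctx)
  ds <- nn_backward(ch$conv_s, nn_backward(ch$bn_s, dsum, ctx), ctx)
  dm <- nn_backward(ch$bn_b, dsum, ctx)
  dm <- nn_backward(ch$conv_b, dm, ctx)
  dm <- apply_act_bw(ch$relu_a, dm, ctx, mod$act)
  dm <- nn_backward(ch$bn_a, dm, ctx)
  dm <- nn_backward(ch$conv_a, dm, ctx)
  ds + nn_backward(ch$bn_in, dm, ctx)
}

nn_count.nn_cbres <- function(mod, shape, acc) {
  ch <- mod$children
  s0 <- nn_count(ch$bn_in, shape, acc)
  sm <- nn_count(ch$conv_a, s0, acc)
  sm <- nn_count(ch$bn_a, sm, acc)
  if (mod$act == "relu") sm <- nn_count(ch$relu_a, sm, acc)
  sm <- nn_count(ch$conv_b, sm, acc)
  sm <- nn_count(ch$bn_b, sm, acc)
  ss <- nn_count(ch$conv_s, shape, acc)
  ss <- nn_count(ch$bn_s, ss, acc)
  acc$add(paste0(mod$path, "/add"), "add", ss, 0L, prod(ss))
  nn_count(ch$cbam, ss, acc)
}

#' Dual dilated convolution block
#'
#' Two successive `3x3` convolutions with dilation rates 1 then 2
#' (`Y = CBAM(BN(conv_d2(BN(conv_d1(X)))))`); the stacked receptive field
#' is 7x7.
#'
#' @inheritParams cbres_block
#' @export
dual_dilate_cb_block <- function(in_ch, cfg) {
  if (!identical(cfg$dilation_rates, c(1L, 2L)))
    stop("dual_dilate_cb requires dilation_rates = c(1, 2)", call. = FALSE)
  dilated_stack(in_ch, cfg, kind = "dual_dilate", default_act = "linear")
}

#' Tri-dilated attention block (TDAU)
#'
#' Three `3x3` convolutions with dilation rates 1, 2, 3; the stacked
#' receptive field is 13x13.
#'
#' @inheritParams cbres_block
#' @export
tridilation_block <- function(in_ch, cfg) {
  if (!identical(cfg$dilation_rates, c(1L, 2L, 3L)))
    stop("tridilation requires dilation_rates = c(1, 2, 3)", call. = FALSE)
  dilated_stack(in_ch, cfg, kind = "tridilation", default_act = "linear")
}

dilated_stack <- function(in_ch, cfg, kind, default_act) {
  w <- cfg$width
  m <- new_mod(kind, name = kind, cfg = cfg, act = bcfg_act(cfg, default_act))
  kids <- list()
  cin <- in_ch
  for (i in seq_along(cfg$dilation_rates)) {
    kids[[paste0("conv", i)]] <-
      nn_conv(cin, w, 3L, dilation = cfg$dilation_rates[i],
              name = paste0("conv", i))
    kids[[paste0("bn", i)]] <- mk_bn(w, cfg, paste0("bn", i))
    kids[[paste0("relu", i)]] <- nn_relu(paste0("relu", i))
    cin <- w
  }
  kids$cbam <- new_cbam(w, cfg$cbam)
  m$children <- kids
  m$n_stage <- length(cfg$dilation_rates)
  m
}

dilated_fw <- function(mod, x, ctx) {
  ch <- mod$children
  for (i in seq_len(mod$n_stage)) {
    x <- nn_forward(ch[[paste0("conv", i)]], x, ctx)
    x <- nn_forward(ch[[paste0("bn", i)]], x, ctx)
    if (i < mod$n_stage) x <- apply_act(ch[[paste0("relu", i)]], x, ctx, mod$act)
  }
  nn_forward(ch$cbam, x, ctx)
}

dilated_bw <- function(mod, dy, ctx) {
  ch <- mod$children
  dy <- nn_backward(ch$cbam, dy, ctx)
  for (i in rev(seq_len(mod$n_stage))) {
    if (i < mod$n_stage) dy <- apply_act_bw(ch[[paste0("relu", i)]], dy, ctx, mod$act)
    dy <- nn_backward(ch[[paste0("bn", i)]], dy, ctx)
    dy <- nn_backward(ch[[paste0("conv", i)]], dy, ctx)
  }
  dy
}

dilated_count <- function(mod, shape, acc) {
  ch <- mod$children
  for (i in seq_len(mod$n_stage)) {
    shape <- nn_count(ch[[paste0("conv", i)]], shape, acc)
    shape <- nn_count(ch[[paste0("bn", i)]], shape, acc)
    if (i < mod$n_stage && mod$act == "relu")
      shape <- nn_count(ch[[paste0("relu", i)]], shape, acc)
  }
  nn_count(ch$cbam, shape, acc)
}

nn_fw.nn_dual_dilate <- dilated_fw
nn_bw.nn_dual_dilate <- dilated_bw
nn_count.nn_dual_dilate <- dilated_count
nn_fw.nn_tridilation <- dilated_fw
nn_bw.nn_tridilation <- dilated_bw
nn_count.nn_tridilation <- dilated_count

#' Split (asymmetric) convolution block
#'
#' A `1xN` convolution followed by an `NxL = Nx1` convolution with batch
#' normalisation after each, then CBAM.  With linear activation the two
#' stages compose to a full `NxN` convolution with a separable kernel.
#'
#' @inheritParams cbres_block
#' @export
splitfusion_block <- function(in_ch, cfg) {
  w <- cfg$width
  n <- cfg$split_n
  m <- new_mod("splitfusion", name = "splitfusion", cfg = cfg,
               act = bcfg_act(cfg, "linear"))
  m$children <- list(
    conv_h = nn_conv(in_ch, w, 1L, kw = n, name = "conv_h"),
    bn1 = mk_bn(w, cfg, "bn1"),
    relu1 = nn_relu("relu1"),
    conv_v = nn_conv(w, w, n, kw = 1L, name = "conv_v"),
    bn2 = mk_bn(w, cfg, "bn2"),
    cbam = new_cbam(w, cfg$cbam))
  m
}

nn_fw.nn_splitfusion <- function(mod, x, ctx) {
  ch <- mod$children
  x <- nn_forward(ch$conv_h, x, ctx)
  x <- nn_forward(ch$bn1, x, ctx)
  x <- apply_act(ch$relu1, x, ctx, mod$act)
  x <- nn_forward(ch$conv_v, x, ctx)
  x <- nn_forward(ch$bn2, x, ctx)
  nn_forward(ch$cbam, x, ctx)
}

nn_bw.nn_splitfusion <- function(mod, dy, ctx) {
  ch <- mod$children
  dy <- nn_backward(ch$cbam, dy, ctx)
  dy <- nn_backward(ch$bn2, dy, ctx)
  dy <- nn_backward(ch$conv_v, dy, ctx)
  dy <- apply_act_bw(ch$relu1, dy, ctx, mod$act)
  dy <- nn_backward(ch$bn1, dy, ctx)
  nn_backward(ch$conv_h, dy, ctx)
}

nn_count.nn_splitfusion <- function(mod, shape, acc) {
  ch <- mod$children
  shape <- nn_count(ch$conv_h, shape, acc)
  shape <- nn_count(ch$bn1, shape, acc)
  if (mod$act == "relu") shape <- nn_count(ch$relu1, shape, acc)
  shape <- nn_count(ch$conv_v, shape, acc)
  shape <- nn_count(ch$bn2, shape, acc)
  nn_count(ch$cbam, shape, acc)
}

#' mu-block configuration
#'
#' @param width output channel count of the block (every branch produces
#'   this width).
#' @param fusion `"concat"` concatenates the six branch outputs and
#'   projects back to `width` with a `1x1` convolution; `"sum"` adds them.
#' @param cbam a [cbam_config()] used by every sub-block and the outer
#'   refinement.
#' @param split_n kernel length of the split branch.
#' @param bn_identity test hook freezing all batch norms in the block.
#' @param activation_cbres,activation_dilated activation settings forwarded
#'   to the sub-blocks.
#' @return an object of class `mu_block_config`.
#' @export
mu_block_config <- function(width, fusion = c("concat", "sum"),
                            cbam = cbam_config(), split_n = 3L,
                            bn_identity = FALSE,
                            activation_cbres = "relu",
                            activation_dilated = "linear") {
  fusion <- match.arg(fusion)
  structure(list(width = as.integer(width), fusion = fusion, cbam = cbam,
                 split_n = as.integer(split_n),
                 bn_identity = isTRUE(bn_identity),
                 activation_cbres = activation_cbres,
                 activation_dilated = activation_dilated),
            class = "mu_block_config")
}

#' The mu-block: six parallel attention branches
#'
#' The input is batch-normalised once and fed to six parallel feature
#' branches: a tri-dilated attention unit, a dual-dilated block, the three
#' stage outputs of a cascade of three residual (CBRes) blocks, and a split
#' `1xN`/`Nx1` block.  Branch outputs are fused (channel concatenation with
#' a `1x1` projection, or summation), batch-normalised and refined by CBAM.
#'
#' @param in_ch input channel count.
#' @param cfg a [mu_block_config()].
#' @return a block module.
#' @export
mu_block <- function(in_ch, cfg) {
  stopifnot(inherits(cfg, "mu_block_config"))
  w <- cfg$width
  sub <- function(ctor, cin, rates = 1L, act) {
    ctor(cin, block_config(w, dilation_rates = rates, split_n = cfg$split_n,
                           cbam = cfg$cbam, activation = act,
                           bn_identity = cfg$bn_identity))
  }
  m <- new_mod("mu", name = "mu", cfg = cfg, n_branches = 6L)
  m$children <- list(
    bn_in = nn_bn(in_ch, identity = cfg$bn_identity, name = "bn_in"),
    tdau = sub(tridilation_block, in_ch, c(1L, 2L, 3L), cfg$activation_dilated),
    dd = sub(dual_dilate_cb_block, in_ch, c(1L, 2L), cfg$activation_dilated),
    cbres1 = sub(cbres_block, in_ch, 1L, cfg$activation_cbres),
    cbres2 = sub(cbres_block, w, 1L, cfg$activation_cbres),
    cbres3 = sub(cbres_block, w, 1L, cfg$activation_cbres),
    sf = sub(splitfusion_block, in_ch, 1L, cfg$activation_dilated),
    proj = if (cfg$fusion == "concat") nn_conv(6L * w, w, 1L, name = "proj"),
    bn_out = nn_bn(w, identity = cfg$bn_identity, name = "bn_out"),
    cbam = new_cbam(w, cfg$cbam))
  m$children <- Filter(Negate(is.null), m$children)
  m
}

nn_fw.nn_mu <- function(mod, x, ctx) {
  ch <- mod$children
  w <- mod$cfg$width
  xn <- nn_forward(ch$bn_in, x, ctx)
  t1 <- nn_forward(ch$tdau, xn, ctx)
  t2 <- nn_forward(ch$dd, xn, ctx)
  y1 <- nn_forward(ch$cbres1, xn, ctx)
  y2 <- nn_forward(ch$cbres2, y1, ctx)
  y3 <- nn_forward(ch$cbres3, y2, ctx)
  t6 <- nn_forward(ch$sf, xn, ctx)
  if (mod$cfg$fusion == "concat") {
    z <- concat_channels_cpp(list(t1, t2, y1, y2, y3, t6))
    z <- nn_forward(ch$proj, z, ctx)
  } else {
    z <- t1 + t2 + y1 + y2 + y3 + t6
  }
  z <- nn_forward(ch$bn_out, z, ctx)
  nn_forward(ch$cbam, z, ctx)
}

nn_bw.nn_mu <- function(mod, dy, ctx) {
  ch <- mod$children
  w <- mod$cfg$width
  dz <- nn_backward(ch$cbam, dy, ctx)
  dz <- nn_backward(ch$bn_out, dz, ctx)
  if (mod$cfg$fusion == "concat") {
    dcat <- nn_backward(ch$proj, dz, ctx)
    dt1 <- slice_channels_cpp(dcat, 1L, w)
    dt2 <- slice_channels_cpp(dcat, w + 1L, w)
    dy1 <- slice_channels_cpp(dcat, 2L * w + 1L, w)
    dy2 <- slice_channels_cpp(dcat, 3L * w + 1L, w)
    dy3 <- slice_channels_cpp(dcat, 4L * w + 1L, w)
    dt6 <- slice_channels_cpp(dcat, 5L * w + 1L, w)
  } else {
    dt1 <- dz; dt2 <- dz; dy1 <- dz; dy2 <- dz; dy3 <- dz; dt6 <- dz
  }
  dy2 <- dy2 + nn_backward(ch$cbres3, dy3, ctx)
  dy1 <- dy1 + nn_backward(ch$cbres2, dy2, ctx)
  dxn <- nn_backward(ch$cbres1, dy1, ctx) +
    nn_backward(ch$tdau, dt1, ctx) +
    nn_backward(ch$dd, dt2, ctx) +
    nn_backward(ch$sf, dt6, ctx)
  nn_backward(ch$bn_in, dxn, ctx)
}

nn_count.nn_mu <- function(mod, shape, acc) {
  ch <- mod$children
  w <- mod$cfg$width
  s0 <- nn_count(ch$bn_in, shape, acc)
  s1 <- nn_count(ch$tdau, s0, acc)
  nn_count(ch$dd, s0, acc)
  sc <- nn_count(ch$cbres1, s0, acc)
  sc <- nn_count(ch$cbres2, sc, acc)
  nn_count(ch$cbres3, sc, acc)
  nn_count(ch$sf, s0, acc)
  if (mod$cfg$fusion == "concat") {
    zshape <- c(s1[1:2], 6L * w, s1[4L])
    zshape <- nn_count(ch$proj, zshape, acc)
  } else {
    zshape <- s1
    acc$add(paste0(mod$path, "/sum"), "add", zshape, 0L, 5 * prod(zshape))
  }
  zshape <- nn_count(ch$bn_out, zshape, acc)
  nn_count(ch$cbam, zshape, acc)
}

# Zero every convolution and MLP weight in a block (test hook: the block
# then maps any input to zero when its batch norms are identity-frozen
# and attention is bypassed).
block_zero_weights <- function(block) {
  for (m in nn_modules(block))
    for (nm in names(m$params)) m$params[[nm]][] <- 0
  invisible(block)
}

# Fix a concat-fusion mu-block's projection to channelwise averaging of the
# six branches (test hook for the fusion oracle).
mu_block_set_avg_projection <- function(block) {
  stopifnot(block$cfg$fusion == "concat")
  w <- block$cfg$width
  pr <- block$children$proj
  pr$params$w[] <- 0
  pr$params$b[] <- 0
  for (i in seq_len(w))
    for (k in 0:5)
      pr$params$w[1L, 1L, i + k * w, i] <- 1 / 6
  invisible(block)
}

#' Run a block on a feature map
#'
#' @param block a module from [cbres_block()], [dual_dilate_cb_block()],
#'   [tridilation_block()], [splitfusion_block()] or [mu_block()].
#' @param f a feature map `(H, W, C, N)`.
#' @param training logical; use batch statistics in batch norm.
#' @return the block output, same spatial shape, `cfg$width` channels.
#' @export
block_forward <- function(block, f, training = FALSE) {
  check_feature_map(f)
  nn_forward(block, f, make_ctx(training = training, grad = FALSE))
}
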