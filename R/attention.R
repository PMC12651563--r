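#' CBAM configuration
#'
#' Settings for the convolutional block attention module used inside every
#' block of the network: channel attention (shared two-layer bottleneck MLP
#' over average- and max-pooled channel descriptors) followed by spatial
#' attention (a `K x K` convolution over the stacked channel-wise mean and
#' max maps).
#'
#' @param reduction_ratio positive integer; the channel-MLP bottleneck
#'   divisor.  The hidden width is `max(1, channels %/% reduction_ratio)`.
#' @param spatial_kernel odd positive integer; side of the spatial-attention
#'   convolution.
#' @param enabled logical; `FALSE` bypasses attention entirely (the module
#'   becomes an exact identity), a hook used by the block-level oracles.
#' @return an object of class `cbam_config`.
#' @export
cbam_config <- function(reduction_ratio = 16L, spatial_kernel = 7L,
                        enabled = TRUE) {
  reduction_ratio <- as.integer(reduction_ratio)
  spatial_kernel <- as.integer(spatial_kernel)
  if (is.na(reduction_ratio) || reduction_ratio < 1L)
    stop("reduction_ratio must be a positive integer", call. = FALSE)
  if (is.na(spatial_kernel) || spatial_kernel < 1L ||
      spatial_kernel %% 2L == 0L)
    stop("spatial_kernel must be an odd positive integer", call. = FALSE)
  structure(list(reduction_ratio = reduction_ratio,
                 spatial_kernel = spatial_kernel,
                 enabled = isTRUE(enabled)),
            class = "cbam_config")
}

#' Create a CBAM module for a given channel count
#'
#' @param channels number of input (= output) channels.
#' @param cfg a [cbam_config()].
#' @return an internal network module; pass it to [apply_cbam()],
#'   [channel_attention_weights()] or [spatial_attention_weights()].
#' @export
new_cbam <- function(channels, cfg = cbam_config()) {
  stopifnot(inherits(cfg, "cbam_config"))
  channels <- as.integer(channels)
  hidden <- max(1L, channels %/% cfg$reduction_ratio)
  std1 <- sqrt(2 / channels)
  std2 <- sqrt(2 / hidden)
  m <- new_mod("cbam", name = "cbam", channels = channels, hidden = hidden,
               cfg = cfg,
               params = list(
                 w1 = matrix(rnorm(hidden * channels, 0, std1), hidden, channels),
                 b1 = double(hidden),
                 w2 = matrix(rnorm(channels * hidden, 0, std2), channels, hidden),
                 b2 = double(channels)))
  m$children <- list(spconv = nn_conv(2L, 1L, cfg$spatial_kernel,
                                      name = "spconv"))
  m
}

# Test hooks -----------------------------------------------------------------

# Zero every attention parameter: both attention maps become constant 0.5.
cbam_zero_init <- function(cbam) {
  cbam$params$w1[] <- 0; cbam$params$b1[] <- 0
  cbam$params$w2[] <- 0; cbam$params$b2[] <- 0
  sc <- cbam$children$spconv
  sc$params$w[] <- 0; sc$params$b[] <- 0
  invisible(cbam)
}

# Force the channel MLP to the identity (requires hidden >= channels,
# i.e. reduction_ratio = 1, so the ReLU bottleneck can pass x through).
cbam_identity_mlp <- function(cbam) {
  if (cbam$hidden < cbam$channels)
    stop("identity MLP needs hidden width >= channels (reduction_ratio = 1)",
         call. = FALSE)
  cbam$params$w1[] <- 0; cbam$params$b1[] <- 0
  cbam$params$w2[] <- 0; cbam$params$b2[] <- 0
  for (i in seq_len(cbam$channels)) {
    cbam$params$w1[i, i] <- 1
    cbam$params$w2[i, i] <- 1
  }
  invisible(cbam)
}

# internals -------------------------------------------------------------------

cbam_mlp <- function(cbam, p) {
  h <- pmax(cbam$params$w1 %*% p + cbam$params$b1, 0)
  cbam$params$w2 %*% h + cbam$params$b2
}

# Channel descriptor pooling: columns of the pooled matrices are (channel,
# sample) pairs reduced over all spatial positions.
channel_pool <- function(x) channel_pool_cpp(x)

# Stacked channel-wise [mean; max] map (H, W, 2, N) plus per-position
# argmax channel (0-based).
spatial_pool <- function(x) spatial_pool_cpp(x)

nn_fw.nn_cbam <- function(mod, x, ctx) {
  if (!mod$cfg$enabled) {
    if (ctx$grad) mod$cache <- list(bypass = TRUE)
    return(x)
  }
  cp <- channel_pool(x)
  a <- cbam_mlp(mod, cp$avg) + cbam_mlp(mod, cp$mx)
  s <- sigmoid(a)
  x1 <- channel_scale_cpp(x, s)
  sp <- spatial_pool(x1)
  z <- nn_forward(mod$children$spconv, sp$st, ctx)
  ss <- sigmoid(z)
  y <- spatial_scale_cpp(x1, ss)
  if (ctx$grad)
    mod$cache <- list(bypass = FALSE, x = x, cp = cp, s = s,
                      x1 = x1, sp = sp, ss = ss)
  y
}

nn_bw.nn_cbam <- function(mod, dy, ctx) {
  cc <- mod$cache
  if (isTRUE(cc$bypass)) return(dy)
  d <- dim(dy)
  hw <- d[1L] * d[2L]
  C <- d[3L]

  # y = x1 * broadcast(ss)
  dx1 <- spatial_scale_cpp(dy, cc$ss)
  dss <- spatial_dot_cpp(dy, cc$x1)

  # spatial attention: sigmoid then K x K conv over [mean; max]
  dz <- dss * cc$ss * (1 - cc$ss)
  dst <- nn_backward(mod$children$spconv, dz, ctx)
  dmean <- dst[, , 1L, , drop = FALSE]
  dmx <- dst[, , 2L, , drop = FALSE]
  spatial_axpy_cpp(dx1, dmean, 1 / C)
  spatial_max_scatter_cpp(dx1, dmx, cc$sp$amax)

  # x1 = x * broadcast(s)
  dx <- channel_scale_cpp(dx1, cc$s)
  ds <- channel_dot_cpp(dx1, cc$x)

  # channel attention: sigmoid(MLP(avg) + MLP(max))
  da <- ds * cc$s * (1 - cc$s)
  w1 <- mod$params$w1; w2 <- mod$params$w2
  bp <- function(p) {
    pre <- w1 %*% p + mod$params$b1
    h <- pmax(pre, 0)
    dh <- (t(w2) %*% da) * (pre > 0)
    list(dw2 = da %*% t(h), db2 = rowSums(da),
         dw1 = dh %*% t(p), db1 = rowSums(dh),
         dp = t(w1) %*% dh)
  }
  g_avg <- bp(cc$cp$avg)
  g_max <- bp(cc$cp$mx)
  accum_grad(mod, "w1", g_avg$dw1 + g_max$dw1)
  accum_grad(mod, "b1", g_avg$db1 + g_max$db1)
  accum_grad(mod, "w2", g_avg$dw2 + g_max$dw2)
  accum_grad(mod, "b2", g_avg$db2 + g_max$db2)

  # pooled-descriptor gradients back to x
  channel_axpy_cpp(dx, g_avg$dp / hw)
  channel_max_scatter_cpp(dx, matrix(g_max$dp, C, d[4L]), cc$cp$amax)
  dx
}

nn_count.nn_cbam <- function(mod, shape, acc) {
  if (!mod$cfg$enabled) return(shape)
  C <- shape[3L]; N <- shape[4L]
  el <- prod(shape)
  mlp_fl <- 2L * 2L * N * (2 * C * mod$hidden)      # two branches, two layers
  ch_fl <- 2 * el + mlp_fl + 2 * C * N + el          # pools, MLP, sigmoid, mul
  acc$add(paste0(mod$path, "/channel"), "cbam_channel", shape,
          length(mod$params$w1) + length(mod$params$b1) +
            length(mod$params$w2) + length(mod$params$b2), ch_fl)
  sp_fl <- 2 * el                                    # mean/max stack
  acc$add(paste0(mod$path, "/pool"), "cbam_pool", shape, 0L, sp_fl)
  nn_count(mod$children$spconv, c(shape[1:2], 2L, N), acc)
  acc$add(paste0(mod$path, "/spatial"), "cbam_spatial", shape, 0L,
          shape[1L] * shape[2L] * N + el)            # sigmoid + mul
  shape
}

# Exported functional surface -------------------------------------------------

#' Channel attention weights
#'
#' `sigmoid(MLP(avgpool(f)) + MLP(maxpool(f)))` with a shared two-layer
#' bottleneck MLP; one weight per channel and sample, strictly in (0,1).
#' With attention disabled every weight is exactly 1.
#'
#' @param f a feature map `(H, W, C, N)`; see [check_feature_map()].
#' @param cbam a module from [new_cbam()].
#' @return a `channels x samples` matrix of weights.
#' @export
channel_attention_weights <- function(f, cbam) {
  check_feature_map(f)
  d <- dim(f)
  if (d[3L] != cbam$channels)
    stop("feature map has ", d[3L], " channels; module expects ",
         cbam$channels, call. = FALSE)
  if (!cbam$cfg$enabled) return(matrix(1, d[3L], d[4L]))
  cp <- channel_pool(f)
  sigmoid(cbam_mlp(cbam, cp$avg) + cbam_mlp(cbam, cp$mx))
}

#' Spatial attention weights
#'
#' `sigmoid(conv_KxK([channel-mean; channel-max]))` with same-padding; one
#' weight per spatial position and sample, strictly in (0,1).
#'
#' @inheritParams channel_attention_weights
#' @return an `(H, W, 1, N)` array of weights.
#' @export
spatial_attention_weights <- function(f, cbam) {
  check_feature_map(f)
  d <- dim(f)
  if (!cbam$cfg$enabled) return(array(1, c(d[1:2], 1L, d[4L])))
  sp <- spatial_pool(f)
  sigmoid(nn_forward(cbam$children$spconv, sp$st, make_ctx()))
}

#' Apply CBAM to a feature map
#'
#' Channel attention first, then spatial attention, both as multiplicative
#' gates; the output has exactly the input's shape and, because every gate
#' is strictly below 1, elementwise magnitude no larger than the input's.
#' With `enabled = FALSE` the input is returned bit-identically.
#'
#' @inheritParams channel_attention_weights
#' @return the refined feature map.
#' @export
apply_cbam <- function(f, cbam) {
  check_feature_map(f)
  nn_fw.nn_cbam(cbam, f, make_ctx())
}
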