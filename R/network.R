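#' Network configuration
#'
#' Defines one instantiation of the segmentation network: a five-stage
#' encoder of mu-blocks with stride-2 downsampling convolutions, a
#' residual-attention bottleneck, and a mirror decoder of nearest-neighbour
#' upsampling, encoder skip concatenation and mu-blocks, closed by a `1x1`
#' convolution with sigmoid activation.
#'
#' The default stage widths double from `base_filters` per stage
#' (17, 34, 68, 136, 272); the bottleneck holds `bottleneck_blocks`
#' residual (CBRes) blocks at `bottleneck_mult` times the deepest encoder
#' width.
#'
#' @param input_size pixels per side of the (square) input, default 352;
#'   must be divisible by `2^depth`.
#' @param input_channels image channels (3 for RGB).
#' @param depth number of downsampling stages.
#' @param base_filters channel width of stage 1.
#' @param width_schedule optional explicit per-stage widths (length `depth`).
#' @param fusion mu-block fusion mode, `"concat"` or `"sum"`.
#' @param cbam a [cbam_config()].
#' @param split_n split-branch kernel length.
#' @param bottleneck_blocks number of residual blocks in the bottleneck.
#' @param bottleneck_mult bottleneck width as a multiple of the deepest
#'   encoder width.
#' @param seed integer seed for weight initialisation.
#' @return an object of class `network_config`.
#' @export
network_config <- function(input_size = 352L, input_channels = 3L,
                           depth = 5L, base_filters = 17L,
                           width_schedule = NULL,
                           fusion = c("concat", "sum"),
                           cbam = cbam_config(), split_n = 3L,
                           bottleneck_blocks = 2L, bottleneck_mult = 2L,
                           seed = 42L) {
  fusion <- match.arg(fusion)
  input_size <- as.integer(input_size)
  depth <- as.integer(depth)
  if (depth < 1L) stop("depth must be >= 1", call. = FALSE)
  if (input_size %% 2L^depth != 0L)
    stop("input_size (", input_size, ") must be divisible by 2^depth (",
         2L^depth, ")", call. = FALSE)
  if (base_filters < 1L) stop("base_filters must be >= 1", call. = FALSE)
  ws <- if (is.null(width_schedule)) as.integer(base_filters * 2L^(0:(depth - 1L)))
        else as.integer(width_schedule)
  if (length(ws) != depth) stop("width_schedule must have length depth",
                                call. = FALSE)
  structure(list(input_size = input_size,
                 input_channels = as.integer(input_channels),
                 depth = depth, base_filters = as.integer(base_filters),
                 width_schedule = ws, fusion = fusion, cbam = cbam,
                 split_n = as.integer(split_n),
                 bottleneck_blocks = as.integer(bottleneck_blocks),
                 bottleneck_mult = as.integer(bottleneck_mult),
                 seed = as.integer(seed)),
            class = "network_config")
}

#' Build the segmentation network
#'
#' Weight initialisation is drawn under `cfg$seed`, so two builds from the
#' same configuration are identical.
#'
#' @param cfg a [network_config()].
#' @return a model object (class `munet_model`).
#' @export
build_munet <- function(cfg) {
  stopifnot(inherits(cfg, "network_config"))
  with_seed(cfg$seed, {
    ws <- cfg$width_schedule
    wb <- cfg$bottleneck_mult * ws[cfg$depth]
    mcfg <- function(w) mu_block_config(w, fusion = cfg$fusion,
                                        cbam = cfg$cbam, split_n = cfg$split_n)
    kids <- list()
    cin <- cfg$input_channels
    for (i in seq_len(cfg$depth)) {
      kids[[paste0("enc", i)]] <- mu_block(cin, mcfg(ws[i]))
      kids[[paste0("down", i)]] <- nn_conv(ws[i], ws[i], 2L, stride = 2L,
                                           name = paste0("down", i))
      cin <- ws[i]
    }
    bin <- ws[cfg$depth]
    for (j in seq_len(cfg$bottleneck_blocks)) {
      kids[[paste0("bott", j)]] <-
        cbres_block(bin, block_config(wb, cbam = cfg$cbam))
      bin <- wb
    }
    cin <- wb
    for (i in rev(seq_len(cfg$depth))) {
      kids[[paste0("up", i)]] <- nn_upsample(paste0("up", i))
      kids[[paste0("dec", i)]] <- mu_block(cin + ws[i], mcfg(ws[i]))
      cin <- ws[i]
    }
    kids$head <- nn_conv(ws[1L], 1L, 1L, name = "head")
    kids$head_sigmoid <- nn_sigmoid("head_sigmoid")
    model <- new_mod("munet", name = "munet", cfg = cfg)
    model$children <- kids
    class(model) <- c("munet_model", class(model))
    assign_paths(model)
    model
  })
}

nn_fw.nn_munet <- function(mod, x, ctx) {
  cfg <- mod$cfg
  ch <- mod$children
  skips <- vector("list", cfg$depth)
  for (i in seq_len(cfg$depth)) {
    x <- nn_forward(ch[[paste0("enc", i)]], x, ctx)
    skips[[i]] <- x
    x <- nn_forward(ch[[paste0("down", i)]], x, ctx)
  }
  for (j in seq_len(cfg$bottleneck_blocks))
    x <- nn_forward(ch[[paste0("bott", j)]], x, ctx)
  split_at <- integer(cfg$depth)
  for (i in rev(seq_len(cfg$depth))) {
    x <- nn_forward(ch[[paste0("up", i)]], x, ctx)
    split_at[i] <- dim(x)[3L]
    d <- dim(x)
    sk <- skips[[i]]
    z <- array(0, c(d[1L], d[2L], d[3L] + dim(sk)[3L], d[4L]))
    z[, , seq_len(d[3L]), ] <- x
    z[, , d[3L] + seq_len(dim(sk)[3L]), ] <- sk
    x <- nn_forward(ch[[paste0("dec", i)]], z, ctx)
  }
  x <- nn_forward(ch$head, x, ctx)
  y <- nn_forward(ch$head_sigmoid, x, ctx)
  if (ctx$grad) mod$cache <- list(split_at = split_at)
  y
}

nn_bw.nn_munet <- function(mod, dy, ctx) {
  cfg <- mod$cfg
  ch <- mod$children
  split_at <- mod$cache$split_at
  dy <- nn_backward(ch$head_sigmoid, dy, ctx)
  dy <- nn_backward(ch$head, dy, ctx)
  dskips <- vector("list", cfg$depth)
  for (i in seq_len(cfg$depth)) {
    dz <- nn_backward(ch[[paste0("dec", i)]], dy, ctx)
    nup <- split_at[i]
    dup <- dz[, , seq_len(nup), , drop = FALSE]
    dskips[[i]] <- dz[, , nup + seq_len(dim(dz)[3L] - nup), , drop = FALSE]
    dy <- nn_backward(ch[[paste0("up", i)]], dup, ctx)
  }
  for (j in rev(seq_len(cfg$bottleneck_blocks)))
    dy <- nn_backward(ch[[paste0("bott", j)]], dy, ctx)
  for (i in rev(seq_len(cfg$depth))) {
    dy <- nn_backward(ch[[paste0("down", i)]], dy, ctx)
    dy <- nn_backward(ch[[paste0("enc", i)]], dy + dskips[[i]], ctx)
  }
  dy
}

nn_count.nn_munet <- function(mod, shape, acc) {
  cfg <- mod$cfg
  ch <- mod$children
  skip_ch <- integer(cfg$depth)
  for (i in seq_len(cfg$depth)) {
    shape <- nn_count(ch[[paste0("enc", i)]], shape, acc)
    skip_ch[i] <- shape[3L]
    shape <- nn_count(ch[[paste0("down", i)]], shape, acc)
  }
  for (j in seq_len(cfg$bottleneck_blocks))
    shape <- nn_count(ch[[paste0("bott", j)]], shape, acc)
  for (i in rev(seq_len(cfg$depth))) {
    shape <- nn_count(ch[[paste0("up", i)]], shape, acc)
    shape <- c(shape[1:2], shape[3L] + skip_ch[i], shape[4L])
    shape <- nn_count(ch[[paste0("dec", i)]], shape, acc)
  }
  shape <- nn_count(ch$head, shape, acc)
  nn_count(ch$head_sigmoid, shape, acc)
}

#' Forward pass producing probabilities and a binary mask
#'
#' @param model a model from [build_munet()].
#' @param images array `(H, W, C, N)` (or `(H, W, C)` for one image) with
#'   values in `[0, 1]`, already resized to the configured input size.
#' @param threshold binarisation threshold; pixels with probability
#'   `>= threshold` are foreground.
#' @return list with `prob` (`(H, W, 1, N)` array in (0,1)) and `mask`
#'   (same shape, values 0/1).
#' @export
predict_mask <- function(model, images, threshold = 0.5) {
  if (length(dim(images)) == 3L) dim(images) <- c(dim(images), 1L)
  check_feature_map(images, "images")
  d <- dim(images)
  sz <- model$cfg$input_size
  if (d[1L] != sz || d[2L] != sz)
    stop("images are ", d[1L], "x", d[2L], " but the model expects ",
         sz, "x", sz, "; resize them first (see resize_sample)",
         call. = FALSE)
  if (min(images) < 0 || max(images) > 1)
    stop("image values must lie in [0, 1]", call. = FALSE)
  prob <- nn_forward(model, images, make_ctx(training = FALSE, grad = FALSE))
  mask <- (prob >= threshold) * 1
  list(prob = prob, mask = mask)
}

#' Model size summary: trainable parameters and forward FLOPs
#'
#' Counts one multiply-accumulate as two FLOPs; convolutions contribute
#' `2*Kh*Kw*Cin*Cout*Hout*Wout`, batch normalisation, activations, pooling
#' and resampling one operation per element.  The count is a deterministic
#' function of the configuration.
#'
#' @param model a model from [build_munet()].
#' @param batch batch size used for the FLOP count (default 1).
#' @return a `munet_summary`: list with `trainable_parameters`,
#'   `flops_forward` and a per-layer data frame `layers`.
#' @export
summarize_model <- function(model, batch = 1L) {
  cfg <- model$cfg
  acc <- new_count_acc()
  nn_count(model, c(cfg$input_size, cfg$input_size, cfg$input_channels,
                    as.integer(batch)), acc)
  layers <- do.call(rbind, acc$rows)
  structure(list(trainable_parameters = n_params(model),
                 flops_forward = sum(layers$flops),
                 layers = layers),
            class = "munet_summary")
}

#' @export
print.munet_summary <- function(x, ...) {
  cat(sprintf("Trainable parameters: %s (%.2f M)\n",
              format(x$trainable_parameters, big.mark = ","),
              x$trainable_parameters / 1e6))
  cat(sprintf("Forward FLOPs:        %s (%.2f G)\n",
              format(x$flops_forward, big.mark = ","),
              x$flops_forward / 1e9))
  cat(sprintf("Layers: %d\n", nrow(x$layers)))
  invisible(x)
}

#' List addressable layer paths of a model
#'
#' Useful for picking a Grad-CAM target layer.
#'
#' @param model a model object.
#' @return character vector of layer paths.
#' @export
list_layers <- function(model) {
  vapply(nn_modules(model), function(m) m$path, "")
}

#' Save / load model weights
#'
#' Weights (parameters plus batch-norm running statistics) are stored as an
#' RDS file keyed by layer path; the architecture itself is rebuilt from
#' its [network_config()].
#'
#' @param model a model object.
#' @param path file path.
#' @return `save_weights` the path, invisibly; `load_weights` the model,
#'   invisibly.
#' @export
save_weights <- function(model, path) {
  saveRDS(list(config = model$cfg, state = get_weights(model)), path)
  invisible(path)
}

#' @rdname save_weights
#' @export
load_weights <- function(model, path) {
  st <- readRDS(path)
  set_weights(model, st$state)
  invisible(model)
}
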