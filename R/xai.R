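# Grad-CAM and input-gradient saliency for dense (per-pixel) prediction.
# The scalar explanation target s is a reduction of the output probability
# map; its gradient is propagated with the same backward passes used for
# training.

as_one_image <- function(image) {
  if (length(dim(image)) == 3L) dim(image) <- c(dim(image), 1L)
  check_feature_map(image, "image")
  if (dim(image)[4L] != 1L) stop("explanations take one image at a time",
                                 call. = FALSE)
  image
}

# Seed gradient ds/dprob for the chosen scalarisation.
target_seed <- function(prob, scalarization, threshold, bbox) {
  seed <- array(0, dim(prob))
  if (scalarization == "sum") {
    seed[] <- 1
  } else if (scalarization == "foreground") {
    fg <- prob >= threshold
    if (any(fg)) seed[fg] <- 1 else seed[] <- 1
  } else if (scalarization == "bbox") {
    if (is.null(bbox)) stop("bbox scalarization needs a bbox", call. = FALSE)
    seed[(bbox[["ymin"]] + 1L):bbox[["ymax"]],
         (bbox[["xmin"]] + 1L):bbox[["xmax"]], , ] <- 1
  }
  seed
}

minmax_norm <- function(m) {
  mx <- max(m)
  if (mx <= 0) return(m * 0)    # identically-zero raw map stays zero
  mn <- min(m)
  if (mx - mn < 1e-300) return(m / mx)
  (m - mn) / (mx - mn)
}

bilinear_up <- function(m, h, w) {
  hs <- nrow(m); ws <- ncol(m)
  if (hs == h && ws == w) return(m)
  u <- (seq_len(h) - 0.5) * hs / h + 0.5
  v <- (seq_len(w) - 0.5) * ws / w + 0.5
  r0 <- pmin(pmax(floor(u), 1L), max(1L, hs - 1L))
  c0 <- pmin(pmax(floor(v), 1L), max(1L, ws - 1L))
  r1 <- pmin(r0 + 1L, hs); c1 <- pmin(c0 + 1L, ws)
  fr <- pmin(pmax(u - r0, 0), 1); fc <- pmin(pmax(v - c0, 0), 1)
  a <- m[r0, c0, drop = FALSE]; b <- m[r1, c0, drop = FALSE]
  cc <- m[r0, c1, drop = FALSE]; d <- m[r1, c1, drop = FALSE]
  a * outer(1 - fr, 1 - fc) + b * outer(fr, 1 - fc) +
    cc * outer(1 - fr, fc) + d * outer(fr, fc)
}

default_cam_layer <- function(model) {
  if (inherits(model, "munet_model")) "munet/dec1" else model$path
}

check_layer <- function(model, target_layer) {
  layers <- list_layers(model)
  if (!target_layer %in% layers)
    stop("unknown layer '", target_layer, "'; available layers:\n  ",
         paste(layers, collapse = "\n  "), call. = FALSE)
  target_layer
}

#' Grad-CAM explanation of a segmentation
#'
#' Runs the model on one image, reduces the output probability map to a
#' scalar target (by default the sum of probabilities over predicted-
#' foreground pixels, falling back to the full sum when nothing crosses
#' the threshold), and backpropagates it to the target layer.  Channel
#' weights are the spatial averages of the gradient; the heat map is the
#' ReLU of the weighted activation sum, bilinearly upsampled to the input
#' size and min-max normalised to `[0, 1]` (an identically zero raw map
#' stays zero).
#'
#' @param model a model from [build_munet()] (any module graph works).
#' @param image `(H, W, C)` or `(H, W, C, 1)` array in `[0, 1]`.
#' @param target_layer layer path (see [list_layers()]); default is the
#'   last decoder mu-block.
#' @param scalarization `"foreground"`, `"sum"`, or `"bbox"`.
#' @param threshold foreground threshold for the default scalarisation.
#' @param bbox 0-based half-open box for `"bbox"` scalarisation.
#' @return an `explanation_map`: list with `heat` (rows x cols matrix in
#'   `[0, 1]`), `target_layer` and `target` (the scalarisation name).
#' @export
grad_cam <- function(model, image, target_layer = NULL,
                     scalarization = c("foreground", "sum", "bbox"),
                     threshold = 0.5, bbox = NULL) {
  scalarization <- match.arg(scalarization)
  image <- as_one_image(image)
  target_layer <- check_layer(model, target_layer %||% default_cam_layer(model))
  hooks <- make_hooks(target_layer)
  ctx <- make_ctx(training = FALSE, grad = TRUE, hooks = hooks)
  prob <- nn_forward(model, image, ctx)
  seed <- target_seed(prob, scalarization, threshold, bbox)
  nn_backward(model, seed, ctx)
  act <- get(target_layer, envir = hooks$acts)
  grd <- get(target_layer, envir = hooks$grads)
  da <- dim(act)
  am <- matrix(act, nrow = da[1L] * da[2L])
  gm <- matrix(grd, nrow = da[1L] * da[2L])
  wts <- colMeans(gm)
  cam <- matrix(pmax(am %*% wts, 0), da[1L], da[2L])
  heat <- minmax_norm(bilinear_up(cam, dim(image)[1L], dim(image)[2L]))
  structure(list(heat = heat, target_layer = target_layer,
                 target = scalarization),
            class = "explanation_map")
}

#' Input-gradient saliency map
#'
#' The maximum over colour channels of the absolute gradient of the
#' scalar target with respect to each input pixel, min-max normalised.
#'
#' @inheritParams grad_cam
#' @return an `explanation_map` (heat matrix in `[0, 1]`).
#' @export
saliency <- function(model, image,
                     scalarization = c("foreground", "sum", "bbox"),
                     threshold = 0.5, bbox = NULL) {
  scalarization <- match.arg(scalarization)
  image <- as_one_image(image)
  ctx <- make_ctx(training = FALSE, grad = TRUE)
  prob <- nn_forward(model, image, ctx)
  seed <- target_seed(prob, scalarization, threshold, bbox)
  dx <- nn_backward(model, seed, ctx)
  heat <- apply(abs(dx[, , , 1L, drop = FALSE]), c(1L, 2L), max)
  structure(list(heat = minmax_norm(heat), target_layer = "input",
                 target = scalarization),
            class = "explanation_map")
}

heat_colors <- function(heat) {
  # blue -> cyan -> green -> yellow -> red ramp
  stops <- rbind(c(0, 0, 0.5), c(0, 1, 1), c(0, 1, 0), c(1, 1, 0), c(1, 0, 0))
  pos <- c(0, 0.25, 0.5, 0.75, 1)
  h <- as.vector(heat)
  out <- sapply(1:3, function(ch)
    stats::approx(pos, stops[, ch], xout = h, rule = 2)$y)
  array(out, c(dim(heat), 3L))
}

#' Overlay a heat map on an image
#'
#' Pixelwise linear blend `(1 - alpha) * image + alpha * colored(heat)`.
#'
#' @param image `(H, W, 3)` array in `[0, 1]`.
#' @param map an `explanation_map` (or a heat matrix in `[0, 1]`).
#' @param alpha blend weight in `[0, 1]`; 0 returns the image unchanged,
#'   1 the pure colour-mapped heat.
#' @return `(H, W, 3)` array in `[0, 1]`.
#' @export
overlay_heat <- function(image, map, alpha = 0.5) {
  heat <- if (inherits(map, "explanation_map")) map$heat else map
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]", call. = FALSE)
  if (!identical(dim(image)[1:2], dim(heat)[1:2]))
    stop("image and heat map shapes differ", call. = FALSE)
  (1 - alpha) * image + alpha * heat_colors(heat)
}
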