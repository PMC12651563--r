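#' Augmentation configuration
#'
#' Per-transform probabilities and ranges for the training-time
#' augmentation recipe.  Geometric transforms (flips, right-angle
#' rotation, and an affine combining rotation, translation, scaling and
#' shear) are applied with identical parameters to image and mask;
#' photometric transforms (colour jitter) touch the image only.  Each
#' transform is gated by an independent uniform draw against its
#' probability, and parameters are sampled uniformly within their ranges.
#'
#' Defaults: horizontal flip p=0.5, vertical flip p=0.5, right-angle
#' rotation p=0.3, colour jitter p=0.5 (brightness 0.6-1.6x, contrast
#' +/-20%, saturation +/-10%, hue +/-0.01), affine p=0.7 (scale 90-120%,
#' translation +/-10%, rotation +/-30 degrees, shear +/-10 degrees).
#'
#' @param hflip_p,vflip_p,rot90_p,color_jitter_p,affine_p gate
#'   probabilities in `[0, 1]`.
#' @param brightness multiplicative factor range (length 2).
#' @param contrast,saturation symmetric fractional ranges (scalar f means
#'   a factor in `[1-f, 1+f]`).
#' @param hue additive hue shift range (fraction of the hue circle).
#' @param scale multiplicative scale range (length 2).
#' @param translation max |shift| as a fraction of the image side.
#' @param rotation max |angle| in degrees.
#' @param shear max |shear| in degrees (sampled per axis).
#' @return an object of class `augmentation_config`.
#' @export
augmentation_config <- function(hflip_p = 0.5, vflip_p = 0.5, rot90_p = 0.3,
                                color_jitter_p = 0.5,
                                brightness = c(0.6, 1.6),
                                contrast = 0.2, saturation = 0.1, hue = 0.01,
                                affine_p = 0.7, scale = c(0.9, 1.2),
                                translation = 0.1, rotation = 30, shear = 10) {
  ps <- c(hflip_p, vflip_p, rot90_p, color_jitter_p, affine_p)
  if (any(ps < 0 | ps > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (brightness[1L] > brightness[2L] || scale[1L] > scale[2L])
    stop("ranges must be well ordered", call. = FALSE)
  structure(list(hflip_p = hflip_p, vflip_p = vflip_p, rot90_p = rot90_p,
                 color_jitter_p = color_jitter_p, brightness = brightness,
                 contrast = contrast, saturation = saturation, hue = hue,
                 affine_p = affine_p, scale = scale,
                 translation = translation, rotation = rotation,
                 shear = shear),
            class = "augmentation_config")
}

rot90_ccw <- function(m) t(m)[rev(seq_len(ncol(m))), , drop = FALSE]

apply_plane <- function(img, f) {
  for (ch in seq_len(dim(img)[3L])) img[, , ch] <- f(img[, , ch])
  img
}

# hue-preserving numeric HSV -> RGB (h, s, v in [0, 1], vectorised)
hsv_to_rgb <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6) %% 6
  f <- h6 - floor(h6)
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  cbind(r, g, b)
}

# Inverse-mapped affine: image bilinear, mask nearest, outside filled 0.
affine_transform <- function(image, mask, angle, sc, tx, ty, shx, shy) {
  h <- nrow(mask); w <- ncol(mask)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  th <- angle * pi / 180
  kx <- tan(shx * pi / 180); ky <- tan(shy * pi / 180)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
  Sh <- matrix(c(1, ky, kx, 1), 2L)
  A <- (R %*% Sh) * sc               # forward (row, col) linear part
  Ainv <- solve(A)
  rows <- matrix(rep(seq_len(h), w), h, w)
  cols <- matrix(rep(seq_len(w), each = h), h, w)
  dy <- rows - cy - ty * h
  dx <- cols - cx - tx * w
  src_r <- Ainv[1L, 1L] * dy + Ainv[1L, 2L] * dx + cy
  src_c <- Ainv[2L, 1L] * dy + Ainv[2L, 2L] * dx + cx

  # bilinear for the image
  r0 <- floor(src_r); c0 <- floor(src_c)
  fr <- src_r - r0; fc <- src_c - c0
  gat <- function(plane, ri, ci) {
    ok <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
    out <- numeric(length(ri))
    out[ok] <- plane[cbind(ri[ok], ci[ok])]
    out
  }
  img_out <- apply_plane(image, function(pl) {
    v <- gat(pl, r0, c0) * (1 - fr) * (1 - fc) +
      gat(pl, r0 + 1, c0) * fr * (1 - fc) +
      gat(pl, r0, c0 + 1) * (1 - fr) * fc +
      gat(pl, r0 + 1, c0 + 1) * fr * fc
    matrix(v, h, w)
  })
  rn <- round(src_r); cn <- round(src_c)
  mv <- gat(mask, rn, cn)
  list(image = img_out, mask = matrix(as.integer(mv >= 0.5), h, w))
}

#' Augment one image/mask pair
#'
#' Transform parameters are drawn from the current RNG stream (seed it
#' with `set.seed()` or pass `seed`), in a fixed order so a given seed
#' always produces the same augmentation.  `force` can override individual
#' gates for testing (e.g. `force = list(hflip = TRUE)` applies the
#' horizontal flip regardless of its probability).
#'
#' @param s an [image_sample()].
#' @param cfg an [augmentation_config()].
#' @param seed optional seed applied locally to the draw.
#' @param force named list of logical gate overrides (`hflip`, `vflip`,
#'   `rot90`, `affine`, `color_jitter`).
#' @return the augmented sample (bounding boxes are dropped).
#' @export
augment_pair <- function(s, cfg, seed = NULL, force = list()) {
  stopifnot(inherits(s, "image_sample"), inherits(cfg, "augmentation_config"))
  if (!is.null(seed)) return(with_seed(seed, augment_pair(s, cfg)))
  img <- s$image; msk <- s$mask

  gate <- function(nm, p) {
    u <- runif(1L)
    if (!is.null(force[[nm]])) isTRUE(force[[nm]]) else u < p
  }
  if (gate("hflip", cfg$hflip_p)) {
    img <- img[, rev(seq_len(ncol(msk))), , drop = FALSE]
    msk <- msk[, rev(seq_len(ncol(msk))), drop = FALSE]
  }
  if (gate("vflip", cfg$vflip_p)) {
    img <- img[rev(seq_len(nrow(msk))), , , drop = FALSE]
    msk <- msk[rev(seq_len(nrow(msk))), , drop = FALSE]
  }
  k <- sample(1:3, 1L)
  if (gate("rot90", cfg$rot90_p)) {
    if (nrow(msk) != ncol(msk))
      stop("right-angle rotation requires square samples; resize first",
           call. = FALSE)
    for (kk in seq_len(k)) {
      img <- apply_plane(img, rot90_ccw)
      msk <- rot90_ccw(msk)
    }
  }
  angle <- runif(1L, -cfg$rotation, cfg$rotation)
  sc <- runif(1L, cfg$scale[1L], cfg$scale[2L])
  tx <- runif(1L, -cfg$translation, cfg$translation)
  ty <- runif(1L, -cfg$translation, cfg$translation)
  shx <- runif(1L, -cfg$shear, cfg$shear)
  shy <- runif(1L, -cfg$shear, cfg$shear)
  if (gate("affine", cfg$affine_p)) {
    at <- affine_transform(img, msk, angle, sc, tx, ty, shx, shy)
    img <- at$image; msk <- at$mask
  }
  br <- runif(1L, cfg$brightness[1L], cfg$brightness[2L])
  co <- runif(1L, 1 - cfg$contrast, 1 + cfg$contrast)
  sa <- runif(1L, 1 - cfg$saturation, 1 + cfg$saturation)
  hu <- runif(1L, -cfg$hue, cfg$hue)
  if (gate("color_jitter", cfg$color_jitter_p)) {
    img <- img * br
    mu <- mean(img)
    img <- (img - mu) * co + mu
    gray <- 0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
    for (ch in 1:3) img[, , ch] <- gray + (img[, , ch] - gray) * sa
    img <- pmin(pmax(img, 0), 1)
    d <- dim(img)
    m <- matrix(aperm(img, c(3L, 1L, 2L)), nrow = 3L)
    hsv <- grDevices::rgb2hsv(m, maxColorValue = 1)
    rgb <- hsv_to_rgb(hsv[1L, ] + hu, hsv[2L, ], hsv[3L, ])
    img <- aperm(array(t(rgb), c(3L, d[1L], d[2L])), c(2L, 3L, 1L))
  }
  img <- pmin(pmax(img, 0), 1)
  image_sample(img, msk, id = s$id, bbox = NULL)
}
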