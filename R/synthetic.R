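#' Specification for the synthetic lesion dataset generator
#'
#' The generator emulates the folder-level structure and gross appearance
#' of colonoscopy polyp data: a smooth pinkish mucosa-like background with
#' low-frequency texture, and one to three brighter, irregularly
#' outlined lesions per image with soft photometric edges but pixel-exact
#' binary masks.  It exists so the full pipeline (loading, resizing,
#' augmentation, training, evaluation, explanation) can run offline.
#'
#' @param n_images number of images to generate.
#' @param image_size pixels per side.
#' @param lesions_range integer range (min, max) of lesions per image.
#' @param radius_range lesion radius range as a fraction of the image side,
#'   inside (0, 0.5).
#' @param irregularity amplitude of the radial boundary perturbation
#'   (fraction of the radius).
#' @param texture_scale standard deviation of the low-frequency background
#'   texture, in intensity units.
#' @param fg_color,bg_color base RGB triplets (in `[0,1]`) for lesion and
#'   background; per-image jitter is added around them.
#' @param seed RNG seed; the whole dataset is a deterministic function of
#'   the spec.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_images, image_size = 352L,
                           lesions_range = c(1L, 3L),
                           radius_range = c(0.08, 0.22),
                           irregularity = 0.25,
                           texture_scale = 0.08,
                           fg_color = c(0.93, 0.62, 0.58),
                           bg_color = c(0.72, 0.42, 0.38),
                           seed = 42L) {
  if (n_images < 1L) stop("n_images must be >= 1", call. = FALSE)
  if (radius_range[1L] <= 0 || radius_range[2L] >= 0.5 ||
      radius_range[1L] > radius_range[2L])
    stop("radius_range must lie within (0, 0.5)", call. = FALSE)
  structure(list(n_images = as.integer(n_images),
                 image_size = as.integer(image_size),
                 lesions_range = as.integer(lesions_range),
                 radius_range = radius_range,
                 irregularity = irregularity,
                 texture_scale = texture_scale,
                 fg_color = fg_color, bg_color = bg_color,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Low-frequency noise field: coarse Gaussian grid upsampled bilinearly.
smooth_noise <- function(size, coarse = max(4L, size %/% 16L)) {
  g <- matrix(rnorm(coarse^2), coarse, coarse)
  u <- (seq_len(size) - 0.5) / size * (coarse - 1) + 1
  i0 <- pmin(floor(u), coarse - 1L)
  fr <- u - i0
  a <- g[i0, i0, drop = FALSE]
  b <- g[i0 + 1L, i0, drop = FALSE]
  cc <- g[i0, i0 + 1L, drop = FALSE]
  d <- g[i0 + 1L, i0 + 1L, drop = FALSE]
  wa <- outer(1 - fr, 1 - fr); wb <- outer(fr, 1 - fr)
  wc <- outer(1 - fr, fr); wd <- outer(fr, fr)
  a * wa + b * wb + cc * wc + d * wd
}

#' Generate a synthetic lesion dataset
#'
#' @param spec a [synthetic_spec()].
#' @return list of image samples (see [image_sample()]); every mask is
#'   nonempty and strictly binary, and lesion bounding boxes are attached.
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    lapply(seq_len(spec$n_images), function(i) synth_one(spec, i))
  })
}

synth_one <- function(spec, idx) {
  sz <- spec$image_size
  img <- array(0, c(sz, sz, 3L))
  base <- pmin(pmax(spec$bg_color + rnorm(3L, 0, 0.04), 0), 1)
  shade <- smooth_noise(sz)
  shade <- shade / max(abs(shade), 1e-8)
  for (ch in 1:3) {
    tex <- smooth_noise(sz, coarse = max(6L, sz %/% 8L))
    img[, , ch] <- base[ch] + spec$texture_scale * tex + 0.03 * shade
  }
  mask <- matrix(0L, sz, sz)
  n_les <- sample(spec$lesions_range[1L]:spec$lesions_range[2L], 1L)
  rows <- matrix(rep(seq_len(sz) - 0.5, sz), sz, sz)
  cols <- t(rows)
  bboxes <- list()
  for (l in seq_len(n_les)) {
    r0 <- runif(1L, spec$radius_range[1L], spec$radius_range[2L]) * sz
    ecc <- runif(1L, 0, 0.25)
    reach <- r0 * (1 + ecc) * (1 + spec$irregularity) + 2
    margin <- min(reach, sz / 2 - 1)
    cy <- runif(1L, margin, sz - margin)
    cx <- runif(1L, margin, sz - margin)
    phi <- runif(3L, 0, 2 * pi)
    amp <- runif(3L, 0, spec$irregularity) / (2:4)
    rot <- runif(1L, 0, pi)
    dy <- (rows - cy); dx <- (cols - cx)
    u <- cos(rot) * dx + sin(rot) * dy
    v <- -sin(rot) * dx + cos(rot) * dy
    rho <- sqrt((u / (1 + ecc))^2 + (v * (1 + ecc))^2)
    th <- atan2(v, u)
    redge <- r0 * (1 + amp[1L] * cos(2 * th + phi[1L]) +
                     amp[2L] * cos(3 * th + phi[2L]) +
                     amp[3L] * cos(4 * th + phi[3L]))
    inside <- rho <= redge
    if (!any(inside))  # degenerate draw; keep at least the centre pixel
      inside[min(max(1, round(cy)), sz), min(max(1, round(cx)), sz)] <- TRUE
    mask[inside] <- 1L
    fg <- pmin(pmax(spec$fg_color + rnorm(3L, 0, 0.04), 0), 1)
    soft <- pmin(pmax((redge - rho) / 1.5 + 0.5, 0), 1)
    dome <- pmax(1 - (rho / pmax(redge, 1e-8))^2, 0)
    for (ch in 1:3)
      img[, , ch] <- img[, , ch] * (1 - soft) +
        soft * (fg[ch] + 0.12 * dome + 0.02 * rnorm(1L))
    rr <- range(which(rowSums(inside) > 0))
    rc <- range(which(colSums(inside) > 0))
    # bbox in 0-based half-open (xmin, ymin, xmax, ymax); x = column
    bboxes[[l]] <- c(xmin = rc[1L] - 1L, ymin = rr[1L] - 1L,
                     xmax = rc[2L], ymax = rr[2L])
  }
  img <- pmin(pmax(img, 0), 1)
  image_sample(img, mask, id = sprintf("synth_%04d", idx), bbox = bboxes)
}

#' Write samples to a Kvasir-style directory layout
#'
#' Creates `images/` and `masks/` folders with matching file stems (PNG,
#' lossless) plus a JSON file describing per-image lesion bounding boxes.
#'
#' @param samples list of image samples.
#' @param root output directory (created if missing).
#' @return `root`, invisibly.
#' @export
write_kvasir_layout <- function(samples, root) {
  dir.create(file.path(root, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(root, "masks"), recursive = TRUE, showWarnings = FALSE)
  bb <- list()
  for (s in samples) {
    png::writePNG(s$image, file.path(root, "images", paste0(s$id, ".png")))
    png::writePNG(s$mask + 0, file.path(root, "masks", paste0(s$id, ".png")))
    if (!is.null(s$bbox))
      bb[[s$id]] <- list(
        height = nrow(s$mask), width = ncol(s$mask),
        bbox = lapply(s$bbox, function(b)
          list(label = "lesion", xmin = unname(b["xmin"]),
               ymin = unname(b["ymin"]), xmax = unname(b["xmax"]),
               ymax = unname(b["ymax"]))))
  }
  if (length(bb))
    jsonlite::write_json(bb, file.path(root, "bounding-boxes.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(root)
}
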