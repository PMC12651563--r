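#' Construct an image sample
#'
#' The unit of the data pipeline: a normalised RGB image, its binary
#' ground-truth mask, an identifier, and optional lesion bounding boxes.
#' Coordinates are 0-based with half-open boxes `(xmin, ymin, xmax, ymax)`
#' where x indexes columns.
#'
#' @param image `(H, W, 3)` array with values in `[0, 1]`.
#' @param mask `(H, W)` matrix containing only 0 and 1.
#' @param id character identifier (filename stem).
#' @param bbox optional list of named integer vectors
#'   `(xmin, ymin, xmax, ymax)`; boxes outside the image are clipped with a
#'   warning.
#' @return an object of class `image_sample`.
#' @export
image_sample <- function(image, mask, id, bbox = NULL) {
  if (length(dim(image)) != 3L || dim(image)[3L] != 3L)
    stop("image must be an (H, W, 3) array [sample ", id, "]", call. = FALSE)
  if (min(image) < 0 || max(image) > 1)
    stop("image values must lie in [0, 1] [sample ", id, "]", call. = FALSE)
  if (!identical(dim(image)[1:2], dim(mask)[1:2]))
    stop("image and mask shapes differ [sample ", id, "]", call. = FALSE)
  if (!all(mask %in% c(0, 1)))
    stop("mask must be strictly binary [sample ", id, "]", call. = FALSE)
  mask <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  if (!is.null(bbox)) {
    h <- nrow(mask); w <- ncol(mask)
    bbox <- lapply(bbox, function(b) {
      cl <- c(xmin = max(0, min(b[["xmin"]], w)),
              ymin = max(0, min(b[["ymin"]], h)),
              xmax = max(0, min(b[["xmax"]], w)),
              ymax = max(0, min(b[["ymax"]], h)))
      if (!identical(as.numeric(cl), as.numeric(b[c("xmin", "ymin", "xmax", "ymax")])))
        warning("bounding box clipped to image bounds [sample ", id, "]",
                call. = FALSE)
      cl
    })
  }
  structure(list(image = image, mask = mask, id = as.character(id),
                 bbox = bbox),
            class = "image_sample")
}

read_any_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::readPNG(path),
         jpg = ,
         jpeg = jpeg::readJPEG(path),
         stop("unsupported image format: ", path, call. = FALSE))
}

find_subdir <- function(root, candidates) {
  for (d in candidates) if (dir.exists(file.path(root, d))) return(file.path(root, d))
  NULL
}

#' Load a dataset in the Kvasir-SEG folder layout
#'
#' Expects `images/` and `masks/` folders (or `image/` / `mask/`) holding
#' JPEG or PNG files with matching stems, and optionally a JSON file
#' describing per-image bounding boxes.  Masks are binarised at 127/255 to
#' absorb JPEG compression noise; files without a partner are skipped with
#' a warning.
#'
#' The bounding-box JSON is a map from file stem to an object with a
#' `bbox` array whose entries carry `xmin`, `ymin`, `xmax`, `ymax`
#' (pixels); unknown fields are ignored.
#'
#' @param root dataset directory.
#' @param bbox_json optional path to the bounding-box JSON; by default the
#'   first `*.json` directly under `root` is used if present.
#' @return list of [image_sample()] objects.
#' @export
load_kvasir <- function(root, bbox_json = NULL) {
  img_dir <- find_subdir(root, c("images", "image"))
  msk_dir <- find_subdir(root, c("masks", "mask"))
  if (is.null(img_dir) || is.null(msk_dir))
    stop("expected images/ and masks/ folders under ", root, call. = FALSE)
  imgs <- list.files(img_dir, pattern = "\\.(png|jpe?g)$", ignore.case = TRUE)
  msks <- list.files(msk_dir, pattern = "\\.(png|jpe?g)$", ignore.case = TRUE)
  istem <- tools::file_path_sans_ext(imgs)
  mstem <- tools::file_path_sans_ext(msks)
  common <- intersect(istem, mstem)
  if (length(common) == 0L)
    stop("no matching image/mask stems under ", root, call. = FALSE)
  orphans <- c(setdiff(istem, mstem), setdiff(mstem, istem))
  if (length(orphans))
    warning(length(orphans), " unmatched file(s) skipped: ",
            paste(head(orphans, 5L), collapse = ", "), call. = FALSE)

  boxes <- NULL
  if (is.null(bbox_json)) {
    js <- list.files(root, pattern = "\\.json$", full.names = TRUE)
    if (length(js)) bbox_json <- js[[1L]]
  }
  if (!is.null(bbox_json) && file.exists(bbox_json))
    boxes <- jsonlite::read_json(bbox_json)

  lapply(sort(common), function(stem) {
    ipath <- file.path(img_dir, imgs[match(stem, istem)])
    mpath <- file.path(msk_dir, msks[match(stem, mstem)])
    img <- tryCatch(read_any_image(ipath),
                    error = function(e) stop("failed to read image for '",
                                             stem, "': ", conditionMessage(e),
                                             call. = FALSE))
    msk <- tryCatch(read_any_image(mpath),
                    error = function(e) stop("failed to read mask for '",
                                             stem, "': ", conditionMessage(e),
                                             call. = FALSE))
    if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
    if (dim(img)[3L] > 3L) img <- img[, , 1:3, drop = FALSE]
    if (length(dim(msk)) == 3L) msk <- msk[, , 1L]
    msk <- (msk > 127 / 255) * 1L
    bb <- NULL
    if (!is.null(boxes) && !is.null(boxes[[stem]])) {
      entry <- boxes[[stem]]
      bb <- lapply(entry$bbox, function(b)
        c(xmin = as.integer(b$xmin), ymin = as.integer(b$ymin),
          xmax = as.integer(b$xmax), ymax = as.integer(b$ymax)))
    }
    image_sample(pmin(pmax(img, 0), 1), msk, id = stem, bbox = bb)
  })
}

# Separable Lanczos-a resampling matrix mapping n_src samples to n_dst.
lanczos_matrix <- function(n_src, n_dst, a = 3) {
  scale <- n_src / n_dst
  support <- a * max(1, scale)
  A <- matrix(0, n_dst, n_src)
  for (i in seq_len(n_dst)) {
    u <- (i - 0.5) * scale + 0.5        # centre in source coordinates
    lo <- max(1L, floor(u - support))
    hi <- min(n_src, ceiling(u + support))
    j <- lo:hi
    t <- (j - u) / max(1, scale)
    w <- ifelse(abs(t) < 1e-12, 1,
                ifelse(abs(t) >= a, 0,
                       a * sin(pi * t) * sin(pi * t / a) / (pi^2 * t^2)))
    if (sum(w) == 0) w[which.min(abs(t))] <- 1
    A[i, j] <- w / sum(w)
  }
  A
}

#' Resize a sample to a square size
#'
#' The image is resampled with a separable Lanczos-3 kernel (edge-
#' preserving, anti-aliasing); the mask with nearest-neighbour sampling so
#' it stays exactly binary; bounding boxes are rescaled proportionally.
#'
#' @param s an [image_sample()].
#' @param size target pixels per side.
#' @return the resized sample.
#' @export
resize_sample <- function(s, size) {
  stopifnot(inherits(s, "image_sample"))
  size <- as.integer(size)
  if (is.na(size) || size <= 0L) stop("size must be positive", call. = FALSE)
  h <- nrow(s$mask); w <- ncol(s$mask)
  Ah <- lanczos_matrix(h, size)
  Aw <- lanczos_matrix(w, size)
  img <- array(0, c(size, size, 3L))
  for (ch in 1:3) img[, , ch] <- Ah %*% s$image[, , ch] %*% t(Aw)
  img <- pmin(pmax(img, 0), 1)
  ridx <- pmin(pmax(floor((seq_len(size) - 0.5) * h / size) + 1L, 1L), h)
  cidx <- pmin(pmax(floor((seq_len(size) - 0.5) * w / size) + 1L, 1L), w)
  msk <- s$mask[ridx, cidx]
  bb <- NULL
  if (!is.null(s$bbox))
    bb <- lapply(s$bbox, function(b)
      c(xmin = as.integer(round(b[["xmin"]] * size / w)),
        ymin = as.integer(round(b[["ymin"]] * size / h)),
        xmax = as.integer(round(b[["xmax"]] * size / w)),
        ymax = as.integer(round(b[["ymax"]] * size / h))))
  image_sample(img, msk, id = s$id, bbox = bb)
}

#' Random train/validation/test split
#'
#' A seeded random permutation followed by contiguous slicing.  Part sizes
#' are the floors of `n * ratios` with the remainder assigned to the
#' training part, so the three parts always form an exact partition.
#'
#' @param samples list of samples (any type).
#' @param ratios length-3 numeric summing to 1 (train, validation, test).
#' @param seed RNG seed; the same seed always yields the same partition.
#' @return list with elements `train`, `val`, `test`.
#' @export
split_dataset <- function(samples, ratios = c(0.8, 0.1, 0.1), seed = 42L) {
  n <- length(samples)
  if (abs(sum(ratios) - 1) > 1e-8)
    stop("ratios must sum to 1", call. = FALSE)
  if (n < sum(ratios > 0))
    stop("fewer samples (", n, ") than split parts", call. = FALSE)
  sizes <- floor(n * ratios)
  sizes[1L] <- sizes[1L] + (n - sum(sizes))
  perm <- with_seed(seed, sample.int(n))
  idx <- split(perm, factor(rep(1:3, times = sizes), levels = 1:3))
  list(train = samples[idx[[1L]]],
       val = samples[idx[[2L]]],
       test = samples[idx[[3L]]])
}
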