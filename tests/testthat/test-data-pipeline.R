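test_that("the generator honours its contract and is seed-deterministic", {
  spec <- synthetic_spec(n_images = 10, image_size = 48, seed = 17)
  ds <- generate_synthetic(spec)
  expect_length(ds, 10)
  for (s in ds) {
    expect_s3_class(s, "image_sample")
    expect_true(all(s$mask %in% c(0L, 1L)))
    expect_gt(sum(s$mask), 0)
    expect_true(min(s$image) >= 0 && max(s$image) <= 1)
  }
  ds2 <- generate_synthetic(spec)
  expect_identical(ds, ds2)
  expect_error(synthetic_spec(5, radius_range = c(0.2, 0.6)), "radius")
})

test_that("lesion sizes respect the configured radius range", {
  ds <- generate_synthetic(synthetic_spec(
    n_images = 5, image_size = 128, lesions_range = c(1, 1),
    radius_range = c(0.1, 0.2), seed = 23))
  for (s in ds) {
    lab <- label_components(s$mask)
    for (k in seq_len(max(lab))) {
      r_eq <- sqrt(sum(lab == k) / pi) / 128
      expect_gte(r_eq, 0.08)
      expect_lte(r_eq, 0.26)
    }
  }
})

test_that("the folder loader matches stems, binarises masks and clips boxes", {
  root <- tempfile()
  ds <- generate_synthetic(synthetic_spec(n_images = 3, image_size = 32,
                                          seed = 3))
  write_kvasir_layout(ds, root)
  # an orphan image with no mask partner
  png::writePNG(array(0.5, c(8, 8, 3)), file.path(root, "images", "orphan.png"))
  expect_warning(loaded <- load_kvasir(root), "unmatched")
  expect_length(loaded, 3)
  expect_identical(lapply(loaded, `[[`, "mask"),
                   lapply(ds, `[[`, "mask"))

  # near-binary mask values (JPEG-style noise) binarise at 127/255
  root2 <- tempfile()
  dir.create(file.path(root2, "images"), recursive = TRUE)
  dir.create(file.path(root2, "masks"), recursive = TRUE)
  png::writePNG(array(0.4, c(6, 6, 3)), file.path(root2, "images", "a.png"))
  png::writePNG(matrix(c(3, 250) / 255, 6, 6), file.path(root2, "masks", "a.png"))
  got <- load_kvasir(root2)
  expect_equal(sort(unique(as.vector(got[[1]]$mask))), c(0L, 1L))
  expect_equal(got[[1]]$mask, matrix(rep(c(0L, 1L), 18), 6, 6))

  # bounding box beyond the image is clipped with a warning
  jsonlite::write_json(
    list(a = list(bbox = list(list(xmin = 2, ymin = 0, xmax = 11, ymax = 4)))),
    file.path(root2, "boxes.json"), auto_unbox = TRUE)
  expect_warning(got2 <- load_kvasir(root2), "clipped")
  expect_equal(unname(got2[[1]]$bbox[[1]]["xmax"]), 6)

  expect_error(load_kvasir(tempfile()), "folders")
})

test_that("resizing uses Lanczos for images and stays binary for masks", {
  ds <- generate_synthetic(synthetic_spec(n_images = 1, image_size = 40,
                                          seed = 5))
  r <- resize_sample(ds[[1]], 24)
  expect_equal(dim(r$image), c(24L, 24L, 3L))
  expect_equal(dim(r$mask), c(24L, 24L))
  expect_true(all(r$mask %in% c(0L, 1L)))

  flat <- image_sample(array(0.37, c(20, 30, 3)), matrix(0L, 20, 30), "flat")
  rf <- resize_sample(flat, 16)
  expect_equal(max(abs(rf$image - 0.37)), 0, tolerance = 1e-6)

  checker <- image_sample(array(0.5, c(8, 8, 3)),
                          outer(1:8, 1:8, function(i, j) (i + j) %% 2L),
                          "check")
  rc <- resize_sample(checker, 4)
  expect_true(all(rc$mask %in% c(0L, 1L)))

  expect_error(resize_sample(flat, 0), "positive")

  # bounding boxes rescale proportionally
  boxed <- image_sample(array(0.2, c(20, 20, 3)), {
    m <- matrix(0L, 20, 20); m[6:10, 6:10] <- 1L; m
  }, "boxed", bbox = list(c(xmin = 5, ymin = 5, xmax = 10, ymax = 10)))
  rb <- resize_sample(boxed, 10)
  expect_equal(unname(rb$bbox[[1]]),
               c(round(5 * 0.5), round(5 * 0.5), round(10 * 0.5),
                 round(10 * 0.5)))
})

test_that("splitting is an exact seeded partition with floor-to-train rule", {
  x <- as.list(1:1000)
  sp <- split_dataset(x, seed = 42)
  expect_equal(lengths(sp), c(train = 800L, val = 100L, test = 100L))
  expect_setequal(unlist(sp), 1:1000)
  sp2 <- split_dataset(x, seed = 42)
  expect_identical(sp, sp2)
  expect_false(identical(sp, split_dataset(x, seed = 43)))

  sp10 <- split_dataset(as.list(1:10), seed = 1)
  expect_equal(lengths(sp10), c(train = 8L, val = 1L, test = 1L))

  expect_error(split_dataset(as.list(1:2), seed = 1), "fewer samples")
  expect_error(split_dataset(as.list(1:10), ratios = c(0.5, 0.1, 0.1)),
               "sum to 1")
})

test_that("forced flips relocate pixels and are involutions", {
  ds <- generate_synthetic(synthetic_spec(n_images = 1, image_size = 16,
                                          seed = 7))
  s <- ds[[1]]
  cfg <- augmentation_config(vflip_p = 0, rot90_p = 0, color_jitter_p = 0,
                             affine_p = 0)
  once <- augment_pair(s, cfg, seed = 1, force = list(hflip = TRUE))
  w <- ncol(s$mask)
  for (rc in list(c(3, 2), c(10, 16))) {
    expect_equal(once$mask[rc[1], w + 1 - rc[2]], s$mask[rc[1], rc[2]])
  }
  twice <- augment_pair(once, cfg, seed = 2, force = list(hflip = TRUE))
  expect_identical(twice$mask, s$mask)
  expect_identical(twice$image, s$image)
})

test_that("photometric jitter clips the image and never touches the mask", {
  img <- array(0.8, c(8, 8, 3))
  msk <- matrix(rbinom(64, 1, 0.5), 8, 8)
  s <- image_sample(img, msk, "p")
  cfg <- augmentation_config(hflip_p = 0, vflip_p = 0, rot90_p = 0,
                             affine_p = 0, brightness = c(1.6, 1.6),
                             contrast = 0, saturation = 0, hue = 0)
  out <- augment_pair(s, cfg, seed = 1, force = list(color_jitter = TRUE))
  expect_true(all(out$image == 1))
  expect_identical(out$mask, msk)
})

test_that("augmentation is reproducible from its seed", {
  ds <- generate_synthetic(synthetic_spec(n_images = 1, image_size = 24,
                                          seed = 9))
  cfg <- augmentation_config()
  a <- augment_pair(ds[[1]], cfg, seed = 123)
  b <- augment_pair(ds[[1]], cfg, seed = 123)
  expect_identical(a, b)
  expect_true(all(a$mask %in% c(0L, 1L)))
})

test_that("an identity affine transform is exact", {
  set.seed(61)
  img <- array(runif(10 * 10 * 3), c(10, 10, 3))
  msk <- matrix(rbinom(100, 1, 0.4), 10, 10)
  at <- munetseg:::affine_transform(img, msk, angle = 0, sc = 1, tx = 0,
                                    ty = 0, shx = 0, shy = 0)
  expect_equal(at$image, img, tolerance = 1e-12)
  expect_identical(at$mask, msk)
})

test_that("masks stay binary through load, resize and augmentation", {
  root <- tempfile()
  ds <- generate_synthetic(synthetic_spec(n_images = 2, image_size = 40,
                                          seed = 10))
  write_kvasir_layout(ds, root)
  loaded <- load_kvasir(root)
  for (s in loaded) {
    r <- resize_sample(s, 32)
    a <- augment_pair(r, augmentation_config(), seed = 5)
    expect_true(all(a$mask %in% c(0L, 1L)))
  }
})
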