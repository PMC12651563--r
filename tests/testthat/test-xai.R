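toy_conv_model <- function(weights, k = 1L, sigmoid = FALSE) {
  ns <- asNamespace("munetseg")
  conv <- ns$nn_conv(3L, 1L, k, name = "conv")
  conv$params$w <- array(weights, c(k, k, 3L, 1L))
  conv$params$b[] <- 0
  kids <- list(conv = conv)
  if (sigmoid) kids$sig <- ns$nn_sigmoid()
  m <- ns$nn_seq(kids, name = "toy")
  ns$assign_paths(m)
  m
}

test_that("a constant-output model yields an all-zero heat map", {
  model <- build_munet(network_config(input_size = 32, base_filters = 2,
                                      seed = 11))
  model$children$head$params$w[] <- 0
  model$children$head$params$b[] <- 0
  img <- array(runif(32 * 32 * 3), c(32, 32, 3, 1))
  cam <- grad_cam(model, img)
  expect_true(all(cam$heat == 0))
  sal <- saliency(model, img)
  expect_true(all(sal$heat == 0))
})

test_that("heat maps match the input resolution for any target layer", {
  model <- build_munet(network_config(input_size = 32, base_filters = 2,
                                      seed = 12))
  img <- array(runif(32 * 32 * 3), c(32, 32, 3, 1))
  for (layer in c("munet/dec1", "munet/enc2", "munet/bott1")) {
    cam <- grad_cam(model, img, target_layer = layer)
    expect_equal(dim(cam$heat), c(32L, 32L))
    expect_true(all(cam$heat >= 0 & cam$heat <= 1))
  }
  expect_error(grad_cam(model, img, target_layer = "nope"),
               "available layers")
})

test_that("saliency of a linear model is exactly proportional to |weights|", {
  set.seed(71)
  w <- rnorm(3)
  model <- toy_conv_model(w, k = 1L, sigmoid = FALSE)
  img <- array(runif(6 * 6 * 3), c(6, 6, 3, 1))
  sal <- saliency(model, img, scalarization = "sum")
  expect_equal(sal$heat, matrix(1, 6, 6))   # constant |w|max, normalised
  # check against the raw gradient before normalisation
  ns <- asNamespace("munetseg")
  ctx <- ns$make_ctx(grad = TRUE)
  ns$nn_forward(model, img, ctx)
  dx <- ns$nn_backward(model, array(1, c(6, 6, 1, 1)), ctx)
  expect_equal(unique(round(as.vector(abs(dx[, , 1, 1])), 12)),
               round(abs(w[1]), 12))
})

test_that("grad-cam of a one-layer model highlights the active region", {
  set.seed(72)
  model <- toy_conv_model(rep(1, 9 * 3) / 27, k = 3L, sigmoid = TRUE)
  img <- array(0, c(16, 16, 3, 1))
  img[1:8, 1:8, , 1] <- 1    # bright top-left quadrant
  cam <- grad_cam(model, img, target_layer = "toy/conv",
                  scalarization = "sum")
  inside <- mean(cam$heat[1:8, 1:8])
  outside <- mean(cam$heat[9:16, 9:16])
  expect_gt(inside, outside)
  expect_equal(max(cam$heat), 1)
})

test_that("explanations of a frozen model are deterministic", {
  model <- build_munet(network_config(input_size = 32, base_filters = 2,
                                      seed = 13))
  img <- array(runif(32 * 32 * 3), c(32, 32, 3, 1))
  expect_identical(saliency(model, img)$heat, saliency(model, img)$heat)
  expect_identical(grad_cam(model, img)$heat, grad_cam(model, img)$heat)
})

test_that("overlay blends linearly between image and colour-mapped heat", {
  set.seed(73)
  img <- array(runif(5 * 5 * 3), c(5, 5, 3))
  heat <- matrix(runif(25), 5, 5)
  expect_equal(overlay_heat(img, heat, alpha = 0), img)
  pure <- overlay_heat(img, heat, alpha = 1)
  half <- overlay_heat(img, heat, alpha = 0.5)
  expect_equal(half, 0.5 * img + 0.5 * pure, tolerance = 1e-12)
  expect_true(all(pure >= 0 & pure <= 1))
  expect_error(overlay_heat(img, heat, alpha = 2), "alpha")
})
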