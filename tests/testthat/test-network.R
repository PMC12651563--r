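test_that("configuration validation enforces divisibility and positivity", {
  expect_error(network_config(input_size = 350), "divisible")
  expect_error(network_config(depth = 0), "depth")
  expect_silent(network_config())  # 352 / 2^5 = 11
  expect_equal(network_config()$width_schedule, c(17L, 34L, 68L, 136L, 272L))
})

test_that("encoder halves and decoder restores the spatial grid", {
  model <- build_munet(network_config(input_size = 64, base_filters = 4,
                                      seed = 1))
  sm <- summarize_model(model)
  downs <- sm$layers[grepl("/down\\d$", sm$layers$layer), "out_shape"]
  expect_equal(sub("x.*", "", downs), as.character(c(32, 16, 8, 4, 2)))
  head_row <- sm$layers[sm$layers$layer == "munet/head_sigmoid", ]
  expect_equal(head_row$out_shape, "64x64x1x1")
})

test_that("forward pass yields a full-resolution probability map", {
  model <- build_munet(network_config(input_size = 64, base_filters = 4,
                                      seed = 2))
  x <- array(0, c(64, 64, 3, 1))
  pm <- predict_mask(model, x)
  expect_equal(dim(pm$prob), c(64L, 64L, 1L, 1L))
  expect_true(all(pm$prob > 0 & pm$prob < 1))
  expect_true(all(pm$mask %in% c(0, 1)))
})

test_that("threshold conventions: boundary is foreground, >1 empties the mask", {
  model <- build_munet(network_config(input_size = 32, base_filters = 2,
                                      seed = 3))
  # zero the head so the output is exactly sigmoid(0) = 0.5 everywhere
  model$children$head$params$w[] <- 0
  model$children$head$params$b[] <- 0
  x <- array(0.5, c(32, 32, 3, 1))
  pm <- predict_mask(model, x, threshold = 0.5)
  expect_true(all(pm$mask == 1))
  pm2 <- predict_mask(model, x, threshold = 1.1)
  expect_true(all(pm2$mask == 0))
  expect_error(predict_mask(model, array(0, c(16, 16, 3, 1))), "resize")
})

test_that("construction is deterministic for a fixed configuration", {
  cfg <- network_config(input_size = 32, base_filters = 3, seed = 9)
  m1 <- build_munet(cfg); m2 <- build_munet(cfg)
  expect_identical(munetseg:::get_weights(m1), munetseg:::get_weights(m2))
  s1 <- summarize_model(m1); s2 <- summarize_model(m2)
  expect_identical(s1$trainable_parameters, s2$trainable_parameters)
  expect_identical(s1$layers, s2$layers)
})

test_that("the size summary matches the closed-form count for one conv layer", {
  conv <- munetseg:::nn_conv(3L, 1L, 1L)
  conv$path <- "lone_conv"
  acc <- munetseg:::new_count_acc()
  out <- munetseg:::nn_count(conv, c(352L, 352L, 3L, 1L), acc)
  row <- acc$rows[[1]]
  expect_equal(row$params, 4)            # 3 weights + 1 bias
  expect_equal(row$flops, 2 * 3 * 352 * 352 + 352 * 352)
  expect_equal(out, c(352L, 352L, 1L, 1L))
})

test_that("weights survive a save/load round trip", {
  cfg <- network_config(input_size = 32, base_filters = 2, seed = 4)
  m1 <- build_munet(cfg)
  f <- tempfile(fileext = ".rds")
  save_weights(m1, f)
  m2 <- build_munet(network_config(input_size = 32, base_filters = 2,
                                   seed = 99))
  load_weights(m2, f)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3, 1))
  expect_identical(predict_mask(m1, x)$prob, predict_mask(m2, x)$prob)
})

test_that("analytic gradients agree with finite differences end to end", {
  set.seed(41)
  ns <- asNamespace("munetseg")
  cfg <- network_config(input_size = 16, depth = 2, base_filters = 3,
                        seed = 5)
  model <- build_munet(cfg)
  x <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  tr <- array(rbinom(16 * 16 * 2, 1, 0.4), c(16, 16, 1, 2))
  lossfn <- function() {
    ctx <- ns$make_ctx(training = TRUE, grad = TRUE)
    prob <- ns$nn_forward(model, x, ctx)
    list(l = segmentation_loss(prob, tr, with_grad = TRUE), ctx = ctx)
  }
  r <- lossfn()
  ns$nn_zero_grad(model)
  ns$nn_backward(model, r$l$grad, r$ctx)
  mods <- Filter(function(m) length(m$params) > 0, ns$nn_modules(model))
  eps <- 1e-5
  worst <- 0
  for (pi in sample(length(mods), 8)) {
    m <- mods[[pi]]
    nm <- sample(names(m$params), 1)
    idx <- sample(length(m$params[[nm]]), 1)
    g_an <- m$grads[[nm]][idx]
    orig <- m$params[[nm]][idx]
    m$params[[nm]][idx] <- orig + eps
    lp <- lossfn()$l$loss
    m$params[[nm]][idx] <- orig - eps
    lm <- lossfn()$l$loss
    m$params[[nm]][idx] <- orig
    g_fd <- (lp - lm) / (2 * eps)
    worst <- max(worst, abs(g_an - g_fd) /
                   max(1e-8, abs(g_an) + abs(g_fd)))
  }
  expect_lt(worst, 1e-3)
})

test_that("layer listing exposes addressable decoder blocks", {
  model <- build_munet(network_config(input_size = 32, base_filters = 2,
                                      seed = 6))
  ll <- list_layers(model)
  expect_true("munet/dec1" %in% ll)
  expect_true(any(grepl("enc1/tdau", ll)))
})
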