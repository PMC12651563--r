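test_that("compound loss matches closed forms", {
  n <- 16L
  truth <- array(rep(c(1, 0), each = n * n / 2), c(n, n, 1, 1))
  prob <- array(0.5, c(n, n, 1, 1))
  l <- segmentation_loss(prob, truth)
  expect_equal(l$bce, log(2), tolerance = 1e-12)
  expect_equal(l$dice_loss, 0.5, tolerance = 1e-5)
  expect_equal(l$loss, 0.5 * log(2) + 0.25, tolerance = 1e-5)

  # endpoints of the mix weight
  expect_equal(segmentation_loss(prob, truth, lambda = 1)$loss, l$bce)
  expect_equal(segmentation_loss(prob, truth, lambda = 0)$loss, l$dice_loss)

  # near-perfect prediction drives both terms to ~0
  eps <- 1e-7
  perfect <- pmin(pmax(truth, eps), 1 - eps)
  lp <- segmentation_loss(perfect, truth)
  expect_lt(lp$loss, 1e-5)
})

test_that("loss is nonnegative and its gradient matches finite differences", {
  set.seed(51)
  prob <- array(runif(8 * 8, 0.05, 0.95), c(8, 8, 1, 1))
  truth <- array(rbinom(64, 1, 0.5), c(8, 8, 1, 1))
  l <- segmentation_loss(prob, truth, with_grad = TRUE)
  expect_gte(l$loss, 0)
  h <- 1e-6
  for (idx in sample(64, 5)) {
    p2 <- prob; p2[idx] <- prob[idx] + h
    p3 <- prob; p3[idx] <- prob[idx] - h
    fd <- (segmentation_loss(p2, truth)$loss -
             segmentation_loss(p3, truth)$loss) / (2 * h)
    expect_equal(l$grad[idx], fd, tolerance = 1e-4)
  }
})

test_that("zero-epoch training returns an empty history without error", {
  ts <- tiny_setup(4)
  res <- train_munet(ts$model, list(train = ts$samples),
                     train_config(epochs = 0, batch_size = 2))
  expect_equal(nrow(res$history), 0)
  expect_null(res$checkpoint)
})

test_that("same seed reproduces the epoch-1 loss with augmentation active", {
  run_once <- function() {
    ts <- tiny_setup(6, seed = 3)
    cfg <- train_config(learning_rate = 1e-3, epochs = 1, batch_size = 2,
                        seed = 42, augment = augmentation_config())
    train_munet(ts$model, list(train = ts$samples), cfg)$history$train_loss
  }
  expect_identical(run_once(), run_once())
})

test_that("non-finite activations abort training with the epoch index", {
  ts <- tiny_setup(4)
  ts$model$children$head$params$w[] <- NaN
  expect_error(
    train_munet(ts$model, list(train = ts$samples),
                train_config(epochs = 2, batch_size = 2)),
    "diverged.*epoch 1")
})

test_that("the saved checkpoint realises the best validation Dice", {
  ts <- tiny_setup(14, seed = 5)
  splits <- list(train = ts$samples[1:10], val = ts$samples[11:14])
  dir <- tempfile()
  cfg <- train_config(learning_rate = 1e-3, epochs = 4, batch_size = 2,
                      seed = 42, checkpoint_dir = dir)
  res <- train_munet(ts$model, splits, cfg)
  expect_equal(res$best_val_dice, max(res$history$val_dice))
  expect_true(file.exists(res$checkpoint))
  expect_true(file.exists(res$checkpoint_min_loss))

  best <- build_munet(network_config(input_size = 32, base_filters = 4,
                                     seed = 5))
  load_weights(best, res$checkpoint)
  dices <- vapply(splits$val, function(s) {
    pm <- predict_mask(best, s$image)
    dice(confusion_counts(pm$mask[, , 1, 1], s$mask))
  }, 0)
  expect_equal(mean(dices), res$best_val_dice, tolerance = 1e-6)
})

test_that("grid candidates rank by Dice with loss as tie-break", {
  ord <- munetseg:::rank_candidates(c(0.8, 0.9, 0.9), c(0.3, 0.2, 0.1))
  expect_equal(ord, c(3L, 2L, 1L))
  # strict dominance
  ord2 <- munetseg:::rank_candidates(c(0.95, 0.70), c(0.1, 0.5))
  expect_equal(ord2[1], 1L)
})

test_that("grid search trains each point and returns the winner", {
  ts <- tiny_setup(10, seed = 6)
  splits <- list(train = ts$samples[1:8], val = ts$samples[9:10])
  cfg <- train_config(epochs = 1, batch_size = 4, seed = 42,
                      grid = list(learning_rate = c(1e-3, 1e-4),
                                  batch_size = 4L, epochs = 1L))
  factory <- function() build_munet(network_config(input_size = 32,
                                                   base_filters = 4,
                                                   seed = 6))
  gs <- grid_search(factory, splits, cfg)
  expect_equal(nrow(gs$table), 2)
  expect_true(all(diff(gs$table$val_dice) <= 0))
  expect_equal(gs$best$learning_rate, gs$table$learning_rate[1])
  expect_error(grid_search(factory, splits,
                           train_config(grid = list(learning_rate = c()))),
               "grid")
})

test_that("a scaled-down network overfits a handful of images", {
  # 8 synthetic images, reference architecture at 64 px / base width 8,
  # 50 epochs x 4 steps = 200 optimisation steps
  samples <- generate_synthetic(
    synthetic_spec(n_images = 8, image_size = 64, seed = 42))
  model <- build_munet(network_config(input_size = 64, base_filters = 8,
                                      seed = 42))
  cfg <- train_config(learning_rate = 3e-3, epochs = 50, batch_size = 2,
                      seed = 42)
  res <- train_munet(model, list(train = samples), cfg)
  expect_gt(res$history$train_dice[30], 0.9)
  expect_gt(tail(res$history$train_dice, 1), 0.95)
})
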