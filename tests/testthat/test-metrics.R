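test_that("confusion counts tally pixels correctly", {
  truth <- matrix(0, 4, 4); truth[1:2, 1:2] <- 1
  pred <- matrix(0, 4, 4); pred[1:2, 1] <- 1
  cc <- confusion_counts(pred, truth)
  expect_equal(unclass(cc)[c("tp", "fp", "tn", "fn")],
               list(tp = 2, fp = 0, tn = 12, fn = 2))

  same <- matrix(rbinom(25, 1, 0.5), 5, 5)
  cc2 <- confusion_counts(same, same)
  expect_equal(cc2$fp + cc2$fn, 0)

  cc3 <- confusion_counts(matrix(1, 3, 3), matrix(0, 3, 3))
  expect_equal(unclass(cc3)[c("tp", "fp", "tn", "fn")],
               list(tp = 0, fp = 9, tn = 0, fn = 0))

  expect_error(confusion_counts(matrix(1, 2, 2), matrix(1, 3, 3)), "shape")
  expect_error(confusion_counts(matrix(0.5, 2, 2), matrix(1, 2, 2)), "binary")
})

test_that("the five metrics match hand-computed values", {
  cc <- list(tp = 2, fp = 0, tn = 12, fn = 2)
  expect_equal(dice(cc), 4 / 6)
  expect_equal(iou(cc), 0.5)
  expect_equal(pixel_accuracy(cc), 14 / 16)
  expect_equal(precision(cc), 1)
  expect_equal(recall(cc), 0.5)

  perfect <- list(tp = 5, fp = 0, tn = 4, fn = 0)
  for (m in list(dice, iou, pixel_accuracy, precision, recall))
    expect_equal(m(perfect), 1)

  disjoint <- list(tp = 0, fp = 3, tn = 2, fn = 4)
  expect_equal(dice(disjoint), 0)
  expect_equal(iou(disjoint), 0)
})

test_that("empty-vs-empty convention gives overlap 1 and undefined rates", {
  empty <- list(tp = 0, fp = 0, tn = 9, fn = 0)
  expect_equal(dice(empty), 1)
  expect_equal(iou(empty), 1)
  expect_true(is.nan(precision(empty)))
  expect_true(is.nan(recall(empty)))
})

test_that("Dice-Jaccard identity holds on 1000 random mask pairs", {
  set.seed(11)
  worst <- 0
  for (i in 1:1000) {
    m <- random_masks(6, runif(1, 0.1, 0.9))
    cc <- confusion_counts(m$a, m$b)
    d <- dice(cc); j <- iou(cc)
    worst <- max(worst, abs(d - 2 * j / (1 + j)))
  }
  expect_lt(worst, 1e-12)
})

test_that("symmetry: dice is symmetric and precision mirrors recall", {
  set.seed(12)
  for (i in 1:50) {
    m <- random_masks(8)
    expect_equal(dice(confusion_counts(m$a, m$b)),
                 dice(confusion_counts(m$b, m$a)))
    p <- precision(confusion_counts(m$a, m$b))
    r <- recall(confusion_counts(m$b, m$a))
    if (!is.nan(p) || !is.nan(r)) expect_equal(p, r)
  }
})

test_that("adding a correctly predicted pixel never hurts overlap metrics", {
  set.seed(13)
  for (i in 1:50) {
    m <- random_masks(8, 0.5)
    miss <- which(m$b == 1 & m$a == 0)
    if (length(miss) == 0) next
    before <- confusion_counts(m$a, m$b)
    a2 <- m$a; a2[sample(miss, 1)] <- 1
    after <- confusion_counts(a2, m$b)
    expect_gte(dice(after), dice(before))
    expect_gte(iou(after), iou(before))
    expect_gte(recall(after), recall(before))
    expect_gte(pixel_accuracy(after), pixel_accuracy(before))
  }
})

test_that("metrics are invariant under joint pixel permutation", {
  set.seed(14)
  m <- random_masks(7)
  perm <- sample(49)
  a2 <- matrix(m$a[perm], 7, 7); b2 <- matrix(m$b[perm], 7, 7)
  expect_equal(unclass(confusion_counts(m$a, m$b)),
               unclass(confusion_counts(a2, b2)))
})

test_that("aggregation uses per-image means and sample sd, excluding NaN", {
  r1 <- metric_report(matrix(c(1, 1, 0, 0), 2), matrix(c(1, 0, 1, 0), 2))
  expect_equal(r1$dice, 0.5)
  agg1 <- aggregate_reports(list(r1))
  expect_equal(agg1$dice, r1$dice)
  expect_equal(agg1$sd$dice, 0)

  # two images with dice 0.6 and 0.8 -> mean 0.7, sd sqrt(0.02)
  mk <- function(target_dice) {
    # tp chosen so 2tp/(2tp+fp+fn) hits the target on a 10-pixel problem
    if (target_dice == 0.6) {
      truth <- matrix(c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0), 2)
      pred <- matrix(c(1, 1, 1, 0, 0, 1, 1, 0, 0, 0), 2)   # tp3 fp2 fn2
    } else {
      truth <- matrix(c(1, 1, 0, 0, 0, 0, 0, 0, 0, 0), 2)
      pred <- matrix(c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0), 2)   # tp2 fp1 fn0
    }
    metric_report(pred, truth)
  }
  a <- mk(0.6); b <- mk(0.8)
  expect_equal(a$dice, 0.6); expect_equal(b$dice, 0.8)
  agg <- aggregate_reports(list(a, b))
  expect_equal(agg$dice, 0.7)
  expect_equal(agg$sd$dice, sqrt(0.02), tolerance = 1e-12)

  # identical reports -> zero sd; empty masks excluded from precision mean
  agg3 <- aggregate_reports(list(a, a, a))
  expect_equal(agg3$sd$dice, 0)
  empty <- metric_report(matrix(0, 2, 2), matrix(0, 2, 2))
  agg4 <- aggregate_reports(list(a, empty))
  expect_equal(agg4$precision, a$precision)
  expect_equal(agg4$dice, mean(c(a$dice, 1)))

  expect_error(aggregate_reports(list()), "empty")
})

test_that("evaluation writes one row per image plus an aggregate", {
  set.seed(15)
  preds <- replicate(3, matrix(rbinom(16, 1, 0.5), 4), simplify = FALSE)
  truths <- replicate(3, matrix(rbinom(16, 1, 0.5), 4), simplify = FALSE)
  ev <- evaluate_masks(preds, truths)
  csv <- tempfile(fileext = ".csv"); json <- tempfile(fileext = ".json")
  df <- write_metric_report(ev, csv = csv, json = json)
  expect_equal(nrow(df), 4)
  expect_equal(df$id[4], "aggregate")
  expect_true(file.exists(csv) && file.exists(json))
  back <- read.csv(csv)
  expect_equal(back$dice, df$dice, tolerance = 1e-12)

  # micro pooling equals metrics on pooled counts
  evm <- evaluate_masks(preds, truths, mode = "micro")
  tot <- Reduce(function(acc, i) {
    cc <- confusion_counts(preds[[i]], truths[[i]])
    Map(`+`, acc, unclass(cc)[c("tp", "fp", "tn", "fn")])
  }, 1:3, init = list(tp = 0, fp = 0, tn = 0, fn = 0))
  expect_equal(evm$aggregate$dice, dice(tot))
})
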