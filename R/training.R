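#' Training configuration
#'
#' @param learning_rate AdamW learning rate.
#' @param weight_decay decoupled weight decay.
#' @param epochs training epochs; 0 is allowed and yields an empty history.
#' @param batch_size images per optimisation step.
#' @param seed master seed fanned out to shuffling and augmentation.
#' @param lambda mix weight of the compound loss:
#'   `lambda * BCE + (1 - lambda) * soft-Dice`.
#' @param threshold binarisation threshold for Dice tracking.
#' @param augment optional [augmentation_config()] applied afresh to the
#'   training inputs each epoch (validation is always evaluated
#'   unaugmented).
#' @param checkpoint_dir directory for the best-validation-Dice checkpoint
#'   (and the minimum-validation-loss checkpoint, tracked from an initial
#'   best of `+Inf`); `NULL` disables checkpointing.
#' @param grid candidate lists for [grid_search()].
#' @param verbose print one line per epoch.
#' @return an object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, weight_decay = 1e-5,
                         epochs = 300L, batch_size = 2L, seed = 42L,
                         lambda = 0.5, threshold = 0.5, augment = NULL,
                         checkpoint_dir = NULL,
                         grid = list(learning_rate = c(5e-5, 5e-4),
                                     batch_size = c(1L, 4L),
                                     epochs = c(100L, 400L)),
                         verbose = FALSE) {
  if (learning_rate <= 0 || weight_decay < 0 || batch_size < 1L)
    stop("invalid optimisation settings", call. = FALSE)
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]", call. = FALSE)
  if (epochs < 0L) stop("epochs must be >= 0", call. = FALSE)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 seed = as.integer(seed), lambda = lambda,
                 threshold = threshold, augment = augment,
                 checkpoint_dir = checkpoint_dir, grid = grid,
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Compound segmentation loss
#'
#' `lambda * BCE + (1 - lambda) * soft-Dice`, where the soft Dice loss of
#' each sample is `1 - (2*sum(p*g) + eps) / (sum(p) + sum(g) + eps)` with
#' `eps = 1e-6`, averaged over the batch, and BCE is the mean binary
#' cross-entropy over all pixels.  Probabilities are clipped away from 0/1
#' before the logarithm.
#'
#' @param prob probability map `(H, W, 1, N)` (or any array).
#' @param truth binary mask of the same shape.
#' @param lambda mix weight in `[0, 1]`; 1 is pure cross-entropy, 0 pure
#'   Dice loss.
#' @param eps soft-Dice smoothing constant.
#' @param with_grad also return the gradient with respect to `prob`.
#' @return list with `loss`, `bce`, `dice_loss` (and `grad` if requested).
#' @export
segmentation_loss <- function(prob, truth, lambda = 0.5, eps = 1e-6,
                              with_grad = FALSE) {
  if (!identical(dim2(prob), dim2(truth)))
    stop("prob and truth shapes differ", call. = FALSE)
  d <- dim(prob) %||% c(length(prob), 1L, 1L, 1L)
  if (length(d) < 4L) { dim(prob) <- c(d, rep(1L, 4 - length(d))); dim(truth) <- dim(prob) }
  n <- dim(prob)[4L]
  pixels <- length(prob)
  clip <- 1e-12
  pc <- pmin(pmax(prob, clip), 1 - clip)
  bce <- -mean(truth * log(pc) + (1 - truth) * log(1 - pc))

  pm <- matrix(prob, ncol = n)
  tm <- matrix(truth, ncol = n)
  inter <- colSums(pm * tm)
  tot <- colSums(pm) + colSums(tm)
  dsc <- (2 * inter + eps) / (tot + eps)
  dice_loss <- mean(1 - dsc)
  out <- list(loss = lambda * bce + (1 - lambda) * dice_loss,
              bce = bce, dice_loss = dice_loss)
  if (with_grad) {
    gb <- (-truth / pc + (1 - truth) / (1 - pc)) / pixels
    gd <- sweep(-2 * tm, 2L, tot + eps, "/") +
      sweep(pm * 0 + 1, 2L, (2 * inter + eps) / (tot + eps)^2, "*")
    gd <- gd / n
    g <- lambda * gb + (1 - lambda) * array(gd, dim(prob))
    out$grad <- g
  }
  out
}

batch_arrays <- function(samples) {
  h <- nrow(samples[[1L]]$mask); w <- ncol(samples[[1L]]$mask)
  n <- length(samples)
  x <- array(0, c(h, w, 3L, n))
  t <- array(0, c(h, w, 1L, n))
  for (i in seq_len(n)) {
    x[, , , i] <- samples[[i]]$image
    t[, , 1L, i] <- samples[[i]]$mask
  }
  list(x = x, t = t)
}

macro_dice <- function(prob, truth, threshold) {
  n <- dim(prob)[4L]
  pm <- matrix((prob >= threshold) * 1, ncol = n)
  tm <- matrix(truth, ncol = n)
  inter <- colSums(pm * tm)
  den <- colSums(pm) + colSums(tm)
  mean(ifelse(den == 0, 1, 2 * inter / den))
}

eval_split <- function(model, samples, cfg, batch = 8L) {
  losses <- c(); dices <- c(); ns <- c()
  i <- 1L
  while (i <= length(samples)) {
    j <- min(i + batch - 1L, length(samples))
    ba <- batch_arrays(samples[i:j])
    prob <- nn_forward(model, ba$x, make_ctx(training = FALSE, grad = FALSE))
    l <- segmentation_loss(prob, ba$t, cfg$lambda)
    losses <- c(losses, l$loss); ns <- c(ns, j - i + 1L)
    dices <- c(dices, macro_dice(prob, ba$t, cfg$threshold))
    i <- j + 1L
  }
  c(loss = sum(losses * ns) / sum(ns), dice = sum(dices * ns) / sum(ns))
}

#' Train a segmentation model
#'
#' AdamW optimisation of the compound BCE + soft-Dice loss.  Training
#' inputs are re-augmented every epoch when `cfg$augment` is set;
#' validation is evaluated unaugmented after each epoch.  A checkpoint is
#' written whenever the validation Dice improves; the minimum validation
#' loss is tracked alongside from an initial best of `+Inf`.
#'
#' @param model a model from [build_munet()] (trained in place).
#' @param datasets list with `train` (list of [image_sample()]) and
#'   optionally `val`.
#' @param cfg a [train_config()].
#' @return list with `history` (one row per epoch), `best_epoch`,
#'   `best_val_dice`, `checkpoint` / `checkpoint_min_loss` paths (or
#'   `NULL`), and the trained `model`.
#' @export
train_munet <- function(model, datasets, cfg) {
  stopifnot(inherits(cfg, "train_config"))
  train <- datasets$train
  val <- datasets$val
  if (length(train) == 0L) stop("no training samples", call. = FALSE)
  opt <- adamw_new(model, lr = cfg$learning_rate,
                   weight_decay = cfg$weight_decay)
  hist <- list()
  best_dice <- -Inf; best_loss <- Inf; best_epoch <- NA_integer_
  ckpt <- ckpt_loss <- NULL
  if (!is.null(cfg$checkpoint_dir)) {
    dir.create(cfg$checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
    ckpt <- file.path(cfg$checkpoint_dir, "best_dice.rds")
    ckpt_loss <- file.path(cfg$checkpoint_dir, "min_loss.rds")
  }
  for (ep in seq_len(cfg$epochs)) {
    ep_samples <- with_seed(derive_seed(cfg$seed, ep), {
      ord <- sample.int(length(train))
      if (is.null(cfg$augment)) train[ord]
      else lapply(train[ord], augment_pair, cfg = cfg$augment)
    })
    tr_loss <- 0; tr_dice <- 0; nb <- 0L
    i <- 1L
    while (i <= length(ep_samples)) {
      j <- min(i + cfg$batch_size - 1L, length(ep_samples))
      ba <- batch_arrays(ep_samples[i:j])
      ctx <- make_ctx(training = TRUE, grad = TRUE)
      prob <- nn_forward(model, ba$x, ctx)
      l <- segmentation_loss(prob, ba$t, cfg$lambda, with_grad = TRUE)
      if (!is.finite(l$loss))
        stop("training diverged (non-finite loss) at epoch ", ep,
             call. = FALSE)
      nn_zero_grad(model)
      nn_backward(model, l$grad, ctx)
      adamw_step(opt)
      tr_loss <- tr_loss + l$loss
      tr_dice <- tr_dice + macro_dice(prob, ba$t, cfg$threshold)
      nb <- nb + 1L
      i <- j + 1L
    }
    row <- data.frame(epoch = ep, train_loss = tr_loss / nb,
                      train_dice = tr_dice / nb,
                      val_loss = NA_real_, val_dice = NA_real_)
    if (length(val)) {
      ev <- eval_split(model, val, cfg)
      row$val_loss <- ev[["loss"]]; row$val_dice <- ev[["dice"]]
      if (ev[["dice"]] > best_dice) {
        best_dice <- ev[["dice"]]; best_epoch <- ep
        if (!is.null(ckpt)) save_weights(model, ckpt)
      }
      if (ev[["loss"]] < best_loss) {
        best_loss <- ev[["loss"]]
        if (!is.null(ckpt_loss)) save_weights(model, ckpt_loss)
      }
    }
    hist[[ep]] <- row
    if (cfg$verbose)
      message(sprintf(
        "epoch %3d  train loss %.4f dice %.4f  val loss %s dice %s",
        ep, row$train_loss, row$train_dice,
        ifelse(is.na(row$val_loss), "-", sprintf("%.4f", row$val_loss)),
        ifelse(is.na(row$val_dice), "-", sprintf("%.4f", row$val_dice))))
  }
  history <- if (length(hist)) do.call(rbind, hist) else
    data.frame(epoch = integer(), train_loss = numeric(),
               train_dice = numeric(), val_loss = numeric(),
               val_dice = numeric())
  list(history = history, best_epoch = best_epoch,
       best_val_dice = if (is.finite(best_dice)) best_dice else NA_real_,
       checkpoint = ckpt, checkpoint_min_loss = ckpt_loss, model = model)
}

#' Hyper-parameter grid search
#'
#' Trains one model per grid point and ranks candidates by best validation
#' Dice, breaking ties by the lower validation loss.
#'
#' @param model_factory function taking no arguments and returning a fresh
#'   model.
#' @param datasets as in [train_munet()].
#' @param cfg a [train_config()]; its `grid` lists define the candidates
#'   and its remaining fields the shared settings.
#' @return list with `best` (the winning `train_config`) and `table`
#'   (one row per grid point, ranked).
#' @export
grid_search <- function(model_factory, datasets, cfg) {
  g <- cfg$grid
  if (length(g) == 0L || any(!vapply(g, length, 0L)))
    stop("empty hyper-parameter grid", call. = FALSE)
  pts <- expand.grid(learning_rate = g$learning_rate %||% cfg$learning_rate,
                     batch_size = g$batch_size %||% cfg$batch_size,
                     epochs = g$epochs %||% cfg$epochs)
  rows <- list(); cfgs <- list()
  for (i in seq_len(nrow(pts))) {
    ci <- cfg
    ci$learning_rate <- pts$learning_rate[i]
    ci$batch_size <- as.integer(pts$batch_size[i])
    ci$epochs <- as.integer(pts$epochs[i])
    ci$checkpoint_dir <- NULL
    res <- train_munet(model_factory(), datasets, ci)
    vd <- max(res$history$val_dice, na.rm = TRUE)
    vl <- min(res$history$val_loss, na.rm = TRUE)
    rows[[i]] <- data.frame(learning_rate = ci$learning_rate,
                            batch_size = ci$batch_size, epochs = ci$epochs,
                            val_dice = vd, val_loss = vl)
    cfgs[[i]] <- ci
  }
  tab <- do.call(rbind, rows)
  ord <- rank_candidates(tab$val_dice, tab$val_loss)
  list(best = cfgs[[ord[1L]]], table = tab[ord, , drop = FALSE])
}

# Ranking rule: best validation Dice first, ties broken by the lower
# validation loss.
rank_candidates <- function(dice, loss) order(-dice, loss)
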