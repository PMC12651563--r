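#' Pixel-wise confusion counts between two binary masks
#'
#' @param pred,truth binary arrays/matrices of identical shape containing
#'   only 0 and 1.
#' @return a `confusion_counts` list with fields `tp`, `fp`, `tn`, `fn`;
#'   the four counts always sum to the number of pixels.
#' @export
confusion_counts <- function(pred, truth) {
  if (!identical(dim2(pred), dim2(truth)))
    stop("pred and truth must have identical shapes", call. = FALSE)
  p <- as.vector(pred); t <- as.vector(truth)
  if (!all(p %in% c(0, 1)) || !all(t %in% c(0, 1)))
    stop("masks must be strictly binary (0/1)", call. = FALSE)
  structure(list(tp = sum(p == 1 & t == 1),
                 fp = sum(p == 1 & t == 0),
                 tn = sum(p == 0 & t == 0),
                 fn = sum(p == 0 & t == 1)),
            class = "confusion_counts")
}

dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

as_counts <- function(c) {
  if (inherits(c, "confusion_counts")) return(c)
  stopifnot(is.list(c), all(c("tp", "fp", "tn", "fn") %in% names(c)))
  c
}

#' Segmentation metrics from confusion counts
#'
#' Dice `2TP/(2TP+FP+FN)`, IoU (Jaccard) `TP/(TP+FP+FN)`, pixel accuracy
#' `(TP+TN)/total`, precision `TP/(TP+FP)` and recall `TP/(TP+FN)`.
#'
#' Empty-vs-empty convention: when both masks are empty, `dice` and `iou`
#' return 1 (perfect agreement).  Precision and recall return `NaN` on a
#' zero denominator; [aggregate_reports()] excludes such values rather than
#' imputing them.
#'
#' @param c a [confusion_counts()] result (or a list with tp/fp/tn/fn).
#' @return a numeric scalar in `[0, 1]` (possibly `NaN` for
#'   precision/recall as described).
#' @export
dice <- function(c) {
  c <- as_counts(c)
  den <- 2 * c$tp + c$fp + c$fn
  if (den == 0) 1 else 2 * c$tp / den
}

#' @rdname dice
#' @export
iou <- function(c) {
  c <- as_counts(c)
  den <- c$tp + c$fp + c$fn
  if (den == 0) 1 else c$tp / den
}

#' @rdname dice
#' @export
pixel_accuracy <- function(c) {
  c <- as_counts(c)
  (c$tp + c$tn) / (c$tp + c$tn + c$fp + c$fn)
}

#' @rdname dice
#' @export
precision <- function(c) {
  c <- as_counts(c)
  if (c$tp + c$fp == 0) NaN else c$tp / (c$tp + c$fp)
}

#' @rdname dice
#' @export
recall <- function(c) {
  c <- as_counts(c)
  if (c$tp + c$fn == 0) NaN else c$tp / (c$tp + c$fn)
}

#' Full metric report for one predicted mask
#'
#' @param pred,truth binary masks of identical shape.
#' @param id optional sample identifier.
#' @return a `metric_report` with dice, iou, pixel_accuracy, precision,
#'   recall and `n_images = 1`.
#' @export
metric_report <- function(pred, truth, id = NA_character_) {
  cc <- confusion_counts(pred, truth)
  structure(list(id = id, dice = dice(cc), iou = iou(cc),
                 pixel_accuracy = pixel_accuracy(cc),
                 precision = precision(cc), recall = recall(cc),
                 n_images = 1L, counts = cc),
            class = "metric_report")
}

#' Evaluate predictions over a dataset
#'
#' @param preds,truths lists of binary masks (or 4-D arrays whose 4th
#'   dimension indexes samples).
#' @param ids optional identifiers.
#' @param mode `"macro"` (default) averages per-image metrics; `"micro"`
#'   pools all confusion counts first.
#' @return list with `per_image` (list of `metric_report`) and `aggregate`.
#' @export
evaluate_masks <- function(preds, truths, ids = NULL,
                           mode = c("macro", "micro")) {
  mode <- match.arg(mode)
  preds <- as_mask_list(preds)
  truths <- as_mask_list(truths)
  if (length(preds) != length(truths))
    stop("preds and truths differ in length", call. = FALSE)
  if (is.null(ids)) ids <- sprintf("sample_%03d", seq_along(preds))
  per <- Map(metric_report, preds, truths, ids)
  agg <- if (mode == "macro") aggregate_reports(per) else {
    tot <- list(tp = 0, fp = 0, tn = 0, fn = 0)
    for (r in per) for (k in names(tot)) tot[[k]] <- tot[[k]] + r$counts[[k]]
    structure(list(id = "pooled", dice = dice(tot), iou = iou(tot),
                   pixel_accuracy = pixel_accuracy(tot),
                   precision = precision(tot), recall = recall(tot),
                   n_images = length(per), sd = NULL),
              class = "metric_report")
  }
  list(per_image = per, aggregate = agg)
}

as_mask_list <- function(x) {
  if (is.list(x)) return(x)
  if (is.array(x) && length(dim(x)) == 4L)
    return(lapply(seq_len(dim(x)[4L]), function(i) x[, , , i, drop = TRUE]))
  if (is.array(x) && length(dim(x)) == 3L)
    return(lapply(seq_len(dim(x)[3L]), function(i) x[, , i]))
  list(x)
}

#' Aggregate per-image metric reports
#'
#' Unweighted per-image (macro) mean and sample standard deviation for each
#' metric; `NaN` entries (undefined precision/recall on empty masks) are
#' excluded from their metric's aggregate.
#'
#' @param reports nonempty list of `metric_report` objects.
#' @return a `metric_report` carrying means, an `sd` list, and `n_images`.
#' @export
aggregate_reports <- function(reports) {
  if (length(reports) == 0) stop("empty report list", call. = FALSE)
  metrics <- c("dice", "iou", "pixel_accuracy", "precision", "recall")
  mns <- list(); sds <- list()
  for (m in metrics) {
    v <- vapply(reports, function(r) r[[m]], 0)
    v <- v[!is.nan(v)]
    mns[[m]] <- mean(v)
    sds[[m]] <- if (length(v) > 1L) sd(v) else 0
  }
  structure(c(list(id = "aggregate"), mns,
              list(n_images = length(reports), sd = sds)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  fmt <- function(m) {
    s <- sprintf("%-15s %.4f", m, x[[m]])
    if (!is.null(x$sd)) s <- paste0(s, sprintf(" ± %.4f", x$sd[[m]]))
    s
  }
  cat(sprintf("Metric report (%s, n = %d)\n", x$id, x$n_images))
  for (m in c("dice", "iou", "pixel_accuracy", "precision", "recall"))
    cat(" ", fmt(m), "\n")
  invisible(x)
}

#' Write an evaluation to CSV and JSON
#'
#' One row per image plus an aggregate row.
#'
#' @param ev result of [evaluate_masks()].
#' @param csv,json output paths (either may be `NULL`).
#' @return invisibly, the data frame written.
#' @export
write_metric_report <- function(ev, csv = NULL, json = NULL) {
  row1 <- function(r)
    data.frame(id = r$id, dice = r$dice, iou = r$iou,
               pixel_accuracy = r$pixel_accuracy, precision = r$precision,
               recall = r$recall, stringsAsFactors = FALSE)
  df <- do.call(rbind, c(lapply(ev$per_image, row1), list(row1(ev$aggregate))))
  if (!is.null(csv)) write.csv(df, csv, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(df, json, dataframe = "rows", digits = NA,
                         na = "null")
  invisible(df)
}
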