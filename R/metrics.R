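#' Dice-based training loss
#'
#' Soft Dice similarity between a binary reference mask and a probability
#' grid, \eqn{s = (2\sum M \odot \hat M + \epsilon) /
#' (\sum M + \sum \hat M + \epsilon)} with \eqn{\epsilon = 1} guarding the
#' empty-mask case; the minimized loss is \eqn{1 - s}, in \[0, 1).
#'
#' @param m binary mask matrix.
#' @param p probability grid, same shape, values in \[0, 1\].
#' @param eps stabilizer (1, following the training objective).
#' @return Scalar loss in \[0, 1).
#' @export
#' @examples
#' m <- matrix(c(1, 1, 0, 0), 2)
#' dice_loss(m, m)                       # 0: perfect overlap
#' dice_loss(m, matrix(0, 2, 2))         # 2/3 missed foreground
dice_loss <- function(m, p, eps = 1) {
  if (!identical(dim(m), dim(p))) stop("mask and prediction shapes differ", call. = FALSE)
  s <- (2 * sum(m * p) + eps) / (sum(m) + sum(p) + eps)
  1 - s
}

# Batch loss and its gradient w.r.t. the probability grid; the per-image
# losses are averaged.
dice_loss_batch <- function(y, p, eps = 1) {
  n <- dim(y)[4L]
  grad <- array(0, dim(p))
  loss <- 0
  for (i in seq_len(n)) {
    mi <- y[, , 1L, i]; pi_ <- p[, , 1L, i]
    num <- 2 * sum(mi * pi_) + eps
    den <- sum(mi) + sum(pi_) + eps
    loss <- loss + (1 - num / den)
    grad[, , 1L, i] <- -(2 * mi * den - num) / den^2 / n
  }
  list(loss = loss / n, grad = grad)
}

#' Pixel confusion counts between two binary masks
#'
#' @param m reference binary mask.
#' @param mhat predicted binary mask (threshold a probability grid first, by
#'   default at 0.5).
#' @return A list of class `"confusion_counts"` with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(m, mhat) {
  if (!identical(dim(m), dim(mhat))) stop("mask shapes differ", call. = FALSE)
  tp <- sum(m == 1 & mhat == 1)
  tn <- sum(m == 0 & mhat == 0)
  fp <- sum(m == 0 & mhat == 1)
  fn <- sum(m == 1 & mhat == 0)
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn), class = "confusion_counts")
}

#' Segmentation metrics from confusion counts
#'
#' Sensitivity, specificity, Dice, intersection-over-union and geometric
#' mean, all as percentages:
#' \deqn{Sen = 100\,TP/(TP+FN),\quad Spe = 100\,TN/(TN+FP),}
#' \deqn{Dice = 100\,2TP/(2TP+FN+FP),\quad IOU = 100\,TP/(TP+FN+FP),}
#' \deqn{GM = \sqrt{Sen \cdot Spe}.}
#' A metric whose denominator is zero is reported as `NA` (undefined) and is
#' excluded from downstream averages.
#'
#' @param counts a [confusion_counts()] object.
#' @return Named numeric vector `sen`, `spe`, `dice`, `iou`, `gm`.
#' @export
metrics_from_counts <- function(counts) {
  tp <- counts$TP; tn <- counts$TN; fp <- counts$FP; fn <- counts$FN
  sen <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  spe <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  dice <- if (2 * tp + fn + fp > 0) 100 * 2 * tp / (2 * tp + fn + fp) else NA_real_
  iou <- if (tp + fn + fp > 0) 100 * tp / (tp + fn + fp) else NA_real_
  gm <- if (!is.na(sen) && !is.na(spe)) sqrt(sen * spe) else NA_real_
  c(sen = sen, spe = spe, dice = dice, iou = iou, gm = gm)
}

#' Pixel-wise area under the ROC curve
#'
#' Ranks every pixel's predicted probability against the binary reference;
#' equals the trapezoidal area under the ROC curve traced by sweeping the
#' decision threshold over the unique probabilities (ties contribute half),
#' reported as a percentage.
#'
#' @param m binary reference mask.
#' @param prob probability grid, same shape.
#' @return AUC in \[0, 100\], or `NA` when the mask holds a single class.
#' @export
pixel_auc <- function(m, prob) {
  if (!identical(dim(m), dim(prob))) stop("shapes differ", call. = FALSE)
  pos <- prob[m == 1]; neg <- prob[m == 0]
  n1 <- length(pos); n0 <- length(neg)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(c(pos, neg))
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  100 * auc
}

#' Evaluate a fitted network on a test set
#'
#' Applies the model to every test image, computes the per-image confusion
#' metrics and AUC, and aggregates mean and standard deviation per metric.
#' Undefined (NA) per-image metrics are excluded from the aggregation; their
#' count is reported.
#'
#' @param object a fitted `"kernseg_fit"`.
#' @param testset list of `image_pair`s, or a `"seg_dataset"` (its `"test"`
#'   split is used).
#' @param threshold binarization threshold for the overlap metrics.
#' @return A list of class `"seg_evaluation"` with `per_image` (data frame)
#'   and `summary` (mean/sd/n per metric).
#' @export
seg_evaluate <- function(object, testset, threshold = 0.5) {
  if (inherits(testset, "seg_dataset"))
    testset <- testset$pairs[testset$split == "test"]
  if (length(testset) == 0L) stop("test set is empty", call. = FALSE)
  probs <- predict(object, testset, type = "prob")
  rows <- lapply(seq_along(testset), function(i) {
    m <- testset[[i]]$mask
    p <- probs[[i]]
    rec <- metrics_from_counts(confusion_counts(m, (p >= threshold) * 1))
    data.frame(id = i, t(rec), auc = pixel_auc(m, p))
  })
  per_image <- do.call(rbind, rows)
  metric_cols <- c("sen", "spe", "dice", "iou", "gm", "auc")
  summary <- do.call(rbind, lapply(metric_cols, function(cl) {
    v <- per_image[[cl]]
    data.frame(metric = cl, mean = mean(v, na.rm = TRUE),
               sd = if (sum(!is.na(v)) > 1L) sd(v, na.rm = TRUE) else 0,
               n = sum(!is.na(v)), n_undefined = sum(is.na(v)))
  }))
  structure(list(per_image = per_image, summary = summary), class = "seg_evaluation")
}

#' @export
print.seg_evaluation <- function(x, ...) {
  cat(sprintf("Segmentation evaluation over %d test images\n", nrow(x$per_image)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write evaluation results as CSV and a JSON summary
#'
#' @param evaluation a `"seg_evaluation"`.
#' @param dir output directory; writes `metrics.csv` and `summary.json`.
#' @return Invisibly, the directory.
#' @export
write_metrics <- function(evaluation, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(evaluation$per_image, file.path(dir, "metrics.csv"), row.names = FALSE)
  s <- split(evaluation$summary[, c("mean", "sd", "n", "n_undefined")],
             evaluation$summary$metric)
  jsonlite::write_json(lapply(s, as.list), file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
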