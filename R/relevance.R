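#' Explanation map: image modulated by its normalized saliency
#'
#' Elementwise product \eqn{\tilde I(\lambda) = \tilde S(\lambda) \odot I};
#' since \eqn{\tilde S \le 1}, no pixel intensity ever increases.
#'
#' @param image grayscale image matrix.
#' @param s_norm normalized saliency map in \[0, 1\], same shape.
#' @return Matrix of the same shape.
#' @export
explanation_map <- function(image, s_norm) {
  if (!identical(dim(image), dim(s_norm))) stop("shapes differ", call. = FALSE)
  image * s_norm
}

#' Class-conditional score of an explanation map
#'
#' Forwards the explanation map through the network up to the pre-activation
#' logits (the penultimate, linear-activation stage) and evaluates the
#' class-conditional score over the mask's `lambda` pixels.
#'
#' @param object a fitted `"kernseg_fit"`.
#' @param i_tilde explanation-map image.
#' @param mask binary mask conditioning the score.
#' @param lambda class label, 0 or 1.
#' @return Scalar score \eqn{\tilde y(\lambda)}.
#' @export
explained_score <- function(object, i_tilde, mask, lambda = 1) {
  g <- predict(object, i_tilde, type = "logits")
  class_conditional_score(g, mask, lambda)
}

#' Original and explanation-map scores for a set of images
#'
#' For each image: computes the saliency map at the explained layer,
#' normalizes it, forms the explanation map, and records the original score
#' \eqn{y(\lambda)} next to the explanation-map score \eqn{\tilde y(\lambda)}.
#'
#' @param object a fitted `"kernseg_fit"`.
#' @param pairs list of `image_pair`s (or a `"seg_dataset"`, whose test
#'   split is used).
#' @param lambda class label (default 1, the nerve).
#' @param layer explained layer passed to [cam_for_image()].
#' @return Data frame with columns `id`, `y`, `y_tilde`.
#' @export
explanation_records <- function(object, pairs, lambda = 1, layer = NULL) {
  if (inherits(pairs, "seg_dataset"))
    pairs <- pairs$pairs[pairs$split == "test"]
  if (length(pairs) == 0L) stop("'pairs' must be nonempty", call. = FALSE)
  rows <- lapply(seq_along(pairs), function(i) {
    img <- pairs[[i]]$image; msk <- pairs[[i]]$mask
    g <- predict(object, img, type = "logits")
    y <- class_conditional_score(g, msk, lambda)
    s_norm <- cam_for_image(object, img, msk, lambda, layer, normalized = TRUE)
    it <- explanation_map(img, s_norm)
    yt <- explained_score(object, it, msk, lambda)
    data.frame(id = i, y = y, y_tilde = yt)
  })
  do.call(rbind, rows)
}

#' Increase Confidence: share of images whose explanation map raises the score
#'
#' Percentage of records with \eqn{\tilde y(\lambda) > y(\lambda)} (strict);
#' the ideal value is 100.
#'
#' @param records data frame with columns `y` and `y_tilde`
#'   (see [explanation_records()]).
#' @return Percentage in \[0, 100\].
#' @export
increase_confidence <- function(records) {
  if (NROW(records) == 0L) stop("'records' must be nonempty", call. = FALSE)
  100 * mean(records$y_tilde > records$y)
}

#' Win: pairwise comparison of explanation-map confidences
#'
#' Percentage of images (paired by position) on which model r's
#' explanation-map score strictly exceeds model r''s. Ties count for neither
#' side, so `win(a, b) + win(b, a) = 100` holds exactly only when no scores
#' tie.
#'
#' @param scores_r,scores_rp numeric vectors of \eqn{\tilde y} scores, same
#'   length and image order.
#' @return Percentage in \[0, 100\].
#' @export
win_rate <- function(scores_r, scores_rp) {
  if (length(scores_r) != length(scores_rp))
    stop("score vectors must have equal length", call. = FALSE)
  if (length(scores_r) == 0L) stop("score vectors must be nonempty", call. = FALSE)
  100 * mean(scores_r > scores_rp)
}

#' Median region-averaged heatmap across a test set
#'
#' Crops each normalized saliency map (and its mask) to the mask's bounding
#' box, rescales the crop to a common canvas, and takes the pixel-wise
#' median across samples — a robust picture of where, within the target
#' region, the model concentrates its evidence. Samples with an empty mask
#' are skipped with a warning.
#'
#' @param maps list of saliency matrices.
#' @param masks list of binary masks paired with `maps`.
#' @param canvas common canvas size (rows, cols), default 64 x 64.
#' @param normalize max-normalize each map before cropping (default); set
#'   `FALSE` when the maps are already on a common scale.
#' @return List with `heatmap` (median canvas), `mask` (median rescaled
#'   mask, in \[0, 1\]) and `n_used`.
#' @export
region_average_heatmap <- function(maps, masks, canvas = c(64L, 64L),
                                   normalize = TRUE) {
  if (length(maps) == 0L || length(maps) != length(masks))
    stop("'maps' and 'masks' must be nonempty paired lists", call. = FALSE)
  crops <- list(); mcrops <- list()
  for (i in seq_along(maps)) {
    msk <- masks[[i]]
    if (sum(msk) == 0) {
      warning(sprintf("sample %d has an empty mask; skipped", i))
      next
    }
    rs <- range(which(rowSums(msk) > 0))
    cs <- range(which(colSums(msk) > 0))
    s <- pmax(maps[[i]], 0)
    if (normalize) s <- normalize_saliency(s)
    crops[[length(crops) + 1L]] <-
      resize_bilinear(s[rs[1L]:rs[2L], cs[1L]:cs[2L], drop = FALSE],
                      canvas[1L], canvas[2L])
    mcrops[[length(mcrops) + 1L]] <-
      resize_bilinear(msk[rs[1L]:rs[2L], cs[1L]:cs[2L], drop = FALSE],
                      canvas[1L], canvas[2L])
  }
  if (length(crops) == 0L) stop("all masks were empty", call. = FALSE)
  st <- array(unlist(crops), c(canvas[1L], canvas[2L], length(crops)))
  sm <- array(unlist(mcrops), c(canvas[1L], canvas[2L], length(mcrops)))
  list(heatmap = apply(st, c(1L, 2L), median),
       mask = apply(sm, c(1L, 2L), median),
       n_used = length(crops))
}
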