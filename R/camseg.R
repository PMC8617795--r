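#' Class-conditional score from a logit grid
#'
#' The scalar from which the class-activation gradients are taken: the mean
#' pre-activation logit over the pixels belonging to class `lambda`,
#' \eqn{y(\lambda) = E\{G_{ij} : M_{ij} = \lambda\}}.
#'
#' @param g logit grid (matrix), the pre-sigmoid network output.
#' @param m binary mask, same shape.
#' @param lambda class label, 0 (background) or 1 (nerve).
#' @return Scalar score.
#' @export
class_conditional_score <- function(g, m, lambda) {
  if (!identical(dim(g), dim(m))) stop("shapes differ", call. = FALSE)
  if (!lambda %in% c(0, 1)) stop("'lambda' must be 0 or 1", call. = FALSE)
  sel <- m == lambda
  if (!any(sel))
    stop(sprintf("no pixel belongs to class %d; score undefined", lambda),
         call. = FALSE)
  mean(g[sel])
}

#' Grad-CAM++ channel weights from features and gradients
#'
#' Computes the per-pixel weighting
#' \eqn{\alpha_{ij} = g_{ij}^2 / (2 g_{ij}^2 + (\sum_{ab} F_{ab})\, g_{ij}^3)}
#' (the closed form obtained by expressing the second and third derivatives
#' of an exponential score through powers of the first-order gradient
#' \eqn{g = \partial y / \partial F}), and the channel weights
#' \eqn{\gamma_d = \sum_{ij} \alpha_{ij} \,\mathrm{ReLU}(g_{ij})}. Cells with
#' a zero denominator get \eqn{\alpha = 0} (no feature, no credit).
#'
#' With `exact = TRUE` the second and third derivatives of the exponential
#' score \eqn{Y = e^y} are evaluated explicitly
#' (\eqn{\partial^k Y = g^k e^y}) and plugged into the derivative form of
#' \eqn{\alpha} — the route used to validate the closed form.
#'
#' @param f feature grid at the explained layer, `Rl x Cl x D` array.
#' @param grad gradient of the class-conditional score w.r.t. `f`, same shape.
#' @param exact use the explicit exponential-score derivatives.
#' @param score scalar score value \eqn{y}; required when `exact = TRUE`.
#' @return List with `alpha` (`Rl x Cl x D`) and `gamma` (length-D weights).
#' @export
gradcampp_weights <- function(f, grad, exact = FALSE, score = NULL) {
  if (!identical(dim(f), dim(grad))) stop("shapes differ", call. = FALSE)
  d <- dim(f)[3L]
  alpha <- array(0, dim(f))
  gamma <- numeric(d)
  for (ch in seq_len(d)) {
    g <- grad[, , ch]
    fsum <- sum(f[, , ch])
    if (exact) {
      if (is.null(score)) stop("'score' is required when exact = TRUE", call. = FALSE)
      d2 <- g^2 * exp(score)
      d3 <- g^3 * exp(score)
      den <- 2 * d2 + fsum * d3
      a <- ifelse(den != 0, d2 / den, 0)
    } else {
      den <- 2 * g^2 + fsum * g^3
      a <- ifelse(den != 0, g^2 / den, 0)
    }
    alpha[, , ch] <- a
    gamma[ch] <- sum(a * pmax(g, 0))
  }
  list(alpha = alpha, gamma = gamma)
}

#' Saliency map from weighted feature maps
#'
#' Channel-weighted sum of the feature maps, ReLU-thresholded so only
#' positively contributing evidence survives, bilinearly upsampled to the
#' output shape: \eqn{S = (\mu \circ \mathrm{ReLU}) \sum_d \gamma_d F_d}.
#'
#' @param f feature grid `Rl x Cl x D`.
#' @param gamma length-D channel weights.
#' @param out_shape target (rows, cols).
#' @return Non-negative matrix of dimension `out_shape`.
#' @export
saliency_map <- function(f, gamma, out_shape) {
  d <- dim(f)
  if (length(gamma) != d[3L]) stop("gamma length must equal channel count", call. = FALSE)
  s <- matrix(0, d[1L], d[2L])
  for (ch in seq_len(d[3L])) s <- s + gamma[ch] * f[, , ch]
  s <- pmax(s, 0)
  resize_bilinear(s, out_shape[1L], out_shape[2L])
}

#' Normalize a saliency map to \[0, 1\]
#'
#' Divides by the maximum entry; an all-zero map is returned unchanged (the
#' degenerate-map convention).
#'
#' @param s non-negative saliency matrix.
#' @return Matrix in \[0, 1\] with maximum exactly 1 unless `s` is all zero.
#' @export
normalize_saliency <- function(s) {
  mx <- max(s)
  if (mx <= 0) return(s * 0)
  s / mx
}

#' Class-activation saliency map for one image
#'
#' End-to-end Grad-CAM++ for segmentation: forwards the image, takes the
#' class-conditional score over the mask's `lambda` pixels, backpropagates
#' to the explained layer (by default the convolutional block just before
#' the RFF insertion, or the bottleneck end when the model has no RFF
#' layer), forms the channel weights and returns the upsampled non-negative
#' saliency map.
#'
#' @param object a fitted `"kernseg_fit"`.
#' @param image grayscale image matrix.
#' @param mask binary mask conditioning the score; `NULL` uses the binarized
#'   prediction.
#' @param lambda class label, 0 or 1.
#' @param layer node id of the explained layer; `NULL` for the default.
#' @param normalized return the max-normalized map?
#' @return Saliency matrix with the image's shape, entries >= 0.
#' @export
cam_for_image <- function(object, image, mask = NULL, lambda = 1, layer = NULL,
                          normalized = FALSE) {
  net <- object$network
  layer <- if (is.null(layer)) net$cam_node else layer
  if (layer < 1L || layer > length(net$nodes)) stop("no such layer", call. = FALSE)
  x <- as_batch(image)
  fw <- forward_net(net, x)
  g_logits <- fw$outs[[net$logits_node]][, , 1L, 1L]
  if (is.null(mask)) mask <- (fw$outs[[net$output_node]][, , 1L, 1L] >= 0.5) * 1
  sel <- mask == lambda
  if (!any(sel))
    stop(sprintf("no pixel belongs to class %d; score undefined", lambda),
         call. = FALSE)
  seed <- array(0, dim(fw$outs[[net$logits_node]]))
  seed[, , 1L, 1L][sel] <- 1 / sum(sel)      # d y(lambda) / d G
  seeds <- list(); seeds[[as.character(net$logits_node)]] <- seed
  bw <- backward_net(net, fw, seeds, param_grads = FALSE)
  gf <- bw$node_grads[[layer]]
  if (is.null(gf))
    stop("explained layer is not upstream of the logits", call. = FALSE)
  f3 <- array(fw$outs[[layer]][, , , 1L], dim(fw$outs[[layer]])[1:3])
  g3 <- array(gf[, , , 1L], dim(gf)[1:3])
  w <- gradcampp_weights(f3, g3)
  s <- saliency_map(f3, w$gamma, dim(image))
  if (normalized) normalize_saliency(s) else s
}
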