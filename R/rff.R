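#' Sample random Fourier feature parameters for the Gaussian kernel
#'
#' Draws the spectral frequencies and phases of the random Fourier features
#' (RFF) map approximating the Gaussian kernel
#' \eqn{\kappa(x, x') = \exp(-\|x - x'\|^2 / 2\sigma^2)}. By Bochner's
#' theorem the frequencies follow the kernel's spectral density, the
#' zero-mean isotropic normal with per-coordinate standard deviation
#' \eqn{1/\sigma}; phases are uniform on \eqn{[0, 2\pi)}.
#'
#' @param P input dimensionality.
#' @param Q number of random features.
#' @param sigma kernel bandwidth (> 0).
#' @param seed integer seed; the draw is deterministic given it.
#' @param trainable logical; if `TRUE` the frequencies and phases receive
#'   gradient updates during training (deep-kernel variant). Default `FALSE`,
#'   the classical fixed-at-initialization RFF.
#' @return An object of class `"rff_params"` with fields `omega` (Q x P),
#'   `b` (length Q), `sigma`, `Q`, `P`, `trainable`.
#' @export
#' @examples
#' p <- sample_rff_params(P = 2, Q = 1000, sigma = 1, seed = 1)
#' z1 <- rff_map(c(0, 0), p); z2 <- rff_map(c(1, 0), p)
#' sum(z1 * z2)          # close to exp(-0.5)
sample_rff_params <- function(P, Q, sigma, seed = 1L, trainable = FALSE) {
  stopifnot_scalar(P, "P", positive = TRUE, integerish = TRUE)
  stopifnot_scalar(Q, "Q", positive = TRUE, integerish = TRUE)
  stopifnot_scalar(sigma, "sigma", positive = TRUE)
  with_seed(seed, {
    omega <- matrix(rnorm(Q * P, mean = 0, sd = 1 / sigma), nrow = Q, ncol = P)
    b <- runif(Q, 0, 2 * pi)
    structure(list(omega = omega, b = b, sigma = sigma,
                   Q = as.integer(Q), P = as.integer(P),
                   trainable = isTRUE(trainable), seed = as.integer(seed)),
              class = "rff_params")
  })
}

#' @export
print.rff_params <- function(x, ...) {
  cat(sprintf("RFF parameters: Q = %d features, P = %d input dims, sigma = %g%s\n",
              x$Q, x$P, x$sigma, if (x$trainable) " (trainable)" else ""))
  invisible(x)
}

#' Apply the random Fourier feature map to a single vector
#'
#' Computes \eqn{\hat\varphi(x) = \sqrt{2/Q}\, \cos(\omega_q^\top x + b_q)}
#' for \eqn{q = 1, \dots, Q}, so that
#' \eqn{\hat\varphi(x)^\top \hat\varphi(x')} approximates the Gaussian
#' kernel value \eqn{\kappa(x - x')}.
#'
#' @param x numeric vector of length `params$P`.
#' @param params an [sample_rff_params()] object.
#' @return Numeric vector of length `params$Q`, entries bounded by
#'   \eqn{\sqrt{2/Q}} in absolute value.
#' @export
rff_map <- function(x, params) {
  if (!inherits(params, "rff_params")) stop("'params' must be rff_params")
  if (length(x) != params$P)
    stop(sprintf("input length %d does not match P = %d", length(x), params$P),
         call. = FALSE)
  sqrt(2 / params$Q) * cos(drop(params$omega %*% x) + params$b)
}

#' Apply the RFF map at every spatial position of a feature grid
#'
#' Treats each spatial position of an `R x C x D` feature grid as a
#' D-dimensional vector and maps it to Q random Fourier features, preserving
#' the spatial (image-shaped) layout; with an 8 x 8 bottleneck and Q set to
#' the channel factor this yields the `8 x 8 x Q` grid entering the decoder.
#'
#' @param f feature grid, `R x C x D` array (or `R x C x D x N` batch).
#' @param params [sample_rff_params()] with `P == D`.
#' @return Array with the same spatial dimensions and `Q` channels.
#' @export
rff_layer_apply <- function(f, params) {
  d <- dim(f)
  squeeze <- length(d) == 3L
  if (squeeze) { f <- array(f, c(d, 1L)); d <- dim(f) }
  if (d[3L] != params$P)
    stop(sprintf("channel count %d does not match P = %d", d[3L], params$P),
         call. = FALSE)
  out <- rff_fw(f, params)$y
  if (squeeze) array(out, dim(out)[1:3]) else out
}

# Internal forward: returns output and the cache needed for backprop.
rff_fw <- function(x, params) {
  d <- dim(x)                               # H W D N
  X <- matrix(aperm(x, c(3L, 1L, 2L, 4L)), nrow = d[3L])   # D x (H*W*N)
  A <- params$omega %*% X + params$b                        # Q x (H*W*N)
  scale <- sqrt(2 / params$Q)
  Z <- scale * cos(A)
  y <- aperm(array(Z, c(params$Q, d[1L], d[2L], d[4L])), c(2L, 3L, 1L, 4L))
  list(y = y, A = A, X = X, scale = scale)
}

rff_bw <- function(gy, cache, params) {
  d <- dim(gy)                              # H W Q N
  G <- matrix(aperm(gy, c(3L, 1L, 2L, 4L)), nrow = params$Q)
  S <- -cache$scale * sin(cache$A) * G      # Q x (H*W*N)
  gX <- crossprod(params$omega, S)          # D x (H*W*N)
  gx <- aperm(array(gX, c(params$P, d[1L], d[2L], d[4L])), c(2L, 3L, 1L, 4L))
  out <- list(gx = gx)
  if (params$trainable) {
    out$gomega <- S %*% t(cache$X)
    out$gb <- rowSums(S)
  }
  out
}

#' Worst-case kernel approximation error over sample pairs
#'
#' For each pair \eqn{(x, x')} compares the RFF inner product with the exact
#' Gaussian kernel \eqn{\exp(-\|x - x'\|^2 / 2\sigma^2)} and returns the
#' maximum absolute deviation — a direct check of the Monte-Carlo estimator
#' whose variance shrinks as \eqn{1/Q}.
#'
#' @param params an [sample_rff_params()] object.
#' @param pairs list of length-2 lists (or a 2-column list) of P-vectors.
#' @return Largest absolute error across pairs.
#' @export
kernel_approx_error <- function(params, pairs) {
  if (length(pairs) == 0L) stop("'pairs' must be nonempty", call. = FALSE)
  errs <- vapply(pairs, function(pr) {
    x <- pr[[1L]]; xp <- pr[[2L]]
    approx <- sum(rff_map(x, params) * rff_map(xp, params))
    exact <- exp(-sum((x - xp)^2) / (2 * params$sigma^2))
    abs(approx - exact)
  }, numeric(1))
  max(errs)
}

#' Median-heuristic bandwidth from feature vectors
#'
#' The default bandwidth when none is configured: the median pairwise
#' Euclidean distance between (a subsample of) bottleneck feature vectors.
#'
#' @param X numeric matrix, rows are feature vectors.
#' @param max_rows subsample cap for the pairwise computation.
#' @param seed seed for the subsample.
#' @return Positive bandwidth estimate.
#' @export
rff_median_sigma <- function(X, max_rows = 500L, seed = 1L) {
  if (nrow(X) > max_rows)
    X <- X[with_seed(seed, sample.int(nrow(X), max_rows)), , drop = FALSE]
  d <- stats::dist(X)
  s <- stats::median(d)
  if (!is.finite(s) || s <= 0) 1 else s
}
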