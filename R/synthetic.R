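#' Configuration for the synthetic ultrasound generator
#'
#' Describes the study conditions emulated by the generator: a single
#' hyperechoic (bright-rimmed) nerve of irregular elliptical cross-section on
#' a darker background, with linear depth attenuation and multiplicative
#' speckle noise. Brightness values are intensities in \[0, 1\]; radii are in
#' pixels.
#'
#' Speckle is modelled as unit-mean gamma multiplicative noise; the default
#' shape 4 gives a point signal-to-noise ratio of 2, close to the
#' Rayleigh statistics of fully developed ultrasound speckle. The default
#' canvas is 128x128 so that four 2x poolings reach an 8x8 bottleneck.
#'
#' @param height,width image size in pixels.
#' @param nerve_radius_range length-2 vector, min/max semi-major axis (px).
#' @param nerve_eccentricity_range length-2 vector in \[0, 1).
#' @param rim_brightness,interior_brightness,background_brightness
#'   intensities in \[0, 1\] for the nerve rim (1--2 px), nerve core and
#'   background tissue.
#' @param speckle_shape positive gamma shape of the unit-mean speckle;
#'   `Inf` disables the noise.
#' @param attenuation_strength top-to-bottom linear intensity loss in \[0, 1\].
#' @param seed base integer seed from which all per-image seeds derive.
#' @return An object of class `"synthetic_config"`.
#' @export
#' @examples
#' cfg <- synthetic_config(height = 64, width = 64, nerve_radius_range = c(6, 12))
#' pair <- generate_image(cfg, seed = 1)
#' range(pair$image); mean(pair$mask)
synthetic_config <- function(height = 128L, width = 128L,
                             nerve_radius_range = c(12, 24),
                             nerve_eccentricity_range = c(0.3, 0.8),
                             rim_brightness = 0.85,
                             interior_brightness = 0.55,
                             background_brightness = 0.25,
                             speckle_shape = 4,
                             attenuation_strength = 0.3,
                             seed = 1L) {
  stopifnot_scalar(height, "height", positive = TRUE, integerish = TRUE)
  stopifnot_scalar(width, "width", positive = TRUE, integerish = TRUE)
  if (length(nerve_radius_range) != 2L || any(nerve_radius_range <= 0) ||
      diff(nerve_radius_range) < 0)
    stop("'nerve_radius_range' must be an increasing positive pair", call. = FALSE)
  if (nerve_radius_range[2L] >= min(height, width) / 2)
    stop("maximum nerve radius must be below min(height, width)/2", call. = FALSE)
  if (length(nerve_eccentricity_range) != 2L ||
      any(nerve_eccentricity_range < 0) || any(nerve_eccentricity_range >= 1))
    stop("'nerve_eccentricity_range' must lie in [0, 1)", call. = FALSE)
  for (nm in c("rim_brightness", "interior_brightness", "background_brightness")) {
    v <- get(nm)
    stopifnot_scalar(v, nm)
    if (v < 0 || v > 1) stop(sprintf("'%s' must be in [0, 1]", nm), call. = FALSE)
  }
  if (!(is.numeric(speckle_shape) && length(speckle_shape) == 1L && speckle_shape > 0))
    stop("'speckle_shape' must be a positive scalar (possibly Inf)", call. = FALSE)
  stopifnot_scalar(attenuation_strength, "attenuation_strength")
  if (attenuation_strength < 0 || attenuation_strength > 1)
    stop("'attenuation_strength' must be in [0, 1]", call. = FALSE)
  structure(list(
    height = as.integer(height), width = as.integer(width),
    nerve_radius_range = as.numeric(nerve_radius_range),
    nerve_eccentricity_range = as.numeric(nerve_eccentricity_range),
    rim_brightness = rim_brightness,
    interior_brightness = interior_brightness,
    background_brightness = background_brightness,
    speckle_shape = speckle_shape,
    attenuation_strength = attenuation_strength,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Generate one synthetic ultrasound image with its nerve mask
#'
#' Renders a filled rotated ellipse (the nerve) with a bright 1--2 px rim and
#' a darker interior on a uniform background, applies a linear top-to-bottom
#' attenuation ramp, multiplies by unit-mean gamma speckle and clips to
#' \[0, 1\]. Deterministic given `(config, seed)`.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed for this image.
#' @return A list of class `"image_pair"` with elements `image` (H x W matrix
#'   in \[0, 1\]) and `mask` (H x W matrix in \{0, 1\}).
#' @export
generate_image <- function(config, seed) {
  if (!inherits(config, "synthetic_config")) stop("'config' must be a synthetic_config")
  H <- config$height; W <- config$width
  with_seed(seed, {
    a <- runif(1, config$nerve_radius_range[1L], config$nerve_radius_range[2L])
    if (a <= 0) stop("degenerate ellipse: radius must be positive", call. = FALSE)
    ecc <- runif(1, config$nerve_eccentricity_range[1L], config$nerve_eccentricity_range[2L])
    b_ax <- a * sqrt(1 - ecc^2)
    theta <- runif(1, 0, pi)
    margin <- a + 2
    cy <- runif(1, margin + 1, H - margin)
    cx <- runif(1, margin + 1, W - margin)
    row <- matrix(seq_len(H), H, W)
    col <- matrix(seq_len(W), H, W, byrow = TRUE)
    u <- cos(theta) * (col - cx) + sin(theta) * (row - cy)
    v <- -sin(theta) * (col - cx) + cos(theta) * (row - cy)
    rho <- sqrt((u / a)^2 + (v / b_ax)^2)
    mask <- (rho <= 1) * 1
    rim_w <- 1.5
    rho_in <- max(1 - rim_w / min(a, b_ax), 0)
    base <- matrix(config$background_brightness, H, W)
    base[rho <= 1] <- config$rim_brightness
    base[rho <= rho_in] <- config$interior_brightness
    att <- 1 - config$attenuation_strength * (seq_len(H) - 1) / (H - 1)
    base <- base * att
    speckle <- if (is.infinite(config$speckle_shape)) 1 else
      matrix(rgamma(H * W, shape = config$speckle_shape, rate = config$speckle_shape), H, W)
    img <- pmin(pmax(base * speckle, 0), 1)
    structure(list(image = img, mask = mask), class = "image_pair")
  })
}

#' Generate a seeded dataset of image/mask pairs with hold-out splits
#'
#' Per-pair seeds are derived from `config$seed`, and samples are assigned to
#' training/validation/testing splits of sizes `floor(0.7 n)`, `floor(0.1 n)`
#' and the remainder by a seeded permutation, so two calls with the same
#' configuration produce identical datasets and splits.
#'
#' @param n number of pairs (at least 10, so no split is empty).
#' @param config a [synthetic_config()].
#' @return A list of class `"seg_dataset"` with `pairs` (list of
#'   `image_pair`), `split` (character vector `"train"/"val"/"test"`) and
#'   `seeds` (per-pair seeds).
#' @export
generate_dataset <- function(n, config) {
  stopifnot_scalar(n, "n", positive = TRUE, integerish = TRUE)
  if (n < 10) stop("'n' must be at least 10 so that no split is empty", call. = FALSE)
  if (!inherits(config, "synthetic_config")) stop("'config' must be a synthetic_config")
  seeds <- vapply(seq_len(n), function(i) child_seed(config$seed, i), integer(1))
  pairs <- lapply(seeds, function(s) generate_image(config, s))
  n_tr <- floor(0.7 * n); n_va <- floor(0.1 * n)
  perm <- with_seed(config$seed, sample.int(n))
  split <- character(n)
  split[perm[seq_len(n_tr)]] <- "train"
  split[perm[n_tr + seq_len(n_va)]] <- "val"
  split[perm[(n_tr + n_va + 1):n]] <- "test"
  structure(list(pairs = pairs, split = split, seeds = seeds, config = config),
            class = "seg_dataset")
}

#' @export
print.seg_dataset <- function(x, ...) {
  d <- dim(x$pairs[[1L]]$image)
  cat(sprintf("Synthetic segmentation dataset: %d pairs of %dx%d images\n",
              length(x$pairs), d[1L], d[2L]))
  print(table(x$split))
  invisible(x)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf("Synthetic ultrasound config: %dx%d px, nerve radius [%g, %g] px,\n",
              x$height, x$width, x$nerve_radius_range[1L], x$nerve_radius_range[2L]))
  cat(sprintf("  speckle shape %g, attenuation %g, seed %d\n",
              x$speckle_shape, x$attenuation_strength, x$seed))
  invisible(x)
}
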