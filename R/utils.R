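# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so generation never perturbs user code.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647L))
  expr
}

# Derive a per-item child seed from a base seed; kept below 2^31.
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(i)) %% 2147483647)
}

stopifnot_scalar <- function(x, name, positive = FALSE, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0) stop(sprintf("'%s' must be positive", name), call. = FALSE)
  if (integerish && x != round(x)) stop(sprintf("'%s' must be an integer", name), call. = FALSE)
  invisible(x)
}

# Bilinear resize of a numeric matrix (rows = image rows).
resize_bilinear <- function(m, out_h, out_w) {
  if (nrow(m) == out_h && ncol(m) == out_w) return(m)
  im <- EBImage::Image(t(m))
  r <- EBImage::resize(im, w = out_w, h = out_h, filter = "bilinear")
  t(EBImage::imageData(r))
}

# Stack a list of H x W x C x 1 arrays (or H x W matrices) into H x W x C x N.
as_batch <- function(x) {
  if (is.list(x)) {
    arrs <- lapply(x, function(e) {
      if (is.matrix(e)) array(e, c(dim(e), 1L, 1L)) else e
    })
    d <- dim(arrs[[1L]])
    out <- array(0, c(d[1L], d[2L], d[3L], length(arrs)))
    for (i in seq_along(arrs)) out[, , , i] <- arrs[[i]]
    return(out)
  }
  if (is.matrix(x)) return(array(x, c(dim(x), 1L, 1L)))
  if (length(dim(x)) == 3L) return(array(x, c(dim(x), 1L)))
  x
}
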