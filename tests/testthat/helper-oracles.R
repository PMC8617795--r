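# Independent oracles used to validate the package's implementations.

# Plain pixel-loop confusion metrics: deliberately naive, no vectorization.
brute_force_metrics <- function(m, mhat) {
  tp <- 0; tn <- 0; fp <- 0; fn <- 0
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      if (m[i, j] == 1) {
        if (mhat[i, j] == 1) tp <- tp + 1 else fn <- fn + 1
      } else {
        if (mhat[i, j] == 1) fp <- fp + 1 else tn <- tn + 1
      }
    }
  }
  sen <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  spe <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  dice <- if (2 * tp + fn + fp > 0) 100 * 2 * tp / (2 * tp + fn + fp) else NA_real_
  iou <- if (tp + fn + fp > 0) 100 * tp / (tp + fn + fp) else NA_real_
  gm <- if (!is.na(sen) && !is.na(spe)) sqrt(sen * spe) else NA_real_
  list(counts = c(TP = tp, TN = tn, FP = fp, FN = fn),
       metrics = c(sen = sen, spe = spe, dice = dice, iou = iou, gm = gm))
}

# Finite-difference Grad-CAM++ oracle on an exponential score head.
# `score_fn(A)` returns the scalar score S for a feature grid A; the exact
# per-pixel weighting is computed from actual 2nd/3rd derivatives of
# Y = exp(S) by central differences, never from the closed form.
fd_gradcampp <- function(f, score_fn, h = 0.05) {
  # The toy score heads used with this oracle are linear in the features, so
  # the only truncation error comes from the exponential; a moderately large
  # step keeps the third-derivative roundoff far below the comparison
  # tolerance, and Richardson extrapolation removes the O(h^2) term.
  d <- dim(f)
  alpha <- array(0, d)
  g1 <- array(0, d)
  for (ci in seq_len(d[3L])) {
    fsum <- sum(f[, , ci])
    for (i in seq_len(d[1L])) for (j in seq_len(d[2L])) {
      Yt <- function(t) {
        ft <- f; ft[i, j, ci] <- ft[i, j, ci] + t
        exp(score_fn(ft))
      }
      y0 <- Yt(0); yh <- Yt(h); ymh <- Yt(-h); y2h <- Yt(2 * h); ym2h <- Yt(-2 * h)
      y4h <- Yt(4 * h); ym4h <- Yt(-4 * h)
      # central differences at h and 2h, Richardson-extrapolated to O(h^4)
      d2_h <- (yh - 2 * y0 + ymh) / h^2
      d2_2h <- (y2h - 2 * y0 + ym2h) / (2 * h)^2
      d2 <- (4 * d2_h - d2_2h) / 3
      d3_h <- (y2h - 2 * yh + 2 * ymh - ym2h) / (2 * h^3)
      d3_2h <- (y4h - 2 * y2h + 2 * ym2h - ym4h) / (2 * (2 * h)^3)
      d3 <- (4 * d3_h - d3_2h) / 3
      den <- 2 * d2 + fsum * d3
      alpha[i, j, ci] <- if (abs(den) > 1e-12) d2 / den else 0
      St <- function(t) {
        ft <- f; ft[i, j, ci] <- ft[i, j, ci] + t
        score_fn(ft)
      }
      g1[i, j, ci] <- (St(h) - St(-h)) / (2 * h)
    }
  }
  gamma <- vapply(seq_len(d[3L]), function(ci)
    sum(alpha[, , ci] * pmax(g1[, , ci], 0)), numeric(1))
  list(alpha = alpha, gamma = gamma, g1 = g1)
}

# Count connected components of a binary matrix (4-connectivity),
# plain flood fill.
count_components <- function(m) {
  lab <- matrix(0L, nrow(m), ncol(m))
  comp <- 0L
  for (i0 in seq_len(nrow(m))) for (j0 in seq_len(ncol(m))) {
    if (m[i0, j0] == 1 && lab[i0, j0] == 0L) {
      comp <- comp + 1L
      stack <- list(c(i0, j0))
      while (length(stack)) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        i <- p[1L]; j <- p[2L]
        if (i < 1 || j < 1 || i > nrow(m) || j > ncol(m)) next
        if (m[i, j] != 1 || lab[i, j] != 0L) next
        lab[i, j] <- comp
        stack <- c(stack, list(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L), c(i, j + 1L)))
      }
    }
  }
  comp
}

random_mask <- function(h, w, p = 0.5) matrix(as.numeric(rbinom(h * w, 1, p)), h, w)
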