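test_that("spectral sampling follows the kernel's spectral density", {
  # sigma = 1: frequency variance should be 1
  p <- sample_rff_params(P = 1, Q = 1e5, sigma = 1, seed = 2)
  expect_lt(abs(var(as.vector(p$omega)) - 1), 0.02)
  # very wide kernel: frequencies collapse to zero
  pw <- sample_rff_params(P = 1, Q = 1e4, sigma = 1e6, seed = 2)
  expect_lt(sd(as.vector(pw$omega)), 1e-5)
  expect_true(all(p$b >= 0 & p$b < 2 * pi))
  expect_identical(p, sample_rff_params(P = 1, Q = 1e5, sigma = 1, seed = 2))
  expect_error(sample_rff_params(P = 0, Q = 2, sigma = 1), "positive")
  expect_error(sample_rff_params(P = 1, Q = 2, sigma = -1), "positive")
})

test_that("the feature map matches its closed form and kernel limits", {
  # zero frequencies and phases: every coordinate is sqrt(2/Q)
  p0 <- sample_rff_params(P = 3, Q = 4, sigma = 1, seed = 1)
  p0$omega[] <- 0; p0$b[] <- 0
  z <- rff_map(c(1, -2, 3), p0)
  expect_equal(z, rep(sqrt(2 / 4), 4))
  expect_equal(sum(z * z), 2)
  # kappa(0) = 1 and kappa at distance 1 for sigma = 1
  p <- sample_rff_params(P = 4, Q = 1e5, sigma = 1, seed = 6)
  x <- c(0.3, -0.2, 0.5, 0.1)
  expect_lt(abs(sum(rff_map(x, p)^2) - 1), 0.02)
  xp <- x + c(1, 0, 0, 0)
  expect_lt(abs(sum(rff_map(x, p) * rff_map(xp, p)) - exp(-0.5)), 0.02)
  expect_error(rff_map(c(1, 2), p), "length")
  # boundedness of each coordinate
  expect_true(all(abs(rff_map(x, p)) <= sqrt(2 / p$Q) + 1e-12))
})

test_that("approximated kernel values are shift-invariant and unbiased over draws", {
  x <- c(0.4, -1); xp <- c(-0.3, 0.2); shift <- c(5, -7)
  vals <- vapply(1:300, function(s) {
    p <- sample_rff_params(P = 2, Q = 64, sigma = 1.5, seed = s)
    c(sum(rff_map(x, p) * rff_map(xp, p)),
      sum(rff_map(x + shift, p) * rff_map(xp + shift, p)))
  }, numeric(2))
  exact <- exp(-sum((x - xp)^2) / (2 * 1.5^2))
  expect_lt(abs(mean(vals[1, ]) - exact), 0.02)          # unbiasedness
  # shift invariance holds for the approximated kernel in expectation
  expect_lt(abs(mean(vals[2, ]) - exact), 0.02)
  expect_lt(abs(mean(vals[1, ]) - mean(vals[2, ])), 0.03)
})

test_that("the RFF layer acts independently per spatial position", {
  p <- sample_rff_params(P = 5, Q = 8, sigma = 2, seed = 3)
  v <- rnorm(5)
  single <- rff_layer_apply(array(v, c(1, 1, 5)), p)
  expect_equal(as.vector(single), rff_map(v, p))
  f <- array(rnorm(4 * 6 * 5), c(4, 6, 5))
  out <- rff_layer_apply(f, p)
  expect_identical(dim(out), c(4L, 6L, 8L))
  # permuting spatial positions permutes outputs identically
  perm_r <- sample(4); perm_c <- sample(6)
  out_perm <- rff_layer_apply(f[perm_r, perm_c, , drop = FALSE], p)
  expect_equal(out_perm, out[perm_r, perm_c, , drop = FALSE])
  expect_error(rff_layer_apply(f, sample_rff_params(P = 4, Q = 8, sigma = 2)),
               "channel")
  # the 8x8 bottleneck keeps its square form with Q channels
  g <- array(rnorm(8 * 8 * 5), c(8, 8, 5))
  expect_identical(dim(rff_layer_apply(g, p)), c(8L, 8L, 8L))
})

test_that("kernel approximation error shrinks with the feature count", {
  set.seed(5)
  pairs <- lapply(1:50, function(i) list(rnorm(4), rnorm(4)))
  errs <- vapply(1:20, function(s) {
    c(kernel_approx_error(sample_rff_params(4, 100L, 1, seed = s), pairs),
      kernel_approx_error(sample_rff_params(4, 10000L, 1, seed = s), pairs))
  }, numeric(2))
  expect_lt(median(errs[2, ]), median(errs[1, ]))
  p <- sample_rff_params(4, 1000L, 1, seed = 1)
  x <- rnorm(4)
  expect_equal(kernel_approx_error(p, list(list(x, x))),
               abs(sum(rff_map(x, p)^2) - 1))
  expect_error(kernel_approx_error(p, list()), "nonempty")
})
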