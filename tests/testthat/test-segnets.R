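test_that("every architecture maps an image to a same-shape probability grid", {
  for (arch in c("fcn", "unet", "resunet")) {
    for (use_rff in c(FALSE, TRUE)) {
      cfg <- model_config(arch, input_size = c(32, 32), depth = 2,
                          base_filters = 2, use_rff = use_rff, Q_factor = 8,
                          rff_sigma = 1)
      net <- kernseg:::build_model(cfg)
      net <- kernseg:::init_network(net, 1L)
      net <- kernseg:::attach_rff(net, cfg)
      fw <- kernseg:::forward_net(net, array(0, c(32, 32, 1, 1)))
      out <- fw$outs[[net$output_node]]
      expect_identical(dim(out), c(32L, 32L, 1L, 1L))
      expect_true(all(out >= 0 & out <= 1))
    }
  }
  expect_error(model_config("unet", input_size = c(30, 30), depth = 2),
               "divisible")
})

test_that("the RFF layer adds parameters when Q exceeds the bottleneck width", {
  base <- model_config("fcn", input_size = c(32, 32), depth = 2, base_filters = 2,
                       use_rff = FALSE)
  rff <- model_config("fcn", input_size = c(32, 32), depth = 2, base_filters = 2,
                      use_rff = TRUE, Q_factor = 8, rff_sigma = 1)  # Q = 8 > 4 channels
  n_base <- n_parameters(kernseg:::init_network(kernseg:::build_model(base), 1L))
  n_rff <- n_parameters(kernseg:::attach_rff(
    kernseg:::init_network(kernseg:::build_model(rff), 1L), rff))
  expect_lt(n_base, n_rff)
})

test_that("U-net and ResUnet differ only by the block structure", {
  u <- model_config("unet", input_size = c(32, 32), depth = 2, base_filters = 4,
                    use_rff = FALSE)
  r <- model_config("resunet", input_size = c(32, 32), depth = 2, base_filters = 4,
                    use_rff = FALSE)
  ops_u <- table(layer_summary(kernseg:::build_model(u))$op)
  ops_r <- table(layer_summary(kernseg:::build_model(r))$op)
  # same macro-structure
  expect_identical(ops_u[["pool"]], ops_r[["pool"]])
  expect_identical(ops_u[["convt"]], ops_r[["convt"]])
  expect_identical(ops_u[["concat"]], ops_r[["concat"]])
  expect_identical(ops_u[["sigmoid"]], ops_r[["sigmoid"]])
  # residual rewiring: one add per block, one relu fewer inside each block
  n_blocks <- 2L * 2L + 1L                    # encoder stages + bottleneck + decoder
  expect_identical(ops_r[["add"]], n_blocks)
  expect_identical(ops_u[["relu"]] - ops_r[["relu"]], n_blocks)
})

test_that("skip connections join encoder and decoder stages of equal resolution", {
  cfg <- model_config("unet", input_size = c(64, 64), depth = 3, base_filters = 2,
                      use_rff = FALSE)
  net <- kernseg:::init_network(kernseg:::build_model(cfg), 1L)
  fw <- kernseg:::forward_net(net, array(0.3, c(64, 64, 1, 1)))
  ls <- layer_summary(net)
  for (id in ls$id[ls$op == "concat"]) {
    ins <- net$nodes[[id]]$inputs
    expect_identical(dim(fw$outs[[ins[1L]]])[1:2], dim(fw$outs[[ins[2L]]])[1:2])
  }
})

test_that("residual blocks satisfy identity, linearity and gradient structure", {
  set.seed(13)
  x <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  w0 <- array(0, c(3, 3, 2, 2)); b0 <- numeric(2)
  expect_equal(residual_block(x, w0, b0, w0, b0), x)
  # transform = identity convolution on non-negative input doubles it
  wid <- array(0, c(1, 1, 2, 2)); wid[1, 1, 1, 1] <- 1; wid[1, 1, 2, 2] <- 1
  xpos <- abs(x)
  expect_equal(residual_block(xpos, wid, b0, wid, b0), 2 * xpos)
  # channel change requires a projection
  w2 <- array(rnorm(3 * 3 * 2 * 3, sd = 0.2), c(3, 3, 2, 3))
  expect_error(residual_block(x, w0, b0, w2, numeric(3)), "projection")
  wp <- array(rnorm(1 * 1 * 2 * 3, sd = 0.2), c(1, 1, 2, 3))
  out <- residual_block(x, w0, b0, w2, numeric(3), wp)
  expect_identical(dim(out), c(4L, 4L, 3L))
  # the Jacobian holds an exact identity component: with zero transform
  # weights, d out / d x is the identity
  h <- 1e-6
  i <- 7
  xp <- x; xp[i] <- xp[i] + h
  jac_col <- (residual_block(xp, w0, b0, w0, b0) - residual_block(x, w0, b0, w0, b0)) / h
  e <- array(0, dim(x)); e[i] <- 1
  expect_equal(jac_col, e, tolerance = 1e-9)
})

test_that("fitted models expose the standard S3 interface", {
  tiny <- fixture_tiny()
  fit <- tiny$fit
  expect_s3_class(fit, "kernseg_fit")
  expect_output(print(fit), "RFF-unet")
  expect_output(summary(fit), "Layer stack")
  cf <- coef(fit)
  expect_true(length(cf) > 0 && all(vapply(cf, is.numeric, logical(1))))
  img <- tiny$ds$pairs[[1L]]$image
  pr <- predict(fit, img)
  expect_identical(dim(pr), dim(img))
  expect_true(all(pr >= 0 & pr <= 1))
  mk <- predict(fit, img, type = "mask")
  expect_true(all(mk %in% c(0, 1)))
  lg <- predict(fit, img, type = "logits")
  expect_equal(1 / (1 + exp(-lg)), pr, tolerance = 1e-12)
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})

test_that("checkpoints round-trip through save and load", {
  tiny <- fixture_tiny()
  path <- withr::local_tempfile(fileext = ".rds")
  seg_save(tiny$fit, path)
  back <- seg_load(path)
  img <- tiny$ds$pairs[[2L]]$image
  expect_identical(predict(back, img), predict(tiny$fit, img))
})
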