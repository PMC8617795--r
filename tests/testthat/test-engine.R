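# Gradient and determinism checks for the computational core.

test_that("convolution, pooling and deconvolution gradients match finite differences", {
  set.seed(101)
  H <- 6; W <- 6; cin <- 3; cout <- 2; N <- 2
  x <- array(rnorm(H * W * cin * N), c(H, W, cin, N))
  w <- array(rnorm(3 * 3 * cin * cout, sd = 0.3), c(3, 3, cin, cout))
  b <- rnorm(cout)
  Lw <- array(rnorm(H * W * cout * N), c(H, W, cout, N))
  fd <- function(f, arr, analytic, picks = 6, h = 1e-5) {
    for (i in sample(length(arr), min(picks, length(arr)))) {
      ap <- arr; ap[i] <- ap[i] + h
      am <- arr; am[i] <- am[i] - h
      expect_equal(analytic[i], (f(ap) - f(am)) / (2 * h), tolerance = 1e-5)
    }
  }
  bw <- kernseg:::conv2d_bw(x, w, Lw)
  fd(function(a) sum(kernseg:::conv2d_fw(a, w, b) * Lw), x, bw$gx)
  fd(function(a) sum(kernseg:::conv2d_fw(x, a, b) * Lw), w, bw$gw)
  fd(function(a) sum(kernseg:::conv2d_fw(x, w, a) * Lw), b, bw$gb)

  Lp <- array(rnorm(3 * 3 * cin * N), c(3, 3, cin, N))
  r <- kernseg:::maxpool2_fw(x)
  gp <- kernseg:::maxpool2_bw(r$idx, Lp, dim(x))
  fd(function(a) sum(kernseg:::maxpool2_fw(a)$y * Lp), x, gp)

  wt <- array(rnorm(2 * 2 * cin * cout, sd = 0.3), c(2, 2, cin, cout))
  bt <- rnorm(cout)
  Lt <- array(rnorm(2 * H * 2 * W * cout * N), c(2 * H, 2 * W, cout, N))
  bwt <- kernseg:::convt2_bw(x, wt, Lt)
  fd(function(a) sum(kernseg:::convt2_fw(a, wt, bt) * Lt), x, bwt$gx)
  fd(function(a) sum(kernseg:::convt2_fw(x, a, bt) * Lt), wt, bwt$gw)

  p <- sample_rff_params(P = cin, Q = 5, sigma = 1.2, seed = 3)
  Lr <- array(rnorm(H * W * 5 * N), c(H, W, 5, N))
  cache <- kernseg:::rff_fw(x, p)
  gr <- kernseg:::rff_bw(Lr, cache, p)
  fd(function(a) sum(kernseg:::rff_fw(a, p)$y * Lr), x, gr$gx)
})

test_that("end-to-end backpropagation through a small U-net matches finite differences", {
  cfg <- model_config("unet", input_size = c(16, 16), depth = 1, base_filters = 2,
                      use_rff = TRUE, Q_factor = 8, rff_sigma = 1,
                      optimizer_seed = 5)
  net <- kernseg:::build_unet(cfg)
  net <- kernseg:::init_network(net, 5L)
  net <- kernseg:::attach_rff(net, cfg)
  set.seed(6)
  x <- array(runif(16 * 16), c(16, 16, 1, 1))
  m <- array(random_mask(16, 16, 0.3), c(16, 16, 1, 1))
  loss_of <- function(n) {
    fw <- kernseg:::forward_net(n, x)
    kernseg:::dice_loss_batch(m, fw$outs[[n$output_node]])$loss
  }
  fw <- kernseg:::forward_net(net, x)
  dl <- kernseg:::dice_loss_batch(m, fw$outs[[net$output_node]])
  seeds <- list(); seeds[[as.character(net$output_node)]] <- dl$grad
  bw <- kernseg:::backward_net(net, fw, seeds)
  g <- kernseg:::flatten_pgrads(net, bw$param_grads)
  params <- kernseg:::collect_params(net)
  h <- 1e-5
  set.seed(7)
  for (key in sample(names(g), 5)) {
    i <- sample(length(params[[key]]), 1)
    pp <- params; pp[[key]][i] <- pp[[key]][i] + h
    pm <- params; pm[[key]][i] <- pm[[key]][i] - h
    fdg <- (loss_of(kernseg:::set_params(net, pp)) -
            loss_of(kernseg:::set_params(net, pm))) / (2 * h)
    expect_equal(g[[key]][i], fdg, tolerance = 1e-4)
  }
})

test_that("initialization and training are reproducible from their seeds", {
  cfg <- model_config("resunet", input_size = c(16, 16), depth = 1,
                      base_filters = 2, use_rff = TRUE, Q_factor = 8,
                      rff_sigma = 1, optimizer_seed = 9)
  n1 <- kernseg:::attach_rff(kernseg:::init_network(kernseg:::build_resunet(cfg), 9L), cfg)
  n2 <- kernseg:::attach_rff(kernseg:::init_network(kernseg:::build_resunet(cfg), 9L), cfg)
  expect_identical(kernseg:::collect_params(n1), kernseg:::collect_params(n2))
  expect_identical(n1$nodes[[n1$rff_node]]$rff, n2$nodes[[n2$rff_node]]$rff)
})

test_that("training reduces the validation loss across seeds", {
  cfg <- synthetic_config(height = 32, width = 32, nerve_radius_range = c(5, 9),
                          seed = 21)
  ds <- generate_dataset(30, cfg)
  for (s in 1:3) {
    mc <- model_config("unet", input_size = c(32, 32), depth = 1,
                       base_filters = 4, use_rff = TRUE, Q_factor = 8,
                       epochs = 5, batch_size = 8, optimizer_seed = s)
    fit <- seg_fit(ds, mc)
    expect_lt(fit$history$val_loss[nrow(fit$history)], fit$history$val_loss[1])
  }
})

test_that("epoch step counts follow the mini-batch arithmetic", {
  cfg <- synthetic_config(height = 16, width = 16, nerve_radius_range = c(3, 5),
                          seed = 31)
  pairs <- lapply(1:36, function(i) generate_image(cfg, seed = i))
  mc <- model_config("fcn", input_size = c(16, 16), depth = 1, base_filters = 2,
                     use_rff = FALSE, epochs = 1, batch_size = 32,
                     optimizer_seed = 2)
  fit <- seg_fit(list(train = pairs[1:32], val = pairs[33:36]), mc)
  expect_identical(fit$history$steps, 1L)   # 32 samples, batch 32: one step
  expect_error(seg_fit(list(train = list(), val = pairs[33:36]), mc), "nonempty")
})
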