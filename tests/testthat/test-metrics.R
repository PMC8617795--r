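test_that("dice loss evaluates its defining formula", {
  ones <- matrix(1, 2, 2); zeros <- matrix(0, 2, 2)
  expect_equal(dice_loss(ones, ones), 0)            # s = 9/9
  expect_equal(dice_loss(ones, zeros), 0.8)         # s = 1/5
  expect_equal(dice_loss(zeros, zeros), 0)          # epsilon rescues 0/0
  expect_error(dice_loss(ones, matrix(1, 3, 2)), "shape")
  # analytic gradient agrees with finite differences
  set.seed(1)
  m <- random_mask(5, 5)
  p <- matrix(runif(25, 0.1, 0.9), 5, 5)
  y4 <- array(m, c(5, 5, 1, 1)); p4 <- array(p, c(5, 5, 1, 1))
  g <- kernseg:::dice_loss_batch(y4, p4)$grad
  h <- 1e-6
  for (i in c(1, 13, 25)) {
    pp <- p; pp[i] <- pp[i] + h
    pm <- p; pm[i] <- pm[i] - h
    fd <- (dice_loss(m, pp) - dice_loss(m, pm)) / (2 * h)
    expect_equal(g[i], fd, tolerance = 1e-5)
  }
})

test_that("confusion counts are exact pixel tallies", {
  m <- matrix(c(1, 0, 0, 0), 2, 2, byrow = TRUE)
  mh <- matrix(c(1, 1, 0, 0), 2, 2, byrow = TRUE)
  cc <- confusion_counts(m, mh)
  expect_identical(unclass(cc), list(TP = 1L, TN = 2L, FP = 1L, FN = 0L))
  expect_identical(sum(unlist(cc)), 4L)
  same <- confusion_counts(m, m)
  expect_identical(same$FP + same$FN, 0L)
  comp <- confusion_counts(m, 1 - m)
  expect_identical(comp$TP + comp$TN, 0L)
})

test_that("metric formulas match direct arithmetic and handle degenerate counts", {
  rec <- metrics_from_counts(structure(list(TP = 3, TN = 95, FP = 1, FN = 1),
                                       class = "confusion_counts"))
  expect_equal(rec[["sen"]], 75)
  expect_equal(rec[["spe"]], 100 * 95 / 96)
  expect_equal(rec[["dice"]], 75)
  expect_equal(rec[["iou"]], 60)
  expect_equal(rec[["gm"]], sqrt(75 * 100 * 95 / 96))
  perfect <- metrics_from_counts(structure(list(TP = 10, TN = 90, FP = 0, FN = 0),
                                           class = "confusion_counts"))
  expect_true(all(perfect == 100))
  zero_sen <- metrics_from_counts(structure(list(TP = 0, TN = 9, FP = 0, FN = 3),
                                            class = "confusion_counts"))
  expect_equal(zero_sen[["sen"]], 0)
  expect_equal(zero_sen[["gm"]], 0)
  no_pos <- metrics_from_counts(structure(list(TP = 0, TN = 9, FP = 1, FN = 0),
                                          class = "confusion_counts"))
  expect_true(is.na(no_pos[["sen"]]))
})

test_that("pixel AUC equals the pair-counting definition", {
  m <- matrix(c(1, 0, 1), 3, 1)
  prob <- matrix(c(0.9, 0.8, 0.1), 3, 1)
  expect_equal(pixel_auc(m, prob), 50)   # one concordant, one discordant pair
  expect_equal(pixel_auc(m, m), 100)     # perfect ranking
  expect_equal(pixel_auc(m, matrix(0.5, 3, 1)), 50)  # uninformative score
  expect_true(is.na(pixel_auc(matrix(1, 2, 2), matrix(0.5, 2, 2))))
})

test_that("pixel AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(21)
  for (rep in 1:20) {
    m <- random_mask(12, 12, p = 0.3)
    if (sum(m) == 0 || sum(m) == length(m)) next
    prob <- matrix(runif(144), 12, 12)
    ref <- 100 * as.numeric(pROC::auc(pROC::roc(as.vector(m), as.vector(prob),
                                                quiet = TRUE, direction = "<")))
    expect_equal(pixel_auc(m, prob), ref, tolerance = 1e-9)
  }
})

test_that("evaluation aggregates per-image records and ignores image order", {
  tiny <- fixture_tiny()
  test_pairs <- tiny$ds$pairs[tiny$ds$split == "test"]
  ev1 <- seg_evaluate(tiny$fit, test_pairs[1])
  expect_equal(ev1$summary$mean[ev1$summary$metric == "dice"],
               ev1$per_image$dice[1])
  expect_true(all(ev1$summary$sd == 0))
  ev <- seg_evaluate(tiny$fit, test_pairs)
  expect_equal(mean(ev$per_image$dice),
               ev$summary$mean[ev$summary$metric == "dice"])
  ev_rev <- seg_evaluate(tiny$fit, rev(test_pairs))
  expect_equal(sort(ev_rev$per_image$dice), sort(ev$per_image$dice))
  expect_equal(ev_rev$summary$mean, ev$summary$mean)
  expect_error(seg_evaluate(tiny$fit, list()), "empty")
})

test_that("an oracle prediction scores 100 on every metric", {
  set.seed(3)
  m <- generate_image(small_synth_config(), seed = 8)$mask
  rec <- metrics_from_counts(confusion_counts(m, m))
  expect_true(all(rec == 100))
  expect_equal(pixel_auc(m, m), 100)
})
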