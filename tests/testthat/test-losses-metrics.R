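test_that("confusion counts match hand-computed toys", {
  t4 <- matrix(c(1L, 1L, 0L, 0L), 2, 2)
  p4 <- matrix(c(1L, 0L, 1L, 0L), 2, 2)
  cc <- confusion(p4, t4, 1L)
  expect_identical(cc, list(TP = 1L, FP = 1L, FN = 1L, TN = 1L))
  expect_identical(with(confusion(t4, t4, 1L), c(FP, FN)), c(0L, 0L))
  comp <- 1L - t4
  cc2 <- confusion(comp, t4, 1L)
  expect_identical(with(cc2, c(TP, TN)), c(0L, 0L))
  expect_error(confusion(matrix(0, 2, 3), t4), "shapes")
})

test_that("dice coefficient covers the identity, disjoint and toy cases", {
  m <- random_mask(8)
  expect_identical(dice_coefficient(confusion(m, m, 1L)), 1)
  a <- matrix(c(1L, 0L, 0L, 0L), 2, 2); b <- matrix(c(0L, 1L, 0L, 0L), 2, 2)
  expect_identical(dice_coefficient(confusion(a, b, 1L)), 0)
  expect_equal(dice_coefficient(list(TP = 1L, FP = 0L, FN = 1L, TN = 2L)),
               2 / 3)
  empty <- matrix(0L, 2, 2)
  expect_identical(dice_coefficient(confusion(empty, empty, 1L)), 1)
})

test_that("hausdorff distance: toys, symmetry and empty-set error", {
  X <- matrix(c(0, 0), 1, 2)
  expect_identical(hausdorff_distance(X, X), 0)
  Y <- matrix(c(3, 4), 1, 2)
  expect_identical(hausdorff_distance(X, Y, 100), 5)
  expect_identical(hausdorff_distance(X, Y, 95), 5)
  expect_error(hausdorff_distance(matrix(numeric(0), 0, 2), Y), "undefined")
})

test_that("hausdorff matches the brute-force oracle on random point sets", {
  set.seed(20)
  for (trial in 1:10) {
    X <- matrix(runif(40, 0, 30), 20, 2)
    Y <- matrix(runif(40, 0, 30), 20, 2)
    expect_equal(hausdorff_distance(X, Y, 100), hausdorff_oracle(X, Y))
    expect_identical(hausdorff_distance(X, Y, 100),
                     hausdorff_distance(Y, X, 100))
    expect_lte(hausdorff_distance(X, Y, 95), hausdorff_distance(X, Y, 100))
    # translation invariance
    sh <- matrix(rep(c(5, -3), each = 20), 20, 2)
    expect_equal(hausdorff_distance(X + sh, Y + sh, 95),
                 hausdorff_distance(X, Y, 95))
  }
})

test_that("soft dice loss: degenerate cases and the hard-mask relation", {
  m <- random_mask(8, 0.4)
  expect_lt(dice_loss(m, m), 1e-6)
  empty <- matrix(0, 4, 4)
  expect_identical(dice_loss(empty, empty), 0)
  ones <- matrix(1, 4, 4)
  expect_gt(dice_loss(empty, ones, eps = 1e-12), 1 - 1e-9)
  expect_error(dice_loss(matrix(2, 2, 2), matrix(1, 2, 2)), "\\[0, 1\\]")
  set.seed(21)
  for (trial in 1:20) {
    p <- random_mask(8); t <- random_mask(8)
    expect_equal(1 - dice_loss(p, t, eps = 1e-12),
                 dice_oracle(p, t), tolerance = 1e-6)
    expect_equal(dice_oracle(p, t), dice_coefficient(confusion(p, t, 1L)))
  }
})

test_that("focal loss: exponent collapse, perfection and a worked value", {
  set.seed(22)
  p <- matrix(runif(16, 0.05, 0.95), 4, 4)
  y <- random_mask(4, 0.5)
  bce <- sum(-y * log(p) - (1 - y) * log(1 - p))
  expect_equal(focal_loss(p, y, gamma = 0), bce, tolerance = 1e-10)
  expect_lt(focal_loss(y, y, gamma = 2), 1e-4)
  expect_equal(focal_loss(0.5, 1, gamma = 2), -(0.5)^2 * log(0.5),
               tolerance = 1e-12)
  expect_equal(-(0.5)^2 * log(0.5), 0.1733, tolerance = 1e-4)
})

test_that("compound loss combines its terms linearly", {
  set.seed(23)
  p <- matrix(runif(64), 8, 8)
  y <- random_mask(8)
  ld <- dice_loss(p, y, 1e-5)
  lf <- focal_loss(p, y, 2, 1e-7)
  expect_equal(combined_loss(p, y, loss_config(alpha = 1, beta = 0)), ld)
  expect_equal(combined_loss(p, y, loss_config(alpha = 0.8, beta = 0.2)),
               0.8 * ld + 0.2 * lf, tolerance = 1e-12)
  expect_equal(combined_loss(p, y, loss_config(alpha = 1.6, beta = 0.4)),
               2 * combined_loss(p, y, loss_config(alpha = 0.8, beta = 0.2)))
  expect_gte(combined_loss(p, y, loss_config()), 0)
})

test_that("compound loss is finitely differentiable along probabilities", {
  set.seed(24)
  p <- matrix(runif(16, 0.1, 0.9), 4, 4)
  y <- random_mask(4)
  eps <- 1e-6
  for (i in c(1, 7, 16)) {
    p2 <- p; p2[i] <- p2[i] + eps
    lp <- combined_loss(p2, y, loss_config())
    p2[i] <- p2[i] - 2 * eps
    lm <- combined_loss(p2, y, loss_config())
    expect_true(is.finite((lp - lm) / (2 * eps)))
  }
})

test_that("loss gradient w.r.t. logits matches finite differences", {
  set.seed(25)
  for (K in c(2L, 3L)) {
    logits <- array(rnorm(8 * 8 * K), c(8, 8, K))
    y <- matrix(sample(0:(K - 1L), 64, replace = TRUE), 8, 8)
    lg <- swunet:::seg_loss_grad(logits, y, loss_config())
    eps <- 1e-6
    for (j in 1:6) {
      i <- sample(length(logits), 1)
      l2 <- logits; l2[i] <- l2[i] + eps
      lp <- swunet:::seg_loss_grad(l2, y, loss_config())$loss
      l2[i] <- l2[i] - 2 * eps
      lm <- swunet:::seg_loss_grad(l2, y, loss_config())$loss
      num <- (lp - lm) / (2 * eps)
      expect_lt(abs(num - lg$dlogits[i]) /
                  max(1e-4, abs(num) + abs(lg$dlogits[i])), 1e-4)
    }
  }
})

test_that("metric report covers identity, toy counts and the column names", {
  m <- random_mask(16, 0.3)
  rp <- full_report(m, m, n_classes = 2L)
  expect_equal(unname(rp$aggregate),
               c(1, 1, 1, 1, 0))
  expect_identical(names(rp$per_class),
                   c("class", "Accuracy", "Dice", "Sensitivity",
                     "Specificity", "H95"))
  t4 <- matrix(c(1L, 1L, 0L, 0L), 2, 2)
  p4 <- matrix(c(1L, 0L, 1L, 0L), 2, 2)
  rp2 <- full_report(p4, t4, n_classes = 2L)
  expect_equal(rp2$per_class$Accuracy, 0.5)
  expect_equal(rp2$per_class$Dice, 0.5)
  expect_equal(rp2$per_class$Sensitivity, 0.5)
  expect_equal(rp2$per_class$Specificity, 0.5)
})

test_that("degenerate classes are flagged undefined, not zeroed", {
  t <- matrix(0L, 8, 8); t[3:5, 3:5] <- 1L
  p <- matrix(0L, 8, 8)
  rp <- full_report(p, t, n_classes = 2L)
  expect_true(is.na(rp$per_class$H95))
  expect_gt(rp$n_undefined, 0)
})

test_that("count metrics are invariant to a shared pixel permutation", {
  set.seed(26)
  p <- random_mask(8); t <- random_mask(8)
  perm <- sample(64)
  pp <- matrix(p[perm], 8, 8); tp <- matrix(t[perm], 8, 8)
  expect_identical(confusion(pp, tp, 1L), confusion(p, t, 1L))
  expect_equal(dice_loss(pp, tp), dice_loss(p, t))
  expect_equal(focal_loss(pp, tp), focal_loss(p, t))
})
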