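test_that("huber matches its closed form and is smooth at the transition", {
  expect_equal(huber(0), 0)
  expect_equal(huber(0.5, delta = 1), 0.125)
  expect_equal(huber(2, delta = 1), 1.5)
  expect_equal(huber(-2, delta = 1), 1.5)
  expect_equal(huber(3, delta = 2), 2 * (3 - 1))
  # continuity and slope continuity at |r| = delta
  eps <- 1e-7
  expect_equal(huber(1 - eps), huber(1 + eps), tolerance = 1e-6)
  slope_in <- (huber(1) - huber(1 - eps)) / eps
  slope_out <- (huber(1 + eps) - huber(1)) / eps
  expect_equal(slope_in, slope_out, tolerance = 1e-5)
})

test_that("voxel weights balance the positive and negative classes", {
  lab <- array(0, dim = c(4, 4, 4))
  lab[1:2, 1:2, 1:2] <- 0.7         # 8 positive voxels out of 64
  w <- voxel_weights(lab)
  expect_equal(unique(w[lab > 0]), 4)            # 64 / (2 * 8)
  expect_equal(unique(w[lab == 0]), 64 / 112)    # 64 / (2 * 56)
  expect_equal(mean(w), 1)
  expect_equal(sum(w[lab > 0]), sum(w[lab == 0]))
  # degenerate single-class labels fall back to uniform weights
  expect_true(all(voxel_weights(array(0, dim = c(3, 3, 3))) == 1))
  expect_true(all(voxel_weights(array(1, dim = c(3, 3, 3))) == 1))
})

test_that("gradient loss matches a direct stencil oracle and kills constants", {
  set.seed(5)
  lab <- array(runif(5^3), dim = c(5, 5, 5))
  expect_equal(gradient_loss(lab, lab), 0)
  expect_equal(gradient_loss(lab + 0.37, lab), 0)

  # single-voxel spike: compare against explicit replicate-padded convolution
  pred <- lab
  pred[3, 3, 3] <- pred[3, 3, 3] + 0.8
  want <- mean(vapply(1:3, function(ax) {
    mean(huber(oracle_second_diff(pred, ax) - oracle_second_diff(lab, ax)))
  }, numeric(1)))
  expect_equal(gradient_loss(pred, lab), want, tolerance = 1e-12)

  # random fields, both derivative orders
  pred2 <- lab + array(rnorm(5^3, sd = 0.3), dim = c(5, 5, 5))
  want2 <- mean(vapply(1:3, function(ax) {
    mean(huber(oracle_second_diff(pred2, ax) - oracle_second_diff(lab, ax)))
  }, numeric(1)))
  expect_equal(gradient_loss(pred2, lab), want2, tolerance = 1e-12)
  expect_gt(gradient_loss(pred2, lab, loss_config(gradient_order = 1)), 0)
  expect_error(gradient_loss(array(0, dim = c(4, 4, 4)), lab), "mismatch")
})

test_that("the composite loss is zero iff prediction equals label", {
  set.seed(11)
  lab <- array(0, dim = c(6, 6, 6))
  lab[3, 3, 3] <- 1; lab[3, 3, 4] <- 0.6
  expect_equal(composite_loss(lab, lab), 0)
  pred <- lab; pred[1, 1, 1] <- 1e-3
  expect_gt(composite_loss(pred, lab), 0)
  # lambda_grad = 0 reduces to the weighted Huber term
  w <- voxel_weights(lab)
  expect_equal(composite_loss(pred, lab, loss_config(lambda_grad = 0)),
               mean(w * huber(pred - lab)))
  # symmetric in the sign of the residual
  e <- array(runif(6^3, 0, 0.2), dim = c(6, 6, 6))
  expect_equal(composite_loss(lab + e, lab), composite_loss(lab - e, lab),
               tolerance = 1e-12)
  expect_error(composite_loss(array(NA_real_, dim = c(6, 6, 6)), lab),
               "non-finite")
})

test_that("analytic loss gradients agree with finite differences", {
  set.seed(2)
  cfg <- loss_config()
  lab <- array(0, dim = c(5, 5, 5)); lab[3, 3, 3] <- 1
  pred <- array(runif(5^3, 0, 0.5), dim = c(5, 5, 5))
  g <- tomopick:::composite_loss_grad(pred, lab, cfg)
  eps <- 1e-6
  for (idx in sample(125, 8)) {
    up <- pred; up[idx] <- up[idx] + eps
    dn <- pred; dn[idx] <- dn[idx] - eps
    fd <- (composite_loss(up, lab, cfg) - composite_loss(dn, lab, cfg)) / (2 * eps)
    expect_equal(g[idx], fd, tolerance = 1e-5)
  }
})
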