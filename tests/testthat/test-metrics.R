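mk_pts <- function(m) tibble::tibble(x = m[, 1], y = m[, 2], z = m[, 3])

test_that("matching finds the globally optimal pairing", {
  gt <- mk_pts(rbind(c(0, 0, 0), c(0, 0, 4)))
  pred <- mk_pts(rbind(c(0, 0, 3), c(0, 0, -1)))
  mt <- match_centroids(gt, pred, dist_threshold = 5)
  expect_equal(sum(mt$pairs$distance), 2)      # optimal crossing beats naive 8
  expect_equal(mt$tp, 2L)
  got <- mt$pairs[order(mt$pairs$gt), ]
  expect_equal(got$pred, c(2L, 1L))

  # identical sets match at distance zero
  set.seed(1)
  pts <- mk_pts(matrix(runif(15, 0, 50), 5))
  mt2 <- match_centroids(pts, pts, dist_threshold = 1)
  expect_equal(mt2$tp, 5L)
  expect_equal(mt2$fp + mt2$fn, 0L)
  expect_equal(max(mt2$pairs$distance), 0)
})

test_that("match totals equal the permutation brute-force minimum", {
  for (seed in 1:30) {
    set.seed(seed)
    n <- sample(1:6, 1); m <- sample(1:6, 1)
    gt <- mk_pts(matrix(runif(3 * n, 0, 30), n))
    pred <- mk_pts(matrix(runif(3 * m, 0, 30), m))
    mt <- match_centroids(gt, pred, dist_threshold = 10)
    cost <- as.matrix(stats::dist(rbind(gt, pred)))[seq_len(n),
                                                    n + seq_len(m),
                                                    drop = FALSE]
    expect_equal(sum(mt$pairs$distance), oracle_min_assignment_cost(cost),
                 tolerance = 1e-9)
    expect_equal(nrow(mt$pairs), min(n, m))
    expect_equal(mt$tp + mt$fp, m)
    expect_equal(mt$tp + mt$fn, n)
  }
})

test_that("precision, recall and F1 follow their defining formulas", {
  gt3 <- mk_pts(rbind(c(0, 0, 0), c(20, 0, 0), c(40, 0, 0)))
  pred2 <- mk_pts(rbind(c(1, 0, 0), c(21, 0, 0)))
  mt <- match_centroids(gt3, pred2, dist_threshold = 5)
  expect_equal(mt$tp, 2L); expect_equal(mt$fp, 0L); expect_equal(mt$fn, 1L)
  met <- prf(mt)
  expect_equal(met[["precision"]], 1)
  expect_equal(met[["recall"]], 2 / 3)
  expect_equal(met[["f1"]], 0.8)
  gl <- glance(mt)
  expect_equal(gl$f1, 0.8)

  perfect <- match_centroids(gt3, gt3, dist_threshold = 1)
  expect_equal(unname(prf(perfect)), c(1, 1, 1))

  # conventions for empty sets
  none <- match_centroids(gt3, mk_pts(matrix(numeric(0), 0, 3)),
                          dist_threshold = 5)
  expect_equal(unname(prf(none)), c(0, 0, 0))
  empty <- match_centroids(mk_pts(matrix(numeric(0), 0, 3)),
                           mk_pts(matrix(numeric(0), 0, 3)), dist_threshold = 5)
  expect_equal(prf(empty)[["f1"]], 0)
})

test_that("precision and recall swap when gt and pred are exchanged", {
  set.seed(3)
  for (i in 1:5) {
    a <- mk_pts(matrix(runif(12, 0, 20), 4))
    b <- mk_pts(matrix(runif(18, 0, 20), 6))
    m1 <- prf(match_centroids(a, b, dist_threshold = 6))
    m2 <- prf(match_centroids(b, a, dist_threshold = 6))
    expect_equal(m1[["precision"]], m2[["recall"]])
    expect_equal(m1[["recall"]], m2[["precision"]])
    expect_equal(m1[["f1"]], m2[["f1"]])
    expect_lte(m1[["f1"]], 2 * 4 / 10 + 1e-12)   # min-side perfect bound
  }
})

test_that("normalized RMSE averages over true positives only", {
  gt <- mk_pts(rbind(c(0, 0, 0)))
  pred <- mk_pts(rbind(c(3, 0, 0)))
  mt <- match_centroids(gt, pred, dist_threshold = 5)
  expect_equal(normalized_rmse(mt, diameter = 10), 0.3)

  gt2 <- mk_pts(rbind(c(0, 0, 0), c(30, 0, 0)))
  pred2 <- mk_pts(rbind(c(3, 0, 0), c(30, 4, 0)))
  mt2 <- match_centroids(gt2, pred2, dist_threshold = 5)
  expect_equal(normalized_rmse(mt2, diameter = 10), sqrt(12.5) / 10)

  perfect <- match_centroids(gt2, gt2, dist_threshold = 5)
  expect_equal(normalized_rmse(perfect, diameter = 10), 0)

  # no true positives -> missing, not zero
  far <- match_centroids(gt, mk_pts(rbind(c(100, 0, 0))), dist_threshold = 5)
  expect_true(is.na(normalized_rmse(far, diameter = 10)))

  # alternative normalization by min(|gt|, |pred|)
  one_hit <- match_centroids(gt2, mk_pts(rbind(c(3, 0, 0), c(200, 0, 0))),
                             dist_threshold = 5)
  expect_equal(normalized_rmse(one_hit, diameter = 10, tp_only = FALSE),
               sqrt(9 / 2) / 10)
})

test_that("the percentile sweep has 13 rows and flags the best F1", {
  set.seed(6)
  gt <- mk_pts(matrix(runif(33, 0, 60), 11))
  # uniform-confidence perfect predictor: F1 = 1 everywhere, tie -> 2%
  pred <- centroid_set(cbind(gt, confidence = 0.7))
  sw <- threshold_sweep(gt, pred, diameter = 10)
  expect_equal(nrow(sw), 13L)
  expect_equal(sw$percentile, seq(2, 98, by = 8))
  expect_true(all(sw$f1 == 1))
  expect_equal(sw$percentile[sw$is_best], 2)
  expect_equal(glance(sw)$f1_max, 1)

  # 9 decoys, all below the 11 true hits in confidence: the 50th percentile
  # of the pooled scores is exactly the weakest true hit, so that row keeps
  # precisely the true positives and attains F1 = 1
  fp <- tibble::tibble(x = runif(9, 100, 160), y = runif(9, 0, 60),
                       z = runif(9, 0, 60), confidence = runif(9, 0.05, 0.2))
  pred2 <- centroid_set(rbind(cbind(gt, confidence = runif(11, 0.6, 0.9)), fp))
  sw2 <- threshold_sweep(gt, pred2, diameter = 10)
  best <- sw2[sw2$is_best, ]
  expect_equal(best$f1, 1)
  expect_equal(best$percentile, 50)
  expect_lt(sw2$f1[1], 1)
  expect_error(threshold_sweep(gt, pred2[0, ], diameter = 10), "empty")
})
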