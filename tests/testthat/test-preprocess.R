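test_that("compute_scale brings particles to the target pixel size", {
  expect_equal(compute_scale(5, 200), 0.25)          # 40 px -> 10 px
  expect_equal(5 / compute_scale(5, 200), 20)        # rescaled voxel size
  expect_equal(compute_scale(10, 100), 1)            # already at target
  expect_equal(compute_scale(13.5, 135), 1)
  expect_equal(compute_scale(4, 100, target_particle_px = 5), 0.2)
})

test_that("resize preserves constants, mass and the target particle size", {
  vc <- volume(array(2.5, dim = c(20, 24, 28)), 4)
  half <- resize_volume(vc, 0.5)
  expect_identical(dim(half), c(10L, 12L, 14L))
  expect_equal(half$voxel_size, 8)
  expect_equal(range(half$data), c(2.5, 2.5))
  expect_equal(resize_volume(vc, 1)$data, vc$data)

  # spike mass survives a down/up round trip (anti-aliased downsampling)
  v <- volume(array(0, dim = c(32, 32, 32)), 1)
  v$data[18, 16, 17] <- 1
  up <- resize_volume(resize_volume(v, 0.5), 2)
  expect_lt(abs(sum(up$data) - 1), 0.1)

  # a diameter-20 label resized by compute_scale spans ~10 voxels
  ps <- particle_set(tibble::tibble(x = 16, y = 16, z = 16), diameter = 20,
                     voxel_size = 1)
  lab <- render_labels(ps, c(33, 33, 33))
  half_lab <- resize_volume(lab, compute_scale(1, 20))
  extent <- sum(half_lab$data[9, 9, ] > 1e-4)
  expect_true(abs(extent - 10) <= 1.5)  # support is diameter + 1 pre-resize
})

test_that("robust normalization is a median/IQR affine map", {
  # fixture with exact quartiles 2, 3, 4 plus one probe voxel of value 5
  x <- array(c(rep(c(2, 3, 4), each = 27), 5), dim = c(2, 41, 1))
  v <- robust_normalize(volume(x, 1))
  expect_equal(v$data[x == 4][1], 0.5)
  expect_equal(v$data[x == 5], 1)  # (5 - median) / IQR = (5 - 3) / 2
  expect_equal(stats::median(v$data), 0)
  expect_equal(diff(stats::quantile(v$data, c(0.25, 0.75), names = FALSE)), 1)

  set.seed(1)
  r <- volume(array(rnorm(10^3, 5, 3), dim = c(10, 10, 10)), 1)
  once <- robust_normalize(r)
  twice <- robust_normalize(once)
  expect_equal(twice$data, once$data, tolerance = 1e-12)  # idempotent

  expect_error(robust_normalize(volume(array(7, dim = c(4, 4, 4)), 1)),
               "interquartile")
})

test_that("chunking covers every voxel with clamped boundary origins", {
  one <- chunk_volume(array(0, dim = c(64, 64, 64)))
  expect_equal(nrow(one), 1L)
  expect_equal(c(one$oz, one$oy, one$ox), c(0L, 0L, 0L))

  eight <- chunk_volume(array(0, dim = c(96, 96, 96)))
  expect_equal(nrow(eight), 8L)
  expect_setequal(unique(eight$oz), c(0L, 32L))

  sq <- chunk_volume(array(rnorm(100^3), dim = c(100, 100, 100)))
  expect_equal(nrow(sq), 27L)
  expect_setequal(unique(sq$ox), c(0L, 32L, 36L))

  # coverage property on awkward shapes
  for (d in list(c(64, 70, 129), c(65, 64, 96))) {
    ch <- chunk_volume(array(0, dim = d))
    for (axis in 1:3) {
      o <- unique(ch[[c("oz", "oy", "ox")[axis]]])
      covered <- sort(unique(unlist(lapply(o, function(s) s + 1:64))))
      expect_identical(covered, 1:d[axis])
      expect_true(all(o >= 0 & o <= d[axis] - 64))
    }
  }

  # volumes smaller than one chunk are zero-padded
  small <- chunk_volume(array(1, dim = c(10, 10, 10)), chunk_size = 16,
                        stride = 8)
  expect_equal(nrow(small), 1L)
  expect_equal(sum(small$data[[1]]), 1000)
  expect_identical(attr(small, "source_shape"), c(10L, 10L, 10L))

  # chunk content matches the source subarray
  x <- array(rnorm(96^3), dim = c(96, 96, 96))
  ch <- chunk_volume(x)
  i <- 5
  expect_equal(ch$data[[i]],
               x[ch$oz[i] + 1:64, ch$oy[i] + 1:64, ch$ox[i] + 1:64])
})

test_that("chunk balancing keeps positives and samples matched negatives", {
  # 17 cubes: 5 positive, 12 negative, via a 16^3-chunk synthetic label grid
  make_sets <- function(n_pos, n_total) {
    lab <- lapply(seq_len(n_total), function(i) {
      a <- array(0, dim = c(16, 16, 16))
      if (i <= n_pos) a[8, 8, 8] <- 1
      a
    })
    img <- lapply(seq_len(n_total), function(i) array(rnorm(16^3), dim = c(16, 16, 16)))
    grid <- tibble::tibble(oz = 0L, oy = 0L, ox = as.integer(16 * (seq_len(n_total) - 1)))
    mk <- function(data) structure(dplyr::mutate(grid, data = data),
                                   chunk_size = 16L, stride = 16L,
                                   class = c("chunk_set", class(grid)))
    list(img = mk(img), lab = mk(lab))
  }
  s <- make_sets(5, 17)
  bal <- balance_chunks(s$img, s$lab, seed = 9)
  expect_equal(nrow(bal), 10L)
  expect_equal(sum(bal$positive), 5L)
  # clamped case: fewer negatives than positives
  s2 <- make_sets(5, 8)
  expect_equal(nrow(balance_chunks(s2$img, s2$lab, seed = 1)), 8L)
  # determinism and no duplicated negatives
  bal2 <- balance_chunks(s$img, s$lab, seed = 9)
  expect_identical(bal$ox, bal2$ox)
  neg_ids <- bal$ox[!bal$positive]
  expect_equal(anyDuplicated(neg_ids), 0L)
  # all-negative labels cannot be balanced
  s3 <- make_sets(0, 4)
  expect_error(balance_chunks(s3$img, s3$lab), "positively annotated")
})
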