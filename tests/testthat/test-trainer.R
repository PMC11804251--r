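test_that("train/validation splits are disjoint, exhaustive and seeded", {
  chunks <- tibble::tibble(id = 1:10, image = as.list(1:10),
                           label = as.list(1:10))
  sp <- split_train_val(chunks, 0.2, seed = 4)
  expect_equal(nrow(sp$train), 8L)
  expect_equal(nrow(sp$val), 2L)
  expect_setequal(c(sp$train$id, sp$val$id), 1:10)
  expect_length(intersect(sp$train$id, sp$val$id), 0)
  sp2 <- split_train_val(chunks, 0.2, seed = 4)
  expect_identical(sp$val$id, sp2$val$id)
  expect_false(identical(sp$val$id, split_train_val(chunks, 0.2, seed = 5)$val$id))
  expect_error(split_train_val(chunks[1, ], 0.5), "at least 2")
})

test_that("backbone gradients propagate the full loss chain correctly", {
  set.seed(8)
  bb <- matched_filter_backbone(kernel_size = 3, seed = 2)
  x <- array(rnorm(6^3), dim = c(6, 6, 6))
  lab <- array(0, dim = c(6, 6, 6)); lab[3, 3, 3] <- 1
  cfg <- loss_config()
  fwd <- bb_forward(bb, x)
  g <- bb_backward(bb, tomopick:::composite_loss_grad(fwd$output, lab, cfg),
                   fwd$cache)
  eps <- 1e-6
  for (i in sample(27, 6)) {
    bp <- bb; bp$kernel[i] <- bp$kernel[i] + eps
    bm <- bb; bm$kernel[i] <- bm$kernel[i] - eps
    fd <- (composite_loss(bb_apply(bp, x), lab, cfg) -
             composite_loss(bb_apply(bm, x), lab, cfg)) / (2 * eps)
    expect_equal(g$kernel[i], fd, tolerance = 1e-4)
  }
  bp <- bb; bp$bias <- bp$bias + eps
  bm <- bb; bm$bias <- bm$bias - eps
  fd <- (composite_loss(bb_apply(bp, x), lab, cfg) -
           composite_loss(bb_apply(bm, x), lab, cfg)) / (2 * eps)
  expect_equal(g$bias, fd, tolerance = 1e-4)
})

test_that("training on a clear phantom task reduces the loss by half", {
  pairs <- make_training_fixture(n_phantoms = 2, shape = 64, chunk = 32,
                                 snr = 10, seed = 10)
  fit <- train_backbone(matched_filter_backbone(seed = 1), pairs,
                        config = train_config(max_epochs = 20, seed = 1))
  log <- tidy(fit)
  expect_lte(nrow(log), 20)
  expect_lt(log$train_loss[nrow(log)], 0.5 * log$train_loss[1])
  expect_lte(fit$best_val, log$val_loss[1])
  expect_lte(fit$best_val, log$val_loss[nrow(log)])
  gl <- glance(fit)
  expect_equal(gl$best_val_loss, fit$best_val)
})

test_that("training is bit-identical for a fixed seed", {
  pairs <- make_training_fixture(n_phantoms = 1, shape = 64, chunk = 32,
                                 snr = 10, seed = 21)
  run <- function() train_backbone(matched_filter_backbone(seed = 3), pairs,
                                   config = train_config(max_epochs = 3, seed = 7))
  f1 <- run(); f2 <- run()
  expect_identical(f1$log, f2$log)
  expect_identical(bb_params(f1$backbone), bb_params(f2$backbone))
})

test_that("early stopping and plateau lr halving follow the schedule", {
  # a frozen constant-output backbone never improves after epoch 1
  pairs <- tibble::tibble(
    oz = 0L, oy = 0L, ox = 0L,
    image = replicate(6, array(rnorm(8^3), dim = c(8, 8, 8)), simplify = FALSE),
    label = replicate(6, { a <- array(0, dim = c(8, 8, 8)); a[4, 4, 4] <- 1; a },
                      simplify = FALSE),
    positive = TRUE)
  fit <- train_backbone(constant_backbone(0.5), pairs,
                        config = train_config(max_epochs = 50,
                                              early_stop_patience = 5,
                                              lr_patience = 2, batch_size = 2,
                                              val_fraction = 0.34, seed = 1))
  log <- tidy(fit)
  expect_equal(nrow(log), 6L)          # patience + 1 epochs
  expect_equal(fit$best_epoch, 1L)
  # lr halves every lr_patience epochs while the plateau lasts:
  # epochs 1-3 at lr0 (halving applied at the end of epoch 3), 4-5 at lr0/2, ...
  lr0 <- 4e-4
  expect_equal(log$lr, lr0 * 2^-floor(pmax(log$epoch - 2, 0) / 2))
})

test_that("fine-tuning resumes weights and honors schedule overrides", {
  pairs <- make_training_fixture(n_phantoms = 1, shape = 64, chunk = 32,
                                 snr = 10, seed = 31)
  fit <- train_backbone(matched_filter_backbone(seed = 1), pairs,
                        config = train_config(max_epochs = 2, seed = 1))
  frozen <- fine_tune(fit, pairs, max_epochs = 0)
  expect_identical(bb_params(frozen$backbone), bb_params(fit$backbone))

  ft <- fine_tune(fit, pairs, max_epochs = 2, lr = 5e-5)
  expect_equal(nrow(ft$log), 2L)
  expect_equal(unique(ft$log$lr), 5e-5)
  expect_lte(ft$best_val, fit$best_val + 1e-9)  # resumed, not restarted
})

test_that("checkpoints round-trip and reject incompatible parameters", {
  pairs <- make_training_fixture(n_phantoms = 1, shape = 64, chunk = 32,
                                 snr = 10, seed = 41)
  fit <- train_backbone(matched_filter_backbone(kernel_size = 7, seed = 1),
                        pairs,
                        config = train_config(max_epochs = 1, seed = 1),
                        meta = list(target_particle_px = 10))
  p <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fit, p)
  back <- load_checkpoint(p)
  expect_identical(bb_params(back$backbone), bb_params(fit$backbone))
  expect_equal(back$meta$target_particle_px, 10)
  expect_identical(back$log, fit$log)
  # tamper: store parameters of the wrong shape
  ck <- readRDS(p)
  ck$params$kernel <- array(0, dim = c(3, 3, 3))
  saveRDS(ck, p)
  expect_error(load_checkpoint(p), "kernel")
})
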