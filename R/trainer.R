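# Training harness: AdamW optimization of a backbone under the composite
# loss, with plateau-halved learning rate, early stopping on the validation
# loss and best-checkpoint selection.

#' Training schedule parameters
#'
#' Defaults follow the reference schedule for centroid-heatmap training: at
#' most 150 epochs, early stopping with a patience of 36 epochs, batches of 10
#' cubes, initial learning rate 4e-4 halved after 6 consecutive epochs without
#' validation improvement, AdamW with weight decay 1e-10, and a 20% validation
#' split.
#'
#' @param max_epochs maximum number of epochs (>= 0).
#' @param early_stop_patience epochs without validation improvement before
#'   stopping.
#' @param batch_size cubes per optimizer step.
#' @param lr initial learning rate.
#' @param lr_factor multiplicative learning-rate decay on plateau.
#' @param lr_patience consecutive stale epochs before the decay is applied.
#' @param weight_decay decoupled (AdamW) weight decay.
#' @param val_fraction fraction of cubes held out for validation.
#' @param seed RNG seed for splitting and shuffling.
#' @return A `train_config` object.
#' @export
train_config <- function(max_epochs = 150, early_stop_patience = 36,
                         batch_size = 10, lr = 4e-4, lr_factor = 0.5,
                         lr_patience = 6, weight_decay = 1e-10,
                         val_fraction = 0.2, seed = 1) {
  stopifnot(max_epochs >= 0, early_stop_patience >= 1, batch_size >= 1,
            lr > 0, lr_factor > 0, lr_factor <= 1, lr_patience >= 1,
            weight_decay >= 0, val_fraction > 0, val_fraction < 1)
  structure(list(max_epochs = max_epochs,
                 early_stop_patience = early_stop_patience,
                 batch_size = batch_size, lr = lr, lr_factor = lr_factor,
                 lr_patience = lr_patience, weight_decay = weight_decay,
                 val_fraction = val_fraction, seed = seed),
            class = "train_config")
}

#' Split cubes into training and validation sets
#'
#' Disjoint and exhaustive: `round(val_fraction * n)` cubes go to validation,
#' the rest to training. Deterministic for a fixed seed.
#'
#' @param chunks a `chunk_pairs` tibble from [balance_chunks()] (any tibble
#'   works).
#' @param val_fraction validation fraction in (0, 1).
#' @param seed RNG seed.
#' @return List with elements `train` and `val`.
#' @export
split_train_val <- function(chunks, val_fraction = 0.2, seed = 1) {
  n <- nrow(chunks)
  if (is.null(n) || n < 2L) stop("need at least 2 chunks to split", call. = FALSE)
  n_val <- round(val_fraction * n)
  val_idx <- withr::with_seed(seed, sort(sample(n, n_val)))
  list(train = chunks[setdiff(seq_len(n), val_idx), ],
       val = chunks[val_idx, ])
}

# Improvement = strictly better than the running best by this margin.
IMPROVE_TOL <- 1e-6

#' Train a backbone on balanced chunk pairs
#'
#' Minimizes [composite_loss()] with AdamW. The learning rate is multiplied by
#' `lr_factor` after `lr_patience` consecutive epochs without validation
#' improvement; training stops after `early_stop_patience` stale epochs or at
#' `max_epochs`. The returned fit carries the parameters of the epoch with the
#' best validation loss.
#'
#' @param backbone a backbone implementing the [backbone-contract].
#' @param data a `chunk_pairs` tibble from [balance_chunks()], or a list with
#'   `train` and `val` elements from [split_train_val()].
#' @param config a [train_config()].
#' @param loss_cfg a [loss_config()].
#' @param meta optional named list recorded in the fit (e.g.
#'   `target_particle_px`, label parameters) so inference can validate
#'   compatibility.
#' @return A `tomo_fit` object: `backbone` (best checkpoint), `log` (tibble of
#'   per-epoch train/val loss and learning rate), `best_epoch`, `best_val`,
#'   `config`, `loss_cfg`, `meta`.
#' @export
train_backbone <- function(backbone, data, config = train_config(),
                           loss_cfg = loss_config(), meta = list()) {
  if (inherits(data, "chunk_pairs") || (is.data.frame(data) && "image" %in% names(data))) {
    data <- split_train_val(data, config$val_fraction, config$seed)
  }
  train <- data$train; val <- data$val
  if (nrow(train) < 1L) stop("empty training split", call. = FALSE)
  if (nrow(val) < 1L) stop("empty validation split", call. = FALSE)

  params <- bb_params(backbone)
  opt <- adamw_init(params)
  lr <- config$lr
  best_val <- Inf; best_params <- params; best_epoch <- 0L
  stale <- 0L; stale_lr <- 0L
  log <- vector("list", config$max_epochs)
  # per-chunk memoization state for backbones that cache input transforms
  train_state <- replicate(nrow(train), new.env(parent = emptyenv()))
  val_state <- replicate(nrow(val), new.env(parent = emptyenv()))

  n_epochs_run <- 0L
  withr::with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(nrow(train))
      epoch_losses <- c()
      for (s in seq(1, length(ord), by = config$batch_size)) {
        idx <- ord[s:min(s + config$batch_size - 1L, length(ord))]
        acc <- NULL; batch_loss <- 0
        for (i in idx) {
          fwd <- bb_forward(backbone, train$image[[i]], train_state[[i]])
          l <- composite_loss(fwd$output, train$label[[i]], loss_cfg)
          if (!is.finite(l)) {
            stop("non-finite training loss at epoch ", epoch,
                 " (chunk ", i, "); try a lower learning rate", call. = FALSE)
          }
          batch_loss <- batch_loss + l
          g_out <- composite_loss_grad(fwd$output, train$label[[i]], loss_cfg)
          g <- bb_backward(backbone, g_out, fwd$cache)
          acc <- if (is.null(acc)) g else mapply(`+`, acc, g, SIMPLIFY = FALSE)
        }
        epoch_losses <- c(epoch_losses, batch_loss / length(idx))
        if (length(acc) > 0) {
          acc <- lapply(acc, `/`, length(idx))
          upd <- adamw_step(opt, bb_params(backbone), acc, lr,
                            config$weight_decay)
          opt <- upd$state
          backbone <- bb_set_params(backbone, upd$params)
        }
      }
      val_loss <- mean(vapply(seq_len(nrow(val)), function(i) {
        composite_loss(bb_forward(backbone, val$image[[i]], val_state[[i]])$output,
                       val$label[[i]], loss_cfg)
      }, numeric(1)))
      log[[epoch]] <- tibble::tibble(epoch = epoch,
                                     train_loss = mean(epoch_losses),
                                     val_loss = val_loss, lr = lr)
      n_epochs_run <- epoch
      if (val_loss < best_val - IMPROVE_TOL) {
        best_val <- val_loss; best_params <- bb_params(backbone)
        best_epoch <- epoch; stale <- 0L; stale_lr <- 0L
      } else {
        stale <- stale + 1L; stale_lr <- stale_lr + 1L
        if (stale_lr >= config$lr_patience) {
          lr <- lr * config$lr_factor; stale_lr <- 0L
        }
        if (stale >= config$early_stop_patience) break
      }
    }
  })

  if (best_epoch > 0L) backbone <- bb_set_params(backbone, best_params)
  structure(list(backbone = backbone,
                 log = if (n_epochs_run > 0) dplyr::bind_rows(log[seq_len(n_epochs_run)])
                       else tibble::tibble(epoch = integer(), train_loss = numeric(),
                                           val_loss = numeric(), lr = numeric()),
                 best_epoch = best_epoch, best_val = best_val,
                 config = config, loss_cfg = loss_cfg, meta = meta),
            class = "tomo_fit")
}

#' Fine-tune a trained model
#'
#' Resumes training from the weights of an existing fit or checkpoint file
#' under an (optionally) overridden schedule — the reference fine-tuning
#' protocol is 20 epochs at a starting learning rate of 5e-5. With
#' `max_epochs = 0` the weights are returned unchanged.
#'
#' @param fit a `tomo_fit` or a checkpoint path from [save_checkpoint()].
#' @param data chunk pairs or a `train`/`val` list, as in [train_backbone()].
#' @param max_epochs,lr schedule overrides (defaults: 20 epochs, lr 5e-5).
#' @param ... further [train_config()] overrides.
#' @return A new `tomo_fit`.
#' @export
fine_tune <- function(fit, data, max_epochs = 20, lr = 5e-5, ...) {
  if (is.character(fit)) fit <- load_checkpoint(fit)
  cfg_args <- utils::modifyList(unclass(fit$config),
                                c(list(max_epochs = max_epochs, lr = lr),
                                  list(...)))
  config <- do.call(train_config, cfg_args)
  if (config$max_epochs == 0L) {
    fit$config <- config
    fit$log <- fit$log[0, ]
    return(fit)
  }
  train_backbone(fit$backbone, data, config = config, loss_cfg = fit$loss_cfg,
                 meta = fit$meta)
}

#' Save / load a training checkpoint
#'
#' The checkpoint stores the backbone constructor spec and parameters together
#' with the training, loss and preprocessing metadata, so inference can verify
#' compatibility. Stored via R serialization (`.rds`).
#'
#' @param fit a `tomo_fit`.
#' @param path output path.
#' @return `path` invisibly; `load_checkpoint()` returns the `tomo_fit`.
#' @export
save_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "tomo_fit"))
  saveRDS(list(spec = bb_spec(fit$backbone), params = bb_params(fit$backbone),
               config = fit$config, loss_cfg = fit$loss_cfg, meta = fit$meta,
               log = fit$log, best_epoch = fit$best_epoch,
               best_val = fit$best_val),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  bb <- backbone_from_spec(ck$spec)
  ref <- bb_params(bb)
  for (nm in names(ref)) {
    if (!identical(dim(ref[[nm]]) %||% length(ref[[nm]]),
                   dim(ck$params[[nm]]) %||% length(ck$params[[nm]]))) {
      stop("incompatible checkpoint: parameter `", nm, "` has shape ",
           paste(dim(ck$params[[nm]]) %||% length(ck$params[[nm]]), collapse = "x"),
           ", expected ",
           paste(dim(ref[[nm]]) %||% length(ref[[nm]]), collapse = "x"),
           call. = FALSE)
    }
  }
  bb <- bb_set_params(bb, ck$params)
  structure(list(backbone = bb, log = ck$log, best_epoch = ck$best_epoch,
                 best_val = ck$best_val, config = ck$config,
                 loss_cfg = ck$loss_cfg, meta = ck$meta),
            class = "tomo_fit")
}

#' @export
print.tomo_fit <- function(x, ...) {
  cat(sprintf("<tomo_fit> %d epoch(s), best val loss %.6g at epoch %d\n",
              nrow(x$log), x$best_val, x$best_epoch))
  invisible(x)
}

## AdamW --------------------------------------------------------------------

adamw_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adamw_step <- function(state, params, grads, lr, weight_decay) {
  state$t <- state$t + 1L
  b1 <- state$beta1; b2 <- state$beta2
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mhat <- state$m[[nm]] / (1 - b1^state$t)
    vhat <- state$v[[nm]] / (1 - b2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + state$eps) -
      lr * weight_decay * params[[nm]]
  }
  list(state = state, params = params)
}
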