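# broom-style accessors for fitted / evaluated objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a training fit
#'
#' @param x a `tomo_fit` from [train_backbone()].
#' @param ... unused.
#' @return The per-epoch training log as a tibble (`epoch`, `train_loss`,
#'   `val_loss`, `lr`).
#' @export
tidy.tomo_fit <- function(x, ...) x$log

#' One-row summary of a training fit
#'
#' @param x a `tomo_fit`.
#' @param ... unused.
#' @return A one-row tibble with epochs run, best epoch, best/final validation
#'   loss and final learning rate.
#' @export
glance.tomo_fit <- function(x, ...) {
  tibble::tibble(epochs = nrow(x$log), best_epoch = x$best_epoch,
                 best_val_loss = x$best_val,
                 final_val_loss = if (nrow(x$log)) x$log$val_loss[nrow(x$log)] else NA_real_,
                 final_lr = if (nrow(x$log)) x$log$lr[nrow(x$log)] else NA_real_)
}

#' Tidy a match result
#'
#' @param x a `match_result` from [match_centroids()].
#' @param ... unused.
#' @return The assignment pairs tibble with a `true_positive` flag.
#' @export
tidy.match_result <- function(x, ...) {
  dplyr::mutate(x$pairs, true_positive = .data$distance <= x$dist_threshold)
}

#' One-row summary of a match result
#'
#' @param x a `match_result`.
#' @param ... unused.
#' @return A one-row tibble with tp/fp/fn counts and precision/recall/F1.
#' @export
glance.match_result <- function(x, ...) {
  met <- prf(x)
  tibble::tibble(tp = x$tp, fp = x$fp, fn = x$fn,
                 precision = met[["precision"]], recall = met[["recall"]],
                 f1 = met[["f1"]], dist_threshold = x$dist_threshold)
}

#' One-row summary of a percentile sweep
#'
#' @param x a `sweep_table` from [threshold_sweep()].
#' @param ... unused.
#' @return The F1-maximal row: percentile, F1_max and normalized RMSE there.
#' @export
glance.sweep_table <- function(x, ...) {
  best <- x[x$is_best, ]
  tibble::tibble(best_percentile = best$percentile, f1_max = best$f1,
                 nrmse_at_f1max = best$nrmse)
}
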