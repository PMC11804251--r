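# Composite training loss: class-balanced per-voxel Huber term plus a
# spatial-gradient term comparing discrete second derivatives of prediction
# and label. Both terms are means over voxels so the scale is independent of
# batch and chunk size.

#' Loss parameters
#'
#' @param delta Huber transition point (default 1).
#' @param lambda_grad weight of the spatial-gradient term (default 1).
#' @param gradient_order compare second-order (default) or first-order spatial
#'   derivatives in the gradient term.
#' @return A `loss_config` object.
#' @export
loss_config <- function(delta = 1, lambda_grad = 1, gradient_order = c(2, 1)) {
  gradient_order <- as.integer(gradient_order[1])
  stopifnot(delta > 0, lambda_grad >= 0, gradient_order %in% c(1L, 2L))
  structure(list(delta = delta, lambda_grad = lambda_grad,
                 gradient_order = gradient_order),
            class = "loss_config")
}

#' Huber penalty
#'
#' `0.5 * r^2` for `|r| <= delta`, linear `delta * (|r| - delta/2)` beyond;
#' continuous and once-differentiable at the transition.
#'
#' @param residual numeric residual(s).
#' @param delta transition point (> 0).
#' @return Penalty value(s), same shape as `residual`.
#' @export
huber <- function(residual, delta = 1) {
  stopifnot(delta > 0)
  a <- abs(residual)
  ifelse(a <= delta, 0.5 * residual^2, delta * (a - 0.5 * delta))
}

huber_grad <- function(residual, delta = 1) {
  ifelse(abs(residual) <= delta, residual, delta * sign(residual))
}

#' Inverse-class-frequency voxel weights
#'
#' Voxels with label > 0 get weight `T / (2|P|)` and label-zero voxels get
#' `T / (2|N|)` where `T = |P| + |N|` is the voxel count. The total weight on
#' positives then equals the total weight on negatives and the mean weight is
#' 1, so the weighted Huber term keeps a stable scale across chunks regardless
#' of how sparse the labels are. If either class is empty all weights are 1.
#'
#' @param label label volume ([volume()] or 3D array) with values in `[0, 1]`.
#' @return A 3D weight array of the same shape.
#' @export
voxel_weights <- function(label) {
  l <- vol_data(label)
  P <- sum(l > 0)
  N <- length(l) - P
  if (P == 0L || N == 0L) return(array(1, dim = dim(l)))
  tot <- length(l)
  w <- array(tot / (2 * N), dim = dim(l))
  w[l > 0] <- tot / (2 * P)
  w
}

# Per-axis discrete derivative volumes (list of 3), replicate borders.
spatial_derivatives <- function(x, order = 2L) {
  d <- dim(x)
  lapply(1:3, function(axis) {
    M <- if (order == 2L) second_diff_matrix(d[axis]) else first_diff_matrix(d[axis])
    apply_axis_op(x, M, axis)
  })
}

# Central first difference with replicate borders (gradient_order = 1 option).
first_diff_matrix <- function(n) {
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    im <- max(1L, i - 1L); ip <- min(n, i + 1L)
    M[i, ip] <- M[i, ip] + 0.5
    M[i, im] <- M[i, im] - 0.5
  }
  M
}

#' Spatial-gradient loss
#'
#' Mean Huber penalty between per-axis discrete second derivatives
#' (`[1, -2, 1]` stencil, replicate borders) of prediction and label; three
#' derivative channels are averaged. Insensitive to adding a constant field to
#' the prediction. First-order derivatives can be selected via
#' [loss_config()].
#'
#' @param pred,label volumes or 3D arrays of identical shape.
#' @param config a [loss_config()].
#' @return Scalar loss value (>= 0).
#' @export
gradient_loss <- function(pred, label, config = loss_config()) {
  p <- vol_data(pred); l <- vol_data(label)
  if (!identical(dim(p), dim(l))) stop("shape mismatch", call. = FALSE)
  dp <- spatial_derivatives(p, config$gradient_order)
  dl <- spatial_derivatives(l, config$gradient_order)
  mean(vapply(1:3, function(a) mean(huber(dp[[a]] - dl[[a]], config$delta)),
              numeric(1)))
}

# Gradient of gradient_loss w.r.t. pred (adjoint stencil application).
gradient_loss_grad <- function(pred, label, config = loss_config()) {
  d <- dim(pred)
  g <- array(0, dim = d)
  for (axis in 1:3) {
    M <- if (config$gradient_order == 2L) second_diff_matrix(d[axis]) else
      first_diff_matrix(d[axis])
    dr <- apply_axis_op(pred - label, M, axis)
    g <- g + apply_axis_op(huber_grad(dr, config$delta), t(M), axis)
  }
  g / (3 * length(pred))
}

#' Composite training loss
#'
#' `mean(w(label) * huber(pred - label)) + lambda_grad * gradient_loss()`,
#' with weights from [voxel_weights()]. Non-negative, and zero exactly when
#' prediction equals label.
#'
#' @param pred,label volumes or 3D arrays of identical shape.
#' @param config a [loss_config()].
#' @return Scalar loss value.
#' @export
composite_loss <- function(pred, label, config = loss_config()) {
  p <- vol_data(pred); l <- vol_data(label)
  if (!identical(dim(p), dim(l))) stop("shape mismatch", call. = FALSE)
  if (!all(is.finite(p)) || !all(is.finite(l))) {
    stop("non-finite values in loss inputs", call. = FALSE)
  }
  w <- voxel_weights(l)
  term <- mean(w * huber(p - l, config$delta))
  if (config$lambda_grad > 0) {
    term <- term + config$lambda_grad * gradient_loss(p, l, config)
  }
  term
}

# Gradient of composite_loss w.r.t. pred.
composite_loss_grad <- function(pred, label, config = loss_config()) {
  w <- voxel_weights(label)
  g <- w * huber_grad(pred - label, config$delta) / length(pred)
  if (config$lambda_grad > 0) {
    g <- g + config$lambda_grad * gradient_loss_grad(pred, label, config)
  }
  g
}
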