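# Detection metrics: optimal ground-truth/prediction assignment, TP/FP/FN
# classification, precision/recall/F1, diameter-normalized RMSE and the
# confidence-percentile sweep for F1_max.

#' Optimally match predicted centroids to ground truth
#'
#' Computes the Euclidean distance matrix between ground-truth and predicted
#' coordinates and solves the minimum-total-cost one-to-one assignment of
#' `min(|gt|, |pred|)` pairs with the Jonker-Volgenant shortest augmenting
#' path algorithm. Matched pairs within `dist_threshold` are true positives;
#' surplus predictions count as false positives and surplus (or badly matched)
#' ground-truth points as false negatives.
#'
#' @param gt a [particle_set()] (or data frame with `x`, `y`, `z`), voxel
#'   units.
#' @param pred a [centroid_set()] (or data frame with `x`, `y`, `z`), same
#'   frame and units as `gt`.
#' @param dist_threshold classification distance, voxels. Defaults to half the
#'   particle diameter, taken from the `gt` attributes when available.
#' @return A `match_result`: list with `pairs` (tibble `gt`, `pred`,
#'   `distance` over the assignment), `tp`, `fp`, `fn` and `dist_threshold`.
#' @export
match_centroids <- function(gt, pred, dist_threshold = NULL) {
  if (is.null(dist_threshold)) {
    if (!is.null(attr(gt, "diameter"))) {
      dist_threshold <- radius_px(gt)
    } else {
      stop("supply `dist_threshold` (voxels) or a particle_set with a diameter",
           call. = FALSE)
    }
  }
  ng <- nrow(gt); np <- nrow(pred)
  if (ng == 0L || np == 0L) {
    return(new_match_result(tibble::tibble(gt = integer(), pred = integer(),
                                           distance = numeric()),
                            tp = 0L, fp = np, fn = ng,
                            dist_threshold = dist_threshold))
  }
  G <- as.matrix(tibble::tibble(x = gt$x, y = gt$y, z = gt$z))
  P <- as.matrix(tibble::tibble(x = pred$x, y = pred$y, z = pred$z))
  cost <- t(vapply(seq_len(ng), function(i) {
    sqrt((P[, 1] - G[i, 1])^2 + (P[, 2] - G[i, 2])^2 + (P[, 3] - G[i, 3])^2)
  }, numeric(np)))
  dim(cost) <- c(ng, np)  # vapply drops to a vector when np == 1
  assign <- solve_assignment(cost)
  pairs <- tibble::tibble(gt = assign$rows, pred = assign$cols,
                          distance = cost[cbind(assign$rows, assign$cols)])
  tp <- sum(pairs$distance <= dist_threshold)
  new_match_result(pairs, tp = tp, fp = np - tp, fn = ng - tp,
                   dist_threshold = dist_threshold)
}

new_match_result <- function(pairs, tp, fp, fn, dist_threshold) {
  structure(list(pairs = pairs, tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), dist_threshold = dist_threshold),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> tp %d, fp %d, fn %d (distance threshold %.3g)\n",
              x$tp, x$fp, x$fn, x$dist_threshold))
  invisible(x)
}

# Minimum-cost assignment over a dense cost matrix (rows <= cols after an
# internal transpose), Jonker-Volgenant / Hungarian shortest augmenting path
# with dual potentials, O(n^2 m). Returns 1-based matched row/col indices.
solve_assignment <- function(cost) {
  flipped <- FALSE
  if (nrow(cost) > ncol(cost)) { cost <- t(cost); flipped <- TRUE }
  n <- nrow(cost); m <- ncol(cost)
  u <- numeric(n + 1); v <- numeric(m + 1)
  p <- integer(m + 1)                     # p[j+1]: row assigned to col j (0 none)
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i; j0 <- 0L
    minv <- rep(Inf, m); used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]; delta <- Inf; j1 <- 0L
      free_j <- which(!used[-1])
      cur <- cost[i0, free_j] - u[i0 + 1] - v[free_j + 1]
      upd <- cur < minv[free_j]
      minv[free_j[upd]] <- cur[upd]
      way[free_j[upd] + 1] <- j0
      j1 <- free_j[which.min(minv[free_j])]
      delta <- minv[j1]
      used_j <- which(used) - 1L
      u[p[used_j + 1] + 1] <- u[p[used_j + 1] + 1] + delta
      v[used_j + 1] <- v[used_j + 1] - delta
      minv[free_j] <- minv[free_j] - delta
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  cols <- which(p[-1] > 0L)
  rows <- p[cols + 1]
  if (flipped) list(rows = cols, cols = rows) else list(rows = rows, cols = cols)
}

#' Precision, recall and F1 from a match
#'
#' `precision = tp / (tp + fp)`, `recall = tp / (tp + fn)`,
#' `F1 = 2 P R / (P + R)`. Zero-denominator conventions: precision is 0 when
#' there are no predictions, recall is 0 when there is nothing to recall and
#' no hit, and F1 is 0 when `P + R = 0`.
#'
#' @param match a `match_result` from [match_centroids()].
#' @return Named numeric vector `c(precision =, recall =, f1 =)`.
#' @export
prf <- function(match) {
  tp <- match$tp; fp <- match$fp; fn <- match$fn
  precision <- if (tp + fp == 0L) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0L) { if (tp > 0L) 1 else 0 } else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}

#' Diameter-normalized centroid RMSE
#'
#' Root-mean-square Euclidean distance over true-positive pairs, divided by
#' the particle diameter. `NA` when there are no true positives. With
#' `tp_only = FALSE` the squared distances of true positives are averaged over
#' `min(|gt|, |pred|)` instead of the TP count.
#'
#' @param match a `match_result`.
#' @param diameter particle diameter in the same units as the coordinates
#'   (voxels).
#' @param tp_only average over true positives (default) or over the smaller
#'   set size.
#' @return Normalized RMSE (>= 0) or `NA_real_`.
#' @export
normalized_rmse <- function(match, diameter, tp_only = TRUE) {
  stopifnot(diameter > 0)
  d <- match$pairs$distance[match$pairs$distance <= match$dist_threshold]
  if (length(d) == 0L) return(NA_real_)
  denom <- if (tp_only) length(d) else min(match$tp + match$fn, match$tp + match$fp)
  sqrt(sum(d^2) / denom) / diameter
}

#' Confidence-percentile sweep for F1_max
#'
#' For each percentile of the pooled prediction confidences (2% to 98% in
#' steps of 8%), retains the predictions with confidence at or above that
#' percentile value and recomputes matching, precision/recall/F1 and
#' normalized RMSE. The row attaining the maximal F1 is flagged (ties go to
#' the lowest percentile).
#'
#' @param gt ground truth, as in [match_centroids()].
#' @param pred a [centroid_set()] with a `confidence` column; must be
#'   non-empty.
#' @param diameter particle diameter in coordinate units (voxels); also sets
#'   the classification threshold to `diameter / 2`.
#' @param percentiles percentiles swept (default `seq(2, 98, by = 8)`).
#' @return A `sweep_table` tibble with columns `percentile`, `threshold`,
#'   `n_kept`, `tp`, `fp`, `fn`, `precision`, `recall`, `f1`, `nrmse`,
#'   `is_best`.
#' @export
threshold_sweep <- function(gt, pred, diameter,
                            percentiles = seq(2, 98, by = 8)) {
  if (nrow(pred) == 0L) stop("empty prediction set; nothing to sweep",
                             call. = FALSE)
  rows <- lapply(percentiles, function(p) {
    # type 1 (inverse ECDF): thresholds are observed confidence values, so a
    # sweep over a perfect prediction keeps every point at low percentiles
    thr <- stats::quantile(pred$confidence, p / 100, names = FALSE, type = 1)
    keep <- pred$confidence >= thr
    mt <- match_centroids(gt, pred[keep, ], dist_threshold = diameter / 2)
    met <- prf(mt)
    tibble::tibble(percentile = p, threshold = thr, n_kept = sum(keep),
                   tp = mt$tp, fp = mt$fp, fn = mt$fn,
                   precision = met[["precision"]], recall = met[["recall"]],
                   f1 = met[["f1"]],
                   nrmse = normalized_rmse(mt, diameter))
  })
  out <- dplyr::bind_rows(rows)
  out$is_best <- seq_len(nrow(out)) == which.max(out$f1)
  structure(out, class = c("sweep_table", class(out)))
}
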