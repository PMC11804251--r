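# Centroid extraction: cubic-neighbourhood peak detection with greedy
# non-maximum suppression, confidence thresholding, mask gating and rescaling
# back to original coordinates.

#' Extract centroids from a confidence map
#'
#' A voxel is a peak candidate iff its value is >= every value in its centred
#' cubic neighbourhood of side `2 * floor(min_distance / 2) + 1`. Candidates
#' are processed in order of decreasing confidence (ties broken toward the
#' lexicographically smallest `(z, y, x)` index); any candidate within
#' Chebyshev distance `< min_distance` of an already accepted peak is
#' suppressed. Finally peaks with confidence below `threshold` are dropped
#' (comparison is `>=`, so a threshold of 1 retains saturated peaks).
#'
#' @param map a `confidence_map`/[volume()] or 3D array.
#' @param min_distance side of the cubic suppression neighbourhood, voxels;
#'   defaults to 10, the particle diameter on the standard rescaled grid.
#' @param threshold confidence cutoff (default 0.3).
#' @return A [centroid_set()] in the `"rescaled"` frame, sorted by decreasing
#'   confidence; coordinates are 0-based voxel indices.
#' @export
find_peaks <- function(map, min_distance = 10, threshold = 0.3) {
  m <- vol_data(map)
  if (!all(is.finite(m))) stop("confidence map contains non-finite values",
                               call. = FALSE)
  stopifnot(min_distance >= 1)
  w <- floor(min_distance / 2)
  mx <- max_filter3(m, w)
  cand <- which(m >= mx, arr.ind = TRUE)   # (z, y, x), 1-based
  conf <- m[cand]
  ord <- order(-conf, cand[, 1], cand[, 2], cand[, 3])
  cand <- cand[ord, , drop = FALSE]; conf <- conf[ord]
  n <- nrow(cand)
  keep <- logical(n)
  acc <- matrix(numeric(0), ncol = 3)
  for (i in seq_len(n)) {
    if (nrow(acc) == 0L ||
        all(pmax(abs(acc[, 1] - cand[i, 1]), abs(acc[, 2] - cand[i, 2]),
                 abs(acc[, 3] - cand[i, 3])) >= min_distance)) {
      keep[i] <- TRUE
      acc <- rbind(acc, cand[i, , drop = FALSE])
    }
  }
  sel <- keep & conf >= threshold
  centroid_set(tibble::tibble(x = cand[sel, 3] - 1, y = cand[sel, 2] - 1,
                              z = cand[sel, 1] - 1, confidence = conf[sel]),
               min_distance = min_distance, threshold = threshold,
               frame = "rescaled")
}

#' Gate centroids by a mask volume
#'
#' Keeps the centroids whose nearest voxel has a positive mask value; scores
#' are unchanged. The mask must live on the same grid as the detection frame.
#'
#' @param centroids a [centroid_set()].
#' @param mask a [volume()] or 3D array, same shape as the detection grid.
#' @return The filtered [centroid_set()].
#' @export
apply_mask <- function(centroids, mask) {
  m <- vol_data(mask)
  if (nrow(centroids) == 0L) return(centroids)
  iz <- round(centroids$z) + 1L; iy <- round(centroids$y) + 1L
  ix <- round(centroids$x) + 1L
  d <- dim(m)
  if (any(iz < 1L | iz > d[1] | iy < 1L | iy > d[2] | ix < 1L | ix > d[3])) {
    stop("centroid outside the mask volume; mask/detection grids mismatch",
         call. = FALSE)
  }
  keep <- m[cbind(iz, iy, ix)] > 0
  centroid_set(tibble::tibble(x = centroids$x[keep], y = centroids$y[keep],
                              z = centroids$z[keep],
                              confidence = centroids$confidence[keep]),
               min_distance = attr(centroids, "min_distance"),
               threshold = attr(centroids, "threshold"),
               frame = centroid_frame(centroids))
}

#' Map centroids back to the original pixel grid
#'
#' Inverts the rescaling applied during preprocessing: coordinates are divided
#' by `scale` and the frame flips to `"original"`. Scores are unchanged.
#'
#' @param centroids a [centroid_set()] in the `"rescaled"` frame.
#' @param scale the scale factor that was applied to the original tomogram
#'   (from [compute_scale()]; > 0).
#' @return A [centroid_set()] in the `"original"` frame.
#' @export
to_original_frame <- function(centroids, scale) {
  stopifnot(scale > 0)
  if (centroid_frame(centroids) != "rescaled") {
    stop("centroids are already in the original frame", call. = FALSE)
  }
  pts <- tibble::tibble(x = centroids$x / scale, y = centroids$y / scale,
                        z = centroids$z / scale,
                        confidence = centroids$confidence)
  centroid_set(pts, min_distance = attr(centroids, "min_distance"),
               threshold = attr(centroids, "threshold"), frame = "original")
}
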