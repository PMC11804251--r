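# Tomogram preprocessing: rescaling to a target particle size, robust
# intensity normalization, overlapping chunk extraction and class balancing.

#' Scale factor bringing a particle to the target pixel size
#'
#' Training and inference operate at a sampling rate at which the particle
#' diameter spans `target_particle_px` voxels. The returned factor multiplies
#' the grid (shape), so downscaling has `scale < 1`; the rescaled voxel size is
#' `voxel_size / scale`.
#'
#' @param voxel_size Angstrom per pixel of the input tomogram.
#' @param diameter particle diameter, Angstrom.
#' @param target_particle_px target particle diameter in voxels (default 10).
#' @return The scale factor `target_particle_px / (diameter / voxel_size)`.
#' @export
compute_scale <- function(voxel_size, diameter, target_particle_px = 10) {
  stopifnot(voxel_size > 0, diameter > 0, target_particle_px > 0)
  target_particle_px / (diameter / voxel_size)
}

#' Resize a volume by trilinear resampling
#'
#' Output dimensions are `round(dim * scale)` (at least 1). Resampling is
#' separable linear interpolation; when `scale < 1` the interpolation kernel
#' support is widened by `1 / scale` (anti-aliased resize), so downscaling
#' averages rather than subsamples and a down/up round trip approximately
#' conserves total image mass. Constant volumes remain constant and the voxel
#' size is divided by the scale.
#'
#' @param vol a [volume()].
#' @param scale positive scale factor.
#' @return The resized [volume()].
#' @export
resize_volume <- function(vol, scale) {
  stopifnot(is_volume(vol), scale > 0)
  d <- dim(vol$data)
  if (identical(scale, 1) || isTRUE(all.equal(scale, 1))) return(vol)
  d_out <- pmax(1L, as.integer(round(d * scale)))
  x <- vol$data
  for (axis in 1:3) {
    x <- apply_axis_op(x, resample_matrix(d[axis], d_out[axis], scale), axis)
  }
  vol_update(vol, x, voxel_size = vol$voxel_size / scale)
}

#' Robust intensity normalization
#'
#' Centres on the median and scales by the interquartile range:
#' `(x - median) / IQR`. The output has median ~0 and IQR ~1, making training
#' statistics comparable across tomograms reconstructed or filtered by
#' different software.
#'
#' @param vol a [volume()].
#' @return The normalized [volume()].
#' @export
robust_normalize <- function(vol) {
  stopifnot(is_volume(vol))
  q <- stats::quantile(vol$data, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3] - q[1]
  if (iqr <= 0) {
    stop("volume interquartile range is zero (constant or near-constant ",
         "intensities); check the input tomogram before normalizing",
         call. = FALSE)
  }
  vol_update(vol, (vol$data - q[2]) / iqr)
}

#' Split a volume into overlapping cubes
#'
#' Per axis the chunk origins are `0, stride, 2*stride, ...`, plus a final
#' origin clamped to `dim - chunk_size` whenever the last strided window does
#' not reach the boundary, so every voxel is covered. Volumes smaller than one
#' chunk are zero-padded up to `chunk_size` (the padding is recorded).
#'
#' @param vol a [volume()] or 3D array.
#' @param chunk_size cube edge, voxels (default 64).
#' @param stride offset between cube origins, voxels (default 32).
#' @return A `chunk_set`: a tibble with integer origin columns `oz`, `oy`,
#'   `ox` (0-based) and a `data` list-column of `chunk_size^3` arrays;
#'   attributes `chunk_size`, `stride`, `source_shape`, `padded_shape`.
#' @export
chunk_volume <- function(vol, chunk_size = 64, stride = 32) {
  x <- vol_data(vol)
  stopifnot(chunk_size >= 1, stride >= 1)
  src <- dim(x)
  pad <- pmax(0L, chunk_size - src)
  if (any(pad > 0L)) {
    y <- array(0, dim = pmax(src, chunk_size))
    y[seq_len(src[1]), seq_len(src[2]), seq_len(src[3])] <- x
    x <- y
  }
  d <- dim(x)
  origins <- lapply(d, function(n) {
    o <- seq(0L, n - chunk_size, by = stride)
    if (o[length(o)] + chunk_size < n) o <- c(o, n - chunk_size)
    as.integer(o)
  })
  grid <- expand.grid(oz = origins[[1]], oy = origins[[2]], ox = origins[[3]],
                      KEEP.OUT.ATTRS = FALSE)
  chunks <- purrr::pmap(grid, function(oz, oy, ox) {
    x[(oz + 1):(oz + chunk_size), (oy + 1):(oy + chunk_size),
      (ox + 1):(ox + chunk_size)]
  })
  out <- tibble::as_tibble(grid)
  out$data <- chunks
  structure(out,
            chunk_size = as.integer(chunk_size), stride = as.integer(stride),
            source_shape = src, padded_shape = dim(x),
            class = c("chunk_set", class(out)))
}

#' Balance positive and negative training cubes
#'
#' Keeps every cube whose label contains at least one positive voxel
#' (label > 0) and adds an equal number of negative cubes sampled uniformly
#' without replacement (all negatives if fewer are available). Deterministic
#' for a fixed seed.
#'
#' @param image_chunks,label_chunks congruent `chunk_set`s from
#'   [chunk_volume()] applied to the tomogram and its label volume.
#' @param seed RNG seed for the negative sample.
#' @return A `chunk_pairs` tibble with columns `oz`, `oy`, `ox`, `image`,
#'   `label`, `positive`.
#' @export
balance_chunks <- function(image_chunks, label_chunks, seed = 1) {
  if (nrow(image_chunks) != nrow(label_chunks) ||
      !all(image_chunks$oz == label_chunks$oz &
           image_chunks$oy == label_chunks$oy &
           image_chunks$ox == label_chunks$ox)) {
    stop("image and label chunk grids are not congruent", call. = FALSE)
  }
  positive <- vapply(label_chunks$data, function(l) any(l > 0), TRUE)
  if (!any(positive)) {
    stop("no cube contains a positively annotated voxel; nothing to train on",
         call. = FALSE)
  }
  neg_idx <- which(!positive)
  n_neg <- min(sum(positive), length(neg_idx))
  keep_neg <- if (n_neg > 0) {
    withr::with_seed(seed, sort(sample(neg_idx, n_neg)))
  } else integer()
  keep <- sort(c(which(positive), keep_neg))
  out <- tibble::tibble(
    oz = image_chunks$oz[keep], oy = image_chunks$oy[keep],
    ox = image_chunks$ox[keep],
    image = image_chunks$data[keep], label = label_chunks$data[keep],
    positive = positive[keep]
  )
  structure(out,
            chunk_size = attr(image_chunks, "chunk_size"),
            stride = attr(image_chunks, "stride"),
            class = c("chunk_pairs", class(out)))
}
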