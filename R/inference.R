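# Full-volume prediction by tiled inference with overlap stitching.

#' Predict a confidence map for a whole tomogram
#'
#' Splits the volume into overlapping cubes with the same clamped-origin
#' tiling used for training ([chunk_volume()]), runs the backbone on each cube
#' independently and fuses overlapping predictions by averaging (optionally
#' cosine-window weighted to suppress seams). The result is clamped to
#' `[0, 1]` so downstream confidence thresholds keep their meaning regardless
#' of the backbone's output range.
#'
#' If `diameter` is given the input is treated as a raw tomogram: it is first
#' rescaled so the particle spans `target_particle_px` voxels and robustly
#' normalized. Otherwise the input must already be rescaled and normalized.
#'
#' @param backbone a backbone implementing the [backbone-contract], or a
#'   `tomo_fit` (its best backbone is used).
#' @param vol a [volume()].
#' @param chunk_size,stride tiling parameters (defaults 64 / 32).
#' @param diameter particle diameter in Angstrom; triggers rescaling +
#'   normalization of raw input.
#' @param target_particle_px target particle size used when rescaling.
#' @param window `"flat"` for plain averaging (default) or `"cosine"` for
#'   Hann-window weighting.
#' @param clamp clamp the fused map to `[0, 1]`? (default TRUE)
#' @return A `confidence_map`: a [volume()] on the (rescaled) grid with a
#'   `provenance` attribute recording the scale factor, tiling and backbone.
#' @export
predict_volume <- function(backbone, vol, chunk_size = 64, stride = 32,
                           diameter = NULL, target_particle_px = 10,
                           window = c("flat", "cosine"), clamp = TRUE) {
  window <- match.arg(window)
  if (inherits(backbone, "tomo_fit")) backbone <- backbone$backbone
  stopifnot(is_volume(vol))
  scale <- 1
  if (!is.null(diameter)) {
    scale <- compute_scale(vol$voxel_size, diameter, target_particle_px)
    vol <- robust_normalize(resize_volume(vol, scale))
  }
  chunks <- chunk_volume(vol$data, chunk_size = chunk_size, stride = stride)
  padded <- attr(chunks, "padded_shape")
  src <- attr(chunks, "source_shape")
  acc <- array(0, dim = padded)
  wt <- array(0, dim = padded)
  w_chunk <- if (window == "cosine") hann_window3(chunk_size) else
    array(1, dim = rep(chunk_size, 3))
  for (i in seq_len(nrow(chunks))) {
    oz <- chunks$oz[i]; oy <- chunks$oy[i]; ox <- chunks$ox[i]
    pred <- bb_apply(backbone, chunks$data[[i]])
    if (!identical(dim(pred), dim(chunks$data[[i]]))) {
      stop("backbone output shape ", paste(dim(pred), collapse = "x"),
           " does not match chunk shape", call. = FALSE)
    }
    zi <- (oz + 1):(oz + chunk_size); yi <- (oy + 1):(oy + chunk_size)
    xi <- (ox + 1):(ox + chunk_size)
    acc[zi, yi, xi] <- acc[zi, yi, xi] + pred * w_chunk
    wt[zi, yi, xi] <- wt[zi, yi, xi] + w_chunk
  }
  fused <- acc / wt
  fused <- fused[seq_len(src[1]), seq_len(src[2]), seq_len(src[3]), drop = FALSE]
  if (clamp) fused <- pmin(pmax(fused, 0), 1)
  out <- volume(fused, voxel_size = vol$voxel_size, origin = vol$origin)
  attr(out, "provenance") <- list(scale = scale, chunk_size = chunk_size,
                                  stride = stride, window = window,
                                  backbone = class(backbone)[1])
  class(out) <- c("confidence_map", class(out))
  out
}

# Separable 3D Hann window, strictly positive so stitching weights never
# vanish at chunk faces.
hann_window3 <- function(n) {
  w1 <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 0.5) / n)
  w1 <- pmax(w1, 1e-3)
  outer(outer(w1, w1), w1) |> array(dim = c(n, n, n))
}
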