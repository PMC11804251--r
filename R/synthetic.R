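# Phantom tomogram simulation: solid spheres of known radius at known centres
# with additive Gaussian noise at a controlled signal-to-noise ratio, so every
# pipeline stage is testable without experimental data.

#' Phantom simulation parameters
#'
#' Defaults describe the standard synthetic study conditions used throughout
#' the package tests: a 96^3 volume with 12 dark spheres of radius 5 voxels at
#' SNR 0.5. SNR is defined as `density_contrast^2 / noise variance` (the
#' definition is stated because "SNR" is overloaded in cryo-ET; real tomograms
#' sit below 0.1 on this scale). Centres are snapped to the voxel grid so the
#' returned ground truth is exact.
#'
#' @param shape output dimensions `c(nz, ny, nx)` (default `c(96, 96, 96)`).
#' @param n_particles number of spheres (default 12).
#' @param radius_px sphere radius in voxels (default 5).
#' @param density_contrast particle-minus-background amplitude; negative by
#'   default because cryo densities are conventionally dark (default -1).
#' @param snr target `contrast^2 / noise variance` (default 0.5).
#' @param min_separation minimum pairwise centre distance, voxels (default
#'   `2 * radius_px`, i.e. non-overlapping spheres).
#' @param wedge_blur optional anisotropic Gaussian sigmas `c(z, y, x)` (or a
#'   single `c(z, xy)` pair) emulating missing-wedge elongation; `NULL`
#'   disables it.
#' @param voxel_size Angstrom per pixel of the phantom grid (default 10, so
#'   the default sphere has a 100 Angstrom diameter and is already at the
#'   standard 10-pixel target size).
#' @param seed RNG seed.
#' @return A `phantom_params` object.
#' @export
phantom_params <- function(shape = c(96, 96, 96), n_particles = 12,
                           radius_px = 5, density_contrast = -1, snr = 0.5,
                           min_separation = 2 * radius_px, wedge_blur = NULL,
                           voxel_size = 10, seed = 1) {
  stopifnot(length(shape) == 3L, all(shape >= 1), n_particles >= 0,
            radius_px >= 1, snr > 0, min_separation >= 0, voxel_size > 0,
            density_contrast != 0)
  structure(list(shape = as.integer(shape), n_particles = as.integer(n_particles),
                 radius_px = radius_px, density_contrast = density_contrast,
                 snr = snr, min_separation = min_separation,
                 wedge_blur = wedge_blur, voxel_size = voxel_size, seed = seed),
            class = "phantom_params")
}

#' Simulate a phantom tomogram
#'
#' Places `n_particles` solid spheres at rejection-sampled grid centres with
#' pairwise distance >= `min_separation` and full containment, optionally
#' applies an anisotropic Gaussian blur, and adds Gaussian noise with standard
#' deviation `|density_contrast| / sqrt(snr)`. Deterministic for a fixed seed.
#'
#' @param params a [phantom_params()].
#' @return List with `volume` (the noisy [volume()]), `particles` (a
#'   [particle_set()] of the placed centres) and `clean` (the noise-free
#'   volume, for SNR checks).
#' @export
simulate_tomogram <- function(params = phantom_params()) {
  stopifnot(inherits(params, "phantom_params"))
  shp <- params$shape
  R <- params$radius_px
  rad <- ceiling(R)
  lim <- c(shp[3], shp[2], shp[1]) - 1 - rad   # x, y, z upper bounds
  if (params$n_particles > 0 && any(lim < rad)) {
    stop("volume too small to contain a sphere of radius ", R, call. = FALSE)
  }
  withr::with_seed(params$seed, {
    centers <- matrix(numeric(0), ncol = 3)
    attempts <- 0L
    budget <- max(1000L, 500L * params$n_particles)
    while (nrow(centers) < params$n_particles) {
      attempts <- attempts + 1L
      if (attempts > budget) {
        stop("could not place ", params$n_particles, " spheres with ",
             "min_separation ", params$min_separation, " after ", budget,
             " attempts; reduce the density", call. = FALSE)
      }
      cand <- floor(runif(3, rad, lim + 1))    # x, y, z on the grid
      ok <- nrow(centers) == 0L ||
        all(sqrt(colSums((t(centers) - cand)^2)) >= params$min_separation)
      if (ok) centers <- rbind(centers, cand)
    }

    clean <- array(0, dim = shp)
    for (k in seq_len(nrow(centers))) {
      cx <- centers[k, 1]; cy <- centers[k, 2]; cz <- centers[k, 3]
      zr <- (cz - rad):(cz + rad); yr <- (cy - rad):(cy + rad)
      xr <- (cx - rad):(cx + rad)
      g <- expand.grid(z = zr, y = yr, x = xr)
      ins <- (g$x - cx)^2 + (g$y - cy)^2 + (g$z - cz)^2 <= R^2
      clean[cbind(g$z, g$y, g$x)[ins, , drop = FALSE] + 1L] <-
        params$density_contrast
    }
    if (!is.null(params$wedge_blur)) {
      sig <- params$wedge_blur
      if (length(sig) == 2L) sig <- c(sig[1], sig[2], sig[2])
      stopifnot(length(sig) == 3L)
      for (axis in 1:3) {
        clean <- apply_axis_op(clean, gaussian_blur_matrix(shp[axis], sig[axis]),
                               axis)
      }
    }
    noise_sd <- abs(params$density_contrast) / sqrt(params$snr)
    noisy <- clean + array(stats::rnorm(prod(shp), sd = noise_sd), dim = shp)
  })

  coords <- tibble::tibble(x = centers[, 1], y = centers[, 2], z = centers[, 3])
  list(volume = volume(noisy, voxel_size = params$voxel_size),
       particles = particle_set(coords,
                                diameter = 2 * R * params$voxel_size,
                                voxel_size = params$voxel_size,
                                tomo_id = sprintf("phantom_seed%d", params$seed)),
       clean = volume(clean, voxel_size = params$voxel_size))
}
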