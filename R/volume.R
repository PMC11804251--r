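#' Construct a tomogram volume
#'
#' A `tomo_volume` wraps a 3D numeric array together with its physical voxel
#' size. The array uses depth-height-width (Z, Y, X) axis order, so
#' `vol$data[z + 1, y + 1, x + 1]` is the voxel at 0-based grid position
#' `(x, y, z)`. Coordinates throughout the package are 0-based voxel indices
#' in X, Y, Z order, matching how they are written to STAR files.
#'
#' @param data 3D numeric array, axis order Z, Y, X.
#' @param voxel_size voxel edge length in Angstrom per pixel (isotropic, > 0).
#' @param origin physical offset of the volume origin in Angstrom, length 3.
#' @return A `tomo_volume` object.
#' @examples
#' v <- volume(array(0, dim = c(8, 8, 8)), voxel_size = 10)
#' dim(v)
#' @export
volume <- function(data, voxel_size = 1, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3D array (Z, Y, X axis order)", call. = FALSE)
  }
  if (any(dim(data) < 1L)) stop("all three dimensions must be >= 1", call. = FALSE)
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || !is.finite(voxel_size) ||
      voxel_size <= 0) {
    stop("`voxel_size` must be a single positive number (Angstrom/pixel)", call. = FALSE)
  }
  storage.mode(data) <- "double"
  structure(
    list(data = data, voxel_size = as.numeric(voxel_size),
         origin = as.numeric(origin)),
    class = "tomo_volume"
  )
}

#' @export
dim.tomo_volume <- function(x) dim(x$data)

#' @export
print.tomo_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<tomo_volume> %d x %d x %d voxels (Z x Y x X), %.4g A/px\n",
              d[1], d[2], d[3], x$voxel_size))
  rng <- range(x$data)
  cat(sprintf("  values in [%.4g, %.4g], mean %.4g\n", rng[1], rng[2], mean(x$data)))
  invisible(x)
}

#' @export
as.array.tomo_volume <- function(x, ...) x$data

is_volume <- function(x) inherits(x, "tomo_volume")

# Accept either a tomo_volume or a bare 3D array; return the array.
vol_data <- function(x) {
  if (is_volume(x)) x$data
  else if (is.array(x) && length(dim(x)) == 3L) x
  else stop("expected a tomo_volume or a 3D array", call. = FALSE)
}

# Replace the data of a volume, keeping metadata (optionally new voxel size).
vol_update <- function(x, data, voxel_size = NULL) {
  volume(data,
         voxel_size = if (is.null(voxel_size)) x$voxel_size else voxel_size,
         origin = x$origin)
}
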