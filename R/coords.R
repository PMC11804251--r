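# Particle and centroid coordinate containers, plus STAR / point-text I/O.
#
# Coordinates are 0-based voxel indices in X, Y, Z order. A particle written
# at array index (z, y, x) therefore has rlnCoordinateX = x - 1 when the array
# index is 1-based; helper functions below keep that bookkeeping in one place.

#' Ground-truth particle coordinates
#'
#' A `particle_set` is a tibble of particle centroids (columns `x`, `y`, `z`,
#' 0-based voxel units of a reference tomogram) carrying the shared particle
#' diameter (Angstrom), the voxel size of the reference frame and a tomogram
#' identifier as attributes.
#'
#' @param coords data frame with numeric columns `x`, `y`, `z` (voxel units).
#' @param diameter particle diameter in Angstrom (> 0). For nonspherical
#'   particles use the longest axis.
#' @param voxel_size Angstrom per pixel of the reference tomogram.
#' @param tomo_id identifier string for the reference tomogram.
#' @return A `particle_set` tibble.
#' @export
particle_set <- function(coords, diameter, voxel_size = 1, tomo_id = "tomo") {
  coords <- tibble::as_tibble(coords)
  stopifnot(all(c("x", "y", "z") %in% names(coords)))
  if (!all(vapply(coords[c("x", "y", "z")], function(c) all(is.finite(c)), TRUE))) {
    stop("particle coordinates must be finite", call. = FALSE)
  }
  if (!is.numeric(diameter) || diameter <= 0) {
    stop("`diameter` must be a positive number (Angstrom)", call. = FALSE)
  }
  if (voxel_size <= 0) stop("`voxel_size` must be positive", call. = FALSE)
  structure(coords,
            diameter = as.numeric(diameter),
            voxel_size = as.numeric(voxel_size),
            tomo_id = tomo_id,
            class = c("particle_set", class(coords)))
}

#' Particle radius in voxels
#'
#' @param particles a [particle_set()].
#' @return `diameter / (2 * voxel_size)`, the particle radius in voxel units.
#' @export
radius_px <- function(particles) {
  attr(particles, "diameter") / (2 * attr(particles, "voxel_size"))
}

#' Predicted centroids with confidence scores
#'
#' @param points data frame with numeric columns `x`, `y`, `z` (0-based voxel
#'   units) and `confidence`.
#' @param min_distance the peak-suppression distance used at detection, voxels.
#' @param threshold the confidence cutoff used at detection.
#' @param frame `"rescaled"` (detection grid) or `"original"` (input tomogram
#'   grid).
#' @return A `centroid_set` tibble sorted by decreasing confidence.
#' @export
centroid_set <- function(points, min_distance = NA_real_, threshold = NA_real_,
                         frame = c("rescaled", "original")) {
  frame <- match.arg(frame)
  points <- tibble::as_tibble(points)
  stopifnot(all(c("x", "y", "z", "confidence") %in% names(points)))
  points <- points[order(-points$confidence, points$z, points$y, points$x), ]
  structure(points,
            min_distance = min_distance,
            threshold = threshold,
            frame = frame,
            class = c("centroid_set", class(points)))
}

centroid_frame <- function(x) attr(x, "frame")

#' Read particle coordinates from a STAR file or point text
#'
#' STAR input must contain a `loop_` with `_rlnCoordinateX/Y/Z` columns
#' (RELION convention, values in voxel units of the reference tomogram);
#' unknown extra columns are preserved as additional tibble columns.
#' `point_text` input is whitespace-separated `x y z`, one particle per line
#' (the format produced by IMOD's `model2point`).
#'
#' @param path input file.
#' @param format `"star"` or `"point_text"`.
#' @param diameter particle diameter, Angstrom.
#' @param voxel_size Angstrom per pixel of the reference tomogram.
#' @param tomo_id identifier for the reference tomogram.
#' @return A [particle_set()]. An empty file yields an empty set with a
#'   warning.
#' @export
read_coordinates <- function(path, format = c("star", "point_text"),
                             diameter, voxel_size = 1, tomo_id = "tomo") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("coordinate file does not exist: ", path, call. = FALSE)
  tab <- if (format == "star") read_star_table(path) else read_point_text(path)
  if (nrow(tab) == 0L) {
    warning("no coordinate records in ", path, "; returning an empty particle set")
  }
  particle_set(tab, diameter = diameter, voxel_size = voxel_size, tomo_id = tomo_id)
}

read_point_text <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(tibble::tibble(x = numeric(), y = numeric(), z = numeric()))
  fields <- strsplit(lines, "\\s+")
  bad <- which(vapply(fields, length, 1L) < 3L)
  if (length(bad) > 0L) {
    stop("unparseable point line ", bad[1], ": '", lines[bad[1]], "'", call. = FALSE)
  }
  vals <- vapply(fields, function(f) {
    v <- suppressWarnings(as.numeric(f[1:3]))
    if (any(is.na(v))) stop("unparseable point line: '", paste(f, collapse = " "),
                            "'", call. = FALSE)
    v
  }, numeric(3))
  tibble::tibble(x = vals[1, ], y = vals[2, ], z = vals[3, ])
}

# Minimal STAR reader: first data_ block, loop_ records, _rln column tags.
read_star_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  stripped <- trimws(lines)
  loop_at <- which(stripped == "loop_")
  if (length(loop_at) == 0L) {
    if (all(!nzchar(stripped))) {
      return(tibble::tibble(x = numeric(), y = numeric(), z = numeric()))
    }
    stop("no loop_ block found in STAR file ", path, call. = FALSE)
  }
  i <- loop_at[1] + 1L
  cols <- character()
  while (i <= length(stripped) && startsWith(stripped[i], "_")) {
    cols <- c(cols, sub("\\s+#\\d+\\s*$", "", sub("^_", "", stripped[i])))
    i <- i + 1L
  }
  rows <- character()
  while (i <= length(stripped)) {
    ln <- stripped[i]
    if (!nzchar(ln) || startsWith(ln, "data_") || ln == "loop_") break
    if (!startsWith(ln, "#")) rows <- c(rows, ln)
    i <- i + 1L
  }
  req <- c("rlnCoordinateX", "rlnCoordinateY", "rlnCoordinateZ")
  missing_cols <- setdiff(req, cols)
  if (length(missing_cols) > 0L) {
    stop("STAR file ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(x = numeric(), y = numeric(), z = numeric()))
  }
  fields <- strsplit(rows, "\\s+")
  nf <- vapply(fields, length, 1L)
  if (any(nf != length(cols))) {
    stop("STAR row with ", nf[nf != length(cols)][1], " fields; expected ",
         length(cols), call. = FALSE)
  }
  mat <- do.call(rbind, fields)
  out <- tibble::tibble(
    x = as.numeric(mat[, match("rlnCoordinateX", cols)]),
    y = as.numeric(mat[, match("rlnCoordinateY", cols)]),
    z = as.numeric(mat[, match("rlnCoordinateZ", cols)])
  )
  if (any(is.na(out$x) | is.na(out$y) | is.na(out$z))) {
    stop("non-numeric coordinate value in STAR file ", path, call. = FALSE)
  }
  extra <- setdiff(cols, req)
  for (cn in extra) {
    v <- mat[, match(cn, cols)]
    num <- suppressWarnings(as.numeric(v))
    out[[map_star_extra(cn)]] <- if (all(!is.na(num))) num else v
  }
  out
}

# rlnAutopickFigureOfMerit round-trips into the `confidence` column.
map_star_extra <- function(name) {
  if (name == "rlnAutopickFigureOfMerit") "confidence" else name
}

#' Write centroids to a RELION-style STAR file
#'
#' Coordinates are multiplied by `scale_to_original` so that files refer to the
#' original (pre-resize) pixel grid, and written as floating point without
#' rounding. Confidence scores go to `rlnAutopickFigureOfMerit`.
#'
#' @param centroids a [centroid_set()] or [particle_set()].
#' @param path output path.
#' @param scale_to_original multiplicative factor from the centroid frame to
#'   the original pixel grid (> 0). Use `1 / scale` after downscaling by
#'   `scale`.
#' @param tomo_name optional `rlnTomoName` value written per row.
#' @return `path`, invisibly.
#' @export
write_star <- function(centroids, path, scale_to_original = 1, tomo_name = NULL) {
  if (!is.numeric(scale_to_original) || scale_to_original <= 0) {
    stop("`scale_to_original` must be a positive number", call. = FALSE)
  }
  x <- centroids$x * scale_to_original
  y <- centroids$y * scale_to_original
  z <- centroids$z * scale_to_original
  if (length(x) > 0 && !all(is.finite(c(x, y, z)))) {
    stop("centroid coordinates must be finite", call. = FALSE)
  }
  conf <- if ("confidence" %in% names(centroids)) centroids$confidence else
    rep(1, length(x))
  cols <- c("rlnCoordinateX", "rlnCoordinateY", "rlnCoordinateZ",
            "rlnAutopickFigureOfMerit")
  vals <- list(format(x, trim = TRUE, digits = 15),
               format(y, trim = TRUE, digits = 15),
               format(z, trim = TRUE, digits = 15),
               format(conf, trim = TRUE, digits = 15))
  if (!is.null(tomo_name)) {
    cols <- c(cols, "rlnTomoName")
    vals <- c(vals, list(rep(tomo_name, length(x))))
  }
  header <- c("", "data_particles", "", "loop_",
              sprintf("_%s #%d", cols, seq_along(cols)))
  body <- if (length(x) == 0L) character() else do.call(paste, vals)
  writeLines(c(header, body), path)
  invisible(path)
}
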