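# MRC2014 volume I/O.
#
# The MRC header is 1024 bytes of little-endian int32/float32 words; voxel
# data follow (after any extended header), X fastest, Z slowest. In memory the
# package uses Z,Y,X axis order, so arrays are permuted on the way in and out.
# Written files are always mode 2 (float32) with mapc/mapr/maps = 1/2/3.

MRC_MODE_BYTES <- c(`0` = 1L, `1` = 2L, `2` = 4L, `12` = 2L)

#' Read an MRC volume
#'
#' Supports MRC2014 modes 0 (int8), 1 (int16), 2 (float32) and 12 (float16).
#' The voxel size is taken from the cell dimensions divided by the grid size;
#' non-orthogonal cells and exotic axis orderings are rejected.
#'
#' @param path path to an MRC file.
#' @return A [volume()] with data in Z,Y,X axis order and `voxel_size` in
#'   Angstrom per pixel.
#' @seealso [write_volume()]
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("MRC file does not exist: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))

  ints <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nx <- ints[1]; ny <- ints[2]; nz <- ints[3]; mode <- ints[4]
  mx <- ints[8]; my <- ints[9]; mz <- ints[10]
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  readBin(con, "numeric", n = 3, size = 4, endian = "little")  # cell angles
  maps <- readBin(con, "integer", n = 3, size = 4, endian = "little")
  readBin(con, "numeric", n = 3, size = 4, endian = "little")  # dmin/dmax/dmean
  readBin(con, "integer", n = 1, size = 4, endian = "little")  # ispg
  nsymbt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  seek(con, 4 * 49)  # words 50-52: origin
  orig <- readBin(con, "numeric", n = 3, size = 4, endian = "little")

  if (!as.character(mode) %in% names(MRC_MODE_BYTES)) {
    stop("unsupported MRC mode ", mode, " (supported: 0, 1, 2, 12)", call. = FALSE)
  }
  if (any(c(nx, ny, nz) < 1L)) stop("invalid MRC dimensions in header", call. = FALSE)
  if (!identical(sort(maps), 1:3)) {
    stop("unsupported MRC axis ordering (mapc/mapr/maps = ",
         paste(maps, collapse = "/"), ")", call. = FALSE)
  }
  vs <- unique(round(cella / c(mx, my, mz), 6))
  if (length(vs) != 1L) {
    stop("anisotropic voxel size in MRC header is not supported", call. = FALSE)
  }
  if (!is.finite(vs) || vs <= 0) {
    stop("non-positive voxel size in MRC header (cella/m = ", vs, ")", call. = FALSE)
  }

  seek(con, 1024 + nsymbt)
  n <- as.numeric(nx) * ny * nz
  raw_vals <- switch(as.character(mode),
    `0`  = as.numeric(readBin(con, "integer", n = n, size = 1, signed = TRUE)),
    `1`  = as.numeric(readBin(con, "integer", n = n, size = 2, signed = TRUE,
                              endian = "little")),
    `2`  = readBin(con, "numeric", n = n, size = 4, endian = "little"),
    `12` = half_to_double(readBin(con, "integer", n = n, size = 2, signed = FALSE,
                                  endian = "little"))
  )
  if (length(raw_vals) != n) stop("truncated MRC data block", call. = FALSE)

  # file order: axis maps[1] fastest ... maps[3] slowest
  arr <- array(raw_vals, dim = c(nx, ny, nz))
  perm_xyz <- match(1:3, maps)        # file slot holding x, y, z
  arr <- aperm(arr, perm_xyz)         # now (x, y, z)
  arr <- aperm(arr, c(3, 2, 1))       # to (z, y, x)
  volume(arr, voxel_size = vs, origin = orig)
}

#' Write an MRC volume
#'
#' Always writes MRC2014 mode 2 (float32) with the voxel size stored in the
#' cell dimensions.
#'
#' @param vol a [volume()].
#' @param path output path; the parent directory must exist.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(is_volume(vol))
  if (!all(is.finite(vol$data))) {
    stop("volume contains non-finite values; refusing to write", call. = FALSE)
  }
  d <- dim(vol$data)                 # (z, y, x)
  nxyz <- c(d[3], d[2], d[1])
  con <- file(path, "wb")
  on.exit(close(con))

  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")

  wi(c(nxyz, 2L))                    # nx ny nz mode
  wi(c(0L, 0L, 0L))                  # nxstart
  wi(nxyz)                           # mx my mz
  wf(nxyz * vol$voxel_size)          # cella
  wf(c(90, 90, 90))                  # cellb
  wi(1:3)                           # mapc mapr maps
  wf(c(min(vol$data), max(vol$data), mean(vol$data)))
  wi(1L)                             # ispg (volume)
  wi(0L)                             # nsymbt
  wi(rep(0L, 25))                    # extra (words 25-49), incl. exttyp/nversion
  wf(vol$origin[seq_len(3)])         # origin
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(vol$data))            # rms
  wi(0L)                             # nlabl
  writeBin(raw(800), con)            # labels

  arr <- aperm(vol$data, c(3, 2, 1))             # back to x fastest
  writeBin(as.numeric(arr), con, size = 4, endian = "little")
  invisible(path)
}

# IEEE 754 half-precision decode for MRC mode 12 (vectorized over uint16).
half_to_double <- function(bits) {
  s <- bits %/% 32768L
  e <- (bits %/% 1024L) %% 32L
  f <- bits %% 1024L
  val <- ifelse(e == 0L, 2^-14 * (f / 1024),
         ifelse(e == 31L, ifelse(f == 0L, Inf, NaN),
                2^(e - 15) * (1 + f / 1024)))
  ifelse(s == 1L, -val, val)
}
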