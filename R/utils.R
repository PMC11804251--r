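`%||%` <- function(a, b) if (is.null(a)) b else a

# Apply an n x n linear operator along one axis of a 3D array via matrix
# multiplication (axis 1 = Z, 2 = Y, 3 = X). Used for second-difference
# stencils, Gaussian blurs and resampling, all of which are separable.
apply_axis_op <- function(v, M, axis) {
  d <- dim(v)
  if (axis == 1L) {
    array(M %*% matrix(v, d[1]), dim = c(nrow(M), d[2], d[3]))
  } else if (axis == 2L) {
    vp <- aperm(v, c(2, 1, 3))
    vp <- array(M %*% matrix(vp, d[2]), dim = c(nrow(M), d[1], d[3]))
    aperm(vp, c(2, 1, 3))
  } else {
    vp <- aperm(v, c(3, 2, 1))
    vp <- array(M %*% matrix(vp, d[3]), dim = c(nrow(M), d[2], d[1]))
    aperm(vp, c(3, 2, 1))
  }
}

# 1D second-difference operator [1, -2, 1] with replicate borders, as a dense
# n x n matrix (n is at most a chunk edge, so dense is cheap and BLAS-fast).
second_diff_matrix <- function(n) {
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    im <- max(1L, i - 1L); ip <- min(n, i + 1L)
    M[i, im] <- M[i, im] + 1
    M[i, i] <- M[i, i] - 2
    M[i, ip] <- M[i, ip] + 1
  }
  M
}

# 1D normalized Gaussian convolution matrix with replicate borders.
gaussian_blur_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  rad <- max(1L, ceiling(3 * sigma))
  w <- exp(-(seq(-rad, rad))^2 / (2 * sigma^2))
  w <- w / sum(w)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- pmin(pmax(i + seq(-rad, rad), 1L), n)   # replicate borders
    for (k in seq_along(j)) M[i, j[k]] <- M[i, j[k]] + w[k]
  }
  M
}

# 1D linear (triangle) resampling matrix from n_in samples to n_out, aligned
# so that output index i maps to input position i / scale. When downscaling
# the kernel support is widened by 1/scale (the standard anti-aliased resize),
# which makes the rows a partition of unity and keeps total image mass stable
# under a down/up round trip. Plain linear interpolation when upscaling.
resample_matrix <- function(n_in, n_out, scale) {
  support <- max(1, 1 / scale)
  M <- matrix(0, n_out, n_in)
  pos <- (seq_len(n_out) - 1) / scale
  j <- seq_len(n_in) - 1
  for (i in seq_len(n_out)) {
    w <- pmax(0, 1 - abs(pos[i] - j) / support)
    M[i, ] <- w / sum(w)
  }
  M
}

# Chebyshev (cubic-neighbourhood) maximum filter with half-width w,
# implemented as three separable running maxima via shifted pmax.
max_filter3 <- function(v, w) {
  if (w < 1) return(v)
  for (axis in 1:3) v <- max_filter_axis(v, w, axis)
  v
}

max_filter_axis <- function(v, w, axis) {
  d <- dim(v)
  n <- d[axis]
  out <- v
  idx <- function(shift) pmin(pmax(seq_len(n) + shift, 1L), n)
  for (s in seq_len(min(w, n - 1L))) {
    ip <- seq_len(n) + s
    im <- seq_len(n) - s
    ip[ip > n] <- NA; im[im < 1] <- NA
    out <- pmax(out, take_axis(v, ip, axis, fill = -Inf),
                take_axis(v, im, axis, fill = -Inf))
  }
  out
}

# Index a 3D array along one axis with NA-able indices, filling with `fill`.
take_axis <- function(v, ind, axis, fill = 0) {
  d <- dim(v)
  ok <- !is.na(ind)
  ind2 <- ind; ind2[!ok] <- 1L
  out <- switch(axis,
                v[ind2, , , drop = FALSE],
                v[, ind2, , drop = FALSE],
                v[, , ind2, drop = FALSE])
  if (any(!ok)) {
    switch(axis,
           out[!ok, , ] <- fill,
           out[, !ok, ] <- fill,
           out[, , !ok] <- fill)
  }
  out
}
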