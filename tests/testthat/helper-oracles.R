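# Independent oracles and fixture builders used across the suite.
# These deliberately re-derive expected results by brute force / closed form,
# without calling the implementation paths they check.

# Exhaustive per-voxel label rendering: evaluates the radial profile at every
# voxel of the grid for every particle and combines by maximum.
oracle_render_labels <- function(coords, shape, R, config = label_config()) {
  lab <- array(0, dim = shape)
  g <- expand.grid(z = seq_len(shape[1]) - 1, y = seq_len(shape[2]) - 1,
                   x = seq_len(shape[3]) - 1)
  for (k in seq_len(nrow(coords))) {
    r <- sqrt((g$x - coords$x[k])^2 + (g$y - coords$y[k])^2 +
                (g$z - coords$z[k])^2)
    s1 <- config$f1 * R / config$width_sigmas
    s2 <- config$f2 * R / config$width_sigmas
    v <- (exp(-r^2 / (2 * s1^2)) + exp(-r^2 / (2 * s2^2))) / 2
    v[r > R] <- 0
    lab <- pmax(lab, array(v, dim = shape))
  }
  lab
}

# Brute-force O(n k^3) neighbourhood peak search with greedy Chebyshev
# suppression, mirroring the documented candidate and tie-break rules.
oracle_find_peaks <- function(m, min_distance, threshold) {
  w <- floor(min_distance / 2)
  d <- dim(m)
  idx <- which(array(TRUE, d), arr.ind = TRUE)
  is_cand <- vapply(seq_len(nrow(idx)), function(i) {
    z <- idx[i, 1]; y <- idx[i, 2]; x <- idx[i, 3]
    m[z, y, x] >= max(m[max(1, z - w):min(d[1], z + w),
                        max(1, y - w):min(d[2], y + w),
                        max(1, x - w):min(d[3], x + w)])
  }, TRUE)
  cand <- idx[is_cand, , drop = FALSE]
  conf <- m[cand]
  ord <- order(-conf, cand[, 1], cand[, 2], cand[, 3])
  cand <- cand[ord, , drop = FALSE]; conf <- conf[ord]
  acc <- matrix(0, 0, 3); keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (nrow(acc) == 0L ||
        all(apply(abs(acc - matrix(cand[i, ], nrow(acc), 3, byrow = TRUE)),
                  1, max) >= min_distance)) {
      keep[i] <- TRUE
      acc <- rbind(acc, cand[i, ])
    }
  }
  sel <- keep & conf >= threshold
  data.frame(z = cand[sel, 1] - 1, y = cand[sel, 2] - 1, x = cand[sel, 3] - 1,
             confidence = conf[sel])
}

# All permutations of 1..m (m <= 7 in the suite), memoized.
.perm_cache <- new.env(parent = emptyenv())
all_perms <- function(m) {
  key <- as.character(m)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  out <- if (m == 1L) list(1L) else {
    acc <- list()
    for (p in all_perms(m - 1L)) {
      for (k in 0:(m - 1L)) acc[[length(acc) + 1L]] <- append(p, m, after = k)
    }
    acc
  }
  .perm_cache[[key]] <- out
  out
}

# Brute-force minimum assignment cost over all permutations.
oracle_min_assignment_cost <- function(cost) {
  if (nrow(cost) > ncol(cost)) cost <- t(cost)
  n <- nrow(cost); m <- ncol(cost)
  best <- Inf
  for (p in all_perms(m)) {
    best <- min(best, sum(cost[cbind(seq_len(n), p[seq_len(n)])]))
  }
  best
}

# Direct second-difference via explicit replicate padding (loss oracle).
oracle_second_diff <- function(v, axis) {
  d <- dim(v)
  n <- d[axis]
  ip <- pmin(seq_len(n) + 1L, n)
  im <- pmax(seq_len(n) - 1L, 1L)
  slice <- function(ind) switch(axis, v[ind, , , drop = FALSE],
                                v[, ind, , drop = FALSE],
                                v[, , ind, drop = FALSE])
  slice(im) - 2 * v + slice(ip)
}

# Small balanced chunk-pair fixture from a noiseless-ish phantom; used by
# trainer tests.
make_training_fixture <- function(n_phantoms = 2, shape = 64, chunk = 32,
                                  snr = 10, n_particles = 6, seed = 1) {
  pairs <- lapply(seq_len(n_phantoms), function(i) {
    sim <- simulate_tomogram(phantom_params(shape = rep(shape, 3),
                                            n_particles = n_particles,
                                            radius_px = 5, snr = snr,
                                            seed = seed + i))
    lab <- render_labels(sim$particles, rep(shape, 3))
    img <- robust_normalize(sim$volume)
    balance_chunks(chunk_volume(img$data, chunk, chunk),
                   chunk_volume(lab$data, chunk, chunk), seed = seed)
  })
  dplyr::bind_rows(pairs)
}

# Constant-output backbone with no trainable parameters (schedule tracing).
constant_backbone <- function(value = 0.5) {
  structure(list(value = value), class = c("constant_backbone", "tomo_backbone"))
}
bb_forward.constant_backbone <- function(backbone, x, state = NULL) {
  list(output = array(backbone$value, dim = dim(x)), cache = NULL)
}
bb_backward.constant_backbone <- function(backbone, grad_output, cache) list()
bb_params.constant_backbone <- function(backbone) list()
bb_set_params.constant_backbone <- function(backbone, params) backbone

# Backbone that returns a different constant on every call (stitching oracle).
sequence_backbone <- function(values) {
  env <- new.env()
  env$i <- 0L
  structure(list(values = values, env = env),
            class = c("sequence_backbone", "tomo_backbone"))
}
bb_forward.sequence_backbone <- function(backbone, x, state = NULL) {
  backbone$env$i <- backbone$env$i + 1L
  list(output = array(backbone$values[backbone$env$i], dim = dim(x)),
       cache = NULL)
}
bb_backward.sequence_backbone <- function(backbone, grad_output, cache) list()
bb_params.sequence_backbone <- function(backbone) list()
bb_set_params.sequence_backbone <- function(backbone, params) backbone

# The generics are called from inside the package, so test-local method
# definitions must be registered explicitly for dispatch to find them.
local({
  for (cls in c("constant_backbone", "sequence_backbone")) {
    for (gen in c("bb_forward", "bb_backward", "bb_params", "bb_set_params")) {
      registerS3method(gen, cls, get(paste0(gen, ".", cls)),
                       envir = asNamespace("tomopick"))
    }
  }
})
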