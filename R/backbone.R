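# Pluggable volumetric backbone contract.
#
# A backbone maps a chunk_size^3 input grid to a same-shape scalar output and
# exposes a named parameter set, so any architecture can be trained under the
# composite loss. Implementations provide four S3 methods:
#
#   bb_forward(backbone, x, state)  -> list(output = <array>, cache = <any>)
#   bb_backward(backbone, grad_output, cache) -> named list of param gradients
#   bb_params(backbone)             -> named list of numeric arrays
#   bb_set_params(backbone, params) -> backbone
#
# `state` is an optional per-chunk environment a backbone may use to memoize
# input transforms (e.g. FFTs) across epochs; it must not change the output.

#' @rdname backbone-contract
#' @param backbone a backbone object.
#' @param x 3D numeric array input chunk.
#' @param state optional environment for per-chunk memoization.
#' @return `bb_forward()`: list with `output` (array shaped like `x`) and
#'   `cache` for [bb_backward()].
#' @export
bb_forward <- function(backbone, x, state = NULL) UseMethod("bb_forward")

#' @rdname backbone-contract
#' @param grad_output gradient of the loss w.r.t. the forward output.
#' @param cache the `cache` element returned by [bb_forward()].
#' @return `bb_backward()`: named list of gradients, congruent with
#'   [bb_params()].
#' @export
bb_backward <- function(backbone, grad_output, cache) UseMethod("bb_backward")

#' @rdname backbone-contract
#' @export
bb_params <- function(backbone) UseMethod("bb_params")

#' @rdname backbone-contract
#' @param params named list of numeric arrays, congruent with [bb_params()].
#' @export
bb_set_params <- function(backbone, params) UseMethod("bb_set_params")

#' Backbone contract
#'
#' S3 generics every trainable backbone implements; see
#' [matched_filter_backbone()] for the built-in default and
#' [identity_backbone()] for a pass-through used in stitching tests.
#'
#' @name backbone-contract
NULL

# Constructor spec for checkpointing: how to rebuild the backbone object.
bb_spec <- function(backbone) UseMethod("bb_spec")

backbone_from_spec <- function(spec, params = NULL) {
  bb <- do.call(spec$constructor, spec$args)
  if (!is.null(params)) bb <- bb_set_params(bb, params)
  bb
}

#' Convenience forward pass
#'
#' @param backbone a backbone object.
#' @param x 3D array.
#' @return The output array only.
#' @export
bb_apply <- function(backbone, x) bb_forward(backbone, x)$output

## ---------------------------------------------------------------------------
## Built-in default: learnable 3D matched filter with a logistic read-out.
##
## output = sigmoid(conv(x, K) + b), with K a kernel_size^3 kernel applied by
## circular FFT convolution. This is the minimal architecture that can learn
## the centroid-heatmap regression task: the kernel converges to a matched
## filter for the particle density and the logistic read-out maps the filter
## response onto the [0, 1] confidence scale. It is linear-in-parameters up to
## the output nonlinearity, so training is fast, stable and deterministic on a
## CPU, while heavier segmentation networks can be plugged in through the same
## contract.

#' Matched-filter backbone
#'
#' The built-in trainable backbone: a single learnable 3D convolution kernel
#' (circular, FFT-based) followed by a bias and a logistic activation. The
#' kernel should be large enough to span the rescaled particle
#' (`kernel_size >= target particle size + ~3`).
#'
#' @param kernel_size odd cube edge of the learnable kernel (default 13).
#' @param seed RNG seed for the small random kernel initialization.
#' @param bias_init initial bias; the default -4 starts predictions near the
#'   background confidence `plogis(-4) ~ 0.018`.
#' @return A backbone object implementing the [backbone-contract].
#' @export
matched_filter_backbone <- function(kernel_size = 13, seed = 1, bias_init = -4) {
  kernel_size <- as.integer(kernel_size)
  if (kernel_size < 1L || kernel_size %% 2L == 0L) {
    stop("`kernel_size` must be a positive odd integer", call. = FALSE)
  }
  K <- withr::with_seed(seed,
    array(stats::rnorm(kernel_size^3, sd = 1e-3), dim = rep(kernel_size, 3)))
  structure(list(kernel = K, bias = bias_init, kernel_size = kernel_size,
                 seed = seed),
            class = c("matched_filter_backbone", "tomo_backbone"))
}

# Embed the centred kernel into an n^3 array with wraparound for circular FFT
# convolution.
embed_kernel <- function(K, n) {
  ks <- dim(K)[1]
  if (ks > n) stop("kernel larger than chunk", call. = FALSE)
  r <- (ks - 1L) %/% 2L
  big <- array(0, dim = c(n, n, n))
  idx <- ((-r:r) %% n) + 1L
  big[idx, idx, idx] <- K
  big
}

#' @export
bb_forward.matched_filter_backbone <- function(backbone, x, state = NULL) {
  d <- dim(x)
  if (length(unique(d)) != 1L) stop("matched-filter backbone expects cubic chunks",
                                    call. = FALSE)
  n <- d[1]
  xf <- if (!is.null(state) && !is.null(state$xf) && identical(state$dim, d)) {
    state$xf
  } else {
    f <- stats::fft(x)
    if (!is.null(state)) { state$xf <- f; state$dim <- d }
    f
  }
  Kf <- stats::fft(embed_kernel(backbone$kernel, n))
  u <- Re(stats::fft(xf * Kf, inverse = TRUE)) / n^3 + backbone$bias
  p <- stats::plogis(u)
  list(output = p, cache = list(xf = xf, pred = p, n = n))
}

#' @export
bb_backward.matched_filter_backbone <- function(backbone, grad_output, cache) {
  # chain through the logistic, then correlate with the input for the kernel
  gu <- grad_output * cache$pred * (1 - cache$pred)
  n <- cache$n
  corr <- Re(stats::fft(Conj(cache$xf) * stats::fft(gu), inverse = TRUE)) / n^3
  r <- (backbone$kernel_size - 1L) %/% 2L
  idx <- ((-r:r) %% n) + 1L
  list(kernel = corr[idx, idx, idx], bias = sum(gu))
}

#' @export
bb_params.matched_filter_backbone <- function(backbone) {
  list(kernel = backbone$kernel, bias = backbone$bias)
}

#' @export
bb_set_params.matched_filter_backbone <- function(backbone, params) {
  stopifnot(identical(dim(params$kernel), dim(backbone$kernel)),
            length(params$bias) == 1L)
  backbone$kernel <- params$kernel
  backbone$bias <- params$bias
  backbone
}

#' @export
bb_spec.matched_filter_backbone <- function(backbone) {
  list(constructor = matched_filter_backbone,
       type = "matched_filter_backbone",
       args = list(kernel_size = backbone$kernel_size, seed = backbone$seed))
}

#' @export
print.matched_filter_backbone <- function(x, ...) {
  cat(sprintf("<matched_filter_backbone> kernel %d^3 + bias (%d parameters)\n",
              x$kernel_size, length(x$kernel) + 1L))
  invisible(x)
}

## ---------------------------------------------------------------------------

#' Identity backbone
#'
#' Returns its input unchanged; has no parameters. Useful for testing tiled
#' inference and stitching in isolation from training.
#'
#' @return A backbone object.
#' @export
identity_backbone <- function() {
  structure(list(), class = c("identity_backbone", "tomo_backbone"))
}

#' @export
bb_forward.identity_backbone <- function(backbone, x, state = NULL) {
  list(output = x, cache = NULL)
}

#' @export
bb_backward.identity_backbone <- function(backbone, grad_output, cache) list()

#' @export
bb_params.identity_backbone <- function(backbone) list()

#' @export
bb_set_params.identity_backbone <- function(backbone, params) backbone

#' @export
bb_spec.identity_backbone <- function(backbone) {
  list(constructor = identity_backbone, type = "identity_backbone", args = list())
}
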