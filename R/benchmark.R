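# End-to-end synthetic benchmark: simulate -> label -> train -> predict ->
# extract -> evaluate, entirely on phantom tomograms.

#' Run the phantom recovery benchmark
#'
#' Simulates `n_train + n_test` phantom tomograms under the standard synthetic
#' study conditions ([phantom_params()] defaults: 96^3 voxels, 12 spheres of
#' radius 5 at SNR 0.5), trains the built-in matched-filter backbone on the
#' training phantoms, and evaluates centroid recovery on the held-out
#' phantoms: tiled prediction, peak extraction at the default threshold, and a
#' confidence-percentile sweep against the exact simulated ground truth.
#'
#' @param n_train,n_test number of training and held-out phantoms (defaults 8
#'   and 2).
#' @param params base [phantom_params()]; the seed of phantom `i` is
#'   `params$seed + i - 1`.
#' @param max_epochs training epochs (default 30).
#' @param kernel_size backbone kernel edge (default 13).
#' @param min_distance,threshold peak-extraction parameters (defaults 10
#'   voxels / 0.3).
#' @param seed seed for training (splitting, shuffling, initialization).
#' @return A tibble with one row per held-out phantom: `tomo`, `n_gt`,
#'   `n_pred`, `f1_max`, `best_percentile`, `nrmse_at_f1max`,
#'   `median_norm_error` (median true-positive centroid distance at the
#'   F1-maximal percentile, as a fraction of the particle diameter). The
#'   trained fit is attached as attribute `"fit"`.
#' @export
phantom_benchmark <- function(n_train = 8, n_test = 2,
                              params = phantom_params(), max_epochs = 30,
                              kernel_size = 13, min_distance = 10,
                              threshold = 0.3, seed = 1) {
  sims <- lapply(seq_len(n_train + n_test), function(i) {
    p <- params
    p$seed <- params$seed + i - 1
    simulate_tomogram(p)
  })
  diameter_px <- 2 * params$radius_px

  pairs <- dplyr::bind_rows(lapply(sims[seq_len(n_train)], function(sim) {
    lab <- render_labels(sim$particles, dim(sim$volume))
    img <- robust_normalize(sim$volume)
    balance_chunks(chunk_volume(img$data), chunk_volume(lab$data), seed = seed)
  }))

  fit <- train_backbone(matched_filter_backbone(kernel_size, seed = seed),
                        pairs,
                        config = train_config(max_epochs = max_epochs,
                                              seed = seed),
                        meta = list(target_particle_px = diameter_px))

  rows <- lapply(seq_len(n_test), function(j) {
    sim <- sims[[n_train + j]]
    map <- predict_volume(fit, robust_normalize(sim$volume))
    peaks <- find_peaks(map, min_distance = min_distance, threshold = threshold)
    sw <- threshold_sweep(sim$particles, peaks, diameter = diameter_px)
    best <- sw[sw$is_best, ]
    keep <- peaks$confidence >= best$threshold
    mt <- match_centroids(sim$particles, peaks[keep, ],
                          dist_threshold = diameter_px / 2)
    tp_d <- mt$pairs$distance[mt$pairs$distance <= mt$dist_threshold]
    tibble::tibble(tomo = n_train + j, n_gt = nrow(sim$particles),
                   n_pred = nrow(peaks), f1_max = best$f1,
                   best_percentile = best$percentile,
                   nrmse_at_f1max = best$nrmse,
                   median_norm_error = stats::median(tp_d) / diameter_px)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "fit") <- fit
  out
}
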