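---
title: "Centroid-based particle picking in cryo-electron tomograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Centroid-based particle picking in cryo-electron tomograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tomopick)
```

## The problem

Cryo-electron tomography reconstructs 3D volumes of vitrified specimens, and
most downstream structural work (subtomogram averaging, classification)
starts from the coordinates of individual macromolecular particles inside
those tomograms. Tomograms are extraordinarily noisy — signal-to-noise ratios
are commonly quoted below 0.1 — so particle picking is the bottleneck:
template matching is computationally heavy and template-bound, while binary
segmentation masks localize objects poorly and need morphological
post-processing to produce centroids.

`tomopick` instead treats picking as **centroid heatmap regression**. Each
annotated particle is painted into a label volume as a smooth, radially
symmetric peak; a volumetric model is trained to regress that heatmap from
the raw tomogram; and particle coordinates are recovered from the predicted
confidence map by neighbourhood peak detection. The heatmap encodes
positional uncertainty directly, behaves like the cross-correlation maps
template matching produces, and makes the extraction step a one-liner rather
than a pipeline of thresholds and morphology.

## Label model

For a particle of radius $R$ (in voxels of the working grid), the label
intensity at distance $r$ from the centroid is the average of two isotropic
Gaussians:

$$
I(r) \;=\; \tfrac12\!\left[
\exp\!\left(-\frac{r^2}{2\sigma_1^2}\right) +
\exp\!\left(-\frac{r^2}{2\sigma_2^2}\right)\right],
\qquad
\sigma_i = \frac{f_i \cdot 2R}{2\,w},
$$

truncated to zero for $r > R$ and normalized so $I(0) = 1$. The widths are
parameterized as fractions $f_1 = 0.95$ and $f_2 = 0.5$ of the particle
*diameter*, under the convention that a Gaussian's "width" spans $\pm w = \pm
3$ sigmas. With the defaults, $\sigma_1 \approx 0.32 R$ and $\sigma_2 \approx
0.17 R$: a broad component that tolerates annotation error plus a sharp
component that pins the peak.

Two choices here were genuinely open and are worth recording:

* **Normalization** is division by the $r = 0$ value, so every particle peaks
  at exactly 1. The downstream confidence threshold (default 0.3) presumes a
  $[0, 1]$ scale, which this guarantees.
* **Combination** of overlapping particles is the voxel-wise *maximum*, not
  the sum. A sum would exceed 1 wherever particles crowd (densely packed
  specimens are exactly the interesting case) and would merge neighbouring
  peaks into a single blob, destroying the peak-per-particle property that
  extraction relies on.
* **Subvoxel centroids** are honored: the profile is evaluated at the exact
  continuous distance from the stated centroid, without snapping. A centroid
  between grid points therefore peaks slightly below 1 at its nearest voxel —
  deliberate, and documented in `render_labels()`.

## Preprocessing

Training and inference operate at a standard sampling rate at which the
particle diameter spans `target_particle_px = 10` voxels (`compute_scale()`),
so one model can serve particles of any physical size. Resampling
(`resize_volume()`) is separable linear interpolation; when downscaling, the
kernel support is widened by the inverse scale — the standard anti-aliased
resize — which keeps total image mass stable (a point spread downscaled and
upscaled again retains its integral) and prevents aliasing of fine noise.

Intensities are normalized robustly (`robust_normalize()`): subtract the
median, divide by the interquartile range. Medians and IQRs are insensitive
to the heavy tails that CTF correction and reconstruction artifacts produce,
so tomograms from different reconstruction packages land on a comparable
scale. No percentile clipping is applied beforehand.

Volumes are split into overlapping 64-voxel cubes with stride 32
(`chunk_volume()`). Origins advance by the stride, with a final origin
clamped to `dim - chunk_size` so every voxel is covered; only volumes smaller
than one chunk are zero-padded. Because almost all voxels are background,
training cubes are class-balanced (`balance_chunks()`): every cube containing
at least one labelled voxel is kept, and an equal number of all-background
cubes is sampled without replacement under a fixed seed.

## Loss

Training minimizes a composite of two terms (`composite_loss()`):

1. a **class-balanced Huber term**: per-voxel Huber penalty
   ($\delta = 1$) between prediction and label, weighted by
   $w = T / (2|P|)$ on labelled voxels and $w = T / (2|N|)$ on background
   voxels, where $|P|$, $|N|$ count the two classes and $T = |P| + |N|$. The
   total weight on each class is then equal and the mean weight is 1, so the
   loss scale is stable across cubes regardless of label sparsity. This
   inverse-class-frequency form is the canonical balance for the stated
   class counts; if either class is absent the weights fall back to 1.
2. a **spatial-gradient term**: the mean Huber penalty between discrete
   second derivatives of prediction and label, computed per axis with the
   `[1, -2, 1]` stencil under replicate borders. It sharpens edges and peak
   flanks that the pointwise term is happy to blur. Adding a constant field
   to the prediction leaves it unchanged; linear ramps cancel everywhere
   except the two border planes, where replication flattens them. Whether the
   reference operator is first- or second-order is ambiguous in the
   literature this follows; second-order is the default and first-order is
   available via `loss_config(gradient_order = 1)`.

The two terms are combined with weight `lambda_grad = 1` (configurable; no
principled value is established) and both reduce by the mean over voxels, so
the loss is independent of batch and chunk size.

## Backbone and training

The backbone is **pluggable**: anything implementing the four-generic
contract (`bb_forward()`, `bb_backward()`, `bb_params()`, `bb_set_params()`)
can be trained. The built-in default, `matched_filter_backbone()`, is
deliberately minimal — a single learnable 13^3 convolution kernel (applied by
circular FFT convolution) plus a bias, passed through a logistic read-out:

$$\hat{y} = \operatorname{sigmoid}(K * x + b).$$

The rationale: the substance of this package is the label model, the loss,
the extraction and the evaluation — not the network. A learnable matched
filter is the smallest model that can solve heatmap regression for a
particle of known size, it trains deterministically on a CPU in minutes, its
~2200 parameters are interpretable (the kernel converges to a centre-surround
template of the particle), and the logistic read-out maps filter responses
onto the $[0, 1]$ confidence scale that extraction expects. Heavier 3D
segmentation networks slot in through the same contract when the task
demands them (crowded fields, nonspherical particles, varying backgrounds).
The convolution is circular; chunk borders therefore see wrapped context,
which overlap-averaged stitching and the interior placement of particles
render harmless in practice.

Training (`train_backbone()`) uses AdamW (decoupled weight decay $10^{-10}$),
batches of 10 cubes, an initial learning rate of $4 \times 10^{-4}$, at most
150 epochs, a 20% validation split, halving of the learning rate after 6
consecutive epochs without validation improvement, and early stopping after
36 stale epochs. "Improvement" means the validation loss beats the running
best by more than $10^{-6}$ (absolute); the returned checkpoint is the one
with the best validation loss, which also gates both schedulers — the
validation loss, not the training loss, is the convergence signal.
Fine-tuning (`fine_tune()`) reloads a checkpoint and reruns the same loop,
by default for 20 epochs at $5 \times 10^{-5}$. Gradient clipping is off by
default. With fixed seeds the whole loop is bit-reproducible.

## Inference and extraction

`predict_volume()` tiles the (rescaled, normalized) tomogram with the same
clamped-origin chunking used in training, predicts each cube independently,
and fuses overlaps by plain averaging (per-voxel coverage is at least 1 and
averaging weights sum to 1; a Hann-window weighting is available behind
`window = "cosine"` for seam suppression, though with a translation-invariant
backbone seams are negligible). The fused map is clamped to $[0, 1]$ so the
confidence semantics hold for any backbone output range.

`find_peaks()` extracts centroids: a voxel is a candidate iff it attains the
maximum of its centred cubic neighbourhood of side
`2 * floor(min_distance / 2) + 1`; candidates are processed in decreasing
confidence with Chebyshev-distance suppression (`min_distance`, default the
particle diameter of 10 voxels on the standard grid); finally a confidence
threshold (default 0.3) is applied. Ties on plateaus resolve to the
lexicographically smallest `(z, y, x)` index, making extraction fully
deterministic. The threshold comparison is `>=` — slightly more permissive
than a strict inequality — so a threshold of 1.0 can still retain saturated
peaks. A mask volume can gate extraction (`apply_mask()`) to a compartment
of interest, and `to_original_frame()` / `write_star()` return coordinates
to the original pixel grid for downstream subtomogram-averaging software.

## Evaluation

`match_centroids()` pairs predictions with ground truth by minimum-total-cost
assignment on the Euclidean distance matrix (a Jonker–Volgenant shortest
augmenting path solver, written here because no assignment solver is
available among the package's dependencies; its optimality is tested against
permutation brute force). Matched pairs within half the particle diameter are
true positives; surpluses are false positives/negatives. `prf()` computes
precision, recall and F1 with explicit zero-denominator conventions
(documented in its help page). `normalized_rmse()` reports the RMS
true-positive distance divided by the particle diameter; when there are no
true positives it is reported as missing, never as zero. Averaging over
`min(|gt|, |pred|)` instead of the TP count is available behind a flag, since
both definitions circulate.

`threshold_sweep()` scans percentiles 2–98% in steps of 8 (13 rows) of the
pooled prediction confidences, recomputing all metrics at each cut, and flags
the F1-maximal row (`F1_max`); ties go to the lowest percentile. Percentile
thresholds use the inverse-ECDF (type 1) quantile so that thresholds are
observed confidence values: a perfect prediction evaluated against itself
then attains F1 = 1 at low percentiles rather than losing its weakest point
to interpolation. Confidences are pooled per evaluation call, not per
tomogram.

## The phantom generator, and what it does not show

`simulate_tomogram()` builds phantoms of uniform solid spheres (dark by
convention, contrast $-1$) at rejection-sampled centres with a minimum
separation of one diameter, full containment, optional anisotropic Gaussian
blur emulating missing-wedge elongation, and additive Gaussian noise.
**SNR is defined as contrast² / noise variance** — stated explicitly because
"SNR" is overloaded in this field. Centres are snapped to the voxel grid so
that the returned ground truth is exact and rendered labels peak at exactly
1 at every centre voxel.

The standard study conditions, fixed once as the generator defaults, are:
96^3 voxels, 12 spheres of radius 5 (so the particle is already at the
10-voxel target size on a 10 Å/px grid), SNR 0.5. Twelve spheres of radius 5
in a 96^3 box is a realistic crowding level — dense enough that suppression
neighbourhoods interact, sparse enough that rejection packing always
succeeds. SNR 0.5 is more benign than real tomograms (< 0.1) by design: the
built-in backbone is a matched filter, not a deep network, and the synthetic
benchmark exists to validate the *pipeline* — labels, loss, stitching,
extraction, matching — not to claim real-data performance. Passing phantoms
shows the machinery is correct; it does not show that the built-in backbone
would pick particles in experimental tomograms, which lack spherical
uniformity, have structured (non-Gaussian, correlated) noise, missing-wedge
artifacts beyond a separable blur, and confounding cellular context.

`phantom_benchmark()` runs the full circle — simulate 8 training + 2 held-out
phantoms, train the built-in backbone for up to 30 epochs, predict, extract,
sweep — and reports per-held-out-phantom `F1_max` and the median
true-positive centroid error as a fraction of the diameter. On these
conditions it reaches `F1_max` above 0.9 with median error at or near 0
voxels; the problem sizes were chosen so the whole benchmark runs in a few
minutes on one CPU core.

## Numerical and convention decisions

* Coordinates are **0-based voxel indices**, `(x, y, z)` in files (STAR
  columns, point text) and `(z, y, x)` as array indices in memory; STAR
  values are written as floating point without rounding, so no half-voxel
  drift accumulates through rescaling round trips.
* All volumes are written as MRC2014 mode 2 (float32); modes 0, 1, 2 and 12
  are read. Non-positive header voxel sizes are rejected rather than
  guessed.
* Binary IMOD models are out of scope; point text from `model2point` is the
  supported path.
* Whether exported STAR coordinates are 0- or 1-based is not standardized
  across ecosystems; 0-based is chosen and stated here.
* `min_distance` defaults to the particle diameter *in rescaled pixels*
  (10), matching the grid extraction operates on.
* Degenerate inputs fail loudly: constant volumes cannot be normalized,
  all-negative label sets cannot be balanced, empty prediction sets cannot
  be swept, and non-finite losses abort training with a diagnostic rather
  than silently producing NaN checkpoints.

## Known limitations

Filamentous assemblies have no centroid and are out of scope. Only one
particle size class is handled per model; mixed-size fields need per-class
models. The built-in backbone's circular convolution assumes chunk-scale
stationarity and will underperform deep architectures on structured
backgrounds. The missing wedge is emulated only as anisotropic blur, not as
a Fourier-domain wedge mask.
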