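---
title: "Structure-based despeckling: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-based despeckling: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(despecklr)
```

## The model

Ultrasound speckle is well modeled as multiplicative noise: homogeneous
tissue looks rough because sub-resolution scatterers interfere with random
phase. A filter that cannot tell tissue boundary from speckle must trade
noise suppression against edge destruction. `despecklr` resolves the trade
by classifying the local *structure* at every pixel before choosing a
filter.

The local descriptor is the diffusion tensor of intensity — the 2×2 Hessian
$H = \begin{pmatrix} I_{xx} & I_{xy} \\ I_{xy} & I_{yy} \end{pmatrix}$
computed at a Gaussian scale. Because $H$ is symmetric its eigenvalues
$\lambda_1, \lambda_2$ (ordered $|\lambda_1| \ge |\lambda_2|$) are real and
its eigenvectors orthogonal. Their configuration encodes the geometry:

* both magnitudes small → featureless (uniform) region;
* $|\lambda_1| \gg |\lambda_2|$ → 1-D (tubular) structure whose tangent is
  the minor eigenvector; $\lambda_1 < 0$ on a bright ridge (local maximum
  across the structure), $\lambda_1 > 0$ in a dark valley;
* both magnitudes large and similar → isotropic concentration, a spot.

"Large" is made operational by normalizing all eigenvalues by the global
maximum magnitude, so the classifier sees contrast-invariant values in
$[-1, 1]$, and by two responses per pixel:
$T_1 = \lambda_1^2 + \lambda_2^2$ (feature strength, in $[0, 2]$) and
$T_2 = (|\lambda_2| + \epsilon)/(|\lambda_1| + \epsilon)$ (isotropy). From
these, $C_l = T_1 (1 - T_2)$ measures linearity and $C_s = T_1 T_2$
spot-ness; the two always sum to $T_1$. The decision rules are applied in
order: uniform if $T_1 \le \beta$; linear if $C_l > C_s$ and
$\lambda_1 \le 0$; boundary if $C_l > C_s$ and $\lambda_1 > 0$; spot if
$T_1 \ge \alpha$ and $C_s > C_l$; otherwise unknown. The extra guard
$\alpha > \beta$ on spots exists because a merely noisy region also has
$C_s > C_l$ — only a strong isotropic response deserves the spot label.

High-curvature boundary segments echo weakly and often classify as isolated
spot/unknown pixels, visually breaking a continuous curve. The refinement
stage queues all spot and unknown pixels and lets each inspect its two
neighbors one step along $\pm v_2$ (the local curve tangent): a linear
neighbor converts the pixel to linear, otherwise a boundary neighbor to
boundary, otherwise it waits for the next sweep. Three sweeps with immediate
label propagation suffice to close short gaps from either end.

Filtering then dispatches per label, always reading only the pass-input
image: linear/boundary pixels get a 9-sample 1-D Gaussian *stick* oriented
along $v_2$ — smoothing along the curve makes it coherent while leaving the
cross-curve profile untouched, which visibly *increases* edge contrast once
the flanks have been median-flattened; uniform and unknown pixels get a 9×9
median (robust to the heavy-tailed speckle distribution and to salt-and-
pepper outliers); spot pixels get a σ = 1 isotropic Gaussian so small spots
blend away while large ones survive. The whole pipeline iterates: pass $k+1$
re-analyzes the output of pass $k$.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `hessian_sigma` | 1.4 | px | derivative scale; sets the size of the structures the tensor responds to |
| `beta` | 0.12 | — | uniform threshold on $T_1$ (normalized eigenvalue energy) |
| `alpha` | 0.45 | — | spot threshold on $T_1$; guards against noise-as-spot |
| `epsilon` | 1e-6 | — | ratio guard in $T_2$; far below any meaningful normalized eigenvalue of 8-bit data |
| `refine_iters` | 3 | sweeps | gap-healing reach (one pixel per sweep from each end) |
| `stick_len`, `stick_sigma` | 9, 1 | px | oriented smoothing support along curves |
| `median_size` | 9 | px | uniform/unknown smoothing window |
| `gauss2d_sigma` | 1 | px | spot smoothing scale |
| `passes` | 2 | — | pipeline iterations; clean data needs 1, heavy speckle up to 3 |

The thresholds β and α and the filter supports are the operating point of
the method for 8-bit ultrasound and gray-level imagery; they interact with
the global eigenvalue normalization, not with absolute image contrast, which
is why they can be fixed constants.

`equalize_each_pass` defaults to `TRUE`: the pipeline literally repeats all
its stages, equalization included, which is the right behavior when the
goal is a readable image. The benchmark harness (`run_benchmark()`) and the
fidelity experiments instead run with equalization off: equalization remaps
intensities away from the clean reference, so PSNR/SSIM against that
reference would measure the remapping rather than the despeckling. Both
modes are exposed; neither is hard-coded as truth.

## The synthetic data

`make_phantom()` renders what the classifier is designed to see: flat
vertical bands (piecewise-uniform "tissue"), polyline ridges with Gaussian
cross-section (bright → expected linear, dark → expected boundary), and
isotropic Gaussian bumps (spots), summed and clipped to [0, 255], together
with a ground-truth mask (crest pixels within 0.5 px of the polyline, spot
centers, flat interiors; everything within a structure's influence zone or
near a band border is *don't-care*). The reference scene
(`default_phantom_spec()`) is 256×256 with bands at 70/120/170, two bright
ridges (+70, +60; width 2 px), one dark curve (−60, width 2 px) and four
spots (±80, radius 3 px) — amplitudes chosen so that ridge and spot
curvatures after tensor smoothing land in the same decade, i.e. no structure
trivially dominates the normalization.

Speckle is simulated as $I^* = \mathrm{clip}(I \cdot n, 0, 255)$ with
$n = \max(0, 1 + \sigma Z)$ and $Z$ a standardized Rayleigh variate. A raw
Rayleigh field could not serve directly: its mean and standard deviation are
locked together, so a non-unit-mean multiplicative field would brighten or
darken the whole image and any fidelity metric would conflate that shift
with noise. Anchoring the mean at 1 keeps brightness, makes σ the field's
standard deviation exactly (verified by Monte-Carlo moment tests), keeps the
Rayleigh positive skew, and yields the closed form
$E[(I - In)^2] = I^2\sigma^2$ on constant images that the tests check
against (128, σ = 0.1 → 25.99 dB).

What the phantom does *not* emulate: log-compressed scan-converted geometry,
depth-dependent attenuation and focus, correlated (non-white) speckle, and
real tissue texture. Passing the phantom tests therefore certifies the
mechanics of classification and filtering, not clinical performance.

## Numerical choices

* **Derivative kernels.** Sampled analytic Gaussian derivatives, truncated
  at 4σ (truncation error < 1e-4 relative), then moment-corrected: the
  second-derivative kernel is forced to zero sum and to respond exactly 2 to
  $x^2$, the first-derivative kernel exactly 1 to $x$. This makes the
  polynomial test cases exact and removes DC leakage.
* **Noise floor.** Floating-point summation leaves $O(\epsilon \cdot I)$
  residue where the true derivative is zero; responses below
  $10^{-11}\max(1, \max|I|)$ are snapped to 0. Without this, the *global*
  eigenvalue normalization would amplify pure round-off on (near-)constant
  images into apparent full-scale structure.
* **Borders.** Mirror reflection about edge-pixel centers everywhere
  (convolutions, median windows, stick sampling); avoids spurious boundary
  responses at the frame.
* **Eigen conventions.** Closed-form 2×2 eigendecomposition; magnitude
  ordering with the trace-zero tie broken toward the negative eigenvalue;
  eigenvector sign canonicalized to non-negative x component (y when x is
  zero); the isotropic/zero matrix maps to the coordinate axes. Stick
  filtering is direction-symmetric, so only determinism is at stake, and
  these conventions pin every output bit.
* **Stick sampling.** Bilinear interpolation at the nine offsets
  $k \cdot v_2$; keeps the oriented response consistent under rotation of
  $v_2$ rather than snapping the stick to lattice directions.
* **Refinement order.** The queue is processed in raster order with
  immediate updates, and rebuilt before each of the three sweeps. Queue
  *order* is not semantically fixed by the algorithm; raster order is chosen
  for determinism.
* **Ties.** $C_l = C_s$ falls through the linear/boundary rules (strict
  inequalities as printed) and can only become spot or unknown.
* **Spot filtering** is evaluated as a full-image Gaussian convolution
  sampled at spot pixels — identical to a local window for interior pixels
  and vectorizable.
* **Equalization** uses integer 256-bin binning with the
  $\mathrm{round}(255 (F(v) - F_{\min})/(1 - F_{\min}))$ mapping; a
  single-valued image is its own fixed point. The mapping is monotone, and
  a second application moves almost all pixels by at most one level.
* **Intensities** stay floating point in [0, 255] across passes; 8-bit
  quantization happens only at file write.

## Problem sizes

The test suite exercises 20–96 px images for unit and property tests, the
256×256 reference phantom for classification accuracy and fidelity trends,
a 512×512 constant field for noise-model moments, and single passes on
256×256 vs 512×512 for the linear-cost check; the whole suite runs in well
under a minute. The acceptance script uses the same sizes.

## Limitations

* Labels are hard: a pixel is exactly one type, and misclassification picks
  the wrong filter for it. The refinement only corrects spot/unknown →
  linear/boundary, never the reverse.
* The global eigenvalue normalization couples the classifier to the single
  strongest structure in the image; an extreme outlier (e.g. a burned-in
  annotation) can compress every other eigenvalue below β.
* The 9×9 median erases genuine structures thinner than ~4 px that the
  classifier fails to mark as linear/boundary.
* PSNR/SSIM on phantoms measure fidelity to a synthetic truth;
  equalization-on output is deliberately not comparable to such a
  reference.
* Performance: stages are separable convolutions, a compiled exact median
  and a vectorized stick, all $O(N)$ in pixel count with small constants;
  only the refinement loop is interpreted R, bounded by the spot/unknown
  census.
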