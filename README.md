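# despecklr

Structure-based speckle reduction for ultrasound images in R.

Speckle is the granular interference noise of coherent imaging: echoes with
random phases interfere constructively and destructively, roughening
homogeneous tissue regions and blurring the boundaries a clinician actually
needs. Uniform smoothing (Gaussian or median) removes speckle but destroys
those boundaries too. `despecklr` instead decides, pixel by pixel, *what kind
of structure* a pixel belongs to and then smooths it with a filter that suits
that structure — so uniform regions get flattened while ridges, boundaries
and spots are preserved or even enhanced. The package is aimed at medical
image-analysis researchers and at anyone filtering multiplicative-noise
imagery; it includes the full evaluation machinery (speckle simulation,
labeled phantoms, PSNR/SSIM, baselines) so every claim can be reproduced
without external data.

## Method

Each despeckling pass runs five stages:

1. **Equalize** (optional): classical 256-bin CDF histogram equalization.
2. **Diffusion tensor**: the intensity Hessian
   `H = [[Ixx, Ixy], [Ixy, Iyy]]` is computed at every pixel by separable
   Gaussian-derivative convolution at scale σ = 1.4 px.
3. **Eigen-analysis**: the closed-form eigensystem of `H` gives the major and
   minor eigenvalues (|λ₁| ≥ |λ₂|) and eigenvectors; eigenvalues are
   normalized by the global maximum magnitude into [−1, 1].
4. **Classification**: from `T₁ = λ₁² + λ₂²` and
   `T₂ = (|λ₂| + ε)/(|λ₁| + ε)` the responses `Cl = T₁(1 − T₂)` (linearity)
   and `Cs = T₁·T₂` (spot-ness) are formed, and each pixel is labeled
   *uniform* (`T₁ ≤ β`), *linear* (bright ridge, `Cl > Cs`, λ₁ ≤ 0),
   *boundary* (dark valley, `Cl > Cs`, λ₁ > 0), *spot*
   (`T₁ ≥ α`, `Cs > Cl`) or *unknown*, with β = 0.12 and α = 0.45. A
   refinement pass then re-examines spot/unknown pixels along their minor
   eigenvector (the local curve tangent) and absorbs them into adjacent
   linear/boundary structures, healing curves broken by weak echoes.
5. **Structure-driven filtering**: linear/boundary pixels get a 9-sample 1D
   Gaussian "stick" (σ = 1) oriented along the minor eigenvector —
   smoothing *along* the curve, never across it; uniform and unknown pixels
   get a 9×9 median; spot pixels get an isotropic 2D Gaussian (σ = 1).

Two passes are the cost-effective default; heavy speckle may warrant three.
Speckle is simulated multiplicatively, `I* = I · n` with a unit-mean
Rayleigh-shaped field `n = max(0, 1 + σZ)`, and results are scored with PSNR
and the Wang et al. SSIM.

## Worked example

```r
library(despecklr)

ph    <- make_phantom(default_phantom_spec(seed = 1))   # clean 256x256 scene
noisy <- multiplicative_rayleigh(ph$image, sigma = 0.3, seed = 1001)
res   <- despeckle(noisy, pipeline_config(passes = 2, equalize_each_pass = FALSE))
print(res)
#> <despeckle_result> 2 pass(es), 256 x 256 image
#>   pass 1: norm_const 21.56 | uniform=54227 linear=5731 boundary=4889 spot=2 unknown=687
#>   pass 2: norm_const 20.01 | uniform=60609 linear=3025 boundary=1718 spot=0 unknown=184

psnr(ph$image, noisy); psnr(ph$image, res$image)
#> PSNR: noisy 16.92 dB -> despeckled 26.99 dB
ssim(ph$image, noisy); ssim(ph$image, res$image)
#> SSIM: noisy 0.123 -> despeckled 0.763
```

The phantom is a labeled synthetic scene (three flat bands, two bright
ridges, one dark curve, four spots). At speckle level σ = 0.3 the pipeline
raises PSNR by ~10 dB over two passes while the per-pass label counts show
the classifier settling: speckle-induced spot/unknown pixels disappear as the
image cleans up, and the surviving linear/boundary pixels trace the true
ridges. `norm_const` is the global eigenvalue scale of each pass.

A command-line wrapper ships in `inst/scripts/despeckle`:

```sh
Rscript inst/scripts/despeckle input.png -o output.png --passes 2 --no-equalize \
    --save-typemap maps/ --diagnostics diag.csv -v
```

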