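---
title: "Methods: despeckle filtering and multiscale AM-FM texture analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: despeckle filtering and multiscale AM-FM texture analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of its methods: the models, the
parameters that matter, the numerical conventions, and the design choices
made where the published description of this class of systems leaves the
design open. Everything quantitative stated here is computed by the test
suite (`tests/testthat/`) or the reproduction script
(`scripts/acceptance.R`); nothing is asserted that the code does not check.

## 1. The AM-FM image model

A grayscale image is modelled as a finite sum of nonstationary components
`f(x, y) = Σₙ aₙ(x, y) cos φₙ(x, y)`, with instantaneous amplitude (IA)
`aₙ ≥ 0` and instantaneous frequency (IF) `∇φₙ` in rad/pixel, convertible
to cycles/mm through the pixel density. Texture is summarized by the IA
and the IF magnitude `‖∇φₙ‖` per pixel and per frequency scale.
Throughout the package the first matrix index `x` runs down rows and the
second index `y` across columns; `ifx` is the row-direction and `ify` the
column-direction phase derivative.

Demodulation (`amfm_demodulate()`) proceeds in four steps.

**Analytic image.** The FFT of the input is one-sided: the half-plane of
negative column frequency is zeroed, the retained half doubled, and the DC
and Nyquist columns kept with weight 1. With this convention the real part
of the analytic image reproduces the input exactly, and a pure column tone
`cos(ω y)` becomes exactly `exp(iω y)` — which is why the single-tone
tests can demand machine-precision recovery. The choice of *which*
half-plane to zero is a convention; tones aligned exactly with the
retained boundary row are the degenerate case of any such convention.

**Channel filterbank.** The analytic spectrum is split into
raised-cosine, flat-top annular-sector channels (`build_filterbank()`).
Three dyadic magnitude scales are used, fixed in physical units:

| scale  | cycles/mm    | wavelengths at 16.66 px/mm | IF spacings `n` |
|--------|--------------|----------------------------|-----------------|
| low    | 1.04 – 2.95  | 5.66 – 16 px               | 1, 2, 3, 4      |
| medium | 2.08 – 5.89  | 2.83 – 8 px                | 1, 2            |
| high   | 4.17 – 11.79 | 1.41 – 4 px                | 1               |

Radially each channel is flat across its band with cosine tails extending
15% (relative) outside it; angularly the half-plane is covered by four
sectors centred at 0°, 45°, 90° and 135° (flat within ±15°, cosine rolloff
to ±30°, the 0° sector wrapping to 180°). Two deliberate choices here:

* *Flat tops.* Any in-band tone sees unit gain, so IA is unbiased for
  single components — the accuracy ceiling the tests verify. Tapered
  (Gabor-like) channels would weight the passband and bias IA wherever a
  component is off-centre.
* *Sector centres at 0/45/90/135.* Axis-aligned and diagonal textures sit
  in flat angular regions. A tone near a sector boundary (e.g. 22.5°)
  still demodulates with correct phase — dominant-channel selection uses
  the maximum modulus and the attenuation is real-valued — but its IA is
  underestimated by up to the crossover attenuation.

The high band nominally reaches 11.79 cycles/mm = 0.71 cycles/px at the
reference density, above the axis Nyquist of 0.5 but below the 2D corner
limit `√2/2`; the filterbank only errors when a band has no support at
all on the discrete grid.

**Dominant component.** Per scale and per pixel, the channel with maximum
response modulus wins; IA is that modulus and the phase is the response
argument. Modulus ties keep the lowest channel index (a deterministic,
order-independent rule; permuting channels changes nothing else, which is
tested).

**IF estimation.** From the unit-amplitude FM image `fm = cos φ̂`, for
each allowed spacing `n` the quantity
`argₙ = (fm(x+n, y) + fm(x−n, y)) / (2 fm(x, y))` equals `cos(n·∂φ/∂x)`
exactly when `φ` is locally linear, so `∂φ/∂x ≈ arccos(argₙ)/n`. Among
spacings with `|argₙ| ≤ 1` the one minimizing `|argₙ|` is kept: the arccos
derivative is smallest where its argument is smallest, so that spacing is
least sensitive to perturbations of `fm`. Ties keep the smallest spacing.
Two caveats are inherent to the estimator and documented rather than
patched:

* It is *unsigned*: `arccos` returns `[0, π]`, so only `|∂φ/∂x|` is
  recovered. All error measurements therefore compare against the
  absolute truth.
* For `n·ω > π` the argument wraps; with the low scale's `n ≤ 4` this can
  in principle select a wrapped spacing near the very top of the band
  (ω ≳ 0.79 rad/px). The phantom's generating frequencies (≤ 0.70
  rad/px) stay clear of the wrap region.

**Validity.** A pixel's IF estimate is kept only if (i) some spacing has
`|argₙ| ≤ 1` in both directions, (ii) `|fm|` at the centre exceeds 10⁻³
(near zeros of the cosine the ratio blows up), (iii) the IA exceeds an
absolute floor of 10⁻⁸ × max |input| (channel responses at FFT round-off
carry no phase information), and (iv) the estimated IF *magnitude lies
inside the scale's own band*. The in-band requirement is what a low-scale
IF rendering shows as dark "failed" regions: in transition zones between
textures the dominant channel mixes components and the estimate leaves
the band. Invalid pixels are `NA` in the IF rasters and excluded from all
features and error statistics.

## 2. The despeckle filters

All eight filters share symmetric (half-sample) boundary reflection and
compute each output pixel from the input raster of the current pass, so
results are independent of pixel visiting order. The windowed filters are
compiled (Rcpp) and each is verified exhaustively against a brute-force
per-pixel R oracle on random images.

| filter         | window | iterations | key parameters |
|----------------|--------|------------|----------------|
| `lsmv`         | 5×5    | 2          | `σₙ²` (noise variance) |
| `wiener`       | 5×5    | 2          | `σₙ²` |
| `kuhawara`     | 4 × 1×5 segments | 2 | — |
| `lsminsc`      | 9 × 3×3 subwindows | 1 | log-domain speckle index |
| `median`       | 5×5    | 1          | — |
| `hybridmedian` | 3 windows of 5×5 | 1 | — |
| `srad`         | PDE    | 100 steps  | `η_s = 4` |
| `nldif`        | PDE    | 10 steps   | `s² = 2`, `α = 0.9`, `m = 0.2` |

Notes on the individually nontrivial choices:

* **`lsmv` weight.** `k = (σ² − ḡ²σₙ²) / (σ²(1 + σₙ²))`, clipped to
  `[0, 1]`, with `ḡ`, `σ²` the 5×5 sample mean and variance. This is the
  classical multiplicative-model (Lee) weight: it is 1 when `σₙ² = 0`
  (noise-free passthrough) and 0 in flat windows (local mean). The
  clipping and the `σ² = 0 → k = 0` rule are part of the contract and are
  tested.
* **`wiener` weight.** `k = (σ² − σₙ²)/σ²` as conventionally stated for
  this filter family. Note the unit mismatch: `σₙ²` is the dimensionless
  multiplicative-noise variance while `σ²` is in squared intensity units,
  so on 0–255 images the filter is nearly an identity unless `σₙ²` is
  rescaled by the caller. The formula is kept in its standard form rather
  than silently "fixed"; the limit behaviours (identity, box mean) are
  what the tests pin down.
* **`kuhawara` segments.** The four 1×5 segments through the centre
  (horizontal, vertical, two diagonals) are the only 1D orientations that
  fit a 5×5 neighbourhood; homogeneity is the sample variance and ties
  keep the first orientation in that fixed order.
* **`lsminsc` domain.** The speckle index `C = σ²ₛ/ḡₛ` is computed on
  `log(1 + image)` (speckle is approximately additive there) while the
  replacement mean is taken in the original intensity domain. Signed
  images are min-shifted before the log. Subwindows with nonpositive
  log-mean are skipped; if all nine are skipped the pixel is unchanged.
* **`srad`.** One explicit step is
  `f ← g + (1/η_s)·div(c ∇g)` with
  `c² = (½|∇g|² − (1/16)(∇²g)²) / (g + ¼∇²g)²`, central-difference
  gradients, 4-neighbour Laplacian, the standard forward/backward
  divergence stencil, and `c` clipped into `[0, 1]` (zero denominators
  give `c = 0`). The step count (100) and `η_s = 4` are configuration
  defaults — the normalization matches the 4-neighbour stencil and keeps
  the explicit scheme in its stable regime (effective step ≤ ¼).
* **`nldif`.** Explicit diffusion `g ← g + m·div(D∇g)` with the tensor
  built from the structure tensor: gradient of the σ = 1 px smoothed
  image, outer product smoothed componentwise at σ = 2 px, eigenvalues
  `μ₁ ≥ μ₂`. Across-contour diffusivity `λ₁ = α(1 − (μ₁−μ₂)²/s²)` while
  `(μ₁−μ₂)² ≤ s²` and 0 beyond; along-contour `λ₂ = α`. The coherence
  condition uses the structure-tensor eigenvalues in both the guard and
  the formula (the two are sometimes conflated in the literature's
  notation). With `s² = 2` the coherent regime is reached at very small
  gradients, so on 0–255 images the filter mostly diffuses along
  contours — the straight-edge preservation test demonstrates exactly
  this.
* **Noise variance.** When not supplied, `σₙ²` is the average over
  non-overlapping 21×21 tiles of the tile-wise variance of
  `log(1 + image)`; tiles must be at least 4× the filter window so local
  texture averages out. The estimator recovers an injected log-domain
  variance within 10% at 1024², which the acceptance script re-measures.

## 3. The synthetic carotid phantom

`generate_phantom()` realizes a 1024×1024 five-band image mimicking a
longitudinal carotid view: three "tissue" backgrounds (amplitudes 158,
102, 182) and two narrow bright strips (amplitude 250, rows 273–306 and
703–750) playing the intima-media walls. Within each band the
row-direction frequency sweeps linearly across columns — backgrounds over
`[π/7.5, π/4.5]` rad/px with `ify = −ifx`, strips over `[π/6.5, π/5.5]`
with `ify = +ifx` — and the phase is synthesized as
`φ(x, y) = ω(y)·(x + s·y)`.

What this construction does and does not guarantee:

* The row-direction discrete derivative is **exactly** `ω(y)` (constant
  per column), so the x-component of the truth is exact and the x-error
  of a good estimator on the noise-free phantom is limited only by
  filterbank distortion and band-boundary smearing.
* The column-direction derivative is `s·ω(y) + ω′(y)(x + s·y)`: the
  nominal truth plus a slow chirp cross-term that grows to ≈ 0.28 rad/px
  at the image corners for the backgrounds. This mismatch is deliberate —
  a linear frequency sweep cannot have both components exact (the mixed
  partials of the phase would disagree) — and it makes the y-component
  systematically harder, which is exactly the asymmetry the evaluation
  harness reports. For the strips the cross-term moves the true
  y-derivative outside the nominal strip band for most pixels, which is
  why in-band recovery is assessed on the x-component.
* Speckle is `g = f + n·f` with `n` i.i.d. uniform on `[−a, a]`,
  `a = √(3·variance)` (zero mean, requested variance), drawn from a fixed
  seed through an RNG scope that does not disturb the caller's stream.
  Sample moments converge to the nominal ones (checked at 2²⁰ pixels
  within 1%), and equal seeds give bit-identical images.

The phantom emulates the *AM-FM structure* of a carotid image — piecewise
amplitudes, in-band frequency content, thin bright strips — and nothing
else: there is no point-spread function, no RF envelope or log
compression, and speckle is white rather than locally correlated. Passing
tests on the phantom therefore validate the estimation chain, not the
full ultrasound physics.

## 4. The evaluation harness

`run_synthetic_experiment()` measures low-scale IF error for the
noise-free image, the speckled image, and each despeckled image, over the
background, strip and combined (union) masks. Choices fixed here:

* **Metric.** Mean squared error in (rad/px)², over `mask ∩ valid`
  pixels, with a 16-px border trim (filterbank and windowed filters are
  unreliable within roughly one analysis wavelength of the edge); mean
  absolute error is available. The combined column is computed over the
  union mask — it is the pixel-count-weighted mean of the region errors,
  never their average, and the tests verify that identity.
* **Unsigned comparison.** The estimator returns `|IF|`, so errors are
  against `|truth|`.
* **Noise variance for the filters.** In simulation the generating value
  is known and is passed to the variance-driven filters by default;
  `estimate_noise = TRUE` switches to the log-domain estimator to mimic
  the clinical workflow.
* **Seed.** One realization per report (seed recorded in the report's
  attributes); the experiment is deterministic given the seed.

On this phantom the measured structure is: x-errors two orders of
magnitude below the squared in-band frequencies, y-errors dominated by
the generator's cross-term, strip errors dominated by transition-zone
smearing (strips are 34–48 rows wide against analysis wavelengths up to
16 px) rather than by speckle. A consequence worth stating plainly: with
flat-top channels and in-band validity masking, the estimator is robust
enough that speckle barely degrades it and despeckle filtering yields
only marginal further improvement on this phantom — systems whose
estimators are more noise-fragile show much larger filter effects in the
same experiment. The acceptance tests encode the comparison against
published reference values for such a system; the cells that disagree
beyond an order of magnitude (all in the strip columns, where this
implementation's errors are 30–60× *smaller*) are left as documented
failures rather than being tuned away, since the reference system's
filterbank and error conventions are not fully specified.

## 5. Texture features and group statistics

* Per image, scale and feature (IA and IF magnitude in cycles/mm): 32-bin
  histograms over fixed ranges — IA over `[0, ia_max]` (cohort-wide
  maximum supplied by the caller for comparability), IF over the scale's
  own band — with values clamped into range so the histograms always sum
  to 1.
* The per-image scalar feature is the **median** over `valid ∩ ROI`
  pixels (robust to the skewed, heavy-tailed IA distributions), giving
  LIA/MIA/HIA and LIF/MIF/HIF.
* Group summaries report mean, SD, median and the 5/10/25/75/90/95
  percentiles of the per-image medians, ×100 by convention; percentiles
  use the linear-interpolation convention (R type 7), pinned by the
  `P25(1..100) = 25.75` test because percentile tables depend on it.
* Group screening uses the two-sided Mann-Whitney rank-sum test per
  feature at α = 0.05 with **no multiple-testing correction by default**
  (the screening-table convention; Bonferroni/FDR are one argument away).
  Small-n exactness (complete separation at 3 vs 3 gives p = 0.1) and
  type-I calibration at n = 20 vs 20 (0.05 ± 0.01 over 2000 null
  simulations) are both tested.

## 6. Preprocessing conventions

* Resolution standardization resamples to 16.66 px/mm with separable
  cubic-spline interpolation (rows then columns, edge-aligned grid);
  constants are preserved exactly and band-limited content round-trips
  within interpolation tolerance.
* Intensity normalization maps the blood median to 2.5 and the
  adventitia median to 185 — midpoints of the conventional 0–5 and
  180–190 target ranges — by an affine map, then clips to `[0, 255]`.
  Normalization follows resolution standardization in the intended
  pipeline; both are plain functions, so either order can be composed.
* ROI extraction keeps a 160-column (9.6 mm) window centred at the mask's
  column centroid (mean column index, ties rounded down), clamped into
  the mask's bounding box so a mask exactly 160 columns wide is returned
  unchanged. Segmentation itself is out of scope: masks are inputs.

## 7. Problem sizes and determinism

The test suite runs the full experiment once at the native 1024×1024 size
(about half a minute with the compiled filters) and otherwise uses 16×16
images for exhaustive oracle comparisons, 128–256² images for
demodulation properties, and 2000 draws for statistical calibration —
sizes chosen so each check is decisive for the property it tests. Every
stochastic input is seeded; filters and the demodulator are deterministic
functions of their input raster.

## 8. Known limitations

* IF estimates are unsigned; orientation sign would need a different
  estimator (e.g. phase-gradient regression on the complex response).
* Transition zones between textures are flagged invalid rather than
  resolved; a multicomponent tracker could do better.
* The filterbank is this package's own design within the standard
  annular-sector family; numerical results in transition zones are
  sensitive to that design, as the documented acceptance differences
  show.
* `wiener`'s classical weight is unit-inconsistent for multiplicative
  noise on raw intensity scales (see §2) and is kept as stated.
* The phantom's y-truth is exact only up to the chirp cross-term (§3).
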