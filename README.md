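# amfmtex

Despeckle filtering and multiscale AM-FM texture analysis of B-mode
ultrasound images, built around the carotid intima-media complex (IMC) use
case.

## The problem

Speckle — locally correlated multiplicative noise inherent to coherent
ultrasound — corrupts the fine texture of the carotid artery wall that
clinicians and researchers use to track early atherosclerosis. Multiscale
Amplitude-Modulation Frequency-Modulation (AM-FM) analysis represents an
image as a sum of nonstationary components

```
f(x, y) = Σₙ aₙ(x, y) · cos φₙ(x, y)
```

where the *instantaneous amplitude* (IA) `aₙ` captures local texture
contrast and the *instantaneous frequency* (IF) `∇φₙ` — reported in
cycles/mm — captures texture granularity, per pixel and per frequency
scale. Because speckle swamps exactly the frequency content these features
measure, despeckle filtering and AM-FM estimation have to be studied
together. This package provides both halves plus the evaluation machinery:

* **Eight despeckle filters** behind one dispatcher `despeckle()`:
  local-statistics (`lsmv`), pixel-wise Wiener (`wiener`), Kuwahara-style
  homogeneous-mask (`kuhawara`), minimum-speckle-index (`lsminsc`), median,
  hybrid median, speckle-reducing anisotropic diffusion (`srad`) and
  coherence-enhancing nonlinear diffusion (`nldif`), with the conventional
  5×5 windows and iteration counts and a log-domain noise-variance
  estimator (`estimate_noise_variance()`).
* **An AM-FM demodulator** `amfm_demodulate()`: analytic image by an
  extended 2D Hilbert operator (FFT half-plane doubling), a raised-cosine
  annular-sector channel filterbank over three dyadic scales (low
  1.04–2.95, medium 2.08–5.89, high 4.17–11.79 cycles/mm at the reference
  16.66 px/mm), per-pixel dominant-component selection, and
  variable-spacing arccos IF estimation that is exact on cosines.
* **Texture features and statistics**: 32-bin IA/IF histograms, group
  percentile summaries, and Mann-Whitney rank-sum screening of feature
  differences between image groups (`compute_features()`,
  `summarize_group()`, `compare_groups()`).
* **A synthetic carotid phantom** (`generate_phantom()`): a 1024×1024
  piecewise-banded chirp image with two bright strips mimicking the IMC
  walls, exact IA/IF ground truth, and zero-mean uniform multiplicative
  speckle (`add_speckle()`), so estimator accuracy can be measured
  region by region (`run_synthetic_experiment()`).
* **Preprocessing** for clinical images: resolution standardization to
  16.66 px/mm, blood/adventitia intensity normalization, and fixed-length
  ROI extraction (`standardize_resolution()`, `normalize_intensity()`,
  `extract_roi()`).

## Worked example

Generate the phantom, speckle it, despeckle with the hybrid median filter,
demodulate, and extract texture features over the bright strips:

```r
library(amfmtex)

tr <- generate_phantom(carotid_phantom_spec())
g  <- add_speckle(tr, speckle_spec(variance = 0.07, seed = 0))
f  <- despeckle(g, "hybridmedian")
am <- amfm_demodulate(f, scales = c("low", "medium", "high"))
summary(am)
#> per-scale AM-FM summary (IF in cycles/mm):
#>   scale valid_frac ia_median if_median_cmm
#>     low     0.9641    103.66         2.089
#>  medium     0.8318     71.10         2.582
#>    high     0.8003     11.27         6.601

ft <- compute_features(am, roi = tr$masks$strips)
round(ft$medians, 3)
#>     LIA     LIF     MIA     MIF     HIA     HIF
#> 176.897   2.153 163.119   2.294  20.755   6.566
```

`valid_frac` is the fraction of pixels with a usable in-band IF estimate at
each scale; the low-scale IF median of 2.09 cycles/mm sits inside the
phantom's generating range (the background sweep corresponds to 1.57–2.62
cycles/mm in magnitude at 16.66 px/mm). The feature medians are the
per-image scalars used for group comparison: amplitude medians track the
band amplitudes (the strips are generated at 250), and the IF medians
increase with scale as designed.

The synthetic experiment reports low-scale IF estimation error (mean
squared error in (rad/pixel)², 16-px border trim) over the background,
strip and combined regions:

```r
run_synthetic_experiment(filters = c("lsmv", "hybridmedian"))
#> Low-scale IF error (mse, seed 0, noise variance 0.07, border 16 px):
#>     condition lifx_backgrounds lifx_strips lifx_combined lify_backgrounds lify_strips lify_combined
#>    noise-free         5.10e-04    1.99e-03      6.35e-04         1.15e-02    9.20e-03      1.13e-02
#>      speckled         6.12e-04    2.05e-03      7.34e-04         1.16e-02    9.24e-03      1.14e-02
#>          lsmv         6.13e-04    1.97e-03      7.28e-04         1.16e-02    9.22e-03      1.14e-02
#>  hybridmedian         6.00e-04    2.09e-03      7.26e-04         1.16e-02    9.26e-03      1.14e-02
```

The noise-free row is the accuracy ceiling; the speckled row shows the
degradation without filtering; the remaining rows show each filter's
effect. The x-component errors are small because the phantom's row
frequency is exactly constant per column; the y-component carries the
generator's deliberate chirp cross-term and is harder everywhere (see the
methods vignette, `vignettes/amfm-despeckle-methods.Rmd`).

## Command line

```sh
Rscript inst/cli/amfmtex phantom --noise-var 0.07 --seed 0 --out-dir out/
Rscript inst/cli/amfmtex despeckle --filter hybridmedian in.tif out.tif
Rscript inst/cli/amfmtex amfm in.tif --pixel-density 16.66 --out-dir amfm/
Rscript inst/cli/amfmtex table1 --filters lsmv,hybridmedian --out table1.csv
```

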