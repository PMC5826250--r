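# numerotune

Tools for studying how **set size** (subitizing vs. estimation range) and
**spatial arrangement** (random, canonical, dice dot patterns) shape
numerosity coding in region-of-interest voxel patterns and behavior.

The package is aimed at cognitive neuroimagers running multivoxel pattern
analyses on ROI data: it implements the Gaussian numerosity-tuning model
with scalar variability, a pairwise-decoding representational-similarity
pipeline, percent-signal-change slope/discontinuity analyses, behavioral
trimming and back-transforms, and a calibrated synthetic-data generator so
that every estimator can be validated by parameter recovery.

## The model

Numerosity-tuned populations are modeled with Gaussian tuning curves whose
width grows proportionally with the preferred numerosity (scalar
variability):

    f(x) = 1 / (sqrt(2*pi) * w * n) * exp(-(x - n)^2 / (2 * (w * n)^2))

`w` is a dimensionless Weber-like width: the curve for numerosity `n` has
s.d. `w * n`, so representations blur as magnitude grows. Sharper tuning
(smaller `w`) means more distinct activity patterns for neighboring
numerosities, which a pairwise classifier reads out as *lower*
classification error. Inverting that logic, the width of the
classification-error "similarity curves" estimates the precision of the
underlying code: `w` is fitted by nonlinear least squares of
`scale * f(x; n, w)` to the error curves, jointly over all reference
numerosities of an arrangement.

Amplitude and behavior are analyzed with two-stage summary statistics:
per-subject OLS slopes of PSC (or log RT) on centered numerosity within each
arrangement x range cell, then group-level sign-flip permutation tests —
including the signature *discontinuity* between the subitizing (2-4) and
estimation (5-8) ranges.

## Worked example

The `analysis/` scripts run the whole workflow at the package's analysis
scale (24 subjects, 80 voxels, 12 exemplars per condition, SNR-preserving
noise scaling):

```sh
Rscript analysis/01_simulate.R    # synthetic patterns, PSC, trials
Rscript analysis/02_decode.R     # pairwise decoding -> similarity matrix
Rscript analysis/03_fit_width.R  # tuning-width fits per arrangement
Rscript analysis/04_amplitude.R  # PSC slopes, discontinuity, contrasts
Rscript analysis/05_behavior.R   # trimming, summaries, RT slopes
```

With the generator's calibrated ground truth (widths 0.094 / 0.241 / 0.276
for dice / canonical / random), the decode + fit stages print:

```
Mean same-arrangement classification error:
     dice canonical    random
    0.010     0.022     0.029
dice       w_hat = 0.085 (scale 0.31, sse 0.1817, converged)
canonical  w_hat = 0.118 (scale 0.49, sse 0.3735, converged)
random     w_hat = 0.134 (scale 0.56, sse 0.3874, converged)
Width ordering matches ground truth (dice < canonical < random).
```

The fitted widths are attenuated (the diagonal of the similarity matrix is
pinned at the chance error 0.5, which anchors the curve peaks but shrinks
the scale of the estimates); what the pipeline recovers — and what the test
suite asserts across 50 seeds — is their *ordering*, i.e. the relative
precision of the three arrangement codes.

The amplitude stage recovers the configured slope structure (true random
estimation slope 0.04, dice estimation slope -0.14, flat canonical) and the
subitizing-to-estimation discontinuity:

```
Slope discontinuity (estimation - subitizing):
  arrangement   delta_slope    p_value n_subjects
1      random  0.0638777154 0.00009999         24
2   canonical -0.0005207196 0.96660334         24
3        dice -0.1429558492 0.00279972         24
```

and the behavior stage reproduces the calibrated condition profile — e.g.
random-estimation error rate back-transformed to 20.0% (calibration 18.8%),
geometric-mean RT 920 ms (calibration 916 ms), 6.6% of trials removed by
trimming (below the 10% bound), random-estimation log-RT slope 0.155
(calibration 0.155).

Programmatic use mirrors the scripts:

```r
library(numerotune)
cfg <- scale_config(generator_config(), n_voxels = 80)
res <- run_pipeline(cfg, output_dir = "results", seed = 1, n_folds = 3)
res$fits$dice$w_hat                 # fitted tuning width, dice arrangement
res$discontinuities                 # per-arrangement slope discontinuity
```

Real ROI data enter through `import_roi_patterns()` (NIfTI coefficient maps
plus a binary mask; voxels ordered by ascending linear mask index) and the
tidy CSV readers (`read_patterns()`, `read_table_csv()`).

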