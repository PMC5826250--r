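---
title: "Modeling numerosity coding: tuning widths, pairwise decoding, and the subitizing-estimation divide"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling numerosity coding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(numerotune)
```

## The scientific problem

When people enumerate a briefly flashed set of dots, two regimes coexist:
*subitizing* — fast, near-errorless apprehension of up to four items — and
*estimation* — approximate, error-prone judgment of larger sets. The
intraparietal sulcus (IPS) carries numerosity information in both regimes,
and the approximate number system is standardly modeled with overlapping
Gaussian tuning curves whose width grows in proportion to the preferred
numerosity (*scalar variability*). Spatial structure matters too: dice-like
and other canonical dot configurations are enumerated faster and more
accurately than random scatters, suggesting a sharper neural representation
for overlearned arrangements.

This package implements the full analysis chain for studying those questions
with region-of-interest voxel patterns and behavioral records:

1. a **tuning model**: the Gaussian numerosity density with scalar
   variability and a nonlinear least-squares estimator of its width;
2. an **RSA pipeline**: cross-validated pairwise decoding of all condition
   pairs, with classification error as the pattern-similarity measure;
3. an **amplitude analysis**: percent-signal-change (PSC) slopes per
   arrangement and number range, and the subitizing-to-estimation
   discontinuity;
4. a **behavioral analysis**: reaction-time trimming, log/logit transforms
   and back-transforms, and per-cell slopes;
5. a **synthetic-data generator** calibrated to published condition
   statistics, so every stage can be validated end to end by parameter
   recovery.

## The tuning model

A population tuned to numerosity $n$ responds to a probe $x$ with density

$$f(x) = \frac{1}{\sqrt{2\pi}\,wn}\, e^{-\frac{(x-n)^2}{2(wn)^2}},$$

where the dimensionless width $w$ plays the role of a Weber fraction: the
tuning s.d. is $w \cdot n$, so curves widen with magnitude and consecutive
numerosities become harder to distinguish as $n$ grows. `tuning_density()`
evaluates $f$, `curve_overlap()` integrates the pointwise minimum of two
curves (a convenient overlap index in $[0,1]$), and `fit_tuning_width()`
estimates $w$ from similarity-curve data by damped Gauss-Newton
(Levenberg-Marquardt) iteration with $w$ (and optionally an amplitude $s$)
log-parameterized to enforce positivity.

```{r tuning}
tuning_density(5, 5, 0.276)          # peak height at the preferred numerosity
curve_overlap(5, 6, 0.094)           # sharp tuning: little overlap
curve_overlap(5, 6, 0.276)           # wide tuning: much more
```

Three numerical choices deserve comment.

**Amplitude.** Classification error is bounded by chance (0.5), while the
literal density peak $1/(\sqrt{2\pi}wn)$ exceeds 1 when $wn$ is small. The
default fit therefore estimates a free amplitude $s$; `fit_scale = FALSE`
reproduces the literal $s = 1$ model. The start value for $w$ is 0.4, the
convergence tolerance is $10^{-8}$ on the change in residual sum of squares,
and the iteration cap is 500, with `converged = FALSE` reported rather than
an error when the cap is hit.

**The diagonal.** A two-class decoder cannot be run on a condition against
itself, so self-similarity points are undefined and `fit_tuning_width()`
drops them by default. However, the arrangement-level estimator
`estimate_arrangement_width()` *pins the diagonal at the chance error 0.5*
by default, and this is deliberate. With integer-spaced probes and the
diagonal excluded, a tuning s.d. below the probe spacing ($wn < 1$, e.g.
the dice width 0.094 at any $n \le 6$) is not identifiable: all
off-diagonal pattern pairs are then close to orthogonal, the error curve is
flat in distance, and an unanchored fit drifts to arbitrarily large widths.
Anchoring the (known) chance point restores the peak of the curve and makes
the fitted width track the precision of the representation. Fitted widths
under the anchor are attenuated — recovery is *ordinal*, not quantitative,
which is exactly the claim the recovery tests assert.

**Joint fitting.** All reference numerosities of an arrangement are fitted
jointly with a single $w$ (curves differ only through the $wn$ scaling), and
subitizing and estimation ranges enter one joint fit. The alternative — one
width per range — would leave the dice estimation range with two
numerosities only.

## Pairwise decoding and similarity curves

`pairwise_decode()` cross-validates a ridge-penalized logistic regression
(logit link) between the voxel patterns of two conditions: stratified folds
(default 5, reduced when exemplars are few), per-fold feature
standardization estimated on training folds only, and a fixed ridge penalty
(default strength 1) because voxel counts typically exceed exemplar counts,
where an unpenalized logit is not even identified. The solver is an exact
IRLS for the convex ridge-logit objective, run in the dual (Gram) space
because the pipeline performs tens of thousands of tiny $n \ll p$ fits; the
test suite pins its predictions against an independent reference
implementation. Fold assignment is deterministic given `seed`.

`similarity_matrix()` runs every unordered condition pair within every
subject and averages `1 - accuracy` across subjects; `similarity_curves()`
slices one arrangement's block into per-reference curves, and
`estimate_arrangement_width()` composes the slicing with the width fit.
Cross-arrangement pairs are computed and stored but do not enter curve
fitting.

## Amplitude and behavioral analyses

Group inference uses two-stage summary statistics throughout, not mixed
models: per-subject ordinary least-squares estimates, then group-level
sign-flip permutation tests. This keeps the package self-contained and
assumption-light; for the balanced designs the generator produces, the
per-subject residual and slope definitions agree in expectation with their
mixed-model counterparts.

* `center_numerosity()` centers the numerosity predictor within each
  arrangement-by-range cell (subitizing = 2-4, estimation = 5-8, dice capped
  at 6), so slopes are comparable across cells.
* `range_slopes()` fits each subject's PSC slope per cell (hemispheres
  pooled by default; `by_hemisphere = TRUE` splits them) and reports the
  group mean with `se = sd/sqrt(n)`.
* `discontinuity_test()` tests the per-subject slope difference
  (estimation - subitizing) with sign-flip permutations, add-one corrected:
  $p = (1 + \#\{|T_{perm}| \ge |T_{obs}|\})/(1 + B)$, $B = 10{,}000$ by
  default, so $p$ is never exactly zero.
* `trim_rts()` removes error trials, reaction times under 200 ms, and
  trials whose log-RT residuals (from a per-subject fit of cell means plus
  centered numerosity) exceed 3 global SDs. The residual screen iterates to
  a fixpoint, which makes trimming idempotent — re-trimming trimmed data
  removes nothing.
* `condition_summaries()` reports per-cell mean log RT of correct trimmed
  trials (back-transformed with `exp`, i.e. a geometric mean) and pooled
  error log odds (back-transformed with the inverse logit to percent).
  Error rates use *all* trials — trimming removes error trials, so the two
  paths necessarily read different trial sets. Cells with zero (or all)
  errors receive a 0.5-count continuity correction to keep the log odds
  finite; a subject-level averaging option exists for sensitivity checks.

One calibration subtlety: the published canonical-estimation log-RT slope
(0.010) is accompanied by a standard error and $z$ statistic that are
mutually inconsistent in the source; the generator uses the printed slope
value as its default and does not attempt to reconcile the inconsistency.

## What the generator emulates — and what it does not

`generator_config()` bundles every constant. Calibrated defaults (from the
published condition-level statistics):

| parameter | default |
|---|---|
| tuning widths $w$ | random 0.276, canonical 0.241, dice 0.094 |
| PSC cell means/SDs | published arrangement x range x hemisphere table |
| PSC slopes per cell | sub: -0.02 / 0.00 / 0.01; est: 0.04 / 0.00 / -0.14 |
| log-RT means (log-ms) | sub: 6.27 / 6.23 / 6.23; est: 6.82 / 6.47 / 6.27 |
| log-RT slopes | random 0.045 / 0.155; canonical 0.041 / 0.010; dice 0.004 / -0.021 |
| error log odds | sub: -5.51 / -5.44 / -6.35; est: -1.46 / -3.38 / -5.94 |
| trials per subject | 336 (two runs of 168) |

Free parameters the source does not determine, chosen once and recorded in
`ground_truth`: 24 subjects, 200 voxels, 12 exemplars per condition, voxel
preferences log-uniform on $[1, 10]$ (numerosity-tuned populations tile the
number line roughly uniformly in log space), pattern gain 1, exemplar noise
s.d. 0.65 (placing adjacent-numerosity decoding in the informative range of
the error curve, matching the magnitude of published similarity curves),
subject-intercept s.d. 0.10 for PSC and log RT, trial-level log-RT s.d.
0.25, and 1% fast-guess contamination uniform on $[50, 200)$ ms so the
trimming path always has work to do.

Voxel patterns are built exactly from the tuning model: voxel $v$ with
preference $p_v$ responds to condition $(a, n)$ with mean
$\exp(-(n - p_v)^2 / (2 (w_a p_v)^2))$, plus independent Gaussian noise per
exemplar. Preferences are fixed within subject and resampled across
subjects. PSC records are cell mean + subject intercept + slope x centered
numerosity + residual noise, with the residual s.d. chosen so the marginal
SD matches the published cell SD. Behavioral trials are balanced across the
19 conditions, with Bernoulli errors from the configured log odds and
log-normal RTs.

The generator reproduces the *statistical structure the analyses assume* —
tuning-governed pattern similarity, linear cell slopes, log-normal RTs. It
does not emulate BOLD time series, hemodynamic convolution,
spatial correlation between voxels, attentional drift, or any dependence of
errors on numerosity within a range (cell-level log odds are flat). Passing
recovery tests therefore validates the estimators against their own
assumptions; they say nothing about, for example, robustness to temporally
autocorrelated noise in real data.

Two properties one might expect of the generator are in fact false, and the
test suite deliberately does not assert them. The *mean* same-arrangement
classification error is not monotone in $w$: at small numerosities a
sub-unit-width curve recruits almost no voxels between integer preferences,
weakening the total signal, so the pattern separation of e.g. 2 vs 3 dots is
*smaller* under dice-like tuning than under wide tuning. The faithful,
robustly monotone prediction — and the one tested — is the confusion of
adjacent *large* numerosities (5 vs 6), where the three widths straddle the
unit probe spacing.

## Problem sizes and the scaling rule

Simulation studies run at a reduced "analysis scale" chosen once:
**24 subjects, 80 voxels, 12 exemplars, 3 decoding folds**, with the
exemplar noise rescaled by `scale_config()` as
$\sigma \mapsto \sigma\sqrt{V/V_0}$ when the voxel count changes — pattern
separations grow with $\sqrt{V}$, so this holds the pattern-level
signal-to-noise ratio of the default configuration. Width-recovery studies
use 25-50 seeded replicates; slope-recovery studies 500 replicates at the
default 24 subjects; null-calibration studies 200 simulations. The
`analysis/` scripts run the same sizes.

## Design choices where the ground was open

* **Cross-validation scheme:** stratified 5-fold over exemplars (3-fold in
  the scaled simulations), folds reduced to the smaller class size when
  exemplars are few. Exemplar counts per condition are a free design
  parameter, so the scheme had to be robust to small classes.
* **Similarity measure:** classification error, stored as a plain mean over
  subjects; subject-level matrices are retained for inspection.
* **Hemispheres** are kept in the PSC data model (the left IPS responds
  more strongly in the calibration table) but pooled for slope estimation by
  default, with a flag for per-hemisphere results.
* **Permutation inference:** 10,000 sign flips with add-one correction;
  under the null the test is slightly conservative (discrete p-values),
  which the calibration test tolerates explicitly (rejection rate at
  $\alpha = .05$ bounded by .075).
* **Error-rate pooling:** trials pooled within cell (closer to a
  logit-link GLM's pooled estimate) rather than averaging subject-level
  proportions; both options are exposed.
* **Tabular dialect:** comma-separated, UTF-8, header row, `.` decimal
  separator, empty missing values — fixed to avoid locale drift. NIfTI
  import orders voxels by ascending linear mask index, documented so
  real-data runs are reproducible.

## Known limitations

* Recovery of $w$ is ordinal under the chance anchor; absolute fitted
  widths are attenuated and should not be compared across studies with
  different probe ranges.
* The two-stage summary-statistics inference ignores per-subject
  uncertainty differences; with balanced synthetic designs this is
  harmless, with badly unbalanced real data a mixed model would be
  preferable.
* Cells with a single distinct numerosity (possible after aggressive
  filtering of real data) silently lose that subject from slope estimates,
  with the count reported in `n_omitted`.
* The decoder assumes exchangeable exemplars; run structure (scanner
  drift, session effects) in real data would require leave-run-out folds,
  which the `n_folds`/seed interface accommodates but does not automate.
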