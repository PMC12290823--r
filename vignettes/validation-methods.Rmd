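---
title: "Validating presurgical fMRI maps against intraoperative stimulation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating presurgical fMRI maps against intraoperative stimulation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(desconcord)
```

## The problem

Before resective brain surgery near the sensorimotor cortex, functional MRI
is used to map eloquent cortex. Task-based fMRI (tbfMRI) localizes the
hand or foot representation through a block-design motor task; seed-based
resting-state fMRI (rsfMRI) maps the sensorimotor network without any task,
which matters for patients who cannot perform one. Intraoperative direct
electrical stimulation (DES) is the clinical gold standard: during surgery
the cortex is stimulated at saved coordinates, and each site is recorded as
positive (pDES, a sensorimotor response was elicited) or negative (nDES,
none).

`desconcord` implements the quantitative machinery for asking how well a
presurgical map agrees with DES: every statistic map is binarized by a
deterministic automatic threshold, the minimum Euclidean distance from each
DES site to the suprathreshold voxels is measured in world millimetres, and
the resulting semicontinuous distances are analysed with ROC curves, binary
agreement tables, overlap indices, and a two-part mixed-effects model.
Because clinical DES data cannot be shared, the package ships a phantom
generator that reproduces the statistical structure of such a cohort, so
the entire analysis is exercised end to end on synthetic data.

## Map generation

Four acquisition schemes are modelled, differing in voxel size, repetition
time and length as in typical clinical protocols: tbfMRI at
1.8 x 1.8 x 3.2 mm (TR 1.5 s, 160 volumes), single-echo rsfMRI at
2 x 2 x 2.2 mm (TR 0.9 s, 500 volumes), and a three-echo rsfMRI scheme at
3 mm (TR 1.15 s, 400 volumes, TE = 8/33/58 ms) whose middle echo doubles as
a 3 mm single-echo scheme.

* **Task GLM.** The block regressor (pairs of 30 s task/control blocks) is
  convolved with a double-gamma haemodynamic response
  `h(t) = g(t; 6, 1) - g(t; 16, 1)/6` (peak at 5 s, late undershoot) and
  fitted voxelwise by ordinary least squares after 6 mm FWHM Gaussian
  smoothing, framewise-displacement regression, and Gaussian-weighted
  high-pass filtering with sigma = 20 TR. The regressor's t statistic is
  converted to a z score by matching tail probabilities at the residual
  degrees of freedom and capped at |z| = 40 so that noise-free fits remain
  finite. No prewhitening is applied: the downstream k-means rescaling is
  invariant to monotone recalibration of the map, so the ordering of voxel
  evidence — not its absolute calibration — is what matters here.
* **Seed connectivity.** After the same smoothing and confound regression,
  the series is band-pass filtered to 0.001–0.01 Hz (an intentionally
  narrow band, kept configurable) by exact FFT projection — the filter is
  idempotent by construction. The map value is the regression slope (beta)
  of each voxel on the variance-standardized mean seed time course; the
  Pearson correlation is retained for quality control.
* **Multi-echo combination.** The mono-exponential signal model
  `S(TE, t) = S0(t) exp(-TE * R2*(t))` separates TE-independent artifact
  fluctuations (in `S0`) from TE-dependent neuronal BOLD fluctuations (in
  `R2*`). A voxelwise T2* is estimated by a log-linear fit of the
  time-averaged signal against TE, and echoes are averaged with weights
  proportional to `TE * exp(-TE / T2*)` (the BOLD-sensitivity-weighted
  combination). Voxels with non-positive mean signal or non-decaying fits
  fall back to uniform weights and are flagged. Under the generator's noise
  model, where thermal noise scales with the echo's signal level, the
  combination strictly improves temporal SNR over any single echo.

Quality metrics are the voxelwise temporal SNR and the mean framewise
displacement, with the conventional 50 mm lever arm for rotations.

## Automatic thresholding

Maps are constrained to the subject's gray-matter mask and clipped at zero:
only positive task activation or positive connectivity is clinically
relevant here, and negative values would drag the intensity rescaling
toward low values. The positive intensities are then rescaled to ranked
k-means labels (101 bins by default, so labels span 1–101) and the
binarization threshold is computed from the label distribution as

> T = m + alpha * s,

with `m` the mean and `s` the population standard deviation of the nonzero
labels and `alpha = 1` by default; voxels with label >= T are retained.
Three conventions in this rule had to be fixed for bit-reproducibility and
are exposed as arguments: the population (not sample) standard deviation,
retention at `>=` (not `>`), and the 101-bin label range.

The 1-D k-means itself is computed exactly, by a weighted
divide-and-conquer dynamic program (in C++), rather than by Lloyd
iterations: the within-cluster sum of squares is the global optimum for
every input, which makes the labelling deterministic, order-independent,
and verifiable against an independent dynamic program in the test suite.
Ties sit with the lower cluster. Because only the ranks of cluster
boundaries matter, the labelling — and hence the binarized map — is
invariant to strictly increasing transforms of the intensities that
preserve the optimal boundaries; this is why miscalibrated z scores and
connectivity betas can be thresholded by one common rule.

## Distance scoring

DES sites are represented by 5 mm radius spheres rasterized on the 1 mm
anatomical grid; the center of gravity of each sphere (the unweighted mean
of member voxel centers, coincident with the coordinate by construction up
to rasterization) is the reference point. Distances are computed
center-of-gravity to voxel-center, entirely in world millimetres through
the affine, never across voxel indices. A surgical-field mask — the union
of all DES spheres dilated by a 15 mm spherical structuring element
(morphological dilation via FFT convolution), intersected with the brain
mask — restricts the search as an accelerator only: when it contains no
suprathreshold voxel the search falls back to the full map and the record
is flagged, so masked and unmasked answers agree whenever the minimizer
lies inside the mask (property-tested). Distances are rounded to integer
millimetres, halves away from zero, since sub-voxel increments on a 1 mm
grid are not meaningful. Maps with no suprathreshold voxels yield an
undefined record that is excluded downstream with a warning.

Positive DES sites are paired only with the matching function's map (a hand
response is evidence about the hand map); negative sites are paired with
every function's map, since "no response" is evidence against all of them.
This pairing is a package-level convention, implemented in one place
(`des_pairings()`), because the opposite choice for positives is also
defensible.

## Agreement statistics

Because patients contribute very unequal numbers of DES sites, distances
are first averaged per subject x function x response, so each subject
carries at most one pDES and one nDES value per function into the ROC. A
distance below the cutoff counts as a positive (agreeing) result;
sensitivity and specificity follow from the pDES/nDES labels. Candidate
cutoffs are midpoints between consecutive unique distances plus sentinels,
which is how non-integer operating points arise from integer distances. The
ROC area is the trapezoid over (1 - specificity, sensitivity) and equals
the tie-corrected Mann-Whitney statistic exactly (an identity the test
suite checks on random data).

Operating cutoffs are the local maxima of the Youden index (sensitivity +
specificity - 1) along the cutoff axis of the task-fMRI ROC — the standard
operating-point statistic when none is otherwise mandated;
plateaus count once at their smallest cutoff, and the top three by Youden
value are kept and rounded to integers. Paired ROC curves are compared with
the DeLong placement-value test, restricted to subject x function x
response groups present in both methods. When the estimated variance of the
AUC difference is zero the test is flagged degenerate: identical AUCs give
p = 1, different AUCs give p = 0.

Map-to-map similarity uses the Dice coefficient `2|A.B|/(|A|+|B|)` and
Jaccard index `|A.B|/|A.B|`, linked by `JI = DSC/(2 - DSC)`; the both-empty
case is defined as 0 and flagged rather than 0/0.

## The two-part mixed model

At an agreement cutoff c, distances become semicontinuous: `y = 0` when
the distance is below c (the site "overlaps" the map) and `y = d`
otherwise — a point mass at zero plus a right-skewed positive part.
Zeroing everything below the cutoff (not only exact zeros) follows from
reading the first model part as the probability of agreement *at that
cutoff*; the exact-zero alternative is exposed as an option. The two-part
model for subject i, row j is

* part A (overlap): `logit P(y_ij = 0) = x_ij' beta_A + u_i`
* part B (distance): `log y_ij | y_ij > 0 ~ N(x_ij' beta_B + v_i,
  sigma_eps^2)`

with `(u_i, v_i)` bivariate normal — SDs `sigma_u`, `sigma_v`, correlation
`rho` — linking a subject's propensity to overlap with how far its
non-overlapping sites sit. Covariates are the DES response indicator and
three acquisition-method dummies against the task-fMRI reference; no
clinical covariates enter.

The marginal likelihood integrates the random effects by two-dimensional
Gauss-Hermite quadrature (default order 15 per dimension). The lognormal
part is quadratic in `v_i`, so it collapses to three sufficient statistics
per subject and the cost is linear in the number of rows; the quadrature is
validated against dense-grid trapezoid integration (2001^2 nodes over
+/- 8 SD) to 1e-6 and is stable in the order (11 vs 31 changes the
log-likelihood by < 1e-4 on the test fixtures). Estimation maximizes over
`(beta_A, beta_B, log sigma_u, log sigma_v, atanh rho, log sigma_eps)` by
BFGS from part-wise starting values (separate logistic and lognormal fits,
small variances, zero correlation) with two additional deterministically
jittered starts; standard errors come from the inverse observed Hessian
with a delta-method transform back to the natural scale. Wald tests use
`df = n_subjects - 2` — subjects minus the number of random effects, the
convention under which a 16-subject cohort reports df = 14 — and the
degenerate `sigma_u = sigma_v = 0` fit reproduces the closed-form separate
MLEs, which pins the likelihood's normalization.

Post-hoc inference reports the five pairwise method contrasts per model
part, with family-wise error controlled within each part-by-cutoff family
of five by Hochberg's step-up procedure; the default "adaptive" variant
replaces the family size by the Hochberg-Benjamini estimate of the number
of true nulls (clamped to [1, m]), and the plain 1988 variant — which
matches `p.adjust(method = "hochberg")` exactly — is also provided, since
the published analyses do not say which of the two their software used.

## The phantom cohort

The generator builds, per subject, an ellipsoidal brain with a cortical
gray-matter shell on a 1 mm anatomical grid spanning an 80 x 80 x 60 mm
region around the motor strip — a deliberately desk-scale field of view
that keeps a 16-subject cohort runnable in minutes while leaving room for
negative sites tens of millimetres from truth. Activation truth is a union
of 6 mm spheres at hand-knob-like and paracentral positions, intersected
with the shell; hands are mapped for every subject, feet for the first
five. Secondary activation blobs 14 mm anterior of the primary centers, at
0.7 relative amplitude, stand in for the premotor/supplementary-motor
engagement that motor tasks and the resting sensorimotor network both
show; they appear in the imaged maps of every scheme but are not DES
ground truth, so — as in patients — the maps contain functionally real
positive cortex that no stimulation site certifies.

Key generative choices, fixed once:

* **DES sites.** Counts vary per subject (0–3 positive, 3–8 negative),
  reproducing the highly unequal repetition that motivates the averaging
  and the mixed model; some subjects have no positives at all. Negative
  sites are placed at lognormal distances from truth (median 17 mm,
  sdlog 0.6, at least 5 mm away); positive sites lie within 16 mm of
  truth. Placed-to-truth distances are deliberately larger than the
  distances the pipeline reports, because thresholded maps extend a few
  millimetres beyond truth: after that halo, *measured* map-to-site
  distances land where clinical sensorimotor cohorts put them (negative
  sites at a median near 12 mm, positives near 4 mm). The two distance
  laws overlap, as in real cohorts — stimulation hits near, not inside,
  the imaged activation — which keeps the ROC away from degeneracy.
* **Signal.** Task scans add a 2% BOLD response (amplitude 20 on a
  baseline of 1000) times the convolved regressor inside truth. Rest scans
  add a shared band-limited (0.003–0.009 Hz) network fluctuation inside
  truth *plus an 8 mm surrounding cortical band at 0.6 relative
  amplitude*: resting-state connectivity maps are characteristically more
  widespread and less specific than task activation, and without this
  extension all four methods would measure essentially one geometry,
  which no real cohort shows. Multi-echo scans realize the neuronal
  fluctuation in `R2*(t)` and a small artifact fluctuation in `S0(t)`.
* **Heterogeneity.** Each subject carries a lognormal response gain
  (sdlog 0.15) and each scan another (sdlog 0.25), emulating the
  session-to-session BOLD amplitude variability that induces correlated
  subject-level variation in map quality — the structure the two-part
  model's random intercepts absorb.
* **Noise.** Additive Gaussian with AR(1) (coefficient 0.3), scaled per
  echo with the echo's signal level; noise is simulated inside the brain
  mask (outside voxels stay at baseline, and nothing downstream reads
  them). Motion parameters are emitted as a known random-walk regressor
  but are not applied as geometric motion — realignment is out of scope.
* **Reproducibility.** Each subject's stream is seeded from (master seed,
  subject index), so any subject regenerates identically in isolation.

What the phantom does *not* emulate: MR physics (no k-space, distortion or
susceptibility), true head motion, lesions and perilesional signal (a
spherical lesion can be carved out, but no inpainting artifacts),
physiological noise spectra, spatially autocorrelated noise beyond the
applied smoothing, or realistic cortical folding. Passing the end-to-end
checks therefore demonstrates that the *analysis machinery* behaves
correctly under the assumed statistical structure — not that any
acquisition scheme would achieve these accuracies in patients.

## Numerical conventions

Filters operate by FFT with zero-padded linear convolution
(edge-renormalized Gaussian running mean for the high-pass; exact
symmetric-bin projection for the band-pass, using integer bin indices so
the projection is exactly idempotent). Smoothing is separable Gaussian with
per-axis sigma in voxel units, reflective boundaries, truncation at 4
sigma, applied through sparse banded operators. Morphological dilation
thresholds an FFT convolution with the voxelized ball at 0.5. The z cap is
40; zero-variance voxels report infinite tSNR and are flagged. All
geometry uses voxel centers; resampling of binarized maps to the
anatomical grid is nearest-neighbour, which keeps maps binary by
construction.

## Problem sizes

The shipped tests and the acceptance script use the cohort defaults above:
16 subjects, four schemes, full-length series (160/500/400 volumes), which
run in a few minutes on one core. Parameter-recovery checks for the
two-part model use 200 subjects with one row per method x response cell
and 50 replicate fits at quadrature order 9. Oracle comparisons (exact 1-D
k-means, brute-force distances, dense-grid likelihood) run at reduced sizes
where the oracle is the bottleneck, with the oracle always implemented
independently of the package path it checks.

## Known limitations

The GLM omits prewhitening, so its z scores are calibrated only under
white noise — harmless for rank-based thresholding, but the z maps should
not be reused for voxelwise inference. The adaptive Hochberg variant is
implemented from the step-up definition with the true-null estimate
plugged in; with five tests per family the two variants rarely differ. The
two-part fit assumes at least one zero and one positive outcome; cohorts
entirely on one side of a cutoff must be analysed at a different cutoff.
DeLong comparisons drop subjects missing a method rather than imputing.
Finally, the phantom's brain is small: negative-site distances are
truncated near ~40 mm, so extreme-tail behaviour of the distance
distribution is not represented.
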