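---
title: "Spectral-slope lifespan analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral-slope lifespan analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific question

The power spectrum of resting-state BOLD fluctuations is approximately
1/f-like in the infraslow band: log power falls roughly linearly with
frequency. The *spectral slope* (SS) — the negative of the slope of a
regression of log10 power on raw frequency over 0.015–0.145 Hz —
summarizes how strongly slow activity dominates. `boldslope` implements a
complete lifespan analysis of this quantity: per-parcel SS estimation
from motion-censored timeseries, penalized-spline age models with FDR
control, fuzzy clustering of age trajectories, spin-permutation tests of
spatial association with metabolic maps, and a per-subject "youthful
index" with robust outlier detection and white-matter correlates. A
seeded synthetic cohort generator provides data with the statistical
structure the analysis assumes, so every stage can be exercised and
validated end to end.

# Spectral estimation

## Censored autocovariance with a Gaussian lag taper

Frames contaminated by head motion are excluded by a valid-frame mask.
The series is demeaned over valid frames; for each lag `m` (1-based,
`m = 1` is zero shift) the raw product sum runs over frame pairs in which
*both* frames are valid, with `n` the number of such pairs. Each lag is
then adjusted by `exp(-q^2/2)/n` where `q = (m-1)*TR/30` is a scaled lag
(the 30 s normalization is treated as a fixed constant of the method).
The default maximum lag is where the taper falls below 1e-3
(`q ≈ 3.72`, about 112 s); later lags contribute nothing after tapering.

## PSD by cosine transform

The one-sided PSD is the cosine transform of the adjusted autocovariance
(the Wiener–Khinchin route, which is what makes frame exclusion
possible):

```
S(f_j) = TR * sum_m w_m * acv_m * cos(2*pi*f_j*(m-1)*TR)
```

on the grid `f_j = j/(2*n_freq*TR)`, `j = 0..n_freq`, with `w_1 = 1` and
`w_m = 2` otherwise. `n_freq = 256` guarantees at least five in-band grid
points for any `TR ≤ 4 s`. Lag-window estimators are not
positivity-preserving; negative values are floored at `1e-12` times the
maximum power before any logging, and floored points are flagged. With
261 frames this flooring occasionally produces extreme slope estimates
when the true slope is very steep (roughly above 11 log10-power/Hz at
the default acquisition) — a genuine property of the estimator that the
synthetic cohort's design respects (see below).

## Semilog slope

SS is the negative OLS slope of log10 power on raw frequency over the
in-band points. Base 10 is fixed: the base scales SS magnitudes, so it
must be pinned for values to be comparable. The semilog (log-normal)
model is preferred over the log–log (power-law) model because it fits
these spectra with higher R²; `compare_spectral_models()` computes both
R² values on identical points so the preference can be verified on any
dataset. A perfectly flat spectrum has slope 0 and its fit R² is
reported as 0 (no variance to explain).

# Lifespan models

Each parcel's SS is modeled across subjects with a generalized additive
model: a thin-plate regression spline of age with basis dimension
`k = 4` and REML-selected smoothing, plus linear sex and head-motion
covariates. The reduced model contains only the covariates. The age
effect is summarized by:

* `p_age` — the p-value of the age smooth. mgcv's standard approximate
  test for penalized smooths is used: in our calibration simulations
  (200 null parcels at n = 455) it is uniform under the null (KS
  p ≈ 0.27, 4.5% rejections at α = 0.05), whereas the deviance-ANOVA
  contrast of full vs reduced fits is slightly anti-conservative
  (6% rejections). The deviance statistic is still returned for
  reporting.
* `delta_r2` — `R²(full) − R²(reduced)` with `R² = 1 − RSS/TSS`
  ("explained variance" is given this concrete definition). Because the
  penalized full model can always reproduce the reduced fit at zero
  penalty cost, `delta_r2 ≥ 0` up to numerical tolerance.

P-values are adjusted across parcels by Benjamini–Hochberg, significant
at `q < 0.05`. Smooths for plotting and clustering are evaluated on a
66-point grid from 20 to 85 years with covariates at their column means
(reference levels are not otherwise identified). Low-SNR parcels are
handled by an exclusion list argument, not recomputed.

# Trajectory clustering

The fitted age smooths of FDR-significant parcels are mean-centered
(not variance-scaled) so that decline *shape*, not amplitude, drives the
clusters; this choice is configurable. Fuzzy c-means uses a fuzzifier of
5, Euclidean distance, at most 10000 iterations, and stops when the
objective improves by less than 1e-5. Initialization is a random
row-stochastic membership matrix from the seed. A point coinciding with
one or more centers concentrates its membership on those centers
(split equally); winner-take-all ties resolve to the lowest cluster
index and are flagged. Clusters are canonically ordered by decreasing
size, so "cluster 1" is always the majority family. The cluster count is
chosen by the mean Euclidean silhouette of the winner-take-all labels
over candidates 2–15; a candidate that collapses to a single non-empty
cluster scores −1. The RSN correspondence index sums RSN probability ×
membership over parcels and is normalized within cluster to sum to one
across networks, making clusters of different sizes comparable.

# Spatial association and the spin test

Two parcel maps are compared by Spearman correlation (average ranks on
ties) over jointly non-missing, non-medial parcels. Significance comes
from a spatial permutation: parcel centroids live on a unit sphere per
hemisphere; each of the (default 10000) permutations draws a uniform
rotation via a normalized 4-D Gaussian quaternion, applies it to the
left hemisphere and its x-mirrored counterpart to the right (the
standard convention; the hemispheres stay in register). Each original
parcel position takes the value of the nearest rotated source parcel
(maximal dot product, i.e. great-circle distance; many-to-one collisions
are allowed), positions whose nearest source is a medial-wall parcel are
dropped, and the correlation is recomputed. The one-sided p-value counts
null correlations strictly greater than the observed one, with the
finite-sample correction `(count + 1)/(R + 1)` so p is never exactly
zero; a two-sided option exists but is off by default, keeping the
printed definition.

Calibration: with isotropic smooth null maps at the default 100-parcel
resolution the test rejects at ≈ 0.045 for α = 0.05. At much coarser
parcellations (e.g. 60 parcels) the nearest-centroid reassignment makes
it mildly anti-conservative (≈ 0.06–0.075) — a known limitation of
nearest-neighbour spin variants, worth remembering when applying the
test to very coarse maps.

# The SS Youthful Index

The reference map is the parcel-wise mean SS of subjects younger than
45; each subject's SSYI is the Spearman correlation of their SS map with
that reference. Outliers are subjects more than 3 scaled MADs from the
median SSYI, with scaled MAD = `1.4826 × median(|x − median|)` (the
Gaussian-consistency constant used by common numerical environments).
T2w volumes are z-scored voxelwise against an atlas (mean, sd) built
from subjects younger than 40 — note the two cutoffs differ by design
(40 y for the intensity atlas, 45 y for the SS reference). SSYI is then
correlated with normalized intensity at every voxel (Pearson, two-sided,
α = 0.05, no multiplicity correction — an exploratory lesion-mapping
style analysis); significant voxels form an ROI whose mean intensity is
each subject's white-matter measure. Finally an ordinary least squares
regression (a linear probability model, deliberately not logistic)
predicts the binarized index — coded 1 = retains the youthful pattern,
0 = outlier — from age, grey-matter volume, head motion, sex and the
FLWM T2w measure. Under this coding, outliers having *higher* FLWM
intensity yields a *negative* FLWM coefficient, which is the sign
convention the reported estimates follow.

# The synthetic cohort

The generator emulates the statistical structure the analysis assumes,
fully reproducibly from one seed (every sub-generator draws from a
stream derived from it).

* **Geometry** — a Fibonacci lattice per hemisphere on a unit sphere
  (the right hemisphere mirrored), a fixed medial-wall cap (~7.5% of
  parcels) excluded from analysis, and probabilistic RSN weights from
  von-Mises–Fisher-like kernels, normalized per parcel.
* **Baseline topography** — the age-20 slope of parcel `p` is
  `6.5 + 2.0 z + 0.8 y + 1.2 (2z²−1) + 1.2·2yz` (range ≈ 2.7–10.3,
  across-parcel sd ≈ 1.7). The second-order terms matter: a purely
  linear field is so smooth that spherical rotations barely decorrelate
  it, which makes spin-test nulls uninformative.
* **Trajectories** — two planted families: continuous decline from age
  20 (0.02 slope-units/yr) and delayed decline from 50 (0.045/yr), the
  delayed family occupying a contiguous 25% cap. Decline amplitude
  scales with `sqrt(baseline/mean baseline)`, so parcels with steeper
  young slopes age more and the age-effect topography tracks the
  metabolic maps, as the analysis is designed to detect. The shape of
  the decline is exposed as a configurable exponent (default linear),
  since plausible alternatives (accelerating decline) exist.
* **Timeseries** — spectral synthesis: Gaussian series whose expected
  one-sided PSD is `10^(a − s f) + noise_floor` with `a = 4` and
  `noise_floor = 1` (in-band powers stay ≥ ~100), via inverse DFT with
  random phases. This gives exact control of the expected semilog slope
  the estimator must recover. Censoring is i.i.d. Bernoulli per frame at
  rate 0.10 (a contiguous-block option exists but is off by default;
  burst-like motion is not modeled).
* **Slope variance budget** — the target fraction of SS variance
  explained by age (`slope_effect_frac`, default 0.10, within the
  0–0.12 range such analyses report) is honoured *including* the
  estimator's own sampling variance, calibrated once by simulation to
  ≈ 2.0 slope-units² for the default acquisition (261 frames,
  TR = 1.97 s, 10% censoring). At the defaults this leaves essentially
  no extra between-subject offset to add — estimation noise already
  supplies the within-parcel residual — which also keeps every target
  slope inside the estimator's stable range (≲ 11).
* **Divergent subjects** — a fraction (default 0.10) of subjects older
  than 45 have their across-parcel slope profile randomly permuted.
  Because SSYI is a rank correlation, this directly destroys the
  topography while preserving the marginal slope values (the multiset of
  slopes is unchanged). Sex, motion and grey-matter volume are generated
  independently of divergence, so the covariate regression has a true
  null for everything except the white-matter term.
* **Metabolic maps** — CMRGlc is a monotone (logistic) transform of the
  young slope topography plus noise (sd 2 against a signal sd of 3,
  giving rank correlations ≈ 0.8); CMRO2 and CBF use noise sds 4 and 6
  and correlate more weakly, in that order.
* **T2w volumes** — a 24³ grid of unit-sd Gaussian noise around a
  constant baseline, with a contiguous frontal ROI carrying +3 intensity
  units in divergent subjects; the reference atlas is the voxelwise
  mean/sd over subjects younger than 40.
* **Covariate distributions** — ages uniform over 18–88, sex
  Bernoulli(0.5), head motion log-normal, GMV Gaussian; only summary
  statistics of the real cohorts are published, so these are generic
  choices, not a distributional claim.

What the generator does *not* emulate: hemodynamic response shape,
physiological (cardiac/respiratory) noise, burst-like motion, spatial
autocorrelation of the noise between neighbouring parcels, and surface
meshes. Passing tests therefore demonstrate that the estimators and
inference machinery behave correctly under the assumed statistical
structure — not that preprocessing artifacts of real data are handled.

# Numerical choices

* Negative PSD values floored at `1e-12 ×` the maximum power; flagged.
* Flat spectra: slope 0, fit R² defined as 0.
* Demeaning over valid frames once, before pairing; no per-lag
  re-demeaning.
* FCM zero-distance rule and winner-take-all tie rule as above; the
  objective trace is recorded per iteration and is non-increasing.
* Spin p-values use the `+1/(R+1)` correction; rotated-map values are
  always a subset of the original map's values.
* MAD = 0 (all values equal) flags nothing.
* Atlas sds are floored at 1e-6 before z-scoring; zero-variance voxels
  are excluded from correlation masks and flagged.
* Manifest hashes use md5 over canonicalized outputs; no timestamps are
  written, so a rerun of the same config is byte-identical.

# Problem sizes used by the test suite

The packaged checks run at sizes chosen to exercise the study
conditions while remaining desk-scale: the default synthetic cohort is
200 subjects × 100 parcels × 261 frames; null-calibration and recovery
simulations for the lifespan models use 200 and 100 replicate parcels at
n = 455 subjects; spin calibration uses 200 repeats of 1000 rotations at
the default 100-parcel resolution; outlier recovery pools three default
cohorts. The full default pipeline completes in about a minute on a
single CPU.

# Known limitations

* The lag-window estimator's variance is substantial at 261 frames
  (slope sd ≈ 1.4), and very steep spectra can produce floored in-band
  values with wild slope estimates; parcel-level SS maps from single
  short runs are noisy objects, which is why rank-based downstream
  statistics are used.
* At 94 analysis parcels the spin test has visibly less spatial power
  than at a 200-parcel resolution; planted associations of moderate
  strength yield p-values in the 0.01–0.1 range rather than the ~1e-4
  attainable with finer maps.
* Per-parcel realized `delta_r2` varies around the 0.10 target (roughly
  0.01–0.25 across parcels) because decline amplitude varies with the
  topography; the *average* matches the target.
* The linear probability model inherits the usual caveats
  (heteroscedastic residuals, predictions outside [0,1]); a logistic
  option exists but the reference path follows the linear fit.
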