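---
title: "Quantifying shared neural representations with cross-modality decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying shared neural representations with cross-modality decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the package answers

Two experimental manipulations — say, two ways of evoking vicarious pain,
one with injury scenes (NS) and one with painful facial expressions (FE) —
may activate overlapping brain regions and still rely on different neural
codes: a region can harbour intermingled neuronal populations whose
voxel-level mixing patterns differ between processes. Overlap of
thresholded univariate maps is therefore weak evidence for a *shared
representation*. The stronger test is predictive: train a multivariate
decoder on one modality and ask whether it classifies the *other*
modality in held-out subjects. Above-chance cross-modality prediction,
together with spatially correlated weight maps, is the operational
definition of a shared representation used throughout this package; its
converse (chance-level transfer despite good within-modality decoding)
indicates modality-specific codes.

`sharedrep` implements that full analysis chain on condition-average
images: whole-brain linear decoding with repeated cross-validation,
between-modality cross-prediction, map-level statistics (group t-maps,
FDR and cluster-extent thresholding, permutation spatial-similarity
tests, bootstrap reliability maps, octant joint-weight summaries),
spherical-searchlight cross-prediction, and pattern-expression transfer
to independent datasets (a graded thermal-pain set and a non-painful
negative-emotion contrast). A synthetic-data generator with planted
ground truth stands in for real fMRI data, so every stage is testable
end to end.

## The decoding model

Each observation is a subject-by-condition masked voxel vector `x` (a
condition-average signal or contrast). The decoder is a soft-margin
linear support-vector machine with hinge loss and penalty `C = 1`,
producing a voxel weight vector `w` and offset `b`.

Pre-processing at train time follows the "scale by the training set"
rule: each voxel is affinely mapped so the training minimum and maximum
become -1 and +1, and test images are transformed with those same
parameters (they may land outside the interval; constant training voxels
map to 0).

Evaluation is subject-paired. The *pattern expression* of an image is
the plain dot product `w . x` (no offset). In the two-alternative forced
choice (2AFC), the member of a subject's (positive, control) pair with
the higher expression is called positive; ties score 0.5. We also report
a single-interval accuracy from the sign of `w . x + b` — the literature
is often ambiguous about which rule a printed "classification accuracy"
used, so both are available. Significance is a one-tailed exact binomial
test of the number of strict wins against chance 0.5 (ties are not
counted as wins, which is conservative), and the effect size is a paired
Cohen's *d*, mean over SD of the per-subject expression differences.

Cross-validation assigns whole subjects to folds (both members of a pair
always share a fold), with fold sizes differing by at most one. The
partition is redrawn `n_repeats` times (default 10) and accuracy, p and
*d* are averaged across repeats. Averaging p values arithmetically is
statistically unconventional but is retained deliberately as the field's
procedure; it also matters quantitatively, as shown below.

### Calibration of the pooled-CV binomial test

Under the null, the number of 2AFC wins pooled across the folds of a
*single* k-fold CV is over-dispersed relative to Binomial(n, 1/2): a
subject's test images also participate in training the other folds'
decoders, which couples outcomes across folds. In simulation (1000 null
datasets, 60 subjects) we measured a win variance of ~22.5 against the
binomial 15 and a 9.1% rejection rate at the 5% level. Averaging p over
repeated partitions restores calibration: 4.5% with 2 repeats and 3.3%
with 10 repeats. The package therefore treats the repeat-averaged p as
the primary inferential quantity, and the test suite checks calibration
with 2 repeats per null replicate (200 replicates at 60 subjects and
2000 voxels), the smallest scale that retains the averaging procedure.

## Map-level statistics

* **Group t-maps** are voxel-wise one-sample t tests of subject contrast
  images, two-tailed at df = n - 1; zero-variance voxels are flagged and
  given p = 1.
* **Thresholding** is Benjamini–Hochberg FDR (default q = 0.05, applied
  jointly over both tails via |t|) followed by a cluster-extent filter:
  18-connected components (faces and edges, not corners — the SPM
  convention) smaller than 100 mm^3 are removed; at 2 mm isotropic
  resolution that removes clusters of up to 12 voxels and keeps 13.
* **Permutation spatial similarity**: the observed Pearson correlation
  between two group maps is referred to a null built by shuffling
  condition labels within subject (sign-flipping contrast rows),
  rebuilding the map and re-correlating — `n_perm` shuffles per
  direction, both directions pooled (per-direction p values are also
  reported). The add-one estimator `(1 + #exceedances)/(1 + 2 n_perm)`
  avoids p = 0. Sign flips leave per-voxel sums of squares unchanged, so
  permuted t-maps need only the permuted means; the null loop is a
  single matrix product.
* **Bootstrap reliability maps** resample subjects with replacement,
  retrain the decoder, and summarize each voxel by z = mean/SD of its
  bootstrap weights with a two-tailed normal p, then FDR + extent
  thresholding. This asks which voxels contribute *reliably*, not merely
  strongly, to the decoder.
* **Octant analysis** summarizes two decoders jointly: each voxel's
  z-scored weights (w_x, w_y) are assigned by angle to eight 45-degree
  sectors — shared-positive (O2, centred 45°), shared-negative (O6,
  -135°), the four selective sectors on the axes, and the two opposite-
  sign sectors. Boundaries belong to the counterclockwise sector, an
  explicit convention with measure-zero impact for continuous weights;
  exact-zero pairs are excluded and counted. The per-octant SSD (sum of
  squared distances from the origin) combines voxel count with weight
  magnitude; dominance of O2 + O6 is the map-level signature of a shared
  code.

## Searchlight cross-prediction

For every in-mask centre, features are restricted to a sphere (radius in
voxel units or mm; 3 voxels equals 6 mm at 2 mm isotropic) and four maps
are computed under one shared fold partition: within-modality CV for
both modalities and both cross-modality directions. Sharing the
partition across centres makes maps comparable and is much cheaper than
re-drawing per centre. Per centre a subject-level one-tailed binomial p
is used (the granularity is not standardized in the literature; the
subject level matches the whole-brain forced-choice test), each map is
FDR-corrected across centres, and the conjunction of all four
significant maps marks local shared representations. Searchlights
default to one repeat; spheres are clipped at the mask with no padding.

## Transfer analyses

Transfer to independent data uses raw dot products — never the training
scaler, since different acquisitions have different units. The
`expression_series()` of a final decoder over a graded thermal set is
(1) correlated with temperature level and with subjective ratings,
pooled across subject-by-level rows (33 subjects by 6 levels gives
df = 196; a within-subject variant is available), and (2) scored by
2AFC between averaged level sets (e.g. the two highest vs the two
lowest temperatures). Specificity runs the pain decoder, under its own
CV fold structure, on the negative-vs-neutral emotion contrast: a
pain-specific code should transfer to somatic pain but stay near chance
on high-arousal negative affect. The synthetic double dissociation —
pain decoder: thermal >> emotion; arousal decoder: emotion >> thermal —
is the testable core of that logic.

## The synthetic-data generator

The generative model is deliberately minimal:

```
image(s, modality, condition) = subject_intercept(s)
                              + sum_k amplitude(condition, k) * pattern_k
                              + N(0, noise_sd) per voxel
```

with four unit-norm, mutually orthogonal planted patterns (shared,
NS-unique, FE-unique, arousal) on disjoint random voxel supports,
orthogonalized by Gram–Schmidt in that order so recovery tests are
unambiguous. Pain conditions load on shared + own-modality-unique +
arousal; the non-painful negative condition loads on arousal only;
controls load nothing. The subject intercept (shared across a subject's
conditions) produces realistic within-subject pairing: it cancels in
paired 2AFC differences but acts as structured noise during training,
exactly as subject-level nuisance variance does in real data. The
thermal set loads the shared pattern linearly in level with jitter, and
ratings are linear in level with Gaussian noise — the simplest monotone
stimulus-response model consistent with pooled correlation analyses.
`simulate_run()` additionally produces blocked 4-D time series (16 s
blocks convolved with a canonical double-gamma HRF, slow cosine drift,
a random-walk motion table whose parameters leak into the signal, and
white noise) for testing the preprocessing chain.

### Default parameters and how they were chosen

No per-voxel effect sizes are published for data of this kind, so the
defaults were calibrated once so that a desk-scale analysis (40–60
subjects, 1000–2000 voxels) reproduces the qualitative accuracy regime
reported for the full-scale study — within-modality 2AFC accuracy near
90%, clearly above-chance but much weaker between-modality and
emotion-specificity accuracies, near-ceiling discrimination of extreme
thermal levels — and then frozen:

| parameter | default | meaning |
|---|---|---|
| `shared`, `ns_unique`, `fe_unique` | 0.8 | pattern amplitudes (units of image intensity along a unit-norm pattern) |
| `arousal` (pain conditions) | 0.2 | arousal confound carried by painful stimuli |
| `arousal_negative` | 0.8 | arousal loading of non-painful negative stimuli |
| `noise_sd` | 0.3 | per-voxel Gaussian noise SD |
| `subject_sd` | 0.3 | SD of the per-subject intercept image |
| thermal `slope` | 0.5 | shared-pattern loading per temperature step |
| `rating_noise` / `loading_noise` | 0.5 / 0.1 | rating and per-image loading jitter SDs |

With these defaults the measured desk-scale regime is: within-modality
93–95%, emotion specificity ~65%, thermal high-vs-low at ceiling, and an
arousal decoder showing the reverse profile. Two cautions follow. First,
passing tests on this generator show the *machinery* is correct and the
inferential procedures calibrated; they say nothing about effect sizes
in real data. Second, the generator omits spatial autocorrelation,
physiological noise spectra, inter-subject anatomical misalignment and
non-Gaussian artifacts — properties that matter for real-data power but
not for the correctness of the procedures.

## Preprocessing conventions

Nuisance regression and high-pass filtering are carried out in one
projection, with discrete-cosine drift regressors (periods above the
128 s cutoff) appended to the nuisance design — the simultaneous
variant, which avoids the reintroduction of removed variance that
sequential filtering can cause. The motion expansion is parameters,
squares, backward differences (leading 0) and squared differences — 24
columns — plus per-volume outlier indicators and a linear trend.
Outlier volumes are retained in block averages but regressed
(`outlier_flags`); excluding them instead is a caller-side choice.
Block averaging shifts the window by 3 TRs for the hemodynamic delay and
maps onsets to the nearest earlier volume — a deterministic rounding
convention. Rank-deficient designs fall back to the pivoted-QR
pseudo-inverse with a warning.

## Numerical choices

* The SVM optimizer runs at a KKT tolerance of 1e-6 (libsvm's default
  1e-3 leaves decision values reproducible only to ~1e-2 at C = 1); the
  tightened tolerance makes them agree with an independently coded dual
  QP solver to better than 1e-4 at negligible cost.
* Weight vectors are re-oriented after fitting so the positive label
  side always has positive decision values, making label-flip symmetry
  exact.
* Degenerate cases have explicit conventions: constant training voxels
  scale to 0; zero-variance t-test voxels get t = 0, p = 1 and a flag;
  zero bootstrap SD with nonzero mean is flagged extreme; zero-SD
  expression differences give an infinite-d flag; exact 2AFC ties score
  0.5.
* Masked vectors use a fixed linearization (x fastest — R's native array
  order) shared by every module; voxel indexing is 1-based inside R and
  only converted to world coordinates at I/O boundaries. Volumes are
  written as float32 NIfTI.

## Problem sizes used by the test suite

The suite exercises the full machinery at desk scale on one CPU:
whole-brain decoding checks use 60 subjects by 2000 voxels (5 seeds for
the shared-vs-unique dissociation; 200 replicates for null calibration
with 2-repeat CV), bootstrap maps use 1000 resamples on 8^3-voxel grids
(one recovery run, 20 null runs), the permutation calibration uses 500
runs of 200 shuffles per direction, and searchlight recovery runs on a
7^3 grid. These sizes were chosen so the complete suite runs in well
under half an hour; all of them are configurable upward, and the
module defaults (10 repeats, 10,000 resamples) match full-scale
practice.

## Known limitations

* The generator's orthogonal, disjoint-support patterns are an idealized
  geometry; real shared representations overlap spatially with their
  confounds.
* Bootstrap p values use the normal approximation of the weight z; a
  percentile option exists but the default mirrors z-map thresholding
  practice.
* Arithmetic averaging of p values across CV repeats is reported because
  it is the field's procedure, not because it is an optimal combination
  rule; treat the averaged p as descriptive and the calibration results
  above as its operating characteristics.
* The pipeline operates on condition-average images; trial-level
  modelling, spatial preprocessing (realignment, normalization,
  smoothing) and surface-based analysis are out of scope.
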