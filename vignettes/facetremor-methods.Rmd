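---
title: "Quantifying hypomimia and facial tremor from landmark trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying hypomimia and facial tremor from landmark trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facetremor)
```

## The measurement problem

Parkinson disease reduces facial expressivity (hypomimia, the "mask face")
and adds involuntary tremor to the small facial muscles.  Both signs are, in
principle, measurable from a few seconds of video of a patient imitating a
smile: hypomimia shrinks how far facial key points travel during the
expression, and tremor adds frame-to-frame positional noise to every key
point.  `facetremor` turns per-frame 106-point facial landmarks (pixel
coordinates, image origin top-left, sampled at 10 Hz) into those two
measurements and into PD/control classifiers built on them.

Two practical obstacles shape the design:

* **rigid head motion.** Patients — particularly PD patients — sway; pixel
  coordinates confound expression with posture.  Amplitude must therefore be
  measured in a head-invariant frame.
* **no public data.** Clinical smile videos are not releasable, so the
  package carries a synthetic cohort generator that reproduces the
  *statistical structure* of the problem, and every claim the test suite
  makes is a claim about that stated world.

## The face-anchored relative frame

Each frame defines a basis from three anchor landmarks: the two inner eye
corners and a nose point.  With origin $o$ at the inter-ocular midpoint,
$a = \mathrm{eye}_R - o$ and $b = o - \mathrm{nose}$, a point $p$ gets
relative coordinates $(x, y)$ solving $p - o = x a + y b$ (an exact 2×2
solve by Cramer's rule).  The anchors land at $(\pm 1, 0)$ and $(0, -1)$ by
construction.  Two points deserve emphasis:

* $a$ and $b$ are *basis* vectors, not Euclidean unit vectors — their pixel
  length is the eye-half-distance.  That is what makes the frame invariant
  under translation, rotation *and uniform scaling* of the image (tested to
  1e-9 over random similarity transforms).
* the image's downward-growing y axis needs no special handling: the basis
  definition absorbs orientation, and the nose pins at $(0,-1)$ exactly
  because $b$ points from the nose up to the origin.

The basis is recomputed **per frame** by default, so head pose changes
within a record cancel frame by frame; a `first_frame` policy exists for
ablation (under it, a rotating head visibly leaks into relative
coordinates — there is a test demonstrating exactly that).  Which nose
point the original method anchored on is not documented anywhere we could
find; the schema therefore makes the anchor names configurable, with the
nose tip as the shipped default.  Degeneracy (collinear anchors) is declared
when $|\det| \le 10^{-6} \, \lVert a\rVert \, \lVert b\rVert$ — a
scale-free tolerance, so the same face fails or passes regardless of image
resolution.

## The eight features per key point

For each of the 106 points, over one record's $N$ frames:

| feature | coordinates | definition |
|---|---|---|
| `R_x_max` | relative | $\max x - \min x$ |
| `R_y_max` | relative | $\max y - \min y$ |
| `cov_rel` | relative | $E(XY) - E(X)E(Y)$, divisor $N$ |
| `cov_abs` | absolute | same, on pixel coordinates |
| `jitter_abs` | absolute | $\frac{1}{N-1}\sum_i d(p_i, p_{i+1})$ |
| `jitter_ppq5` | absolute | $\frac{1}{N-4}\sum_i d(p_i, \bar p_{i\pm2})$ |
| `jitter_rap` | absolute | $\frac{1}{N-2}\sum_i d(p_i, \bar p_{i\pm1})$ |
| `jitter_ddp` | absolute | $\frac{1}{N-2}\sum_i \lvert d(p_i,p_{i+1}) - d(p_{i-1},p_i)\rvert$ |

The split is deliberate: amplitude features use the relative frame (they
measure expression, so posture must cancel), while the jitter block and
`cov_abs` use raw pixel coordinates (tremor and head shake are physical
displacements; normalizing them away would destroy the signal).  The jitter
statistics adapt the classical acoustic cycle-to-cycle jitter family
(absolute, RAP, PPQ5, DDP) from 1-D period sequences to 2-D positional
trajectories, replacing period differences with Euclidean distances.

Numerical choices:

* windows are fully interior — no partial windows at record ends — giving
  the divisors above; records shorter than 5 frames (the PPQ5 window) are
  rejected outright, mirroring record-level filtering of unusable videos;
* covariance uses the population divisor $N$ because the definition is
  written in expectation form;
* jitters are plain averages of pixel distances, not normalized by mean
  position (the acoustic convention of relative jitter does not transfer:
  the mean *position* of a landmark is an arbitrary image coordinate);
* the windowed jitters compute the deviation from the window mean as a mean
  of pairwise differences, which is algebraically identical but returns an
  exact 0 for a static trajectory instead of ~1e-14 rounding residue;
* one printed source formula repeats the x symbols in the vertical-range
  definition; it is implemented as the y-range, the evident intent.

All four jitters are verified against independently coded brute-force
double-loop oracles to 1e-12 on 1000+ random trajectories, vanish on
constant trajectories, and (RAP/PPQ5) vanish on any affine-in-time motion.

A record therefore yields $106 \times 8 = 848$ named features
(`{point}__{feature}`, point-major order).

## Significance screening

For each feature, a two-sided Welch $t$-test compares PD vs control record
values; per family, the report counts how many of the 106 key points fall
below each α (.05 and .005 by default).  Decisions made here:

* the source method's test statistic is unnamed; Welch is the defensible
  default when group variances differ (tremor features guarantee they do),
  and a Mann–Whitney option is one flag away;
* **no multiple-testing correction** — the screen counts raw significance
  by design; it characterizes families, it does not certify points;
* records are the test units by default, mirroring the original 176-record
  framing; because ~3 records per subject violate independence, an
  `aggregate_subjects` flag averages records within subject first;
* degenerate features (zero variance in both groups) get $p = 1$ when the
  means agree.

On tremor-contrast synthetic cohorts (PD noise SD 3× control) all four
jitter families saturate at or near 106/106 significant points while
amplitude families lag — the same qualitative ordering the clinical study
reports, with tremor features the stronger markers.

## Feature compression and classification

**LASSO.** L1-penalized *linear* regression of the 0/1 label on standardized
features (the source describes exactly this, not logistic LASSO; a logistic
variant sits behind a flag).  Standardization is mandatory — L1 on
mixed-scale features is meaningless.  A feature survives iff its weight
exceeds 1e-8 in absolute value.  The penalty sweep (default: 30 log-spaced
points over $[10^{-4}, 10^{-1}]$ plus 0.004) tracks the retained count and
downstream LR/SVM accuracy, both on the training set and under grouped
cross-validation, since the original figure does not say which it shows.

**Classifiers.** LR (weak-ridge logistic, $\lambda = 1/n$), RBF-kernel
soft-margin SVM ($C = 1$, "scale" gamma) fit by simplified SMO, CART (Gini,
unlimited depth), and a 100-tree bagged random forest with $\sqrt p$
features per split and impurity importances.  These are implemented
in-package because the target environment has no R implementation of them;
each is unit-tested on separable, permuted and degenerate data, and the
forest's importances back the key-point ranking.

**Cross-validation is grouped by subject.** Every subject contributes ~3
records; if they straddle the train/test split, a classifier can score
highly by recognizing *identity* rather than disease.  All evaluation in
this package assigns whole subjects to folds (stratified by class).  This is
the main methodological caveat against clinical headline numbers of the
F1 ≈ 0.99 magnitude obtained without a documented split protocol.

**Sequence model.** Relative-coordinate tracks are first-differenced with
the stated sign convention $\Delta x_i = x_{i-1} - x_i$ (212 channels), and
a single-layer LSTM (hidden 64; tests use 32 for runtime) reads the series;
the final hidden state feeds a linear softmax head.  Full-batch Adam
(2e-3), early stopping on a subject-grouped validation split.  The head is
zero-initialized, so an untrained (0-epoch) model predicts the training
majority class exactly — a convenient, testable baseline.  BPTT gradients
are verified against central-difference numerical gradients for both
architectures.  On default cohorts the LSTM reliably reaches F1 ≥ 0.95 held
out while the simple tanh RNN hovers near chance — reproducing the
LSTM ≫ RNN ordering the original experiment reports.

## The synthetic world

`synthetic_config()` defaults state the emulated study design: 33 PD / 31
control subjects, 3 records each, 50 frames per record at 0.1 s.  Each
record is a stylized frontal 106-point face plus:

* a **smile**: half-sine displacement over the record, applied to the mouth
  region, outer eye corners and nose wings, directed away from the mouth
  center with an upward pull.  Peak displacement: 0.25 relative units
  (control) vs 0.10 (PD) — hypomimic smiles at well under half the control
  excursion; multiplicative log-normal per-subject (SD 0.2) and per-record
  (SD 0.05) variability;
* **tremor**: per-frame isotropic Gaussian positional noise on every point,
  SD 0.2 px (control) vs 0.6 px (PD).  Tremor is modeled as *white* noise,
  not an oscillation: at 10 Hz sampling, physiological 4–6 Hz tremor sits at
  or above the Nyquist frequency, so any sinusoidal model would be aliased
  anyway, and white positional noise is precisely what the jitter
  statistics measure;
* optional **rigid head motion** (linear drift, default 5 px per record, or
  rotation) applied to all points — the nuisance the relative frame must
  cancel.  A property test verifies the nuisance is invisible to the
  amplitude block yet raises absolute-coordinate jitter, which is the whole
  motivation for the two coordinate systems.

What a green test does *not* establish: realism of face geometry, detector
noise characteristics (landmark jitter from the detector itself is absorbed
into the tremor SD), expression-onset timing differences (bradykinesia),
asymmetric or localized tremor, and any claim about clinical
generalization.  The generator's effects are strong and clean by intent;
classifier F1 ≈ 1 on it validates the pipeline's mechanics, not clinical
performance.

## Limitations

* **Mid-penalty LASSO selectivity.**  One acceptance assertion is
  deliberately left failing: that signal-bearing features are retained at
  ≥ 5× the rate of noise features at the *middle* of the penalty grid.
  Under the stated generator the smile displaces all signal points
  coherently, so their amplitude features are nearly collinear; LASSO keeps
  a few representatives and, at weak-to-mid penalties, pads the fit with
  small-weight noise features that absorb in-sample residuals.  Measured
  honestly, the mid-grid rate ratio is ≈ 1 (and it *decreases* with more
  records, as more noise correctors become affordable).  Selectivity does
  emerge where compression is strong: at the sparse end of the grid the
  survivor set is essentially all signal points (rate ratios of 10–30×),
  which is asserted separately and passes.  The generator was not re-tuned
  to force the mid-grid bound.
* The SMO, CART, forest and LSTM implementations favor clarity and
  determinism over speed; they are desk-scale (hundreds of records), not
  production learners.
* Landmark detection itself is out of scope: the package starts from
  landmark files (a Face++-dialect JSON importer and a canonical CSV), and
  video decoding / API calls are intentionally excluded.
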