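---
title: "Quantitative 4D lineage analysis of C. elegans embryos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative 4D lineage analysis of C. elegans embryos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

`wormlineage` analyses tracked nuclear lineages of early *C. elegans*
embryos: it aligns embryos in time and space, builds a control reference
model, extracts thirteen per-cell features, screens for group
differences with a permutation-calibrated false discovery rate, and
predicts embryo death with a repeated cross-validation Lasso. The
motivating biology is the unequal first cleavage of the zygote into a
larger anterior AB cell (~60% of the embryo) and a smaller posterior
P1 cell; embryos in which this division is equalized (relative AB size
48--53%) die at high rates, and the package quantifies which lineage
features distinguish dying from surviving embryos.

This vignette documents the models, the tunable parameters, and the
design decisions; the README shows a worked example.

## Data model

A lineage is a long-format table with one row per nucleus observation
(`cell`, `frame`, `time_min`, `x`, `y`, `z`, `diameter`, `parent`),
wrapped in an `embryo_lineage` object together with per-embryo metadata
(experimental group, relative AB size in percent, mounting compression
in micrometres, frame interval, outcome). Structural invariants are
checked on construction: strictly increasing frames per cell, 0 or
exactly 2 daughters, daughters appearing only after the mother's last
frame. Cell names follow the Sulston convention, with the early
P-lineage divisions (P0 through P4, EMS) handled by an explicit table
because the suffix rule does not cover them. StarryNite/AceTree
`t###-nuclei` exports are read best-effort with a user-adjustable
column mapping, since deposited dialects vary.

## Temporal and spatial alignment

**Temporal.** Each embryo's cell-count growth curve, centred at its ABa
division (time zero), is compared with a reference curve (the mean
centred curve of the control cohort). The alignment scale is the value
in [0.5, 2.0] maximizing the Pearson correlation between the linearly
interpolated curves on a shared 1-minute grid, searched on a fixed grid
with step 0.001 (ties resolved toward 1.0). Aligned time is
`(raw - t_zero) * scale`. The grid search is a package choice -- the
quantity being maximized (curve correlation) admits no closed form.

**Spatial.** The anterior--posterior (A-P) axis is the first principal
component of all nuclear positions in the first 100 recorded frames;
dorso-ventral (D-V) is the component of the MS-lineage centroid
orthogonal to A-P; left--right completes a right-handed frame. Signs:
the AB-lineage centroid defines the anterior (negative A-P) side and
the MS side is ventral (positive D-V). The PCA runs on centred *raw*
coordinates, and per-axis extent normalization is applied afterwards in
the embryo frame. Normalizing by extents before the PCA would make the
inferred frame depend on the recording orientation, breaking the
rotation-equivariance the rest of the pipeline (and its tests) relies
on; applying it after axis inference preserves both properties.
Normalized coordinates are rescaled by the control-mean extents so they
remain micrometre-equivalent.

**Reference model.** Control embryos are aligned and their per-cell
metaphase landmarks superimposed by Generalized Procrustes Analysis:
iterated least-squares rigid superposition (Kabsch, rotation +
translation) of each embryo onto the running mean shape, until the mean
residual changes by less than 1e-6 (at most 100 iterations). Scaling
GPA is available via `scale_gpa = TRUE` but off by default, because
extent normalization has already removed size. The model stores per
cell the mean metaphase position, the mean unit division vector
(mean of unit vectors, re-normalized), 1-minute mean trajectories, and
the control mean and sample SD (n-1 denominator throughout) of each
alignment-free feature. The GPA consensus is defined up to a global
rigid motion; all reported quantities (residuals, deviations, angles)
are invariant to it.

## The thirteen per-cell features

Timing: `StartTime` (birth), `EndTime` (division), `LifeTime`
(difference), on the aligned clock. Position at metaphase: `pAP`,
`pLR`, `pDV`. Motility: `totdis` (summed frame-to-frame displacement)
and `netdis` (birth-to-end distance). Division orientation: `aAP`,
`aLR`, `aDV` (angles of the division vector to the three axes) and, by
comparison with the reference model, `aMean` (angle to the reference
division vector) and `pOV` (distance to the reference metaphase
position).

Operational definitions forced by the 2.5-minute sampling: metaphase is
the mother's last tracked frame, anaphase onset the daughters' first
frame. The division vector points from the first-named daughter (a/l/d,
or the first entry of the P-lineage table) to its sister, at the
daughters' first common frame. Angles are reported in degrees on
[0, 180] without folding, so inverted divisions (e.g. a left-right
MSa/MSp swap) remain distinguishable near 180. Cells already present at
recording start have missing `StartTime` (not zero); cells whose
division is not observed have missing `EndTime`; both propagate as
missing values into the classifier, whose imputation handles them.

Qualitative phenotype flags re-derive the discrete defects: EMS
division skew above 35 degrees at anaphase onset, MSa/MSp left-right
inversion (both L-R coordinates sign-flipped relative to the reference,
required magnitude above 0.5 um to avoid scoring near-midline cells),
extra divisions in the P4 (germline) subtree, AB--P1 division
asynchrony, and a T-shaped 4-cell arrangement proxy (AB daughter axis
within 30 degrees of A-P while the P2--ABp distance exceeds 1.5 times
the mean inter-cell distance; the original scoring was visual, so this
rule is a documented, tunable proxy).

## Group statistics

Feature screening between dying and surviving equalized embryos uses
Welch's unequal-variance t-test per feature with the relative mean
difference `(mean_a - mean_b)/mean_b` as effect size (the absolute
difference is available by flag), a 15% effect threshold, and a p-value
cutoff chosen by permutation: for each alpha on the descending grid
{0.05, 0.02, 0.01, 0.008, 0.005, 0.002, 0.001}, the expected number of
features passing the joint rule under 100 label shuffles is divided by
the observed count (`max(observed, 1)` to avoid division by zero), and
the largest alpha with estimated FDR at or below 10% is selected. The
same shuffle set is reused across the grid for variance reduction. A
coverage rule (at least 5 scored embryos per group) gates every tested
feature. Benjamini--Hochberg adjustment across features, one-way ANOVA
with Tukey HSD across groups, and per-cell SD/CV variability summaries
use the standard `stats` routines. The robustness screen ("mean
unchanged, variability increased") combines Welch p >= 0.05 with a
one-sided F variance-ratio test at 0.05; the F test is a package
decision and a Levene-type alternative is exposed.

## Survival classifier

Preprocessing, in order: drop features whose variance on the 0--1
rescaled column is below 2.5% (rescaling makes the threshold
unit-free); drop features with more than 25% missing values; impute the
rest with the outcome-group mean; min--max scale to [0, 1]. Group-mean
imputation leaks the label into imputed cells and is kept for fidelity
to the original workflow; `imputation = "overall_mean"` avoids it.
Embryos are never dropped.

The classifier is L1-penalized logistic regression (glmnet). Per
repetition (250 by default) a stratified 5-fold split is drawn --
stratification is a package decision; with 14-vs-17 class sizes an
unstratified split risks single-class folds -- and the shrinkage
parameter is chosen to minimize the cross-validated mean squared error
between predicted probability and the 0/1 label (squared-error loss on
probabilities, as the selection criterion; deviance is what glmnet
optimizes within each fit). Selected features are read from a refit on
the full data at the chosen lambda; cross-validated accuracy uses the
held-out (prevalidated) predictions at threshold 0.5. The best model is
the repetition with the global minimum CV error; its ROC is enumerated
over the sorted unique predicted probabilities, with the Youden-optimal
and 0.5-threshold operating points reported. Stage comparisons (4-, 8-,
15-, 28-cell feature universes, defined as cumulative cohorts of the
canonical division rounds) restrict to embryos scored at all stages.

With few embryos and many features, a single label permutation can
leave one chance-correlated noise feature stably selected; what
permutation reliably destroys is the planted (true) feature's inclusion
and the cross-validated accuracy, which is how the permutation control
is asserted in the test suite.

## The synthetic embryo generator

The simulator emulates the statistical structure the analysis assumes,
not embryo mechanics. Defaults encode the study conditions: cohort
sizes 10/18/21/28/7 (wild type, control, equalized alive, equalized
dead, inverted), relative AB size around 60% (unmanipulated), 48--53%
(equalized) or below 48% (inverted), a 2.5-minute frame interval, an
eggshell ellipsoid with half-axes 25 x 15 x 12.5 um, and a fraction of
recordings truncated at the 26-cell stage.

* **Clocks.** Per-founder, per-generation mean cell-cycle durations;
  each duration is the mean times a lognormal factor (CV 6% by
  default), which cannot go negative. AB--P1 asynchrony is
  `0.5 + 0.3 * (AB% - 50)` minutes times noise: about 3.5 min at 60%
  AB, a residual fraction of a minute at equal sizes, matching the
  reported direction and magnitudes. P1-lineage cycles shorten by 2%
  per percentage point of AB-size decrease (3.5% for P4, reproducing
  the ~33% P4 shortening at equalized sizes).
* **Geometry.** Daughters are placed astride the mother along a static
  per-cell canonical division axis (a/p along A-P, l/r along L-R, with
  fixed oblique axes for the named P-lineage divisions so MS ends up
  ventral and C dorsal, plus a small deterministic per-cell tilt).
  Every frame, positions relax by 10 sweeps of pairwise soft-sphere
  overlap resolution and are projected back inside the eggshell; cell
  radii scale as (volume fraction)^(1/3) with the AB:P1 volume split
  set by the relative AB size. Ten sweeps (rather than more) keep the
  full cohort simulation within a few minutes in pure R while leaving
  the packing geometrically stable. Mounting compression flattens the
  shell dorsoventrally; a random imaging pose (rotation jitter, part of
  the noise model) de-aligns the recording frame from the canonical
  axes so that axis inference is actually exercised.
* **Planted signatures.** Dying embryos (equalized-dead and inverted
  groups) always receive a dorsal shift of ABar progeny (2.5 um) and
  inflated Ca motility (x2.5), plus, probabilistically, an MS
  division-angle skew (SD 30 degrees), an EMS skew (>35 degrees, p =
  0.19) and an extra germline division (p = 0.35, realized as a D-like
  fast re-division of Z2 so it falls inside the recording window).
  Outcome labels are a deterministic function of the planted draw, so
  the classifier has a learnable target, and `planted_truth()` reports
  the (cell pattern, feature) pairs carrying planted effects. The
  magnitudes of the dead signatures are calibration knobs of the
  simulator -- the source measurements do not quantify them -- chosen
  once at values a lineaging microscopist would call a clear phenotype
  (a few micrometres, tens of degrees).

What the simulator does **not** model: cytoplasmic flows, eggshell
deformation, cell death, mis-tracking and naming errors, or faithful
wild-type coordinates. Passing tests therefore demonstrate that the
pipeline recovers known structure from data with this statistical
shape, not that it reproduces any particular real embryo.

## Numerical choices and degenerate inputs

Sample SD (n-1) everywhere. Angles clamp the cosine into [-1, 1]
before `acos`. The temporal-alignment correlation requires at least 10
minutes of curve overlap and skips scales where either curve is
constant; ties prefer scales nearest 1. Axis inference warns when the
first two principal axes are within 20% of each other (ill-conditioned
A-P axis) and errors without MS-lineage cells (D-V undefined). GPA
requires at least 4 shared landmarks per embryo. Zero-variance features
receive p = 1 with a warning; a feature with equal min and max scales
to all-zero and is then removed by the variance filter. ROC on
single-class input is an error.

## Problem sizes in the tests

The test suite exercises the full pipeline at reduced sizes chosen to
keep the default run fast while preserving every code path: cohorts of
20--30 embryos, 25--50 CV repetitions, 30--40 label shuffles, and
screening cohorts of 30 vs 30 with 500 features. The acceptance script
(`scripts/acceptance.R`) runs the complete study-condition setup: 84
embryos, 100 shuffles, 250 repetitions, all four stages.

## Known limitations

* The temporal scale is a single global factor; stage-specific pace
  changes are absorbed into residual curve mismatch.
* Landmark correspondence is by name only; naming errors upstream
  propagate directly.
* Group-mean imputation inflates apparent classifier accuracy by
  construction (documented above); use `overall_mean` for unbiased
  estimates.
* With tens of embryos and hundreds of features, the minimum-CV-MSE
  lambda often retains one or two chance features under the null;
  inclusion frequencies should be read against the permutation
  control, not in isolation.
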