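---
title: "Trajectory radiomics for breast MRI subtype classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trajectory radiomics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mrtraj)
```

## The problem and the model

Immunohistochemical (IHC) subtypes of invasive breast cancer — Luminal A,
Luminal B, HER2-positive and triple negative (TN) — differ in prognosis and
therapy response, and multiparametric MRI carries quantitative signatures of
them. `mrtraj` implements a whole-tumor radiomics pipeline over two MR
modalities: dynamic contrast-enhanced (DCE) imaging acquired at six time
points (one pre-contrast, five post-contrast) and diffusion-weighted imaging
(DWI) at three b-values (50, 400, 800 s/mm²), with a single whole-tumor 3D
mask per modality propagated identically to every volume of its series.

The catalog has five parts: (a) 14 shape features on the first-postcontrast
DCE mask; (b) 92 texture features per DCE phase (552); (c) **sequential DCE
features** — for each of the 92 base texture features, statistics of its
six-point trajectory across phases, ten per base feature (920); (d) the same
92 texture features per DWI b-value (276); and (e) sequential DWI features,
eight per base feature (736; kurtosis and entropy are dropped because three
points cannot support them) — 2,498 columns in total.

The sequential statistics are the package's core computation. Six are
per-subject descriptive statistics of the trajectory $x_1..x_T$ (population
moments, since a trajectory is a fixed short sequence, not a sample): mean,
variance $\sum (x_t-\bar x)^2/T$, skewness $m_3/m_2^{3/2}$, kurtosis
$m_4/m_2^2$, energy $\sum x_t^2$, and Shannon entropy (bits) of the
$|x|$-normalized mass. Four are *cohort-interactive*, comparing subject $i$
with the remaining subjects:

* **Kendall tau-b**: the mean tie-corrected rank correlation
  $(C-D)/\sqrt{(n_0-n_1)(n_0-n_2)}$ between subject $i$'s trajectory and
  each other subject's;
* **conservation**: the mean fraction of the $T-1$ successive steps whose
  difference signs agree with the other subject's;
* **stability**: $1/(1+\mathrm{RMSD})$ between the min–max-normalized
  trajectory and the mean normalized trajectory of the others;
* **dispersion**: the root mean square of the subject's per-time-point
  cohort z-scores (population sd).

The original supplementary material defining these four interactive
statistics is not available; the definitions above are this package's
pinned, documented interpretations of "interactive information between the
current subject and the remainder of the subjects", chosen as the most
standard readings (pairwise-averaged tau-b rather than a reference-curve
tau; leave-one-out means for conservation/stability; full-cohort z-scores
for dispersion so that the cohort mean square of dispersion² is exactly 1
per time point). Each lives behind its own function so a surfaced reference
definition could be swapped in.

Every statistic whose defining denominator vanishes (constant trajectory,
all-zero mass, zero sd) returns 0, and any non-finite extracted value is
imputed to 0 with a warning — the neutral value after z-scoring.

## Texture and shape features

No enumeration of the original 92 texture features exists in the source
analysis, so the set is pinned to the standard radiomics families in a
frozen manifest: 18 first-order, 23 GLCM (including sum average, excluding
the maximal-correlation coefficient), 16 GLRLM, 16 GLSZM, 14 GLDM and
5 NGTDM. Matrix families are computed from gray levels discretized to a
**fixed bin count of 32 inside the mask**, which makes them invariant to
affine intensity rescaling — appropriate for arbitrary-unit MR signal.
Co-occurrence and run-length counts are accumulated over the 13 unique 3D
directions at distance 1 (symmetric GLCM), size zones use 26-connectivity,
GLDM uses dependence tolerance 0, and NGTDM the 26-neighbourhood mean.
Under this pinned aggregation a 2-level checkerboard plane has GLCM
contrast 24/42 (its in-plane diagonals pair equal levels), not the 1 that an
axial-only convention would give.

Shape features use a marching-tetrahedra isosurface at level 0.5 of the
anti-aliased (separable 1-2-1 smoothed) mask with linearly interpolated edge
crossings. Meshing the binary mask directly overestimates surface area by
25–30% on digital balls (staircase facets; sphericity ≈ 0.78, and ≈ 0.91
even for standard marching cubes); the anti-aliased mesh recovers the smooth
area to within about 1% (digital ball of radius 10: sphericity 0.99). Masks
thinner than the smoothing support, which anti-aliasing would swallow, fall
back to the binary mesh. Axis lengths are $4\sqrt{\lambda}$ from the
population covariance of voxel centres; the maximum 3D diameter is the
largest pairwise distance between surface voxel centres.

## Two-stage feature selection

Stage 1 (coarse) computes, per feature, a hypothesis-test p-value (one-way
ANOVA for the four-class task, pooled two-sample t-test for TN vs non-TN;
constant columns get p = 1 by convention) and the stratified 5-fold CV error
of a single-feature linear-discriminant classifier (the evaluation suite's
headline model family), and accepts a feature iff

$$\left(\frac{p}{a}\right)^2 + \left(\frac{e}{b}\right)^2 < 1,$$

strictly — boundary points are rejected. Defaults are $(a,b) = (0.6, 0.85)$
for four-class and $(0.54, 0.76)$ for binary; `tune_acceptance_factors()`
reproduces the ergodic 0.01-step grid scan toward ~50% retention, with ties
broken by smaller ellipse area then smaller $a$, and an integer
(`ceiling`) target count so the degenerate one-feature case resolves to the
smallest accepting ellipse. Raw p-values are used with no multiplicity
correction, mirroring the source procedure.

Stage 2 (fine) standardizes the accepted columns and ranks them by the
magnitude of the standardized coefficients of three regularized linear
models — lasso, ridge, elastic net (mixing 0.5) — with penalty strength
chosen by internal stratified 5-fold CV (binomial or multinomial loss;
multinomial importance sums |coefficients| across classes; ties share mean
ranks). The three ranks are summed; the top 40 are scanned greedily in
fused-score order, keeping a feature only if its absolute Pearson
correlation with everything already kept is ≤ 0.4, down to 20 (four-class)
or 8 (binary) features. The original analysis removed correlated features
"manually"; the greedy scan is the deterministic, auditable automation of
that step. The Rad-score is a logistic linear predictor (binary) or first
linear-discriminant axis (four-class) over the standardized final features,
with a ridge jitter of 1e-6 when the fit is singular or separates
perfectly.

Selection runs on the full cohort before CV evaluation, mirroring the
source sequence; this leaks information into the later model comparison,
which is why the analysis drivers include a label-permutation control that
pushes the identical pipeline to its optimism floor.

## The 20-classifier comparison

`build_model_zoo()` pins the five families (3 trees, LDA/QDA, 6 SVMs,
4 KNNs, 5 ensembles of 30 learners) with explicit hyperparameters, since
the source names only presets: trees prune to ≤ 100/20/4 splits; SVMs use
box constraint 1, polynomial degrees 2/3 (coef0 = 1), Gaussian kernel scales
$\sqrt P/4, \sqrt P, 4\sqrt P$; KNNs use k = 1/10/100 (capped at
n_train − 1) plus squared-inverse-distance weighted k = 10; ensembles are
random-subspace LDA and 1-NN at subspace dimension ⌈P/2⌉, SAMME AdaBoost and
RUSBoost on ≤ 20-split trees at learning rate 0.1, and bagged unpruned trees
(random forest with mtry = P). QDA falls back to a diagonally shrunk
Gaussian discriminant when class covariances are singular. Evaluation is
stratified 5-fold CV repeated 10 rounds; accuracy is pooled correct/total
per round and averaged over rounds (with n = 134 the alternative
mean-of-fold-accuracies differs by at most one subject's rounding). Features
are standardized within training folds for all models.

## The synthetic cohort

The phantom generator provides the study conditions for every test: an
ellipsoidal lesion (default semi-axes 10×8×7 mm on a 48³ 1-mm grid) over a
noisy background, with per-subtype parameters chosen once to encode the
qualitative radiology the method exploits — Luminal A enhances slowly and
persistently (wash-in 30/phase to peak at phase 5) with fine texture
(correlation length 0.8 voxels) and the highest ADC (1.15×10⁻³ mm²/s);
Luminal B is intermediate (45/phase, peak 4, washout 8; 1.0×10⁻³); HER2+
enhances fast with early washout (65, peak 2, washout 15; 0.9×10⁻³); TN is
brisk with marked washout (55, peak 3, washout 25), the coarsest texture
(2.6 voxels) and the lowest, most heterogeneous ADC (0.8×10⁻³, sd
3.5×10⁻⁴). DCE signal is piecewise linear in phase; DWI signal is
$S_0 e^{-b\,\mathrm{ADC}}$ voxelwise with truncated-normal per-voxel ADC and
a multiplicative texture field on $S_0$ (which preserves exact
log-linearity of the lesion mean in b). Class prevalences default to
26/68/18/22. Per-subject seeds are drawn deterministically from the cohort
seed. What the phantoms do **not** emulate: MR physics (coil profiles, EPI
distortion, fat saturation), rim enhancement and necrotic cores,
inter-subject variation of lesion size or of the enhancement/diffusion
parameters (same-class subjects differ only in their noise and texture-field
realizations, so within-class feature variance is small and phantom-cohort
accuracies saturate near 100% — far above what heterogeneous patients
allow), and registration error. Passing tests therefore demonstrate the
pipeline's statistical behaviour, not clinical performance.

The direct table generator plants `n_informative` columns with
prevalence-weighted standardized class-mean patterns. Patterns are greedily
spread to pairwise correlation ≤ 0.8 and the default effect size is 0.8 sd:
with unit within-class variance the marginal correlation between planted
features is then pattern correlation × effect²/(1+effect²) < 0.4, below the
pruning threshold. This is a well-posedness requirement of the recovery
benchmark, not a tuning convenience — in a 4-class problem the contrast
space is 3-dimensional, so unconstrained random patterns routinely make
planted features mutually redundant at |r| > 0.4 and the pruning stage then
*correctly* discards part of the planted "ground truth".

## Numerical choices and limitations

* Population moments throughout the sequential statistics; denominators
  that vanish return 0 (logged).
* Discretization: fixed 32 bins; with fewer than 2 occupied levels the
  matrix families take their defined limits (e.g. GLCM contrast 0).
* Ranking ties share mean ranks; fused-score ties resolve by coarse-stage
  column order; pruning may return fewer than the target count (logged).
* glmnet paths use 60 lambdas with stratified internal folds; results are
  bit-reproducible for a fixed seed.
* Problem sizes in the tests and acceptance script (2-subject catalogs on
  24³ grids, a 40-subject end-to-end cohort, 10–50 selection seeds) were
  chosen as the smallest sizes at which the checked properties are stable.
* Known limitations: no DICOM ingestion, no inter-acquisition registration
  or resampling (masks must share their series' exact grid), no
  pharmacokinetic or ADC-map modelling (the method deliberately works on
  raw DWI signal), and no nested-CV variant of the headline numbers — the
  permutation control quantifies, rather than removes, the full-cohort
  selection optimism.
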