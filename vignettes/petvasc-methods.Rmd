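---
title: "petvasc: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{petvasc: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Active giant-cell arteritis (GCA) and atherosclerosis both produce elevated
[18F]FDG uptake in the aortic wall, which makes them hard to separate
visually — especially on follow-up scans of treated patients, where uptake
is attenuated by glucocorticoids. The two diseases differ in *texture*
rather than only in intensity: granulomatous GCA inflammation lines the
wall homogeneously, while atherosclerotic uptake is patchy and
heterogeneous, driven by focal lipid-rich plaques and calcification.
`petvasc` implements a radiomics pipeline that exploits exactly this
difference: per-segment texture features feed a classifier grid, segment
probabilities are aggregated to a scan-level call, and
occlusion-sensitivity maps show *where* in the aorta the evidence sits.

Because clinical PET volumes cannot be redistributed, the package ships a
synthetic vessel phantom that reproduces the statistical structure the
analysis relies on. Every stage — normalisation, feature extraction, model
selection, decision rules, explainability — runs end to end on simulated
cohorts and is tested that way.

## The phantom

Each synthetic scan is a straight cylindrical vessel wall (outer radius
15 mm, thickness 6 mm) embedded in uniform background on a scanner-like
grid (3.19 × 3.19 × 2 mm voxels). The tube is cut axially into four
contiguous blocks standing in for the ascending aorta, arch, descending
aorta and abdominal aorta. Anatomy is deliberately schematic: the analysis
consumes per-segment voxel statistics, so exact masks and controllable
texture matter; curvature does not. Noise is Gaussian on activity, clipped
at zero — the pipeline ingests *reconstructed* images, so scanner physics
(Poisson counts, PSF, attenuation) is out of scope by design.

Activity defaults (Bq/mL): GCA wall 4200 with voxel-level CV 0.15
(homogeneous, elevated); atherosclerotic wall 2500 with, per segment, a
Poisson(2.5) number of spherical 7-mm patches at 3800 (focal, intermediate
intensity); background 1800. Metadata are drawn as weight ~ U(55, 110) kg,
BMI ~ U(20, 38) kg/m², sex ~ Bernoulli(0.5), injected dose 3 MBq/kg, which
couples a patient-level scale factor into all SUL values through the
LBM/dose normalisation.

These defaults were calibrated once, by pilot simulation, to satisfy four
properties simultaneously and were then frozen:

* GCA segments have **higher SULmax** than atherosclerotic ones (rank test
  p < 0.01 at 20 patients per class) — patches are hot but stay below the
  homogeneous GCA level, as reported for real cohorts;
* GCA segments are **less heterogeneous** (lower within-segment CV,
  p < 0.01) — the patchy class carries the extra variance;
* the task is **learnable** (reference configuration reaches CV AUC
  ≥ 0.85) without being a toy with zero class overlap;
* classifier probabilities are **informative**, not pinned at 0/1, so
  occlusion maps have signal to redistribute.

A first-guess parameterisation with a much larger contrast (GCA 8000
vs. atherosclerosis 3000 Bq/mL) made the classes perfectly separable;
every probability saturated and explainability maps degenerated. Real
cohorts do not behave that way, so the calibrated overlap is the more
faithful emulation.

What the phantom does **not** model: curved anatomy and segment-specific
geometry, spill-over from adjacent structures, attenuation-CT artefacts,
calcification as an image feature (only its 0–4 visual score is
simulated), scanner harmonisation differences, and biological covariance
between uptake and patient metadata. Passing tests therefore demonstrate
internal correctness and sensible statistical behaviour of the pipeline —
not clinical performance, which can only be established on real scans.

## SUL normalisation and resampling

Activity is converted to standardised uptake values normalised to lean
body mass,

$$\mathrm{SUL} = \frac{\text{activity [Bq/mL]}}{\text{dose [Bq]} / \text{LBM [g]}},$$

with the sex-specific James-type estimate
LBM(male) = 9270·W / (6680 + 216·BMI) and
LBM(female) = 9270·W / (8780 + 244·BMI) (W in kg). The unit convention
makes a uniform activity numerically equal to dose/LBM map to SUL = 1
exactly, which the tests assert. No decay correction is applied (a fixed
60-minute uptake protocol is assumed), and no plasma-glucose correction —
SUV by body weight or BSA is out of scope.

Volumes are then resampled to isotropic 2 mm spacing with cubic B-spline
interpolation. The resampler uses the exact recursive prefilter (pole
√3 − 2, mirror boundaries, closed-form initialisation for short signals),
so it reproduces polynomials up to degree three: an axial linear ramp
resamples to machine-precision accuracy away from the boundaries, which
the suite checks against the analytic line. Conversion happens *before*
resampling (the voxelwise map commutes with interpolation; the order is
fixed for reproducibility). Label masks are resampled with
nearest-neighbour so segment labels cannot blend.

## Features

Each segment yields 95 features: 18 first-order statistics, 24 grey-level
co-occurrence (GLCM), 16 run-length (GLRLM), 16 size-zone (GLSZM), 5
neighbouring-grey-tone difference (NGTDM) and 14 dependence (GLDM)
features on the discretised ROI, plus SULmax and SULmean on raw SUL. The
GLCM set includes both JointAverage and SumAverage (redundant for
symmetric matrices, retained to keep the documented family count of 24)
and the maximal correlation coefficient.

Numerical conventions:

* **Discretisation**: fixed bin width of 0.25 SUL anchored at the ROI
  minimum — the usual recommendation for PET, where absolute SUL
  differences carry meaning; both settings are configurable.
* **Directions**: GLCM and GLRLM are built per 3D direction (the 13 unique
  directions of the 26-neighbourhood) and the per-direction feature values
  averaged. GLSZM zones, NGTDM neighbourhoods and GLDM dependence counts
  (tolerance 0, i.e. equal level) use the full 26-connected neighbourhood.
* **Degenerate ROIs**: masks below 10 voxels raise a typed error;
  constant-valued ROIs return skewness, kurtosis and entropies of 0 and
  otherwise finite values.
* **Invariances**: features are invariant to ROI translation, and adding a
  constant to all SUL values shifts only the intensity features because
  bin edges track the ROI minimum. Both are asserted as properties.

The implementations are validated against brute-force oracles: naive
pair/run/zone/dependence counters written in the most literal loop style,
compared matrix-by-matrix on small random ROIs, plus hand-enumerated
values on a printed 3×3 toy grid.

Features with absolute Pearson correlation above 0.9 to an earlier kept
feature are dropped by a greedy scan in canonical manifest order —
deterministic, idempotent, and equivalent to its brute-force oracle on
random tables. Zero-variance features have no defined correlation and are
kept with a warning.

## The model grid

The default grid crosses 7 feature selectors × 9 feature counts
(2–30) × 7 classifiers = 441 configurations. Selectors: ANOVA F,
mutual information, recursive elimination (linear-SVM weights, dropping
the weakest 20% per round), lasso entry order, random-forest importance,
absolute point-biserial correlation, and chi-squared on
quartile-discretised features. Classifiers: random forest, logistic
regression, RBF support-vector machine, 5-nearest-neighbours, naive
Bayes, gradient boosting, linear discriminant analysis. Only the
ANOVA + random-forest + 10-features configuration is externally anchored;
the remaining registry entries are conventional, widely used stand-ins and
fully overridable in the configuration.

Evaluation is ten-fold cross-validation with **patient-wise,
group-stratified folds**: all segments of a patient share a fold, so
within-patient correlation (shared dose, LBM, scanner scale) can never
leak across the train/validation boundary. Within each fold, features are
z-scored and the selector fitted on the fold-training rows only. PPV and
NPV inside CV use a 0.5 probability threshold. The final model is chosen
by mean CV AUC with deterministic tie-breaks (PPV + NPV, then fewer
features, then configuration name), and the untouched test set is scored
by all ten fold models, reported as mean ± SD. Patient overlap between
train and test tables is a hard error, and the patient-wise 80/20 split is
itself stratified by group to avoid degenerate single-class test sets at
small n.

## Scan-level decisions

A scan's probability is the **maximum** over its segment probabilities — a
scan is as suspicious as its most suspicious segment. The operating
threshold maximises the generalised Youden index
J = 2(w·sensitivity + (1−w)·specificity) − 1 over the midpoints between
consecutive sorted unique probabilities (plus ±∞), with ties resolved
towards the highest qualifying threshold; the default weight w = 0.5
recovers the classical J = sensitivity + specificity − 1. The weight is
exposed because "generalised" Youden is sometimes used with cost
weighting.

The pipeline fits this threshold **on the follow-up set itself**,
mirroring how such thresholds are typically derived retrospectively; this
is in-sample and optimistic, the report flags it, and a frozen external
threshold can be supplied instead for honest prospective use. PPV, NPV
and accuracy come with 95% Wilson score intervals, which behave sensibly
at the small counts typical of follow-up cohorts (≈ 20 scans).

## Occlusion maps

A cubic patch (default 8 mm edge, 4 mm stride, i.e. half-overlapping)
slides over each segment's bounding box; at every position the patch is
occluded, the full 95-feature vector re-extracted, the model re-scored,
and each covered mask voxel accumulates baseline − occluded probability.
The per-voxel map is the average over all patches covering the voxel, so
positive (red) values mark regions supporting the active-GCA call.

The default occlusion rule **fills patch voxels with the ROI minimum**
(the grey-patch convention of the occlusion-map literature). The
alternative of removing patch voxels from the mask is retained as an
option but is not the default for a reason found during implementation:
radiomic features are intensive statistics of the masked voxel set, so
deleting voxels from a homogeneous hot wall leaves SULmean and the texture
matrices nearly unchanged — the map comes out flat precisely in the
segments that drive the prediction. Filling with a cold value, by
contrast, perturbs the evidence the way a genuinely inactive region would.

Maps are deterministic given (volume, mask, model, spec); deltas are
bounded in [−1, 1]; per-voxel patch-coverage counts are checked against an
independently reconstructed stride-lattice in the tests. Patches that
would leave the ROI below the minimum voxel count are skipped and the
voxels they cover simply receive fewer contributions.

## Problem sizes and reproducibility

The simulated study conditions are 20 + 20 baseline patients (160
segments; 140 after calcification exclusion with the default one flagged
segment per GCA patient on average) and 7 active + 12 inactive follow-up
scans; the label-permutation null uses a 25 + 25-patient cohort so that
exactly 200 segment labels are shuffled. These sizes were chosen to match
the scale of a single-centre clinical cohort while keeping a full test run
on one CPU in minutes. A single global seed fans out to per-stage seeds
through a deterministic hash, so any stage can be re-run in isolation;
rerunning the pipeline under the same seed reproduces every artefact
byte-for-byte, and the run manifest records content hashes to make reruns
diffable.

## Known limitations

* Phantom realism, as listed above; absolute performance numbers on
  phantoms do not transfer to clinical data.
* The calcification score is an input, not derived from images; automatic
  scoring is out of scope.
* The Youden threshold in the follow-up stage is in-sample.
* The grid deliberately performs no hyperparameter tuning beyond its three
  axes; classifier hyperparameters sit at conventional defaults.
* Wavelet- or filter-derived feature classes and CT radiomics are not
  implemented.
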