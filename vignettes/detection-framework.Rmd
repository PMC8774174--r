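---
title: "Automatic PDAC detection from CT likelihood maps: methods and design"
author: "pdacdetect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic PDAC detection from CT likelihood maps: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdacdetect)
```

## The problem

Pancreatic ductal adenocarcinoma (PDAC) is frequently missed on
contrast-enhanced CT while still small and resectable: lesions are
poorly marginated and sometimes iso-attenuating relative to normal
parenchyma. Segmentation-oriented deep-learning detectors address this
by producing a *voxel-level tumor likelihood map* over the scan; but the
map itself is only the middle of a clinical detection system. What turns
it into a usable tool is the inference-time scaffolding around it —
automatic localization of the pancreas, suppression of implausible
predictions, conversion of the map into a ranked list of candidate
lesions and a single per-patient score — and a statistically careful
evaluation protocol at both the patient and the lesion level.

`pdacdetect` implements exactly that scaffolding, with the trained
network abstracted behind a pluggable adapter and a synthetic phantom +
mock-detector generator standing in for patients and models, so that
every stage is testable at desk scale. The networks themselves (their
architecture, training, weights) are deliberately out of scope.

## Pipeline

For one scan the inference chain is:

1. **Coarse pancreas localization.** The scan is downsampled (by default
   halving the in-plane axes, mirroring a 512×512 → 256×256 coarse grid)
   and a coarse pancreas segmenter — in production a low-resolution
   segmentation network, in testing an oracle built from ground truth —
   produces a binary mask on the coarse grid.
2. **ROI extraction** (`extractROI`). The coarse mask is upsampled back
   to the original grid (nearest neighbor), dilated with a *spherical
   kernel defined in millimetres* to close gaps, and expanded by a fixed
   margin; the bounding box of the result is cropped out of the scan.
   An empty coarse mask raises a `pancreasNotFound` condition; cohort
   drivers record the patient and continue rather than abort.
3. **Detection.** The tumor detector runs on the cropped ROI only and
   returns a likelihood map (and, for models that also segment the
   organ, a pancreas mask). Outputs are placed back into original-image
   space, zero outside the ROI (`runPatient`).
4. **Post-processing** (`maskToPancreas`). When a pancreas segmentation
   is available, the likelihood map is masked so that only predictions
   inside the pancreas region survive. Masking can only remove
   candidates and lower scores, never add.
5. **Candidate extraction** (`extractCandidates`). Iteratively: take the
   global maximum voxel (the peak), grow the 3D-connected region of
   voxels with at least 40% of the peak likelihood, record it as a
   candidate scored by its peak, zero it out, repeat — until no peak of
   at least `minPeak` remains or five candidates have been extracted.
6. **Patient score** (`patientLikelihood`): the maximum of the
   (post-processed) map — equal to the confidence of the first
   candidate. Multiple models are combined by voxelwise averaging of
   their maps (`ensembleMaps`).

## Evaluation protocol

- **Patient level:** ROC curve of patient scores, positives vs
  negatives; AUC by the trapezoidal rule, which under the
  unique-threshold sweep equals the rank-sum estimator
  $P(s^+ > s^-) + \tfrac12 P(s^+ = s^-)$ (verified against an
  $O(n^2)$ pairwise oracle in the tests).
- **Lesion level:** a candidate is a true positive when its 3D DICE
  overlap with a ground-truth lesion is at least 0.1 (inclusive).
  Matching is greedy in descending confidence and one-to-one: each
  candidate takes the unmatched lesion of highest DICE. The FROC curve
  plots lesion sensitivity (pooled over all lesions in the cohort)
  against the mean number of false-positive candidates per patient,
  averaged over *all* patients, tumor-free ones included — a mixed
  cohort is exactly where FP rates matter clinically.
- **pAUC-FROC** (`paucFroc`): sensitivity integrated over the FP axis
  restricted to [0.001, 5] FP/patient, linear scale, trapezoid on the
  piecewise-linear interpolation with the last sensitivity carried
  forward; its maximum is 4.999. The linear axis is the natural reading
  of reported pAUC values on a 0–5 scale.
- **Model comparison** (`permutationTest`): paired patient-level
  sign-flip permutation test. Under the null the A/B assignment is
  exchangeable within a patient, so each of the (default) 100,000
  iterations swaps per patient with probability ½ and recomputes the
  AUC-ROC or pAUC-FROC difference. Two-sided p-values use the +1
  finite-sample correction so p is never 0; significance is judged at
  $\alpha = 0.025$ (97.5% confidence) divided by the number of pairwise
  comparisons (Bonferroni).
- **Ensemble spread** (`meanCurves`): member curves are step-interpolated
  onto a common grid; the band is the pointwise 2.5/97.5 percentile.

## The synthetic generator

`phantomSpec()`/`makePhantom()` build a label map with the annotation
classes of a pancreatic-CT protocol: a curved tubular pancreas
(spline through jittered control points, radius 14 mm by default — a
~28 mm-thick organ), an internal pancreatic duct, a common bile duct,
vein and artery tubes, and 0+ spherical tumors centered on the pancreas
centerline with radii drawn from 8–14 mm (axial diameters 1.6–2.8 cm,
matching the size distribution of resectable PDAC; `tumorSize` measures
the maximum axial diameter the way a radiologist would). The default
grid is 64×64×40 voxels at 2×2×2.5 mm — a 128×128×100 mm field of view,
large enough for the ROI chain to act nontrivially while keeping a
242-patient cohort study tractable on one CPU.

`mockDetectorSpec()`/`mockDetect()` emulate a trained detector with
controllable operating characteristics:

- each true lesion is detected independently with probability `pDet`;
  a detected lesion receives a Gaussian blob centered on it with peak
  drawn from Beta(5, 2) and half-maximum surface at the lesion's
  equivalent-sphere radius, so the extracted candidate overlaps the
  lesion well (DICE ≈ 0.8–0.9);
- false-positive blobs arrive as Poisson(`fpRate`) per patient with
  peaks from Beta(2, 5) — stochastically dominated by true-positive
  peaks, giving non-degenerate ROC/FROC curves — and fixed 3 mm sigma;
  a configurable fraction (default 30%) is placed entirely outside the
  pancreas region so that masking has a measurable, predictable effect;
- blob centers are kept mutually separated by their extraction-time
  radii, and blobs are truncated at 45% of their peak — just above the
  40% relative extraction threshold. Both choices exist for the same
  reason: each planted blob must correspond to exactly one extracted
  candidate. A blob with a long low tail would be peeled into annular
  secondary candidates by the iterative extractor, and overlapping
  blobs would merge; either would break the identity between the
  generator's `pDet`/`fpRate` and the FROC plateau that the validation
  relies on.

Cohorts (`makeCohort`, `makePhantomCohort`) use one seeded
L'Ecuyer-CMRG stream with a per-patient substream indexed by patient
counter: bit-reproducible, order-independent, and safely extensible.

`sampleCohortScores()` draws the *patient score* directly from its
analytic distribution under the mock detector (max over Bernoulli × Beta
true-positive peaks and Poisson-thinned Beta false-positive peaks).
This is the marginal the volumetric path produces, verified against it
in the tests, and is used where thousands of replicate cohorts are
needed for score-level statistics (permutation-test calibration) and
the spatial maps themselves are irrelevant.

What the generator does *not* emulate: CT intensities and noise,
iso-attenuation contrast physics, irregular lesion margins, detector
failure modes correlated with anatomy (e.g. missing iso-dense lesions
that only secondary signs reveal). Passing tests therefore validate the
*inference and evaluation machinery* — geometry, extraction, scoring,
statistics — not the clinical performance of any real detector.

## Numerical and design choices

- **Axis convention:** arrays are indexed `(x, y, z)` in the native
  NIfTI/R layout; bounding boxes are 1-based and inclusive; world
  coordinates come from spacing and origin only, and oblique/rotated
  NIfTI orientations are rejected at read time.
- **Connectivity:** 3D candidates use the 26-neighborhood by default
  (6 available for sensitivity analysis). "At least 40% of the peak" is
  inclusive; peak ties break deterministically toward the lowest linear
  index; candidate removal zeroes the voxels.
- **Termination:** `minPeak` (default 1e-6) defines "no candidates
  remained" — a vanishing peak stops extraction.
- **Dilation radius 5 mm and ROI margin 10 mm** are package defaults:
  5 mm closes coarse-mask gaps of up to two low-resolution voxels, and
  10 mm absorbs coarse-grid quantization plus moderate
  under-segmentation. In a deployed system the margin is worth tuning
  on cross-validation data; both are configurable everywhere they
  appear, and ROI-containment tests exercise the defaults against
  2-voxel erosions of the coarse mask.
- **Coarse binarization** at 0.5 when an adapter returns probabilities.
- **DICE of two empty masks** is an error, not 0: it only arises from a
  bookkeeping bug upstream.
- **Lesion-size subgroup:** with `maxSizeCm` set, lesions above the
  cutoff leave the FROC denominator, candidates matched to them are
  ignored (neither TP nor FP), and positive patients with no retained
  lesion leave the ROC analysis. The protocol names only the subgroup
  ("tumors < 2 cm"); this is our reading of how to score it without
  penalizing detections of the excluded lesions.
- **Permutation unit:** patients (sign-flip of the paired per-patient
  predictions), applied to ensembled predictions; the alternative —
  resampling at the model level — would test a different null.

## Problem sizes used in validation

The shipped tests run the complete chain at the scales a single CPU
handles in minutes: oracle-equivalence sweeps on 100 random maps up to
12³ voxels; a 100-patient perfect-detector cohort (AUC exactly 1,
pAUC exactly 4.999); operating-characteristic recovery on 200-patient
cohorts at three (pDet, fpRate) settings with 3-sigma binomial/Poisson
acceptance bands; masking-effect measurement on 200 patients;
permutation-test calibration over 400 replicate 100-patient cohorts at
2,000 iterations per test (the protocol's 100,000 iterations are kept
as the default for real comparisons and exercised in the end-to-end
run); and a full 119 + 123 development-scale study with two detector
configurations, evaluation and comparison.

## Worked example

```{r example, eval = FALSE}
phantoms <- makePhantomCohort(nPos = 20, nNeg = 20, seed = 1)
run <- runCohortPipeline(phantoms, mockDetectorSpec(pDet = 0.8,
                                                    fpRate = 1.0),
                         seed = 2)
ev <- evaluateCohortRun(run)
ev$aucRoc      # patient-level discrimination
ev$paucFroc    # lesion-level localization over [0.001, 5] FP/patient
```

## Known limitations

- The generator's lesions are spheres with clean margins; real PDAC is
  infiltrative. Operating-characteristic recovery is exact *for the
  generator's own contract*, not a statement about clinical data.
- Only axis-aligned geometry is supported; DICOM ingestion, oblique
  reformats and HU calibration are out of scope.
- The oracle coarse segmenter bounds what the ROI stage can achieve;
  with a real coarse network the pancreas-not-found path and the margin
  become load-bearing and should be revalidated per dataset.
- FROC false positives are averaged over all patients; protocols that
  average over negatives only will report higher FP/patient on mixed
  cohorts.
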