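---
title: "Methods: automated CT body composition and its validation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated CT body composition and its validation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctcomp)
library(dplyr)
```

## The measurement problem

Skeletal muscle mass is a prognostic marker in oncology: sarcopenic patients
have worse overall survival and more postoperative complications. The
established imaging surrogate is the cross-sectional area (CSA) of muscle on
a single axial CT slice at the third lumbar vertebra (L3), normalized by
height squared into the skeletal muscle index,

$$\mathrm{SMI} = \frac{\mathrm{CSA_{muscle}}\ [\mathrm{cm^2}]}{\mathrm{height}^2\ [\mathrm{m^2}]}.$$

Manual measurement is slow, so practical pipelines combine an external
deep-learning segmentation backend (which produces anatomical label maps)
with deterministic postprocessing. `ctcomp` implements that postprocessing
and the statistics used to validate it. The segmentation model itself is out
of scope by design: the package consumes label maps from any backend, and
ships a phantom generator so every stage is testable without patient data.

## Pipeline stages and their conventions

1. **Ingest.** CT volumes are read from NIfTI (or a single DICOM series,
   converted on ingest with the rescale slope/intercept applied) and
   canonicalized to right-anterior-superior (RAS) axis order, so the axial
   axis is last and slice indices increase toward the head. Reorientation
   permutes and flips the grid only — the world coordinates of every voxel
   are unchanged, and the operation is idempotent. Files without a usable
   qform/sform are rejected as metadata errors rather than guessed at.
   Label maps must match the CT geometry within 0.1 µm; mismatches are
   errors, never silently resampled, because grid alignment is the
   backend's contract. No in-plane resampling is performed at all: CSA is
   spacing-aware, so working at native resolution adds no error.

2. **Spine reduction and localization.** Vertebra labels are intersected
   with a vertebral-bodies mask, discarding arches and spinous/transverse
   processes whose voxels would drag the center of mass posteriorly. The
   vertebra center is the *unweighted* mean world-*z* of its body voxels
   (the label is binary, so HU weighting has no basis), computed in
   millimetres rather than voxel indices so anisotropic spacing cannot bias
   it. The center slice is the slice plane nearest that *z*; an exact tie
   between two planes resolves to the inferior slice, a deterministic rule
   matching the craniocaudal reading direction of manual protocols. The
   slice span of a vertebra is every slice containing at least one of its
   body voxels; boundary slices shared with a neighbor count for both
   (the simplest rule consistent with averaging over "all L3 levels" —
   span sensitivity is covered by tests rather than a reassignment
   heuristic).

3. **Spine QC.** Automated vertebra labelling fails in recognizable ways:
   missing labels, swapped ordering after lumbarization/sacralization, and
   label fragments merged across levels. `qc_spine()` surfaces all three
   (missing labels between the extremes present; centers not strictly
   monotonic in *z*; axial extent beyond 2.5× the median — a configurable
   default, since no principled constant exists). QC reports; it never
   "fixes" anatomy, because relabeling anomalies without rib-level context
   would be guesswork.

4. **Tissue assignment.** Compartment masks are confined to the body trunk
   (a voxelwise intersection that removes arms, head and neck), then tissue
   is assigned per voxel by closed HU intervals:

   | Tissue | Compartment | HU window |
   |---|---|---|
   | SM_total | muscle | [−29, 150] |
   | SM_psoas | psoas | [−29, 150] |
   | VAT | visceral | [−190, −30] |
   | SAT | subcutaneous | [−190, −30] |
   | IMAT | muscle | [−190, −30] |

   Both ends are closed: this keeps the muscle and adipose windows disjoint
   (the open gap (−30, −29) belongs to neither). Thresholding is purely
   voxelwise — no connected-component or island filtering — so known
   artifacts of HU-only segmentation, e.g. bowel content counted as VAT,
   are reproduced rather than silently corrected. IMAT is computed and
   reported but never enters the SMI.

5. **Quantification.** Per slice, `csa_cm2 = n_voxels × dx × dy / 100`.
   Two reference measurements are exposed because both are in clinical use:
   the CSA on the single center slice (mirroring manual single-slice
   reading) and the unweighted mean over the vertebra's slice span, which
   damps the strong slice-to-slice variability of psoas measurements.
   Relative profiles express each slice as a percentage of the center-slice
   value, indexed by signed offset (negative = inferior), which is the
   standard way to display slice-selection sensitivity.

## The phantom generator

`phantom_spec()`/`generate_phantom()` rasterize an abdomen-like scene from
analytic primitives (ellipses, annuli, cylinders) by voxel-center
membership: an elliptical trunk, a subcutaneous fat ring, an abdominal-wall
muscle band, two psoas discs (optionally tapering along *z*), a stack of
vertebral bodies with posterior spinous processes, a small intramuscular
fat inclusion, and an adipose-range "bowel content" blob. Optional failure
modes reproduce documented error classes: out-of-trunk "arm" blobs wrongly
included in the muscle compartment, missing vertebra labels, swapped
labels, and a detached label fragment.

Defaults are chosen so the phantom is *diagnostic*, not photorealistic:

* Tissue HU means sit strictly inside their windows (muscle 50 HU, fat
  −100 HU, bone 400 HU, bowel −50 HU), so with `noise_sd = 0` thresholding
  must recover every compartment voxel exactly — any per-voxel discrepancy
  is a bug, not noise. Noise tests use σ ∈ {5, 15, 40} HU, the last
  emulating genuinely noisy scans.
* The grid (96 × 96 × 56 voxels at 2 × 2 × 2.5 mm) and organ extents are
  deliberately smaller than a real abdomen so that full-pipeline tests run
  in seconds; absolute CSAs (≈ 42 cm² SM_total) are therefore below typical
  adult values (≈ 80–180 cm²), while every *relationship* the pipeline
  relies on (containment, disjointness, unit conversion, center-of-mass
  geometry) is at scale.
* Ground truth is computed by an independent per-voxel membership recount
  over the generated label maps, not by the pipeline under test, and
  analytic areas (πr², πab) audit the rasterization; discs with radius
  ≥ 20 voxels agree with the analytic area to well under 1.5%.

What the phantom does **not** emulate — real organ anatomy, contrast
phases, beam hardening, metal artifacts, partial-volume mixing at tissue
boundaries — bounds what passing tests show: they verify the postprocessing
and statistics are correct *given* label maps, not that any particular
segmentation backend produces good label maps.

`generate_cohort()` extends the phantom to populations: per-subject
lognormal scaling of in-plane extents (default SD 0.06 on the log scale,
i.e. ≈ ±12% spread in linear size, a plausible anthropometric range),
heights uniform on [1.55, 1.95] m, and overall survival from an exponential
proportional-hazards law whose log-hazard decreases linearly in the true
SMI (baseline median OS 24 months, administrative censoring at 60 months —
magnitudes typical of surgical-oncology cohorts). The exponential law is a
test-harness choice, not a claim about any real cohort: it makes the null
(`hazard_coef = 0`) and alternative exactly known, so Cox coverage and
C-index behavior can be calibrated. Subject-level CSAs are analytic areas
of the scaled primitives, so cohorts of hundreds of subjects are drawn
without rasterizing volumes; each row carries a scaled `phantom_spec` from
which the full volume can be materialized on demand (grid fit is checked at
rasterization, since an unusually large subject is a legitimate cohort
member even when the default grid cannot hold them).

## Validation statistics

**Agreement.** `bland_altman()` reports bias = mean(auto − manual), the
sample SD of differences, and limits of agreement bias ± 1.96 SD. Outliers
are pairs outside the limits of agreement — the standard Bland–Altman
reading of "beyond the 95% interval" (the alternative reading, the CI of
the bias, shrinks with n and would flag most points in large samples).
Pearson r comes with a Fisher-z 95% CI. Degenerate pairs (fewer than 4, or
zero variance) leave the correlation fields `NA` rather than failing the
agreement summary.

**Level variability.** `fit_level_model()` fits
`csa ~ level + (1 | patient)` by REML with L3 as the reference level:
fixed effects quantify the systematic offset of L2/L4 measurements while
the random intercept absorbs between-patient size. Inference is
large-sample Wald (the estimator and inference method are conventional
defaults; with hundreds of patients the difference from finite-sample
corrections is negligible). Relative level values are derived from fixed
effects only, `100 (β_ref + β_level)/β_ref`, so L3 ≡ 100%. An exactly
noiseless fit has a degenerate information matrix in lme4; the package then
reports zero standard errors (the model-based covariance is the zero
matrix) and `NA` p-values rather than failing.

**Prognosis.** `survival_analysis()` reports Kaplan–Meier median OS with
95% CI; a Cox model (Efron ties) on the cohort-internal median split of
SMI, oriented so the hazard ratio is low-SMI vs high-SMI (HR > 1 = low
muscle mass adverse — the orientation is documented because published
reports often leave it implicit); Harrell's C with risk = −SMI, so C > 0.5
means higher SMI predicts longer survival; and the ROC AUC of SMI for
above-median OS. AUC labels handle censoring conservatively: events before
the median OS are the below-median class, subjects observed beyond it
(event or censored) the above-median class, and subjects censored before
the median are excluded as indeterminate. `concordance_index()` is
verified against brute-force comparable-pair enumeration (including tied
times, tied risks and censoring) on every fixture up to n = 30.

## Numerical choices and degenerate inputs

* Geometry comparison tolerance: 1e−4 mm on spacing and affine entries.
* Center-slice tie-break: inferior slice (deterministic; ties occur for
  any even-slice symmetric vertebra).
* HU data are held as doubles regardless of on-disk type; out-of-range
  values ([−1024, 3071]) are QC-flagged, not rejected.
* Axial spacing above 8 mm triggers a QC warning, not an error (thick
  slices degrade CSA estimates but may still be the only imaging
  available).
* Heights outside (0.5, 2.5) m warn; nonpositive heights are errors.
* Zero reference CSA makes a relative profile undefined — an error, not
  `Inf`.
* Empty compartments, all-zero label maps and header-only outputs are
  valid and exercised by tests.

## Problem sizes

The shipped tests and the acceptance script use the default 96 × 96 × 56
phantom, cohorts of 150–500 subjects, a 200-patient level-model recovery
(patient SD 20 cm², residual SD 5 cm², offsets −10/+5 cm² on a 100 cm²
reference), and 100 replicates of a 300-subject null cohort for Cox CI
coverage. These sizes give Monte-Carlo error comfortably below the
assertion tolerances while keeping a full run around half a minute.

## Limitations

* The package validates postprocessing and statistics; it cannot detect a
  backend whose label maps are anatomically wrong but geometrically
  consistent (beyond the spine QC heuristics).
* Vertebral anomalies are surfaced, never corrected.
* Only 2-D per-slice areas are produced, no 3-D volumes, and no
  partial-volume correction is attempted.
* The phantom's survival generator is a calibration device; effect sizes
  estimated from it say nothing about clinical effect sizes.

## A worked example

```{r example}
ph <- generate_phantom(phantom_spec())
run <- run_measure(run_config(ph$ct, ph$labels, subject = "demo",
                              height_m = 1.75))
run$measurements |>
  select(tissue, csa_reference_cm2, csa_vertebra_mean_cm2, smi_cm2_m2)
```

The noiseless phantom measures identically under both reference modes (its
structures are z-uniform within the vertebra span), and every value equals
the generator's voxel-count ground truth exactly.
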