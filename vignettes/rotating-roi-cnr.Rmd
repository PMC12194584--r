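---
title: "Statistical rotating-ROI CNR measurement on the ACR CT phantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical rotating-ROI CNR measurement on the ACR CT phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acrcnr)
```

## The measurement problem

Low-contrast detectability is the limiting image-quality property for many
CT diagnoses, and it is monitored in quality-control programs by measuring
the contrast-to-noise ratio (CNR) on a phantom with a low-contrast module.
In the ACR accreditation phantom the reference target is a 25 mm cylinder
whose CT number sits only about 6 HU (≈ 0.6 %) above the water-equivalent
background. The ACR tolerance is a CNR of at least 1.0.

Two things make automation non-trivial. First, the object is nearly
invisible: intensity-based segmentation of a 6 HU disc in noise of
comparable magnitude is unreliable, especially for sharp reconstruction
kernels where the noise SD can exceed the contrast by an order of
magnitude. Second, although the object's radial distance from the phantom
centre is fixed by construction (55 mm), its angle is arbitrary, and the
phantom itself is rarely perfectly centred in the gantry.

The statistical method implemented here sidesteps segmentation entirely. It
uses only the known radial geometry plus an exhaustive angular search with
ROI *statistics* as the detection signal, which degrades gracefully with
noise because the 25 mm ROI averages ≈ 2300 pixels at typical spacings.

## The procedure

1. **Body segmentation.** Pixels above a threshold (default −300 HU, midway
   between air at −1000 HU and the body) are labelled; the largest connected
   component is kept and internal holes are filled (`segment_phantom()`).
   The largest-component rule discards couch fragments; hole filling makes
   the footprint insensitive to any hypodense internal structure.
2. **Centroid.** The *binary* (unweighted) centroid of the footprint
   (`phantom_centroid()`), in physical mm. An intensity-weighted centroid
   would be biased by the low-contrast insert itself; the binary centroid is
   not. The equivalent diameter of the footprint is checked against the
   nominal 200 mm body ([150, 250] mm accepted; outside that range the
   result is flagged suspect but still computed).
3. **Angular profile.** A circular ROI (default 25 mm diameter) is centred
   55 mm from the centroid and stepped clockwise in 2° increments; the mean
   CT number at each of the 180 positions forms the angular profile
   (`angular_profile()`). Angle 0° is 12 o'clock on the displayed image, and
   an ROI centre is `centroid + r·(sin θ, −cos θ)` in (x, y) display
   coordinates with y pointing down.
4. **Localization.** The object angle is the profile argmax, first
   occurrence on exact ties (`locate_low_contrast_object()`). Ties are
   measure-zero on real noisy data; the rule exists for synthetic edge
   cases. No sub-step refinement is attempted: with a 25 mm ROI on a 25 mm
   object, a ≤ 1° quantization error (≈ 1 mm of arc at 55 mm) costs a
   negligible fraction of ROI–object overlap.
5. **CNR.** With the object ROI at the detected position and a background
   ROI at the centroid (`measure_cnr()`),
   CNR = (CT̄_obj − CT̄_bg) / SD_bg, with the *sample* (n−1) standard
   deviation — the convention of scanner consoles, and slightly conservative.
   Contrast is signed, not absolute; the module-2 reference object is
   hyperdense, so values are positive in practice.

`auto_cnr()` composes the five stages and tags any stage failure with the
stage name. Stacks are processed per slice and summarized as mean ± SD
across slices (`summarize_cnr()`) — never as a ratio of averaged contrast to
averaged noise, since the per-slice ratio is the quantity whose distribution
the QC comparison tests.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `radius_mm` | 55 | mm | radial position of the ACR module-2 reference cylinder |
| `roi_diameter_mm` | 25 | mm | "25 mm ROI" read as *diameter*, matching the 25 mm object; a 25 mm radius could not stay inside the body at 55 mm radius |
| `step_deg` | 2 | ° | 180 positions per rotation; adjacent ROIs overlap heavily, so the maximum cannot fall between steps |
| `background_roi_diameter_mm` | 25 | mm | chosen symmetric with the object ROI; reported with every result |
| `threshold_hu` | −300 | HU | midway between air and body; robust to all tabulated noise levels (≈ 2–50 HU) |

All ROI geometry is computed in millimetres from the pixel spacing, so field
of view and matrix size need no special handling.

## The synthetic phantom generator

`phantom_config()` / `generate_slice()` render a module-2-like slice: a
200 mm body disc at 90 HU in −1000 HU air, one 25 mm disc at 55 mm radius at
a configurable angle and contrast (default +6 HU), optional 2–6 mm
decorative cylinders, a configurable phantom-centre offset, and additive
Gaussian noise on body pixels. Disc edges are antialiased by area fraction
(4 × 4 supersampling of rim pixels) so that ROI means are not biased by
rasterization. Slices are deterministic in `(config, slice_seed)`;
`generate_stack()` derives per-slice seeds from the stack seed, and the
caller's RNG state is restored afterwards.

Defaults mirror the conditions of published ACR-phantom studies: 235 mm
reconstruction FOV on a 512 matrix (0.459 mm pixels; matrix size is not
dictated by the phantom, 512 is the common reconstruction), contrast 6 HU
within the reported 5–7 HU range, and noise SD spanning ≈ 2–5 HU for smooth
kernels up to ≈ 50 HU for edge kernels. The nominal background of 90 HU is
irrelevant to the algorithm, which uses only differences.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: CT noise is spatially correlated by the
reconstruction kernel (white noise here), there is no beam hardening, no
partial-volume averaging across slice thickness, and kernel variation is
represented purely by the noise SD. These simplifications are adequate for
validating a mean/SD-based statistic and its geometry, not for
model-observer or noise-texture work.

## Numerical choices and degenerate inputs

* ROI membership: a pixel belongs to a circular ROI iff its centre is within
  the radius (Euclidean, mm). Pixel counts agree with the analytic area to
  well under 2 % for diameters ≥ 10 mm at 0.459 mm spacing.
* A noiseless background (SD exactly 0) makes the CNR undefined; that is an
  explicit error, not an Inf.
* A uniform phantom with no object is localized *somewhere* (the argmax of
  pure noise) with CNR near 0 — no crash, and the magnitude is bounded by
  the sampling noise of the ROI means.
* An air-only image fails at segmentation with a "no phantom found" error.
* The Mann–Whitney comparison uses midranks for ties, exact enumeration of
  all label assignments for combined n ≤ 12 (QC series are small), and a
  tie-corrected normal approximation with continuity correction above that.
  Significance is reported at α = 0.05 with the p-value always printed, and
  no multiple-testing correction, matching QC practice of testing each
  parameter series on its own.
* Percent difference between series is |mean_a − mean_ref| / mean_ref × 100
  with the manual series as reference; the definition is printed in every
  comparison report because "difference" columns in the literature are
  often left undefined.

## Validation problem sizes

The test suite validates localization on 100 noisy (SD 3 HU, contrast 6 HU)
slices with random angles and up to 5 mm misalignment (≥ 95 must hit within
one 2° step); CNR recovery on 20-slice stacks (mean within 10 % of the
configured contrast/noise ratio of 2.0); a monotone mean-CNR trend across
noise SDs {4.2, 3.6, 2.9, 2.7} HU; and sub-2 mm localization error at 10 mm
misalignment. Unit tests run on 256-pixel matrices for speed; the
full-geometry checks use the default 512 matrix.

## Known limitations

* The method scores only the largest (25 mm) low-contrast object; the 2–6 mm
  cylinder series is beyond a mean-based statistic at these contrasts.
* Correlated noise narrows the gap between the profile maximum and the
  background fluctuations; with very sharp kernels the localization still
  works (the ROI mean averages thousands of pixels) but the CNR itself
  approaches 0, as the tabulated edge-kernel values show.
* DICOM support is deliberately minimal: single-frame, uncompressed
  little-endian CT objects with linear rescale. Compressed transfer
  syntaxes, LUTs and multi-frame objects are rejected with explicit errors.
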