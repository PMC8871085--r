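---
title: "Metal-preserving bone-subtraction CTA: method and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metal-preserving bone-subtraction CTA: method and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clipkeep)
```

## The problem

Bone-subtraction CT angiography (BS-CTA) acquires two co-registered head CT
volumes — one without contrast agent and one during iodine contrast
injection — and subtracts them voxelwise. Bone and soft tissue are identical
in both scans and cancel, leaving the contrast-filled vessels. The weakness
of the technique for post-surgical patients is that aneurysm clips and coils
(titanium/cobalt alloys) are *also* identical in both scans: subtraction
removes the implant together with the bone, and the rendered angiogram loses
exactly the device the follow-up examination is about.

`clipkeep` implements a threshold-and-reinsert remedy. Because metallic
implants are far denser than skull bone on the Hounsfield scale, they can be
located on the non-contrast volume alone, segmented precisely inside a local
region of interest, and written back into the subtracted volume.

## The procedure

Each axial slice of the non-contrast volume is processed independently:

1. **Global metal threshold.** Pixels strictly above `threshold_hu`
   (default 3500 HU) are candidate metal. Skull bone stays below this level,
   implant alloys above it, so the candidate mask is metal-specific.
   Detection deliberately uses the *non-contrast* slice: on the contrast
   slice, iodine-filled vessels and partial-volume metal can approach each
   other in HU.
2. **Connected components.** Candidates are labelled (8-connectivity by
   default; clips are thin oblique structures that 4-connectivity tends to
   fragment) and each component gets its inclusive bounding box
   `[r_min, r_max] x [c_min, c_max]` and pixel count.
3. **ROI construction.** For each component a rectangular ROI is centred on
   the bounding-box midpoint with half-extents
   `ceiling(alpha * max(r_max - cc_row, cc_row - r_min))` (and analogously
   for columns), floored at one pixel and clipped to the frame. The
   enlargement factor `alpha` (default 1.5) guarantees context around the
   implant while keeping the ROI free of unrelated structures.
4. **Otsu refinement.** The ROI's histogram (256 equal-width bins over the
   ROI's own HU range) is split at the level `k*` maximizing the
   between-class variance
   `sigma_BC^2(k) = (m_G P(k) - m(k))^2 / (P(k) (1 - P(k)))`,
   with `P(k)` the cumulative class probability, `m(k)` the cumulative first
   moment and `m_G` the global mean level. Pixels above the threshold (upper
   edge of bin `k*`) inside the ROI form the metal mask. The refinement
   recovers implant pixels *below* the conservative global threshold (e.g.
   partial-volume edges) that the 3500 HU cut would miss.
5. **Subtraction and re-insertion.** The BS-CTA volume is the plain signed
   difference `contrast - noncontrast` (no clamping). Masked voxels are then
   replaced by their non-contrast values (`merge_mode =
   "replace_noncontrast"`), i.e. the implant's own image information is
   incorporated without blending; `"max_union"` is available as an
   alternative. Every voxel outside the mask is bit-identical to the plain
   subtraction — a conservation property the test suite checks exhaustively.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `threshold_hu` | 3500 HU | global metal cut on the non-contrast slice; bone < 3500 < alloy |
| `alpha` | 1.5 | ROI enlargement factor relative to the component half-extent |
| `otsu_bins` | 256 | ROI histogram resolution (8-bit convention, applied to HU directly) |
| `connectivity` | 8 | component neighbourhood; 4 available |
| `roi_mode` | per_component | one ROI per component; `global` pools all candidates into one box |
| `merge_mode` | replace_noncontrast | how masked voxels re-enter the subtracted volume |

## Conventions and numerical choices

* Axis order is (slice, row, column) and **all indices are 1-based**,
  matching R's indexing; bounding boxes and ROIs use inclusive bounds.
* The component "centre" is the bounding-box midpoint rounded half away
  from zero. A `half_extent` mode computes the half-extent form
  `((r_max - r_min)/2, (c_max - c_min)/2)` instead; it is retained for
  auditability only, since a half-extent is not a location and an ROI built
  around it cannot be guaranteed to contain the component.
* ROI half-extents use the *maximum* distance from the centre to either box
  bound. Using only the upper-bound distance would undercover boxes with an
  even extent once the midpoint is rounded to an integer (bounds 10–13
  round to centre 12 and would lose row 10 at `alpha = 1`); the symmetric
  form keeps the full bounding box inside the ROI for every `alpha >= 1`,
  so no metal pixel is lost to rounding.
* Otsu split: candidates with `P(k)` equal to 0 or 1 are skipped (the
  variance ratio is undefined there); plateaus of equal variance are broken
  toward the smallest `k`, which makes the pipeline deterministic. Both
  binarization predicates are strict (`> threshold`).
* A constant-intensity ROI has no histogram to split. The default fallback
  binarizes that ROI at the global `threshold_hu` instead of aborting the
  slice (`degenerate_fallback = "skip"` drops the ROI entirely).
* Registration is a precondition, not a feature: a shape or spacing mismatch
  raises a registration-assumption error rather than silently resampling.
* NIfTI voxel values are taken as already in HU; DICOM stored values are
  rescaled by the slope/intercept tags and slices sorted by ascending
  patient z. Masks are written as NIfTI volumes with values {0, 1}.

## Evaluation metrics

Segmentation accuracy against a reference mask X for a predicted mask Y is
reported as the Dice similarity coefficient
`DSC(X, Y) = 2|X ∩ Y| / (|X| + |Y|)` and the bidirectional Hausdorff
distance `HD(X, Y) = max(hd(X, Y), hd(Y, X))` with
`hd(X, Y) = max_{x in X} min_{y in Y} ||x - y||` (Euclidean, voxel index
units; an optional spacing argument measures in millimetres). Per-slice
values are summarized as mean ± sample SD, median, minimum/maximum and a
95% confidence interval using the t distribution — at the handful of slices
an implant spans, a normal interval would be visibly too narrow. Evaluating
two empty masks raises an error rather than inventing a convention; silent
defaults there hide bugs.

```{r metrics-example}
x <- matrix(FALSE, 4, 4); x[1, 1:4] <- TRUE
y <- matrix(FALSE, 4, 4); y[1, 1:3] <- TRUE; y[2, 1] <- TRUE
dsc(x, y)
summarize_values(c(1, 2, 3))[c("ci95_lo", "ci95_hi")]
```

## The synthetic phantom

No patient data ship with the package, so every claim is exercised on a
parametric head phantom: an ellipsoidal skull shell (default 1500 HU)
around brain soft tissue (35 HU), vessel tubes (adding 400 HU, present in
the contrast volume only), and implants at 4000 HU present identically in
both volumes. 4000 HU is a plausible value for clip alloys at typical tube
potentials, not a measured constant. The default volume is 64×128×128
voxels at 0.75×0.5×0.5 mm — a scaled-down head chosen so the full
phantom–pipeline–evaluation chain runs in seconds; all thresholds operate
on HU values and are unaffected by the grid size. Noise is i.i.d. Gaussian,
drawn independently for the two volumes (two scans, two realizations —
which is what makes the subtracted background nonzero in the noisy regime),
and misregistration is an integer-voxel roll of the contrast volume with
air fill.

Presets cover the clinically recurring cases: `single_clip`, `two_clips`,
`coil` (a ball of scattered high-HU voxels), `clip_near_bone` and
`misregistered`.

```{r phantom-run}
ph <- generate_phantom(phantom_preset("single_clip", seed = 7))
res <- run_pipeline(ph$noncontrast, ph$contrast)
dsc(ph$metal_truth, res$metal_mask)
max(abs(res$bscta$voxels[ph$bone_truth]))
```

What the phantom does *not* emulate: partial-volume edges, beam-hardening
physics, scanner noise texture, anatomy beyond an ellipsoid. Streak
artifacts are available only as a labelled parametric pattern
(`degrade(kind = "streak")`). Passing tests on the phantom therefore
demonstrate algorithmic correctness — thresholding, labelling, ROI
arithmetic, Otsu optimality, conservation, metric exactness — not clinical
performance on patient volumes.

## The documented failure mode

When an implant sits against the skull, the ROI around it contains a large
bone fraction, and the best two-class split of a brain/bone/metal histogram
can fall *below* bone: bone is then segmented together with the implant.
The `clip_near_bone` preset reproduces this deliberately — a thin oblique
blade whose bounding box straddles the inner bone boundary — and the test
suite asserts the failure (the mask strictly contains bone voxels,
DSC < 1). The adjacency algebra is easy to see in the two-class form
`sigma_BC^2 = P(1-P)(mu_1 - mu_0)^2`: with enough bone mass relative to
metal, separating brain from everything bright beats separating metal from
everything dark. The method inherits this limitation by design; it is a
threshold method, not a classifier.

A related consequence of the spike-valued phantom: *mild* streak artifacts
(tens to a few hundred HU) cannot change the segmentation at all, because
every Otsu split inside the wide empty gap between streaked soft tissue and
metal produces the identical mask. The streak degradation test therefore
uses a severe (2000 HU) streak, which genuinely pulls the split below the
streak class.

## Validation strategy and problem sizes

Every non-trivial computation is checked against an independently coded
oracle: Otsu selection against an exhaustive per-split scan in the
two-class-means form (1000+ random histograms of 16–256 bins), component
labelling against a dense min-label propagation, DSC against direct
counting and HD against an all-pairs scan (500+ random mask pairs up to
32×32), and the t-interval against its closed form plus an empirical
coverage simulation (10,000 Gaussian samples of n = 9). End-to-end, the
noise-free single-clip phantom must be recovered *exactly* (DSC = 1,
HD = 0, bone residual exactly 0, vessel voxels exactly at their contrast
increment), the 20 HU noisy presets to DSC ≥ 0.95 and HD ≤ 2 voxels, and a
2-voxel misregistration must leave >100 HU bone-edge residuals that the
registered pair does not have. `scripts/acceptance.R` recomputes all of
these from scratch at a user-supplied seed.

## Known limitations

* Per-slice 2D processing (matching the method's slice-wise design); a 3D
  component analysis is a possible extension, not implemented.
* No registration, no metal-artifact reduction, no dual-energy
  decomposition; inputs must be co-registered.
* The DICOM reader is deliberately minimal: single-frame, uncompressed,
  little-endian series with rescale tags present. Anything else is rejected
  with a format error naming the file.
* The 3500 HU default was established at a single tube potential; whether
  it generalizes across acquisition protocols is untested here.
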