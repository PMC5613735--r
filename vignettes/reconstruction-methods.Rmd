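---
title: "Serial-section reconstruction: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serial-section reconstruction: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histovol)
```

## The problem

Mapping the 3D distribution of a fluorescently labelled cell population —
for example a tdTomato-expressing cardiomyocyte subpopulation in a mouse
heart — from serial coronal cryosections requires turning a stack of
independently imaged, slightly misaligned 2D section images into a single
registered, classified voxel volume. histovol implements that
reconstruction as a deterministic, configurable pipeline:

1. per-image linear **auto-contrast**;
2. **marking** of positively stained regions (red channel at or above a
   threshold) by adding a fixed intensity boost during grayscale
   conversion;
3. **Gaussian smoothing and down-sampling**;
4. landmark-based **rigid registration** (rotation + translation only) of
   every slice to a reference slice;
5. three-class **intensity classification** into positive / negative /
   non-tissue background;
6. nearest-neighbour **repair of damaged slices**;
7. seeded 3D **region growing** to remove extra-organ noise;
8. majority-label **XY down-sampling**; and
9. output as a **legacy ASCII VTK structured-points** file for Paraview.

## The model, stage by stage

### Marking and grayscale conversion

Positive staining lives in the red channel (e.g. tdTomato fluorescence).
A pixel whose red value is at or above `red_threshold` (default 25, the
midpoint of the 20–30 working range typical for such stacks; per-slice
overrides are supported because real thresholds are chosen by visual
inspection) has `mark_boost` (default 100) added to its grayscale luma
(`0.299 R + 0.587 G + 0.114 B`, rounded half-up). Since the negative
tissue band sits below 80, the +100 plateau guarantees that marked pixels
land strictly above the positive classification threshold. The threshold
comparison is inclusive (`>=`) so boundary pixels stay positive; marking
is recorded in a flag and a second marking attempt is an error rather
than a silent no-op, to surface pipeline-wiring bugs.

The stage order — contrast, then marking, then smoothing, then
registration — is fixed: marking precedes smoothing so that the boost
plateau survives blurring, and registration uses nearest-neighbour
resampling so plateaus are never blended into intermediate values.

### Auto-contrast

One linear transfer function per image (channels rescaled jointly, so
red dominance is preserved) maps the saturation-clipped low tail to 0 and
the high tail to 255. With saturation fraction $s$ and $n$ samples, the
clip bounds are the sorted values at ranks $\lfloor sn \rfloor + 1$ and
$\lceil (1-s)n \rceil$. The default saturation is 0 (pure min–max
stretch): the pipeline's inputs are already 8-bit images with a
meaningful intensity scale, and tail clipping on images dominated by
black background would move the tissue band unpredictably relative to
the fixed classification thresholds. Constant images pass through
unchanged.

### Gaussian smoothing and down-sampling

Smoothing uses a normalized kernel of radius $\lceil 3\sigma \rceil$ with
a half-sample-symmetric (reflective) boundary, which preserves the image
mean exactly (tested to 1e-6 in floating point); decimation keeps every
`factor`-th pixel starting at index 0, so output dims are
`ceiling(dim/factor)`. Smoothing exists to anti-alias before decimation,
so the default `gaussian_sigma = "auto"` resolves to `factor/2` when
`factor > 1` and to 0 when no down-sampling is requested — blurring
without decimation would only smear the marked plateau across class
boundaries.

### Rigid registration

The transform model is strictly rigid, `p' = R(θ)p + t`: sections are
translated and rotated on the stage but not scaled, sheared, or flipped
(the determinant of the fitted rotation is forced to +1). The per-pair
estimator is the closed-form least-squares fit: centroid subtraction,
2×2 cross-covariance `H = Σ m̃ᵢ f̃ᵢᵀ`, SVD `H = USVᵀ`,
`R = V diag(1, det(VUᵀ)) Uᵀ`, `t = f̄ − R m̄`. Landmarks are matched
point lists (`x y` per line, 0-based pixel coordinates, paired by row
order).

The reference slice defaults to the middle of the stack
(`floor(n/2)`, 0-based) — the natural anchor when alignment errors
propagate outward. The default `"chain"` mode fits each slice to its
nearest landmark-bearing neighbour toward the reference and composes
the fits, which is how serial-section alignment is done in practice
(corresponding points need only be identifiable between neighbouring
sections); `"direct"` mode fits every slice straight to the reference
and is preferable when one landmark set spans the whole stack. Slices
without landmarks are an error unless flagged damaged, in which case
they pass through with the identity and are repaired after
classification.

Resampling is nearest-neighbour everywhere, by inverse warping with
out-of-frame samples set to 0. Bilinear interpolation would invent
intermediate intensities that straddle classification thresholds.

### Classification

With thresholds `positive_above = 80` and `background_below = 3`:
intensity > 80 is positive, 3–80 inclusive is negative tissue, < 3 is
non-tissue background. The strictness pattern (strict above, inclusive
band, strict below) is the only reading that makes the three bands
partition the 8-bit range; class counts always sum to the voxel total.

### Damaged-slice repair

Slices whose tissue background is too dim to classify (flagged in the
manifest) are repaired *after* classification: every background or
negative voxel takes the label at the same (x, y) in the nearest
non-damaged slice, ties toward lower z. Positive voxels on damaged
slices are preserved, because the bright positive signal remains
distinguishable even when tissue contrast is lost. Copying labels is the
nearest-neighbour analogue at the label level; interpolating intensities
instead would resurrect the very pixels that could not be classified.
The repair's error scales with how fast the organ cross-section changes
between neighbouring slices, so it is most accurate away from the organ
poles.

### Region growing

Extra-organ noise (stray fluorescence, dust, stitching remnants) is
removed by growing a region from a seed through tissue voxels (negative
or positive) and relabelling unreached tissue as background. Labels
inside the region are never altered. Connectivity defaults to 6 (face
neighbours): with strongly anisotropic z-spacing, 26-connectivity lets
single-voxel diagonal contacts bridge physically separate structures;
both options are exposed and both are oracle-tested. The `"auto"` seed
is the tissue voxel nearest the tissue centroid (first such voxel in
linear order on ties), which lands inside the organ for any convex-ish
silhouette; an explicit `(x, y, z)` seed on tissue may be given instead,
and a background seed is an error.

### Volume down-sampling and VTK output

XY down-sampling (Z is never reduced — one voxel per physical section)
takes the majority label per `factor × factor` block, ties broken
positive > negative > background so sparse signal is not erased by
rounding; x/y spacing is multiplied by the factor. The volume is written
as legacy ASCII VTK structured points with unsigned_char scalars
(default map: background 0, negative 100, positive 200, echoing the
~100-intensity class separation used in marking), x varying fastest.
ASCII keeps output diffable and byte-stable; the package also ships a
strict reader for this dialect, used as the writer's round-trip oracle.
Spacing and units (`spacing`, `unit_label`) are carried verbatim as
metadata; the package performs no unit conversion. `spacing` in the
configuration describes the voxels at classification resolution, before
the XY down-sampling factor is applied.

## The synthetic-data generator

`generate_stack()` emulates the features of such stacks that the
pipeline's correctness depends on, with exact ground truth:

- a single smoothly varying elliptical organ silhouette per slice
  (elliptic scale profile along z with a floor of 0.6, plus a small
  sinusoidal centre drift of 6 px), guaranteeing the single connected
  3D component that region growing assumes;
- positive clusters bright in red (180–235) over tissue whose red
  autofluorescence is dim (N(6, 2.5), clipped at 12) and whose luma is
  N(40, 6): the red channel is genuinely bimodal, as in a
  well-expressed fluorescent reporter. The first cluster is a
  transmural band running through every slice — the mapped population
  is present in every section, concentrated in one contiguous structure
  — with ellipsoidal satellites scattered through the organ. This keeps
  the per-image dynamic range comparable across slices, which is what
  makes a single global red threshold workable after per-image
  auto-contrast (with slices lacking any positive signal, auto-contrast
  would stretch tissue red past a global threshold — the reason
  per-slice thresholds exist in practice, and the reason the package
  supports `red_threshold_overrides`);
- per-slice rigid misalignment, uniform in ±3° and ±8 px by default
  (5° / 10 px are used in the registration-recovery validation);
- extra-organ speckle blobs at density 5e-5 per pixel (a few blobs per
  256×256 slice) with tissue-like brightness, which classification
  labels as tissue and region growing must remove;
- damaged slices with tissue luminance scaled by 0.02 (below the
  background threshold after rounding) but positive clusters retained
  at full red brightness;
- analytic landmarks (default 8) on the mid-stack organ boundary,
  emitted in both the canonical and each misaligned frame — landmarks
  are placed by a human in real workflows, so they are inputs here, not
  detections.

The default stack is 256 × 256 × 24: large enough that boundary effects
are second-order, small enough that the full pipeline runs in seconds.
What the generator deliberately does **not** model: stitching artifacts,
uneven illumination, anatomical texture, partial-volume effects at
section boundaries, or non-rigid tissue deformation. Passing tests
therefore demonstrate the correctness of the pipeline's operations and
their composition, not robustness to every artifact of real histology;
on real data the per-slice threshold overrides and the damaged-slice
list are the knobs that absorb what the generator idealizes away.

## Numerical choices and degenerate inputs

- The rigid fit requires ≥ 2 landmark pairs with ≥ 2 distinct moving
  points; all-coincident points are a degenerate-input error. For
  perfectly collinear configurations where the reflection/rotation
  decision is ambiguous, the +1-determinant branch is taken.
- Luma and resampled intensities round half-up; all 8-bit values clip to
  [0, 255].
- Registration recovery on noise-free landmarks is exact to well below
  1e-6 rad / 1e-6 px (validated over 50 random slices); with noisy
  landmarks the closed form is never worse than a θ-grid oracle at step
  1e-3 rad.
- Determinism: the generator draws all randomness from its own seed in a
  fixed order and restores the caller's RNG state; the pipeline itself
  uses no randomness, so fixed inputs give byte-identical VTK output.
- Validation problem sizes: 50 slices for registration recovery, 100
  random 20×20×10 volumes for the region-growing oracle, 256×256×24 for
  the end-to-end run — sizes at which each check's statistics are stable
  while the whole suite stays fast.

## Known limitations

- Rigid-only registration cannot correct section stretching or folding;
  an affine or elastic model is out of scope by design.
- Damaged-slice repair copies labels, so a damaged slice at a z-position
  of rapid anatomical change inherits its donor's geometry.
- The legacy VTK reader accepts only the writer's own dialect; it is a
  round-trip oracle, not a general VTK parser.
- Thresholds are global by default; real stacks may need the per-slice
  overrides.
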