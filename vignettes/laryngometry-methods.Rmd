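---
title: "Methods: laser-calibrated quantitative laryngoscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: laser-calibrated quantitative laryngoscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Endoscopic images of the larynx and oropharynx have no intrinsic metric
scale: the same anatomy imaged a few millimetres closer looks larger, so
absolute lengths and areas cannot be read off the pixels. The device this
package models solves that with projected laser fiducials. For laryngeal
stills, a pair of parallel 515 nm beams spaced 1 mm apart appears as two
green dots; their pixel distance fixes the mm-per-pixel conversion. For
oropharyngeal stills, three laser lines are projected — two parallel (again
at the known spacing) and a third tilted by 8.5 degrees. Because a tilted
beam sweeps laterally as it travels, the lateral offset between the tilted
line's course on two surfaces separated by depth `d` along the viewing axis
is `d * tan(theta)`, which turns a lateral pixel measurement into a depth.

On top of the calibration the package quantifies post-intubation mucosal
change in two complementary ways: *appearance* (region colour and texture,
summarized by a weighted function index and assessed by ROC analysis) and
*geometry* (the calibrated morphometric parameters: per-side vocal fold
length, midpoint width and area, vocal fold angle, glottic area, the
oropharyngeal inlet cross-section (CSAOI), and retropalatal depth, with
pre/post percent change).

## Triangulation model and its assumptions

The tangent relation `depth = (far_offset - near_offset) / tan(theta)` is
the normative model here. Whether the clinical rig tilts its third line in
the image plane or toward the optical axis is not something this package
can observe; we assume the lateral-offset-proportional-to-depth form and
state it as an assumption. Offsets are measured perpendicular to the
reference-line direction and converted to millimetres *before* the tangent
relation, using the scale derived from the parallel line pair on the near
surface. The dot-pair separation is likewise treated as depth-independent
over the working range — a stated approximation of the physical rig, where
beam parallelism makes the projected spacing nearly constant.

Fiducial detection is deliberately simple and robust rather than clever:
the laser-dominant channel (`G - max(R, B)`) is clamped at zero, passed
through an exact 3x3 median filter (a 19-exchange sorting network, fully
vectorized), thresholded at `max(0.15, 0.3 * max)`, and labelled into
connected components with `EBImage::bwlabel()`. Dots are located by
intensity-weighted centroids (sub-pixel); lines by weighted
total-least-squares fits to component pixels. A frame with fewer than two
blobs (or a line count other than three) raises a detection error — the
operational form of the clinical rule of excluding frames with blur or
glare.

## Colour and texture features

Colour is reported as per-channel mean intensities plus CIELab. "Hue"
throughout the package means the per-channel (R, G, B) mean intensity of a
region, not the HSV hue angle — the channel-wise reading is the one that
matches per-channel texture analysis. The sRGB-to-Lab conversion is the
standard two-stage map (gamma expansion, D65 matrix to XYZ, cube-root
compression); the white point is taken as the row sums of the conversion
matrix so that pure white maps to exactly (100, 0, 0) and every gray falls
exactly on the L* axis. A region's Lab is computed from its mean RGB by
default (stable for small regions); per-pixel Lab averaging is available
via `per_pixel_lab = TRUE`.

Texture uses gray-level co-occurrence matrices. The published method names
the four features (energy, contrast, correlation, homogeneity) but no GLCM
parameters, so the package fixes documented defaults in `glcm_params()`:
8 levels, equal-width quantization over the fixed intensity range [0, 1],
the four unit-distance offsets (0,1), (1,0), (1,1), (1,-1), symmetric
counting, features averaged over offsets. Quantizing over the fixed [0, 1]
range (rather than each region's own min-max) matters: it lets texture
amplitude differences between regions and subjects express themselves in
contrast, which is the behaviour the inflammation analysis relies on.
Co-occurrence is computed per colour channel; whether the clinical analysis
used gray-scale or per-channel matrices is ambiguous, and per-channel is
the reading consistent with reporting features "under different hue
conditions". Degenerate correlation (zero marginal variance, e.g. a
perfectly uniform region) is defined as 1: a perfectly homogeneous region
is perfectly predictable. Polygon membership uses the even-odd rule on
pixel centres with a half-open convention, so adjacent regions never
double-count pixels; only pixel pairs falling entirely inside the region
mask contribute to its GLCM.

## The function index

The inflammation score is the published weighted quadratic

    index = 0.35 * color^2 + 0.34 * contrast^2 + 0.32 * correlation^2

applied to cohort-normalized features. Three choices the formula leaves
open are resolved as follows, all configurable:

* the bare "CIELab" term is the region's a* coordinate (red-green axis),
  because the discriminating signal is the trend toward red; a
  delta-E-from-cohort-mean alternative can be substituted by passing
  `color_feature`;
* contrast and correlation come from the R channel, the most
  discriminative one in the clinical comparison;
* features are min-max normalized across the analysis cohort, making the
  three terms commensurate before squaring. A constant feature normalizes
  to all zeros. Cohort normalization means a score is only meaningful
  relative to its cohort; the package does not ship fixed clinical
  reference ranges because none are published.

Energy and homogeneity are computed and reported but excluded from the
index, matching the printed formula. The weights' provenance (learned or
chosen) is unknown; they are configuration with the printed defaults.

## Morphometry constructions

The published parameter names do not define constructions, so the package
fixes them: fold *length* is the caliper extent along the polygon's
principal axis (eigenvector of the vertex scatter); *width* is the
perpendicular extent of the polygon's cross-section at 50% of that length;
*area* is the vertex-exact shoelace area; the glottic area is the area of
the annotated glottal-gap polygon (folds excluded); vocal *area* is per
fold, not combined. The vocal angle is the interior angle at the anterior
commissure between rays to the two vocal processes. CSAOI is the annotated
inlet polygon's area using the oropharyngeal scene's own line-derived
scale. Repeated evaluations are aggregated by field-wise maximum
(`aggregate_max()`), mirroring the clinical protocol of taking the maximum
of at least three readings; maxima of different fields may come from
different evaluations. Percent change follows the pre = 100% convention
(`100 * post / pre`), with the signed change (`signed = TRUE`) alongside.

## What the phantom emulates — and what it does not

Clinical images behind the published analysis are not deposited, so every
stage is validated on synthetic phantoms with exact ground truth. A
laryngeal phantom renders: a flesh-toned mucosa with smooth stochastic
texture; a dark glottal gap flanked by two rectangular folds meeting at a
configurable angle; an interarytenoid band; and two Gaussian laser dots
(sigma = 2 px, pure green) at the pixel spacing implied by the true scale.
The inflammation parameter (0-1) acts on three channels at once: it shifts
the base colour toward red (+0.16 on R at full severity), scales a
fine-grain noise field (roughness, driving GLCM contrast), and scales a
coarse blotch field (smoothed at sigma = 8 px, driving spatial coherence
and hence GLCM correlation upward). The vocal folds receive 35% of the
interarytenoid effect, reproducing the clinical ordering in which the
interarytenoid region — where the endotracheal tube rests — discriminates
best. Between-subject variability is modelled by a random base-colour
offset (sd 0.02 on R) and a log-normal texture-amplitude multiplier
(sd 0.15); these defaults were chosen once as plausible biological
variability and give feature-level effect sizes large enough to separate
classes without being trivial. The published study never characterizes
normal-vs-inflamed colour/texture distributions numerically, so these
effect sizes are free design parameters of the phantom, not calibrated to
the clinical tables — which is also why the clinical AUC/accuracy values
are context, not test fixtures.

The phantom deliberately omits: lens distortion, specular highlights,
motion blur, perspective foreshortening, vascular markings, and any
photorealism. Passing phantom tests therefore demonstrates correctness of
the measurement chain (calibration, features, geometry, scoring, ROC), not
robustness to clinical image artefacts.

Oropharyngeal phantoms render two surfaces (near above, far below, the far
one darker), the three-line pattern with the tilted line anchored at the
surface boundary, the lateral jump `depth * tan(theta)` on the far course,
and a hexagonal inlet of known area on the far surface.

## Numerical choices and degenerate inputs

* Determinism: every generator consumes an explicit integer seed; identical
  configuration and seed reproduce scenes bit-identically. Cohort scene
  seeds are drawn once from the master seed.
* ROC ties are handled by simultaneous steps over unique thresholds, which
  makes the trapezoidal AUC equal the Mann-Whitney statistic with half
  credit for ties; the Youden tie-break prefers higher specificity, with a
  1e-12 tolerance on J comparisons to absorb floating-point noise.
* Score orientation is reported as-is (an AUC below 0.5 is not silently
  flipped).
* Constant scores yield the degenerate one-point ROC with J = 0; constant
  features normalize to zero; a zero-variance GLCM marginal yields
  correlation 1.
* Polygons must be simple; self-intersection is checked pairwise over
  non-adjacent edges. Degenerate (zero-extent) fold polygons, coincident
  calibration dots, and coincident angle landmarks raise geometry errors.
* Coarse phantom noise fields are generated at quarter resolution and
  bilinearly upsampled — an implementation detail that preserves the
  correlation structure while keeping generation fast.

## Validation problem sizes

The shipped test suite exercises: 50 randomized laryngeal phantoms with
true scales in [0.02, 0.1] mm/px for calibration recovery (tolerance 1%);
50 oropharyngeal phantoms with depths in [2, 30] mm for depth recovery
(tolerance 5%); 200 random images up to 16x16 at up to 8 gray levels for
exact (1e-12) GLCM/feature agreement with a brute-force pair-enumeration
oracle; 100 tied random instances for exact trapezoid-vs-Mann-Whitney AUC
agreement; 50 randomized fold geometries for morphometry recovery (median
relative error under 5% per metric); and a 20 + 20 pre/post phantom cohort
for end-to-end discrimination (function-index AUC above 0.9, interarytenoid
features outperforming fold features), plus 20 replicate null cohorts with
zero class separation. For the null check the package assesses the *mean*
AUC across replicates against the chance band [0.3, 0.7]: a single 20 + 20
split has a null AUC standard deviation of about 0.09, so individual
replicates stray outside that band by chance alone, while the mean of 20
replicates (sd about 0.02) is a stable statistic. Default phantom rasters
are 480 x 360 px at 0.05 mm/px, a 24 x 18 mm field of view.

## Known limitations

* Annotations (region polygons, landmarks, the near/far surface split) are
  inputs; the package does not segment anatomy automatically.
* The geometry of the tilted-line rig is modelled, not calibrated from
  data; a real device would need a one-time geometric validation against a
  physical step target.
* Cohort min-max normalization makes index scores cohort-relative;
  comparing scores across cohorts requires a shared normalization.
* Confidence intervals on AUC and cross-validated cutoffs are out of
  scope, as are video handling and multi-frame tracking.
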