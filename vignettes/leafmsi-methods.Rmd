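---
title: "Methods: spatial-spectral analysis of backlit multispectral leaf images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial-spectral analysis of backlit multispectral leaf images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Leaf nitrogen status in corn is commonly assessed with a SPAD chlorophyll
meter, which samples a few square millimetres per reading. Snapshot
multispectral transmittance imaging replaces that point measurement with a
full-leaf raster: a single leaf is flattened by a grid of thin nylon guard
threads, lit from below by four LED banks (blue 460 nm, green 525 nm, red
630 nm, NIR 850 nm), and photographed by a 1920 x 1200 monochrome camera,
one frame per band. Chlorophyll absorbs strongly in red and hardly at all
in NIR, so per-pixel band ratios track chlorophyll - and therefore nitrogen
supply - across the leaf surface, not just on average.

`leafmsi` implements the full processing chain from raw band stacks to a
cross-validated nitrogen-treatment classifier:

1. **Flat-field calibration**: each band is divided by a white-reference
   image of a uniform board under the same LED, removing illumination
   nonuniformity (`calibrate()`): `cal = raw / max(white, eps)`.
2. **Guard-thread reconstruction**: the occluding threads are detected
   with an oriented Gabor bank and filled by harmonic inpainting
   (`detect_threads()`, `inpaint()`).
3. **Leaf segmentation**: NDVI = (NIR - R)/(NIR + R) is ~0 on the bright
   transmittance background and clearly positive on leaf tissue; a
   threshold plus morphology isolates the leaf (`ndvi()`,
   `segment_leaf()`).
4. **Spatial-spectral features**: all six pairwise normalized-difference
   heatmaps `(Ia - Ib)/(Ia + Ib)`, a principal-axis zone grid, a vein mask
   from edge detection, and per-region moment and GLCM texture statistics
   (`index_heatmaps()`, `zone_leaf()`, `segment_veins()`,
   `extract_features()`).
5. **Classification**: a stratified 10-fold cross-validated random forest
   over the feature table, with a whole-leaf mean-NDVI baseline evaluated
   by pairwise Welch t-tests (`train_evaluate()`,
   `baseline_ndvi_test()`).

Because real field data of this kind are typically confidential, the
package ships a synthetic scene generator (`synth_config()`,
`generate_leaf_scene()`, `render_stack()`, `generate_dataset()`) that
produces backlit leaf images *with ground truth* - leaf, vein and thread
masks and the underlying chlorophyll field - so every stage is testable
quantitatively.

## The synthetic scene model

The generator emulates the transmittance imaging regime:

- **Geometry.** A lanceolate silhouette with a rounded base and pointed
  tip (half-width profile `u^0.35 (1-u)^0.75` along the axis), random
  length (72-88% of frame width), width (10-16% of frame height), tilt
  (within 4 degrees) and arch. A tapering midrib plus parallel secondary
  veins that follow the margin taper and converge at the tip.
- **Optics.** Beer-Lambert transmittance per band,
  `T_b = exp(-k_b * chl)`, with default absorbances ordered
  red (2.0) > blue (1.6) > green (0.8) >> NIR (0.05), matching chlorophyll
  optics qualitatively. The model is monotone in chlorophyll and gives
  closed-form oracles: calibration must return exactly `T_b`, and a
  unit-chlorophyll pixel has NDVI
  `(e^-0.05 - e^-2)/(e^-0.05 + e^-2)`.
- **Chlorophyll field.** Treatment mean scale x base-to-tip gradient
  (nitrogen-deficient leaves fade toward the tip) x a smooth low-frequency
  texture; reduced by a factor 0.5 on veins; zero off-leaf.
- **Illumination and sensor.** Per-band positive order-2 polynomial
  surfaces with a vignetting bowl, normalized to mean 1; a global exposure
  factor of 0.7 leaves sensor headroom so noise-free renders never clip
  (clipping would break the calibration identity); Gaussian noise with sd
  1% of full scale, clipped to `[0, 255]`.
- **Guard threads.** Five straight near-vertical lines of 2 px width
  spanning the frame, attenuating the signal by a factor 0.1. They are
  drawn as a non-crossing comb (evenly spaced, tilts within 6 degrees) so
  the ground-truth mask has exactly five separable line components;
  a crossing grid would merge them into one connected component and make
  per-thread accounting ambiguous.

Default treatment effects place the six nitrogen rates (0-120% of the
farmer's normal rate) on well-separated mean chlorophyll scales (0.30,
0.70, 0.90, 1.10, 1.35, 1.20; within-class log-sd 0.025), with the 120%
class dropping below 100% to mimic over-fertilization stress, and
base-to-tip gradient slopes falling with nitrogen supply. Three scenario
constructors modify this: `synth_config_overlap()` (only the 0% class is
separable in mean NDVI; the rest share a mean and differ only in
gradient), `synth_config_spatial_contrast()` (two classes with identical
mean chlorophyll whose gradients point in opposite directions - a
mean-NDVI classifier is at chance by construction while zone features
separate them), and `synth_config_mean_separable()` (two classes split
purely by mean).

What the generator does *not* emulate: realistic venation networks,
optical blur, 3-D leaf curvature (the device flattens leaves), specular
effects, or the within-treatment variance structure of real fields - the
effect sizes are design choices, not estimates. Passing tests therefore
demonstrate that the *computational chain* is correct and that the
spatial-feature thesis holds when spatial signal exists; they do not
predict field accuracy.

## Numerical and design choices

- **Raster convention.** Row-major matrices, origin top-left; all masks
  share the stack's shape. Bands are always carried in canonical order
  (blue, green, red, nir); on-disk order is declared, never inferred.
- **TIFF storage.** Integer stacks are stored as 8/16-bit pages and
  round-trip bit-exactly. Float stacks are stored on the 32-bit page
  type as `value/1024`; the storage grid is fixed-point, giving ~2.4e-7
  absolute precision, and values are pre-snapped to the grid so repeated
  round trips are byte-stable.
- **Thread detection** runs on the band-mean *log* transmittance:
  occlusion is multiplicative, so on a log scale a thread has the same
  contrast over dark leaf and bright background, which keeps recall
  uniform. The bank holds even-symmetric, DC-free Gabor kernels at
  orientations {75, 90, 105} degrees (matching the near-vertical guard
  comb; fully configurable), wavelength twice the expected thread width,
  envelope sd 0.45 x wavelength. The *signed* dark-line response is
  thresholded at `mean + 3 sd`; using the magnitude instead would turn the
  cosine sidelobes into detections and widen the mask. The flagged set is
  dilated by 2 px, and components are kept only if they are large
  (>= 50 px), elongated (major/minor spread >= 5) and straight
  (perpendicular sd <= 4 px) - the straightness test is what rejects
  curved leaf margins.
- **Inpainting** solves the discrete Laplace equation on the masked
  pixels with Dirichlet data from the unmasked ring, via an exact sparse
  Cholesky factorization (one factorization, one solve per band). An
  iterative Jacobi/Gauss-Seidel sweep would approximate the same
  operator; the direct solve is deterministic and leaves no
  iteration-tolerance artifacts. At the frame border missing stencil
  neighbours are dropped. A masked component with no unmasked neighbour
  at all is an error. The solution obeys the discrete maximum principle
  per component and reproduces affine fields exactly in the interior.
- **Segmentation** replaces a hosted segmentation model with an NDVI
  threshold (default 0.1, configurable) + closing (radius 3) + hole
  filling + largest component (>= 500 px): on transmittance images the
  NDVI plane already carries the leaf/background separation, and the
  contract (single component, area, centroid, axis) is segmenter-
  agnostic, so an external segmenter can be plugged in.
- **Zoning** uses the mask's principal-axis frame with *equal-count*
  rank binning (default 4 longitudinal x 2 lateral), which is
  deterministic, shape-adaptive and rotation-equivariant; the axis sign
  is fixed by the third moment of the longitudinal coordinate (the
  pointed tip is the long tail), so "base to tip" is well defined.
- **Vein segmentation** works on the smoothed green band (strongest
  structural contrast in transmittance), hysteresis-thresholds the
  gradient magnitude at mean + {1, 2} sd of the in-leaf distribution,
  closes with radius 2 to bridge the two gradient flanks across each vein
  centerline, erodes a 3 px margin so the leaf outline is not detected,
  and keeps elongated components only.
- **Statistics.** Population moments (denominator n); skewness
  `m3/m2^1.5`; *excess* kurtosis `m4/m2^2 - 3`; constant regions report
  `NA`. GLCM: 16 equal-width levels over the region's range (making the
  features affine-invariant), offsets {(0,1),(1,0),(1,1),(1,-1)},
  symmetric, normalized, features averaged over offsets. Empty or
  degenerate regions yield explicit `NA`s; the classifier imputes with
  the training fold's median.
- **Classification.** Stratified k-fold CV (default 10), random forest
  with 500 trees, `sqrt(p)` features per split, unlimited depth; the seed
  drives both the fold assignment and the forests, so reports are
  reproducible. The baseline uses Welch's unequal-variance t-test on
  whole-leaf mean NDVI with raw pairwise p-values (a Holm-adjusted matrix
  is attached for reference).

## Problem sizes used in the checks

Reconstruction, calibration and segmentation checks run at the generator's
default camera-frame size (1200 x 1920, 2 px threads): the false-positive
budget for thread detection is only meaningful when threads are as thin
relative to the frame as the real guard. Aggregates use 12 scenes in the
test suite and 6 in the acceptance script. The cross-validation studies
(6-class recovery with n = 120, the spatial-gain contrast with 2 x 20, and
the overlap baseline with 6 x 10) run at a reduced 300 x 480 frame with
1 px threads - a simulation-size choice that leaves effect sizes, noise
level and the feature pipeline unchanged.

## Known limitations

- The default NDVI threshold (0.1) assumes a transmittance background,
  where background NDVI is ~0 with a few-percent noise sd while even a
  nitrogen-starved leaf tip stays above ~0.15; it is a starting point for
  reflectance-style data, not a calibrated value.
- Thread detection assumes thin, straight, dark occlusions with
  near-known orientations; strongly curved or bright occluders need a
  different bank and polarity.
- Harmonic inpainting smooths texture across wide masked gaps; for the
  2-3 px guard threads this bias is far below the sensor noise, but the
  method is not intended for large occlusions.
- GLCM features are computed per region at a fixed 16-level quantization;
  very small regions (a few dozen pixels) quantize coarsely and their
  texture features are noisy - they are reported, not suppressed.
- The synthetic generator's treatment effect sizes are configuration, not
  field estimates; classifier accuracies on synthetic data say nothing
  quantitative about field performance.
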