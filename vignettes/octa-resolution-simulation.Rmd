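---
title: "Simulating and quantifying OCTA angiograms across lateral resolutions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and quantifying OCTA angiograms across lateral resolutions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the package addresses

OCT angiography (OCTA) detects retinal blood flow as motion contrast and
projects it into en-face angiograms. The standard quantitative metrics —
perfusion density (PD, the fraction of area with detected flow), vessel
density (VD, skeletonized vessel length per unit area, in 1/mm) and foveal
avascular zone (FAZ) morphometry — all depend on how well individual
capillaries are resolved. A beam-expander telescope that magnifies the beam
at the pupil (2.2x, from 0.86 mm to about 1.9 mm) shrinks the retinal spot
from roughly 25 to 14 um, and a denser scan pattern (300 samples over
2.25 mm instead of 3 mm, i.e. 7.5 instead of 10 um pitch) raises sampling
resolution, at the cost of a quadratically shorter Rayleigh range (depth of
focus). `octaquant` provides a forward model of this acquisition chain, the
standard quantification chain, and the paired statistics, so that the
effect of lateral resolution on OCTA metrics can be studied with known
ground truth.

Everything downstream is testable because the input vasculature is
synthetic and its geometry exactly known: recovered VD can be compared to
true centerline length, the detected FAZ to the true polygon, and the
paired cohort statistics to the direction the resolution mechanism
predicts.

## The synthetic vascular network

`generate_network()` builds a parafoveal capillary bed in continuous mm
coordinates (origin at the fovea center, x rightward, y downward):

* **FAZ**: an irregular star-shaped polygon (low-order harmonic
  perturbations of a circle), scaled so its shoelace area equals the
  target exactly; the default target of 0.18 mm^2 is a typical healthy-eye
  value. Per-eye jitter in the cohort harness (SD 0.05 mm^2) emulates the
  wide between-subject spread of FAZ size.
* **Capillary mesh**: Poisson-disc (Bridson) samples outside the FAZ with
  minimum spacing derived from the point density, joined by their Delaunay
  triangulation, with edges longer than 2.4x the disc radius or crossing
  the FAZ removed and the remainder pruned so each node keeps at most its
  three shortest edges. Poisson-disc plus Delaunay was chosen over
  growth-model alternatives because only the statistical structure of the
  mesh (spacing, degree, FAZ ring, capillary-free zones, vortices) matters
  to the downstream metrics, and it is fast and controllable. The default
  density of 380 points/mm^2 yields a true centerline length density of
  about 31 mm^-1 in the 1-2 mm annulus, in the range reported for the
  healthy parafovea.
* **Arterioles and venules**: alternating jittered radial polylines from
  the field edge to the FAZ ring. Capillaries within 50 um of an arteriole
  centerline are removed — the periarteriolar capillary-free zone that
  lets readers tell arteries from veins; venules carry no free zone. The
  50 um half-width is plausible but not validated against morphometry.
* **Vortices** (deep capillary complex only): node coordinates within
  0.3 mm of each vortex center are swirled (rotation decaying linearly
  with distance), which orients nearby capillary edges tangentially while
  keeping the graph valid. This realizes the "re-orient tangentially"
  idea as a coordinate warp rather than per-edge surgery, so no dangling
  edges are created.
* Stray components are bridged to the main one so the graph outside the
  FAZ is connected.

`network_ground_truth()` is the oracle: centerline length clipped to a
region (1 um arc-length subdivision), perfused area as the union of vessel
capsules on a 1 um raster, and FAZ area/perimeter from the polygon.

## Image formation

The forward model is deliberately minimal: rasterize the network as binary
capsules on a 2 um working raster, convolve with a normalized Gaussian
point-spread function whose 1/e^2 intensity diameter is the configured
retinal spot size (sigma = diameter/4; mirror-reflected borders so the
periphery is not artificially darkened), and area-average onto the
acquisition grid (box integration emulating detector integration; the box
edges may be fractional, handled exactly through an integral image). Noise
follows OCT envelope statistics: multiplicative speckle on the signal
(coefficient of variation 0.25 by default) plus an additive Rayleigh
background floor (scale 0.05 against a vessel signal of order 0.3-1).
Optional motion artifacts shift individual rows, and defocus widens the
PSF. The defaults were set so that rendered scans have realistic
vessel-to-background contrast and pass the signal-strength quality gate;
they are not calibrated to any instrument's measured noise figures.

What this model does *not* include: interferogram/OMAG-level flow
statistics, projection artifacts between slabs, eye-tracking residuals,
axial structure, or vessel-size-dependent flow contrast. Passing tests
therefore demonstrate correct behaviour of the quantification chain under
a controlled, resolution-limited acquisition — not clinical equivalence.

## The quantification chain

1. **Frangi vesselness**: multi-scale Hessian tubularity with
   scale-normalized Gaussian derivatives, scales {1, 1.5, 2, 3} px,
   blobness weight beta = 0.5, and the structureness weight set per scale
   to half the maximum Hessian Frobenius norm ("auto"). The auto choice
   makes the map invariant to positive rescaling of the image, which in
   turn makes PD and VD invariant to intensity scaling.
2. **Noise floor**: mean raw intensity over the structure-free set — the
   lowest quartile of the *smoothed* vesselness map. Regional (smoothed)
   selection is deliberate: picking individual low-vesselness pixels
   preferentially selects locally dark pixels and biases the level well
   below the true background mean, whereas regions chosen for having no
   structure keep their interior intensities unbiased (a small residual
   bias, about 10% on pure noise, remains because the quietest regions of
   random noise are slightly darker; it is absorbed by the threshold
   multiplier). Estimating noise from the en-face image rather than the
   volume is a necessary deviation from volume-based instrument pipelines,
   since the forward model produces no volume.
3. **Binarization**: threshold the vesselness-weighted intensity at
   `k x noise level`, drop 8-connected components below 10 px, fill
   4-connected holes below 10 px. The default `k = 0.2` was calibrated
   once against ground truth: because the structureness term compresses
   the enhanced image well below the raw-intensity scale on which the
   noise floor is measured, multipliers near 1 under-detect capillaries
   severely; `k = 0.2` recovers the true centerline length within 15% at
   beam-expander resolution and is exposed in the configuration.
4. **Skeletonization**: Guo-Hall thinning (topology preserving; the
   component count is asserted on every run) followed by a conservative
   cleanup that removes simple pixels from any residual 2x2 block. Like
   all erosion-based thinning, free line ends erode by about half the
   vessel width; the VD link-length measure (pitch per orthogonal link,
   pitch*sqrt(2) per diagonal link) is oracle-tested against analytic
   polyline lengths within 2%.
5. **Densities** on the 1-2 mm fovea-centered annulus: PD as a fraction in
   [0, 1] (reported figures near 0.4 are fractions, not percent), VD in
   1/mm.
6. **FAZ**: morphological closing with a 40 um disk (physical units, so
   both pitches use the same scale; 40 um ~ one intercapillary distance,
   chosen so gaps left by missed capillaries do not leak the flood fill),
   flood fill of the background component containing the fovea center,
   failure if that component reaches the image border. Perimeter uses the
   4-direction Crofton estimate — boundary-pixel counting would inflate
   perimeters of smooth shapes by up to 8/pi and bias circularity low —
   and circularity is 4*pi*area/perimeter^2.

## Registration and averaging

Repeats are registered by whitened phase correlation with local upsampled
DFT refinement (0.1 px), a translation-only model matching per-A-scan
transformation vectors; a correlation peak below 0.2 raises a registration
failure. Aligned scans are resampled bilinearly and averaged, which
reduces background noise close to the theoretical 1/sqrt(n). Standard
scans can be cropped to the beam-expander footprint for side-by-side
comparison.

## Statistics

Paired comparisons use the Wilcoxon signed-rank test: zero differences are
dropped, ties receive average ranks, p-values come from exact enumeration
of all sign assignments for n <= 12 and from a tie-corrected,
continuity-corrected normal approximation otherwise (the two branches
agree within 0.01 at the cutover). Repeatability uses ICC(A,1) — two-way
model, absolute agreement, single measure — with McGraw-Wong F-based 95%
confidence bounds. Scans fail the quality gate when signal strength is
below 7 or artifacts affect more than 10% of the image; both boundaries
pass inclusively. No multiplicity correction is applied; p-values are
reported raw.

The cohort harness renders each synthetic eye under both configurations
(three repeats each, independent noise), uses the first usable repeat for
the paired comparison (falling back to the second when gating or FAZ
segmentation fails), and computes ICC across repeats per arm.

## What the synthetic study reproduces

With 22 synthetic eyes the harness reproduces the direction of the
resolution effects: mean VD is substantially higher at beam-expander
resolution (coarser optics merge and miss thin capillaries, fragmenting
the skeleton), FAZ circularity is not higher (finer capillary detection
roughens the detected boundary), and FAZ area is by far the most
repeatable metric (ICC near 1, versus markedly lower for VD and PD).
Magnitudes are not claimed: human eyes differ from the generator in
anatomy, contrast, and artifact structure.

## Numerical choices and degenerate inputs

* Working raster 2 um (oversamples the finest 14 um PSF); ground-truth
  raster 1 um; cohort problem size 22 eyes x 2 configurations x 3 repeats
  at 300x300 px, chosen as the smallest sizes at which all the effects of
  interest are stable.
* All randomness flows from one master seed through a deterministic
  Lehmer-style derivation; no function leaves a footprint in the global
  RNG state.
* Constant images give an all-zero vesselness map (not an error);
  all-foreground and all-background perfusion masks warn but return;
  a FAZ whose background reaches the border raises a segmentation error,
  mirroring automatic-segmentation failures on real scans.
* 8-connectivity for foreground components, 4-connectivity for holes
  (standard duality); pixel centers at half-integer physical offsets;
  annulus membership is inner-inclusive, outer-exclusive.

## Known limitations

* The noise model is an en-face emulation, not an interferometric one;
  absolute PD/VD values are only loosely comparable to those of real instruments.
* Erosion-based thinning shortens free vessel ends by about half the
  local width, biasing VD slightly low everywhere (it cancels in paired
  comparisons).
* The detected vessel width is optics-limited, so overlap measures (Dice)
  against the anatomical (thin) truth are geometrically bounded near 0.55;
  overlap is therefore also assessed against the truth rendered at the
  resolution-matched apparent width (radii widened in quadrature with the
  PSF 1/e^2 radius, half the spot diameter — the apparent radius of a thin
  blurred vessel).
* Vortex and capillary-free-zone parameters are plausible-looking, not
  validated against histology.
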