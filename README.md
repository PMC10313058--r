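# octaquant

Simulation and quantification of OCT angiography (OCTA) en-face images,
built to study how **lateral optical resolution and sampling density** shape
the standard OCTA metrics. It is aimed at imaging scientists and ophthalmic
reading centers who need ground-truth-validated implementations of the
common quantification chain, and at anyone comparing acquisition modes —
e.g. a standard configuration (~25 µm retinal spot, 3 mm field sampled at
10 µm) against a beam-expander configuration (2.2× pupil-beam
magnification, ~14 µm spot, 2.25 mm field at 7.5 µm).

## What it computes

For an en-face angiogram the package implements the standard chain:

1. **Frangi vesselness** `V(x)`: multi-scale Hessian tubularity; per scale
   σ the eigenvalues |λ₁| ≤ |λ₂| of the σ²-normalized Hessian give
   `V = exp(−R_B²/2β²)·(1 − exp(−S²/2c²))` with blobness `R_B = λ₁/λ₂` and
   structureness `S = √(λ₁²+λ₂²)`, zero where λ₂ > 0 (bright vessels).
2. **Noise-based binarization**: threshold `k · noise`, the noise floor
   measured in structure-free areas (lowest vesselness quartile), then
   small-object removal and hole filling → perfusion mask.
3. **Skeletonization** (topology-preserving Guo–Hall thinning) → 1-px
   centerlines.
4. **Metrics** on the 1–2 mm fovea-centered annulus:
   * perfusion density `PD = detected-flow area / region area` (fraction),
   * vessel density `VD = centerline length / region area` (mm⁻¹),
   * FAZ area, Crofton perimeter and circularity `4π·area/perimeter²`.

Around that core: a synthetic parafoveal vasculature generator with known
ground truth (Poisson-disc + Delaunay capillary mesh, FAZ polygon,
arterioles/venules with capillary-free zones, optional vortices), a
physical image-formation model (Gaussian PSF, area-average grid sampling,
speckle + Rayleigh background noise, repeats, motion artifacts),
phase-correlation registration/averaging, quality gating (signal strength
< 7 or > 10 % artifacts fails), exact Wilcoxon signed-rank tests and
ICC(A,1) repeatability, and a paired-cohort study harness.

## Worked example

```r
library(octaquant)

net  <- generate_network(vasculature_spec(), seed = 42)
cfgs <- default_optical_configs()

scan <- render_scan(net, cfgs$beam_expander, noise_spec(), seed = 7)
q    <- quantify_scan(scan)

gt      <- network_ground_truth(net, annulus_region(1, 2))
true_vd <- gt$true_vessel_length / (pi * (1^2 - 0.5^2))

round(c(vd = q$vd, true_vd = true_vd,
        pd = q$pd, faz_area = q$faz_area, faz_circ = q$faz_circularity), 3)
#>       vd  true_vd       pd faz_area faz_circ
#>   26.833   30.917    0.437    0.194    0.897
```

The detected vessel density (26.8 mm⁻¹) recovers the true centerline
length density (30.9 mm⁻¹) to within 15 % — the shortfall is real physics:
the finite spot merges the closest capillaries and thinning erodes free
vessel ends. The FAZ area (0.194 mm²) tracks the generated polygon
(0.180 mm²), slightly wide because sub-threshold capillaries at the rim
enlarge the avascular region. Rendering the *same* eye under the standard
configuration instead yields VD ≈ 23 mm⁻¹: coarser optics fragment thin
capillaries, which is precisely the resolution effect the paired cohort
harness (`run_cohort()`) quantifies with Wilcoxon and ICC statistics.

A thin command-line wrapper over these functions is installed at
`inst/cli/octaquant.R` (subcommands `optics`, `simulate-network`,
`simulate-scan`, `quantify`, `faz`, `average`, `study`).

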