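---
title: "Longitudinal tibia microCT analysis: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal tibia microCT analysis: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tibiamct)
```

## Scope

tibiamct implements the full analysis chain used in paired-limb in vivo
microCT studies of the mouse tibia, where the right limb is repeatedly
scanned (and therefore irradiated) and the left limb serves as the
within-animal control. The chain covers:

1. image preprocessing and segmentation,
2. trabecular and cortical morphometry,
3. densitometric calibration and 40-partition spatial mapping of bone
   mineral content,
4. voxel-based micro-finite-element estimates of apparent stiffness and
   criterion-based strength, and
5. the mixed-effects statistical contract used to estimate the paired
   Radiation&Side effect.

A synthetic phantom generator with analytic ground truth supports validation
and end-to-end simulation without animal data.

## Preprocessing and segmentation

Images are smoothed with a 3x3x3 Gaussian kernel (sigma = 0.65 voxels,
discretely sampled and renormalised to unit sum, replicate padding at the
borders). The global threshold is chosen automatically from the grey-value
histogram: 256 equal-width bins, smoothed by a centred 5-bin moving average
(window shrinking symmetrically at the edges), the two most prominent peaks
located (plateau-aware prominence, boundary bins eligible), and the
threshold set to the midpoint of the two peak centres. Voxels with values
greater than or equal to the threshold are bone: the boundary rule is
inclusive. Components smaller than 10 voxels under 26-connectivity are
removed ("smaller than" is strict: a 10-voxel speck survives).

Tibia length is the occupied slice extent, `(z_last - z_first + 1)` times
the slice spacing: a single occupied slice has length one voxel, not zero.

`align_principal_axis()` rotates the bone's principal inertia axis onto the
image z axis (trilinear resampling by default). The proximal direction is
chosen automatically from the sign of the third moment of the voxel
distribution along the axis: the mass-heavy (proximal, trabecular-rich) end
is placed at low z. Mirroring for right limbs is composed into the same
affine so the image is resampled once.

## Trabecular morphometry

The trabecular VOI starts 0.2 mm distal to the reference slice (the
growth-plate bridging slice, supplied per scan) and spans 1 mm. The
cortical shell is removed per slice by an automatic endosteal contour: the
2D component whose filled hull gains the most area is taken as the shell,
its hull is eroded past the estimated shell thickness, and only bone inside
the eroded interior is kept.

Local thickness uses the model-independent maximal-sphere definition: the
thickness at a voxel is the diameter of the largest sphere fully contained
in the phase that covers the voxel. It is computed from the exact Euclidean
distance transform with distance-ridge sphere propagation. In voxel units
the painted diameter is `2 * dt - 1`, which makes an 11-slice digital plate
measure exactly 11 voxels; an exhaustive-sphere oracle in the test suite
verifies bit-for-bit equality of the fast implementation on random masks.
Tb.Th is the volume-weighted mean of this map over the bone phase, Tb.Sp the
same over the background phase within the VOI region.

Tb.N uses the ratio convention `Tb.N = (BV/TV) / Tb.Th`, consistent with
plate-model reporting in longitudinal in vivo studies; no
direct-counting (mid-axis) alternative is attempted.

## Cortical morphometry

The cortical VOI spans 1 mm centred at the midshaft, defined as 50% of the
computed tibia length. Intracortical pores are closed per slice with a
morphological closing by a disk of radius 10 pixels. Tt.Ar is the mean
filled periosteal area, Ct.Ar the mean closed bone area, and Ct.Th the mean
3D maximal-sphere thickness of the closed cortical phase — a 3D measure
rather than a per-slice 2D one, so oblique walls are not overestimated. An
open (non-annular) section is detected (thin arc relative to its lateral
extent) and flagged with a warning rather than silently filled.

## Densitometry

Calibration is linear, `TMD = intercept + slope * grey`, fitted by least
squares to known-density phantom inserts; calibrated values below zero are
clamped to zero. The densitometric VOI starts at the reference slice and
spans 80% of the tibia length. The fibula is excluded by per-slice
component tracking: the tibial region is seeded at the proximal slice and
propagated distally, keeping the 2D components that overlap the slightly
dilated filled hull of the previous slice's tibial region.

The VOI is divided into 40 partitions: 10 equal longitudinal sections
(remainder slices assigned to the most distal section) crossed with 4
quadrants delimited by vertical planes at +-45 degrees through each
section's bone centroid. Quadrant labels default to lateral, anterior,
medial, posterior for the +x, +y, -x, -y sectors; analysing right limbs
mirrored into the left frame keeps the labels anatomically consistent.
BMC is the sum of TMD over bone voxels times the voxel volume; BMD divides
by the full partition volume, so per partition `BMD = TMD * BV/TV / 100`
holds as an identity, and partition BMC sums exactly to whole-VOI BMC.
Paired left/right partition maps are reported as percent differences,
summarised across animals by median and SD.

## Micro-finite-element models

Each bone voxel becomes an 8-node hexahedral element with homogeneous
isotropic properties, E = 14.8 GPa and nu = 0.3. The element matrix is
integrated with 2x2x2 Gauss quadrature, which is exact for the trilinear
element (the test suite checks equality with a 3-point quadrature oracle to
1e-10). One element matrix is shared by all elements. The global system is
solved matrix-free with Jacobi-preconditioned conjugate gradients to a
relative residual of 1e-8; problem sizes up to a few hundred thousand DOF
solve in seconds to minutes on one CPU core.

Two load cases are provided:

* **Stiffness**: proximal surface nodes fully fixed; distal surface nodes
  prescribed a 1 mm compressive longitudinal displacement with transverse
  DOFs left free (free transverse DOFs keep the nu = 0 prism solution exact
  and avoid artificial end constraint). Apparent stiffness is the summed
  longitudinal proximal reaction divided by the applied displacement.
* **Strength**: proximal surface fixed; a 1 N compressive probe load applied
  on the distal surface as a uniform pressure via consistent nodal forces
  (each distal element face contributes a quarter of its share to each of
  its four nodes). A uniform pressure reproduces the uniform stress state of
  the analytic prism oracle to solver precision, which per-node-equal forces
  cannot (they create a Saint-Venant boundary layer at percent level).

Element centroid strains are averaged to the nodes, principal strains taken
from the closed-form symmetric eigendecomposition, and nodes within 10% of
the model length of either end excluded. A node fails when its third
principal strain passes -10300 microstrain (compression) or its first
principal strain passes +8000 microstrain (tension). Because the model is
linear, each node has a safety factor (the load scale at which it first
fails), and the criterion strength is the applied load times the k-th
smallest safety factor with `k = ceiling(0.02 * N)` — the load at which 2%
of considered nodes have failed. The test suite confirms this percentile
rule equals incremental load-scaling brute force to 1e-6.

## Statistical contract

Per parameter, measurements are modelled with a linear mixed-effects ANOVA:
fixed effects Strain, Intervention and Radiation&Side plus all two-way
interactions, and a random intercept per mouse (REML, sum-to-zero
contrasts). Term significance uses type-III F tests with Satterthwaite
degrees of freedom. Assumptions are checked with Shapiro-Wilk on the model
residuals and Levene's test across intervention groups and across strains;
when Levene triggers, splitting by the factor with the smaller p-value is
recommended. Non-significant two-way interactions are pruned iteratively
(largest p first, refitting each time); main effects are always retained.

The paired radiation effect is reported from estimated marginal means of
side averaged over the remaining factors: the R - L difference, its 95%
Satterthwaite confidence interval, and the difference as a percentage of
the estimated left-limb mean (CI scaled by the same left mean), alongside
the SD of the within-mouse paired differences. `percent_difference()`
reproduces published worked examples of this convention exactly after
rounding.

## Phantom generator

`generate_tibia_phantom()` builds a miniature tibia-like object (about
4.2 mm, 10.4 um voxels by default): a cortical shell whose periosteal
radius and wall thickness vary along the bone, and a proximal lattice of
longitudinal trabecular rods (diameter 52 um, jittered 130 um grid) with
analytic ground truth for rod count, rod diameter, total cross-sectional
area and calibration. The right limb of a pair shares the left geometry
mirrored across the sagittal plane, with a `radiation_effect()` applied
(rod count, rod thickness, periosteal area) and an independent noise
realisation; with zero effect and zero noise the right image is the exact
voxelwise mirror of the left. The image is deliberately smaller than a real
scan so that full studies run in minutes; the measured absolute values
(e.g. Tb.Th ~40 um after filtering) are tools for validating the chain, not
reproductions of animal data.

Default parameters:

| Quantity | Default | Units |
|---|---|---|
| Voxel spacing | 10.4 | um |
| Image size | 108 x 108 x 400 | voxels |
| Gaussian sigma | 0.65 | voxels |
| Despeckle minimum | 10 | voxels |
| Trabecular VOI offset / height | 0.2 / 1.0 | mm |
| Cortical VOI height | 1.0 | mm |
| Densitometric VOI fraction | 0.8 | of tibia length |
| Closing disk radius | 10 | pixels |
| E, nu | 14800, 0.3 | MPa, - |
| Strain limits (comp/tens) | -10300 / +8000 | microstrain |
| Failure node fraction | 0.02 | - |
| End exclusion | 0.10 | of length |
| CG tolerance | 1e-8 | relative |

## Reproducibility

Every stochastic step is seeded: phantom generation from `phantom_spec()`'s
seed, study runs from `run_config()`'s seed (per-mouse sub-seeds are drawn
once up front), and record simulations from their own seed argument.
`run_study()` writes CSVs with a provenance header carrying a configuration
hash and the seed.
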