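---
title: "Quantifying spatial physiology in colony biofilms: methods and design"
author: "colonyvox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spatial physiology in colony biofilms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The measurement problem

A bacterial colony growing on a filter membrane becomes, within a day, a
dome several hundred micrometres tall in which oxygen is consumed faster
than it diffuses in. The interior turns anoxic, metabolism stratifies, and
cells at different depths live in qualitatively different chemical worlds.
colonyvox quantifies that stratification from multi-channel 3D confocal
stacks using five coupled measurements:

* **biovolume** — total biomass from per-slice segmentation;
* **oxygen-proxy depth profiles** — fluorescence of a constitutive reporter
  whose chromophore requires oxygen to mature, versus distance to the
  air-facing surface, in three geometries (axial cylinder, basal plane,
  isotropic distance shells);
* **dead-cell mapping** — colocalization of a membrane-impermeant dead-cell
  stain with the stable reporter, restricted to the oxic shell;
* **ratiometric growth readout** — the ratio of a degradation-tagged
  (unstable) reporter to a stable one, whose fold-change between two heights
  reads out spatial growth-rate differences;
* **morphometry** — colony height-versus-radius profiles and the slope at a
  fixed height (the "bulge" metric distinguishing convex, cross-feeding
  supported domes from conical ones), plus strain ratios in a ring around a
  mixed inoculum for competition assays.

Every stage is validated by parameter recovery on synthetic colonies with
exact ground truth; no external data are required.

# Coordinate conventions

All lengths are micrometres. Voxel centers sit at `(i - 0.5) * dx`; the base
plane (filter surface) is the bottom face of slice 1, so a voxel in slice k
sits at height `(k - 0.5) * dz` and the top face of the topmost occupied
voxel defines the local colony height. Stacks are normalized at ingestion to
base-at-z-index-1 order; stacks recorded apex-first (colonies are typically
imaged facing down on an inverted microscope) are flipped by
`readStack(..., runConfig(zOrientation = "apex_at_0"))`. When a beads
channel is present (fluorescent beads settle on the filter),
`locateFocalPlane()` identifies the substrate slice as the z-slice of
maximal bead intensity.

# Segmentation and biovolume

The colony outline in each z-slice is detected on the image gradient:
Gaussian pre-smoothing (`smoothSigma`, default 1 px), central-difference
gradient magnitude, Otsu threshold on that magnitude (or a fixed override,
`gradientThreshold`), hole-filling of the supra-threshold edge band, and
retention of the largest connected component.

Two numerical choices matter here:

* **Half-maximum boundary refinement.** The supra-threshold gradient band
  straddles the true edge with a half-width of roughly
  `sigma * sqrt(2 ln 2)` pixels, so filling it dilates the region and would
  bias the area of a 20 µm disk by ~10%. Integer-radius erosion cannot fix
  this without ±0.5 px quantization. Instead the smoothed slice is
  re-thresholded at the gradient-weighted mean intensity of the edge band —
  for a smoothed step this equals the intensity at the true edge (its
  half-maximum) — which recovers a 10×10×5 µm cuboid at exactly 500 µm³ and
  a 50 µm hemisphere within 0.1% at 1 µm voxels.
* **Axial contiguity.** Slices whose segmented area falls below
  `minSliceArea` (default 20 µm²) are treated as empty, and only the
  contiguous run of occupied slices containing the largest-area slice is
  kept: a colony is one axially connected object, and isolated noise-only
  "slices" above the apex otherwise corrupt the height profile.

Biovolume follows the per-slice convex-area convention: the convex hull of
each slice mask (pixel centers in or on the hull polygon, times pixel area)
is the biomass measure for that plane, and the sum over slices times the
slice spacing is the biovolume. The hull makes the measure insensitive to
interior intensity loss — exactly the property needed when the anoxic
interior of the colony is dim.

# Distance to the air-facing surface

Oxygen arrives from the air, so the physiological depth coordinate is the
Euclidean distance to the *air-facing* surface: mask voxels with a
6-connected neighbor that is outside the mask or beyond the grid, except
below the base plane, which is substrate (filter), not air. The
`includeBase` switch restores distance-to-any-boundary for users who want
it; it is off by default because the reference measurements normalize to the
colony-air interface.

Distances are computed with a separable parabolic-envelope distance
transform over the *physical* per-axis voxel spacing (implemented in C++),
so anisotropic confocal stacks (e.g. 0.6 × 0.6 × 2 µm) are handled exactly.
The transform is exact: tests compare it voxel-for-voxel against a
brute-force minimum over surface voxels on random 32³ masks, including
anisotropic spacings, to 1e-9 µm.

# Fluorescence profiles and the decay length

Three profile geometries share one normalization philosophy — report
fold-changes relative to the colony surface, where oxygen is plentiful:

* `axialCylinderProfile()`: mean intensity per z-slice within a vertical
  cylinder of radius 3.3 µm on the colony axis, normalized to the mean over
  the topmost 2 µm of the cylinder. A 2 µm reference band (rather than a
  single voxel) is used for noise robustness.
* `basalPlaneProfile()`: intensity in the base slice versus the in-plane
  2D distance to the colony edge, normalized to the edge bin.
* `shellProfile()`: all colony voxels binned by distance-to-surface
  (default 2 µm shells, ≈2–4 voxels at typical calibrations), orientation-
  agnostic; normalized to the outermost 2 µm shell.

`fitDecayLength()` estimates a decay length as −1/slope of a least-squares
line through log(mean intensity) versus distance. Bins with fewer than
`minCount` voxels or with means below 5% of the peak bin mean are excluded:
after background subtraction, deeper bins sit at the noise floor and a
median-based background estimate is slightly biased for Poisson noise, so
including them would flatten the fit. On exact exponential input the fit
returns the decay length to 1e-6 relative; the 5% floor then simply limits
the fit to about three decay lengths of dynamic range.

Background subtraction (`subtractBackground()`) uses the median intensity
outside the colony mask, which is robust to the bright bead spots at the
base plane.

# Viability and growth readouts

`deadFractionProfile()` computes, per height bin (default 10 µm), the
thresholded volume positive in both the stable-reporter and dead-stain
channels divided by the thresholded stable-reporter volume. Two coordinates
act simultaneously: binning is in height z above the base, while the
analysis is restricted to voxels within 30 µm of the air-facing surface (the
oxic shell), because only there is the oxygen-dependent stable reporter
bright enough to threshold reliably. Thresholds default to Otsu computed
within the colony mask only, so background outside the colony cannot skew
them; because the threshold acts on intensity (a function of depth) and not
on the death label, per-bin fractions remain unbiased even when dim voxels
are excluded. The estimator recovers a linear death-probability ramp within
0.005 absolute per bin at the default study conditions.

`reporterRatioFoldChange()` computes per-height-bin ratios of the unstable
to the stable reporter as quotients of bin sums — not means of per-voxel
quotients, which explode at dim voxels — after per-channel background
subtraction (on by default; the reference measurements do not state whether
ratios were background-corrected, so the choice is explicit and recorded in
provenance). The fold-change divides the ratio in a bin centered at 100 µm
by the ratio in a bin at 0 µm (clipped at the base), both restricted to the
oxic shell. The default query-bin width of 5 µm keeps the finite-bin bias of
a linear ratio field below 3%.

`competitionRingRatio()` thresholds each strain's reporter within a ring of
width 35 µm at 350 µm from the inoculum edge (2D distance transform of the
complement of the inoculum footprint) and reports area₁/(area₁+area₂).
`normalizeSignal()` implements the bulk normalizations (per-biovolume,
per-colony-count × mean volume, per-OD).

# Morphometry and the bulge metric

`heightRadiusProfile()` reports, per radial bin of one xy-voxel around the
basal-footprint centroid, the azimuthal mean of the local top-face height
(empty columns contribute 0, so the profile decays to zero at the edge; the
azimuthal *maximum* was rejected as noise-sensitive). No monotone cleanup is
applied — mid-height bulges are the signal. `slopeAtHeight()` smooths the
profile with a 5-bin moving average, locates the radius where the profile
crosses the query height by linear interpolation, and evaluates the central
finite difference there.

For the generator's shape family `h(r) = H (1 − (r/R)^p)` the slope at
height h is `−(Hp/R) (1 − h/H)^((p−1)/p)`, so at equal H and R the bulged
dome (p = 2) is *less* negative than the cone (p = 1) exactly when
`h > 3H/4`: near the apex the dome rounds off while the cone keeps constant
slope. The bulge-contrast validation therefore uses H = R = 120 µm with the
query at 100 µm; for mid-height queries on taller domes this family gives
the opposite ordering, which is a property of the parametrization, not of
the measurement. Validation against closed forms uses a cone
(H = 200, R = 400: slope −0.5 everywhere) and a hemisphere
(R = 200: slope −√3 at 100 µm), both recovered within 5% at 1 µm voxels.

# The synthetic-colony generator

`renderColony()` rasterizes an axisymmetric dome (filter-grown colonies of
non-motile parental strains are highly reproducible and axially symmetric;
asymmetric or motile-spread morphologies are out of scope) and renders:

* **stable reporter**: `surfaceIntensity * exp(−d / lambdaDecay)` with d the
  *analytic* distance to the continuous dome surface, computed from an
  arc-length-resampled surface curve on an (r, z) lookup grid — deliberately
  independent of the package's own distance transform, so recovery tests do
  not share code with the code they test. The exponential form is a
  generator choice, not a biological claim: the reference measurements show
  a monotone decrease of reporter fluorescence with depth but no functional
  form, and an exponential with a free decay length (default 20 µm) is the
  simplest shape that makes decay-length recovery a sharp test.
* **dead stain**: per-voxel Bernoulli with the clamped linear height ramp
  `p(z) = pmax * clamp((z − d0)/(d1 − d0), 0, 1)` (defaults 50, 150, 0.3) —
  the fewest-parameter shape matching death increasing towards the colony
  top; the stain intensity mirrors the stable reporter at dead voxels so
  colocalization is non-trivial yet exactly invertible.
* **unstable reporter**: `g0 (1 + g1 z) * stable` with defaults g0 = 0.3,
  g1 = 0.01/µm, i.e. the ratio doubles between 0 and 100 µm.
* **beads**: ≥10 bright 2×2×1-voxel spots at the base plane outside the
  footprint.
* **noise**: Poisson on signal + background (default 5 a.u.), then Gaussian
  read noise (default sd 2 a.u.) — the shot-then-read order of sCMOS/EMCCD
  detection. With noise off, rendered voxels equal the ground-truth fields
  exactly, and equal seeds give bitwise-equal stacks.

Default geometry is H = R = 150 µm at 1 µm isotropic voxels with a p = 2
dome. Real parental colonies are millimetres wide; the default is scaled so
that the probe heights that matter (30 µm oxic shell, 100 µm reference
height) fit inside a desk-scale grid of ~15M voxels. The hemisphere shape
(`shape = "hemisphere"`) exists because the power family cannot produce a
spherical cap, and caps have closed-form volumes and slopes for validation.

What the generator does *not* emulate — single-cell texture, a mechanistic
oxygen reaction–diffusion field, matrix heterogeneity, z-dependent optical
attenuation, or time dynamics — bounds what passing tests show: the
measurements are correct for smooth axisymmetric colonies under
shot-plus-read noise, not that real colonies satisfy those assumptions.

# Problem sizes and determinism

Validation runs use: the default 150 µm colony for decay-length, viability
and ratio recovery (three seeds); 120 µm colonies for the bulge contrast and
the end-to-end pipeline determinism check; a 50 µm hemisphere at 1 and
0.5 µm voxels for biovolume convergence; twenty random 32³ masks for the
distance-transform oracle. These sizes keep a full validation pass in
minutes on one CPU while leaving every estimator with thousands of voxels
per bin. `runPipeline()` writes no timestamps, and all randomness flows from
the spec/config seed, so identical inputs produce byte-identical outputs —
the provenance JSON records the configuration, seed, package version and an
input checksum.

# Known limitations

* The per-slice convex hull overestimates biovolume for strongly concave
  footprints (not observed in the target morphologies).
* `detectColonies()` merges touching colonies (connected components); the
  generator places colonies without overlap by construction.
* The basal-plane profile approximates the 3D surface distance by the
  in-plane edge distance, which is exact only where the colony flank is
  steep; its decay length reads ~10–15% high on the default dome and it is
  validated accordingly.
* Ratio readouts are relative growth proxies; no absolute growth rate in
  1/h is claimed or calibrated.
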