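---
title: "Methods: mitotic chromatin quantification and its synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mitotic chromatin quantification and its synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoquant)
```

# Scope and measurement model

mitoquant quantifies properties of mitotic chromatin from calibrated
multi-channel fluorescence stacks: compaction, congression to the spindle
equator, displacement from a monopolar pole, exclusion of microtubules and
other macromolecules (partition coefficients), Ki-67 surface confinement,
chromatin mobility (FRAP), and mitotic-entry signalling (ratiometric FRET).
All geometry is physical: 0-based `(y, x)` pixel indices with pixel centers
at integer coordinates, and every distance is an index difference times the
calibration (µm per pixel, µm per z-slice, seconds per frame). Images are
assumed background-limited rather than photon-starved: shot noise plus a
modest Gaussian read-noise floor, structures at least a PSF wide, and a
dark extracellular region available as a background reference.

# Shared segmentation primitives

Every metric composes the same small toolbox, so its conventions matter:

* **Gaussian denoising** (`gaussian_denoise`, σ in px; σ = 2 for most DNA
  channels, σ = 1 for CENP-A spots, σ = 5 for FRET channels). σ = 0 is the
  identity; filtering is slice-wise in (y, x) for 3D input.
* **Otsu dark** (`otsu_dark_mask`): 256-bin between-class-variance argmax;
  the bright class is the object, membership decided at bin resolution,
  ties resolve to the lowest threshold. Constant images are an error.
* **Phansalkar local threshold** (`phansalkar_mask`): after min–max
  rescaling to [0, 1], foreground iff
  `v > m (1 + p e^{−q m} + k (s/r − 1))` with (k, r, p, q) =
  (0.25, 0.5, 2, 10); mean m and *population* SD s over the clipped disc
  neighbourhood, so border pixels use exactly the in-image neighbourhood
  (no padding convention to document away).
* **Prominence maxima** (`find_maxima`): peaks whose height above the
  highest saddle to any higher region reaches the threshold, computed by a
  descending union–find sweep. Equal-valued plateaus are single maxima
  reported at their centroid; on exact peak-height ties the plateau earliest
  in raster order survives a merge; the global maximum has prominence ∞ and
  is always reported; border-touching plateaus are dropped when edge
  exclusion is on. These rules make spot counts deterministic.
* **Physical morphology** (`morph_offset`, `ring_roi`): erosion/dilation by
  thresholding the exact Euclidean distance transform at a µm offset, so a
  "shrink by 0.2 µm" is calibration-true on any pixel size.
* **Rolling-ball background** (`rolling_ball_background`): grayscale
  opening with a flat disc, subtracted and clipped at 0. The classic
  paraboloid ball is deliberately not reproduced: the result only
  preconditions a local threshold, and the opening form is exactly
  analysable (constants map to 0, thin lines survive, ramps flatten).
* **Skeleton length** (`skeletonize_length`): Zhang–Suen thinning, then
  length as the sum over 8-adjacent skeleton pairs of 1 or √2 pixel steps.
  This step rule overcounts by ≤ 2 px at free ends and junction triangles,
  which is below the tolerance of every ratio built on it.
* **Profiles**: line profiles use bilinear sampling at 1 px steps with a
  symmetric width average; radial profiles bin pixels at integer radii
  within an orientation sector (Θ = 360° full circle, Θ = 180° half-plane —
  the integration angle is the *full* cone, a convention recorded in the
  output because plugin conventions differ).

`otsu_dark_mask`, `phansalkar_mask`, `find_maxima`, and the 8-connected
labeling behind `regions_from_mask` are each tested for exact agreement
with independent brute-force oracles (exhaustive threshold search,
per-pixel formula evaluation, widest-path flooding, BFS flood fill) on
random ≤ 64×64 images.

# Metric-specific conventions

**Congression.** The band profile (defaults: 22.5 µm length, 7.06 µm
width, 5 µm central window; a 12.04 µm wide-band preset exists) is sampled
along the detected pole-to-pole axis; each sample is background-subtracted
with negatives clipped to 0 so the fraction stays in [0, 1]. The fraction
is invariant to uniform intensity scaling and to any constant offset that
is also supplied as the background.

**Chromatin density.** Mean DNA intensity in the σ = 2 + Otsu mask,
normalized to a control mean. An optional `background` argument subtracts a
camera/extracellular offset first; the amplitude-ratio validation uses it
because a density *ratio* is only meaningful on an offset-free scale.
The central z-section is the caller's choice (automated callers use the
slice maximizing in-mask tubulin or DNA mean).

**Monopolar displacement.** The cumulative radial distribution is computed
at full pixel-radius resolution (the limit of an infinitesimally binned
radial profile) rather than on integer-radius bins: whole-bin cuts at
0.3 R and R otherwise quantize the ratio by several percent at R ≈ 30 px.
Background subtraction keeps negative residuals, so noise integrates to
zero instead of inflating the 99% edge radius; the ratio is floored at 0.

**Kinetochores and foci.** Spots are prominence maxima (100 for
immunofluorescence presets, 2000 for live CENP-A, 3000 for γH2A.X);
distances to the chromatin surface are signed Euclidean distances to the
nearest boundary pixel (negative inside), with anisotropic z handled by
scaling coordinates before measuring. The displacement rule is strict:
outside means > +0.5 µm. Per-spot distances are returned so manual review
remains possible.

**Partition coefficients.** Four variants share one record type.
The line variant localizes the boundary at the 50% point between the
inside and outside plateaus of the DNA reference profile (the side with
the higher DNA mean is "inside") and reads the probe ±1 µm from it; when
the nominal segment is too short for both offsets (the 1.3 µm tubulin
preset), the sampled line is extended along its direction and the result
flagged. The mask/ring variant shrinks the mask by 0.2 µm, rings at
1.5/0.5 µm, and subtracts an extracellular background from both sides.
The circle variant demands a 5 µm cytoplasmic disc with ≥ 1 µm clearance
from every DNA region *and* full containment in the cell mask, found by
maximizing the distance transform. The droplet variant measures a
concentric disc of exactly 25% of each droplet's area against a
droplet-free buffer rectangle ("~25%" and "~5 µm" are resolved to the
printed numbers, configurable). The line and droplet variants perform no
background subtraction — the assays they mirror do not — so they report
the ratio of raw levels.

**Ki-67 profiles.** The first-peak rule scans from the cytoplasmic end for
the first local maximum exceeding the local background by 3 SD *and* 10%
of the profile range; the relative floor exists because a pure 3σ rule
admits near-threshold noise bumps in the dark cytoplasm, which misalign
whole profiles. Curves are resampled on a 0.05 µm grid over the common
support; the chromatid-centre position is supplied as an offset from the
control peak (the geometric centre of the chromatid, which an
intensity-weighted definition would shift only for very asymmetric
chromatids).

**FRAP.** The double normalization makes the curve exactly invariant to a
constant background and to any per-frame multiplicative factor common to
both traces — the two corrections it exists to perform, both asserted as
exact identities in the tests. The fit uses the base-2 parameterization
`N(t) = F0 + m (1−F0)(1 − 2^{−t/τ})` so τ *is* the half-recovery time,
bounded Levenberg–Marquardt (m ∈ [0,1], τ > 0, F0 ∈ [0,1]) with
quantile-based initialization; degenerate flat curves (m ≈ 0) defeat the
optimizer and fall back to the closed-form plateau estimate with τ
undefined. Fits need ≥ 10 post-bleach points; sampling should cover a few
half-times (the validation uses Δt = τ/20 and 100 post-bleach frames).

**FRET.** The measured quantity is the in-mask mean of the pixelwise
FRET/CFP ratio after background subtraction and σ = 5 denoising; pixels
with non-positive corrected CFP are excluded and counted rather than
propagated as NaN. The display map is clipped to [0, 1.4]. Double
normalization of both channels by the same factor cancels exactly.

**Filaments.** The fluorescence pipeline is σ = 2 denoise → rolling ball →
min–max rescale → Phansalkar → skeletonize; skeleton pixels are assigned
to chromatin vs buffer by mask membership, pairs crossing the boundary are
dropped from both (a ≤ 1-px-per-crossing effect). Both the raw length
ratio and the per-area ratio are reported, since "density" may or may not
imply area normalization. Tomogram polylines are clipped against the voxel
mask by subsampling at a quarter of the smallest voxel pitch with midpoint
membership — simple, oracle-verifiable, and < 0.5% from a 1 nm-pitch
reference; the analysed z-window excludes the blurry top and bottom
slices, and per-domain lengths are normalized by the in-window domain
volumes.

**Statistics.** `compare_groups` delegates to the standard two-tailed
Wilcoxon rank-sum routine: exact for tie-free samples with n < 50, normal
approximation with tie correction otherwise; it matches exhaustive
permutation enumeration for n ≤ 8. p-values below 10⁻¹⁵ are reported as
that upper bound with a flag, because the exact magnitude is numerically
meaningless. No multiple-testing correction is applied at this layer.

# The synthetic-scene generator

Raw microscopy for studies of this kind is typically available only on
request, so validation is built on generated scenes whose every true
parameter is recorded (`scene_truth`) before noise is applied. The
generator renders continuous models onto the pixel grid:

* **Bipolar cells** (240×240 px at 0.1 µm/px): chromatin as hard discs of
  radius 1.2 µm (chromosome-arm scale) blurred by a PSF of σ = 1.5 px
  (0.15 µm, Airyscan-like); two Gaussian tubulin poles 11 µm apart; the
  central and peripheral disc groups are *rebalanced analytically* so the
  true fraction of DNA mass in the central 5 µm window equals the request
  to well under 1%, and the achieved value is what SceneTruth records.
  Kinetochores are isotropic Gaussian spots (σ = 2 px) placed ≥ 0.3 µm
  deep inside or at a stated distance outside the chromatin surface, with
  ≥ 1 µm mutual separation so they are individually resolvable — merged
  spots would test the microscope, not the classifier. Partition scenes
  for the circle and line variants use a single 4 µm chromatin mass (a
  metaphase-plate-scale ROI): the un-shrunk DNA ROI of the circle variant
  averages a boundary band of width ≈ PSF, and only a body much larger
  than the PSF keeps that band a small area fraction, exactly as in the
  real assay. The probe channel carries no extracellular offset in scenes
  for the variants that do not background-subtract.
* **Monopolar cells**: a central tubulin aster and a chromatin annulus
  (3–5 µm) with an optional inner-disc mass fraction; the true
  inner/outer ratio is computed by pixel-exact integration of the
  noiseless channel, independent of the metric's code path.
* **Droplet fields** (256×256 px): non-overlapping discs of radius
  0.8–1.6 µm with ≥ 0.8 µm gaps (closer droplets would fuse optically and
  merge under any threshold), probe at `P ×` buffer level inside,
  PSF σ = 1 px (the mirrored assay images are deconvolved), and a reserved
  droplet-free corner for the buffer ROI.
* **Filament fields**: straight segments with midpoints drawn from a
  *padded* region and clipped to the field, making the line process
  stationary across the image (sampling midpoints only inside the field
  depletes the borders and biases per-area ratios upward — a generator
  bug class worth naming). 400 segments per field give the homogeneity
  check its statistical power; per-scene true in/out lengths come from
  analytic chord clipping against the disc union. Exclusion scenes remove
  in-chromatin portions before rendering.
* **FRAP series**: the bleach-ROI trace follows
  `bg + β^f · pre · ((1−d) + d·m·(1 − 2^{−t/τ}))` with a per-frame
  acquisition-bleaching factor β and the whole-region mean following
  `bg + β^f · pre` (recovery from a large pool); masks and all parameters
  are recorded.
* **FRET triplets**: FRET = r × CFP inside the nucleus, per-channel
  extracellular backgrounds, a YFP mask channel, and a recorded 1 µm²
  background square.
* **Tomogram fixtures**: persistent random-walk polylines in a
  64×64×40 voxel volume (8 nm voxels) with a voxelized chromatin ball;
  ground-truth per-domain lengths by 0.5 nm dense sampling against the
  same voxel mask — a separate code path from the metric.

Noise is Poisson shot noise on the noiseless expectation plus additive
Gaussian read noise at 2% of the scene's dynamic range (a stated generator
convention, not a claim about any particular camera), clipped at 0;
averaging many realizations recovers the noiseless scene, which is a
tested property. All randomness flows through an explicit seed and the
caller's RNG state is restored.

What the generator does **not** emulate: realistic 3D PSFs and spectral
bleed-through, intensity-dependent noise calibration, autofluorescence,
drift, or any actual chromatin/microtubule mechanics. Passing recovery
tests therefore demonstrates that the *measurement pipeline* is unbiased
and correctly calibrated on images matching its assumptions — not that it
is robust to every real-world artefact.

# Validation design and problem sizes

The acceptance suite (one `testthat` block per claim, plus
`scripts/acceptance.R` which recomputes everything from scratch) runs:
primitive-oracle equivalence on 20 images per primitive; 20 congression
scenes across central fractions 0.1–0.9 (recovery within ±0.03); density
ratios 0.29/0.53 (±0.03); the partition grid P ∈ {0.2, 1, 5} × four
variants, median over 3 fields (8 cells for the two-point line readout)
within 10% (15% line), with statistically uniform probes returning
1.00 ± 0.02; exact kinetochore label recovery noiselessly and ±1 spot with
noise; the analytic uniform-disc radial ratio 0.09/0.91 within 3% for
R ≥ 30 px; the FRAP grid m ∈ {0.3, 0.6, 0.9} × τ ∈ {0.5, 2, 8} s with 20
series each (m within 0.05, τ within 10% on medians); FRET ratios
{0.3, 0.7, 1.2} within 2% and exact rescale invariance; filament length
conservation and 1 nm-oracle agreement within 0.5%, exclusion ratios
≤ 0.05, and per-area homogeneity medians within 1 ± 0.15 over 8 fields;
and Mann–Whitney exactness on 100 random small-sample datasets. These
sizes were chosen so each estimate's sampling error is comfortably below
its tolerance while the whole suite stays desk-scale.

# Known limitations

* Blur is 2D and slice-wise; there is no 3D deconvolution or axial PSF
  model, so 3D metrics treat z only through the calibration.
* `rolling_ball_background` and `phansalkar_mask` evaluate dense
  neighbourhoods; at the classic presets (radius 740 and 100 px on
  multi-megapixel images) they are correct but slow — the package favours
  auditability over speed there.
* The line-profile partition readout is two point samples per cell and is
  therefore intrinsically noisy at low probe levels; medians over several
  cells are the intended use.
* Otsu on fields dominated by background can place the threshold inside
  the background mode if the foreground class is vanishingly small; the
  particle-size filter (default 5 px², the unitless-particle convention,
  logged per run) is the guard.
* Equal-height maxima tie-breaking (raster order) is deterministic but not
  guaranteed to match any particular interactive tool's corner cases.
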