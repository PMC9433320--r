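# mitoquant

Quantification of mitotic chromatin biology from fluorescence microscopy:
how compact mitotic chromosomes are, how well they congress to the spindle
equator, how strongly they exclude microtubules and other macromolecules,
how Ki-67 coats their surface, and how mobile the underlying chromatin is.
The package is written for cell biologists who have multi-channel confocal
or Airyscan stacks (DNA/H2B, tubulin, CENP-A, injected probes, Ki-67,
FRET biosensor channels) and want the corresponding quantitative readouts
as reproducible, scriptable measurements instead of one-off ImageJ macros.

## What it measures

Every metric is built from a small set of shared segmentation primitives
(Gaussian denoising, global Otsu and local Phansalkar thresholds,
prominence-based maxima, physical-unit morphology on the Euclidean distance
transform, rolling-ball background subtraction, Zhang-Suen skeletons, line
and radial profiles — all calibrated in micrometres):

- **DNA congression** — fraction of background-corrected DNA density in the
  central 5 µm window of a 22.5 µm × 7.06 µm band profile along the
  pole-to-pole axis: `f = Σ I(|s| ≤ w/2) / Σ I`.
- **Chromatin density** — mean DNA intensity inside the Otsu-dark chromatin
  mask, normalized to a control mean; also the line-profile peak-window
  (200 nm) variant.
- **Monopolar radial displacement** — around a monopolar spindle pole, the
  edge radius R containing 99% of cumulative H2B intensity, and the ratio
  `Σ I(r ≤ 0.3R) / Σ I(0.3R < r ≤ R)`.
- **Kinetochore displacement** — CENP-A maxima (prominence criterion) with
  signed Euclidean distance to the chromatin mask surface; displaced iff
  > 0.5 µm outside.
- **Partition coefficients** `P = (I_in − bg) / (I_out − bg)` in four
  variants: line-profile (±1 µm around the DNA half-max boundary),
  shrunken-mask/ring, DNA-regions vs cytoplasmic 5 µm circle, and in vitro
  droplet interior (25%-area concentric disc) vs buffer rectangle.
- **Ki-67 surface confinement** — boundary-crossing profiles aligned at the
  first Ki-67 peak (or at the DNA half-max edge), averaged per group, and
  scored as surface/interior ratio at control-defined positions.
- **FRAP** — double normalization
  `N(t) = [(I_roi−bg)/(I_tot−bg)] · [(I_tot,pre−bg)/(I_roi,pre−bg)]` and a
  bounded fit of `N(t) = F0 + m (1−F0)(1 − 2^{−t/τ})` for mobile fraction m
  and half-time τ.
- **FRET/CFP ratio** — background-subtracted, σ = 5 denoised emission ratio
  inside the YFP-derived nuclear mask (aurora-B biosensor readout).
- **Microtubule density per compartment** — skeleton length of the
  denoised/background-subtracted/Phansalkar-thresholded tubulin channel
  inside vs outside chromatin ROIs; and, for electron-tomogram annotations,
  polyline length clipped against a voxelized chromatin domain per unit
  domain volume.
- **Condensation CV** (σ/µ of a field), apoptotic index (1.2× control
  median rule), γH2A.X focus counts, normalized two-channel intensity
  ratios, and a two-tailed Mann-Whitney comparison layer.

Because raw data for such studies are rarely deposited, the package ships a
seeded **synthetic-scene generator** (`make_cell_scene`,
`make_droplet_field`, `make_filament_field`, `make_frap_series`,
`make_fret_pair`, `make_tomogram_fixture`) that renders each scene class
from a continuous model and records every true parameter in a `SceneTruth`
record. All metrics are validated by parameter recovery against that
ground truth; the test suite and the acceptance script are built entirely
on it.

## Worked example

```r
library(mitoquant)

scene <- make_cell_scene("bipolar", list(central_fraction = 0.6,
                                         n_spots_inside = 6L,
                                         n_spots_outside = 4L), seed = 1)
scene$stack
#> calibrated_stack: 240 x 240 px, 1 z, 3 channel(s) [dna, tubulin, cenpa], 1 frame(s)
#> calibration: 0.1 um/px

poles <- detect_poles(get_channel(scene$stack, "tubulin"), "bipolar",
                      pixel_size_um = 0.1)
f <- congression_fraction(get_channel(scene$stack, "dna"),
                          axis_spec(poles[1, ], poles[2, ]),
                          background_mean = 20, pixel_size_um = 0.1)
f
#> [1] 0.597   # generator truth: 0.600

kd <- kinetochore_displacement(get_channel(scene$stack, "cenpa"),
                               get_channel(scene$stack, "dna"),
                               prominence = 100, pixel_size_um = 0.1)
c(fraction_outside = as.numeric(kd), n_spots = attr(kd, "n_spots"))
#> fraction_outside          n_spots
#>             0.40            10.00
```

The measured congression fraction (0.597) recovers the scene's true
central fraction (0.600) within the package's stated 0.03 tolerance, and
the kinetochore classifier reproduces the generated 4-of-10 displaced
spots exactly.

The `analysis/` directory holds the numbered workflow scripts
(`01_simulate_scenes.R` … `06_group_stats.R`) that generate example
scenes, run each metric family over its parameter range, and write tables
under `results/`.

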