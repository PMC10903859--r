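---
title: "Methods: fibrosis and airspace quantification in whole lung slices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fibrosis and airspace quantification in whole lung slices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alveoquant)
```

## The measurement model

A stained lung section on a slide contains four kinds of collagen
signal, only one of which is pathology: fibrotic deposits in the
parenchyma, the physiological collagen of the pleural rim, the walls of
conducting airways and vessels, and stain debris. `alveoquant`
quantifies fibrosis as a *fraction of the parenchyma* after removing
the other three by construction:

1. **Sample detection.** Band threshold on one channel of the RGB
   image, blue by default: both eosinophilic tissue and collagen
   stains absorb enough blue to separate from the white slide. The
   band is closed on both ends (`lower <= v <= upper`); a particle
   size filter and optional declarative exclusions clean debris.
2. **Pleura.** The sample outline is hole-filled and reduced by a
   user-set distance: pixels of the filled outline farther than the
   pleura thickness from the exterior (exact Euclidean distance
   transform) form the interior; the rest is the pleural band. Filling
   first matters — interior alveolar boundaries are not pleura.
3. **Air ducts and walls.** Ducts are user-supplied ROIs (no automatic
   detection; identifying a bronchiole is an anatomical judgement, not
   an image-processing one). Walls are the distance band of the wall
   thickness around the ducts, clipped to the filled sample.
4. **Parenchyma.** Sample tissue minus pleura, ducts and walls. Where
   regions overlap, precedence is ducts > walls > pleura > parenchyma;
   removal semantics are only unambiguous with an ordering, and duct
   structures are anatomically the most definite.
5. **Fibrosis.** Band threshold on the green channel of the parenchyma
   image (SR) or of the connective-tissue reconstruction of a color
   deconvolution (MT), clipped to the parenchyma mask — the clip is
   structural, not cosmetic, because blanked surroundings are white
   (green 255) and would enter a wide band. A second size filter
   removes specks.
6. **Airspace.** The tissue is virtually closed by the pleural band
   and duct walls; candidate airspace is the sample interior minus
   this closed phase. Components touching the frame border are
   background leaking through an unclosed boundary: they are discarded
   and counted as a QC flag. Duct lumina are excluded (conducting
   airways are not alveoli). Survivors pass area and circularity
   bands.

The compiled ratios are `fibrosis_fraction = F/P`,
`airspace_fraction = A/(P+A)` and `tissue_density = P/(P+A)`. The
tissue-density formula is an interpretation — combining the two areas
into a density admits several denominators, and this choice makes
density and airspace fraction complementary and unit-free.
`P` is the extracted tissue-pixel area; the enclosing region area
`P + A` is reported as an auxiliary column for users who prefer the
region denominator.

## Parameters that matter

| parameter | unit | default | rationale |
|---|---|---|---|
| `microns_per_pixel` | µm/px | none (mandatory) | calibration is a constructor argument; guessing it from metadata risks silent unit errors |
| sample threshold | gray | blue ∈ [0, 245] | excludes the white slide at noise SD ≤ 5; polarity/channel overridable |
| sample size filter | µm² | ≥ 500 | removes noise speckles far below any tissue fragment |
| pleura thickness | µm | 30 | a study parameter; no universal anatomical default exists |
| wall thickness | µm | 40 | idem; covers peri-duct collagen in the benchmark geometry |
| fibrosis threshold | gray | green ∈ [0, 90] (SR), [0, 150] (MT pseudo-RGB) | calibrated on the synthetic benchmark; real slides need per-batch values |
| fibrosis size filter | µm² | ≥ 100 | drops sub-cellular specks |
| airspace filter | µm², — | area ≥ 50, circularity ∈ [0, 1] | admits merged, irregular alveoli by default |

Thresholds always live on the 0–255 scale; inputs with more than 8
bits per sample are linearly rescaled over their observed range on
load. There is deliberately no automatic threshold selection (Otsu and
relatives): threshold choice is part of the study design here, and the
ledger records it.

## Numerical conventions

- **Coordinates.** Pixel `(x, y)` = (column, row), 0-based; a pixel is
  inside a polygon iff its center is inside or on the boundary
  (even-odd rule plus an explicit on-edge test). ImageJ `.roi`
  vertices live on the pixel-corner grid and are shifted by −0.5 on
  import, which preserves filled areas.
- **Connectivity.** Particles are 8-connected (the particle-analyzer
  convention), implemented as a 4-connected labeling whose diagonal
  label adjacencies are merged through graph components. Negative
  space is likewise taken 8-connected, which implies the 4-connected
  dual for the surrounding tissue boundary and avoids topological
  paradoxes on the grid.
- **Perimeter.** Moore contour tracing through pixel centers of the
  outer boundary, axial steps 1, diagonal steps √2. Perimeter
  conventions differ by more than 10 % between estimators, so the
  package treats its own estimator as the reference: a 100 px square
  measures circularity 0.801 (analytic limit π/4 ≈ 0.785) and a
  radius-60 digital disk 0.906. Degenerate components: a single pixel
  uses the crack-length convention (perimeter 4 px); tracing stops
  when the initial boundary move repeats. Inner hole boundaries are
  not added to the perimeter.
- **Distances.** µm are converted to px by rounding half-up; distance
  bands use the exact Euclidean distance transform. On a digital disk
  (R = 100 px, t = 10 px) the band area is within 0.9 % of the
  analytic annulus.
- **Optical density.** `OD = -log10((v + 1)/background)` with a
  one-gray-level epsilon: bounds OD at ≈ 2.4 decades for 8-bit data
  and makes results bit-reproducible. Negative concentrations after
  unmixing lie outside the stain gamut and are clipped to 0. The MT
  stain matrix pins the classic plugin constants (methyl blue,
  ponceau-fuchsin); the third vector is the normalized orthogonal
  complement, so the matrix is invertible and the residual channel is
  well-defined. Custom per-batch vectors can be supplied from file.
- **Ledger.** JSON lines, one record per stage, carrying every
  parameter that influenced the stage plus particle counts and QC
  warnings; timestamps are the only non-reproducible field.

## The synthetic benchmark

`generate_slice()` builds the study conditions the tests run under: an
elliptical section (semi-axes 480 × 400 µm on a 512 × 512 px frame at
2 µm/px), a 30 µm pleural rim, three non-overlapping ducts of radius
40–80 µm with 40 µm walls, alveoli as merging disks of radius 15–40 µm
at 150 per mm² of parenchyma, fibrotic patches painted until their
share of the parenchyma tissue is within 0.01 of the 0.2 target, and
Gaussian noise of SD 5 gray levels. These values were chosen once as a
plausible mouse-lung geometry at this magnification; alveolar merging
yields irregular airspaces on purpose, so circularity tests use
dedicated disk and slit fixtures instead. SR coloration is an
empirical palette (pale pink tissue, red-dominant collagen), while MT
is rendered through the physical Beer–Lambert forward model — this
deliberately exercises the direct-channel SR path and the
deconvolution MT path separately.

What the generator does **not** emulate: anti-aliased edges, nuclear
speckle, stain gradients, scanner vignetting, tiling artifacts,
cellular infiltrates and mucus. Passing the recovery tests therefore
shows that the pipeline's geometry, unmixing and accounting are
correct under known coloration; it does not show that the default
thresholds transfer to any real staining batch — on real data they are
study parameters, as in interactive practice.

Unit tests run on a reduced 256 × 256 px frame with two ducts for
speed; the end-to-end recovery checks and the acceptance script use
the full default conditions above across seeded replicates (ten seeds
per stain in the test suite, five per stain in the acceptance script).
Recovery accuracy at these conditions is well inside ±0.02 absolute
for the fibrosis fraction and ±0.03 for the airspace fraction.

## Design decisions that were genuinely open

- **Threshold polarity.** Whether sample detection selects tissue
  directly or selects-and-inverts the slide is not fixed by the
  protocol text; the default selects tissue on the blue channel, and
  both channel and band are overridable.
- **Duct lumina.** They are negative space but not alveoli; they are
  excluded from airspace via an optional duct mask argument, recorded
  in the ledger.
- **ROI export.** The package reads ImageJ `.roi`/`.zip` containers
  and writes its JSON dialect; writing ImageJ's binary format is
  omitted as optional interoperability.
- **Deconvolution round-trip sampling.** Quantized round-trip checks
  sample concentrations inside the stain gamut (all per-channel ODs
  ≥ 0 and ≤ 2.4): out-of-gamut triples clip at 8 bits and are
  unrecoverable for any implementation.
- **Repair semantics.** Break repair is declarative (stroke ROIs plus
  an optional disk closing); the ledger records which was used, so the
  formerly interactive step is replayable.

## Known limitations

- Stains that do not suppress green in collagen (or heavily faded
  batches) need a custom detection channel or stain vectors.
- Cellular infiltrates and mucus are not distinguishable from tissue
  by SR/MT color alone; they inflate the parenchyma denominator
  exactly as they do in expert practice.
- Images must fit in memory; pyramidal whole-slide formats are out of
  scope (stitched micrographs at this magnification do fit).
- Fractions are area-based; no stereological quantities (mean linear
  intercept) are computed.
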