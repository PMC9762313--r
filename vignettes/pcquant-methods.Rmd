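---
title: "Quantifying protocell uptake, transport and tumor burden: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying protocell uptake, transport and tumor burden: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

pcquant re-implements, as a tested and reusable pipeline, the
image-quantification procedures behind a protocell (PC) delivery study in
larval zebrafish: micron-scale protein-polymer microcapsules (~2 µm across,
sized to pass the narrowest vessels) are injected into circulation, taken up
by leukocytes, and used to deliver an anti-miR oligonucleotide; the study's
readouts are all image-derived — what fraction of immune cells contain PCs,
how fast free PCs circulate, whether PCs sit in lysosomes and still carry
cargo, how pigmented and how large tumors are, and how much tumor volume and
stain-positive area serial histological sections carry.

The original measurements were made interactively on microscope stacks that
are not redistributable. The package therefore pairs every quantification
with a synthetic-scene generator that plants known ground truth, so each
stage can be validated end to end without the original data. This vignette
records the models, the parameters that matter, the numerical choices, and
what the synthetic validation does and does not establish.

## Detection model

All object-based readouts share one detection pipeline
(`detect()`), mirroring the interactive workflows it replaces:

1. **Pre-filter** — optional 2D median (radius r, salt-and-pepper noise),
   Gaussian (σ, shot noise), or variance filter (textured-region
   enhancement, used to find tissue sections). All window filters use
   nearest-replication edge handling and act on each yx plane independently;
   anisotropic z is never mixed into 2D morphology.
2. **Background subtraction** — optional rolling-ball: the background is the
   grayscale opening of the image with a non-flat ball structuring element
   (height profile $\sqrt{r^2 - d^2} - r$), subtracted and clipped at zero.
   Structures narrower than the ball survive; broad plateaus are removed.
3. **Threshold** — Otsu (256-bin histogram spanning [min, max]; the
   between-class variance $\omega_0\omega_1(\mu_0-\mu_1)^2$ is maximized
   over all 255 splits; ties resolve to the lowest bin; the threshold is the
   chosen bin's upper-edge intensity), mean, or fixed. The raw threshold
   $t_0$ is then adjusted as $t = \max(k\,t_0,\ t_{\min})$: the
   user-controlled multiplier $k$ first, then the minimum permitted
   threshold, which exists to keep background out of the segmentation in
   low-signal images. $t_{\min}$ is an absolute intensity by default, or a
   fraction of the intensity range with `t_min_fractional = TRUE`.
4. **Binarization** — strictly greater than $t$, so a threshold at the image
   maximum yields an empty mask.
5. **Hole filling** — optional; background components not connected to the
   image border become foreground, in the mask's native dimensionality,
   tracing the background with the complementary connectivity (foreground
   8 ↔ background 4; 26 ↔ 6).
6. **Labeling** — connected components ("contiguous foreground-labeled
   regions") at 4/8 (2D) or 6/26 (3D) connectivity; the default is 8/26.
   Labels are numbered by each component's first-encountered voxel in the
   array's linear (raster) order, making label maps reproducible across
   runs and platforms.
7. **Watershed split** — optional; touching convex objects are divided by
   the watershed of the negated Euclidean distance transform, seeded from
   distance maxima and constrained to the mask, so the labels partition
   exactly the input foreground. Seed merging uses an intensity tolerance
   on the distance map (default 1 px of depth). In 3D stacks the split is
   applied per z-slice.
8. **Filtering** — objects below a voxel-count threshold are dropped;
   when a region-of-interest mask is given, objects whose centroid falls
   outside it are dropped; survivors are relabeled canonically.

Every parameter travels in a `DetectionParams` object and is recorded in
the output label map's provenance, so a detection is reproducible from its
parameter record.

## The quantifications

* **Containment** (`containment()`): a PC is *inside* a cell iff the cell
  label at the PC's rounded centroid voxel is nonzero. The centroid rule is
  the default because the assay's readout is binary in/out and centroids
  are robust to boundary noise; a `full_overlap` variant (every PC voxel in
  one cell) is available for sensitivity checks. Reported:
  per-cell PC counts, % of PCs inside any cell, % of cells containing ≥1
  PC, with the conservation identity n_inside + n_outside = n_total.
* **Colocalization** (`overlap_fraction()`, `classify_marker_positive()`):
  the fraction of an object's voxels inside a marker mask; an object is
  marker-positive when that fraction reaches τ. τ = 1 encodes the "fully
  colocalized" criterion used for lysosome residence (originally a manual
  call, automated here as an explicit rule); τ = 0.5 is the default for
  intact-PC calls (membrane channel vs cargo channel).
* **Pigmentation** (`pigmentation_fraction()`): % of region pixels on the
  pigment side of an automatically computed threshold. The threshold method
  and polarity are configurable because the original procedure named only
  "the threshold function"; the defaults are Otsu with dark-side-positive,
  the natural choice for pigment on a bright brightfield background.
* **Fluorescent pixel count** (`fluorescent_pixel_count()`): region pixels
  strictly above a threshold; the burden proxy for whole-fin images.
* **Areas and growth** (`tumor_area()`, `relative_growth()`): pure pixel
  counting times pixel size squared — deliberately no sub-pixel area
  estimation, matching the source workflows — and a timecourse normalized
  to its first timepoint (a zero baseline is an error, not an Inf).
* **Stained sections** (`positive_area_fraction()`,
  `double_positive_area_fraction()`, `quantify_sections()`): stain-positive
  area over tumor area per section. Both the area-fraction mode and a
  cell-count mode (running `detect()` on the stain channel) are provided,
  because the study reports area fractions in figures while describing
  cell counting in methods.
* **Volume** (`section_volume()`): the Cavalieri estimator
  $V = \sum_k A_k \cdot t$ with thickness t = 10 µm by default, the
  histology sectioning thickness.

## Tracking

`link()` connects per-frame detections into tracks. For each frame pair,
a candidate link is *admissible* iff its physical length is at most
`max_link_distance` **and** its displacement direction deviates from the
preferred flow direction (default 0° = left-to-right) by at most
`max_deviation` (default 70°). The deviation gate is a hard rule, matching
"maximum permitted deviation", and is inclusive at the boundary so behavior
at the printed limit is deterministic; zero-length displacements carry no
direction and pass. Among admissible links a minimum-total-distance
one-to-one assignment is chosen globally per frame pair (Hungarian
algorithm with potentials, exact), not greedily — a greedy mode exists only
as a cross-check. Unmatched detections start new tracks; tracks shorter
than `min_track_length` are discarded; gap closing is off by default
(`allow_gap_frames = 0`) since the source procedure does not describe it.
An optional soft angular cost (µm per degree) can be added for sensitivity
analysis without replacing the hard gate.

Instantaneous velocity is
$v_i = \lVert p_{i+1}-p_i\rVert \cdot \text{pixel size} /
(\Delta\text{frames}\cdot\Delta t)$. The original movies' frame interval is
not published, so velocities in physical units always require explicit
user calibration — `link()` refuses to run without it.

## The synthetic scenes

`gen_uptake_scene()` emulates the in-vivo uptake assay: soft-edged cell
bodies (logistic radial falloff, width 0.75 µm — soft edges make the
threshold choice non-trivial, as in real fluorescence) in channel 1 and
2-µm PC spheres in channel 2, over a smooth background (offset 0.05 of
peak, gradient 0.02 in a random direction) with Poisson shot noise plus
Gaussian read noise. The noise model is parameterized by a single snr =
peak signal / Poisson sd at peak: the normalized render n(x) is scaled to
snr² expected photons, Poisson-sampled, read noise (sd = 0.5 · snr) added,
and rescaled; snr = ∞ returns the noiseless render exactly. Defaults: 50
cells of radius 4–7 µm and 60 PCs in a 140 × 140 µm field at 0.5 µm/px,
40% of cells loaded with 1–2 PCs each — titer presets scale PC count and
loaded fraction 5 : 2 : 1, matching the study's high/medium/low injected
densities.

"Inside" is decided *at generation time*, geometrically: an inside PC's
center lies within its owner's radius minus one PC radius; an outside PC
clears every cell boundary by ≥ 2 µm (at least one PC radius). Placement
keeps cells ≥ 3 µm apart and PC centers ≥ 2 diameters apart (multi-PC
cells place their PCs on a jittered ring, since independent uniform draws
cannot guarantee the separation once the first PC lands centrally). These
margins are chosen so that the planted truth remains unambiguous under the
soft-edge rendering and default detection — the generator's contract is
that geometry, not the renderer, defines the answer. One global seed
drives hierarchical substreams (cells, ownership, placement, background,
noise), so changing the PC count never moves the cells, and every
generator is bitwise deterministic.

`gen_flow_movie()` advances particles by speed(t)·Δt along a fixed
direction with sinusoidal pulsatility (default period 0.5 s, a larval
heartbeat); the truth stores every per-step displacement, so velocity
recovery can be checked exactly. `gen_section_series()` slabs a sphere or
ellipsoid at thickness t, rasterizing the cross-section at each slab
midpoint (k+½)t; at 0.25 µm/px the rasterization error stays well below
the midpoint-rule sectioning error (~t²/8r² relative), so the volume error
shrinks visibly as sections thin — 0.50%, 0.12%, 0.04% at 10, 5, 2.5 µm
for a 50-µm sphere. `gen_pigment_image()` draws exactly
round(f·n) pixels from a dark mode (0.2 ± 0.03) and the rest from a bright
mode (0.8 ± 0.03), keeping the modes separable so threshold recovery is
exact to within a pixel.

What the synthetic scenes do **not** emulate: optics (no PSF beyond the
soft edge; no depth attenuation), cell shape irregularity (blobs are
radially symmetric), vascular geometry and flow fields (particles move in
straight lines), photobleaching, and overlapping or touching cells in the
uptake scene (touching objects are exercised separately in the watershed
tests). Passing the recovery tests therefore demonstrates correctness of
the measurement code under controlled conditions, not segmentation
robustness on difficult real images — on real data the k, t_min and size
thresholds exist precisely because defaults fail.

## Image containers and I/O

Stacks are dialect-explicit: the axis order of a TIFF is declared (any
subset of `tzcyx`), never guessed; multi-page files without a declaration
are an error, as is missing calibration. Pixel indices are 0-based with
voxel centers at integers, so physical position = index × pixel size.
Written TIFFs carry their calibration and axis layout in a plain-text
sidecar (`<path>.meta`); 8- and 16-bit files round-trip as native integer
counts, and the `"float"` dtype stores values in [0,1] as 32-bit samples
on the s/2³² fixed-point grid (`storage_quantize()` exposes the grid; data
already on it round-trip bit-for-bit, and quantization error is ≤ 2⁻³³ —
finer than single precision on [0,1]). Quantification tables are CSV with
full-precision (`%.17g`) numerics and, from workflows, a provenance header
(package version, workflow name, seed, config hash) so any run is
reproducible from its outputs alone.

## Workflows

`run_workflow()` maps names onto the study's quantifications — `pigment`,
`fpc`, `growth`, `speed`, `uptake`, `cells`, `lyso`, `intact`, `sections`,
`volume`, `synth` — validating the whole `workflow_config()` before any
image is read (unknown keys are rejected), logging every parameter value,
and writing tidy CSVs. Reruns with the same config and seed are
byte-identical. The numbered scripts under `analysis/` are thin narrative
drivers over these functions and write their tables under `results/`.

## Problem sizes and test design

The validation suite runs at deliberately modest sizes chosen to exercise
every code path while staying quick: 10 uptake scenes of 50 cells / 60 PCs
at snr 20 for containment recovery; 200 random histograms against an
exhaustive Otsu search; 100 random masks (up to 32³ voxels) against a
flood-fill labeling oracle at both connectivities; 200 random frame pairs
(≤ 7 detections) against brute-force assignment enumeration; 100-frame
movies for velocity recovery; and sphere sectioning at 10/5/2.5 µm for the
Cavalieri estimator. Oracles are independent re-derivations (naive loops,
BFS, permutation enumeration), never the implementation called twice.

## Known limitations

* Watershed splitting is 2D (per-slice in stacks); objects touching only
  across z are not separated.
* The Otsu histogram is always 256 bins over [min, max]; images whose
  informative range is a tiny fraction of their dynamic range should be
  pre-scaled or use `t_min_fractional`.
* Tracking assumes 2D projected movies (as acquired in the study) and has
  no motion model; dense, fast scenes with crossings beyond the gate's
  discrimination will fragment.
* The containment centroid rule can misclassify a PC pressed exactly
  against a cell boundary if detection dilates the cell by more than the
  planted clearance; the synthetic clearance margins are set so this does
  not occur at the study conditions.
* TIFF support covers grayscale single-sample pages (the study's
  modality); RGB pages and proprietary microscope formats are out of
  scope.
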