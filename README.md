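# pcquant

Quantification of protocell uptake, transport and tumor burden from
fluorescence microscopy.

Micron-scale protein–polymer microcapsules ("protocells", ≈2 µm) can be
injected into the circulation of larval zebrafish, where leukocytes engulf
them — turning the capsules into Trojan-horse carriers for oligonucleotide
cargo. Every readout in such experiments is image-derived: the fraction of
immune cells containing protocells, the speed of free capsules in vessels,
colocalization of capsules with lysosomes or with their cargo,
pigmentation and area of tumors over time, and tumor volume reconstructed
from serial histological sections. pcquant implements these measurements
as a tested, scriptable pipeline for people who need the numbers behind
such figures to be reproducible: image analysts replacing interactive
Fiji-style workflows, and method developers who need ground-truthed
benchmarks.

## What it computes

* **Detection** (`detect()`): median/Gaussian/variance pre-filters,
  rolling-ball background subtraction, Otsu/mean/fixed thresholding with
  the user-controlled adjustment *t* = max(*k·t₀*, *t*<sub>min</sub>),
  strict binarization, hole filling, connected-components labeling
  (4/8/6/26), watershed splitting of touching cells, size and ROI filters.
* **Containment** (`containment()`): a protocell is inside a cell iff the
  cell label at its centroid voxel is nonzero; reports % of PCs inside and
  % of cells containing ≥1 PC with exact count conservation.
* **Colocalization** (`classify_marker_positive()`): object positive iff
  its overlap fraction with a marker mask ≥ τ (τ = 1 encodes the "fully
  colocalized" lysosome rule; τ = 0.5 for intact-capsule calls).
* **Tracking** (`link()`): directionally gated linking — admissible links
  lie within a distance gate *and* within ±70° (inclusive) of the flow
  direction — solved as an exact minimum-cost assignment per frame pair;
  instantaneous velocities *v* = ‖Δp‖ · pixel_size / (Δframes · Δt).
* **Areas, growth, volume**: pigmentation and stain-positive area
  fractions, fluorescent pixel counts, tumor area in µm², growth relative
  to the first timepoint, and the Cavalieri volume Σ areaₖ × thickness
  (10 µm sections by default).
* **Synthetic scenes** (`gen_uptake_scene()`, `gen_flow_movie()`,
  `gen_section_series()`, `gen_pigment_image()`): deterministic generators
  that plant known ground truth (containment flags, per-step velocities,
  analytic volumes, dark-pixel fractions) so every stage above is
  verifiable without original imaging data.

## Worked example

Generate an uptake scene at the study conditions (50 cells, 40% loaded
with 1–2 protocells each, snr 20), detect both channels, and score
containment:

```r
library(pcquant)

sc <- gen_uptake_scene(scene_params(n_cells = 50, frac_cells_with_pc = 0.4,
                                    snr = 20, seed = 1))
dp <- uptake_detection_params()
cells <- detect(sc$stack, "cells", dp$cells)
pcs   <- detect(sc$stack, "pcs",   dp$pcs)
res <- containment(cells$labels, pcs)
res$pct_cells_with_pc   # 40        (planted: 40)
res$pct_pcs_inside      # 55        (planted: 55)
sc$truth$pct_pcs_inside # 55
```

`res$per_cell` lists protocell counts per cell and `res$per_pc` each
protocell's inside/outside call with its owning cell. Running the whole
analysis over ten scenes (`Rscript analysis/02_uptake_quantification.R`)
prints:

```
== Uptake quantification (10 scenes, 50 cells, 40% loaded, snr 20) ==
detected cells/PCs per scene: 50-50 / 60-60
% cells containing PCs: mean 40.00 (planted 40)
% PCs inside cells:     mean 49.17 (planted mean 49.17)
max |pipeline - truth| on % PCs inside: 0.000 points
```

i.e. detection recovers every planted object and the containment
percentages match the ground truth exactly at this noise level. The other
numbered scripts under `analysis/` run the tracking, pigmentation, growth
and serial-section analyses the same way and write their tables under
`results/`.

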