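---
title: "Clone morphometrics: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clone morphometrics: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonemetrics)
```

## The scientific problem

When a patch of cells in a packed epithelium acquires a fate that mismatches
its surroundings — a misspecified clone in a *Drosophila* wing disc, for
example — the interface between the two populations often behaves like a
contractile boundary. The minority patch rounds up (its boundary becomes
more circular), its cells constrict apically (smaller apical areas than the
surrounding cells), and junctional actomyosin accumulates along the
heterotypic interface. A physical reading is the Laplace relation: a closed
contractile boundary of line tension $\gamma$ and radius $r$ exerts a
pressure $\Delta P = \gamma / r$ on its interior, so smaller enclosed
patches are squeezed harder ([`interface_pressure()`]).

`clonemetrics` packages the quantitative readouts used to test this picture
on segmented apical surfaces:

* **interface circularity**, the isoperimetric quotient
  $c = 4\pi A / P^2$ of the clone's exterior boundary ($c = 1$ for a
  circle, $\pi/4 \approx 0.785$ for a square, lower for ragged outlines);
* **apical-area statistics**, mean cell area inside the clone versus in the
  surrounding wild-type ring, and their ratio;
* **mixing index**, the mean number of distinct wild-type cells in direct
  junctional contact with a frontline clone cell;
* **contact length**, clone perimeter divided by the number of frontline
  cells;
* **clone-area recovery** within a region of interest and
  **remaining-clone counts** (elimination readouts);
* **interfacial junction-intensity enrichment**, heterotypic over
  homotypic mean junction intensity.

Because no raw imaging data are deposited for this class of experiment, the
package carries a first-class synthetic-tissue generator whose ground truth
exercises every downstream stage, from rasterized image channels through
segmentation to the statistical report.

## The synthetic epithelium

`generate_epithelium()` draws seed points uniformly in a rectangular field
and builds a bounded Voronoi tessellation, relaxed by Lloyd iterations
(seeds moved to cell centroids and re-tessellated). This is a geometric,
not mechanical, model: the analysis measures static geometry, and a
centroidal Voronoi tessellation reproduces the relevant statistical
structure of a packed apical surface (convex polygonal cells, ~6 neighbors,
small area dispersion) at a fraction of the cost of a vertex model, with
exact ground truth.

The tessellation core is a power diagram (weighted Voronoi) computed by
half-plane clipping, compiled in C++. Each cell polygon carries a per-edge
neighbor label, so the adjacency graph and its shared-junction lengths in
µm are exact by construction, clone boundaries are chained exactly from
member-cell edges, and the sum of cell areas equals the field area to
machine precision — an invariant the test suite asserts at 0.1%.

Default study conditions: 400 cells in a 60 × 60 µm field (mean apical
area 9 µm², matching the few-µm² scale of columnar disc epithelia imaged
at high magnification), 3 Lloyd iterations (area CV ≈ 0.1), pixel size
0.1 µm (63×-objective scale), clones of 20 cells, three per tissue.
Contiguous clones grow by random neighbor accretion from a random founder,
constrained to the field interior and non-adjacent to other clones —
separate induction events whose interfaces can all be analyzed. Dispersed
clones draw their cells independently at random, emulating genotypes whose
cells detach and mix. Every stochastic step takes an explicit seed; there
is no hidden RNG state, and all outputs are bit-reproducible.

### Interface compaction

`apply_interface_compaction()` implements apical constriction by
re-tessellating with down-weighted clone seeds. The weight of each clone
cell is iterated toward a per-cell target area (`compaction` × the mean
area of the wild-type ring within graph distance 2) rather than applied as
one global offset — a global offset collapses the smallest clone cell into
an empty power cell long before strong compaction values are reached,
whereas the per-cell iteration reaches area ratios of 0.3 within ~1% while
every cell stays a valid polygon and the tiling stays exact. At
`compaction = 1` the geometry is untouched, so the neutral
(wild-type-clone-like) control is literally the same tissue.

### Boundary smoothing

Interface tension is emulated kinematically: Laplacian smoothing of the
clone's exterior boundary vertices. Vertices are shared between incident
polygons and moved consistently, so the tissue remains a tiling; vertices
on the field border are pinned. A per-iteration guard freezes any proposed
move that would flip a neighboring polygon's orientation or shrink it
below 25% of its original area, which keeps all cells simple under strong
smoothing (λ = 0.3 per iteration; 25 iterations raise a typical 20-cell
clone from circularity ≈ 0.2 to ≈ 0.6, and the increase is monotone in
the iteration count).

A side effect worth knowing: at strong compaction a clone cell
occasionally loses its last junction to the clone body and becomes a
detached fragment. The ≥10-cell circularity gate and the fragment filter
(below) absorb these, which mirrors how small near-clone fragments are
excluded in real analyses.

### Rendering

`render_channels()` rasterizes the tissue (pixel centers at
$(i + 0.5)\,\mathrm{px}$) and emits three channels on a unit intensity
scale: `membrane` (1 on all junction pixels), `clone` (1 inside clone
cells; `"loss"` mode inverts it, for clones identified by loss of a
nuclear stain), and `junction` (junction pixels at 1, heterotypic
junctions multiplied by `interface_enrichment`). Noise is additive
Gaussian, clamped at zero; shot noise, optics blur, and z-artifacts are
deliberately out of scope. Consequently, passing tests demonstrate
correctness of the measurement chain on data whose statistical structure
matches the assumptions — not robustness to every confocal artifact; on
real data the segmentation parameters would need tuning against manual
ground truth. The magnitude of interfacial enrichment in real tissue is
not asserted — the parameter is free, default 2.

## Segmentation

`detect_clone_mask()` follows the blur-and-threshold recipe: Gaussian blur
(default σ = 2.0 px for gain-of-marker detection, σ = 3.5 px for
loss-of-stain detection) followed by Otsu thresholding by default, with a
fixed-value override; the threshold method used is recorded in the
returned object since the original protocol specifies only
"intensity-based thresholding". No hole-filling or size filtering is
applied by default.

`segment_cells()` re-implements junction-based cell segmentation as a
seeded watershed: the blurred membrane channel is thresholded (Otsu), cell
interiors are the dark regions, seeds are distance-transform maxima, and
the watershed partition is propagated across the membrane ridge so the
label image tiles the frame. Regions below `min_cell_area_um2` merge into
the neighbor with the longest shared contact. The pre-watershed blur
default is 0.5 px, chosen for crisp junctional signal where heavier
blurring measurably displaces boundaries; it is a parameter, not a claim
about all data. Validation is against generator ground truth, not against
any external toolkit: on noise-free renders of 400-cell tissues, 100% of
cells match one-to-one with Jaccard ≥ 0.8, ≥90% of adjacency edges are
recovered, and all clone metrics agree with ground truth within 5%.

Cell polygons of segmented tissues are traced from the label image and
smoothed with a short circular moving average (window ≈ 0.4 µm) so pixel
staircasing does not inflate perimeters; rasterized boundaries may exceed
the isoperimetric bound by at most 2%, and the tests assert exactly that
ceiling. Cells touching the image border are flagged and excluded from
per-cell area statistics and clone shape metrics (their polygons are
truncated).

The "apical projection" of image stacks is approximated by
maximum-projecting the n brightest membrane slices
(`apical_project()`) — a surrogate for surface-following selective-plane
projection, which would require fitting the apical surface and is out of
scope. For apically concentrated signal the brightest slices are the
apical ones, and the tests pin the selected slice indices on synthetic
stacks.

## Graph metrics and their conventions

Clones are connected components of same-label cells on the adjacency
graph; contact requires a shared junction of positive length (vertex
touches do not count). Components below `min_cells = 10` are kept but
flagged, and circularity is only reported for clones above the gate.
Circularity and perimeter use the exterior boundary only; enclosed
wild-type islets are reported as holes. Frontline cells are clone cells
with at least one heterotypic junction.

Two conventions are deliberate choices where the field's usage is loose:

* **Mixing-index aggregation.** The per-cell quantity (number of distinct
  wild-type contacts of a frontline cell) is aggregated per clone by the
  arithmetic mean; the maximum is also exported
  (`clone_metrics_table()$mixing_index_max`). The mean is robust to one
  unusual frontline cell, and on lattice fixtures both agree with
  enumeration (single hexagonal cell → 6; 7-cell rosette → 3).
* **"Surrounding bulk".** The outside-area sample is the wild-type,
  non-border cells within graph distance `k = 2` of the clone. One ring is
  sensitive to the immediate interface deformation that compaction itself
  induces; two rings approximate the local bulk while staying local. `k`
  is exposed everywhere.

The fragment filter removes 1–10-cell clones whose boundary lies within
20 µm of a ≥10-cell clone — presumed split-offs — and never anything at or
above the size gate. The 20 µm proximity is a documented default (the
original exclusion rule states no distance), exposed in configuration.

## Statistics

Comparisons use the unpaired two-sided Wilcoxon rank-sum (Mann–Whitney)
test via `stats::wilcox.test`: exact permutation p-values when the pooled
sample is ≤ 12 without ties, otherwise the normal approximation with tie
and continuity corrections. The exact branch matches a full enumeration
oracle to machine precision in the tests, and its simulated type-I error
at nominal 0.05 is ≈ 0.04 (discreteness makes it conservative).
Significance tiers: `ns` for p ≥ 0.05, then `*`, `**`, `***` at 0.05,
0.01, 0.001; the boundary p = 0.05 is not significant. No multiple-testing
correction is applied, matching per-comparison reporting. Box summaries
use type-7 (linear interpolation) quartiles and 1.5 × IQR whiskers, with
points beyond the whiskers listed as outliers. Cell-area heatmaps use a
fixed diverging scale, deep red at 0.2 µm² to light green at 12 µm², so
panels are comparable across runs.

## The pipeline

`run_simulate()` / `run_pipeline()` tie the stages together under a YAML
config with named scenarios (`neutral`, `compacted`, `dispersed`,
`enriched`), persisting every intermediate (tissue JSON, multi-channel
TIFF, 16-bit label TIFF, per-clone CSV, comparisons CSV, Markdown report)
and skipping stages whose configuration hash matches a previous run, so a
rerun from the quantification stage reuses cached simulations and is
byte-identical. Unknown configuration keys fail validation by name.

Problem sizes used by the test suite and the acceptance script — 400-cell
tissues, 10 tissues per arm (≈ 30 analyzable clones per arm), 5 seeds per
compaction target, 2,000 null draws for the type-I simulation — were
chosen as the smallest sets at which the distributional checks are stable
across seeds.

## Known limitations

* Geometry only: no mechanics, no apoptosis or extrusion, no time
  evolution, no 3D; the generator cannot say anything about *why*
  interfaces smooth, only whether the pipeline measures smoothing
  correctly.
* The Voronoi cell-shape ensemble is more regular than stressed epithelia;
  dispersal is modeled by label assignment, not by cell rearrangement.
* The apical-projection surrogate ignores surface topography.
* Enrichment magnitudes, the neighborhood radius, and the fragment
  proximity are conventions exposed as parameters, not biological claims.
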