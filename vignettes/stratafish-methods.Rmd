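---
title: "Laminar spatial analysis of imaging spatial transcriptomics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Laminar spatial analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

stratafish analyses imaging-based spatial transcriptomics (e.g. MERFISH) of
layered tissue, with the mouse retina as the motivating system: three nuclear
layers (ONL, INL, GCL, apical to basal) curved around a tissue center, each
populated by distinct major cell classes and their molecular subtypes. This
vignette is the package's own account of the models it implements, the
tunable parameters, the numerical choices, and what the synthetic validation
does and does not demonstrate.

## Dual-segmentation fusion and quality control

Membrane-stain segmenters perform unevenly across retinal layers, so the
pipeline consumes two candidate polygon sets: a primary set (good in the
outer layers) and a rescue set (good in the ganglion cell layer). All
primary polygons are kept; a rescue polygon is added only when its area
overlap with the union of primary polygons, divided by the rescue polygon's
own area, is strictly below `overlap_threshold` (default 0.001, i.e. 0.1%).
The normalizing denominator is a genuine choice — the rule decides the
rescue polygon's fate, so its own area is the default — and the primary-side
denominator is available via `denominator = "primary"`.

Intersection areas are computed exactly by Sutherland–Hodgman clipping
against a convex clip region, with ear-clipping triangulation when the clip
ring is non-convex (triangles partition the ring, so areas add). Overlap
against the *union* of primaries uses pairwise inclusion–exclusion, which is
exact whenever no point is covered by three or more primary polygons;
segmentation outputs are near-disjoint, so this is the regime that matters.
Fractions within 1e-6 (relative) of the threshold are treated as exactly at
it, so clipping round-off cannot flip the strict `<` rule.

Each retained cell passes five inclusive interval filters: mean DAPI
intensity ≥ 80, minimum-enclosing-circle radius in [10, 80], polygon area in
[500, 10,000], perimeter in [50, 400] (all geometric quantities in image
pixels — these bounds are pixel-scale quantities, not micrometers), and at
least 10 assigned transcripts. The enclosing circle is exact (Welzl's
move-to-front algorithm); area is the unsigned shoelace value. DAPI means
are inputs: image processing is out of scope.

Decoded transcripts are assigned to the containing polygon, otherwise to the
polygon with minimal boundary distance. Candidates are retrieved from a
uniform grid over polygon centroids and the pool expands ring by ring until
the best distance is certified minimal (any unexamined polygon is at least
its centroid distance minus the maximal polygon radius away). Exact ties go
to the lexicographically smallest cell id. There is no maximum-distance cap
by default; `max_dist` provides one.

## Alpha-shape boundary estimation and normalized depth

Layer boundaries are estimated from cell centroids by the alpha-shape with
`alpha = 100` µm, the radius at which the boundary tracks the tissue edge
tightly at native retinal curvature. A centroid is *alpha-extreme* when an
open ball of radius alpha has it on the boundary and contains no other
centroid; edges connect extreme pairs admitting an empty witness ball
through both. Both tests are exact: the extreme test reduces to whether open
"forbidden" arcs cover the circle of candidate ball centers (decided by a
wrap-aware sweep over sorted arcs), and edge emptiness is checked against
every point. The test suite holds an independently written brute-force
oracle (endpoint-coverage formulation) and the two must agree exactly.

Only the largest closed component of the edge graph is retained — one tissue
section has one outer boundary. An arc-shaped section's chain runs along the
outer (apical) edge, around the cut ends, and back along the inner (basal)
edge.

The section's hypothetical center is a least-squares circle fit of all
centroids. We use the Taubin algebraic fit rather than the simpler Kåsa
normal equations: for a band whose thickness is an appreciable fraction of
its radius and which spans only part of a circle, the Kåsa fit is biased
toward small radii by hundreds of micrometers, while the Taubin fit stays
within ~1% of the radius. Collinear input falls back to the centroid with a
warning.

Edges are classified by the witness ball: apical when the empty witness
center lies radially farther from the tissue center than the edge midpoint,
basal when nearer. Edges in the angular tails of the section
(`lateral_fraction` = 0.025 per end) are lateral cut faces and excluded;
single-pass majority smoothing repairs isolated disagreements, replacing the
interactive curation a human would do on a handful of arcs. Distances use
the straight edge segments; classification uses the arc (witness) geometry.

Normalized laminar depth is `d_apical / (d_apical + d_basal)`. The package
defaults to the apical-referenced reading (0 = apical boundary), so "the top
20% of the layer" is `depth_ratio <= 0.2`; `from = "basal"` flips the
convention, and both raw distances are always returned. Cells equidistant at
zero (on both chains) are flagged rather than given a ratio.

One geometric constraint is worth spelling out: an empty ball of radius 100
µm cannot fit inside a concavity of radius below 100 µm, so the basal chain
of a band is only recoverable when the tissue's inner radius exceeds alpha.
Validation fixtures therefore sit at realistic retinal curvature (bands at
roughly 900–1100 µm), where alpha = 100 µm behaves exactly as it does on
real sections.

## Amacrine layer assignment and the displacement test

An amacrine cell (AC) is assigned to the INL when it lies radially outward
of its nearest point on the INL basal chain, to the GCL otherwise; cells
radially beyond the apical chain are flagged `outside`. The boundary is
first estimated from the unambiguous INL-resident majors (BC, HC, MG).
Because AC somata dominate the basal INL stratum, that first chain sits
slightly inside the true edge; `assign_ac_layers()` therefore rebuilds the
alpha-shape including the ACs currently assigned to the INL and reassigns
(one pass by default). The plexiform gap between INL and GCL keeps the
refinement from crossing layers. On synthetic sections this yields ≥ 99%
agreement with ground truth away from the chain itself.

Displacement significance uses a within-section permutation test: subtype
labels are shuffled within each section (layer labels fixed), 1000 times by
default, and the p-value is the fraction of permutations whose null GCL
proportion strictly exceeds the observed one. A subtype is called displaced
at p < 0.05 with at least `min_cells = 10` cells. The plain estimator can
return exactly 0; a conservative `(k+1)/(n_perm+1)` variant is exposed. The
shuffle permutes AC subtype labels only — the test population is the ACs.
Under exchangeable labels the test is calibrated: across 500 null
replicates the empirical type-I error at 0.05 stays within its binomial
band and the p-values are near-uniform. Because GCL counts are integers,
null proportions tie with the observed one and the strictly-greater
estimator leans very slightly liberal (ties shrink p); the mid-p tie
correction recovers exact uniformity, and the conservative
`(k+1)/(n_perm+1)` variant is available when a guaranteed-valid p is
preferred.

## Regional composition

Oriented sections (posterior side up) are split at the midpoint of the x
range; the left/right halves map to anatomical regions (dorsal/ventral or
temporal/nasal) through explicit metadata, never guessed from coordinates.
Per section and region, unit proportions are computed either over all cells
or within the unit's major type, and the two regions are compared by a
two-sided two-sample t-test across sections (significance at 0.05).
Laminar-position differences between subtypes are tested pairwise on
per-section mean depths with Benjamini–Hochberg adjustment; per-subtype
box-plot summaries use the 1.5 × IQR whisker convention.

## Label transfer and cell-type-restricted imputation

The co-embedding itself (e.g. canonical-correlation alignment of imaging and
scRNA-seq profiles) is an input, not computed here; the synthetic generator
supplies latents for both modalities drawn from the same per-subtype
Gaussians, emulating a successful co-embedding in d = 15 dimensions.

Label transfer trains a linear multi-class SVM (one-vs-one, pairwise-coupling
probability calibration, seed-fixed) on reference latents and labels. Each
query cell is represented by the mean latent of its k = 3 nearest reference
neighbors (Euclidean) and takes the label with maximum class probability.
The SVM kernel and calibration scheme are package decisions — validated by
synthetic recovery, not prescribed by any upstream method.

Imputation estimates a query cell's full transcriptome as a weighted sum of
reference expression over its k = 30 nearest reference cells **of the same
cell type** (major type by default; pass subtype labels for a finer
restriction). Kernel mode uses Gaussian weights with per-cell bandwidth
equal to the median candidate distance, normalized to the simplex. Fit mode
re-optimizes the per-cell simplex weights (softmax parameterization,
monotone backtracking gradient ascent) to maximize the mean per-gene Pearson
correlation between imputed and measured panel genes, starting from the
kernel solution — so it never scores below kernel mode on that objective.
Convergence is declared when the objective improves by less than 1e-5, with
a 50-iteration cap. Weights structurally never cross the type restriction;
query types absent from the reference are flagged and left unimputed.
Evaluation reports per-gene Pearson correlations across cells, excluding
zero-variance genes from the medians.

## The synthetic generator

The generator is first-class, tested code; its defaults are the study
conditions everything else is validated under:

* geometry: arc bands at native curvature — GCL [800, 825] µm, INL
  [835, 895] µm, ONL [905, 975] µm around the center, spanning π/4–3π/4, with
  plexiform gaps between bands;
* scale: densities (0.04/0.08/0.10 cells/µm² for GCL/INL/ONL) give
  ~18,000 cells per section, matching the per-section scale of a MERFISH
  retina experiment, and counts are Poisson around subtype profiles scaled
  to 80 transcripts per cell over a 300-gene panel within a 400–500-gene
  universe;
* composition: per-layer major-type mixes (rod-dominated ONL; BC/AC/MG/HC
  INL; RGC GCL) and within-major subtype abundances, with the rod bipolar
  (RBC) share of BCs 35% in the dorsal half and 30% in the ventral half;
* laminar structure: per-subtype depth laws are Beta distributions on the
  normalized layer depth — bounded on [0, 1] and able to reproduce both
  apical skews (RBC, Beta(2, 8)) and basal skews (BC1B-like, Beta(6, 4));
  the real per-subtype depth families are unknown, so Beta is a stand-in,
  not an inference about the data. Müller glia and one BC subtype span the
  full depth so the basal INL stratum is populated by boundary-informative
  majors, as it is in tissue;
* displacement: each AC is displaced into the GCL with its subtype's
  probability — 0.05 background for nine subtypes and 0.2/0.5/0.8 for three
  seeded subtypes, spanning the 20–85% range characteristic of genuinely
  displaced amacrine types;
* expression: log-normal baseline per gene, per-major marker blocks (8
  genes, ×10) and per-subtype markers (2 genes, ×8), plus pervasive
  log-normal subtype variation (σ = 0.6) so held-out genes carry
  subtype-discriminating signal, as transcriptome-wide differences do;
* latents: subtype means placed by maximin sampling with ≥ 6σ pairwise
  separation (σ = 1), shared between the section and the reference;
* segmentation fixtures: 12-gon polygons in pixel coordinates (9.26 px/µm)
  sized so QC thresholds bite, plus a constructed block of square pairs with
  exact, recorded overlap fractions; spots scattered uniformly inside each
  cell's polygon per the count matrix; DAPI ~ Normal(150, 40) truncated at 0.

Counts are Poisson (no overdispersion): MERFISH panel counts are small and
the simplest noise model exercises every pipeline stage. Everything is 2D;
the analysis operates on 2D centroids.

What passing on this generator shows — and what it does not. It shows the
geometry is exact (against brute-force oracles), the permutation test is
calibrated, seeded effects at realistic sizes are recovered, and the
transfer/imputation machinery is correct under a faithful co-embedding. It
does not show robustness to segmentation artifacts beyond the modeled ones,
to batch effects or a failed co-embedding (latents are shared by
construction), to overdispersed counts, or to depth laws outside the Beta
family. Real-data performance inherits the upstream tools' quality.

## Problem sizes and numerics

Validation uses the sizes at which the properties are informative but the
suite stays fast: 200 random instances (n ≤ 60) for the geometry oracles, a
2000-cell band for boundary recovery, 500 replicates × 1000 permutations for
calibration, three ~18k-cell sections for displacement recovery, 5000/2000
reference/query cells for transfer, and one full-scale section for the
end-to-end run. Tolerances: depth MAE < 0.05 against radial truth;
displacement ratios within ±0.05; transfer accuracy ≥ 0.95; held-out
imputation median PCC ≥ 0.8.

Numerical tie-breaks are explicit throughout: strict `<` at the merge
threshold with a 1e-6 relative equality band; lexicographic cell-id
tie-break in spot assignment (1e-9 relative distance band); open-ball
emptiness with a 1e-9·alpha slack so the defining points of a witness ball
never block it; ambiguous both-empty edges resolved by chain smoothing.
Degenerate inputs (collinear point sets, zero-area rings, cells on both
chains, all-zero cells, single-class training labels) are rejected or
flagged, never silently guessed.

## Known limitations

Pairwise inclusion–exclusion makes union overlaps approximate if primary
polygons triple-overlap (warned when detectable). The alpha value must be
below the tissue's inner radius of curvature or the basal boundary cannot
exist. The quadrant split assumes the section was rotated posterior-up and
divides at the x midpoint — asymmetric sections need the recorded rotation.
The fit-mode imputation objective is non-convex; the optimizer guarantees
monotone improvement over the kernel start, not a global optimum.
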