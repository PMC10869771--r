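---
title: "Methods: models, conventions and design choices in spatialniche"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, conventions and design choices in spatialniche}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatialniche)
```

This vignette documents the statistical models, geometric conventions and
numerical choices behind `spatialniche`, in the spirit of a methods
section: what is computed, under which assumptions, and why the defaults
are what they are.

## Data model and QC

The package operates downstream of transcript-to-cell segmentation. A
dataset is a `spatial_cell_set`: a per-cell table (centroid in µm,
segmentation statistics, optional type), optionally the per-molecule
table it came from, and a gene-by-cell sparse count matrix whose columns
correspond one-to-one to the cells. Coordinates are continuous µm
positions throughout; integer indices exist only for grid tiles and
spots, and both are 1-based. `cell_id = 0` is the reserved id for noise
(unassigned) molecules, matching the common segmenter convention; every
operation ignores such molecules except where "unassigned" is itself the
quantity of interest.

QC retains a cell only if its transcript count **strictly exceeds**
`min_transcripts` (default 5, i.e. at least 6 molecules). The strict
inequality is deliberate and tested; the threshold is configurable. Area,
elongation and confidence gates exist but are **off by default**: useful
values depend on the segmenter, magnification and tissue, and a permissive
default is safer than an invented one. The filter never modifies retained
rows; it only subsets, and it attaches a report
(`n_in = n_retained + n_removed`, per-gate removal counts; a cell failing
several gates is counted in each).

Cell typing assigns each cell the modal molecule-cluster label of its
molecules. Ties are broken by lexicographic order of the label strings —
a deterministic, seed-free rule chosen for reproducibility; any other
deterministic rule would serve, but this one is trivially auditable.
Cells with no labeled molecule receive an explicit `"unlabeled"` value
rather than being dropped.

## Organ coordinates

The organ frame is an outer boundary plus a user-chosen origin (for
kidney sections, the papilla center). The position of a cell `p` is then

* **depth** `d = |p − b| / |o − b|`, where `b` is the **first
  intersection of the ray from the origin `o` through `p`** with the
  boundary — 0 at the capsule, 1 at the origin;
* **angle** `atan2(p_y − o_y, p_x − o_x) ∈ (−π, π]`.

The ray-intersection convention was a genuine design decision: a
plausible alternative measures the distance to the *nearest* boundary
point. We chose the ray form because numerator and denominator then refer
to the same boundary point, which guarantees `d ∈ [0, 1]` for interior
points, makes depth exactly `1 − r/R` for a circle with concentric origin,
and makes depth strictly monotone along any ray from the origin. The
nearest-point variant is available via `method = "nearest"` for
comparison, without those guarantees and without any claim of equivalence.
Conventions for degenerate inputs are fixed and tested: a point at the
origin gets depth 1 and angle 0; points outside the boundary are clamped
to depth 0, flagged in the `outside` column, and counted in an attribute.

The boundary can be supplied as a polygon, estimated from the cell cloud,
or given as an exact parametric circle. The estimator is an alpha shape
built from the classic empty-disc edge test (an edge joins two points at
distance ≤ 2α when one of the two α-discs through them contains no other
point), with candidate generation on a uniform grid hash; at `α = ∞` the
test degenerates to the half-plane test and the result is exactly the
convex hull. The default `α` is **3× the median nearest-neighbor
spacing** — scale-adaptive, so the same default works in px-sized toy
examples and mm-sized sections. If a clean single ring covering ≥ 99% of
the points does not emerge, α is grown by 1.5× (up to six attempts) before
falling back, with a warning, to the convex hull. Multi-lobed organs and
tissues with holes are out of scope: the boundary is a single outer ring.
The origin is never auto-picked; `suggest_origin()` proposes the centroid
of a named cell type (e.g. urothelium) and the caller decides.

Depth profiles bin `[0, 1]` into `n_bins` equal-width bins
(`findInterval`, right-closed at 1) and report per-bin category counts and
within-bin proportions. Empty bins carry count 0 and proportion `NA` —
never NaN from 0/0.

## Proximity statistics

Two readouts cover the two regimes seen in tissue. For **localized**
populations (glomerular cell types), cell-centric readouts: the distance
from each reference cell to its nearest target-type cell (self excluded
when the types coincide), and multi-scale density profiles — count,
areal density `count/(πr²)`, or composition fraction at radii `r`, or the
target fraction among the k nearest cells. For **diffuse** populations
(immune cells, fibroblasts), pair enrichment: among all unordered cell
pairs within radius `r`, the fraction of the given type pair, divided by
the mean of the same fraction under `N` random permutations of the type
labels over the fixed positions.

Conventions, each a deliberate choice:

* unordered pairs, self-pairs excluded — symmetric by construction, so
  the result for (A, B) equals (B, A) exactly;
* default radius 50 µm — the cell-contact-scale searching area
  conventional for this assay in kidney sections;
* `N = 1000` permutations by default, `p = (1 + #{null ≥ obs}) / (1 + N)`
  — the additively smoothed permutation p-value, whose smallest
  attainable value `1/(N+1)` is itself a useful positive-control check;
* **no edge correction**: the null permutes labels over the same
  geometry, so boundary effects cancel in the ratio. This is documented
  rather than corrected because the ratio — not the raw pair probability
  — is the reported statistic;
* the neighbor-query contract is exactness: any acceleration structure
  must return the brute-force set, and tests enforce agreement with an
  O(n²) oracle. The shipped implementation *is* a (chunked) brute force,
  which is entirely adequate at the 10³–10⁴-cell scale of segmented
  fields of view;
* same-type pairs for a type with fewer than 2 cells are flagged
  `insufficient` rather than silently reported.

The rank-sum test computes U from joint midranks. For total `n ≤ 20` the
two-sided p is exact by complete enumeration of all `choose(n, n_a)`
group assignments (ties included), `p = min(1, 2·min(P(U ≤ u),
P(U ≥ u)))`; identical samples therefore give exactly `p = 1`. Larger
samples use the normal approximation with continuity and tie correction.
Both branches are cross-checked against `stats::wilcox.test` in the test
suite; the in-package implementation exists because the exact path must
handle ties, which the standard exact routine refuses.

## Registration and spot integration

Registration is **landmark-based least-squares similarity** (rotation,
optional isotropic scale, translation) — the operational form of
"align vertically, rotate to overlap". In 2D the orientation-preserving
fit is a complex linear regression `dst ≈ a·src + b` with
`a = s·e^{iθ}`, solved in closed form; this also behaves correctly for
the minimal 2-landmark case. The orientation-reversing model
(`dst ≈ a·conj(src) + b`) is fitted alongside, and when it explains the
landmarks strictly better the input is rejected with an error:
reflections are forbidden by contract, because a reflected "alignment" of
serial sections almost always signals a landmark-pairing mistake.
The RMS landmark residual is attached to every fit.

Cells and transcripts are binned onto a spot grid by **nearest spot
center**, with ties broken by smallest spot id. By default there is no
distance cutoff, matching the "closest spot it lies within" reading; an
optional `max_distance` (a natural choice is `pitch/2`) is exposed
because a cell midway between 55 µm spots does not physically lie in any
spot. Grid geometry (square or hexagonal) is taken from the positions
table, never assumed. Per-spot composition is then a direct count: spots
with no cells are flagged empty and excluded from proportion tables
rather than producing 0/0.

Deconvolution benchmarking computes Pearson r between measured and
predicted proportions. Because it is genuinely ambiguous which scope such
a comparison should use, the report always contains **all three, named**:
pooled over all spot × type entries, per type across spots, and per spot
across types. Zero-variance vectors yield `NA` with an explicit reason.
Type names are harmonized only through an explicit two-column mapping —
never fuzzy string matching.

## The synthetic tissue generator

The simulator emulates the *inputs* of the pipeline, with recorded ground
truth: a circular organ of radius `R` (default 1500 µm) with concentric
depth zones (cortex `[0, 0.35)`, medulla `[0.35, 0.7)`, papilla
`[0.7, 1]`); per type, a homogeneous Poisson number of cells (default
intensity 6×10⁻⁵ cells/µm², ≈ 2300 cells in the default section) placed
uniformly in the type's zone annulus; per cell, per-gene Poisson
transcript counts from the type's expression program (default: 200 genes,
3 markers per type at mean 3, background mean 0.05 — ≈ 20 molecules per
cell), scattered uniformly in a 5 µm disk around the centroid; uniform
noise molecules at 5×10⁻⁴ /µm² with `cell_id = 0`; optional flipping of a
fraction of molecule-cluster labels; and 12-gon cell outlines. The
default 13 types and the planted monocyte/failed-repair-PT and
podocyte/glomerular-EC niche pairs mimic a kidney section qualitatively;
they are a documentation device, not a claim about real data.

All randomness flows through one named generator (Mersenne-Twister,
inversion normals, rejection sampling) seeded explicitly per call, with
the caller's RNG state restored — fixed seeds therefore reproduce outputs
byte for byte across platforms, which the suite verifies at the file
level. What the generator deliberately does **not** emulate: gene–gene
covariance and dropout structure, segmentation errors (mis-assigned
molecules beyond uniform label flips), anisotropic cell shapes, and 3D
effects. Tests passing on this generator therefore validate geometry,
bookkeeping and statistical calibration — not robustness to real
segmentation noise.

## Problem sizes and runtime choices

The shipped tests and the acceptance script run at deliberately desk-size
scales — sections of radius 300–800 µm (≈ 150–900 cells), 1000-point
geometry checks, 1000-permutation nulls on 360–1000 cells — chosen so the
whole suite completes in well under a minute while every statistical
check retains comfortable margins (e.g. the CSR calibration bound of 3
null SD, or 3 standard errors for generator means). Scaling the same code
to full sections (10⁴–10⁵ cells) is a matter of runtime, not of different
code paths; the only quadratic-memory step, pairwise distance formation,
is chunked.

## Known limitations

* Boundary estimation assumes a single, simply-connected outer ring;
  hollow or multi-lobed sections need a user-supplied polygon.
* Pair enrichment conditions on the global set of close pairs; it is not
  conditioned per reference type, and permutation counts make the
  smallest attainable p `1/(N+1)`.
* The registration model is similarity-only: no shear, no non-rigid
  warping. Sections that deformed during handling will register with a
  visible residual, which is reported but not corrected.
* The benchmark harness evaluates externally produced deconvolution
  predictions; it does not implement any deconvolution method itself.
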