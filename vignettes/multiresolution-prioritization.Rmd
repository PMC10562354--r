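---
title: "Methods: multi-resolution conservation prioritization on synthetic forest landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-resolution conservation prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(priorigrid)
```

## The question the package answers

Spatial conservation prioritization ranks the cells of a landscape by their
joint importance for a set of biodiversity features, so that the top-ranked
fraction of cells forms a candidate protected-area network.  The input
features come as raster layers, and the raster resolution decides how much
of the landscape's fine structure survives into the analysis.  Sparse,
scattered features — a rare tree species occurring as single stems, thin
lines of downed deadwood — can dissolve into the surrounding forest matrix
when cells are aggregated, while common, evenly spread features are barely
affected.  `priorigrid` builds a controlled, fully synthetic test bed for
that effect: it simulates an object-level boreal forest landscape, turns it
into stratified feature rasters at a 16 m baseline, re-runs the same
prioritization at five coarser resolutions, and measures what coarsening
does to the selected areas and to each feature's protection.

## The prioritization model

Each feature $j$ enters as a raster layer with landscape total $T_j$; cell
$i$ holds share $q_{ij} = x_{ij}/T_j$.  When a set of cells is protected,
feature $j$'s protected fraction is $r_j = \sum_{i \in \text{protected}}
q_{ij}$, and its conservation benefit is the concave power law

$$v_j(r_j) = r_j^{\,z}, \qquad z = 0.25,$$

the exponent following the species–area relationship.  Benefits are
additive across features, so a candidate landscape state is worth
$\sum_j w_j r_j^z$ (all weights $w_j = 1$ by default).  The ranking is
built by greedy reverse deletion: starting from the full landscape, the
cell whose removal loses the least total benefit,

$$\delta_i = \sum_j w_j \left( r_j^z - (r_j - q_{ij})^z \right),$$

is removed, the $r_j$ are updated, and the process repeats until no cells
remain.  The $k$-th removed cell of $N$ receives rank $k/N$, so the
highest-priority cell has rank 1 and any top fraction is nested inside
every larger one.  Concavity ($z < 1$) is what produces rarity preference:
a cell holding all of a rare feature is more expensive to delete than a
cell holding most of a common one, which `rank_cells()`'s two-cell example
demonstrates.

Two implementation paths exist internally: the definitional one
(recompute every cell's loss from scratch each iteration) and an
incremental one that rescores only cells holding a feature whose $r_j$
changed.  The incremental path is the production code; the test suite
checks exact agreement of the two on hundreds of small random stacks,
because that equivalence is the correctness argument for the cache.
A `warp` batch size > 1 removes several cells per iteration for speed;
the default is 1 (exact greedy).

Ties — above all the loss-0 ties among cells with no feature value — are
broken lexicographically by (row, column) by default, making the ranking
fully deterministic; a seeded random tie rule is available because the
reference software's internal order is unspecified.

## The synthetic landscape generator

The generator reproduces the statistical structure that the resolution
experiment needs, with defaults fixed to the study conditions:

* **Site-fertility classes** (f1 herb-rich, f2 mesic, f3 sub-xeric,
  f4 low-productive) with area shares 32.4 / 51.1 / 15.6 / 0.9 %.  A
  Gaussian-smoothed white-noise field is thresholded at the empirical
  quantiles implied by the shares, which guarantees the achieved shares to
  within one cell and makes each class spatially contiguous; the rare f4
  class sits in the upper tail of the field and therefore forms a few
  continuous patches rather than isolated cells.  The `smoothness`
  parameter (metres, default 80) sets the patch size.  The original survey
  classification is replaced by this field because exact share control and
  patch contiguity are the two properties the analysis depends on.
* **Four tree species groups** calibrated so landscape volume shares
  approximate 40 % spruce, 35 % pine, 17 % birch, 5 % aspen.  Spruce,
  pine and birch are clustered (Thomas process: Poisson cluster parents,
  Poisson offspring counts, 15 m Gaussian dispersal, parents drawn in a
  buffered window so edge cells are not depleted); aspen is a homogeneous
  Poisson scatter at low density — single stems, the sparse, scattered
  feature whose fate the experiment tracks.  Densities are modulated
  across site classes by affinity multipliers and realised by thinning,
  which yields the exact inhomogeneous intensity.  Default stem density is
  about 290 stems/ha across the four groups, a realistic dominant-canopy
  density for managed boreal forest, with aspen kept below a tenth of
  spruce's stem count.
* **Tree sizes.** Heights are truncated normal (default truncation 2–40 m,
  species-specific means 15–22 m).  DBH follows the power law
  $d = a\,h^b$ and stem volume the form-factor cylinder
  $v = c\,d^2 h \cdot 10^{-4}$.  These are deliberate placeholders: the
  published Finnish species-specific equations are not reproduced here, so
  the coefficients live in `species_params()` where users can substitute
  them.  Only monotonicity and realistic magnitudes matter for the
  resolution experiment.
* **Downed deadwood (DDW)** as line segments: Poisson midpoints (12 per
  hectare by default), uniform orientation, lognormal lengths (mean
  ~6 m), truncated-normal diameters (mean 18 cm), cylinder volumes
  (~2 m³/ha).  No spatial clustering is imposed on DDW — nothing in the
  study system pins its point pattern down, so the neutral uniform Poisson
  is used and exposed for change.  A segment whose endpoints would leave
  the extent has its position and orientation redrawn, which keeps the
  rasterized volume balance exact.

What the generator does **not** emulate: detection error of remote-sensing
pipelines (omission/commission bias of treetop or trunk detection),
correlation between tree size and site class, stand-level management
structure (clear-cut boundaries, even-aged stands), and standing dead
trees as a separate category.  Passing tests therefore show that the
*analysis chain* behaves correctly and that the coarsening effect follows
from spatial sparsity alone; they do not validate any particular remote
sensing product.

## From objects to feature stacks

Trees are binned into 16 m cells (half-open cell intervals, origin
top-left; objects on the far edge are clamped into the last cell).  Per
cell and species the layers are `Hmax` (tallest tree, m), `Hmean`
(arithmetic mean height, m) and `Vol` (summed stem volume, m³).  DDW
segment volumes are split across cells proportionally to the clipped
within-cell length, so cell sums conserve object totals to rounding.
Each of the 13 variables is then stratified by site class — the class-c
layer equals the input where the cell's class is c, zero elsewhere —
giving the 52-layer baseline stack (13 × 4).

Empty cells carry 0 rather than NoData inside the landscape.  That choice
makes coarse-block means and sums well defined everywhere; it also means
`Hmean` at coarse resolutions is a block mean over *all* fine cells,
including empty ones.  Whether empty cells should instead be excluded from
the mean is a genuine convention choice; the alternative
(`mean_rule = "mean_nonzero"`) is implemented and off by default.

## Aggregation

Coarse stacks at 32, 48, 64, 80 and 96 m are produced from the 16 m
baseline by block aggregation with the variable-bound rules: `Hmean` by
block mean, `Hmax` by block maximum, `Vol` and `DDWVol` by block sum (sum
conserves landscape totals exactly, which the tests assert at 1e-9).
Every coarse stack derives directly from the baseline, never by chaining
through intermediate resolutions, so the max rule has no path dependence.
The default extent is a multiple of 960 m — the least common multiple of
the six cell sizes — so every resolution tiles the landscape exactly and
no partial-block edge rule is needed.  With 52 layers at six resolutions
the pyramid holds 312 layers (288 living-tree, 24 DDW).

## Evaluating the coarsening error

Each resolution is ranked independently, and the top 2 % and 10 % of
cells are selected (ceiling cell counts, so a coarse selection may exceed
the nominal fraction by up to one cell; the footprint cell count is
reported alongside).  Coarse selections are expanded to the 16 m lattice
— one coarse cell becomes its $(R/16)^2$ constituent baseline cells — and
compared with the baseline selection:

* **Spatial error**: overlap = shared area / baseline-selection area, and
  error of omission = 1 − overlap.  Normalising by the baseline area is
  the only convention under which the two sum to 1, which is the identity
  the report maintains.
* **Conservation error**: per feature, protected sums are evaluated **on
  the baseline data** inside each mask, and the error is the relative
  change (coarse − baseline)/baseline — negative when the coarse solution
  protects less of the feature than the baseline solution.  The baseline
  solution's protected sum is the reference, not each feature's
  theoretical best-case selection; that reading is consistent with how the
  comparison is defined, though "highest attainable protection" could
  also be read per-feature.  Features with a zero baseline protected sum
  are flagged undefined instead of propagating NaN.

## Numerical choices

* Remaining fractions are clamped at 0 after subtraction; a share
  exceeding its remaining fraction by more than 1e-9 raises an internal
  consistency error rather than silently clamping.
* Zero-total features carry no ranking information and are dropped with a
  warning; an all-zero stack is an error.
* Ranks $k/N$ are compared with the threshold $(N-m)/N$ computed from the
  same integers, so top-fraction membership involves no floating-point
  ambiguity.
* ASCII-grid rasters are written with 17 significant digits, which
  round-trips doubles exactly; report CSVs carry the seed and a hash of
  the configuration so re-runs are byte-comparable.

## Problem sizes

The package's own experiments run on a 960 × 960 m landscape — 3600
baseline cells, about 27 000 stems and 1100 DDW segments — which is large
enough for the rare class (~32 f4 cells) and rare species to exist in
every replicate while a full six-resolution experiment completes in a few
seconds.  The seed-averaged acceptance experiment uses ten replicates at
resolutions 16/32/96 m, the three needed for the coarsening contrast.
Property suites run on enumerable stacks of at most 12 cells where the
greedy oracle is affordable.

## Known limitations

* The greedy reverse deletion is the additive-benefit rule only; core-area
  ranking, connectivity transforms, condition layers and hierarchical
  masks of full prioritization software are out of scope.
* Conservation errors on a synthetic landscape are seed-averaged
  tendencies; single seeds can deviate, and per-seed monotonicity of
  overlap across all six resolutions is not guaranteed (nor asserted).
* The allometries are placeholders; absolute volumes are realistic in
  magnitude but not species-accurate.
* Rasters carry no CRS; coordinates are local Cartesian metres.
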