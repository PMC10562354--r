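# priorigrid

Raster resolution decides what a conservation plan can see.  When
biodiversity feature maps are aggregated from a fine grid to a coarse one,
sparse and scattered features — a rare tree species occurring as single
stems, thin lines of downed deadwood — dissolve into the surrounding
forest matrix, and a prioritization run on the coarse data quietly trades
them away for common features.  `priorigrid` is a self-contained test bed
for that effect, aimed at landscape ecologists and conservation planners
who want to quantify how much resolution their features can afford to
lose.

The package

* **simulates** object-level boreal forest landscapes: a four-class
  site-fertility mosaic (32.4/51.1/15.6/0.9 % area shares), clustered
  spruce/pine/birch and sporadic single-stem aspen (landscape volume
  shares ≈ 40/35/17/5 %), and downed-deadwood (DDW) line segments;
* **rasterizes** them into a 16 m baseline stack of 52 feature layers —
  per-species H<sub>max</sub>, H<sub>mean</sub>, Vol plus DDW volume, each
  stratified by site class;
* **aggregates** the stack to 32, 48, 64, 80 and 96 m with
  variable-bound rules (mean / max / sum), 312 layers in all;
* **ranks** cells at each resolution with a Zonation-style greedy
  additive benefit function: feature benefit v<sub>j</sub>(r<sub>j</sub>)
  = r<sub>j</sub><sup>z</sup> with z = 0.25, cells removed one by one to
  minimize the loss Σ<sub>j</sub> w<sub>j</sub>[r<sub>j</sub><sup>z</sup>
  − (r<sub>j</sub> − q<sub>ij</sub>)<sup>z</sup>], yielding a nested
  priority ranking in (0, 1];
* **evaluates** each coarse solution against the 16 m baseline: spatial
  overlap and error of omission (they sum to 1), and per-feature
  conservation error computed on the baseline data.

## Worked example

```r
library(priorigrid)

cfg <- default_config()          # 960 x 960 m landscape, 3600 cells @ 16 m
cfg$landscape$seed <- 42L
report <- run_experiment(cfg)
print(report)
```

```
Multi-resolution prioritization report
  resolutions (m): 16, 32, 48, 64, 80, 96 
  top fractions: 0.02, 0.1 
  seed: 42 

Spatial error vs baseline:
 resolution_m top_fraction overlap omission footprint_cells
           16         0.02   1.000    0.000              72
           16         0.10   1.000    0.000             360
           32         0.02   0.319    0.681              72
           32         0.10   0.422    0.578             360
           48         0.02   0.264    0.736              72
           48         0.10   0.300    0.700             360
           64         0.02   0.208    0.792              80
           64         0.10   0.269    0.731             368
           80         0.02   0.222    0.778              75
           80         0.10   0.264    0.736             375
           96         0.02   0.139    0.861              72
           96         0.10   0.247    0.753             360
```

Already the first coarsening step (16 → 32 m, a fourfold cell area) drops
the shared area with the baseline selection to about a third for the top
2 % and to 0.42 for the top 10 %; further coarsening continues the decline
more slowly.  The per-feature conservation error shows who pays for it:

```r
ce <- subset(report$conservation,
             resolution_m == 96 & top_fraction == 0.02 & defined)
round(tapply(ce$conservation_error, ce$species, mean), 3)
```

```
 aspen  birch   none   pine spruce 
-0.794 -0.251 -0.648 -0.140 -0.470 
```

At 96 m the sporadic, rare aspen loses on average ~79 % of the protection
the baseline solution gave it (`none` is DDW), while the common pine loses
~14 % — the sparse-feature signature the package exists to measure.
Single stages are available as `generate_site_classes()`,
`generate_trees()`, `generate_ddw()`, `build_baseline_stack()`,
`build_pyramid()`, `rank_cells()` (a classed object with `print`,
`summary`, `plot` methods), `top_fraction()`, `performance_curve()`,
`spatial_error()` and `conservation_error()`; a thin CLI over the same
functions ships in `inst/cli/priorigrid.R`.  See the methods vignette
(`vignettes/multiresolution-prioritization.Rmd`) for the model, the
generator's assumptions and the numerical conventions.

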