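# mangrovedyn

Tools for very-high-resolution mapping of **fringing mangrove patches**
along rocky volcanic coastlines, written for coastal ecologists and
remote-sensing analysts who digitize habitat polygons over satellite
imagery and need to (1) quantify how faithfully the polygons render the
true patch outlines, (2) validate the resulting binary map against
field data, (3) compare mapping methods statistically, (4) track patch
dynamics between two survey epochs, and (5) summarise cover relative to
the coastline. Everything runs on plain planar geometry in a metric
projected CRS and is exercised end-to-end on a seeded synthetic
coastal-landscape generator, so the full pipeline is testable offline.

## What it computes

**Patch complexity.** For a patch polygon *pol* with perimeter *P*,
area *A*, convex hull *H* and *n* boundary nodes:

- Complexity 1 = *P/A* (m⁻¹),
- Complexity 2 = 0.8·ampl·nodes + 0.2·conv, with
  ampl = (*P* − *P*(H))/*P* and conv = (*A*(H) − *A*)/*A*(H),
- Complexity 3 = node count, reported as the layer mean.

Convex patches score exactly zero on Complexity 2; heavily digitized
sinuous patches score in the tens, which is what makes the metric a
useful fingerprint of mapping fidelity across studies.

**Accuracy assessment.** Random validation points in 100 m (3.14 ha)
site buffers, point-in-polygon classification (boundary = mangrove),
confusion matrix, overall accuracy, Cohen's kappa, and the pooled
two-proportion Z test

Z = (x₁/n₁ − x₂/n₂) / √(ρ(1−ρ)(1/n₁ + 1/n₂)),  ρ = (x₁+x₂)/(n₁+n₂),

with |Z| ≥ 1.96 flagging a significant accuracy difference. Digitizer
quality control (≥ 50% of a polygon's perimeter coinciding with the
reference outline) and Cochran survey sample sizes with
finite-population correction round out the module.

**Classification chains.** Gaussian maximum-likelihood classification
of RGB(+NIR) scenes, either whole-scene (MLC1) or with a prior land/sea
split along the coastline (MLC2), and a hybrid chain that masks
vegetation by NDVI ≥ 0.2, segments it by region growing, and keeps
segments intersecting the MLC2 mangrove class. Classified rasters are
traced to polygons (4-connected, holes preserved) and filtered at a
10 m² minimum mapping unit.

**Change analysis.** Spatio-temporal analysis of moving polygons
between two epochs at a 15 m grouping threshold: stable (STB),
expansion (EXP), contraction (CON), generation (GEN) and disappearance
(DIS) event areas, obeying the conservation identities
area(t) = STB+CON+DIS and area(t+Δ) = STB+EXP+GEN, plus two-sample
Kolmogorov–Smirnov comparison of patch-size distributions and
coastline-normalised change summaries.

**Coastal statistics.** Cover by distance band from the coastline with
interpolated d50/d90, the fraction of coastline fronted by mangrove,
and cover density (ha per km of coastline) by island or age group.

## Worked example

```r
library(mangrovedyn)

# a seeded synthetic fringing landscape with a scripted decade of change
ls <- generate_landscape(landscape_script(seed = 42, n_patches = 120),
                         scene = FALSE)

summarize_layer(ls$layer_t1)
#> Layer complexity: 124 patches, mean area 0.28 ha
#>   Complexity 1 (perim/area): 0.185 1/m
#>   Complexity 2 (ampl/nodes/conv): 0.93
#>   Complexity 3 (mean nodes): 16.0  (total nodes 1984)

ev <- stamp_events(ls$layer_t, ls$layer_t1, dist_threshold = 15)
change_summary(ev, ls$coastline)
#> Change summary over 18.1 km of coastline:
#>  category    area_ha  ha_per_km
#>       STB 26.8155035 1.48449483
#>       EXP  6.3624060 0.35222008
#>       CON  0.3260897 0.01805219
#>       GEN  1.9915163 0.11024949
#>       DIS  0.3448964 0.01909332
#> cover 27.5 ha -> 35.2 ha (+28.0%)

# compare two published map accuracies at 500 validation points each
z_compare_accuracy(99.1, 77.5, n1 = 500, n2 = 500)
#> Z = 10.626 (p1 = 0.991, p2 = 0.775, pooled rho = 0.883)  |Z| >= 1.96: significant

prof <- distance_band_profile(ls$layer_t1, ls$coastline,
                              edges = c(100, 200, 500, 1000))
attr(prof, "d50"); attr(prof, "d90")
#> d50 = 133 m, d90 = 344 m
```

The change summary recovers the generator's planted event ledger
exactly (the suite asserts agreement to 10⁻⁶ m²), most of the cover
sits within the first coastline bands as scripted, and the Z value says
a 99.1%-accurate map is far more accurate than a 77.5% one at 500
points apiece.

A command-line interface wraps the same functions
(`inst/cli/mangrovedyn.R` with subcommands `simulate`, `complexity`,
`validate`, `classify`, `change`, `coaststats`), reading GeoJSON/WKT
vectors and ESRI ASCII grid rasters and writing JSON/CSV reports.

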