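---
title: "Methods: mapping, validating and tracking fringing mangrove patches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping, validating and tracking fringing mangrove patches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mangrovedyn)
```

`mangrovedyn` implements the quantitative machinery behind very-high-
resolution mapping of fringing mangrove: scoring how faithfully digitized
patch polygons render real patch outlines, assessing binary map accuracy
against field data, benchmarking semi-automatic classification chains,
and tracking patch dynamics between two survey epochs. This vignette
documents the models, the tunable parameters, the numerical choices, and
what the synthetic test landscape does and does not demonstrate.

## Geometry substrate

All analysis happens on planar polygons in a metric projected CRS
(UTM-style coordinates in metres). Patches are simple polygons with
optional holes; the exterior ring is stored counter-clockwise, holes
clockwise, the closing vertex is stored once, and duplicate consecutive
vertices — common digitization artefacts that would inflate node counts —
are dropped at ingest. Holes contribute to perimeter and node counts and
subtract from area, the standard GIS convention; convex hulls are taken
over the exterior ring only, since an interior ring can never touch the
hull.

Two non-obvious primitives are worth describing:

* **Intersection areas** between two polygons are computed by signed
  fan-triangulation: each ring is fanned into triangles carrying the
  sign of their signed area, and the area of overlap is the
  sign-weighted sum of pairwise triangle-triangle clip areas
  (Sutherland–Hodgman on counter-clockwise triangles). This is exact to
  floating point for simple polygons with holes and needs no general
  polygon-boolean machinery. The change analysis only ever needs
  *areas* of overlap, never the overlap shapes, so change events carry
  the participating epoch polygons as their geometry together with
  exact category areas.
* **Raster-to-polygon tracing** emits directed unit edges around the
  4-connected pixel components of a class (interior kept on the left)
  and chains them into rings, taking the leftmost turn at pinch
  vertices so every ring stays simple; collinear vertices are then
  merged. 4-connectivity is deliberate — 8-connectivity lets components
  leak across diagonals and produces self-touching rings.

The minimum mapping unit filter erases patches *smaller* than the MMU
(default 10 m²); the boundary is inclusive, so a patch of exactly 10 m²
survives.

## Complexity metrics

Three per-patch scores quantify boundary irregularity, which for
digitized mangrove is a proxy for how much of the true sinuous outline
(invaginations, lobes) the mapping method captured:

* **Complexity 1** = perimeter / area (m⁻¹). Scale-dependent by design:
  halving the linear scale doubles the score.
* **Complexity 2** = `0.8 · ampl · nodes + 0.2 · conv`, where
  `ampl = (P − P_hull)/P` is the relative boundary-amplitude excess
  over the convex hull, `nodes` the vertex count, and
  `conv = (A_hull − A)/A_hull` the convexity deficit. Both `ampl` and
  `conv` vanish exactly on convex polygons, so the score is zero there;
  it is unbounded in the node count on purpose — layer means in the
  tens are meaningful and comparable across studies. The score is
  invariant under rigid motion and uniform scaling. The notch-frequency
  term of the original boundary-complexity formulation is deliberately
  replaced by the node count, which is the variant actually usable on
  sinuous digitized outlines; only this variant is implemented.
* **Complexity 3** = the node count, summarised at layer level as the
  mean number of nodes per polygon.

Layer summaries are computed after MMU filtering when the layer has been
filtered, and report patch count, mean patch area (ha), mean Complexity
1 and 2, mean nodes and total nodes. Hole vertices count as nodes by
default (they are genuine digitized detail); `exterior_only = TRUE` is
available where a comparison layer stores no holes.

## Accuracy assessment

Validation is binary (mangrove / non-mangrove). Around each field site a
100 m-radius buffer (3.14 ha) is drawn and `n` points (default 500) are
placed uniformly in the disc; each point is classified by
point-in-polygon against the map, with boundary points counted as
mangrove — a deterministic convention that avoids tie ambiguity on
shared edges. The confusion matrix yields overall accuracy (percent
correct) and Cohen's kappa `(p_o − p_e)/(1 − p_e)`; degenerate marginals
(chance agreement 1) return `NA` with a warning rather than a spurious
number. The validation can be repeated with fresh seeds
(`validate_map(..., repeats = 3)`), reporting the mean across repeats,
which guards against a single unlucky point draw.

Two maps are compared with the pooled two-proportion Z statistic

\[ Z = \frac{x_1/n_1 - x_2/n_2}
          {\sqrt{\rho(1-\rho)(1/n_1 + 1/n_2)}},\qquad
   \rho = \frac{x_1+x_2}{n_1+n_2}, \]

with `|Z| ≥ 1.96` flagging a significant difference at the 5% level.
When recomputing comparisons from *printed* accuracy percentages, note
that published accuracies are usually rounded; the recomputed statistic
can then differ from a published one by up to half a unit in its last
decimal, which is an artefact of the rounding, not of the formula.

Digitizer quality control rates a candidate polygon accurate when at
least half of its exterior perimeter coincides with the reference
outline. "Coincides" is operationalised as arc length lying within a
distance tolerance (default 5 m) of the reference boundary, measured by
dense arc-length sampling (step = tol/10); the published procedure gives
no numeric definition of coincidence, so the tolerance is an explicit,
documented parameter rather than a hidden constant.

Survey sample sizes use Cochran's formula at maximum variance
(`n₀ = z²·0.25/m²`) with finite-population correction, rounded up. The
99%-confidence quantile defaults to the conventional two-decimal value
2.58 (2.576 is available); plain fraction-of-population sampling is
provided for stratified designs such as an 8% quality-control sample.

## Classification chains

Three semi-automatic chains are provided for RGB(+NIR) scenes:

* **MLC1** — Gaussian maximum likelihood over the whole scene. Each
  class gets a sample mean and covariance (ridge-regularised when not
  positive definite); pixels take the class with the highest
  log-likelihood plus log prior, priors equal by default (the common
  GIS-tool default), ties broken deterministically in alphabetical
  class order.
* **MLC2** — the same classifier applied separately to the land and sea
  sides of the coastline, each side with its own class set. The
  land/sea split uses the pixel-centre rule against the coastline
  polyline. Separating the sides removes the classic failure where
  sea-surface features sharing the mangrove RGB signature (e.g. algae)
  are committed to mangrove.
* **HYBRID** — NDVI (`(NIR−R)/(NIR+R)`, vegetated at ≥ 0.2, an
  inclusive threshold) masks the scene to vegetation; a region-growing
  segmentation partitions the mask; segments intersecting the MLC2
  mangrove class in at least one pixel are selected whole.

Region growing merges a neighbouring pixel into a segment when its
Euclidean distance to the running segment mean, in band space normalised
to [0, 1], is at most the difference threshold (default 0.75); segments
below the minimum size (default 750 px) are merged into their most
spectrally similar neighbour. The exact similarity semantics of the
original segmentation tool are not published; this normalised-distance
reading is a documented stand-in, and the growth order (row-major seeds)
makes the result deterministic. The 750 px operational minimum presumes
full-resolution image tiles; on compact benchmark scenes the minimum is
scaled proportionally (the benchmark helper uses roughly mask-size/60),
otherwise every desk-scale segment would be merged away.

Classified rasters are converted to patch polygons (holes preserved) and
MMU-filtered, so classification outputs flow directly into the
complexity, validation and change modules.

## Change analysis (two-epoch moving polygons)

Patches from epochs *t* and *t+Δ* are grouped by union-find whenever
their boundaries lie within the grouping threshold (default 15 m,
matched to typical inter-epoch georeferencing error; the threshold
semantics are equivalent to buffering every polygon by half the
threshold and grouping on overlap, implemented via exact
boundary-to-boundary distances instead of buffer geometry). Within a
mixed group, the overlap area is **stable** (STB), the epoch-t remainder
**contraction** (CON), and the epoch-t+Δ remainder **expansion** (EXP);
groups with only new polygons are **generation** (GEN) and groups with
only vanished polygons **disappearance** (DIS). By construction the
category areas satisfy the conservation identities

```
area(t)   = STB + CON + DIS
area(t+Δ) = STB + EXP + GEN
```

which hold on every input to float precision and are asserted
property-style in the tests. Patches within one epoch are assumed
non-overlapping, as digitized map products are. Only these five level-1
categories are implemented; higher-level displacement/convergence events
of the full moving-polygon taxonomy are out of scope. Epoch alignment is
a user-supplied rigid shift (estimated externally from stable coastal
features); automatic co-registration is out of scope. Patch-size
distributions between epochs are compared with the two-sample
Kolmogorov–Smirnov test (asymptotic p-values).

## Coastal statistics

Cover is apportioned to half-open distance bands `[e_{i−1}, e_i)` from
the coastline by deterministic dense point sampling of each patch, with
sample weights rescaled so each patch contributes exactly its true area
— discretization therefore only blurs the split between adjacent bands,
never the total, and the band areas always sum to the layer area. The
distances holding 50% and 90% of cover (d50, d90) are interpolated
weighted quantiles of the sampled distances. The fraction of coastline
fronted by mangrove samples the coastline at a fixed arc step (default
10 m) and asks whether mangrove lies within the fronting distance.
There is no published definition of when a stretch of coast "is
protected" by mangrove, so the fronting distance (default 50 m) is a
prominent, documented parameter and the published coastline-protection
percentage is *not* treated as a reproduction target. Cover density per
group is simply ha of cover per km of coastline, with optional
aggregation of islands into geological-age groups.

## The synthetic landscape generator

Every pipeline stage is exercised on generated landscapes, so the
package is fully testable without imagery downloads. A landscape script
bundles one seed with all parameters; identical scripts give identical
landscapes.

* **Coastline** — a smoothed Gaussian random walk sampled every 50 m;
  land lies below the curve, sea above. This is the simplest
  construction that yields an irregular but single-valued shore.
* **Patches** — star-shaped polygons (radial vertices around an anchor,
  default 16 vertices with ±35% radial roughness), rescaled to exact
  target areas. Sizes follow a truncated log-normal (meanlog
  `log(1000)` m², sdlog 1.56, truncated to [25, 5·10⁴] m²), chosen so
  ~85% of patches fall below 0.5 ha — the size structure reported for
  fringing mangrove on volcanic coasts. Anchor depths from the shore
  are exponential with 100 m mean (truncated at 700 m), which puts
  about half the cover within 100 m and ~90% within 500 m of the
  coastline. Placement enforces a clearance (default 40 m) larger than
  the 15 m grouping threshold *after* the largest scripted expansion,
  so planted events can never merge across patches.
* **Change script** — each patch is independently stable (60%),
  expanded (30%, +80% area), contracted (8%, −30%), or removed (2%),
  and 5% new patches are generated; expansions and contractions scale
  the star about its anchor, so the two epochs nest exactly and the
  ledger records exact planted STB/EXP/CON/GEN/DIS areas. The mix nets
  ≈ +24.6% expected cover change per decade, the magnitude reported
  for expanding pristine fringes; realised change in a single landscape
  varies substantially around that mean because the size law is
  heavy-tailed.
* **Scene** — a window of the landscape rasterised at 3 m: sea/land by
  the coastline, mangrove from the epoch-t+Δ layer, a sand strip along
  the shore, deciduous vegetation as smoothed-noise blobs plus a collar
  hugging every mangrove patch, lava elsewhere. Classes get Gaussian
  band values (R, G, B, NIR means in [0, 1] encoding the qualitative
  tonality differences: dark lush green/high-NIR mangrove, paler
  deciduous, dark flat lava, bright sand, low-NIR water). Texture
  beyond per-class noise is not synthesised.
* **Confusable benchmark** — pulls the deciduous mean towards mangrove
  (default 80% of the way) and plants sea-surface algae sharing the
  mangrove spectrum on ~8% of the scene. This reproduces the two
  documented failure modes: whole-scene MLC commits algae to mangrove
  (MLC2 cannot, by construction), and segment selection overspills into
  the deciduous collar (HYBRID below MLC2). On this benchmark the
  accuracy ordering *truth > MLC2 > {MLC1, HYBRID}* emerges with gaps
  of several points across seeds.

What passing on synthetic data does **not** show: real mangrove spectra
overlap non-Gaussianly with seasonal state, real patches are not
star-shaped, georeferencing error is not a pure rigid shift, and the
published headline figures (total cover, the 35% protected coastline,
the 99.1%/0.97 field validation) depend on the deposited survey layer,
unpublished field points and proprietary imagery — they are checked only
through the arithmetic that their printed inputs allow.

## Numerical choices and scale of the checks

Ring validity uses exact orientation tests; near-duplicate vertices are
collapsed at 10⁻⁹ m. Clipping treats points on a half-plane boundary as
inside, making intersection areas stable on shared edges. The isoperimetric
inequality, hull monotonicity, STAMP conservation (1000 random epoch
pairs), K-S and Z type-I error rates (2000 simulations each), and the
traced-polygon cell/edge/corner oracles are asserted as properties under
fixed seeds. Default test and acceptance problem sizes (landscapes of
tens to hundreds of patches, scenes of ~10⁵ pixels) were chosen as the
smallest sizes at which the stochastic properties are stable; all are
parameters, so larger studies are one argument away.
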