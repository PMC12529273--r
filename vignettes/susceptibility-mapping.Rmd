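---
title: "Methods: air-pollution susceptibility mapping and its case-control analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: air-pollution susceptibility mapping and its case-control analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smcair)
```

`smcair` builds an air-pollution (AP) susceptibility index over a study
region and uses it in a georeferenced case-control analysis. This
vignette is the package's account of the science: the model, the
parameters that matter, what the synthetic data generator does and does
not emulate, the numerical conventions, and the places where the design
was genuinely open and a choice had to be made.

## The susceptibility model

The index is a weighted linear combination (WLC) of five factor score
rasters on a common metric grid (10 m working resolution by default):

$$S = \sum_i w_i x_i, \qquad x_i \in [1,3], \qquad \sum_i w_i = 1 .$$

Each factor is mapped onto the ordinal susceptibility range 1 (low) to
3 (high) before weighting, so $S$ is a convex combination bounded by
the cell-wise extremes of its inputs. The factors, with defaults and
their rationale:

* **Distance to polluting facilities** (`distance_raster` +
  `classify_by_breaks`). Exact Euclidean distance from each cell center
  to the nearest registered polluting facility, classified high
  (< 2000 m), moderate (2000-4000 m), low (> 4000 m). The 2000 m break
  reflects the radius within which emissions from a hazardous activity
  are conventionally taken to impact the atmosphere; 4000 m is the
  outer bound beyond which impacts are considered minimal.
* **Facility density** (`kde_raster` + `rescale_minmax_1_3`). Quartic
  (finite-support) kernel density of facility points, reported in
  events per km², bandwidth 2000 m by default for the same
  physical reason. There are no literature thresholds linking facility
  density to pollution levels, so the density surface is min-max
  rescaled linearly onto $[1,3]$ rather than cut at fixed breaks: the
  observed minimum maps to 1, the maximum to 3, and a constant surface
  maps to all-low. Kernel and bandwidth are configurable; the Gaussian
  alternative is truncated at $4h$.
* **Distance to major roads**: same construction as facility distance
  with breaks at 100 m and 300 m — under 100 m is where road-traffic
  pollution is strongest, beyond 300 m its health impact is much
  reduced.
* **Land use** (`landuse_scores`): industrial fabric (with transport
  and waste infrastructure) scores 3, residential/commercial 2,
  natural, forested or agricultural cover 1. Unmapped categories are a
  hard error, never silently defaulted.
* **Radiation-fog proneness** (`fog_scores`): a binary polygon overlay.
  Fog-prone low-lying zones — where nocturnal cold-air drainage pools
  and disperses pollutants poorly — score 3, everything else 1. The
  binary factor uses the extreme scores $\{1,3\}$ rather than
  $\{1,2\}$ so that "high" means 3 for every factor entering the
  overlay; a proxy for stagnant-air accumulation in the absence of
  wind-field data.

**Class closure.** Because the high class of the distance factors is
defined by a strict inequality (< 2000 m, < 100 m), the moderate class
owns both of its endpoints: with breaks $(b_1, b_2)$, high is
$v < b_1$, moderate $b_1 \le v \le b_2$, low $v > b_2$. The same
closure is used when the continuous index is classified (below).

### AHP weighting

Weights come from a Saaty-scale pairwise judgment matrix via
`ahp_weights()`. The default method is *column normalization* (Saaty's
approximate eigenvector): each column of the judgment matrix is
normalized to sum 1 and averaged across columns within rows. A power
iteration for the principal eigenvector is available as a cross-check;
on realistic (near-consistent) judgment matrices the two agree to well
under 0.02 per weight, which the test suite verifies on 100 randomly
generated Saaty-rounded matrices. Note that no such agreement bound
holds for *arbitrary* reciprocal Saaty matrices — a matrix with
near-random judgments can be inconsistent enough for the two
estimators to diverge by an order of magnitude more, which is why the
property is tested on matrices generated the way judgments arise (a
latent priority vector with each ratio snapped to the scale).

Consistency is reported as $\lambda_{max}$ (the consistency-vector
mean $\frac{1}{n}\sum_i (A w)_i / w_i$), $CI = (\lambda_{max} - n)/(n - 1)$
and $CR = CI / RI(n)$ with Saaty's random indices; $CR \le 0.1$ is the
conventional acceptability threshold. Reciprocity violations
($|a_{ij} a_{ji} - 1| > 10^{-9}$) warn but do not block: the bundled
judgment matrix is analysed exactly as published, including its
non-reciprocal land-use/roads pair.

**An open inconsistency, and how it is handled.** The bundled matrix's
column-normalized weights round to $\{0.37, 0.37, 0.13, 0.09, 0.04\}$,
with 0.13 on the *land-use* row and 0.09 on the *roads* row — the
matrix says land use dominates roads (entry 3 in its favor). The
published weight column attaches 0.13 to roads and 0.09 to land use,
i.e. the same multiset with those two assignments transposed, and
offers no resolution. `canonical_weights()` therefore supports both:
`"published"` (the default for the pipeline, with a warning noting the
transposition) and `"recomputed"` (what the matrix itself yields).
Weights are fully configurable per run and recorded in the manifest.

### Classifying the index

The source analysis never states how the continuous index was cut into
its three classes. `classify_susceptibility()` defaults to
*equal intervals of the theoretical range*: $[1, 5/3)$ low,
$[5/3, 7/3)$ moderate, $[7/3, 3]$ high. This rule is deterministic and
data-independent — two maps built with the same weights are classified
identically regardless of their value distributions — which makes it
the right default for a reproducible pipeline. Tertile (quantile)
classing is available as an option, and the choice is recorded in the
output metadata. The observed class shares cannot disambiguate which
rule the original analysis used, so this remains a declared choice.

## The synthetic study region

`generate_region()` and `generate_residences()` produce a fully
synthetic study region and cohort with the statistical structure the
analysis assumes, so every downstream stage runs with no external
data. The defaults are the study conditions: a 20 km × 15 km planar
metric region, 10 m working cells (50 m in the coarse profile used by
the simulation studies), 25 polluting facilities, 8 major roads, a
land-use mosaic of industrial/residential/natural patches
(8%/42%/50%), a fog-prone band along the low-lying south edge
occupying 18% of the region height, 120 postal centroids, and a cohort
of 164 cases and 209 controls.

Construction choices worth knowing:

* **Land use** is a jittered-lattice Voronoi mosaic of 400 near-equal
  patches whose category counts are allocated to the requested
  fractions by largest remainder, so realized cell shares track the
  configuration to within a couple of percentage points.
* **Facilities** sample industrial cells uniformly (with sub-cell
  jitter), mimicking the clustering of registered polluting activities
  on industrial land. **Roads** cross the region edge to edge with
  gentle jitter.
* **Postal centroids** snap to cell centers, weighted toward
  residential land; residences are placed *at* centroids, so many
  records share coordinates exactly — deliberately reproducing the
  coarse geocoding of postal-code centroids, which matters downstream
  (coincident neighbors in the spatial weights, nugget effects in the
  variogram).
* **The cohort**: case and control locations are independent draws
  from the same centroid distribution (residential weight ×3). With a
  planted cluster, case intensity is multiplied by `cluster_excess`
  inside a disk (default 2 km radius), creating a known High-High
  cluster; with `cluster_excess = 1` the groups are exchangeable by
  construction, which is the planted null the calibration tests rely
  on. Controls draw their birth day from the realized case birth days,
  emulating the systematic same-day 2:1 control sampling of the study
  design; the field is carried but matched analysis is deliberately
  not performed downstream, mirroring the unmatched chi-square
  treatment of the source analysis (whose study-area subset no longer
  has the 2:1 ratio).
* **Determinism**: one root seed expands into per-layer streams
  (land use, facilities, roads, fog, centroids; cases, controls, birth
  days), so changing one layer's count does not perturb the others.
  The RNG is pinned to Mersenne-Twister.

What the generator does *not* emulate: road-network topology,
demographic structure, pregnancy-trimester exposure windows, wind or
dispersion fields, and the geography of any real region. Passing tests
therefore demonstrate that the *methods* behave correctly under the
assumed statistical structure — they are not evidence about any real
study area.

## Cluster detection

`local_morans_i()` computes Anselin's Local Moran's I on the binary
case indicator (case 1, control 0) over all residence points, under
row-standardized distance-band weights (`distance_band_weights`,
default band 4 km — the conventional maximum reach of industrial
emissions). The indicator choice makes a High-High label mean "a local
excess of cases", which is exactly the quantity of epidemiological
interest and is directly testable on planted clusters; the alternative
reading (case-only intensity) offers no such calibrated null.
Coincident points are mutual neighbors (distance 0 within any band)
and a point is only ever excluded as its own neighbor — necessary
because snapped geocoding makes shared coordinates the norm, not the
exception.

Inference is by conditional permutation: each point's own value is
held fixed while the remaining values are permuted among the other
positions (a compiled engine; 999 permutations by default, p
granularity 1/1000). For tiny instances (`n_perm = "exact"`, up to 9
points) all permutations are enumerated, and the test suite checks the
sampled engine against hand-computed statistics and the exhaustive
distribution.

**Two-sided labelling.** The default p-value is the folded two-sided
permutation p, $\min(1, 2\min(p_{upper}, p_{lower}))$, and points are
labelled (HH/LL/HL/LH by value and spatial-lag quadrant) where
$p \le \alpha = 0.05$. A one-tailed rule at the same $\alpha$ would
label roughly $2\alpha$ of points under the exchangeable null (each
tail contributes its own $\alpha$); the folded p keeps the null
labelling rate near the nominal level, which the suite verifies across
100 null cohorts (observed rate must average ≤ 7.5%). One-tailed
p-values remain available via `alternative = "greater"`/`"less"`.
Isolated points (no neighbor within the band) are labelled as such and
never tested.

## Exposure tables and tests

`build_contingency()` overlays residences on a class raster (half-open
cell membership, below) and cross-tabulates class against group,
keeping zero rows and reporting nodata-cell residences in an
exclusions attribute rather than dropping them silently.
`pearson_chi2()` wraps the standard Pearson test with Yates continuity
correction applied automatically to 2×2 tables *only*: reproducing the
published fog-factor p-value (.922) requires the correction (the
uncorrected value is ≈ .77), implying the original software corrected
2×2 tables, and that behavior is the default here with an explicit
flag to disable it.

`frequency_report()` renders counts and group percentages (one
decimal, denominators recomputed from the rows actually tabulated) and
applies statistical-secrecy suppression strictly below 3: a count of 2
renders as `<3` with its percentage withheld, a count of 3 is shown.
Two published quantities are knowingly *not* reproduced as printed:
the municipality/parish rows of the published table sum to 169/213
rather than the stated 164/209 and use an inconsistent percentage
denominator, and two published p-values (roads .927, land use .017) do
not recompute from their printed counts (.956 and .016 respectively).
The package recomputes consistently from the data it is given rather
than mimicking those artifacts.

## The kriged odds-ratio surface

The source analysis names "an odds ratio calculated using kriging
interpolation" without a variogram model, neighborhood, or an exact
construction. The package's declared construction is *indicator
kriging*: ordinary kriging of the case indicator yields a surface
$\hat p(s)$ of local case probability, which becomes an odds ratio
against the study-wide odds,

$$OR(s) = \frac{\hat p(s) / (1 - \hat p(s))}{n_{cases} / n_{controls}},$$

so $OR = 1$ means no local excess of cases. $\hat p$ is clipped to
$[\varepsilon, 1-\varepsilon]$ ($\varepsilon = 10^{-6}$) before the
odds transform. Everything is configurable and recorded in output
metadata.

Geostatistical conventions:

* The empirical semivariogram bins pairs up to a maximum lag (default:
  a third of the largest pair distance). Coincident pairs are kept in
  the first bin — for snapped geocoding they are exactly what carries
  the nugget information.
* Models: exponential (default) and spherical, parameterized by
  nugget, partial sill and the *practical* range (the exponential
  model uses $\gamma(h) = c_0 + c_1(1 - e^{-3h/a})$). Fitting is
  weighted least squares with pair-count weights, refined from a fixed
  multi-start grid over the range, so it is deterministic.
* The kriging system uses semivariances between distinct locations
  with $\gamma(0^+) = c_0$ off the diagonal and 0 on it: coincident
  observations are regularized by the nugget instead of making the
  system singular. If the fitted nugget is exactly zero and duplicate
  coordinates exist, the duplicates are jittered by 0.1 m (warned) or
  the call fails, per configuration. With a zero nugget and distinct
  points the predictor honors the data exactly, which the tests
  assert.
* Prediction uses the 16 nearest observations per cell (configurable);
  repeated neighbor sets share one factorization.

## Numerical conventions and degenerate inputs

* **Grid geometry**: row 1 is the top of the grid (maximum y); the
  center of cell $(i, j)$ is
  $(x_{min} + (j - \tfrac12)c,\; y_{max} - (i - \tfrac12)c)$. Grids
  anchor at the top-left corner of the requested bounds and expand
  right/down by whole cells (`ceiling`), so they always cover the
  bounds.
* **Cell membership is half-open** with ties to the right/below: a
  point on a shared vertical edge belongs to the cell on its right, on
  a shared horizontal edge to the cell below. This makes sampling at
  any cell center return that cell's own value, for every cell — the
  consistency the suite asserts exhaustively.
* **Nodata**: −9999 for continuous/score rasters, 0 for class rasters
  (valid classes are always 1-3). Nodata propagates through
  classification and the overlay; residences on nodata cells are
  excluded-and-reported.
* **Degenerate paths** are explicit: an empty facility layer yields
  all-low distance and density factors; a constant raster min-max
  rescales to all-low; constant marks are a zero-variance error for
  Local Moran; all-coincident points are an error for the variogram;
  tables with a zero margin are a degenerate-table error naming the
  margin.
* Rasters are exchanged as plain-text Esri ASCII grids with a JSON
  sidecar for semantics (kind, nodata, categories, CRS tag); vectors
  as GeoJSON; residences as CSV. Integer rasters round-trip
  bit-identically, continuous rasters within $10^{-9}$ relative.
  Coordinates are planar metric throughout; the CRS is opaque metadata
  and no geodesy is performed.

## Problem sizes used by the test suite

The simulation studies run on the coarse profile: the default region
at 50 m cells, 100 cohorts per study, 999 conditional permutations for
Local Moran (199 for the small pipeline fixture), and kriging onto a
500 m prediction grid with 16 neighbors. The planted-cluster studies
use excess ×4 in a 2 km disk at the region center; recovery is
declared when a High-High-labelled case point lies inside the disk,
and the kriged check compares mean OR inside versus outside the disk.
These sizes are the package's chosen balance between statistical
resolution and a suite that a maintainer will actually run.

## Known limitations

* The index is a susceptibility proxy, not a concentration estimate:
  no wind, dispersion, or emission-volume data enter it.
* Weights, breaks and bandwidths are literature-informed defaults, not
  fitted quantities; sensitivity analysis over judgments
  (fuzzy/group AHP) is out of scope.
* Local Moran is computed on points (not areal units), on the binary
  indicator; scan statistics and space-time clustering are out of
  scope.
* The kriged OR construction is declared, not inferred from the
  source; alternative relative-risk surfaces (kernel ratio, Bayesian
  geostatistics) are out of scope.
* The synthetic generator's realism is statistical, not geographic;
  results on it validate methods, never substantive conclusions about
  any real region.
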