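# smcair

Spatial multicriteria air-pollution susceptibility mapping for
case-control epidemiology.

Epidemiological studies of air pollution (AP) and birth defects are
limited by how hard maternal exposure is to measure: pollutant
concentrations are rarely available at residential scale, so exposure
must be approximated from the spatial structure of its sources.
`smcair` implements, as a tested and reusable R pipeline, a
susceptibility-index approach to this problem: five environmental
factors are rasterized, classified, weighted by the analytic hierarchy
process (AHP), and combined by weighted linear combination (WLC) into a
continuous susceptibility index

    S = Σᵢ wᵢ·xᵢ ,   xᵢ ∈ [1, 3],  Σ wᵢ = 1,

which is then cut into low / moderate / high classes and carried into
the case-control analysis: Local Moran's I cluster detection over the
residence points, exposure contingency tables with Pearson chi-square
tests and statistical-secrecy suppression, and an ordinary-kriged
odds-ratio surface of the case indicator. A synthetic study-region
generator reproduces the statistical structure the analysis assumes
(point pollution sources on industrial land, a major-road network, a
categorical land-use mosaic, a low-lying fog-prone band, and coarse
postal-centroid geocoding of 164 case / 209 control residences, with an
optional planted spatial excess of cases), so the entire pipeline runs
end-to-end without any external geographic data.

The five factors and their scoring:

| factor | raster | classes |
|---|---|---|
| distance to polluting facilities | Euclidean distance | high < 2000 m, moderate 2000-4000 m, low > 4000 m |
| facility density | quartic kernel density (h = 2000 m) | min-max rescaled onto [1, 3] |
| land use | categorical | industrial 3, residential 2, natural 1 |
| distance to major roads | Euclidean distance | high < 100 m, moderate 100-300 m, low > 300 m |
| radiation-fog proneness | binary polygon overlay | prone 3, not prone 1 |

AHP weights come from a Saaty pairwise judgment matrix via column
normalization (Saaty's approximate eigenvector), with the consistency
ratio CR = CI / RI reported; the bundled judgment matrix yields the
weight multiset {0.37, 0.37, 0.13, 0.09, 0.04} with CR = 0.09.

## Worked example

Weights and consistency of the bundled judgment matrix:

```r
library(smcair)
ahp_weights(bundled_ahp_matrix())
#> AHP weights (column_normalization)
#> distance  density  landuse    roads      fog
#>   0.3714   0.3714   0.1313   0.0891   0.0368
#> lambda_max = 5.3996, CI = 0.0999, CR = 0.0892 (0.09 displayed)
```

(The load warns that the matrix's land-use/roads pair is non-reciprocal
as published; it is analysed exactly as printed.)

Contingency analysis of the bundled published exposure counts:

```r
tabs <- contingency_from_counts(published_exposure_counts())
pearson_chi2(tabs$susceptibility)
#> Pearson chi-square (susceptibility): X2 = 2.315, df = 2, p = 0.314 (none)
pearson_chi2(tabs$fog)
#> Pearson chi-square (fog): X2 = 0.010, df = 1, p = 0.922 (yates)
frequency_report(tabs$susceptibility)
#>   exposure       class    group       n   pct suppressed display
#> 1 susceptibility low      case       25  15.2 FALSE      25
#> 2 susceptibility moderate case       92  56.1 FALSE      92
#> 3 susceptibility high     case       47  28.7 FALSE      47
#> ...
```

So 28.7% of cases (about 29%) and 31.1% of controls fall in the
high-susceptibility class: no significant association between the index
and case status (p = .314), which is the substantive result the
contingency stage reports. Counts below 3 would render as `<3` under
the statistical-secrecy rule.

End-to-end on a synthetic region with a planted case cluster
(intensity ×4 inside a 2 km disk):

```r
cfg <- pipeline_config(
  region = region_config(cell_size = 50),
  cohort = cohort_config(cluster_center = c(10000, 7500),
                         cluster_radius = 2000, cluster_excess = 4),
  krige_cell_size = 500, seed = 42
)
out <- run_all(cfg, out_dir = "run1", quiet = TRUE)
glance(out$moran)
#>       n n_significant  n_hh n_isolated global_i alpha  band
#> 1   373            45     2          0  0.00923  0.05  4000
```

The planted excess shows up as High-High labelled case points inside
the disk and as an elevated kriged odds ratio there (mean OR 3.90
inside versus 1.26 outside in this run). `autoplot()` methods exist for
rasters, susceptibility maps, Local Moran results and OR surfaces;
`out_dir` receives all layers (ASCII-grid rasters, GeoJSON vectors,
CSV tables) plus a `manifest.json` recording every stage's parameters
and seeds.

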