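# knoxclust

Space-time clustering analysis of childhood leukemia (or any rare
point-referenced disease) with a Monte Carlo null that adjusts for shifting
regional populations.

The package is aimed at spatial epidemiologists working with registry data:
one row per case with projected planar birth coordinates (meters) and a birth
date, plus census-style snapshots of the child population. It implements the
full three-step analysis:

1. **Knox tests over a lag grid.** For spatial lag *s* and temporal lag *t*,
   the Knox statistic counts case pairs born less than *s* meters and less
   than *t* days apart (strict inequalities). Expected counts and p-values
   come from a Monte Carlo null that keeps birth dates fixed and resamples
   birth locations from the time-interpolated child population — so uneven
   regional population growth cannot masquerade as clustering. The search
   over the grid is corrected with the max-statistic (min-p) adjustment, and
   the best lag pair becomes the *critical lags* (s\*, t\*).
2. **Clustered vs nonclustered cases.** Cases born within the critical lags
   of at least one other case are *clustered*. Characteristics are compared by
   logistic regression with likelihood-ratio tests, unadjusted and adjusted
   for a per-case *child-population-density index* — the log odds of being
   clustered by chance alone, logit Pr(≥ 1 neighbor under the null) — with
   Monte Carlo p-values for location-derived covariates and Holm step-down
   correction across characteristics.
3. **Cluster sizes.** Clustered cases are linked into local clusters as
   connected components of the close-pair graph; the observed number of
   clusters of each size or bigger is tested against the Monte Carlo null.

Because registry microdata cannot be shipped, the package includes a
first-class synthetic registry generator (`sim_config()`,
`generate_population()`, `generate_cases()`) producing shifting populations,
null or mini-epidemic case processes, marker enrichment, location-derived
covariates and sibling pairs.

## Worked example

Simulate a registry with induced mini-epidemics (expected 25 clusters of one
excess case each, radius 500 m, duration 365 days, 3× marker enrichment), then
run the Knox grid:

```r
library(knoxclust)
cfg <- sim_config(region_extent = c(0, 30000, 0, 30000), n_children = 120000,
                  cell_size_m = 1500, n_population_centers = 5,
                  snapshot_dates = as.Date(c("1985-01-01", "2000-01-01", "2015-01-01")),
                  n_cases = 500, cluster_rate = 25, seed = 2026)
pop   <- generate_population(cfg)
cases <- generate_cases(cfg, pop)
kt    <- knox_test(cases, pop, B = 999, seed = 1)
kt
#> Knox space-time interaction test (501 cases, 999 MC replicates)
#>
#> spatial                   182 d      365 d      548 d      730 d
#> 0.5 km     obs/exp      43/15.9    63/31.6    74/46.7    88/62.2
#>            ratio           2.70       1.99       1.59       1.41
#>            p              0.001      0.001      0.001      0.006
#> 1 km       obs/exp      81/62.6  142/124.2  201/184.1  262/244.7
#>            ratio           1.29       1.14       1.09       1.07
#>            p              0.034      0.099      0.178      0.213
#> ...
#> critical lags: 500 m, 182 days (min p = 0.001)
#> max-statistic adjusted p = 0.011
```

At (0.5 km, 182 d) the simulation shows 43 close pairs where the
population-shift null expects 15.9 — a ratio of 2.70 — and the evidence
survives correction for searching 20 lag combinations (adjusted p = 0.011).
Link clusters and compare the marker between clustered and nonclustered cases,
adjusting for child population density:

```r
lab <- link_clusters(cases, kt$critical_lags["s"], kt$critical_lags["t"])
lab
#> Cluster labeling at critical lags 500 m, 182 days
#>   84 of 501 cases clustered (16.8%) in 41 local clusters
#>   size spectrum (size: clusters): 1: 417, 2: 39, 3: 2

di  <- density_index(cases, pop, kt$critical_lags["s"], kt$critical_lags["t"],
                     B = 499, seed = 2)
fit <- fit_clustering_model(cases, lab$clustered, "marker_positive",
                            density = di, ref_level = "no")
fit
#> Clustered vs nonclustered: marker_positive (density adjusted, LRT p = 0.004206)
#>  level n_clustered N_clustered n_nonclustered N_nonclustered   or ci_low ci_high
#>     no          22          46            130            185 1.00     NA      NA
#>    yes          24          46             55            185 2.63   1.36    5.11

sst <- size_spectrum_test(cases, pop, kt$critical_lags["s"], kt$critical_lags["t"],
                          B = 999, seed = 3)
sst
#> Cluster-size spectrum vs 999 Monte Carlo null replicates (lags 500 m, 182 d)
#>  size observed  mc_mean mc_min mc_max observed_cum  p_mc
#>     1      417 4.71e+02    441    490          458 1.000
#>     2       39 1.36e+01      4     27           41 0.001
#>     3        2 9.12e-01      0      5            2 0.277
#>     ...
```

The marker is enriched among clustered cases (density-adjusted OR 2.63, 95% CI
1.36–5.11), and the excess of clusters is confined to pairs (39 observed
size-2 clusters vs at most 27 in any of 999 null replicates, p = 0.001) —
exactly the structure the generator induced. `run_pipeline(analysis_config(...))`
chains all steps (including sibling exclusion and Holm correction) from CSV or
in-memory inputs and writes CSV/JSON outputs plus a run-metadata log.

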