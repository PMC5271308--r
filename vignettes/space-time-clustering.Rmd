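---
title: "Space-time clustering of childhood leukemia: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Space-time clustering of childhood leukemia: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(knoxclust)
```

## The scientific problem

Childhood leukemia (CL) is rare, and several etiological hypotheses — notably
an infectious trigger acting around birth — predict that incident cases should
aggregate in space *and* time more than chance allows. `knoxclust` implements
a three-step analysis of point-referenced registry data (birth location in
projected planar meters, birth date) that tests for such space-time
interaction, classifies individual cases as clustered or not, and then asks
whether clustered cases differ from nonclustered cases in clinical or
demographic characteristics (for example, carrying a cytogenetic marker such
as the ETV6-RUNX1 fusion).

The methodological crux is the null hypothesis. Children are not uniformly
distributed, and the spatial distribution of the child population *shifts over
time*; naive Knox tests confound this population drift with genuine
interaction. Here the null is therefore built by Monte Carlo: case locations
are resampled from the time-varying child population, conditional on each
case's birth date.

## Step 1 — Knox tests over a lag grid

For spatial lag $s$ and temporal lag $t$, the Knox statistic is the number of
unordered case pairs $(i, j)$ with

$$\lVert x_i - x_j \rVert < s \quad\text{and}\quad |d_i - d_j| < t,$$

with **strict** inequalities (a pair exactly at the lag is not close — the
clustered-case definition is "born less than 1 km and less than 2 years
apart"). Distances are Euclidean on projected planar coordinates; no geodesic
computation is done, so the caller must supply a metric projection.

`knox_test()` evaluates the statistic on a grid of lags (default 0.5, 1, 2, 5,
10 km by 6, 12, 18, 24 months). Because the registry convention counts months
and years in round days we fix "6 months" = 182 days, "12" = 365, "18" = 548,
"24 months" = 730 days; the calendar ambiguity is irrelevant at the precision
of the analysis but the convention matters for exact reproducibility.

**The Monte Carlo null.** Each of the $B$ replicates keeps all birth dates and
covariates fixed and redraws every case's birth location from the
time-interpolated population intensity at that case's birth date: a grid cell
is chosen with probability proportional to its interpolated child count, then
the location is uniform within the cell. Population intensity between two
census-style snapshots is linearly interpolated per cell; outside the covered
range the nearest snapshot is used. This conditional-location resampling is a
reconstruction of the published "population-shift-adjusted" procedure, whose
full specification is not public; it is the simplest mechanism that makes
uneven regional growth part of the null. Per cell of the grid,

$$E(s,t) = \frac{1}{B}\sum_b O_b(s,t), \qquad
  p(s,t) = \frac{1 + \#\{b : O_b \ge O_{\text{obs}}\}}{B + 1}.$$

The add-one convention is used for every Monte Carlo p-value in the package,
so $p \in \{1/(B+1), \dots, 1\}$ and the test is exact at level
$\alpha$ whenever $\alpha(B+1)$ is an integer (we use $B = 999$ by default,
$B = 199$ in simulation studies).

**Multiple testing over the grid.** Searching 20 lag combinations inflates the
familywise error. The adjusted p-value uses the standard max-statistic (min-p)
construction on the same null ensemble: each replicate's per-cell p-value is
computed against the ensemble leaving itself out, and

$$p_{\text{adj}} = \frac{1 + \#\{b : \min_c p_b(c) \le \min_c p_{\text{obs}}(c)\}}{B+1}.$$

This is always $\ge \min_c p_{\text{obs}}(c)$, and simulation (see the
acceptance tests) confirms the familywise rejection rate is nominal while the
uncorrected min-p rate is inflated.

**Critical lags.** The lag pair with the smallest per-cell p-value becomes the
critical lags $(s^\ast, t^\ast)$ used downstream. Ties — common at coarse
p-value resolution — are broken deterministically: larger observed/expected
ratio, then smaller spatial lag, then smaller temporal lag. The preference for
smaller lags under equal evidence keeps the clustered-case definition tight.

## Step 2 — clustered vs nonclustered cases

A case is **clustered** if at least one other case lies within
$(s^\ast, t^\ast)$ of it. `compare_characteristics()` then contrasts clustered
and nonclustered cases by logistic regression with clustering status as the
outcome, one characteristic at a time, with likelihood-ratio tests at the
characteristic level and Wald confidence intervals per level; cases with a
missing (or untested) value are excluded listwise per characteristic, so the
denominators vary across rows as they do in registry practice.

**The child-population-density index.** Cases in dense areas are clustered by
chance more easily, so any covariate correlated with population density
(urbanization, neighborhood socioeconomic position, ...) acquires a spurious
association with clustering status. The adjustment covariate is the per-case
log odds of being clustered *by chance alone*:
$\mathrm{logit}(p_i)$ with $p_i = \Pr(\ge 1$ other case within
$(s^\ast,t^\ast)$ of case $i$ under the null$)$. Two estimators are provided:

* `"mc"` (default): case $i$ stays at its observed location and date; the
  other cases are resampled from the null $B$ times; $p_i$ is the share of
  replicates with a neighbor within the lags.
* `"poisson"`: $\lambda_i$ = expected number of temporally close cases landing
  in the spatial disc, computed from the normalized cell intensities at each
  other case's birth date, and $p_i = 1 - e^{-\lambda_i}$. Cell/disc overlap
  is integrated on a 6 × 6 sub-grid per cell, accurate to a few percent even
  when the disc radius is comparable to the cell size.

Both estimators condition on the case's own birth date (the published index is
not specified at this level of detail; conditioning matches the null used
everywhere else in the package). Estimates are clamped to
$[1/(2B),\, 1 - 1/(2B)]$ before the logit so the index stays finite; clamping
is reported with a warning. The two estimators agree to about 0.1 on the logit
scale for moderate $\lambda$ (this is a unit test). In synthetic urban/rural
data generated under the null, a spurious "urban" association with clustering
status is attenuated toward OR 1 once the index enters the model — the
behavior that motivates the adjustment.

**Geographically determined covariates.** For covariates that are themselves
deterministic functions of birth location (distance bands to a point source),
the likelihood-ratio test is invalid: proximity of cases induces dependence of
their covariate values. `mc_covariate_pvalue()` calibrates the LRT statistic
by rerunning the whole chain per null replicate — resample locations,
re-classify clustered status at $(s^\ast, t^\ast)$, recompute the covariate
from the new locations, refit — and applies the add-one formula.

**Multiple testing across characteristics.** Characteristic-level p-values are
Holm step-down corrected (`holm_adjust()`, a labeled wrapper around the
standard step-down procedure). Which rows form the family is a configuration
choice (`characteristics` in `analysis_config()`); the package corrects across
exactly the characteristics it is asked to compare in one call.

## Step 3 — cluster sizes

Clustered cases are linked into **local clusters** as connected components of
the close-pair graph (edges = pairs within the critical lags, components via
igraph); chains merge transitively, so a cluster is a group in which every
member is close to at least one other member. `size_spectrum_test()` tabulates
clusters by exact size and compares, for every size $k$, the observed number
of clusters *of size $k$ or bigger* to the null distribution, again with
add-one Monte Carlo p-values. Per exact size the replicate mean, minimum and
maximum are reported alongside.

For sizes never reached by the data or the replicates the cumulative count is
0 for everything and the add-one convention yields exactly 1.0; some published
tables print 0.999 for such rows (apparently $1 - 1/(B+1)$ without the add-one
numerator), and we deliberately report 1.0 and document the difference rather
than replicate an unexplained convention.

## The synthetic registry generator

No real childhood-cancer registry microdata can be shipped, so
`generate_population()` / `generate_cases()` produce data with the statistical
structure the analysis assumes:

* a child population of (by default) 1.2 million in a 100 × 70 km region,
  laid out as a mixture of Gaussian population centers on a 1 km cell grid,
  whose mixture weights drift linearly between census-style snapshots
  (1985–2015) — this gives the regional population shifts the null must
  absorb;
* (by default) 1,282 cases with birth dates uniform over 1985–2014 and birth
  locations drawn from the interpolated intensity at the birth date, i.e.
  exactly the null mechanism;
* optional induced "mini-epidemics": Poisson-many cluster seeds, each with
  excess cases uniform in a 500 m disc and within ±½ of a 365-day window
  (a Matérn-like cluster in space, boxcar in time). The published analysis has
  no generative alternative model; this is the minimal alternative a Knox
  test should detect, and all its geometry parameters are reported with any
  result that uses them. Induced cases are carved out of `n_cases` so the
  study size stays fixed, and carry a `truth_cluster_id` for parameter
  recovery;
* a binary marker ("yes"/"no"/"untested") with background prevalence 0.25,
  in-cluster prevalence 0.75 by default (a 3× enrichment), and a
  missing-completely-at-random untested fraction of 0.556 — matching a
  registry in which 569 of 1,282 cases were cytogenetically tested. Treating
  untestedness as MCAR deliberately ignores that testing arrived mid-study;
* spatially determined covariates: an `urban` flag (local interpolated cell
  count above the children-weighted median) and `dist_source_m` (distance to
  fixed point sources), plus sex;
* sibling pairs born within 50 m and 3 years sharing a `sibling_group`, so
  the sibling-exclusion rule (`exclude_siblings()`: keep the earliest-born,
  ties to the lowest id; non-sibling pairs under 50 m are flagged for review,
  not dropped) is exercisable.

What the generator does **not** emulate: real geography and commuting or
migration between birth and diagnosis, age-incidence structure by subtype,
calendar trends in incidence, non-random testing, and household or school
contact networks. Passing tests therefore demonstrate that the machinery is
correct and calibrated under the stated mechanisms — not that any particular
real registry exhibits clustering.

## Numerical and reproducibility choices

* Dates are handled as integer days; "2 years" = 730 days, "6 months" = 182
  days throughout.
* All randomness flows from one root seed; `run_pipeline()` derives named
  per-stage substreams, and every generator/test function takes an explicit
  seed and restores the caller's RNG state.
* Close-pair enumeration sorts by date and scans a sliding temporal window,
  so the per-replicate cost is proportional to the number of temporally close
  pairs rather than $n^2$; replicate cell draws are batched per case. A
  registry-scale run (1,282 cases, $B = 999$, full grid) takes seconds.
* 2 × 2 odds ratios use the Haldane–Anscombe 0.5 continuity correction only
  when a cell is zero, with a warning (published tables have no zero cells,
  so this is an extension).
* Possible separation in logistic fits is flagged and the Monte Carlo
  fallback suggested rather than silently reported.

## Simulation study sizes

The packaged tests run: type-I calibration over 200 null studies of 500 cases
at $B = 199$ on a 30 × 30 km / 120,000-children population (per-cell and
familywise rejection rates must sit in the exact binomial 99% band around
0.05); a power/recovery study over 100 seeds with an expected 25 induced
clusters of one excess case each (Knox rejection well above the null rate, a
positive mean clustered-vs-nonclustered marker log-OR, and a significant
excess at cluster size 2 but not at sizes ≥ 4); and oracle-equivalence checks
of pair counts, flags and components against brute-force reimplementations on
200 random instances. These sizes were chosen so the whole suite runs in a
couple of minutes while keeping the binomial bands tight enough to be
meaningful.

## Known limitations

* The null-replicate mechanism and the density index are reconstructions of
  summarized procedures; where the original specification is unavailable the
  package documents its own choice rather than claiming equivalence.
* The Knox test analyzes place and time of *birth* only; clustering at
  diagnosis, scan statistics, and geodesic distances are out of scope.
* The Poisson density estimator ignores within-replicate dependence between
  neighbors (it exponentiates a sum of marginal probabilities); the MC
  estimator is the default for inference.
* With coarse population cells relative to the smallest spatial lag, both the
  null and the density index inherit discretization error; choose
  `cell_size_m` at or below the smallest lag of interest.
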