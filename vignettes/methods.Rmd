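---
title: "Detecting and clustering ecosystem change in gridded water-content time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and clustering ecosystem change in gridded water-content time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecotrend)
```

## The problem

Satellite records of soil moisture (SM, m³·m⁻³) and L-band vegetation
optical depth (VOD, a microwave proxy for vegetation water content and
aboveground biomass) now span a decade or more at ~25 km resolution.
Regions where both variables drift monotonically — soils drying while
canopies thin, or both recovering together — are fingerprints of large
ecosystem changes: deforestation, wildfire, reforestation, shifts in
rainfall regimes. Finding those regions honestly from the data poses three
statistical problems at once:

1. **Serial correlation.** Monthly geophysical series are strongly
   autocorrelated, which inflates the false-positive rate of any naive
   trend test.
2. **Massive multiplicity with spatial correlation.** Tens of thousands of
   grid cells are tested simultaneously, and neighbouring cells are not
   independent, so per-cell p-values cannot simply be thresholded (nor is a
   Bonferroni-style correction appropriate — it ignores the spatial
   structure and destroys power).
3. **Interpretation.** A per-variable map of significant trends is not yet
   an "ecosystem change": it is the *joint* direction of SM and VOD change,
   with auxiliary precipitation trends, that distinguishes (say) rainfall-
   driven greening from irrigation-driven cropland change.

This package implements the full chain: per-cell trend testing on annual
quantile series with an AR(1) correction, cluster-based permutation control
of field-wise significance, merging of quantile-wise maps into signed
change maps, rule-based bivariate clustering, and per-cluster reporting
(trends in %/yr, areas in km², fractional land-cover change in km²). A
synthetic-data module generates data cubes with the statistical structure
the analysis assumes, so every stage can be validated against known truth
without any satellite download.

## Per-cell trend model

For one cell and one quantile level $q \in \{0.1, 0.25, 0.5, 0.75, 0.9\}$,
the tested series is the annual $q$-quantile $y_t$ of the twelve monthly
values of calendar year $t$ (linear interpolation between order statistics,
the R type-7 rule — stated explicitly because quantile tables depend on
it). Working on annual-distribution quantiles removes the seasonal cycle
without modelling it, and testing five levels separately distinguishes
changes in the wet and dry tails from changes in the median.

The lag-1 sample autocorrelation $r_1$ of $y_t$ is estimated and the
residual series

$$y'_t = y_t - r_1\, y_{t-1}, \qquad t = 2,\dots,n$$

is formed (pre-whitening; the residual is undefined at $t=1$, so the series
shortens by one). The Mann–Kendall test is then applied to $y'_t$:
$S = \sum_{i<j} \mathrm{sign}(y'_j - y'_i)$ with tie-corrected variance
$\mathrm{Var}(S) = \left[n(n-1)(2n+5) - \sum_g t_g(t_g-1)(2t_g+5)\right]/18$
and a continuity-corrected standardized score with a two-sided normal
p-value. Trend magnitude is Sen's slope — the median of all pairwise slopes
— computed on the *original* (un-whitened) annual series, since
pre-whitening rescales magnitudes; an OLS slope is available as a config
alternative (`slope_method = "ols"`) because either estimator is defensible
for the "mean linear trend" of a short annual series, and the two agree
closely on our synthetic data.

Design choices worth stating: $r_1$ is the plain sample autocorrelation of
the tested annual series (trend-free pre-whitening, which detrends before
estimating $r_1$, is available via `prewhiten_ar1(detrend = TRUE)` but off
by default — with ten annual values the detrending step costs more in
variance than it recovers in bias); years with more than half their months
missing are dropped; cells with fewer than three usable years are masked
rather than raising an error, since gappy cells are normal in satellite
products.

Why this matters is measurable: on stationary AR(1) series with
$\phi = 0.5$ and $n = 30$, the raw Mann–Kendall test rejects at the 0.05
level roughly 20% of the time; the pre-whitened test is restored to ~5%
(the test suite and `scripts/acceptance.R` recompute both rates on 5000
replicates).

## Field significance by cluster permutation

Per-cell testing at $\alpha = 0.05$ flags ~5% of a pure-noise map, and
spatial correlation makes those false positives clump into plausible-looking
patches. The correction is permutation-based: under the null of no trend,
the *year labels* of the annual series are exchangeable. Each permutation
draws ONE shuffle of the years and applies it identically at every cell —
this preserves each year's spatial field intact, and with it the spatial
correlation of the data, which is exactly what makes null clusters large.
The full per-cell chain (including re-estimating $r_1$) is re-run on the
shuffled series, cells with $p < \alpha$ are labeled into connected
components (8-neighbour connectivity by default; 4 is available), and the
largest component size is recorded. Observed clusters are retained only if
their size exceeds the 0.95 quantile of this null max-cluster-size
distribution — the standard max-statistic construction, which controls the
family-wise error of retaining any spurious cluster.

The shared shuffle is load-bearing. The test suite demonstrates that
shuffling each cell independently *deflates* the null (mean max cluster
size drops by a factor of ~5 on a spatially correlated field), because it
destroys the spatial correlation of the significance field; a threshold
calibrated that way would be far too lenient. On 200 pure-noise scenarios
(40×40 cells, 10 years, AR(1) $\phi=0.5$, spatially smoothed), the
fraction of scenarios with any retained cluster is ~0.05, while naive
per-cell testing flags something in essentially every scenario.

Permutation counts: the null quantile is a tail statistic, so `n_perm` has
a floor of 100; the package default is 500. The validation runs in this
package use 200 permutations per map, which resolves the 0.95 quantile to
within a cell or two on the problem sizes used here (40×40 to 48×60 grids,
10 years) — sizes chosen so the whole pipeline and its repeated-simulation
calibration checks run comfortably on a single CPU.

## Merging quantiles and bivariate clustering

The five quantile-wise maps per variable are merged: a cell is significant
if it lies in a retained cluster for at least one quantile; its sign is the
majority Mann–Kendall sign over its significant quantiles, with an exact
tie demoting the cell to not-significant (conservative: we refuse to
fabricate a direction); its slope is the median Sen slope over the
significant quantiles. The merged map also carries the median slope over
*all* quantiles, so that downstream rules can use a trend magnitude for a
variable that is not itself significant at a cell.

Cells significant in SM and/or VOD are then categorized by their joint sign
signature. The three signatures that correspond to coherent ecosystem
change stories are $(+,+)$ (wetter soil, more vegetation water), $(-,-)$
(drier and losing biomass) and $(-,+)$ (drier soil under a growing canopy —
the signature of young plantations drawing down soil water). Two auxiliary
splits refine them, mirroring how the change types differ in practice:

* $(+,+)$ splits on the precipitation relative trend (default threshold
  1 %/yr): above it, the gain is rainfall-driven ("A-like"); below it, the
  gain occurs without a rainfall change ("D-like", e.g. irrigation or
  land-use change).
* $(-,-)$ splits on joint loss magnitude, $\tfrac12(|\Delta_{SM}\%| +
  |\Delta_{VOD}\%|)$: the default threshold is the 75th percentile of that
  magnitude among $(-,-)$ cells, separating gradual degradation ("B-like")
  from abrupt, severe loss ("E-like", e.g. fire). A 2-means midpoint split
  is available (`mag_split = "kmeans"`) and is the better choice when the
  two loss populations are closer to equal in area; the quantile default
  reflects that severe-loss regions are characteristically much smaller
  than gradual-degradation regions.

Each category is decomposed into connected components and components
smaller than `min_area_cells` (default 20) are dropped. The procedure is
deliberately rule-based and deterministic — signs, two thresholds,
contiguity, an area floor — rather than an unsupervised clustering, so
every cluster's membership is auditable; an exploratory k-means refinement
in standardized trend space can be layered on by the user from the exported
slope layers. The residual $(+,-)$ signature (wetter soil, less vegetation)
is kept as its own category rather than discarded: it has no canonical
change story, and surfacing it is more honest than hiding it.

Cluster quality is scored by the mean silhouette coefficient in z-scored
trend-feature space (`separability_score`, backed by `cluster::silhouette`).
On the synthetic five-cluster scenario the joint SM+VOD feature space
separates the clusters better than SM or VOD alone in 10/10 seeds — the
joint space is the point of the method, since several cluster pairs are
indistinguishable in either marginal.

Areas use the equal-angle approximation $A = a^2 \cos(\mathrm{lat})$ for a
nominal cell size $a$ (625 km² at the equator for 25-km cells), summed over
cluster cells.

## Land-cover accounting

Categorical land-cover maps on a finer grid (one class per fine cell, the
twelve broad plant-functional-type categories: water bodies, four forest
types, grasslands, shrub lands, two cropland types, urban, permanent
snow/ice, barren) are aggregated to per-class area *fractions* on the
analysis grid — fractions, not dominant types, because a 25–30 km cell that
goes from 60% to 35% forest is precisely the signal of interest. The
coarse/fine ratio is a free integer factor rather than the hard-coded
500 m → 30 km of real products, so synthetic grids can stay small.
Differencing two epochs gives per-class fraction changes that sum to zero
per cell (land is conserved); multiplying by cell areas and summing over a
cluster gives the per-class km² change table. Net change is reported;
gross turnover ($\sum |\Delta| \times$ area) is attached as an attribute
since the two answer different questions. Water, urban and barren classes
participate identically — no masking.

## The synthetic-data generator

`generate_cube()` builds
`base_mean + seasonal sinusoid + spatially smoothed AR(1) noise + regional
ramps`:

* **Temporal noise** is AR(1) per cell (coefficient `ar1_phi`, innovation
  sd `noise_sd`), started from the stationary distribution. This is the
  simplest process with the "strong temporal autocorrelation" that
  motivates pre-whitening, with one interpretable knob.
* **Spatial correlation** comes from smoothing each monthly noise slice
  with a normalized Gaussian kernel of width `spatial_corr_cells` (in
  cells), applied as separable circulant (wrap-around) matrices. The
  wrap-around boundary keeps the operator doubly stochastic, so the field
  mean is preserved exactly; and because a weighted sum of independent
  AR(1) processes with common $\phi$ is again AR(1) with the same $\phi$,
  smoothing leaves the per-cell temporal autocorrelation untouched. Two
  knobs, two orthogonal correlation structures.
* **Seasonality** is a single 12-month sinusoid (`seasonal_amp`). This is
  sufficient because the trend tests operate on annual-distribution
  quantiles, which are invariant to within-year phase; the generator does
  not attempt realistic phenology shapes (double growing seasons,
  asymmetric green-up), and passing tests say nothing about those.
* **Trends** are linear ramps `slope × elapsed_years` added inside region
  masks *after* smoothing, so region edges are sharp and recovery scoring
  against the truth masks is unambiguous.
* **Physical ranges** are clipped only where configured: SM to [0,1], NDVI
  to [−1,1], VOD and precipitation to non-negative. Precipitation is
  truncated at zero rather than log-transformed; quantile-based testing is
  insensitive to mild truncation and the defaults keep truncation rare.

`make_five_cluster_scenario()` fixes the study conditions used throughout
the validation: a 48×60 grid of 25-km cells, 10 years of monthly data,
$\phi = 0.5$, smoothing length 1.5 cells, and five disjoint rectangular
regions (buffered by ≥5 cells so connected-component recovery is
unambiguous) carrying the canonical signatures — A $(+,+)$ with a positive
precipitation trend, D $(+,+)$ without one, B $(-,-)$ mild, E $(-,-)$
strong (twice B's slopes, and the smallest region, as severe-loss regions
characteristically are), C $(-,+)$. Noise levels (SM 0.010 m³·m⁻³, VOD
0.015, NDVI 0.02, precipitation 10 mm/month) are set so that per-cell
trends are detectable but individual cells near region edges can fail —
i.e. the field-significance stage has real work to do. Real products'
noise magnitudes and spatial correlation lengths are not published at this
level of abstraction; these values are a testability choice, not a realism
claim, and were fixed once when the generator was written. Paired
land-cover epochs with scripted transitions (forest→grass in B,
grass→forest in D, forest/grass→shrub in E) complete the scenario.

What the generator does *not* emulate — retrieval error structure,
radio-frequency interference, orbit gaps, realistic phenology, land-cover
misclassification — bounds what passing tests mean: they validate the
statistics of the pipeline, not its behaviour on any real product's
artefact mix.

## Numerical and degenerate-input choices

* Constant series: $r_1$ is defined as 0, Mann–Kendall returns
  $S=0, Z=0, p=1$ (a null result, not an error); Sen's slope on an
  all-constant series with no distinct time pair is an error.
* The continuity correction in $Z$ is applied (classical practice for the
  discrete $S$).
* Ties contribute to the variance correction through group sizes computed
  exactly; the permutation engine uses the same tie-aware code path.
* The null size threshold uses R's default type-7 quantile of the
  `n_perm` max-cluster sizes; retention requires strictly exceeding it.
* All permutation and generation functions take explicit integer seeds and
  are bitwise reproducible; `set.seed` is called inside, with the caller's
  RNG state saved and restored.
* The vectorized engine computes all cells simultaneously (column-major
  matrices of annual series), which is what makes 200 permutations × 15
  maps × thousands of cells tractable in pure R; gappy cells drop to a
  per-cell fallback path with identical arithmetic.

## Worked example

```{r example, eval = FALSE}
library(ecotrend)
sc  <- make_five_cluster_scenario(seed = 1)
run <- run_pipeline(sc, n_perm = 200, seed = 1)
summary(run)
plot(run)                         # cluster label map
plot(run$series[["1"]]$sm)        # annual boxplots + trend for cluster 1
```

## Known limitations

* The bivariate split thresholds (precipitation 1 %/yr; magnitude 75th
  percentile) are documented configuration values, not estimates; on data
  whose loss populations are balanced, switch the magnitude split to
  `"kmeans"`.
* Merging by "significant in ≥1 quantile" unions five tests per variable,
  so a run occasionally yields a small spurious cluster beyond the injected
  ones — the price of sensitivity to tail-only changes; the area floor
  removes most of them.
* The permutation test assumes whole years are exchangeable under the
  null; slow non-monotonic decadal variability (e.g. ENSO phases) violates
  that and would be detected as trend by any 10-year method.
* No seasonal Mann–Kendall variant, no change-point detection, no
  cluster-mass statistics; these are deliberate non-goals.
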