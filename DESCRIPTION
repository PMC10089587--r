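Package: ecotrend
Title: Trend Detection and Change Clustering for Gridded Soil Moisture and Vegetation Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects statistically significant monotonic trends in monthly
    gridded environmental time series (soil moisture, vegetation optical
    depth, NDVI, precipitation) with an AR(1) pre-whitened Mann-Kendall test
    applied to annual-distribution quantiles, corrects for multiple testing
    across the grid with a cluster-based year-permutation test that preserves
    spatial correlation, merges quantile-wise significance maps into signed
    change maps, groups cells into homogeneous bivariate change clusters,
    and summarizes per-cluster trends, areas and fractional land-cover
    change. Includes a synthetic data-cube generator with known AR(1) noise,
    spatial correlation, seasonality and injected regional trends for
    validation of the whole pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, cluster, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
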