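test_that("degenerate generator settings give the exact deterministic field", {
  sp <- synthetic_spec(n_lat = 4, n_lon = 5, n_years = 3, noise_sd = 0,
                       seasonal_amp = 0, base_mean = 0.2)
  cube <- generate_cube(sp, list(), "sm")
  expect_true(all(cube$values == 0.2))
  # seasonality adds exactly the configured sinusoid
  sp2 <- synthetic_spec(n_lat = 2, n_lon = 2, n_years = 3, noise_sd = 0,
                        seasonal_amp = 0.05, base_mean = 0.2)
  cube2 <- generate_cube(sp2, list(), "sm")
  expect_equal(cube2$values[, 1, 1],
               0.2 + 0.05 * sin(2 * pi * (rep(0:11, 3)) / 12))
})

test_that("an injected ramp shifts annual means by slope x elapsed years", {
  sp <- synthetic_spec(n_lat = 5, n_lon = 5, n_years = 10, noise_sd = 0,
                       seasonal_amp = 0, base_mean = 0.2)
  mask <- matrix(FALSE, 5, 5); mask[2:3, 2:4] <- TRUE
  cube <- generate_cube(sp, list(region_trend(mask, c(sm = 0.01))), "sm")
  y1 <- mean(cube$values[1:12, 2, 2])
  y10 <- mean(cube$values[109:120, 2, 2])
  expect_equal(y10 - y1, 0.09, tolerance = 1e-9)
  # cells outside the mask untouched
  expect_true(all(cube$values[, 5, 5] == 0.2))
})

test_that("generator errors on invalid specs and mismatched masks", {
  expect_error(synthetic_spec(ar1_phi = 1), "ar1_phi")
  expect_error(synthetic_spec(noise_sd = -1), "noise_sd")
  expect_error(synthetic_spec(n_years = 2), "n_years")
  sp <- synthetic_spec(n_lat = 4, n_lon = 4, n_years = 3)
  bad <- region_trend(matrix(TRUE, 3, 3), c(sm = 0.1))
  expect_error(generate_cube(sp, list(bad), "sm"), "shape")
})

test_that("generated noise has the configured lag-1 autocorrelation", {
  sp <- synthetic_spec(n_lat = 3, n_lon = 3, n_years = 50, ar1_phi = 0.8,
                       noise_sd = 0.01, spatial_corr_cells = 0,
                       seasonal_amp = 0.02, base_mean = 0.5)
  cube <- generate_cube(sp, list(), "vod", seed = 21)
  for (cell in list(c(1, 1), c(2, 3), c(3, 2))) {
    v <- cube$values[, cell[1], cell[2]]
    des <- v - ave(v, rep(1:12, 50))     # remove the seasonal cycle
    r1 <- lag1_autocorrelation(des)
    expect_gt(r1, 0.7)
    expect_lt(r1, 0.9)
  }
})

test_that("spatial smoothing preserves the field mean", {
  base <- synthetic_spec(n_lat = 24, n_lon = 24, n_years = 4, ar1_phi = 0.5,
                         noise_sd = 1, spatial_corr_cells = 0,
                         seasonal_amp = 0, base_mean = 0)
  smoothed <- base; smoothed$spatial_corr_cells <- 2.5
  c0 <- generate_cube(base, list(), "x", seed = 13)
  c1 <- generate_cube(smoothed, list(), "x", seed = 13)
  expect_equal(mean(c1$values), mean(c0$values), tolerance = 1e-6)
  # and induces positive correlation between neighbours
  a <- c1$values[, 10, 10]; b <- c1$values[, 10, 11]
  expect_gt(cor(a, b), 0.5)
})

test_that("identical spec and seed give bitwise-identical cubes", {
  sp <- synthetic_spec(n_lat = 6, n_lon = 6, n_years = 5, noise_sd = 0.02)
  c1 <- generate_cube(sp, list(), "sm", seed = 4)
  c2 <- generate_cube(sp, list(), "sm", seed = 4)
  expect_identical(c1$values, c2$values)
  c3 <- generate_cube(sp, list(), "sm", seed = 5)
  expect_false(identical(c1$values, c3$values))
})

test_that("injected Sen slope is recoverable from annual medians", {
  sp <- synthetic_spec(n_lat = 6, n_lon = 6, n_years = 10, ar1_phi = 0.5,
                       noise_sd = 0.002, spatial_corr_cells = 1,
                       seasonal_amp = 0.03, base_mean = 0.3)
  mask <- matrix(FALSE, 6, 6); mask[2:5, 2:5] <- TRUE
  cube <- generate_cube(sp, list(region_trend(mask, c(sm = 0.01))), "sm",
                        seed = 31)
  tm <- trend_map(cube, 0.5)
  rel_err <- abs(tm$slope[mask] - 0.01) / 0.01
  expect_true(all(rel_err < 0.10))
})

test_that("five-cluster scenario has the canonical signatures and disjoint buffered regions", {
  sc <- make_five_cluster_scenario(seed = 1)
  sc_same <- make_five_cluster_scenario(seed = 1)
  expect_identical(sc$cubes$sm$values, sc_same$cubes$sm$values)
  expect_identical(sc$cubes$vod$values, sc_same$cubes$vod$values)
  masks <- lapply(sc$truth_regions, `[[`, "mask")
  # pairwise disjoint
  total <- Reduce(`+`, masks)
  expect_true(all(total <= 1))
  sgn <- sapply(sc$truth_regions, function(rt)
    sign(rt$slopes[c("sm", "vod")]))
  expect_equal(unname(sgn["sm", ]), c(1, -1, -1, 1, -1))
  expect_equal(unname(sgn["vod", ]), c(1, -1, 1, 1, -1))
  # A/D separator: positive precip trend in A, none in D
  expect_gt(sc$truth_regions$A$slopes[["precip"]], 0)
  expect_equal(sc$truth_regions$D$slopes[["precip"]], 0)
  # losses more pronounced in E than in B
  expect_gt(abs(sc$truth_regions$E$slopes[["sm"]]),
            abs(sc$truth_regions$B$slopes[["sm"]]))
  expect_gt(abs(sc$truth_regions$E$slopes[["vod"]]),
            abs(sc$truth_regions$B$slopes[["vod"]]))
})

test_that("landcover epoch generation applies scripted transitions and conserves fractions", {
  g <- make_grid(6, 6)
  # no transitions: epochs identical
  lc0 <- generate_landcover_epochs(g, 3, transitions = list(), seed = 2)
  expect_equal(lc0[[1]]$fractions, lc0[[2]]$fractions)
  # complete conversion of forest to grass inside a mask
  mask <- matrix(FALSE, 6, 6); mask[2:4, 2:4] <- TRUE
  lc <- generate_landcover_epochs(g, 3, transitions = list(
    list(mask = mask, from = "evergreen broadleaf forest",
         to = "grasslands", fraction = 1)), seed = 2)
  i_f <- match("evergreen broadleaf forest", pft_classes())
  i_g <- match("grasslands", pft_classes())
  d <- epoch_difference(lc[[1]], lc[[2]])
  expect_equal(d[i_f, , ][mask], -lc[[1]]$fractions[i_f, , ][mask])
  expect_equal(d[i_g, , ][mask], lc[[1]]$fractions[i_f, , ][mask])
  D <- matrix(d, nrow = dim(d)[1])
  expect_true(all(D[, !as.vector(mask)] == 0))
  # partition of unity in both epochs
  for (ep in lc)
    expect_equal(as.vector(apply(ep$fractions, c(2, 3), sum)),
                 rep(1, 36), tolerance = 1e-9)
  expect_error(generate_landcover_epochs(g, 3, transitions = list(
    list(mask = mask, from = "grasslands", to = "shrub lands", fraction = 1.2))),
    "fraction")
})

test_that("cube and truth serialization round-trips through text files", {
  dir <- tempfile()
  sp <- synthetic_spec(n_lat = 4, n_lon = 3, n_years = 3, noise_sd = 0.01)
  cube <- generate_cube(sp, list(), "sm", seed = 6)
  write_cube(cube, dir)
  back <- read_cube(dir)
  expect_equal(back$values, cube$values, tolerance = 1e-12)
  expect_equal(back$variable, "sm")
  expect_equal(back$time, cube$time)
  sc <- make_five_cluster_scenario(seed = 2, n_years = 3)
  tf <- tempfile(fileext = ".json")
  write_truth(sc, tf)
  tr <- read_truth(tf)
  expect_equal(length(tr$regions), 5)
  expect_equal(tr$regions[[1]]$mask, sc$truth_regions$A$mask)
  expect_equal(tr$regions[[5]]$slopes[["sm"]],
               sc$truth_regions$E$slopes[["sm"]])
  unlink(dir, recursive = TRUE); unlink(tf)
})
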