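# minimal trend_map + retained-cluster pair for merge tests
fake_quantile_map <- function(grid, sig, sgn, slope, q, ref = 1) {
  tm <- structure(list(variable = "sm", q = q, grid = grid,
                       p = matrix(ifelse(sig, 0.001, 0.5),
                                  grid$n_lat, grid$n_lon),
                       S = matrix(sgn * 10, grid$n_lat, grid$n_lon),
                       slope = matrix(slope, grid$n_lat, grid$n_lon),
                       ref_mean = matrix(ref, grid$n_lat, grid$n_lon)),
                  class = "trend_map")
  lab <- matrix(0L, grid$n_lat, grid$n_lon)
  lab[sig] <- 1L
  list(trend_map = tm, clusters = list(labels = lab))
}

test_that("quantile-map merging follows the majority-sign and median-slope rules", {
  g <- make_grid(1, 1)
  qs <- c(0.1, 0.25, 0.5, 0.75, 0.9)
  # unanimous positive across 5 quantiles, slopes 1..5 -> median 3
  maps <- lapply(1:5, function(i)
    fake_quantile_map(g, sig = matrix(TRUE, 1, 1), sgn = 1, slope = i, q = qs[i]))
  cm <- merge_quantile_maps(maps)
  expect_true(cm$significant[1, 1])
  expect_equal(cm$sign[1, 1], 1L)
  expect_equal(cm$slope[1, 1], 3)
  # significant nowhere
  maps0 <- lapply(1:5, function(i)
    fake_quantile_map(g, sig = matrix(FALSE, 1, 1), sgn = 1, slope = i, q = qs[i]))
  cm0 <- merge_quantile_maps(maps0)
  expect_false(cm0$significant[1, 1])
  expect_equal(cm0$sign[1, 1], 0L)
  # 2 positive vs 2 negative significant quantiles: the tie demotes the cell
  sgns <- c(1, 1, -1, -1, 1)
  sigs <- c(TRUE, TRUE, TRUE, TRUE, FALSE)
  mapst <- lapply(1:5, function(i)
    fake_quantile_map(g, sig = matrix(sigs[i], 1, 1), sgn = sgns[i],
                      slope = sgns[i], q = qs[i]))
  cmt <- merge_quantile_maps(mapst)
  expect_false(cmt$significant[1, 1])
  expect_equal(cmt$sign[1, 1], 0L)
})

test_that("merging a merged map with itself changes nothing (idempotence)", {
  g <- make_grid(4, 4)
  sig <- matrix(FALSE, 4, 4); sig[1:2, 1:2] <- TRUE
  maps <- lapply(c(0.1, 0.5, 0.9), function(q)
    fake_quantile_map(g, sig, sgn = 1, slope = 0.3, q = q))
  cm <- merge_quantile_maps(maps)
  remap <- list(list(trend_map = structure(
    list(variable = "sm", q = 0.5, grid = g,
         p = ifelse(cm$significant, 0.001, 0.5),
         S = cm$sign * 10, slope = cm$slope, ref_mean = cm$ref_mean),
    class = "trend_map"),
    clusters = list(labels = matrix(as.integer(cm$significant), 4, 4))))
  cm2 <- merge_quantile_maps(remap)
  expect_equal(cm2$significant, cm$significant)
  expect_equal(cm2$sign, cm$sign)
  expect_equal(cm2$slope[cm$significant], cm$slope[cm$significant])
})

test_that("cluster areas use cosine-of-latitude weighting and are additive", {
  g_eq <- make_grid(1, 1, cell_km = 25, lat0 = -25 / 111.195 / 2)  # centered on equator
  m <- matrix(TRUE, 1, 1)
  expect_equal(cluster_area(m, g_eq), 625, tolerance = 1e-6)
  g_60 <- make_grid(1, 1, cell_km = 25, lat0 = 60 - 25 / 111.195 / 2)
  expect_equal(cluster_area(m, g_60), 625 * cos(60 * pi / 180), tolerance = 0.01 * 312.5)
  g <- make_grid(10, 10)
  a <- matrix(FALSE, 10, 10); a[1:3, 1:3] <- TRUE
  b <- matrix(FALSE, 10, 10); b[7:9, 7:9] <- TRUE
  expect_equal(cluster_area(a | b, g), cluster_area(a, g) + cluster_area(b, g))
})

test_that("bivariate clustering recovers constructed sign-signature regions exactly", {
  g <- make_grid(30, 30)
  F <- matrix(FALSE, 30, 30)
  rA <- F; rA[2:7, 2:7] <- TRUE         # (+,+), precip up
  rB <- F; rB[2:12, 10:19] <- TRUE      # (-,-), mild; large enough that the
                                        # within-category split quantile falls
                                        # below the strong-loss region
  rC <- F; rC[2:7, 22:27] <- TRUE       # (-,+)
  rD <- F; rD[15:20, 2:7] <- TRUE       # (+,+), no precip trend
  rE <- F; rE[15:20, 12:17] <- TRUE     # (-,-), strong
  sig <- rA | rB | rC | rD | rE
  sm_slope <- 0.004 * (rA + rD) - 0.003 * rB - 0.004 * rC - 0.008 * rE
  vod_slope <- 0.005 * rA + 0.009 * rD - 0.006 * rB + 0.008 * rC - 0.012 * rE
  pr_slope <- 2.5 * rA
  sm <- fake_change_map(g, sig & sm_slope != 0, sign(sm_slope), sm_slope, ref = 0.2)
  vod <- fake_change_map(g, sig, sign(vod_slope), vod_slope,
                         ref = matrix(0.35, 30, 30), variable = "vod")
  pr <- fake_change_map(g, rA, sign(pr_slope), pr_slope,
                        ref = matrix(80, 30, 30), variable = "precip")
  cs <- bivariate_cluster(sm, vod, pr, min_area_cells = 10)
  expect_equal(nrow(cs$table), 5)
  expect_setequal(cs$table$subtype, c("A", "B", "C", "D", "E"))
  for (pair in list(list(rA, "A"), list(rB, "B"), list(rC, "C"),
                    list(rD, "D"), list(rE, "E"))) {
    bj <- best_jaccard(pair[[1]], cs)
    expect_equal(bj$jaccard, 1)
    expect_equal(cs$table$subtype[cs$table$label == bj$label], pair[[2]])
  }
  # C signature: negative SM, positive VOD
  rowC <- cs$table[cs$table$subtype == "C", ]
  expect_equal(rowC$sign_sm, -1L)
  expect_equal(rowC$sign_vod, 1L)
  # signatures never contradict the underlying sign layers
  for (k in cs$table$label) {
    cells <- cs$labels == k
    r <- cs$table[cs$table$label == k, ]
    s_sm <- ifelse(sm$significant, sm$sign, sign(sm$slope_all))[cells]
    expect_true(all(s_sm == r$sign_sm | s_sm == 0))
  }
  # a dominating area filter empties the result
  cs_empty <- bivariate_cluster(sm, vod, pr, min_area_cells = 1000)
  expect_equal(nrow(cs_empty$table), 0)
})

test_that("a lone (-,+) region gives a single C-signature cluster", {
  g <- make_grid(12, 12)
  r <- matrix(FALSE, 12, 12); r[4:9, 4:9] <- TRUE
  sm <- fake_change_map(g, r, -r, -0.004 * r, ref = 0.2)
  vod <- fake_change_map(g, r, +r, 0.008 * r, ref = 0.35, variable = "vod")
  pr <- fake_change_map(g, matrix(FALSE, 12, 12), matrix(0, 12, 12),
                        matrix(0, 12, 12), ref = 80, variable = "precip")
  cs <- bivariate_cluster(sm, vod, pr, min_area_cells = 5)
  expect_equal(nrow(cs$table), 1)
  expect_equal(cs$table$subtype, "C")
})

test_that("silhouette separability behaves like the standard score", {
  set.seed(17)
  # two well-separated blobs
  X <- rbind(matrix(rnorm(100, 0), ncol = 2), matrix(rnorm(100, 6), ncol = 2))
  lab <- rep(1:2, each = 50)
  expect_gt(separability_score(X, lab), 0.7)
  # random labels on one cloud: near zero
  X1 <- matrix(rnorm(200), ncol = 2)
  expect_lt(abs(separability_score(X1, sample(1:2, 100, TRUE))), 0.1)
  expect_error(separability_score(X, rep(1, 100)), "fewer than 2")
  # cross-check against a direct silhouette computation on a tiny case
  Xt <- matrix(c(0, 0, 10, 10, 0.5, -0.5, 10.5, 9.5), ncol = 2)
  lt <- c(1, 1, 2, 2)
  Z <- scale(Xt)
  d <- as.matrix(dist(Z))
  sil <- sapply(1:4, function(i) {
    a <- mean(d[i, setdiff(which(lt == lt[i]), i)])
    b <- mean(d[i, lt != lt[i]])
    (b - a) / max(a, b)
  })
  expect_equal(separability_score(Xt, lt), mean(sil), tolerance = 1e-10)
})
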