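# annual per-cell aggregate: mean of monthly values for state variables,
# SUM over months for precipitation (annual cumulative precipitation)
.annual_aggregate <- function(cube, fun = c("mean", "sum")) {
  fun <- match.arg(fun)
  V <- .cube_matrix(cube)
  yrs <- sort(unique(cube$time$year))
  A <- matrix(NA_real_, length(yrs), ncol(V))
  for (iy in seq_along(yrs)) {
    M <- V[cube$time$year == yrs[iy], , drop = FALSE]
    A[iy, ] <- if (fun == "mean") colMeans(M) else colSums(M)
  }
  list(years = yrs, values = A)
}

.default_agg <- function(variable) if (variable == "precip") "sum" else "mean"

#' Per-cluster annual series and trend summary
#'
#' For each year, the area-weighted spatial mean over the cluster mask of the
#' per-cell annual aggregate (mean of the monthly values; SUM for
#' precipitation, i.e. annual cumulative precipitation), along with boxplot
#' statistics (median, quartiles, 1.5 IQR whiskers) of the spatial
#' distribution. The trend of the annual mean series is Sen's slope (an OLS
#' slope with its standard error is reported alongside) and the relative
#' trend is percent of the series mean per year.
#'
#' @param cube a \code{data_cube}
#' @param mask logical n_lat x n_lon cluster mask (non-empty)
#' @param grid an \code{eco_grid} (defaults to the cube's)
#' @param agg \code{"mean"} or \code{"sum"}; default by variable
#' @return object of class \code{cluster_series}: \code{years}, \code{mean}
#'   (area-weighted spatial means), \code{box} (data.frame of per-year
#'   spatial boxplot stats), \code{trend}, \code{trend_ols},
#'   \code{trend_ols_se}, \code{rel_trend}
#' @export
cluster_annual_series <- function(cube, mask, grid = cube$grid,
                                  agg = .default_agg(cube$variable)) {
  if (!any(mask)) stop("cluster mask is empty")
  ag <- .annual_aggregate(cube, agg)
  idx <- which(mask)
  w <- as.vector(grid_area_matrix(grid))[idx]
  w <- w / sum(w)
  A <- ag$values[, idx, drop = FALSE]
  m <- as.vector(A %*% w)
  box <- t(apply(A, 1, function(v) {
    qs <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- qs[3] - qs[1]
    lo <- min(v[v >= qs[1] - 1.5 * iqr])
    hi <- max(v[v <= qs[3] + 1.5 * iqr])
    c(lower = lo, q25 = qs[1], median = qs[2], q75 = qs[3], upper = hi)
  }))
  ny <- length(ag$years)
  fit <- stats::lm(m ~ seq_len(ny))
  ols_se <- suppressWarnings(summary(fit)$coefficients[2, 2])  # 0-residual fits
  trend <- sen_slope(m)
  structure(list(variable = cube$variable, agg = agg, years = ag$years,
                 mean = m, box = data.frame(year = ag$years, box),
                 trend = trend,
                 trend_ols = unname(stats::coef(fit)[2]),
                 trend_ols_se = unname(ols_se),
                 rel_trend = relative_trend(trend, mean(m)),
                 n_cells = length(idx)),
            class = "cluster_series")
}

#' @export
print.cluster_series <- function(x, ...) {
  cat(sprintf("<cluster_series> %s (%s over months), %d cells, %d years\n",
              x$variable, x$agg, x$n_cells, length(x$years)))
  cat(sprintf("  trend %.4g units/yr (Sen), %.4g +/- %.4g (OLS), %.2f %%/yr\n",
              x$trend, x$trend_ols, x$trend_ols_se, x$rel_trend))
  invisible(x)
}

#' @export
plot.cluster_series <- function(x, ...) {
  b <- x$box
  graphics::plot(x$years, x$mean, type = "n",
                 ylim = range(b$lower, b$upper),
                 xlab = "year", ylab = x$variable, ...)
  graphics::segments(b$year, b$lower, b$year, b$upper, col = "grey60")
  graphics::rect(b$year - 0.25, b$q25, b$year + 0.25, b$q75,
                 col = "grey85", border = "grey40")
  graphics::segments(b$year - 0.25, b$median, b$year + 0.25, b$median, lwd = 2)
  graphics::lines(x$years, x$mean, col = "firebrick", lwd = 2)
  invisible(x)
}

#' Squared Pearson correlation of two annual series
#'
#' @param x,y numeric vectors of equal length >= 3, both non-constant
#' @return R-squared in [0, 1]
#' @export
series_r2 <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("series must have equal length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("R^2 undefined for a constant series")
  stats::cor(x, y)^2
}

#' Quantile table of a cluster's pooled distribution for selected years
#'
#' For each requested year, the {0.1, 0.25, 0.5, 0.75, 0.9} quantiles of the
#' pooled in-mask distribution (all cells x all months of that year). A
#' spatial-average-then-quantile variant pools the monthly spatial means
#' instead.
#'
#' @param cube a \code{data_cube}
#' @param mask logical cluster mask
#' @param years integer vector of years within the cube span
#' @param pool \code{"cells"} (default: pool spatial and monthly values) or
#'   \code{"spatial_mean"} (quantiles of the 12 monthly spatial means)
#' @return data.frame with columns year, Q10, Q25, Q50, Q75, Q90
#' @export
quantile_table <- function(cube, mask, years, pool = c("cells", "spatial_mean")) {
  pool <- match.arg(pool)
  if (!all(years %in% cube$time$year))
    stop("year outside the cube's time span: ",
         paste(setdiff(years, cube$time$year), collapse = ", "))
  V <- .cube_matrix(cube)
  idx <- which(mask)
  rows <- lapply(years, function(yy) {
    M <- V[cube$time$year == yy, idx, drop = FALSE]
    v <- if (pool == "cells") as.vector(M) else rowMeans(M, na.rm = TRUE)
    qs <- stats::quantile(v, c(0.1, 0.25, 0.5, 0.75, 0.9),
                          na.rm = TRUE, names = FALSE)
    data.frame(year = yy, Q10 = qs[1], Q25 = qs[2], Q50 = qs[3],
               Q75 = qs[4], Q90 = qs[5])
  })
  do.call(rbind, rows)
}

#' Run the full change-detection pipeline
#'
#' Executes, for each of soil moisture and vegetation optical depth (plus
#' precipitation as the auxiliary split variable): annual-quantile trend maps
#' at each configured quantile level, the shared-year-permutation cluster
#' null, retention of field-significant clusters, quantile-map merging; then
#' bivariate clustering of the merged maps, per-cluster annual series for
#' every variable, and (when land-cover epochs are supplied) per-cluster
#' land-cover change tables. Deterministic given \code{seed}.
#'
#' @param scenario a \code{scenario} from
#'   \code{\link{make_five_cluster_scenario}}, or a list with \code{cubes}
#'   (named list of \code{data_cube}s including \code{sm}, \code{vod},
#'   \code{precip}) and optionally \code{landcover_epochs}
#' @param quantiles quantile levels (default c(0.1, 0.25, 0.5, 0.75, 0.9))
#' @param alpha_cell per-cell significance level (default 0.05)
#' @param field_threshold null quantile for cluster retention (default 0.95)
#' @param n_perm permutations per trend map (>= 100; default 500)
#' @param connectivity 4 or 8 (default 8)
#' @param min_area_cells minimum cluster size in cells (default 20)
#' @param seed integer seed
#' @param out_dir optional directory: writes cluster table, per-cluster
#'   series, land-cover tables (CSV) and a JSON run manifest
#' @return object of class \code{ecotrend_run}: \code{change_maps},
#'   \code{clusters} (a \code{cluster_set}), \code{series} (per cluster x
#'   variable), \code{landcover} (per-cluster km^2 change tables or NULL),
#'   \code{manifest}
#' @export
run_pipeline <- function(scenario, quantiles = c(0.1, 0.25, 0.5, 0.75, 0.9),
                         alpha_cell = 0.05, field_threshold = 0.95,
                         n_perm = 500, connectivity = 8, min_area_cells = 20,
                         seed = 1, out_dir = NULL) {
  cubes <- scenario$cubes
  if (is.null(cubes$sm) || is.null(cubes$vod) || is.null(cubes$precip))
    stop("pipeline needs cubes named sm, vod and precip")
  if (n_perm < 100) stop("n_perm must be >= 100")
  change_maps <- list()
  for (v in c("sm", "vod", "precip")) {
    per_q <- lapply(seq_along(quantiles), function(i) {
      q <- quantiles[i]
      cfg <- field_sig_config(alpha_cell, field_threshold, n_perm,
                              connectivity,
                              seed = (seed * 1000 + match(v, names(cubes)) * 100 + i) %%
                                     .Machine$integer.max)
      tm <- trend_map(cubes[[v]], q, alpha_cell)
      nl <- permutation_null(cubes[[v]], q, cfg)
      list(trend_map = tm, clusters = retain_significant_clusters(tm, nl, cfg))
    })
    change_maps[[v]] <- merge_quantile_maps(per_q)
  }
  cs <- bivariate_cluster(change_maps$sm, change_maps$vod, change_maps$precip,
                          min_area_cells = min_area_cells,
                          connectivity = connectivity)
  series <- list()
  for (k in cs$table$label) {
    mk <- cs$labels == k
    series[[as.character(k)]] <-
      lapply(cubes, function(cc) cluster_annual_series(cc, mk))
  }
  landcover <- NULL
  if (!is.null(scenario$landcover_epochs)) {
    ep <- scenario$landcover_epochs
    delta <- epoch_difference(ep[[1]], ep[[2]])
    landcover <- lapply(cs$table$label, function(k)
      cluster_landcover_summary(delta, cs$labels == k, change_maps$sm$grid,
                                classes = ep[[1]]$classes))
    names(landcover) <- cs$table$label
  }
  manifest <- list(seed = seed, quantiles = quantiles,
                   alpha_cell = alpha_cell, field_threshold = field_threshold,
                   n_perm = n_perm, connectivity = connectivity,
                   min_area_cells = min_area_cells,
                   n_clusters = nrow(cs$table),
                   package_version = as.character(utils::packageVersion("ecotrend")))
  run <- structure(list(change_maps = change_maps, clusters = cs,
                        series = series, landcover = landcover,
                        manifest = manifest),
                   class = "ecotrend_run")
  if (!is.null(out_dir)) .write_run(run, out_dir)
  run
}

.write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$clusters$table,
                   file.path(out_dir, "clusters.csv"), row.names = FALSE)
  for (k in names(run$series)) {
    tr <- do.call(rbind, lapply(run$series[[k]], function(s)
      data.frame(variable = s$variable, trend = s$trend,
                 trend_ols = s$trend_ols, rel_trend = s$rel_trend)))
    utils::write.csv(tr, file.path(out_dir, sprintf("series_cluster_%s.csv", k)),
                     row.names = FALSE)
  }
  if (!is.null(run$landcover)) {
    lc <- do.call(rbind, lapply(names(run$landcover), function(k)
      data.frame(cluster = k, class = names(run$landcover[[k]]),
                 net_km2 = as.numeric(run$landcover[[k]]))))
    utils::write.csv(lc, file.path(out_dir, "landcover_change.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.ecotrend_run <- function(x, ...) {
  cat("Gridded change-detection run\n")
  cat(sprintf("  quantiles: %s; alpha=%.3g; field threshold %.2f; %d permutations\n",
              paste(x$manifest$quantiles, collapse = ", "),
              x$manifest$alpha_cell, x$manifest$field_threshold,
              x$manifest$n_perm))
  print(x$clusters)
  invisible(x)
}

#' @export
summary.ecotrend_run <- function(object, ...) {
  tab <- object$clusters$table
  if (!nrow(tab)) return(tab)
  rel <- t(vapply(as.character(tab$label), function(k) {
    s <- object$series[[k]]
    vapply(s, function(si) si$rel_trend, 0)
  }, numeric(length(object$series[[1]]))))
  colnames(rel) <- paste0(names(object$series[[1]]), "_rel_pct_yr")
  cbind(tab[, c("label", "subtype", "sign_sm", "sign_vod", "n_cells", "area_km2")],
        round(rel, 2))
}

#' @export
plot.ecotrend_run <- function(x, ...) plot(x$clusters, ...)
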