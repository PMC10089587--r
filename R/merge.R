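#' Merge quantile-wise trend maps into one signed change map
#'
#' A cell is significant if it lies in a field-significance-retained cluster
#' for at least one quantile level; its sign is the majority Mann-Kendall
#' sign over its significant quantiles (an exact tie demotes the cell to not
#' significant rather than fabricating a direction), and its slope is the
#' median Sen slope over the significant quantiles. The median slope over
#' ALL quantiles (\code{slope_all}) is kept as an auxiliary layer so that
#' downstream splits can use a trend magnitude even where a variable is not
#' itself significant.
#'
#' @param maps list with one element per quantile level, each a list with
#'   fields \code{trend_map} (a \code{\link{trend_map}}) and \code{clusters}
#'   (the matching \code{\link{retain_significant_clusters}} result)
#' @return object of class \code{change_map} with layers \code{significant},
#'   \code{sign}, \code{slope}, \code{rel_slope}, \code{slope_all},
#'   \code{rel_slope_all}, \code{ref_mean}
#' @export
merge_quantile_maps <- function(maps) {
  stopifnot(length(maps) >= 1)
  tm1 <- maps[[1]]$trend_map
  nl <- tm1$grid$n_lat; nn <- tm1$grid$n_lon
  for (m in maps) {
    if (!all(dim(m$trend_map$p) == c(nl, nn)))
      stop("trend maps on inconsistent grids")
    if (m$trend_map$variable != tm1$variable)
      stop("trend maps for different variables")
  }
  nq <- length(maps)
  ncell <- nl * nn
  SIG <- matrix(FALSE, nq, ncell)
  SGN <- matrix(0, nq, ncell)
  SL <- matrix(NA_real_, nq, ncell)
  RM <- matrix(NA_real_, nq, ncell)
  for (i in seq_len(nq)) {
    SIG[i, ] <- as.vector(maps[[i]]$clusters$labels > 0)
    SGN[i, ] <- as.vector(sign(maps[[i]]$trend_map$S))
    SL[i, ] <- as.vector(maps[[i]]$trend_map$slope)
    RM[i, ] <- as.vector(maps[[i]]$trend_map$ref_mean)
  }
  pos <- colSums(SIG & SGN > 0)
  neg <- colSums(SIG & SGN < 0)
  significant <- (pos + neg) > 0 & pos != neg
  sgn <- integer(ncell)
  sgn[significant & pos > neg] <- 1L
  sgn[significant & neg > pos] <- -1L
  SLsig <- SL
  SLsig[!SIG] <- NA_real_
  slope <- apply(SLsig, 2, stats::median, na.rm = TRUE)
  slope[!significant] <- NA_real_
  slope_all <- apply(SL, 2, stats::median, na.rm = TRUE)
  ref_mean <- colMeans(RM, na.rm = TRUE)
  rel <- ifelse(significant & ref_mean != 0, 100 * slope / ref_mean, NA_real_)
  rel_all <- ifelse(ref_mean != 0, 100 * slope_all / ref_mean, NA_real_)
  lay <- function(v) matrix(v, nl, nn)
  structure(list(variable = tm1$variable, grid = tm1$grid,
                 significant = lay(significant), sign = lay(sgn),
                 slope = lay(slope), rel_slope = lay(rel),
                 slope_all = lay(slope_all), rel_slope_all = lay(rel_all),
                 ref_mean = lay(ref_mean),
                 quantiles = vapply(maps, function(m) m$trend_map$q, 0)),
            class = "change_map")
}

#' @export
print.change_map <- function(x, ...) {
  cat(sprintf("<change_map> %s: %d significant cells (%d +, %d -) over %d quantiles\n",
              x$variable, sum(x$significant, na.rm = TRUE),
              sum(x$sign == 1, na.rm = TRUE), sum(x$sign == -1, na.rm = TRUE),
              length(x$quantiles)))
  invisible(x)
}

#' Area of a cluster mask in km^2
#'
#' Sum of cos(latitude)-weighted cell areas over the mask.
#'
#' @param cluster logical n_lat x n_lon mask
#' @param grid an \code{eco_grid}
#' @return area in km^2
#' @export
cluster_area <- function(cluster, grid) {
  if (!all(dim(cluster) == c(grid$n_lat, grid$n_lon)))
    stop("mask does not match grid")
  sum(grid_area_matrix(grid)[which(cluster)])
}

#' Bivariate change clustering in soil-moisture / vegetation trend space
#'
#' Cells significant in at least one of the two change maps are categorized
#' by their (sign SM, sign VOD) pair, the non-significant variable's sign
#' taken from its all-quantile median slope. The (+,+) category is split by
#' the precipitation relative trend (above the threshold: rainfall-driven,
#' "A-like"; below: "D-like"); the (-,-) category is split by joint relative
#' trend magnitude (above the within-category quantile: strong losses,
#' "E-like"; below: "B-like"). (-,+) cells form the "C-like" category and
#' (+,-) cells a residual mixed category. Each category is decomposed into
#' connected components and components smaller than \code{min_area_cells}
#' are dropped.
#'
#' @param sm,vod,precip \code{change_map}s on a shared grid
#' @param min_area_cells minimum component size in cells (default 20)
#' @param precip_rel_threshold precipitation relative-trend split for the
#'   (+,+) category, percent per year (default 1)
#' @param mag_split \code{"quantile"} (threshold at \code{mag_quantile} of
#'   the joint magnitude among (-,-) cells, default) or \code{"kmeans"}
#'   (midpoint of a 2-means split)
#' @param mag_quantile quantile for the magnitude split (default 0.75)
#' @param connectivity 4 or 8 (default 8)
#' @return object of class \code{cluster_set}: \code{labels} (integer
#'   matrix) and \code{table} (one row per cluster: subtype, signature,
#'   cells, area_km2, median slopes and relative slopes)
#' @export
bivariate_cluster <- function(sm, vod, precip, min_area_cells = 20,
                              precip_rel_threshold = 1,
                              mag_split = c("quantile", "kmeans"),
                              mag_quantile = 0.75, connectivity = 8) {
  mag_split <- match.arg(mag_split)
  nl <- sm$grid$n_lat; nn <- sm$grid$n_lon
  if (!all(dim(vod$sign) == c(nl, nn)) || !all(dim(precip$sign) == c(nl, nn)))
    stop("change maps on different grids")
  anysig <- (sm$significant | vod$significant)
  anysig[is.na(anysig)] <- FALSE
  s_sm <- ifelse(sm$significant, sm$sign, sign(sm$slope_all))
  s_vod <- ifelse(vod$significant, vod$sign, sign(vod$slope_all))
  rel_sm <- ifelse(sm$significant & !is.na(sm$rel_slope),
                   sm$rel_slope, sm$rel_slope_all)
  rel_vod <- ifelse(vod$significant & !is.na(vod$rel_slope),
                    vod$rel_slope, vod$rel_slope_all)
  rel_pr <- precip$rel_slope_all

  subtype <- matrix(NA_character_, nl, nn)
  pp <- anysig & s_sm > 0 & s_vod > 0
  nnm <- anysig & s_sm < 0 & s_vod < 0
  subtype[pp & rel_pr > precip_rel_threshold] <- "A"
  subtype[pp & !(rel_pr > precip_rel_threshold)] <- "D"
  if (any(nnm, na.rm = TRUE)) {
    mag <- (abs(rel_sm) + abs(rel_vod)) / 2
    vals <- mag[which(nnm)]
    thr <- if (mag_split == "kmeans" && length(unique(vals)) > 1) {
      cen <- sort(stats::kmeans(vals, centers = 2, nstart = 5)$centers)
      mean(cen)
    } else stats::quantile(vals, mag_quantile, names = FALSE)
    subtype[nnm & mag > thr] <- "E"
    subtype[nnm & !(mag > thr)] <- "B"
  }
  subtype[anysig & s_sm < 0 & s_vod > 0] <- "C"
  subtype[anysig & s_sm > 0 & s_vod < 0] <- "M"

  labels <- matrix(0L, nl, nn)
  rows <- list()
  nextlab <- 0L
  slope_sm <- ifelse(sm$significant & !is.na(sm$slope), sm$slope, sm$slope_all)
  slope_vod <- ifelse(vod$significant & !is.na(vod$slope), vod$slope, vod$slope_all)
  slope_pr <- precip$slope_all
  for (st in c("A", "B", "C", "D", "E", "M")) {
    m <- !is.na(subtype) & subtype == st
    if (!any(m)) next
    lc <- label_clusters(m, connectivity)
    for (k in seq_len(lc$n)) {
      cells <- lc$labels == k
      if (sum(cells) < min_area_cells) next
      nextlab <- nextlab + 1L
      labels[cells] <- nextlab
      rows[[nextlab]] <- data.frame(
        label = nextlab, subtype = st,
        sign_sm = as.integer(sign(stats::median(s_sm[cells]))),
        sign_vod = as.integer(sign(stats::median(s_vod[cells]))),
        precip_split = st %in% c("A", "D"),
        n_cells = sum(cells),
        area_km2 = cluster_area(cells, sm$grid),
        sm_slope_med = stats::median(slope_sm[cells], na.rm = TRUE),
        vod_slope_med = stats::median(slope_vod[cells], na.rm = TRUE),
        precip_slope_med = stats::median(slope_pr[cells], na.rm = TRUE),
        sm_rel_med = stats::median(rel_sm[cells], na.rm = TRUE),
        vod_rel_med = stats::median(rel_vod[cells], na.rm = TRUE))
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = integer(0), subtype = character(0),
               sign_sm = integer(0), sign_vod = integer(0),
               precip_split = logical(0), n_cells = integer(0),
               area_km2 = numeric(0), sm_slope_med = numeric(0),
               vod_slope_med = numeric(0), precip_slope_med = numeric(0),
               sm_rel_med = numeric(0), vod_rel_med = numeric(0))
  structure(list(labels = labels, table = tab, grid = sm$grid,
                 min_area_cells = min_area_cells,
                 precip_rel_threshold = precip_rel_threshold,
                 connectivity = connectivity),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d cluster(s)\n", nrow(x$table)))
  if (nrow(x$table))
    print(x$table[, c("label", "subtype", "sign_sm", "sign_vod",
                      "n_cells", "area_km2")], row.names = FALSE)
  invisible(x)
}

#' @export
summary.cluster_set <- function(object, ...) {
  object$table
}

#' @export
plot.cluster_set <- function(x, ...) {
  graphics::image(t(x$labels)[, rev(seq_len(nrow(x$labels)))],
                  col = c("grey90", grDevices::hcl.colors(max(1, max(x$labels)), "Dark 3")),
                  axes = FALSE, main = "change clusters", ...)
  invisible(x)
}

#' Cluster separability in trend-feature space
#'
#' Mean silhouette coefficient of the labeled cells in standardized
#' (z-scored) feature space; near 1 means compact, well-separated clusters,
#' near 0 overlapping ones.
#'
#' @param features numeric matrix, one row per cell, one column per trend
#'   feature (e.g. SM slope, VOD slope)
#' @param labels integer/character cluster labels, one per row; rows with
#'   NA or 0 labels are dropped
#' @return mean silhouette width in [-1, 1]
#' @export
separability_score <- function(features, labels) {
  features <- as.matrix(features)
  keep <- !is.na(labels) & labels != 0 &
    !apply(features, 1, function(r) any(is.na(r)))
  X <- features[keep, , drop = FALSE]
  li <- as.integer(factor(labels[keep]))
  if (length(unique(li)) < 2)
    stop("separability undefined for fewer than 2 clusters")
  if (any(table(li) < 2))
    stop("each cluster needs at least 2 cells")
  X <- scale(X)
  X[is.nan(X)] <- 0                       # constant feature column
  sil <- cluster::silhouette(li, stats::dist(X))
  mean(sil[, "sil_width"])
}
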