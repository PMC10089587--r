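#' Default plant-functional-type land-cover classes
#'
#' The broad PFT categories used for fractional land-cover accounting:
#' water bodies, four forest types, grasslands, shrub lands, two cropland
#' types, urban, permanent snow/ice and barren.
#'
#' @return character vector of class names
#' @export
pft_classes <- function() {
  c("water bodies",
    "evergreen needle leaf forest", "evergreen broadleaf forest",
    "deciduous needle leaf forest", "deciduous broadleaf forest",
    "grasslands", "shrub lands",
    "cereal croplands", "broadleaf croplands",
    "urban and built-up lands", "permanent snow/ice",
    "barren or sparsely vegetated")
}

#' Aggregate a fine categorical map to coarse per-class fractions
#'
#' Each coarse cell covers a \code{factor x factor} block of fine cells; the
#' fraction of each class among those fine cells is returned.
#'
#' @param fine_classes character or factor matrix of class names on the fine
#'   grid; dimensions must be divisible by \code{factor}
#' @param factor integer refinement factor (>= 1)
#' @param classes ordered class list (default \code{\link{pft_classes}})
#' @param grid optional \code{eco_grid} for the coarse grid (attached to the
#'   result)
#' @param epoch optional epoch year label
#' @return object of class \code{frac_landcover}: list with \code{classes},
#'   \code{fractions} (\code{n_class x n_lat x n_lon} array), \code{grid},
#'   \code{epoch}
#' @export
aggregate_fractions <- function(fine_classes, factor, classes = pft_classes(),
                                grid = NULL, epoch = NA) {
  stopifnot(factor >= 1)
  fd <- dim(fine_classes)
  if (any(fd %% factor != 0)) stop("fine grid dimensions not divisible by factor")
  codes <- match(as.vector(fine_classes), classes)
  if (anyNA(codes)) {
    bad <- unique(as.vector(fine_classes)[is.na(codes)])
    stop("unknown land-cover class: ", paste(bad, collapse = ", "))
  }
  nl <- fd[1] %/% factor; nn <- fd[2] %/% factor
  # coarse cell index of each fine cell (column-major over coarse lat,lon)
  ri <- (seq_len(fd[1]) - 1) %/% factor + 1
  ci <- (seq_len(fd[2]) - 1) %/% factor + 1
  coarse <- outer(ri, (ci - 1) * nl, "+")
  nc <- length(classes)
  counts <- matrix(0, nc, nl * nn)
  tab <- table(factor(codes, levels = seq_len(nc)), as.vector(coarse))
  counts[, as.integer(colnames(tab))] <- tab
  fr <- counts / factor^2
  structure(list(classes = classes,
                 fractions = array(fr, c(nc, nl, nn)),
                 grid = grid, epoch = epoch),
            class = "frac_landcover")
}

#' @export
print.frac_landcover <- function(x, ...) {
  d <- dim(x$fractions)
  cat(sprintf("<frac_landcover> %d classes on %d x %d grid (epoch %s)\n",
              d[1], d[2], d[3], as.character(x$epoch)))
  invisible(x)
}

#' Per-class fraction change between two land-cover epochs
#'
#' @param a,b \code{frac_landcover} objects on the same grid and class set,
#'   with \code{a} the earlier epoch
#' @return \code{n_class x n_lat x n_lon} array of fraction changes
#'   \code{b - a}; per-cell changes sum to zero over classes
#' @export
epoch_difference <- function(a, b) {
  if (!identical(a$classes, b$classes)) stop("class sets differ")
  if (!identical(dim(a$fractions), dim(b$fractions))) stop("grids differ")
  if (!is.na(a$epoch) && !is.na(b$epoch) && a$epoch > b$epoch)
    stop("first epoch must precede second")
  b$fractions - a$fractions
}

#' Per-cluster land-cover change table in km^2
#'
#' Converts per-class fraction changes to areas: for each class, the sum over
#' the cluster's cells of (fraction change x cell area). Net change is
#' reported; gross turnover (sum of |change| x area) is attached as an
#' attribute.
#'
#' @param delta per-class change array from \code{\link{epoch_difference}}
#' @param cluster logical n_lat x n_lon mask of the cluster
#' @param grid \code{eco_grid} of the coarse map
#' @param classes class names (rows of \code{delta})
#' @return named numeric vector, km^2 of net change per class (sums to ~0)
#' @export
cluster_landcover_summary <- function(delta, cluster, grid,
                                      classes = pft_classes()) {
  d <- dim(delta)
  if (!all(d[2:3] == c(grid$n_lat, grid$n_lon))) stop("delta does not match grid")
  if (!all(dim(cluster) == c(grid$n_lat, grid$n_lon))) stop("mask does not match grid")
  area <- grid_area_matrix(grid)
  idx <- which(cluster)
  D <- matrix(delta, d[1])            # classes x cells
  w <- as.vector(area)[idx]
  net <- as.vector(D[, idx, drop = FALSE] %*% w)
  names(net) <- classes
  attr(net, "gross_km2") <- as.vector(abs(D[, idx, drop = FALSE]) %*% w)
  net
}

#' Generate a pair of synthetic land-cover epochs
#'
#' Epoch 1 is a patchy categorical map on a grid \code{refine_factor} times
#' finer than \code{grid} (patches from thresholded smoothed noise). Epoch 2
#' applies the scripted transitions: inside each (coarse) mask, the given
#' fraction of fine cells of class \code{from} is converted to class
#' \code{to}. Both epochs are returned aggregated to \code{grid}.
#'
#' @param grid coarse \code{eco_grid}
#' @param refine_factor integer >= 1
#' @param transitions list of lists with fields \code{mask} (coarse logical
#'   matrix), \code{from}, \code{to} (class names) and \code{fraction} in
#'   [0, 1]
#' @param classes class names (default \code{\link{pft_classes}})
#' @param seed integer seed
#' @return list of two \code{frac_landcover} objects (epochs 1 and 2)
#' @export
generate_landcover_epochs <- function(grid, refine_factor, transitions = list(),
                                      classes = pft_classes(), seed = 1) {
  stopifnot(refine_factor >= 1)
  for (tr in transitions)
    if (tr$fraction < 0 || tr$fraction > 1)
      stop("transition fraction must lie in [0, 1]")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  nf_lat <- grid$n_lat * refine_factor
  nf_lon <- grid$n_lon * refine_factor
  # patchy map: smooth a noise field, cut it into as many bands as classes
  # actually present (use a vegetated subset so transitions have material)
  pool <- c("evergreen broadleaf forest", "grasslands", "shrub lands",
            "cereal croplands", "deciduous broadleaf forest", "water bodies")
  F0 <- matrix(stats::rnorm(nf_lat * nf_lon), nf_lat, nf_lon)
  F0 <- .smooth_matrix(nf_lat, refine_factor * 2) %*% F0 %*%
        t(.smooth_matrix(nf_lon, refine_factor * 2))
  br <- stats::quantile(F0, probs = seq(0, 1, length.out = length(pool) + 1))
  br[1] <- -Inf; br[length(br)] <- Inf
  fine1 <- matrix(pool[cut(F0, br, labels = FALSE)], nf_lat, nf_lon)

  fine2 <- fine1
  up <- function(m) m[rep(seq_len(nrow(m)), each = refine_factor),
                      rep(seq_len(ncol(m)), each = refine_factor)]
  for (tr in transitions) {
    fm <- up(tr$mask)
    cand <- which(fm & fine2 == tr$from)
    n_conv <- round(tr$fraction * length(cand))
    if (n_conv > 0) fine2[sample(cand, n_conv)] <- tr$to
  }
  list(aggregate_fractions(fine1, refine_factor, classes, grid, epoch = 1),
       aggregate_fractions(fine2, refine_factor, classes, grid, epoch = 2))
}
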