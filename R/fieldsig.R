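#' Configuration for cluster-based field significance
#'
#' @param alpha_cell per-cell significance level (default 0.05)
#' @param field_threshold null-distribution quantile above which an observed
#'   cluster is retained (default 0.95)
#' @param n_perm number of permutations (>= 100, default 500)
#' @param connectivity neighbourhood definition, 4 or 8 (default 8)
#' @param seed integer seed for the permutation stream
#' @return object of class \code{field_sig_config}
#' @export
field_sig_config <- function(alpha_cell = 0.05, field_threshold = 0.95,
                             n_perm = 500, connectivity = 8, seed = 1) {
  if (field_threshold <= 0 || field_threshold >= 1)
    stop("field_threshold must lie in (0, 1)")
  if (n_perm < 100) stop("n_perm must be >= 100")
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  structure(list(alpha_cell = alpha_cell, field_threshold = field_threshold,
                 n_perm = as.integer(n_perm), connectivity = connectivity,
                 seed = seed),
            class = "field_sig_config")
}

#' Label connected components of a significance mask
#'
#' Connected components under 4- or 8-neighbour connectivity, labeled in
#' row-major discovery order (label 1 is the component whose first cell comes
#' first scanning row by row). NA cells count as background.
#'
#' @param sig_mask logical matrix
#' @param connectivity 4 or 8
#' @return object of class \code{labeled_clusters}: \code{labels} (integer
#'   matrix, 0 = background), \code{sizes} (cells per label), \code{n}
#' @export
label_clusters <- function(sig_mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  nr <- nrow(sig_mask); nc <- ncol(sig_mask)
  mask <- sig_mask
  mask[is.na(mask)] <- FALSE
  lab <- matrix(0L, nr, nc)
  cells <- which(mask)
  sizes <- integer(0)
  if (length(cells)) {
    # row-major scan order of the TRUE cells
    r0 <- (cells - 1L) %% nr + 1L
    c0 <- (cells - 1L) %/% nr + 1L
    ord <- cells[order(r0, c0)]
    if (connectivity == 4) {
      dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
    } else {
      dr <- c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L)
      dc <- c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L)
    }
    nlab <- 0L
    for (s in ord) {
      if (lab[s] != 0L) next
      nlab <- nlab + 1L
      stack <- s
      lab[s] <- nlab
      sz <- 0L
      while (length(stack)) {
        cur <- stack[length(stack)]
        stack <- stack[-length(stack)]
        sz <- sz + 1L
        r <- (cur - 1L) %% nr + 1L
        cc <- (cur - 1L) %/% nr + 1L
        nbr <- r + dr; nbc <- cc + dc
        ok <- nbr >= 1L & nbr <= nr & nbc >= 1L & nbc <= nc
        nb <- (nbc[ok] - 1L) * nr + nbr[ok]
        nb <- nb[mask[nb] & lab[nb] == 0L]
        if (length(nb)) {
          lab[nb] <- nlab
          stack <- c(stack, nb)
        }
      }
      sizes[nlab] <- sz
    }
  }
  structure(list(labels = lab, sizes = sizes, n = length(sizes)),
            class = "labeled_clusters")
}

#' @export
print.labeled_clusters <- function(x, ...) {
  cat(sprintf("<labeled_clusters> %d cluster(s)", x$n))
  if (x$n) cat(", sizes:", paste(x$sizes, collapse = " "))
  cat("\n")
  invisible(x)
}

#' Null distribution of the largest significant cluster
#'
#' For each permutation the year labels of the per-cell annual-quantile
#' series are shuffled with ONE shared permutation applied identically at
#' every cell, so each year's spatial field stays intact and the spatial
#' correlation of the data is preserved. The full per-cell chain (lag-1
#' autocorrelation, AR(1) pre-whitening, Mann-Kendall test) is re-run on the
#' shuffled series, cells with p below \code{alpha_cell} are labeled, and the
#' largest connected cluster size is recorded. Deterministic given
#' \code{cfg$seed}.
#'
#' @param cube a \code{data_cube}
#' @param q quantile level
#' @param cfg a \code{field_sig_config}
#' @return object of class \code{perm_null}: \code{sizes} (length
#'   \code{n_perm}), plus the config used
#' @export
permutation_null <- function(cube, q, cfg = field_sig_config()) {
  stopifnot(inherits(cfg, "field_sig_config"))
  asr <- annual_quantile_series(cube, q)
  A <- .annual_matrix(asr)
  .permutation_null_annual(A, cube$grid, cfg)
}

# engine working directly on the annual matrix so quantile extraction is
# done once per cube, not once per permutation
.permutation_null_annual <- function(A, grid, cfg) {
  ny <- nrow(A)
  usable <- colSums(!is.na(A)) == ny        # gappy cells sit out of the null
  Ac <- A[, usable, drop = FALSE]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  sizes <- integer(cfg$n_perm)
  sigv <- logical(length(usable))
  for (b in seq_len(cfg$n_perm)) {
    Ap <- Ac[sample.int(ny), , drop = FALSE]
    mk <- .mk_grid(.prewhiten_grid(Ap))
    sigv[] <- FALSE
    sigv[usable] <- mk$p < cfg$alpha_cell
    lc <- label_clusters(matrix(sigv, grid$n_lat, grid$n_lon),
                         cfg$connectivity)
    sizes[b] <- if (lc$n) max(lc$sizes) else 0L
  }
  structure(list(sizes = sizes, alpha_cell = cfg$alpha_cell,
                 connectivity = cfg$connectivity, n_perm = cfg$n_perm,
                 seed = cfg$seed),
            class = "perm_null")
}

#' @export
print.perm_null <- function(x, ...) {
  cat(sprintf("<perm_null> %d permutations, max-cluster sizes: median %g, q95 %g\n",
              x$n_perm, stats::median(x$sizes),
              stats::quantile(x$sizes, 0.95, names = FALSE)))
  invisible(x)
}

#' Retain observed clusters larger than the permutation null
#'
#' Labels the observed cells with p below \code{alpha_cell} and keeps only
#' clusters whose size exceeds the \code{field_threshold} quantile of the
#' null max-cluster-size distribution; everything else is removed. Retained
#' clusters are relabeled 1..k in their original discovery order, and each
#' gets the dominant sign of its cells' Mann-Kendall scores.
#'
#' @param trend_map a \code{trend_map}
#' @param null_sizes a \code{perm_null} (or integer vector of null sizes)
#' @param cfg a \code{field_sig_config} consistent with the null
#' @return a \code{labeled_clusters} with extra fields \code{signs} and
#'   \code{size_threshold}
#' @export
retain_significant_clusters <- function(trend_map, null_sizes,
                                        cfg = field_sig_config()) {
  sizes_null <- if (inherits(null_sizes, "perm_null")) null_sizes$sizes else null_sizes
  sig <- trend_map$p < cfg$alpha_cell & !is.na(trend_map$p)
  if (!all(dim(sig) == c(trend_map$grid$n_lat, trend_map$grid$n_lon)))
    stop("significance mask does not match the grid")
  thr <- stats::quantile(sizes_null, cfg$field_threshold, names = FALSE, type = 7)
  lc <- label_clusters(sig, cfg$connectivity)
  keep <- which(lc$sizes > thr)
  lab <- matrix(0L, nrow(sig), ncol(sig))
  signs <- integer(0)
  for (k in seq_along(keep)) {
    cells <- lc$labels == keep[k]
    lab[cells] <- k
    signs[k] <- as.integer(sign(sum(sign(trend_map$S[cells]), na.rm = TRUE)))
  }
  structure(list(labels = lab, sizes = lc$sizes[keep], signs = signs,
                 n = length(keep), size_threshold = thr),
            class = "labeled_clusters")
}
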