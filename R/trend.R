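# ---- vectorized per-cell engine -------------------------------------------
# All .xxx_grid() helpers operate on an n x m matrix Y: n time steps in rows,
# m cells in columns, no NAs. They are the single code path behind both the
# scalar user-facing functions and the gridded pipeline, so the permutation
# null can re-run the full test thousands of times at vector speed.

# lag-1 sample autocorrelation per column; 0 for constant columns
.r1_grid <- function(Y) {
  n <- nrow(Y)
  D <- Y - rep(colMeans(Y), each = n)
  den <- colSums(D * D)
  num <- colSums(D[-n, , drop = FALSE] * D[-1, , drop = FALSE])
  ifelse(den > 0, num / den, 0)
}

# residual series y'_t = y_t - r1 * y_{t-1}, t = 2..n (length n-1 per column)
.prewhiten_grid <- function(Y, r1 = NULL) {
  n <- nrow(Y)
  if (is.null(r1)) r1 <- .r1_grid(Y)
  Y[-1, , drop = FALSE] - rep(r1, each = n - 1) * Y[-n, , drop = FALSE]
}

# Mann-Kendall S, tie-corrected Var(S), continuity-corrected Z, two-sided p
.mk_grid <- function(Y) {
  n <- nrow(Y); m <- ncol(Y)
  S <- numeric(m)
  for (i in seq_len(n - 1))
    for (j in seq(i + 1, n))
      S <- S + sign(Y[j, ] - Y[i, ])
  # tie correction: each member of a tie group of size t contributes
  # (t-1)(2t+5), summing to t(t-1)(2t+5) per group
  tie <- numeric(m)
  for (i in seq_len(n)) {
    cnt <- numeric(m)
    for (k in seq_len(n)) cnt <- cnt + (Y[k, ] == Y[i, ])
    tie <- tie + (cnt - 1) * (2 * cnt + 5)
  }
  varS <- (n * (n - 1) * (2 * n + 5) - tie) / 18
  Z <- numeric(m)
  pos <- S > 0 & varS > 0
  neg <- S < 0 & varS > 0
  Z[pos] <- (S[pos] - 1) / sqrt(varS[pos])
  Z[neg] <- (S[neg] + 1) / sqrt(varS[neg])
  p <- 2 * stats::pnorm(-abs(Z))
  p[S == 0] <- 1
  list(S = S, var_S = varS, Z = Z, p = p)
}

# Sen slope per column: median over all pairwise slopes (y_j - y_i)/(j - i)
.sen_grid <- function(Y, t = seq_len(nrow(Y))) {
  n <- nrow(Y); m <- ncol(Y)
  np <- n * (n - 1) / 2
  P <- matrix(NA_real_, np, m)
  k <- 0L
  for (i in seq_len(n - 1))
    for (j in seq(i + 1, n)) {
      k <- k + 1L
      P[k, ] <- (Y[j, ] - Y[i, ]) / (t[j] - t[i])
    }
  # column medians via a single order() pass (no per-column sort calls)
  Ps <- matrix(P[order(col(P), P)], nrow = np)
  if (np %% 2L == 1L) Ps[(np + 1L) / 2L, ] else
    (Ps[np / 2L, ] + Ps[np / 2L + 1L, ]) / 2
}

# ---- scalar user-facing functions -----------------------------------------

#' Lag-1 autocorrelation of a series
#'
#' Plain sample autocorrelation at lag 1, centered on the series mean:
#' \eqn{r_1 = \sum_{t<n}(y_t-\bar y)(y_{t+1}-\bar y) / \sum (y_t-\bar y)^2}.
#' Returns 0 for a constant series.
#'
#' @param y numeric vector, length >= 3, no NAs
#' @return lag-1 autocorrelation in [-1, 1]
#' @export
lag1_autocorrelation <- function(y) {
  y <- as.numeric(y)
  if (anyNA(y)) y <- y[!is.na(y)]
  if (length(y) < 3) stop("need at least 3 values for lag-1 autocorrelation")
  .r1_grid(matrix(y, ncol = 1))[1]
}

#' AR(1) pre-whitening of a series
#'
#' Removes lag-1 serial correlation by forming the residual series
#' \eqn{y'_t = y_t - r_1 y_{t-1}} for \eqn{t = 2..n}, where \eqn{r_1} is the
#' sample lag-1 autocorrelation (\code{\link{lag1_autocorrelation}}). The
#' returned series has length \eqn{n - 1}: the residual is undefined at
#' \eqn{t = 1}.
#'
#' @param y numeric vector, length >= 3
#' @param detrend if \code{TRUE}, estimate \eqn{r_1} on the series after
#'   removing its Sen-slope linear trend (trend-free pre-whitening variant);
#'   default \code{FALSE}, plain pre-whitening
#' @return numeric vector of length \code{length(y) - 1}
#' @export
prewhiten_ar1 <- function(y, detrend = FALSE) {
  y <- as.numeric(y)
  if (length(y) < 3) stop("need at least 3 values to pre-whiten")
  r1 <- if (detrend) {
    b <- sen_slope(y)
    lag1_autocorrelation(y - b * seq_along(y))
  } else lag1_autocorrelation(y)
  y[-1] - r1 * y[-length(y)]
}

#' Mann-Kendall trend test of a series
#'
#' Rank-based test for a monotonic trend. The score
#' \eqn{S = \sum_{i<j} \mathrm{sign}(y_j - y_i)} counts concordant minus
#' discordant pairs; its variance is tie-corrected,
#' \eqn{Var(S) = [n(n-1)(2n+5) - \sum_g t_g(t_g-1)(2t_g+5)]/18}, and the
#' standardized score uses the classical continuity correction
#' (\eqn{(S-1)/\sqrt{Var}} for \eqn{S>0}, 0 at \eqn{S=0},
#' \eqn{(S+1)/\sqrt{Var}} for \eqn{S<0}) with a two-sided normal p-value.
#' An all-tied series gives \eqn{S=0, Z=0, p=1}.
#'
#' @param y numeric vector, length >= 3
#' @param prewhiten apply AR(1) pre-whitening before testing (default FALSE:
#'   the caller decides; \code{\link{trend_map}} pre-whitens)
#' @return object of class \code{mk_trend}: list with \code{S}, \code{var_S},
#'   \code{Z}, \code{p}, \code{sen_slope}, \code{r1}, \code{n_eff}
#' @examples
#' mk_trend(c(1, 2, 3, 4, 5))   # S = 10, Z = 2.20, p = 0.0275
#' @export
mk_trend <- function(y, prewhiten = FALSE) {
  y <- as.numeric(y)
  if (length(y) < 3) stop("need at least 3 values for the Mann-Kendall test")
  r1 <- lag1_autocorrelation(y)
  yt <- if (prewhiten) y[-1] - r1 * y[-length(y)] else y
  mk <- .mk_grid(matrix(yt, ncol = 1))
  slope <- if (all(y == y[1])) NA_real_ else sen_slope(y)
  structure(list(S = mk$S, var_S = mk$var_S, Z = mk$Z, p = mk$p,
                 sen_slope = slope, r1 = r1, n_eff = length(yt),
                 prewhitened = prewhiten),
            class = "mk_trend")
}

#' @export
print.mk_trend <- function(x, ...) {
  cat("Mann-Kendall trend test",
      if (x$prewhitened) "(AR(1) pre-whitened)" else "", "\n")
  cat(sprintf("  S = %g, Var(S) = %.4g, Z = %.4f, p = %.4g\n",
              x$S, x$var_S, x$Z, x$p))
  cat(sprintf("  Sen slope = %.6g per step, r1 = %.4f, n = %d\n",
              x$sen_slope, x$r1, x$n_eff))
  invisible(x)
}

#' Sen's slope of a series
#'
#' Median of all pairwise slopes \eqn{(y_j - y_i)/(t_j - t_i)}, \eqn{i < j};
#' the robust trend-magnitude companion of the Mann-Kendall test.
#'
#' @param y numeric vector, length >= 2
#' @param t time points (default 1..n)
#' @return slope in units of y per unit of t
#' @export
sen_slope <- function(y, t = seq_along(y)) {
  y <- as.numeric(y)
  ok <- !is.na(y)
  y <- y[ok]; t <- t[ok]
  if (length(y) < 2) stop("need at least 2 values for Sen's slope")
  if (all(y == y[1]) && length(unique(t)) < 2)
    stop("slope undefined: all time points identical")
  .sen_grid(matrix(y, ncol = 1), t)[1]
}

#' Relative trend in percent per year
#'
#' @param slope trend in variable units per year
#' @param reference_mean reference level in variable units (non-zero)
#' @return trend in percent of the reference level per year
#' @export
relative_trend <- function(slope, reference_mean) {
  if (any(reference_mean == 0)) stop("relative trend undefined for zero reference mean")
  100 * slope / reference_mean
}

# ---- annual quantile series -----------------------------------------------

#' Annual quantile series of a data cube
#'
#' For each cell and calendar year, the empirical q-quantile (linear
#' interpolation between order statistics, R type 7) of that year's monthly
#' values. Years with more than half of their months missing are set to NA;
#' cells with fewer than 3 usable years are fully masked.
#'
#' @param cube a \code{data_cube}
#' @param q quantile level in (0, 1)
#' @return object of class \code{annual_series}: list with \code{q},
#'   \code{years} and \code{values}, an \code{n_years x n_lat x n_lon} array
#' @export
annual_quantile_series <- function(cube, q) {
  stopifnot(q > 0, q < 1)
  V <- .cube_matrix(cube)                    # n_time x ncell
  yrs <- sort(unique(cube$time$year))
  ncell <- ncol(V)
  A <- matrix(NA_real_, length(yrs), ncell)
  for (iy in seq_along(yrs)) {
    M <- V[cube$time$year == yrs[iy], , drop = FALSE]
    A[iy, ] <- .col_quantile(M, q, min_frac = 0.5)
  }
  usable <- colSums(!is.na(A)) >= 3
  A[, !usable] <- NA_real_
  structure(list(variable = cube$variable, q = q, years = yrs,
                 grid = cube$grid,
                 values = array(A, c(length(yrs), cube$grid$n_lat, cube$grid$n_lon))),
            class = "annual_series")
}

# type-7 quantile of each column of M (rows = months); columns with more than
# (1 - min_frac) of rows missing give NA
.col_quantile <- function(M, q, min_frac = 0.5) {
  n <- nrow(M); m <- ncol(M)
  if (!anyNA(M)) {
    Ms <- matrix(M[order(col(M), M)], nrow = n)
    h <- (n - 1) * q + 1
    lo <- floor(h); hi <- ceiling(h)
    return(Ms[lo, ] + (h - lo) * (Ms[hi, ] - Ms[lo, ]))
  }
  out <- rep(NA_real_, m)
  nav <- colSums(!is.na(M))
  for (jj in which(nav >= ceiling(min_frac * n) & nav >= 1)) {
    out[jj] <- stats::quantile(M[, jj], q, na.rm = TRUE, names = FALSE, type = 7)
  }
  out
}

# annual series as n_years x ncell matrix
.annual_matrix <- function(as_obj) {
  d <- dim(as_obj$values)
  dim(as_obj$values) <- c(d[1], d[2] * d[3])
  as_obj$values
}

# ---- per-cell trend map ----------------------------------------------------

#' Per-cell trend map for one quantile level
#'
#' Runs the full per-cell chain independently at every grid point: annual
#' q-quantile series, AR(1) pre-whitening, Mann-Kendall test on the residual
#' series, and Sen's slope on the original (un-whitened) annual series.
#' Cells with missing years fall back to a per-cell path; cells with fewer
#' than 3 usable years are masked.
#'
#' @param cube a \code{data_cube}
#' @param q quantile level in (0, 1)
#' @param alpha_cell per-cell significance level for the \code{sig} layer
#' @param slope_method \code{"sen"} (default) or \code{"ols"}
#' @return object of class \code{trend_map}: per-cell layers (matrices
#'   \code{n_lat x n_lon}) \code{S}, \code{var_S}, \code{Z}, \code{p},
#'   \code{slope}, \code{r1}, \code{sig}, \code{ref_mean}; plus \code{n_eff}
#' @export
trend_map <- function(cube, q, alpha_cell = 0.05, slope_method = c("sen", "ols")) {
  stopifnot(alpha_cell > 0, alpha_cell < 1)
  slope_method <- match.arg(slope_method)
  asr <- annual_quantile_series(cube, q)
  A <- .annual_matrix(asr)
  res <- .trend_from_annual(A, slope_method)
  nl <- cube$grid$n_lat; nn <- cube$grid$n_lon
  lay <- function(v) matrix(v, nl, nn)
  structure(list(variable = cube$variable, q = q, grid = cube$grid,
                 years = asr$years,
                 S = lay(res$S), var_S = lay(res$var_S), Z = lay(res$Z),
                 p = lay(res$p), slope = lay(res$slope), r1 = lay(res$r1),
                 sig = lay(res$p < alpha_cell & !is.na(res$p)),
                 ref_mean = lay(colMeans(A)),
                 n_eff = nrow(A) - 1, alpha_cell = alpha_cell),
            class = "trend_map")
}

# engine on an annual matrix (years x cells), NA-tolerant
.trend_from_annual <- function(A, slope_method = "sen") {
  ny <- nrow(A); m <- ncol(A)
  out <- list(S = rep(NA_real_, m), var_S = rep(NA_real_, m),
              Z = rep(NA_real_, m), p = rep(NA_real_, m),
              slope = rep(NA_real_, m), r1 = rep(NA_real_, m))
  nav <- colSums(!is.na(A))
  complete <- nav == ny
  if (any(complete)) {
    Ac <- A[, complete, drop = FALSE]
    r1 <- .r1_grid(Ac)
    mk <- .mk_grid(.prewhiten_grid(Ac, r1))
    out$S[complete] <- mk$S
    out$var_S[complete] <- mk$var_S
    out$Z[complete] <- mk$Z
    out$p[complete] <- mk$p
    out$r1[complete] <- r1
    out$slope[complete] <- if (slope_method == "sen") .sen_grid(Ac)
                           else .ols_grid(Ac)
  }
  # gappy but usable cells: drop missing years, run the same chain per cell
  for (jj in which(!complete & nav >= 3)) {
    y <- A[, jj]; keep <- !is.na(y)
    yv <- y[keep]; tv <- which(keep)
    r1 <- .r1_grid(matrix(yv, ncol = 1))[1]
    mk <- .mk_grid(matrix(yv[-1] - r1 * yv[-length(yv)], ncol = 1))
    out$S[jj] <- mk$S; out$var_S[jj] <- mk$var_S
    out$Z[jj] <- mk$Z; out$p[jj] <- mk$p; out$r1[jj] <- r1
    out$slope[jj] <- if (slope_method == "sen") .sen_grid(matrix(yv, ncol = 1), tv)[1]
                     else .ols_grid(matrix(yv, ncol = 1), tv)[1]
  }
  out
}

# ordinary least-squares slope per column, exposed as the config alternative
.ols_grid <- function(Y, t = seq_len(nrow(Y))) {
  tc <- t - mean(t)
  colSums(Y * tc) / sum(tc * tc)
}

#' @export
print.trend_map <- function(x, ...) {
  cat(sprintf("<trend_map> %s q=%.2f: %d x %d cells, %d significant at alpha=%.3g\n",
              x$variable, x$q, x$grid$n_lat, x$grid$n_lon,
              sum(x$sig, na.rm = TRUE), x$alpha_cell))
  invisible(x)
}
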