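# Physical ranges used for clipping generated values. Only variables listed
# here are clipped; anything else is left unbounded.
.var_ranges <- list(
  sm     = c(0, 1),      # volumetric soil moisture, m3/m3
  vod    = c(0, Inf),    # vegetation optical depth, unitless
  ndvi   = c(-1, 1),
  precip = c(0, Inf)     # mm/month, truncated at 0
)

#' Specification of a synthetic monthly data cube
#'
#' Collects the knobs of the generator: grid size, AR(1) temporal noise,
#' Gaussian spatial smoothing of the noise field, a 12-month sinusoidal
#' seasonal cycle, and a base level. The generated signal is
#' \code{base_mean + seasonality + smoothed AR(1) noise + regional ramps}.
#'
#' @param n_lat,n_lon grid size in cells
#' @param cell_km nominal cell size (km)
#' @param lat0 southern edge latitude (degrees)
#' @param n_years number of complete years (>= 3)
#' @param ar1_phi AR(1) coefficient of the monthly noise, in [0, 1)
#' @param noise_sd innovation standard deviation (variable units)
#' @param spatial_corr_cells Gaussian smoothing length of each noise slice,
#'   in cells (0 = no spatial correlation)
#' @param seasonal_amp amplitude of the seasonal sinusoid (variable units)
#' @param base_mean base level (variable units)
#' @param seed integer seed
#' @return object of class \code{synthetic_spec}
#' @export
synthetic_spec <- function(n_lat = 40, n_lon = 40, cell_km = 25, lat0 = -30,
                           n_years = 10, ar1_phi = 0.5, noise_sd = 0.01,
                           spatial_corr_cells = 1.5, seasonal_amp = 0.03,
                           base_mean = 0.2, seed = 1) {
  if (ar1_phi < 0 || ar1_phi >= 1) stop("ar1_phi must lie in [0, 1)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (n_years < 3) stop("n_years must be >= 3")
  if (spatial_corr_cells < 0) stop("spatial_corr_cells must be >= 0")
  structure(list(n_lat = n_lat, n_lon = n_lon, cell_km = cell_km, lat0 = lat0,
                 n_years = n_years, months_per_year = 12L,
                 ar1_phi = ar1_phi, noise_sd = noise_sd,
                 spatial_corr_cells = spatial_corr_cells,
                 seasonal_amp = seasonal_amp, base_mean = base_mean,
                 seed = seed),
            class = "synthetic_spec")
}

#' A region with an injected monotonic trend
#'
#' @param mask logical n_lat x n_lon matrix, TRUE inside the region
#' @param slopes named numeric vector of trends in variable units per year,
#'   e.g. \code{c(sm = 0.004, vod = 0.007)}; variables not named get slope 0
#' @param label optional region label
#' @return object of class \code{region_trend}
#' @export
region_trend <- function(mask, slopes, label = NA_character_) {
  if (!is.matrix(mask) || !is.logical(mask)) stop("mask must be a logical matrix")
  if (!any(mask)) stop("region mask is empty")
  structure(list(mask = mask, slopes = slopes, label = label),
            class = "region_trend")
}

# circulant Gaussian smoothing matrix for one dimension (rows sum to 1);
# wrap-around distance keeps the operator doubly stochastic, so the global
# field mean is preserved exactly
.smooth_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  d <- pmin(d, n - d)                       # circular distance
  K <- exp(-d^2 / (2 * sigma^2))
  K / rowSums(K)
}

# smooth every time slice of V (n_time x n_lat x n_lon) with separable
# circulant Gaussian kernels
.smooth_slices <- function(V, sigma) {
  if (sigma <= 0) return(V)
  d <- dim(V)
  Kl <- .smooth_matrix(d[2], sigma)
  Kn <- .smooth_matrix(d[3], sigma)
  # latitude pass: lat as leading dimension
  A <- aperm(V, c(2, 1, 3)); da <- dim(A)
  A <- Kl %*% matrix(A, da[1]); dim(A) <- da
  # longitude pass
  B <- aperm(A, c(3, 2, 1)); db <- dim(B)
  B <- Kn %*% matrix(B, db[1]); dim(B) <- db
  aperm(B, c(2, 3, 1))
}

#' Generate one synthetic monthly data cube
#'
#' Builds \code{base_mean + seasonal sinusoid + spatially smoothed AR(1)
#' noise + slope * elapsed_years} inside each region mask, then clips to the
#' variable's physical range if one is configured (\code{sm} in [0,1],
#' \code{ndvi} in [-1,1], \code{vod} and \code{precip} non-negative).
#' The AR(1) noise starts from its stationary distribution; smoothing each
#' monthly slice with a normalized circulant Gaussian kernel leaves the
#' per-cell lag-1 autocorrelation at \code{ar1_phi} (a weighted sum of
#' independent AR(1) processes with common phi is again AR(1) with phi).
#' Deterministic given \code{seed}.
#'
#' @param spec a \code{synthetic_spec}
#' @param region_trends list of \code{region_trend} objects (may be empty)
#' @param variable variable name; selects the slope entry of each region and
#'   the clipping range
#' @param seed integer seed (default \code{spec$seed})
#' @return a \code{data_cube}
#' @export
generate_cube <- function(spec, region_trends = list(), variable = "sm",
                          seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  nl <- spec$n_lat; nn <- spec$n_lon
  nt <- spec$n_years * spec$months_per_year
  for (rt in region_trends)
    if (!all(dim(rt$mask) == c(nl, nn)))
      stop("region mask shape does not match the grid")
  grid <- make_grid(nl, nn, spec$cell_km, spec$lat0)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  V <- array(0, c(nt, nl, nn))
  if (spec$noise_sd > 0) {
    phi <- spec$ar1_phi
    X <- matrix(stats::rnorm(nt * nl * nn, sd = spec$noise_sd), nt)
    X[1, ] <- X[1, ] / sqrt(1 - phi^2)     # stationary start
    if (phi > 0) for (t in 2:nt) X[t, ] <- phi * X[t - 1, ] + X[t, ]
    dim(X) <- c(nt, nl, nn)
    V <- .smooth_slices(X, spec$spatial_corr_cells)
  }
  month <- (seq_len(nt) - 1) %% 12 + 1
  seas <- spec$seasonal_amp * sin(2 * pi * (month - 1) / 12)
  V <- V + spec$base_mean + seas           # recycles over time dimension
  elapsed <- (seq_len(nt) - 1) / 12        # years since start
  for (rt in region_trends) {
    sl <- if (variable %in% names(rt$slopes)) rt$slopes[[variable]] else 0
    if (sl != 0) {
      idx <- which(rt$mask)                # cell indices, column-major
      ramp <- outer(elapsed * sl, rep(1, length(idx)))
      M <- matrix(V, nt)
      M[, idx] <- M[, idx] + ramp
      dim(M) <- c(nt, nl, nn)
      V <- M
    }
  }
  rng <- .var_ranges[[variable]]
  if (!is.null(rng)) V <- pmin(pmax(V, rng[1]), rng[2])
  data_cube(V, grid, variable = variable,
            units = switch(variable, sm = "m3/m3", precip = "mm/month", ""))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# rectangular mask helper
.rect_mask <- function(n_lat, n_lon, rows, cols) {
  m <- matrix(FALSE, n_lat, n_lon)
  m[rows, cols] <- TRUE
  m
}

#' Five-cluster synthetic scenario
#'
#' Builds a complete multi-variable scenario with five disjoint rectangular
#' regions (labels A-E, buffered by >= 5 cells) whose injected trend signs
#' follow the canonical bivariate change signatures: A and D gain both soil
#' moisture and vegetation water ((+,+)); B and E lose both ((-,-)), with
#' markedly stronger losses in E; C loses soil moisture while vegetation
#' water rises ((-,+)). A has a clear positive precipitation trend while D
#' has none, which is what makes the two (+,+) regions separable. Land-cover
#' epochs with scripted class transitions inside B, D and E are attached.
#'
#' @param seed integer seed
#' @param n_years number of years (default 10)
#' @param noise_scale multiplies all noise standard deviations (1 = the
#'   default moderate-noise conditions; 0 = noise-free)
#' @return object of class \code{scenario}: list with \code{cubes} (one
#'   \code{data_cube} per variable sm/vod/ndvi/precip), \code{truth_regions},
#'   \code{landcover_epochs}, \code{grid} and \code{spec}
#' @export
make_five_cluster_scenario <- function(seed = 1, n_years = 10, noise_scale = 1) {
  nl <- 48; nn <- 60
  regions <- list(
    A = .rect_mask(nl, nn,  6:17,  6:17),
    B = .rect_mask(nl, nn,  6:18, 25:37),
    C = .rect_mask(nl, nn,  6:17, 44:55),
    D = .rect_mask(nl, nn, 26:37,  6:17),
    E = .rect_mask(nl, nn, 28:34, 28:34)
  )
  slopes <- list(
    A = c(sm =  0.004, vod =  0.005, ndvi =  0.005, precip =  2.5),
    B = c(sm = -0.003, vod = -0.006, ndvi = -0.004, precip = -1.0),
    C = c(sm = -0.004, vod =  0.008, ndvi =  0.003, precip =  0.0),
    D = c(sm =  0.004, vod =  0.009, ndvi =  0.004, precip =  0.0),
    E = c(sm = -0.006, vod = -0.012, ndvi = -0.008, precip = -2.0)
  )
  truth <- Map(function(m, s, l) region_trend(m, s, l),
               regions, slopes, names(regions))
  base <- list(sm = 0.20, vod = 0.35, ndvi = 0.50, precip = 80)
  nsd  <- list(sm = 0.010, vod = 0.015, ndvi = 0.020, precip = 10)
  amp  <- list(sm = 0.03, vod = 0.05, ndvi = 0.08, precip = 20)
  cubes <- list()
  for (v in names(base)) {
    sp <- synthetic_spec(n_lat = nl, n_lon = nn, cell_km = 25, lat0 = -30,
                         n_years = n_years, ar1_phi = 0.5,
                         noise_sd = nsd[[v]] * noise_scale,
                         spatial_corr_cells = 1.5,
                         seasonal_amp = amp[[v]], base_mean = base[[v]],
                         seed = seed)
    # distinct but seed-derived stream per variable
    vseed <- (seed * 101 + match(v, names(base))) %% .Machine$integer.max
    cubes[[v]] <- generate_cube(sp, truth, variable = v, seed = vseed)
  }
  grid <- cubes$sm$grid
  lc <- generate_landcover_epochs(
    grid, refine_factor = 4,
    transitions = list(
      list(mask = regions$B, from = "evergreen broadleaf forest",
           to = "grasslands", fraction = 0.4),
      list(mask = regions$D, from = "grasslands",
           to = "deciduous broadleaf forest", fraction = 0.3),
      list(mask = regions$E, from = "evergreen broadleaf forest",
           to = "shrub lands", fraction = 0.5),
      list(mask = regions$E, from = "grasslands",
           to = "shrub lands", fraction = 0.4)
    ),
    seed = seed)
  structure(list(cubes = cubes, truth_regions = truth,
                 landcover_epochs = lc, grid = grid,
                 spec = list(seed = seed, n_years = n_years,
                             noise_scale = noise_scale)),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> %d x %d grid, %d years, %d truth regions (%s), seed %d\n",
              x$grid$n_lat, x$grid$n_lon, x$spec$n_years,
              length(x$truth_regions),
              paste(names(x$truth_regions), collapse = ","),
              x$spec$seed))
  invisible(x)
}
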