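#' Regular latitude-longitude analysis grid
#'
#' Builds the coarse analysis grid used by every stage of the pipeline.
#' Cell areas are computed per latitude row as \code{cell_km^2 * cos(lat)},
#' the usual equal-angle approximation for a nominal cell size, so a 25-km
#' cell at the equator covers 625 km^2 and half of that at 60 degrees.
#'
#' @param n_lat,n_lon number of grid rows (latitude) and columns (longitude)
#' @param cell_km nominal cell edge length in km at the equator
#' @param lat0 latitude (degrees) of the southern edge of the grid
#' @param lon0 longitude (degrees) of the western edge of the grid
#' @return an object of class \code{eco_grid}: list with \code{lat_centers},
#'   \code{lon_centers} (degrees), \code{cell_km} and \code{cell_area_km2}
#'   (one value per latitude row, km^2)
#' @export
make_grid <- function(n_lat, n_lon, cell_km = 25, lat0 = -30, lon0 = 0) {
  stopifnot(n_lat >= 1, n_lon >= 1, cell_km > 0)
  step_deg <- cell_km / 111.195  # km per degree of latitude (spherical Earth)
  lat <- lat0 + (seq_len(n_lat) - 0.5) * step_deg
  lon <- lon0 + (seq_len(n_lon) - 0.5) * step_deg
  if (any(abs(lat) >= 90)) stop("grid extends beyond a pole; lower n_lat or lat0")
  area <- cell_km^2 * cos(lat * pi / 180)
  structure(list(n_lat = n_lat, n_lon = n_lon,
                 lat_centers = lat, lon_centers = lon,
                 cell_km = cell_km, cell_area_km2 = area),
            class = "eco_grid")
}

#' @export
print.eco_grid <- function(x, ...) {
  cat(sprintf("<eco_grid> %d x %d cells, %.0f km nominal, lat [%.2f, %.2f]\n",
              x$n_lat, x$n_lon, x$cell_km,
              min(x$lat_centers), max(x$lat_centers)))
  invisible(x)
}

#' Per-cell area matrix of a grid
#'
#' @param grid an \code{eco_grid}
#' @return n_lat x n_lon matrix of cell areas (km^2)
#' @export
grid_area_matrix <- function(grid) {
  matrix(grid$cell_area_km2, grid$n_lat, grid$n_lon)
}

#' Monthly gridded data cube
#'
#' Container for one variable's monthly values on a lat/lon grid. Values are
#' stored as an \code{n_time x n_lat x n_lon} array; missing observations are
#' \code{NA}. Time is a strictly increasing monthly calendar.
#'
#' @param values numeric array \code{n_time x n_lat x n_lon}
#' @param grid an \code{eco_grid} matching the last two dimensions
#' @param start_year first calendar year
#' @param start_month first calendar month (1-12)
#' @param variable variable name, e.g. \code{"sm"}
#' @param units unit string, e.g. \code{"m3/m3"}
#' @return an object of class \code{data_cube}
#' @export
data_cube <- function(values, grid, start_year = 2010, start_month = 1,
                      variable = "var", units = "") {
  d <- dim(values)
  if (length(d) != 3L) stop("values must be a 3-d array (time, lat, lon)")
  if (d[2] != grid$n_lat || d[3] != grid$n_lon)
    stop("values spatial dimensions do not match grid")
  n_time <- d[1]
  mo <- (start_month - 1 + seq_len(n_time) - 1) %% 12 + 1
  yr <- start_year + (start_month - 1 + seq_len(n_time) - 1) %/% 12
  structure(list(variable = variable, units = units, grid = grid,
                 time = data.frame(year = yr, month = mo),
                 values = values),
            class = "data_cube")
}

#' @export
print.data_cube <- function(x, ...) {
  tr <- range(x$time$year)
  cat(sprintf("<data_cube> %s [%s]: %d months (%d-%d), %d x %d grid, %.1f%% missing\n",
              x$variable, x$units, nrow(x$time), tr[1], tr[2],
              x$grid$n_lat, x$grid$n_lon,
              100 * mean(is.na(x$values))))
  invisible(x)
}

# cells as columns: n_time x (n_lat*n_lon) matrix view, column-major over (lat, lon)
.cube_matrix <- function(cube) {
  d <- dim(cube$values)
  dim(cube$values) <- c(d[1], d[2] * d[3])
  cube$values
}
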