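#' Write a data cube to a plain-text directory
#'
#' Serializes a cube as a CSV value matrix (rows = months, columns = cells in
#' column-major lat/lon order) plus a JSON metadata header with the variable,
#' units, grid and time axis. The format round-trips exactly through
#' \code{\link{read_cube}}.
#'
#' @param cube a \code{data_cube}
#' @param dir output directory (created if needed)
#' @return the directory, invisibly
#' @export
write_cube <- function(cube, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(variable = cube$variable, units = cube$units,
               n_lat = cube$grid$n_lat, n_lon = cube$grid$n_lon,
               cell_km = cube$grid$cell_km,
               lat0 = cube$grid$lat_centers[1] -
                 0.5 * cube$grid$cell_km / 111.195,
               lon0 = cube$grid$lon_centers[1] -
                 0.5 * cube$grid$cell_km / 111.195,
               start_year = cube$time$year[1],
               start_month = cube$time$month[1],
               n_time = nrow(cube$time))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(matrix(cube$values, nrow(cube$time)),
                     file.path(dir, "values.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Read a data cube written by \code{\link{write_cube}}
#'
#' @param dir directory containing \code{meta.json} and \code{values.csv}
#' @return a \code{data_cube}
#' @export
read_cube <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  V <- as.matrix(utils::read.table(file.path(dir, "values.csv"), sep = ","))
  dimnames(V) <- NULL
  grid <- make_grid(meta$n_lat, meta$n_lon, meta$cell_km, meta$lat0, meta$lon0)
  data_cube(array(V, c(meta$n_time, meta$n_lat, meta$n_lon)), grid,
            start_year = meta$start_year, start_month = meta$start_month,
            variable = meta$variable, units = meta$units)
}

# run-length encode a logical matrix (column-major) for compact JSON truth files
.rle_encode <- function(mask) {
  r <- rle(as.vector(mask))
  list(dim = dim(mask), lengths = r$lengths, values = r$values)
}

.rle_decode <- function(enc) {
  matrix(inverse.rle(list(lengths = as.integer(enc$lengths),
                          values = as.logical(enc$values))),
         enc$dim[1], enc$dim[2])
}

#' Write a scenario's ground truth to JSON
#'
#' Region masks are stored run-length encoded with their injected slopes and
#' the generator seed, so downstream recovery can be scored without
#' re-generating the scenario.
#'
#' @param scenario a \code{scenario}
#' @param path output JSON file
#' @return the path, invisibly
#' @export
write_truth <- function(scenario, path) {
  truth <- lapply(scenario$truth_regions, function(rt)
    list(label = rt$label, mask = .rle_encode(rt$mask),
         slopes = as.list(rt$slopes)))
  jsonlite::write_json(list(seed = scenario$spec$seed,
                            n_years = scenario$spec$n_years,
                            regions = truth),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a scenario truth file
#'
#' @param path JSON file from \code{\link{write_truth}}
#' @return list with \code{seed}, \code{n_years} and \code{regions} (each a
#'   list with \code{label}, logical \code{mask}, named \code{slopes})
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  regions <- lapply(seq_len(nrow_or_len(x$regions)), function(i) {
    r <- if (is.data.frame(x$regions)) lapply(x$regions, `[[`, i) else x$regions[[i]]
    list(label = r$label, mask = .rle_decode(r$mask),
         slopes = unlist(r$slopes))
  })
  list(seed = x$seed, n_years = x$n_years, regions = regions)
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
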