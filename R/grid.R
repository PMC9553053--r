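#' Define a regular latitude/longitude grid
#'
#' A grid is described by its cell-center coordinates. Latitude centers are
#' degrees north (ascending), longitude centers degrees east in `[-180, 180)`
#' (ascending). The analysis grid of the pipeline is a 1-degree grid with
#' centers at x.5.
#'
#' @param lat_centers numeric, ascending latitude cell centers in `[-90, 90]`.
#' @param lon_centers numeric, ascending longitude cell centers in `[-180, 180)`.
#' @param cell_size cell edge length in degrees (1.0 for the analysis grid).
#' @return An object of class `grid_definition`.
#' @export
grid_definition <- function(lat_centers, lon_centers, cell_size = 1.0) {
  lat_centers <- as.numeric(lat_centers)
  lon_centers <- as.numeric(lon_centers)
  if (anyNA(lat_centers) || anyNA(lon_centers)) {
    stop("grid coordinates must be finite", call. = FALSE)
  }
  if (any(lat_centers < -90 | lat_centers > 90)) {
    stop("latitude centers must lie in [-90, 90]", call. = FALSE)
  }
  if (any(lon_centers < -180 | lon_centers >= 180)) {
    stop("longitude centers must lie in [-180, 180)", call. = FALSE)
  }
  if (is.unsorted(lat_centers, strictly = TRUE) ||
      is.unsorted(lon_centers, strictly = TRUE)) {
    stop("grid coordinates must be strictly ascending with no duplicates",
         call. = FALSE)
  }
  check_uniform <- function(x, what) {
    if (length(x) >= 2) {
      d <- diff(x)
      if (max(d) - min(d) > 1e-8 * max(abs(d))) {
        stop(what, " spacing is not uniform", call. = FALSE)
      }
    }
  }
  check_uniform(lat_centers, "latitude")
  check_uniform(lon_centers, "longitude")
  structure(
    list(lat = lat_centers, lon = lon_centers, cell_size = as.numeric(cell_size)),
    class = "grid_definition"
  )
}

#' The 1-degree analysis grid over a lat/lon extent
#'
#' Centers are placed at x.5 following the convention of the common analysis
#' grid.
#'
#' @param lat_range,lon_range length-2 numeric extents in degrees.
#' @return A `grid_definition` with 1-degree cells.
#' @export
analysis_grid <- function(lat_range = c(-40, 40), lon_range = c(-180, 180)) {
  lat <- seq(floor(lat_range[1]) + 0.5, ceiling(lat_range[2]) - 0.5, by = 1)
  lon <- seq(floor(lon_range[1]) + 0.5, ceiling(lon_range[2]) - 0.5, by = 1)
  lon <- lon[lon >= -180 & lon < 180]
  grid_definition(lat, lon, cell_size = 1.0)
}

#' @export
print.grid_definition <- function(x, ...) {
  cat(sprintf("<grid_definition> %d x %d cells (%.3g deg), lat [%g, %g], lon [%g, %g]\n",
              length(x$lat), length(x$lon), x$cell_size,
              min(x$lat), max(x$lat), min(x$lon), max(x$lon)))
  invisible(x)
}

#' Five-year analysis windows tiling 1850-2100
#'
#' Windows are `[1850-1854], [1855-1859], ..., [2095-2099]`; the terminal year
#' 2100 is folded into the last window, which therefore spans 2095-2100. Each
#' window is labeled by its start year.
#'
#' @param start,end horizon in years.
#' @param width window width in years (5 for the analysis).
#' @return A data.frame with columns `start_year`, `end_year`, `label_year`.
#' @export
time_windows <- function(start = 1850, end = 2100, width = 5) {
  starts <- seq(start, end - width, by = width)
  ends <- starts + width - 1
  # fold a trailing partial window (e.g. [2100-2100]) into the final full one
  ends[length(ends)] <- end
  data.frame(start_year = starts, end_year = ends, label_year = starts)
}

#' A time axis of single years (annual data)
#'
#' @param years integer years.
#' @return A time-axis data.frame (`start_year == end_year == label_year`).
#' @export
annual_axis <- function(years) {
  years <- as.integer(years)
  data.frame(start_year = years, end_year = years, label_year = years)
}

validate_time_axis <- function(time_axis) {
  need <- c("start_year", "end_year", "label_year")
  if (!is.data.frame(time_axis) || !all(need %in% names(time_axis))) {
    stop("time_axis must be a data.frame with start_year, end_year, label_year",
         call. = FALSE)
  }
  if (any(time_axis$end_year < time_axis$start_year)) {
    stop("time windows must have end_year >= start_year", call. = FALSE)
  }
  if (nrow(time_axis) > 1 && is.unsorted(time_axis$start_year)) {
    stop("time_axis must be increasing", call. = FALSE)
  }
  time_axis
}

#' Bundle gridded values with a grid and a time axis
#'
#' `values` is an array indexed `(time, lat, lon)`; `NA` encodes missing cells
#' and the missing mask is preserved through every transform in the package.
#'
#' @param grid a `grid_definition`.
#' @param variable_id one of `"sst"`, `"dhw"`, `"arag"`, `"storm_cat"`,
#'   `"storm_return"`, `"pop_density"`, `"land_use_fraction"`.
#' @param units free-text units string.
#' @param time_axis data.frame with `start_year`, `end_year`, `label_year`
#'   (see [time_windows()], [annual_axis()]).
#' @param values numeric array of dim `(ntime, nlat, nlon)`; a matrix is
#'   accepted for a single time step.
#' @return An object of class `grid_field`.
#' @export
grid_field <- function(grid, variable_id, units, time_axis, values) {
  stopifnot(inherits(grid, "grid_definition"))
  variable_id <- match.arg(variable_id, c(
    "sst", "dhw", "arag", "storm_cat", "storm_return",
    "pop_density", "land_use_fraction"
  ))
  time_axis <- validate_time_axis(time_axis)
  if (is.matrix(values)) values <- array(values, dim = c(1L, dim(values)))
  if (length(dim(values)) != 3L) {
    stop("values must be a (time, lat, lon) array", call. = FALSE)
  }
  expect_dim <- c(nrow(time_axis), length(grid$lat), length(grid$lon))
  if (!identical(as.integer(dim(values)), as.integer(expect_dim))) {
    stop(sprintf("values dim (%s) inconsistent with time axis and grid (%s)",
                 paste(dim(values), collapse = ","),
                 paste(expect_dim, collapse = ",")), call. = FALSE)
  }
  structure(
    list(grid = grid, variable_id = variable_id, units = units,
         time_axis = time_axis, values = values),
    class = "grid_field"
  )
}

#' @export
print.grid_field <- function(x, ...) {
  cat(sprintf("<grid_field> %s [%s], %d time steps (%d-%d), %d x %d cells, %d missing\n",
              x$variable_id, x$units, nrow(x$time_axis),
              min(x$time_axis$start_year), max(x$time_axis$end_year),
              length(x$grid$lat), length(x$grid$lon), sum(is.na(x$values))))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-8) {
  length(a$lat) == length(b$lat) && length(a$lon) == length(b$lon) &&
    max(abs(a$lat - b$lat)) <= tol && max(abs(a$lon - b$lon)) <= tol
}
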