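#' Neighborhood specification for local-stressor metrics
#'
#' @param radius_km great-circle radius around a reef site (50 km in the
#'   analysis).
#' @return An object of class `neighborhood_spec`.
#' @export
neighborhood_spec <- function(radius_km = 50) {
  if (!is.numeric(radius_km) || radius_km <= 0) {
    stop("radius_km must be positive", call. = FALSE)
  }
  structure(list(radius_km = radius_km, distance_metric = "great-circle"),
            class = "neighborhood_spec")
}

#' Great-circle distance in kilometers
#'
#' Haversine distance on a sphere of radius 6371 km.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in degrees (vectorized).
#' @return Distance(s) in km.
#' @export
great_circle_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371000) / 1000
}

# Indices and relative area weights of raster cells whose centers lie within
# radius_km of a site. Weights are proportional to cos(latitude), the area of
# a fixed-angular-size cell on the sphere.
cells_in_radius <- function(grid, site, spec) {
  nlat <- length(grid$lat)
  nlon <- length(grid$lon)
  lat_c <- rep(grid$lat, times = nlon)
  lon_c <- rep(grid$lon, each = nlat)
  d <- great_circle_km(site$lon, site$lat, lon_c, lat_c)
  keep <- which(d <= spec$radius_km)
  list(
    lat_i = ((keep - 1L) %% nlat) + 1L,
    lon_i = ((keep - 1L) %/% nlat) + 1L,
    weight = cos(lat_c[keep] * pi / 180)
  )
}

#' Mean population density within a site's neighborhood
#'
#' Area-weighted mean of the density raster over all cells whose centers lie
#' within the great-circle radius of the site, per time step of the raster.
#'
#' @param pop_raster `grid_field` with `variable_id = "pop_density"`
#'   (persons per km^2).
#' @param site one-row data.frame with `lat`, `lon` (and `site_id`).
#' @param spec a [neighborhood_spec()].
#' @return Data.frame `label_year, value` (persons per km^2).
#' @export
neighborhood_population_metric <- function(pop_raster, site, spec = neighborhood_spec()) {
  stopifnot(inherits(pop_raster, "grid_field"))
  cells <- cells_in_radius(pop_raster$grid, site, spec)
  if (length(cells$weight) == 0) {
    stop("no raster cells within ", spec$radius_km,
         " km of site; radius too small for the raster resolution", call. = FALSE)
  }
  value <- vapply(seq_len(nrow(pop_raster$time_axis)), function(t) {
    v <- pop_raster$values[cbind(t, cells$lat_i, cells$lon_i)]
    ok <- !is.na(v)
    if (!any(ok)) return(NA_real_)
    sum(v[ok] * cells$weight[ok]) / sum(cells$weight[ok])
  }, numeric(1))
  data.frame(label_year = pop_raster$time_axis$label_year, value = value)
}

#' Summed agricultural + urban land-use fraction within a neighborhood
#'
#' Area-weighted mean of (agricultural fraction + urban fraction) over the
#' land cells within the great-circle radius; ocean cells are excluded from
#' the average. A fully oceanic neighborhood yields 0 (open ocean), with a
#' message.
#'
#' @param ag_field,urban_field `grid_field`s of land-use fractions in
#'   `[0, 1]` on the same grid and time axis.
#' @param land_mask logical matrix (lat x lon), `TRUE` for land cells.
#' @param site one-row data.frame with `lat`, `lon`.
#' @param spec a [neighborhood_spec()].
#' @return Data.frame `label_year, value` (unitless fraction in `[0, 1]`).
#' @export
neighborhood_landuse_metric <- function(ag_field, urban_field, land_mask, site,
                                        spec = neighborhood_spec()) {
  stopifnot(inherits(ag_field, "grid_field"), inherits(urban_field, "grid_field"))
  if (!same_grid(ag_field$grid, urban_field$grid)) {
    stop("agricultural and urban fields must share a grid", call. = FALSE)
  }
  cells <- cells_in_radius(ag_field$grid, site, spec)
  land <- land_mask[cbind(cells$lat_i, cells$lon_i)]
  if (!any(land)) {
    message("no land cells within ", spec$radius_km, " km of site ",
            site$site_id, "; land-use metric 0 (open ocean)")
    return(data.frame(label_year = ag_field$time_axis$label_year, value = 0))
  }
  li <- cells$lat_i[land]
  lj <- cells$lon_i[land]
  wt <- cells$weight[land]
  value <- vapply(seq_len(nrow(ag_field$time_axis)), function(t) {
    v <- ag_field$values[cbind(t, li, lj)] + urban_field$values[cbind(t, li, lj)]
    ok <- !is.na(v)
    if (!any(ok)) return(NA_real_)
    sum(v[ok] * wt[ok]) / sum(wt[ok])
  }, numeric(1))
  data.frame(label_year = ag_field$time_axis$label_year, value = value)
}
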