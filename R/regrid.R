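#' Regrid a field with bilinear interpolation
#'
#' Each target value is the bilinear combination of the 4 surrounding source
#' cell centers. If any of the 4 neighbors is missing the result is missing
#' (conservative: no coastal values are fabricated). Longitude wraps across
#' the dateline when the source grid is global.
#'
#' @param field a `grid_field` on the source grid.
#' @param target a `grid_definition` covered by the source grid.
#' @return A `grid_field` on `target` with the same variable, units and time
#'   axis.
#' @export
regrid_bilinear <- function(field, target) {
  stopifnot(inherits(field, "grid_field"), inherits(target, "grid_definition"))
  src <- field$grid
  nt <- nrow(field$time_axis)
  if (nt < 1) stop("field must have at least one time step", call. = FALSE)

  lat_w <- axis_brackets(target$lat, src$lat, wrap = FALSE, what = "latitude")
  lon_w <- axis_brackets(target$lon, src$lon, wrap = TRUE, what = "longitude")

  out <- array(NA_real_, dim = c(nt, length(target$lat), length(target$lon)))
  for (t in seq_len(nt)) {
    slice <- field$values[t, , , drop = TRUE]
    if (is.null(dim(slice))) {
      slice <- matrix(slice, length(src$lat), length(src$lon))
    }
    v00 <- slice[cbind(rep(lat_w$i0, times = length(target$lon)),
                       rep(lon_w$i0, each = length(target$lat)))]
    v01 <- slice[cbind(rep(lat_w$i0, times = length(target$lon)),
                       rep(lon_w$i1, each = length(target$lat)))]
    v10 <- slice[cbind(rep(lat_w$i1, times = length(target$lon)),
                       rep(lon_w$i0, each = length(target$lat)))]
    v11 <- slice[cbind(rep(lat_w$i1, times = length(target$lon)),
                       rep(lon_w$i1, each = length(target$lat)))]
    wy <- rep(lat_w$w, times = length(target$lon))
    wx <- rep(lon_w$w, each = length(target$lat))
    val <- (1 - wy) * (1 - wx) * v00 + (1 - wy) * wx * v01 +
      wy * (1 - wx) * v10 + wy * wx * v11
    out[t, , ] <- matrix(val, length(target$lat), length(target$lon))
  }
  grid_field(target, field$variable_id, field$units, field$time_axis, out)
}

# Bracketing indices and fractional weights of query points along one axis.
# For a query q between centers x[i0] and x[i1], w is the weight on x[i1].
axis_brackets <- function(q, x, wrap, what) {
  n <- length(x)
  spacing <- if (n > 1) diff(x)[1] else 360
  global <- wrap && n > 1 && (360 - (x[n] - x[1])) <= spacing + 1e-8
  i0 <- i1 <- integer(length(q))
  w <- numeric(length(q))
  for (k in seq_along(q)) {
    qq <- q[k]
    if (wrap) {
      for (shift in c(0, 360, -360)) {
        if (qq + shift >= x[1] - 1e-12 && qq + shift <= x[n] + 1e-12) {
          qq <- qq + shift
          break
        }
      }
    }
    if (qq >= x[1] - 1e-12 && qq <= x[n] + 1e-12) {
      qq <- min(max(qq, x[1]), x[n])
      i <- findInterval(qq, x)
      if (i == n) i <- n - 1L
      if (n == 1L) {
        i0[k] <- i1[k] <- 1L; w[k] <- 0
      } else {
        i0[k] <- i; i1[k] <- i + 1L
        w[k] <- (qq - x[i]) / (x[i + 1L] - x[i])
      }
    } else if (global) {
      # across the dateline seam between x[n] and x[1] + 360
      qq <- ((qq - x[1]) %% 360) + x[1]
      i0[k] <- n; i1[k] <- 1L
      w[k] <- (qq - x[n]) / (x[1] + 360 - x[n])
    } else {
      stop("target ", what, " ", q[k], " lies outside the source domain",
           call. = FALSE)
    }
  }
  list(i0 = i0, i1 = i1, w = w)
}

#' Average a gridded time series into 5-year windows
#'
#' Input steps at monthly, annual or decadal cadence are reduced to the
#' analysis windows (see [time_windows()]): the value of a window is the
#' arithmetic mean of all non-missing input steps whose years fall inside it;
#' a multi-year (e.g. decadal) input step contributes to every window it
#' spans. Windows inside the input span with no contributing steps become
#' missing, with a warning.
#'
#' @param field a `grid_field` whose time axis is at least as fine as the
#'   windows.
#' @param window_years window width in years (5 for the analysis).
#' @return A `grid_field` on the window time axis.
#' @export
average_windows <- function(field, window_years = 5) {
  stopifnot(inherits(field, "grid_field"))
  ta <- field$time_axis
  wins <- time_windows(1850, 2100, window_years)
  span <- c(min(ta$start_year), max(ta$end_year))
  keep <- wins$end_year >= span[1] & wins$start_year <= span[2]
  wins <- wins[keep, , drop = FALSE]
  rownames(wins) <- NULL
  if (nrow(wins) == 0) stop("input lies outside the 1850-2100 horizon", call. = FALSE)

  nlat <- length(field$grid$lat)
  nlon <- length(field$grid$lon)
  out <- array(NA_real_, dim = c(nrow(wins), nlat, nlon))
  empty <- character(0)
  for (w in seq_len(nrow(wins))) {
    in_w <- ta$end_year >= wins$start_year[w] & ta$start_year <= wins$end_year[w]
    if (!any(in_w)) {
      empty <- c(empty, as.character(wins$label_year[w]))
      next
    }
    sub <- field$values[in_w, , , drop = FALSE]
    out[w, , ] <- apply(sub, c(2, 3), function(x) {
      if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
    })
  }
  if (length(empty)) {
    warning("windows with no input steps left missing: ",
            paste(empty, collapse = ", "), call. = FALSE)
  }
  grid_field(field$grid, field$variable_id, field$units, wins, out)
}

#' Assign sites to their nearest analysis-grid cell
#'
#' Nearest cell center along each axis; ties break toward the smaller cell
#' index. Adds `lat_i`, `lon_i` columns (1-based indices into the grid's
#' latitude and longitude centers).
#'
#' @param sites data.frame with `lat`, `lon` columns.
#' @param grid a `grid_definition`.
#' @return `sites` with `lat_i` and `lon_i` set.
#' @export
assign_cells <- function(sites, grid) {
  nearest <- function(q, x) {
    vapply(q, function(v) which.min(abs(x - v)), integer(1))
  }
  sites$lat_i <- nearest(sites$lat, grid$lat)
  sites$lon_i <- nearest(sites$lon, grid$lon)
  sites
}

#' Sample a gridded field at reef sites
#'
#' Each site takes the value of its own grid cell (nearest-center assignment,
#' no interpolation at this step); missing cell values stay missing in the
#' output rather than being dropped.
#'
#' @param field a `grid_field`.
#' @param sites data.frame of sites; `lat_i`/`lon_i` are used if present,
#'   otherwise assigned with [assign_cells()].
#' @return Long data.frame `site_id, label_year, value`, sites in input order.
#' @export
sample_at_sites <- function(field, sites) {
  stopifnot(inherits(field, "grid_field"))
  if (!all(c("lat_i", "lon_i") %in% names(sites))) {
    sites <- assign_cells(sites, field$grid)
  }
  half <- field$grid$cell_size / 2 + 1e-9
  off_lat <- abs(sites$lat - field$grid$lat[sites$lat_i]) > half
  off_lon <- abs(sites$lon - field$grid$lon[sites$lon_i]) > half
  if (any(off_lat | off_lon)) {
    stop("sites outside the grid: ",
         paste(sites$site_id[off_lat | off_lon], collapse = ", "),
         call. = FALSE)
  }
  nt <- nrow(field$time_axis)
  ns <- nrow(sites)
  val <- field$values[cbind(rep(seq_len(nt), times = ns),
                            rep(sites$lat_i, each = nt),
                            rep(sites$lon_i, each = nt))]
  data.frame(
    site_id = rep(sites$site_id, each = nt),
    label_year = rep(field$time_axis$label_year, times = ns),
    value = val,
    stringsAsFactors = FALSE
  )
}

#' Cylindrical equal-area (Behrmann) projection
#'
#' Forward projection to kilometers on a sphere of radius 6371 km with
#' standard parallel 30 degrees; used to lay the 1-km reef grid over polygon
#' outlines.
#'
#' @param lon,lat degrees.
#' @return Two-column matrix `x, y` in km.
#' @export
behrmann_xy <- function(lon, lat) {
  r <- 6371
  k <- cos(30 * pi / 180)
  cbind(x = r * (lon * pi / 180) * k,
        y = r * sin(lat * pi / 180) / k)
}

#' @rdname behrmann_xy
#' @param x,y projected coordinates in km.
#' @export
behrmann_lonlat <- function(x, y) {
  r <- 6371
  k <- cos(30 * pi / 180)
  cbind(lon = (x / (r * k)) * 180 / pi,
        lat = asin(pmin(1, pmax(-1, y * k / r))) * 180 / pi)
}

#' Convert reef polygons into 1-km reef sites
#'
#' Polygons are projected to a cylindrical equal-area grid (standard parallel
#' 30 deg), overlaid with a `resolution_km` raster aligned to the projection
#' origin, and one site is emitted for every cell whose center falls inside
#' any polygon. Duplicate coverage of a cell by several polygons collapses to
#' a single site.
#'
#' @param polygons list of two-column (lon, lat) matrices, e.g. from
#'   [read_geojson_polygons()].
#' @param resolution_km reef-grid resolution (1 km for the analysis).
#' @param reef_class class label for the emitted sites.
#' @param grid optional `grid_definition` for cell assignment.
#' @return Data.frame of reef sites.
#' @export
rasterize_reef_polygons <- function(polygons, resolution_km = 1,
                                    reef_class = "coral", grid = NULL) {
  if (length(polygons) == 0) stop("empty geometry set", call. = FALSE)
  proj <- lapply(polygons, function(m) behrmann_xy(m[, 1], m[, 2]))
  allxy <- do.call(rbind, proj)
  res <- resolution_km
  ix <- seq(floor(min(allxy[, 1]) / res), ceiling(max(allxy[, 1]) / res))
  iy <- seq(floor(min(allxy[, 2]) / res), ceiling(max(allxy[, 2]) / res))
  centers <- cbind(x = rep((ix + 0.5) * res, times = length(iy)),
                   y = rep((iy + 0.5) * res, each = length(ix)))
  inside <- rep(FALSE, nrow(centers))
  for (p in proj) {
    inside <- inside | mgcv::in.out(p, centers)
  }
  centers <- centers[inside, , drop = FALSE]
  ll <- behrmann_lonlat(centers[, 1], centers[, 2])
  sites <- data.frame(
    site_id = sprintf("reef_%05d", seq_len(nrow(centers))),
    lat = ll[, 2], lon = ll[, 1],
    reef_class = rep(reef_class, nrow(centers)),
    stringsAsFactors = FALSE
  )
  if (!is.null(grid)) sites <- assign_cells(sites, grid)
  sites
}
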