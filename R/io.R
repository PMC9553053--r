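#' Write a gridded field to the package's plain-CSV grid format
#'
#' One row per (time window, cell), columns
#' `start_year,end_year,label_year,lat,lon,value`, preceded by `#`-comment
#' metadata lines carrying `variable_id`, `units` and `cell_size`. Values are
#' printed with 17 significant digits so that write-then-read reproduces the
#' field bit-exactly, including the missing-value mask.
#'
#' @param field a `grid_field`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(field, path) {
  stopifnot(inherits(field, "grid_field"))
  nt <- nrow(field$time_axis)
  nlat <- length(field$grid$lat)
  nlon <- length(field$grid$lon)
  # expand in (time, lat, lon) order; array index order matches values layout
  idx <- expand.grid(t = seq_len(nt), i = seq_len(nlat), j = seq_len(nlon))
  num <- function(x) sprintf("%.17g", x)
  v <- field$values[cbind(idx$t, idx$i, idx$j)]
  lines <- c(
    paste0("# variable_id: ", field$variable_id),
    paste0("# units: ", field$units),
    paste0("# cell_size: ", num(field$grid$cell_size)),
    "start_year,end_year,label_year,lat,lon,value",
    paste(field$time_axis$start_year[idx$t],
          field$time_axis$end_year[idx$t],
          field$time_axis$label_year[idx$t],
          num(field$grid$lat[idx$i]),
          num(field$grid$lon[idx$j]),
          ifelse(is.na(v), "NA", num(v)),
          sep = ",")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a gridded field from the plain-CSV grid format
#'
#' @param path file written by [write_grid_csv()] (or assembled by hand with
#'   the same columns and metadata comments).
#' @return A `grid_field`.
#' @export
read_grid_csv <- function(path) {
  head_lines <- readLines(path, n = 20L)
  meta_lines <- grep("^#", head_lines, value = TRUE)
  meta <- function(key, default = NA_character_) {
    hit <- grep(paste0("^#\\s*", key, ":"), meta_lines, value = TRUE)
    if (length(hit) == 0) return(default)
    sub(paste0("^#\\s*", key, ":\\s*"), "", hit[1])
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("start_year", "end_year", "label_year", "lat", "lon", "value")
  if (!all(need %in% names(df))) {
    stop("grid CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  lat <- sort(unique(df$lat))
  lon <- sort(unique(df$lon))
  ta <- unique(df[order(df$start_year), c("start_year", "end_year", "label_year")])
  rownames(ta) <- NULL
  cell <- as.numeric(meta("cell_size", NA))
  if (is.na(cell)) cell <- if (length(lat) > 1) diff(lat)[1] else 1
  grid <- grid_definition(lat, lon, cell_size = cell)
  vals <- array(NA_real_, dim = c(nrow(ta), length(lat), length(lon)))
  ti <- match(df$start_year, ta$start_year)
  li <- match(df$lat, lat)
  lj <- match(df$lon, lon)
  vals[cbind(ti, li, lj)] <- df$value
  grid_field(grid, meta("variable_id", "sst"), meta("units", ""), ta, vals)
}

#' Read a reef-site table
#'
#' @param path CSV with header columns `site_id, lat, lon, reef_class`.
#' @param grid optional `grid_definition`; when given, sites are assigned to
#'   their nearest grid cell (see [assign_cells()]).
#' @return A data.frame of sites (one `ReefSite` per row).
#' @export
read_sites_csv <- function(path, grid = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "lat", "lon", "reef_class")
  if (!all(need %in% names(df))) {
    stop("site CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(df$reef_class), c("coral", "rocky"))
  if (length(bad)) {
    stop("unknown reef_class: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  df$site_id <- as.character(df$site_id)
  if (!is.null(grid)) df <- assign_cells(df, grid)
  df
}

#' Read polygon rings from a GeoJSON file
#'
#' Supports `Polygon` and `MultiPolygon` geometries in a `FeatureCollection`,
#' a bare `GeometryCollection`, or a single geometry. Only the outer ring of
#' each polygon is used (reef outlines have no holes at the scales handled
#' here).
#'
#' @param path GeoJSON file.
#' @return A list of two-column matrices (lon, lat), one per outer ring.
#' @export
read_geojson_polygons <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = FALSE)
  rings <- list()
  add_geom <- function(geom) {
    ring_mat <- function(ring) {
      do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    }
    if (identical(geom$type, "Polygon")) {
      rings[[length(rings) + 1L]] <<- ring_mat(geom$coordinates[[1]])
    } else if (identical(geom$type, "MultiPolygon")) {
      for (poly in geom$coordinates) {
        rings[[length(rings) + 1L]] <<- ring_mat(poly[[1]])
      }
    }
  }
  if (!is.null(g$features)) {
    for (f in g$features) add_geom(f$geometry)
  } else if (!is.null(g$geometries)) {
    for (geom in g$geometries) add_geom(geom)
  } else if (!is.null(g$type)) {
    add_geom(g)
  }
  if (length(rings) == 0) stop("no polygon geometry found in ", path, call. = FALSE)
  lapply(rings, function(m) {
    colnames(m) <- c("lon", "lat")
    m
  })
}

#' Read a storm-event catalog
#'
#' @param path CSV with header columns `year, lat, lon, category`.
#' @return A data.frame of storm events (Saffir-Simpson categories 1-5).
#' @export
read_storms_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("year", "lat", "lon", "category")
  if (!all(need %in% names(df))) {
    stop("storm CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  storm_catalog(df)
}

#' Validate a storm catalog
#'
#' @param events data.frame with `year, lat, lon, category`.
#' @return The validated data.frame.
#' @export
storm_catalog <- function(events) {
  if (nrow(events)) {
    if (any(events$category < 1 | events$category > 5)) {
      stop("storm categories must be Saffir-Simpson 1-5", call. = FALSE)
    }
    if (any(events$year < 1850 | events$year > 2100)) {
      stop("storm years must lie in [1850, 2100]", call. = FALSE)
    }
  }
  events
}
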