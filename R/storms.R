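#' Per-window storm severity and return period at a site
#'
#' For each analysis window, events attributed to the site within a trailing
#' lookback span (default 20 years, ending at the window's end year) are
#' summarized as the worst Saffir-Simpson category observed (0 if none) and
#' the return period of major (category >= 4) storms, estimated as
#' `span length / count of category >= 4 events` (infinite when none
#' occurred).
#'
#' Attribution: by default an event affects a site when it falls inside the
#' site's 1-degree grid cell; alternatively, supply `impact_radius_km` to
#' attribute every event within that great-circle radius.
#'
#' @param events storm catalog data.frame (`year, lat, lon, category`), e.g.
#'   from [read_storms_csv()]. An empty catalog is valid.
#' @param site one-row data.frame with `lat`, `lon`.
#' @param windows window table from [time_windows()].
#' @param lookback_years trailing span used to estimate the return period.
#' @param impact_radius_km optional great-circle attribution radius.
#' @param grid optional `grid_definition` giving the site's cell center; when
#'   absent the 1-degree cell containing the site is used.
#' @return Data.frame `label_year, worst_category, return_period`.
#' @export
storm_metric <- function(events, site, windows, lookback_years = 20,
                         impact_radius_km = NULL, grid = NULL) {
  if (nrow(events) == 0) {
    hit <- events
  } else if (!is.null(impact_radius_km)) {
    d <- great_circle_km(site$lon, site$lat, events$lon, events$lat)
    hit <- events[d <= impact_radius_km, , drop = FALSE]
  } else {
    if (!is.null(grid)) {
      idx <- assign_cells(site, grid)
      center <- c(grid$lat[idx$lat_i], grid$lon[idx$lon_i])
      half <- grid$cell_size / 2
    } else {
      center <- c(floor(site$lat) + 0.5, floor(site$lon) + 0.5)
      half <- 0.5
    }
    hit <- events[abs(events$lat - center[1]) <= half &
                    abs(events$lon - center[2]) <= half, , drop = FALSE]
  }
  worst <- numeric(nrow(windows))
  rp <- numeric(nrow(windows))
  for (w in seq_len(nrow(windows))) {
    span_end <- windows$end_year[w]
    span_start <- span_end - lookback_years + 1
    in_span <- hit$year >= span_start & hit$year <= span_end
    worst[w] <- if (any(in_span)) max(hit$category[in_span]) else 0
    n_major <- sum(in_span & hit$category >= 4)
    rp[w] <- if (n_major == 0) Inf else lookback_years / n_major
  }
  data.frame(label_year = windows$label_year,
             worst_category = worst, return_period = rp)
}
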