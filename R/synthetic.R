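#' Scenario names recognized by the synthetic generator
#'
#' @return Character vector, best case first.
#' @export
scenario_names <- function() {
  c("RCP2.6-SSP1", "RCP4.5-SSP2", "RCP8.5-SSP5")
}

#' Synthetic scenario configuration
#'
#' Encodes, per stressor, where and when the planted threshold crossings
#' occur as a linear function of position, emulating the spatial structure of
#' the projections the pipeline is designed for: heat stress arrives first
#' near the equator and later at higher latitude; acidification first at high
#' latitude; population pressure spreads from the western edge and land-use
#' pressure from the eastern edge of the domain; major storms radiate from a
#' pantropical band. Worse scenarios shift every climatic crossing earlier
#' and steepen its spread, so scenario curves are ordered by construction.
#'
#' @param name one of [scenario_names()].
#' @return An object of class `scenario_config`: per-variable `(offset,
#'   slope)` year parameters (and band half-width for storms), plus noise
#'   levels.
#' @export
scenario_config <- function(name = scenario_names()) {
  name <- match.arg(name)
  par <- switch(name,
    "RCP8.5-SSP5" = list(dhw = c(2000, 4), arag = c(2010, 4),
                         pop_density = c(1950, 6), land_use = c(1960, 7),
                         storm = c(1990, 6, 10)),
    "RCP4.5-SSP2" = list(dhw = c(2020, 5), arag = c(2030, 5),
                         pop_density = c(1970, 8), land_use = c(1980, 10),
                         storm = c(2010, 8, 7)),
    "RCP2.6-SSP1" = list(dhw = c(2050, 8), arag = c(2060, 8),
                         pop_density = c(1990, 14), land_use = c(2000, 14),
                         storm = c(2035, 12, 3))
  )
  structure(
    list(name = name, par = par,
         margin = c(dhw = 1.0, arag = 0.1, pop_density = 10, land_use = 0.05),
         noise_sd = c(dhw = 1 / 6, arag = 0.1 / 6, pop_density = 10 / 6,
                      land_use = 0.05 / 6),
         horizon = c(1850, 2100)),
    class = "scenario_config"
  )
}

# Snap a real-valued crossing year onto the window label containing it;
# NA when the crossing falls beyond the horizon.
snap_to_label <- function(year) {
  lab <- 1850 + 5 * floor((year - 1850) / 5)
  lab[year < 1850] <- 1850
  lab[lab > 2095] <- NA
  as.integer(lab)
}

#' Per-window series with a planted permanent threshold crossing
#'
#' Builds a monotone trend that sits strictly on the suitable side of the
#' threshold before `planted_year` and strictly on the unsuitable side from
#' `planted_year` onward (clamped to `threshold +- cap` so values stay
#' physically plausible), plus truncated-normal noise bounded below half the
#' margin between trend and threshold. Classification of the series
#' therefore recovers `planted_year` exactly; `planted_year = NA` yields a
#' series that never crosses.
#'
#' @param threshold the suitability limit in the variable's units.
#' @param comparator `"lt"` (unsuitable above the limit) or `"gt"`
#'   (unsuitable below).
#' @param planted_year window label of the first permanently unsuitable
#'   window, or `NA` for never.
#' @param windows window table from [time_windows()].
#' @param margin per-window trend step away from the threshold.
#' @param noise_sd noise standard deviation; must be below `margin / 2`
#'   (draws are additionally truncated at `0.499 * margin`).
#' @param cap clamp on `|trend - threshold|`.
#' @return Numeric vector of per-window metric values (uses the current RNG
#'   stream).
#' @export
plant_crossing_series <- function(threshold, comparator, planted_year, windows,
                                  margin, noise_sd = margin / 6,
                                  cap = 6 * margin) {
  if (noise_sd >= margin / 2) {
    stop("noise_sd must stay below margin / 2 for exact recovery", call. = FALSE)
  }
  dir <- if (comparator == "lt") 1 else -1
  n <- nrow(windows)
  if (is.na(planted_year)) {
    offset <- rep(-margin, n)
  } else {
    i_cross <- match(planted_year, windows$label_year)
    if (is.na(i_cross)) stop("planted_year is not a window label", call. = FALSE)
    offset <- pmin(pmax(margin * (seq_len(n) - i_cross) + margin / 2, -cap), cap)
  }
  noise <- pmin(pmax(stats::rnorm(n, 0, noise_sd), -0.499 * margin),
                0.499 * margin)
  threshold + dir * offset + noise
}

# Planted crossing label for one variable at one cell, from the scenario's
# linear position-to-year rules.
planted_label <- function(config, variable, lat, lon_i, n_lon) {
  p <- config$par[[variable]]
  y <- switch(variable,
    dhw = p[1] + p[2] * abs(lat),
    arag = p[1] + p[2] * (20 - abs(lat)),
    pop_density = p[1] + p[2] * (lon_i - 1),
    land_use = p[1] + p[2] * (n_lon - lon_i),
    storm = if (abs(abs(lat) - 10) <= p[3]) p[1] + p[2] * abs(abs(lat) - 10) else NA
  )
  if (is.na(y)) NA_integer_ else snap_to_label(y)
}

#' Generate a synthetic gridded world with known exceedance truth
#'
#' Builds per-window gridded metric fields for heat stress (window-max DHW),
#' aragonite saturation, neighborhood population density and land-use
#' fraction, each cell carrying a planted permanent crossing year per
#' [plant_crossing_series()]; a storm catalog whose category >= 4 events
#' start exactly at each cell's planted storm year (plus Poisson background
#' storms of category 1-3); and reef sites jittered around sampled cell
#' centers. The planted truth table enables exact pipeline-recovery tests.
#'
#' @param config a [scenario_config()] (or scenario name).
#' @param n_sites number of reef sites (at most one per grid cell).
#' @param grid `grid_definition` for the world (default a 20 x 20 one-degree
#'   reef region, 0-20 N / 120-140 E).
#' @param seed integer RNG seed; identical seeds give bit-identical worlds.
#' @return An object of class `synthetic_world`: list with `grid`, `windows`,
#'   `sites`, `fields` (named `grid_field`s), `storm_catalog`, `truth`
#'   (site x variable planted years), `scenario`, `seed`.
#' @export
generate_world <- function(config = scenario_config("RCP8.5-SSP5"),
                           n_sites = 200,
                           grid = analysis_grid(c(0, 20), c(120, 140)),
                           seed = 1) {
  if (is.character(config)) config <- scenario_config(config)
  stopifnot(inherits(config, "scenario_config"))
  nlat <- length(grid$lat)
  nlon <- length(grid$lon)
  if (n_sites > nlat * nlon) {
    stop("n_sites exceeds the number of grid cells", call. = FALSE)
  }
  set.seed(seed)
  windows <- time_windows()
  nw <- nrow(windows)

  field_vars <- c(dhw = "dhw", arag = "arag", pop_density = "pop_density",
                  land_use = "land_use_fraction")
  units <- c(dhw = "degC-weeks", arag = "omega", pop_density = "persons km-2",
             land_use = "fraction")
  comparator <- c(dhw = "lt", arag = "gt", pop_density = "lt", land_use = "lt")
  limits <- c(dhw = 8, arag = 3.3, pop_density = 100, land_use = 0.5)

  cell_truth <- array(NA_integer_, dim = c(nlat, nlon, 5),
                      dimnames = list(NULL, NULL, stressor_variables()))
  fields <- list()
  for (v in names(field_vars)) {
    vals <- array(NA_real_, dim = c(nw, nlat, nlon))
    for (i in seq_len(nlat)) {
      for (j in seq_len(nlon)) {
        lab <- planted_label(config, v, grid$lat[i], j, nlon)
        cell_truth[i, j, v] <- lab
        vals[, i, j] <- plant_crossing_series(
          limits[[v]], comparator[[v]], lab, windows,
          margin = config$margin[[v]], noise_sd = config$noise_sd[[v]]
        )
      }
    }
    if (v == "dhw") vals <- pmax(vals, 0)       # DHW cannot be negative
    if (v == "land_use") vals <- pmin(pmax(vals, 0), 1)
    fields[[v]] <- grid_field(grid, field_vars[[v]], units[[v]], windows, vals)
  }

  events <- list()
  for (i in seq_len(nlat)) {
    for (j in seq_len(nlon)) {
      lab <- planted_label(config, "storm", grid$lat[i], j, nlon)
      cell_truth[i, j, "storm"] <- lab
      if (!is.na(lab)) {
        yrs <- lab:2100
        events[[length(events) + 1L]] <- data.frame(
          year = yrs, lat = grid$lat[i], lon = grid$lon[j],
          category = rep(4L, length(yrs))
        )
      }
      n_bg <- stats::rpois(1, 3)
      if (n_bg > 0) {
        events[[length(events) + 1L]] <- data.frame(
          year = sort(sample(1850:2100, n_bg, replace = TRUE)),
          lat = grid$lat[i], lon = grid$lon[j],
          category = sample(1:3, n_bg, replace = TRUE)
        )
      }
    }
  }
  storm_cat <- storm_catalog(do.call(rbind, events))

  cells <- sample.int(nlat * nlon, n_sites)
  lat_i <- ((cells - 1L) %% nlat) + 1L
  lon_i <- ((cells - 1L) %/% nlat) + 1L
  sites <- data.frame(
    site_id = sprintf("site_%03d", seq_len(n_sites)),
    lat = grid$lat[lat_i] + stats::runif(n_sites, -0.2, 0.2),
    lon = grid$lon[lon_i] + stats::runif(n_sites, -0.2, 0.2),
    reef_class = sample(c("coral", "rocky"), n_sites, replace = TRUE,
                        prob = c(0.9, 0.1)),
    lat_i = lat_i, lon_i = lon_i,
    stringsAsFactors = FALSE
  )

  truth <- do.call(rbind, lapply(stressor_variables(), function(v) {
    vi <- match(v, stressor_variables())
    data.frame(site_id = sites$site_id, variable_id = v,
               truth_year = cell_truth[cbind(lat_i, lon_i, vi)],
               stringsAsFactors = FALSE)
  }))

  structure(
    list(grid = grid, windows = windows, sites = sites, fields = fields,
         storm_catalog = storm_cat, truth = truth,
         scenario = config$name, seed = seed),
    class = "synthetic_world"
  )
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("<synthetic_world> %s, %d sites on %d x %d grid, %d windows, %d storm events, seed %d\n",
              x$scenario, nrow(x$sites), length(x$grid$lat), length(x$grid$lon),
              nrow(x$windows), nrow(x$storm_catalog), x$seed))
  invisible(x)
}

#' Extract the per-site metric table from a world
#'
#' Samples every gridded stressor field at the reef sites and computes the
#' storm metric from the catalog, yielding the long table the exceedance
#' stage consumes.
#'
#' @param world a `synthetic_world`.
#' @return Long data.frame `site_id, variable_id, label_year, value, value2`
#'   (`value2` is the storm return period).
#' @export
world_metrics <- function(world) {
  stopifnot(inherits(world, "synthetic_world"))
  pieces <- lapply(c("dhw", "arag", "pop_density", "land_use"), function(v) {
    m <- sample_at_sites(world$fields[[v]], world$sites)
    m$variable_id <- v
    m$value2 <- NA_real_
    m
  })
  storm <- do.call(rbind, lapply(seq_len(nrow(world$sites)), function(k) {
    s <- world$sites[k, ]
    sm <- storm_metric(world$storm_catalog, s, world$windows, grid = world$grid)
    data.frame(site_id = s$site_id, label_year = sm$label_year,
               value = sm$worst_category, variable_id = "storm",
               value2 = sm$return_period, stringsAsFactors = FALSE)
  }))
  out <- rbind(do.call(rbind, pieces), storm)
  out[, c("site_id", "variable_id", "label_year", "value", "value2")]
}

#' Run the full suitability pipeline on a synthetic world
#'
#' @param world a `synthetic_world`.
#' @param thresholds threshold set (default [default_thresholds()]).
#' @return List with `metrics`, `years` (per site x stressor exceedance) and
#'   `outcomes` (a `site_outcomes`).
#' @export
run_world <- function(world, thresholds = default_thresholds()) {
  metrics <- world_metrics(world)
  years <- compute_exceedance(metrics, thresholds, world$windows)
  list(metrics = metrics, years = years, outcomes = site_outcomes(years))
}

#' Compare recovered exceedance years with the planted truth
#'
#' @param world a `synthetic_world`.
#' @param years data.frame from [compute_exceedance()] (e.g.
#'   `run_world(world)$years`).
#' @return List with `n`, `n_match`, `fraction_match` and the merged
#'   `comparison` table.
#' @export
truth_recovery <- function(world, years) {
  cmp <- merge(world$truth, years, by = c("site_id", "variable_id"))
  match_ok <- (is.na(cmp$truth_year) & is.na(cmp$exceedance_year)) |
    (!is.na(cmp$truth_year) & !is.na(cmp$exceedance_year) &
       cmp$truth_year == cmp$exceedance_year)
  list(n = nrow(cmp), n_match = sum(match_ok),
       fraction_match = mean(match_ok), comparison = cmp)
}

#' Weekly SST series with a planted thermal-stress crossing
#'
#' Produces, per site, a weekly SST series whose window-max DHW first reaches
#' the 8 deg C-weeks limit permanently at the planted year: a seasonal
#' baseline staying at least 0.5 deg C below the MMM (never a hotspot), and
#' from the planted year onward a sustained 12-week +1.5 deg C anomaly each
#' year, which accumulates to a DHW peak of 18 deg C-weeks.
#'
#' @param planted_years named integer vector of window labels (`NA` = never),
#'   one per site.
#' @param mmm maximum monthly mean climatology (deg C) shared by the sites.
#' @param seed RNG seed for the bounded baseline noise.
#' @param years simulated calendar years.
#' @param noise_sd baseline noise sd, truncated at 0.3 deg C so noise can
#'   never create a hotspot.
#' @return Named list of data.frames `year, week, sst`.
#' @export
generate_weekly_sst <- function(planted_years, mmm, seed = 1,
                                years = 1850:2100, noise_sd = 0.1) {
  set.seed(seed)
  week <- 1:52
  lapply_named <- function(x, f) {
    out <- lapply(seq_along(x), f)
    names(out) <- names(x)
    out
  }
  lapply_named(planted_years, function(k) {
    planted <- planted_years[[k]]
    yr <- rep(years, each = 52)
    wk <- rep(week, times = length(years))
    base <- mmm - 1.2 + 0.7 * sin(2 * pi * (wk - 13) / 52)
    noise <- pmin(pmax(stats::rnorm(length(yr), 0, noise_sd), -0.3), 0.3)
    sst <- base + noise
    if (!is.na(planted)) {
      hot <- yr >= planted & wk >= 10 & wk <= 21
      sst[hot] <- mmm + 1.5
    }
    data.frame(year = yr, week = wk, sst = sst)
  })
}
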