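#' Cumulative fraction of sites permanently unsuitable by year
#'
#' The curve behind the suitability-timeline figures: for each evaluation
#' year, the fraction of sites whose permanent exceedance year (overall, or
#' for one stressor) is at or before that year. Sites are weighted equally
#' (each is one 1-km reef cell).
#'
#' @param outcomes a `site_outcomes` object.
#' @param stratum `"overall"` or one of [stressor_variables()].
#' @param eval_years ordered years at which to evaluate the curve.
#' @return An object of class `cumulative_curve`: data.frame
#'   `eval_year, fraction` with attribute `stratum`.
#' @export
cumulative_fraction <- function(outcomes, stratum = "overall",
                                eval_years = seq(1850, 2100, by = 5)) {
  stopifnot(inherits(outcomes, "site_outcomes"))
  if (identical(stratum, "overall")) {
    yrs <- outcomes$sites$overall_year
  } else {
    sel <- outcomes$years$variable_id == stratum
    if (!any(sel)) stop("no outcomes for stratum ", stratum, call. = FALSE)
    yrs <- outcomes$years$exceedance_year[sel]
  }
  if (length(yrs) == 0) stop("empty outcome list", call. = FALSE)
  fraction <- vapply(eval_years, function(y) {
    mean(!is.na(yrs) & yrs <= y)
  }, numeric(1))
  structure(
    data.frame(eval_year = eval_years, fraction = fraction),
    stratum = stratum, class = c("cumulative_curve", "data.frame")
  )
}

#' Earliest year at which a cumulative curve reaches a fraction
#'
#' E.g. the year by which 75% of reef sites face permanently unsuitable
#' conditions; exact attainment counts.
#'
#' @param curve a `cumulative_curve`.
#' @param q target fraction in `[0, 1]`.
#' @return The earliest evaluation year with `fraction >= q`, or `NA` if the
#'   curve never reaches `q`.
#' @export
year_reaching_fraction <- function(curve, q) {
  hit <- which(curve$fraction >= q)
  if (length(hit) == 0) NA_integer_ else as.integer(curve$eval_year[hit[1]])
}

#' Mean and median unsuitability dates for the still-viable cohort
#'
#' Restricts to sites still suitable after `viable_after` (overall year later
#' than it, or never unsuitable) and reports, per stressor and overall, the
#' mean and median of the defined exceedance years within that cohort. Sites
#' never becoming unsuitable are excluded from the averages and reported as a
#' count.
#'
#' @param outcomes a `site_outcomes` object.
#' @param viable_after cohort cutoff year (2005: the start of the scenario
#'   period).
#' @return Data.frame `stratum, mean_year, median_year, n_exceeding, n_never`.
#' @export
cohort_mean_year <- function(outcomes, viable_after = 2005) {
  stopifnot(inherits(outcomes, "site_outcomes"))
  keep_ids <- outcomes$sites$site_id[
    is.na(outcomes$sites$overall_year) |
      outcomes$sites$overall_year > viable_after
  ]
  row_for <- function(stratum, yrs) {
    y <- yrs[!is.na(yrs)]
    data.frame(
      stratum = stratum,
      mean_year = if (length(y)) mean(y) else NA_real_,
      median_year = if (length(y)) stats::median(y) else NA_real_,
      n_exceeding = length(y),
      n_never = sum(is.na(yrs)),
      stringsAsFactors = FALSE
    )
  }
  yr <- outcomes$years[outcomes$years$site_id %in% keep_ids, ]
  per_var <- lapply(split(yr, yr$variable_id), function(d) {
    row_for(d$variable_id[1], d$exceedance_year)
  })
  overall <- row_for(
    "overall",
    outcomes$sites$overall_year[outcomes$sites$site_id %in% keep_ids]
  )
  out <- rbind(do.call(rbind, per_var), overall)
  rownames(out) <- NULL
  out
}

#' Distribution of sites by number of exceeded stressors at 2100
#'
#' @param outcomes a `site_outcomes` object.
#' @return Named numeric vector of shares over counts 0-5, summing to 1.
#' @export
stressor_count_shares <- function(outcomes) {
  stopifnot(inherits(outcomes, "site_outcomes"))
  counts <- outcomes$sites$n_stressors_2100
  shares <- vapply(0:5, function(k) mean(counts == k), numeric(1))
  names(shares) <- as.character(0:5)
  shares
}

#' Export the date-of-unsuitability map
#'
#' Per-site table of overall unsuitability dates (sites never permanently
#' unsuitable are flagged as suitable through 2100), optionally also
#' aggregated onto an analysis grid where a cell takes the earliest year of
#' its sites (conservative), written in the package's gridded CSV format.
#'
#' @param outcomes a `site_outcomes` object.
#' @param sites site table with `site_id, lat, lon`.
#' @param path optional CSV output path for the site table.
#' @param grid optional `grid_definition`; when given, the returned list also
#'   carries `grid_years`, a lat x lon matrix of earliest overall years.
#' @param grid_path optional output path for the gridded product.
#' @return Invisibly, a list with `table` (the per-site data.frame) and, if
#'   requested, `grid_years`.
#' @export
export_date_map <- function(outcomes, sites, path = NULL, grid = NULL,
                            grid_path = NULL) {
  stopifnot(inherits(outcomes, "site_outcomes"))
  if (nrow(outcomes$sites) == 0) stop("empty outcome list", call. = FALSE)
  tab <- merge(sites[, c("site_id", "lat", "lon")], outcomes$sites,
               by = "site_id", sort = FALSE)
  tab$suitable_through_2100 <- is.na(tab$overall_year)
  if (!is.null(path)) utils::write.csv(tab, path, row.names = FALSE)
  out <- list(table = tab)
  if (!is.null(grid)) {
    tab2 <- assign_cells(tab, grid)
    gy <- matrix(NA_real_, length(grid$lat), length(grid$lon))
    for (k in seq_len(nrow(tab2))) {
      y <- tab2$overall_year[k]
      if (is.na(y)) next
      i <- tab2$lat_i[k]; j <- tab2$lon_i[k]
      gy[i, j] <- if (is.na(gy[i, j])) y else min(gy[i, j], y)
    }
    out$grid_years <- gy
    if (!is.null(grid_path)) {
      gf <- grid_field(grid, "sst", "year",
                       data.frame(start_year = 2100, end_year = 2100,
                                  label_year = 2100),
                       array(gy, dim = c(1, dim(gy))))
      gf$variable_id <- "overall_year"
      write_grid_csv(gf, grid_path)
    }
  }
  invisible(out)
}
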