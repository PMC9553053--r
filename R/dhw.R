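#' Calendar month of a week in the 52-week year
#'
#' Weeks are numbered 1-52; week `w` is anchored at its mid-day
#' `(w - 0.5) * 7` of a 365-day year.
#'
#' @param week integer week-of-year, 1-52.
#' @return Integer month 1-12.
#' @export
month_of_week <- function(week) {
  cum <- cumsum(c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31))
  day <- (week - 0.5) * 7
  findInterval(day, cum[-12] + 0.5) + 1L
}

#' Maximum monthly mean (MMM) climatology
#'
#' The bleaching-stress baseline: monthly mean SST is computed within each
#' baseline year, averaged month-wise across the baseline years, and the
#' warmest of the 12 climatological months is returned.
#'
#' @param weekly_sst data.frame with columns `year`, `week` (1-52), `sst`
#'   (deg C).
#' @param baseline_years integer years defining the climatology baseline
#'   (default the 1850-2005 historical period).
#' @return MMM in deg C.
#' @export
compute_mmm_climatology <- function(weekly_sst, baseline_years = 1850:2005) {
  sub <- weekly_sst[weekly_sst$year %in% baseline_years & !is.na(weekly_sst$sst), ]
  if (nrow(sub) == 0) stop("no weekly SST inside the baseline years", call. = FALSE)
  sub$month <- month_of_week(sub$week)
  missing_months <- setdiff(1:12, unique(sub$month))
  if (length(missing_months)) {
    stop("incomplete climatology; no data for months: ",
         paste(month.abb[missing_months], collapse = ", "), call. = FALSE)
  }
  ym <- stats::aggregate(sst ~ month + year, data = sub, FUN = mean)
  clim <- stats::aggregate(sst ~ month, data = ym, FUN = mean)
  max(clim$sst)
}

#' Degree heating weeks from weekly SST
#'
#' NOAA Coral Reef Watch convention: the weekly hotspot is
#' `sst - mmm` when at least 1 deg C above the maximum monthly mean and 0
#' otherwise; DHW at week `w` is the sum of hotspots over the trailing 12
#' weeks including `w` (the first 11 weeks use the available partial window).
#' Missing weeks count as hotspot 0 and are reported via a message.
#'
#' @param weekly_sst numeric vector of weekly SST (deg C), in time order, or
#'   a data.frame with columns `year`, `week`, `sst`.
#' @param mmm maximum monthly mean climatology (deg C).
#' @param accumulation_weeks trailing accumulation span (12 weeks).
#' @return DHW in deg C-weeks: a numeric vector, or the input data.frame with
#'   a `dhw` column when a data.frame was supplied.
#' @export
compute_dhw <- function(weekly_sst, mmm, accumulation_weeks = 12) {
  if (!is.finite(mmm)) stop("mmm must be finite", call. = FALSE)
  df_in <- is.data.frame(weekly_sst)
  sst <- if (df_in) weekly_sst$sst else as.numeric(weekly_sst)
  if (anyNA(sst)) {
    message(sum(is.na(sst)), " missing weeks treated as hotspot 0")
  }
  anom <- sst - mmm
  hot <- ifelse(!is.na(anom) & anom >= 1, anom, 0)
  n <- length(hot)
  # direct trailing sums (not cumsum differences): exact, no cancellation
  dhw <- vapply(seq_len(n), function(w) {
    sum(hot[max(1L, w - accumulation_weeks + 1L):w])
  }, numeric(1))
  if (df_in) {
    weekly_sst$dhw <- dhw
    weekly_sst
  } else {
    dhw
  }
}

#' Reduce weekly DHW to the per-window metric
#'
#' The thermal-stress value of an analysis window is the maximum weekly DHW
#' attained inside it, the quantity the 8 deg C-weeks suitability threshold
#' applies to.
#'
#' @param dhw data.frame with columns `year` and `dhw` (one row per week),
#'   e.g. from [compute_dhw()] on a data.frame.
#' @param windows window table from [time_windows()].
#' @return Data.frame `label_year, value`; windows with no weeks are missing.
#' @export
window_dhw_metric <- function(dhw, windows) {
  stopifnot(all(c("year", "dhw") %in% names(dhw)))
  value <- vapply(seq_len(nrow(windows)), function(w) {
    in_w <- dhw$year >= windows$start_year[w] & dhw$year <= windows$end_year[w]
    if (!any(in_w)) return(NA_real_)
    max(dhw$dhw[in_w])
  }, numeric(1))
  data.frame(label_year = windows$label_year, value = value)
}
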