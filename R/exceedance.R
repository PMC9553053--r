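#' Binary suitability of a metric value
#'
#' A value is suitable (1) when the strict "ideal-side" inequality of its
#' threshold holds, unsuitable (0) otherwise; a value exactly at the limit is
#' unsuitable. For the compound storm threshold, conditions are unsuitable
#' when the worst category reaches the category limit AND the major-storm
#' return period is at or below the return-period limit (or either, under the
#' disjunction rule). Missing values yield a missing flag.
#'
#' @param value metric value(s) in the variable's units (worst category for
#'   storms).
#' @param spec a [threshold_spec()].
#' @param value2 for `compound_storm`: the return period(s) in years.
#' @return Integer vector of 0/1/NA flags (1 = suitable).
#' @export
classify <- function(value, spec, value2 = NULL) {
  if (!inherits(spec, "threshold_spec")) stop("spec must be a threshold_spec", call. = FALSE)
  if (spec$comparator == "lt") {
    flag <- value < spec$limit
  } else if (spec$comparator == "gt") {
    flag <- value > spec$limit
  } else {
    if (is.null(value2)) stop("compound_storm needs value2 = return period", call. = FALSE)
    cat_exceeded <- value >= spec$limit$category
    rp_exceeded <- value2 <= spec$limit$return_years
    flag <- if (spec$rule == "conjunction") {
      !(cat_exceeded & rp_exceeded)
    } else {
      !(cat_exceeded | rp_exceeded)
    }
  }
  as.integer(flag)
}

# Gap rule: a missing flag inherits the previous window's flag; leading
# missing flags default to suitable.
fill_flags <- function(flags) {
  if (length(flags) == 0) return(flags)
  if (is.na(flags[1])) flags[1] <- 1L
  for (i in seq_along(flags)[-1]) {
    if (is.na(flags[i])) flags[i] <- flags[i - 1L]
  }
  flags
}

#' First year of permanent threshold exceedance
#'
#' The label year of the first window of the terminal run of unsuitable
#' windows, i.e. the first year after which conditions remain unsuitable
#' through the end of the horizon (2100). A recovery resets the clock; if the
#' final window is suitable there is no permanent exceedance and `NA` is
#' returned.
#'
#' @param flags integer 0/1 suitability flags, one per window, covering the
#'   full horizon. Missing flags are filled by persistence (leading gaps
#'   count as suitable).
#' @param windows window table from [time_windows()] (same length as
#'   `flags`).
#' @return Integer year, or `NA` if never permanently unsuitable.
#' @export
permanent_exceedance_year <- function(flags, windows) {
  n <- length(flags)
  if (n == 0) stop("empty flag vector", call. = FALSE)
  if (n != nrow(windows)) stop("flags and windows lengths differ", call. = FALSE)
  flags <- fill_flags(as.integer(flags))
  if (flags[n] == 1L) return(NA_integer_)
  last_suitable <- max(c(0L, which(flags == 1L)))
  as.integer(windows$label_year[last_suitable + 1L])
}

#' Overall environmental unsuitability date
#'
#' The earliest year at which any stressor permanently crosses its tolerance
#' threshold at a site.
#'
#' @param per_variable_years named numeric/integer vector of per-stressor
#'   permanent exceedance years (`NA` = never).
#' @return The minimum defined year, or `NA` if all are undefined.
#' @export
overall_unsuitability_year <- function(per_variable_years) {
  y <- per_variable_years[!is.na(per_variable_years)]
  if (length(y) == 0) NA_integer_ else as.integer(min(y))
}

#' Number of stressors permanently exceeded by a given year
#'
#' @param per_variable_years per-stressor exceedance years (`NA` = never).
#' @param year evaluation year (2100 for the end-of-century count).
#' @return Integer count 0-5.
#' @export
count_stressors_at <- function(per_variable_years, year = 2100) {
  sum(!is.na(per_variable_years) & per_variable_years <= year)
}

#' Per-site, per-stressor permanent exceedance years
#'
#' Classifies every metric value against its threshold, fills gaps by
#' persistence, and scans each site x stressor series for the terminal
#' unsuitable run.
#'
#' @param metrics long data.frame `site_id, variable_id, label_year, value`
#'   (plus `value2` carrying the storm return period). Every series must
#'   cover all analysis windows.
#' @param thresholds named list of `threshold_spec`s keyed by `variable_id`.
#' @param windows window table from [time_windows()].
#' @return Data.frame `site_id, variable_id, exceedance_year` (`NA` = never).
#' @export
compute_exceedance <- function(metrics, thresholds, windows) {
  if (!"value2" %in% names(metrics)) metrics$value2 <- NA_real_
  vars <- unique(metrics$variable_id)
  unknown <- setdiff(vars, names(thresholds))
  if (length(unknown)) {
    stop("no threshold for variable(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  pieces <- lapply(vars, function(v) {
    spec <- thresholds[[v]]
    mv <- metrics[metrics$variable_id == v, ]
    mv <- mv[order(mv$site_id, mv$label_year), ]
    yrs <- vapply(split(seq_len(nrow(mv)), mv$site_id), function(ix) {
      if (length(ix) != nrow(windows)) {
        stop("series for ", v, " does not cover all ", nrow(windows),
             " windows", call. = FALSE)
      }
      flags <- classify(mv$value[ix], spec, mv$value2[ix])
      permanent_exceedance_year(flags, windows)
    }, integer(1))
    data.frame(site_id = names(yrs), variable_id = v,
               exceedance_year = unname(yrs), stringsAsFactors = FALSE)
  })
  do.call(rbind, pieces)
}

#' Combine per-stressor exceedance years into site outcomes
#'
#' @param years data.frame from [compute_exceedance()].
#' @return An object of class `site_outcomes`: a list with `years` (the
#'   input) and `sites` (`site_id, overall_year, n_stressors_2100`).
#' @export
site_outcomes <- function(years) {
  by_site <- split(years$exceedance_year, years$site_id)
  sites <- data.frame(
    site_id = names(by_site),
    overall_year = vapply(by_site, overall_unsuitability_year, integer(1)),
    n_stressors_2100 = vapply(by_site, count_stressors_at, numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(sites) <- NULL
  structure(list(years = years, sites = sites), class = "site_outcomes")
}

#' @export
print.site_outcomes <- function(x, ...) {
  n <- nrow(x$sites)
  cat(sprintf("<site_outcomes> %d sites; %d (%.0f%%) permanently unsuitable by 2100\n",
              n, sum(!is.na(x$sites$overall_year)),
              100 * mean(!is.na(x$sites$overall_year))))
  invisible(x)
}

#' Threshold sensitivity sweep
#'
#' Re-runs classification, permanent-exceedance scanning and the cumulative
#' curve under each perturbed threshold set, so the stability of the
#' suitability timeline against threshold choice can be inspected.
#'
#' @param metrics long metric table as in [compute_exceedance()].
#' @param windows window table from [time_windows()].
#' @param perturbations named list of threshold sets (e.g. built with
#'   [perturb_thresholds()]); include the baseline as one entry to anchor the
#'   comparison.
#' @param baseline threshold set whose comparators every perturbation must
#'   preserve (a perturbation may move a limit, never flip the ideal side).
#' @param eval_years years at which cumulative fractions are evaluated
#'   (default the window labels plus 2100).
#' @return An object of class `sensitivity_sweep`: list with `summary` (one
#'   row per perturbation: fraction unsuitable by 2100, median and mean
#'   overall year), `curves` (long: perturbation, eval_year, fraction) and
#'   `outcomes` (per-perturbation `site_outcomes`).
#' @export
sensitivity_sweep <- function(metrics, windows, perturbations,
                              baseline = default_thresholds(),
                              eval_years = NULL) {
  if (is.null(names(perturbations)) || any(names(perturbations) == "")) {
    names(perturbations) <- paste0("perturbation_", seq_along(perturbations))
  }
  if (is.null(eval_years)) eval_years <- sort(unique(c(windows$label_year, 2100)))
  for (nm in names(perturbations)) {
    th <- perturbations[[nm]]
    for (v in names(th)) {
      if (!is.null(baseline[[v]]) &&
          !identical(th[[v]]$comparator, baseline[[v]]$comparator)) {
        stop("perturbation '", nm, "' inverts the comparator sense for ", v,
             call. = FALSE)
      }
    }
  }
  outcomes <- lapply(perturbations, function(th) {
    site_outcomes(compute_exceedance(metrics, th, windows))
  })
  curves <- do.call(rbind, lapply(names(outcomes), function(nm) {
    cv <- cumulative_fraction(outcomes[[nm]], "overall", eval_years)
    data.frame(perturbation = nm, eval_year = cv$eval_year,
               fraction = cv$fraction, stringsAsFactors = FALSE)
  }))
  summary <- do.call(rbind, lapply(names(outcomes), function(nm) {
    oy <- outcomes[[nm]]$sites$overall_year
    data.frame(
      perturbation = nm,
      frac_unsuitable_2100 = mean(!is.na(oy)),
      median_overall_year = if (any(!is.na(oy))) stats::median(oy, na.rm = TRUE) else NA_real_,
      mean_overall_year = if (any(!is.na(oy))) mean(oy, na.rm = TRUE) else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  structure(list(summary = summary, curves = curves, outcomes = outcomes),
            class = "sensitivity_sweep")
}
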