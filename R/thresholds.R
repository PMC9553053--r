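#' Stressor variable identifiers used by the suitability pipeline
#'
#' @return Character vector of the five analyzed stressors.
#' @export
stressor_variables <- function() {
  c("dhw", "arag", "storm", "pop_density", "land_use")
}

#' One stressor's suitability threshold
#'
#' A threshold has a comparator giving the "ideal" side and a limit in the
#' variable's units; the comparison is strict, so a value exactly at the
#' limit is unsuitable. The `compound_storm` comparator carries two limits
#' (Saffir-Simpson category and return period in years).
#'
#' @param variable_id one of [stressor_variables()].
#' @param comparator `"lt"` (suitable strictly below the limit), `"gt"`
#'   (suitable strictly above), or `"compound_storm"`.
#' @param limit numeric limit; for `compound_storm`, a named list/vector with
#'   `category` and `return_years`.
#' @param neighborhood optional [neighborhood_spec()] documenting the radius
#'   the metric was computed over.
#' @param rule for `compound_storm`: `"conjunction"` (unsuitable only when
#'   the category AND return-period limits are both exceeded) or
#'   `"disjunction"` (either suffices).
#' @return An object of class `threshold_spec`.
#' @export
threshold_spec <- function(variable_id, comparator, limit, neighborhood = NULL,
                           rule = c("conjunction", "disjunction")) {
  comparator <- match.arg(comparator, c("lt", "gt", "compound_storm"))
  rule <- match.arg(rule)
  if (comparator == "compound_storm") {
    limit <- as.list(limit)
    if (!all(c("category", "return_years") %in% names(limit))) {
      stop("compound_storm limit needs 'category' and 'return_years'",
           call. = FALSE)
    }
    if (!all(vapply(limit, is.finite, logical(1)))) {
      stop("threshold limits must be finite", call. = FALSE)
    }
  } else if (length(limit) != 1 || is.na(limit)) {
    stop("limit must be a single finite number (or Inf/-Inf for a disabled threshold)",
         call. = FALSE)
  }
  structure(
    list(variable_id = variable_id, comparator = comparator, limit = limit,
         neighborhood = neighborhood, rule = rule),
    class = "threshold_spec"
  )
}

#' Default suitability thresholds for the five stressors
#'
#' Conditions are suitable when, strictly: DHW < 8 deg C-weeks; aragonite
#' saturation state > 3.3; storms below category 4 or rarer than one major
#' storm per 5 years; population density below 10^2 persons per km^2 (the
#' log10-density-below-2 criterion stated in linear space) within 50 km; and
#' summed agricultural + urban land-use fraction below 0.5 within 50 km.
#'
#' @param storm_rule how the two storm limits combine; see [threshold_spec()].
#' @return Named list of `threshold_spec`s keyed by variable.
#' @export
default_thresholds <- function(storm_rule = "conjunction") {
  nb <- neighborhood_spec(50)
  list(
    dhw = threshold_spec("dhw", "lt", 8),
    arag = threshold_spec("arag", "gt", 3.3),
    storm = threshold_spec("storm", "compound_storm",
                           list(category = 4, return_years = 5),
                           rule = storm_rule),
    pop_density = threshold_spec("pop_density", "lt", 100, neighborhood = nb),
    land_use = threshold_spec("land_use", "lt", 0.5, neighborhood = nb)
  )
}

#' Read a threshold configuration from YAML
#'
#' The file maps variable ids to `comparator`, `limit` (scalar, or
#' `category`/`return_years` for storms), optional `radius_km` and `rule`.
#' See `inst/extdata/thresholds.yaml` for the shipped defaults.
#'
#' @param path YAML file.
#' @return Named list of `threshold_spec`s.
#' @export
read_threshold_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- lapply(names(cfg), function(v) {
    entry <- cfg[[v]]
    nb <- if (!is.null(entry$radius_km)) neighborhood_spec(entry$radius_km) else NULL
    limit <- if (entry$comparator == "compound_storm") {
      list(category = entry$category, return_years = entry$return_years)
    } else {
      entry$limit
    }
    threshold_spec(v, entry$comparator, limit, neighborhood = nb,
                   rule = if (!is.null(entry$rule)) entry$rule else "conjunction")
  })
  names(out) <- names(cfg)
  out
}

#' Shift a threshold set for sensitivity analysis
#'
#' @param thresholds named list of `threshold_spec`s (the baseline).
#' @param shifts named list of per-variable shifts: a number for scalar
#'   limits, or a list with `category`/`return_years` entries for the storm
#'   threshold. Unnamed variables are left untouched.
#' @param relative if `TRUE`, shifts are relative (`limit * (1 + shift)`),
#'   otherwise absolute (`limit + shift`).
#' @return A perturbed threshold set.
#' @export
perturb_thresholds <- function(thresholds, shifts, relative = FALSE) {
  bump <- function(x, s) if (relative) x * (1 + s) else x + s
  for (v in names(shifts)) {
    if (is.null(thresholds[[v]])) {
      stop("no baseline threshold for variable ", v, call. = FALSE)
    }
    th <- thresholds[[v]]
    if (th$comparator == "compound_storm") {
      s <- as.list(shifts[[v]])
      for (nm in names(s)) th$limit[[nm]] <- bump(th$limit[[nm]], s[[nm]])
    } else {
      th$limit <- bump(th$limit, shifts[[v]])
    }
    thresholds[[v]] <- th
  }
  thresholds
}
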