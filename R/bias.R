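#' Per-pixel delta bias of a model against empirical data
#'
#' Earth System Model fields carry pixel-level biases that can flip a
#' threshold test by themselves. The delta correction is the difference
#' between the empirical and modeled means over the historical period the two
#' have in common:
#' `delta(pixel) = mean_common(empirical) - mean_common(model)`.
#'
#' @param model_hist,empirical_hist `grid_field`s on the analysis grid with
#'   the same `variable_id`.
#' @param common_period length-2 integer years; time steps overlapping
#'   `[common_period[1], common_period[2]]` enter the means.
#' @return An object of class `bias_field` with the per-pixel `delta` matrix.
#' @export
compute_bias <- function(model_hist, empirical_hist,
                         common_period = c(1850, 2005)) {
  stopifnot(inherits(model_hist, "grid_field"),
            inherits(empirical_hist, "grid_field"))
  if (!same_grid(model_hist$grid, empirical_hist$grid)) {
    stop("model and empirical fields must share the analysis grid", call. = FALSE)
  }
  if (!identical(model_hist$variable_id, empirical_hist$variable_id)) {
    stop("variable_id mismatch between model and empirical fields", call. = FALSE)
  }
  period_mean <- function(field) {
    keep <- field$time_axis$end_year >= common_period[1] &
      field$time_axis$start_year <= common_period[2]
    if (!any(keep)) stop("no temporal overlap with the common period", call. = FALSE)
    sub <- field$values[keep, , , drop = FALSE]
    apply(sub, c(2, 3), function(x) {
      if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
    })
  }
  delta <- period_mean(empirical_hist) - period_mean(model_hist)
  structure(
    list(grid = model_hist$grid, variable_id = model_hist$variable_id,
         delta = delta, common_period = common_period),
    class = "bias_field"
  )
}

#' Apply a delta bias correction to a projection
#'
#' Adds the per-pixel delta to every time step; the missing mask of the
#' output is the union of the projection's and the delta's masks, so pixels
#' without an empirical baseline stay missing rather than passing through
#' uncorrected.
#'
#' @param projection `grid_field` to correct.
#' @param bias `bias_field` from [compute_bias()].
#' @return The corrected `grid_field`.
#' @export
apply_bias <- function(projection, bias) {
  stopifnot(inherits(projection, "grid_field"), inherits(bias, "bias_field"))
  if (!same_grid(projection$grid, bias$grid)) {
    stop("projection and bias grids differ", call. = FALSE)
  }
  if (!identical(projection$variable_id, bias$variable_id)) {
    stop("variable_id mismatch between projection and bias", call. = FALSE)
  }
  out <- projection$values
  for (t in seq_len(nrow(projection$time_axis))) {
    out[t, , ] <- out[t, , ] + bias$delta
  }
  grid_field(projection$grid, projection$variable_id, projection$units,
             projection$time_axis, out)
}

#' Pointwise mean across an ensemble of fields
#'
#' Simple multi-model combination: the missing-aware mean over (typically
#' bias-corrected) model fields on identical grids and time axes.
#'
#' @param fields list of `grid_field`s.
#' @return A `grid_field`; cells missing in every member stay missing.
#' @export
ensemble_mean <- function(fields) {
  stopifnot(length(fields) >= 1)
  f1 <- fields[[1]]
  if (length(fields) == 1) return(f1)
  for (f in fields[-1]) {
    if (!same_grid(f$grid, f1$grid) ||
        !identical(nrow(f$time_axis), nrow(f1$time_axis))) {
      stop("ensemble members must share grid and time axis", call. = FALSE)
    }
  }
  stack <- vapply(fields, function(f) f$values,
                  array(0, dim = dim(f1$values)))
  tot <- apply(stack, 1:3, function(x) {
    if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  })
  grid_field(f1$grid, f1$variable_id, f1$units, f1$time_axis, tot)
}
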