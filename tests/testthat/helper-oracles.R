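# Independent brute-force oracles used to cross-check the implementation.

# Earliest window whose suffix is entirely unsuitable, by exhaustive scan.
oracle_exceedance <- function(flags, windows) {
  n <- length(flags)
  for (w in seq_len(n)) {
    if (all(flags[w:n] == 0L)) return(as.integer(windows$label_year[w]))
  }
  NA_integer_
}

# DHW by summing hotspots over every explicit trailing 12-week slice.
oracle_dhw <- function(sst, mmm) {
  hot <- pmax(sst - mmm, 0)
  hot[hot < 1] <- 0
  vapply(seq_along(sst), function(w) {
    sum(hot[max(1, w - 11):w])
  }, numeric(1))
}

# Small fixture: a grid field whose values follow a given function of
# (time index, lat, lon).
make_field <- function(lat, lon, years, fn, variable_id = "sst", units = "degC") {
  grid <- grid_definition(lat, lon)
  ta <- annual_axis(years)
  vals <- array(NA_real_, dim = c(length(years), length(lat), length(lon)))
  for (t in seq_along(years)) {
    for (i in seq_along(lat)) {
      for (j in seq_along(lon)) {
        vals[t, i, j] <- fn(t, lat[i], lon[j])
      }
    }
  }
  grid_field(grid, variable_id, units, ta, vals)
}

# site_outcomes built from a vector of overall years (NA = never), using a
# single carrier stressor.
make_outcomes <- function(years_vec) {
  years <- data.frame(
    site_id = sprintf("s%03d", seq_along(years_vec)),
    variable_id = rep("dhw", length(years_vec)),
    exceedance_year = as.integer(years_vec),
    stringsAsFactors = FALSE
  )
  site_outcomes(years)
}
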