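# Suitability thresholds for the five analyzed stressors. Comparators give
# the "ideal" side; comparisons are strict (a value at the limit is
# unsuitable). Population density is compared in linear space: density below
# 10^2 persons/km^2 is the log10-density-below-2 criterion.
dhw:
  comparator: lt
  limit: 8          # degC-weeks
arag:
  comparator: gt
  limit: 3.3        # aragonite saturation state
storm:
  comparator: compound_storm
  category: 4       # Saffir-Simpson
  return_years: 5
  rule: conjunction
pop_density:
  comparator: lt
  limit: 100        # persons per km^2 (= log10 density < 2)
  radius_km: 50
land_use:
  comparator: lt
  limit: 0.5        # summed agricultural + urban fraction
  radius_km: 50
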