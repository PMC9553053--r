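# Weekly series whose months have prescribed mean SSTs, for MMM fixtures.
weekly_from_monthly <- function(monthly, years) {
  wk <- 1:52
  do.call(rbind, lapply(years, function(y) {
    data.frame(year = y, week = wk, sst = monthly[month_of_week(wk)])
  }))
}

test_that("MMM is the warmest climatological monthly mean", {
  monthly <- c(26, 26, 27, 28, 28.5, 29, 29, 28.5, 28, 27, 26, 26)
  ws <- weekly_from_monthly(monthly, 2000)
  expect_equal(compute_mmm_climatology(ws, 2000), 29.0)

  const <- weekly_from_monthly(rep(27.3, 12), 1999:2001)
  expect_equal(compute_mmm_climatology(const, 1999:2001), 27.3)

  # two baseline years whose month-wise mean is the list above
  two <- rbind(weekly_from_monthly(monthly + 0.5, 2000),
               weekly_from_monthly(monthly - 0.5, 2001))
  expect_equal(compute_mmm_climatology(two, 2000:2001), 29.0)
  # oracle: brute-force month-wise mean then max
  two$month <- month_of_week(two$week)
  mm <- sapply(split(two, two$month), function(d) {
    mean(tapply(d$sst, d$year, mean))
  })
  expect_equal(compute_mmm_climatology(two, 2000:2001), max(mm))
})

test_that("MMM errors name incomplete months and empty baselines", {
  ws <- weekly_from_monthly(rep(27, 12), 2000)
  ws <- ws[month_of_week(ws$week) != 6, ]
  expect_error(compute_mmm_climatology(ws, 2000), "Jun")
  expect_error(compute_mmm_climatology(ws, 1980), "baseline")
})

test_that("DHW accumulates hotspots over a trailing 12-week window", {
  mmm <- 28
  # sustained +1.5 anomaly reaches 12 x 1.5 = 18 degC-weeks
  sst <- c(rep(mmm, 10), rep(mmm + 1.5, 20))
  dhw <- compute_dhw(sst, mmm)
  expect_equal(max(dhw), 18.0)
  expect_equal(dhw[10 + 12], 18.0)

  # hotspots below the 1 degC floor never accumulate
  expect_true(all(compute_dhw(rep(mmm + 0.9, 60), mmm) == 0))

  # a single +2 week yields DHW 2 in exactly the 12 windows containing it
  one <- rep(mmm, 60); one[20] <- mmm + 2
  dhw <- compute_dhw(one, mmm)
  expect_equal(which(dhw == 2), 20:31)
  expect_true(all(dhw[-(20:31)] == 0))
})

test_that("DHW matches the explicit sliding-window oracle and is monotone in SST", {
  set.seed(31)
  mmm <- 27
  for (r in 1:25) {
    sst <- mmm + rnorm(104, 0, 1.2)
    expect_equal(compute_dhw(sst, mmm), oracle_dhw(sst, mmm))
    bumped <- sst + runif(104, 0, 0.5)
    expect_true(all(compute_dhw(bumped, mmm) >= compute_dhw(sst, mmm)))
    expect_true(all(compute_dhw(sst, mmm) >= 0))
  }
  # missing weeks count as hotspot zero, with a message
  gap <- rep(mmm + 1.5, 24); gap[5] <- NA
  expect_message(dhw <- compute_dhw(gap, mmm), "missing weeks")
  expect_equal(dhw[16], 18 - 1.5)   # window weeks 5-16 lost one hotspot
  expect_equal(max(dhw), 18)        # later windows clear the gap
})

test_that("per-window DHW metric is the within-window maximum", {
  wins <- data.frame(start_year = c(2000, 2005), end_year = c(2004, 2009),
                     label_year = c(2000, 2005))
  dhw <- data.frame(year = rep(2000:2009, each = 2),
                    dhw = rep(c(4, 0, 0, 0, 0, 9, 0, 0, 0, 0), each = 2))
  out <- window_dhw_metric(dhw, wins)
  expect_equal(out$value, c(4, 9))
  empty <- window_dhw_metric(data.frame(year = 2000, dhw = 0),
                             data.frame(start_year = 2010, end_year = 2014,
                                        label_year = 2010))
  expect_true(is.na(empty$value))
})

test_that("storm metric reports worst category and major-storm return period", {
  site <- data.frame(site_id = "s", lat = 10.2, lon = 130.3)
  win <- data.frame(start_year = 2000, end_year = 2004, label_year = 2000)
  # lookback span is 1985-2004

  none <- data.frame(year = 1990, lat = 10.5, lon = 130.5, category = 3)
  m <- storm_metric(none, site, win)
  expect_lte(m$worst_category, 3)
  expect_equal(m$return_period, Inf)

  four <- data.frame(year = c(1986, 1992, 1998, 2003), lat = 10.5,
                     lon = 130.5, category = 4)
  expect_equal(storm_metric(four, site, win)$return_period, 5.0)

  one5 <- data.frame(year = 1995, lat = 10.5, lon = 130.5, category = 5)
  m <- storm_metric(one5, site, win)
  expect_equal(m$worst_category, 5)
  expect_equal(m$return_period, 20.0)

  # events outside the site's one-degree cell are not attributed
  away <- data.frame(year = 1995, lat = 12.5, lon = 130.5, category = 5)
  expect_equal(storm_metric(away, site, win)$worst_category, 0)
  # ... unless an impact radius is requested that reaches them
  m <- storm_metric(away, site, win, impact_radius_km = 500)
  expect_equal(m$worst_category, 5)

  # empty catalogs are valid
  m <- storm_metric(none[0, ], site, win)
  expect_equal(m$worst_category, 0)
  expect_equal(m$return_period, Inf)
})

test_that("storm return period never increases as events are added", {
  set.seed(41)
  site <- data.frame(site_id = "s", lat = 5.4, lon = 110.6)
  wins <- time_windows()
  events <- data.frame(year = sample(1850:2100, 30, replace = TRUE),
                       lat = 5.5, lon = 110.5,
                       category = sample(1:5, 30, replace = TRUE))
  rp_prev <- storm_metric(events[0, ], site, wins)$return_period
  for (k in seq_len(nrow(events))) {
    rp <- storm_metric(events[1:k, , drop = FALSE], site, wins)$return_period
    expect_true(all(rp <= rp_prev))
    rp_prev <- rp
  }
})

test_that("great-circle distances follow the 6371-km sphere", {
  expect_equal(great_circle_km(0, 0, 0, 0), 0)
  expect_equal(great_circle_km(0, 0, 180, 0), pi * 6371, tolerance = 1e-6)
  expect_equal(great_circle_km(0, 0, 1, 0), 2 * pi * 6371 / 360,
               tolerance = 1e-6)
})

test_that("neighborhood population metric is an area-weighted in-radius mean", {
  site <- data.frame(site_id = "s", lat = 0, lon = 0)
  nb <- neighborhood_spec(50)

  uni <- make_field(seq(-2, 2, 0.25), seq(-2, 2, 0.25), 2000,
                    function(t, la, lo) 100, variable_id = "pop_density",
                    units = "persons km-2")
  expect_equal(neighborhood_population_metric(uni, site, nb)$value, 100)

  # population concentrated beyond 50 km contributes nothing
  far <- make_field(seq(-2, 2, 0.25), seq(-2, 2, 0.25), 2000,
                    function(t, la, lo) {
                      if (great_circle_km(0, 0, lo, la) > 50) 5000 else 0
                    }, variable_id = "pop_density", units = "persons km-2")
  expect_equal(neighborhood_population_metric(far, site, nb)$value, 0)

  # two equal-area cells (same latitude) with densities 0 and 200 average
  # 100; the lat-3 row sits ~330 km away, outside the radius
  two <- grid_field(grid_definition(c(0, 3), c(-0.2, 0.2), cell_size = 0.4),
                    "pop_density", "persons km-2", annual_axis(2000),
                    array(c(0, 7777, 200, 8888), dim = c(1, 2, 2)))
  expect_equal(neighborhood_population_metric(two, site, nb)$value, 100)

  # values strictly outside the radius never change the metric
  two$values[1, 2, ] <- -123
  expect_equal(neighborhood_population_metric(two, site, nb)$value, 100)

  tiny <- make_field(c(30), c(30), 2000, function(t, la, lo) 1,
                     variable_id = "pop_density", units = "persons km-2")
  expect_error(neighborhood_population_metric(tiny, site, nb), "radius")
})

test_that("neighborhood land-use metric sums fractions over land cells only", {
  site <- data.frame(site_id = "s", lat = 0, lon = 0)
  nb <- neighborhood_spec(50)
  g <- grid_definition(seq(-1, 1, 0.25), seq(-1, 1, 0.25), cell_size = 0.25)
  ones <- function(v) {
    grid_field(g, "land_use_fraction", "fraction", annual_axis(2000),
               array(v, dim = c(1, 9, 9)))
  }
  all_land <- matrix(TRUE, 9, 9)
  m <- neighborhood_landuse_metric(ones(0.3), ones(0.25), all_land, site, nb)
  expect_equal(m$value, 0.55)

  # fully natural cover
  m <- neighborhood_landuse_metric(ones(0), ones(0), all_land, site, nb)
  expect_equal(m$value, 0)

  # half the in-radius land fully converted, half untouched; the two land
  # cells sit on the same latitude so their area weights are equal
  ag <- ones(0)
  row0 <- which(g$lat == 0)
  mask <- matrix(FALSE, 9, 9)
  mask[row0, c(4, 6)] <- TRUE   # lon -0.25 and +0.25 deg, ~28 km from site
  ag$values[1, row0, 6] <- 1
  m <- neighborhood_landuse_metric(ag, ones(0), mask, site, nb)
  expect_equal(m$value, 0.5)

  # open-ocean neighborhood: metric 0 with a message
  no_land <- matrix(FALSE, 9, 9)
  expect_message(
    m <- neighborhood_landuse_metric(ones(0.4), ones(0.4), no_land, site, nb),
    "open ocean"
  )
  expect_equal(m$value, 0)
})
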