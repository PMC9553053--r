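test_that("bilinear regridding is exact for constant and linear fields", {
  src_lat <- seq(-4.5, 4.5, 1)
  src_lon <- seq(100.5, 109.5, 1)
  tgt <- grid_definition(seq(-2.25, 2.75, 0.5), seq(102.25, 107.25, 0.5),
                         cell_size = 0.5)

  const <- make_field(src_lat, src_lon, 2000, function(t, la, lo) 3.14)
  out <- regrid_bilinear(const, tgt)
  expect_true(all(abs(out$values - 3.14) < 1e-12))

  ramp <- make_field(src_lat, src_lon, 2000:2001, function(t, la, lo) lo)
  out <- regrid_bilinear(ramp, tgt)
  for (t in 1:2) {
    expect_equal(out$values[t, 1, ], tgt$lon, tolerance = 1e-12)
  }
})

test_that("the center of a 2x2 cell block is the mean of the four corners", {
  f <- make_field(c(0.5, 1.5), c(10.5, 11.5), 2000,
                  function(t, la, lo) 0)
  f$values[1, 2, 2] <- 4
  tgt <- grid_definition(1, 11, cell_size = 1)
  out <- regrid_bilinear(f, tgt)
  expect_equal(out$values[1, 1, 1], 1.0)
})

test_that("bilinear output stays within the envelope of its four neighbors", {
  set.seed(21)
  f <- make_field(seq(-9.5, 9.5, 1), seq(-19.5, 19.5, 1), 2000:2002,
                  function(t, la, lo) rnorm(1))
  tgt_lat <- runif(25, -9.5, 9.5)
  tgt_lon <- runif(25, -19.5, 19.5)
  for (k in 1:25) {
    tgt <- grid_definition(tgt_lat[k], tgt_lon[k], cell_size = 1)
    out <- regrid_bilinear(f, tgt)
    i <- findInterval(tgt_lat[k], f$grid$lat)
    j <- findInterval(tgt_lon[k], f$grid$lon)
    for (t in 1:3) {
      nb <- f$values[t, i:(i + 1), j:(j + 1)]
      expect_gte(out$values[t, 1, 1], min(nb) - 1e-12)
      expect_lte(out$values[t, 1, 1], max(nb) + 1e-12)
    }
  }
})

test_that("missing source neighbors propagate and disjoint domains error", {
  f <- make_field(c(0.5, 1.5), c(10.5, 11.5), 2000, function(t, la, lo) 1)
  f$values[1, 1, 1] <- NA
  tgt <- grid_definition(1, 11, cell_size = 1)
  expect_true(is.na(regrid_bilinear(f, tgt)$values[1, 1, 1]))

  far <- grid_definition(50.5, 11, cell_size = 1)
  expect_error(regrid_bilinear(f, far), "outside the source domain")
})

test_that("longitude wraps across the dateline for global grids", {
  lon <- seq(-179.5, 179.5, 1)
  f <- make_field(c(-0.5, 0.5), lon, 2000,
                  function(t, la, lo) sin(lo * pi / 180))
  tgt <- grid_definition(0, 179.75, cell_size = 0.5)
  out <- regrid_bilinear(f, tgt)
  # 179.75 sits a quarter of the way from the center at 179.5 to the one at
  # -179.5 (= 180.5) across the seam
  expect_equal(out$values[1, 1, 1],
               0.75 * sin(179.5 * pi / 180) + 0.25 * sin(-179.5 * pi / 180),
               tolerance = 1e-12)
})

test_that("window averaging matches hand-computed means", {
  f5 <- make_field(0.5, 10.5, 2005:2009, function(t, la, lo) t)
  out <- average_windows(f5)
  expect_equal(nrow(out$time_axis), 1)
  expect_equal(out$time_axis$label_year, 2005)
  expect_equal(out$values[1, 1, 1], 3.0)

  # annual series equal to the year: first window mean is 1852
  fy <- make_field(0.5, 10.5, 1850:2100, function(t, la, lo) 1849 + t)
  out <- average_windows(fy)
  expect_equal(out$values[1, 1, 1], 1852.0)
  expect_equal(nrow(out$time_axis), 50)
  # last window folds 2100 in: mean of 2095..2100
  expect_equal(out$values[50, 1, 1], mean(2095:2100))

  # constant monthly series: every window equals the constant
  ta <- data.frame(start_year = rep(2000:2004, each = 12),
                   end_year = rep(2000:2004, each = 12),
                   label_year = rep(2000:2004, each = 12))
  g <- grid_definition(0.5, 10.5)
  fm <- grid_field(g, "sst", "degC", ta, array(7.25, dim = c(60, 1, 1)))
  out <- average_windows(fm)
  expect_true(all(out$values == 7.25))
})

test_that("window averaging assigns decadal steps to every window they span", {
  g <- grid_definition(0.5, 10.5)
  ta <- data.frame(start_year = c(2000, 2010), end_year = c(2009, 2019),
                   label_year = c(2000, 2010))
  f <- grid_field(g, "sst", "degC", ta, array(c(1, 3), dim = c(2, 1, 1)))
  out <- average_windows(f)
  expect_equal(out$time_axis$label_year, c(2000, 2005, 2010, 2015))
  expect_equal(as.numeric(out$values), c(1, 1, 3, 3))
})

test_that("window averaging is idempotent and flags empty windows", {
  fy <- make_field(c(0.5, 1.5), 10.5, 1990:2019,
                   function(t, la, lo) rnorm(1))
  once <- average_windows(fy)
  expect_warning(twice <- average_windows(once), NA)
  expect_equal(twice$values, once$values)
  expect_equal(twice$time_axis, once$time_axis)

  gap <- make_field(0.5, 10.5, c(2000:2004, 2015:2019),
                    function(t, la, lo) 1)
  expect_warning(out <- average_windows(gap), "2005, 2010")
  expect_true(all(is.na(out$values[2:3, 1, 1])))
  expect_equal(out$values[c(1, 4), 1, 1], c(1, 1))
})

test_that("sampling at sites uses nearest cell centers and keeps missing values", {
  f <- make_field(c(0.5, 1.5), c(0.5, 1.5), 2000:2001,
                  function(t, la, lo) la * 10 + lo + t / 10)
  f$values[2, 1, 1] <- NA
  sites <- data.frame(site_id = c("a", "b", "c"),
                      lat = c(0.4, 0.45, 1.3), lon = c(0.4, 0.42, 1.4),
                      reef_class = "coral", stringsAsFactors = FALSE)
  tab <- sample_at_sites(f, sites)
  expect_equal(nrow(tab), 6)
  # a and b share the (0.5, 0.5) cell: identical series including the gap
  expect_equal(tab$value[tab$site_id == "a"], tab$value[tab$site_id == "b"])
  expect_true(is.na(tab$value[tab$site_id == "a" & tab$label_year == 2001]))
  expect_equal(tab$value[tab$site_id == "c" & tab$label_year == 2000],
               1.5 * 10 + 1.5 + 0.1)

  # permutation invariance in site order
  perm <- sample_at_sites(f, sites[c(3, 1, 2), ])
  a <- tab[order(tab$site_id, tab$label_year), ]
  b <- perm[order(perm$site_id, perm$label_year), ]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)

  out <- data.frame(site_id = "x", lat = 40, lon = 0.5, reef_class = "coral")
  expect_error(sample_at_sites(f, out), "x")
})

test_that("reef polygons rasterize to one site per occupied 1-km cell", {
  # rectangle spanning [0.1, 2.1] km in projected space: exactly the four
  # cell centers (0.5, 0.5), (0.5, 1.5), (1.5, 0.5), (1.5, 1.5) fall inside
  corners_xy <- rbind(c(0.1, 0.1), c(2.1, 0.1), c(2.1, 2.1), c(0.1, 2.1),
                      c(0.1, 0.1))
  corners_ll <- behrmann_lonlat(corners_xy[, 1], corners_xy[, 2])
  sites <- rasterize_reef_polygons(list(corners_ll))
  expect_equal(nrow(sites), 4)
  got_xy <- behrmann_xy(sites$lon, sites$lat)
  expect_equal(sort(round(got_xy[, 1], 9)), c(0.5, 0.5, 1.5, 1.5))
  expect_equal(sort(round(got_xy[, 2], 9)), c(0.5, 0.5, 1.5, 1.5))

  # a sub-km^2 polygon containing a single center
  tiny_xy <- rbind(c(0.4, 0.4), c(0.6, 0.4), c(0.6, 0.6), c(0.4, 0.6),
                   c(0.4, 0.4))
  tiny_ll <- behrmann_lonlat(tiny_xy[, 1], tiny_xy[, 2])
  expect_equal(nrow(rasterize_reef_polygons(list(tiny_ll))), 1)

  # two overlapping polygons collapse shared cells
  both <- rasterize_reef_polygons(list(corners_ll, tiny_ll))
  expect_equal(nrow(both), 4)

  expect_error(rasterize_reef_polygons(list()), "empty geometry")
})

test_that("GeoJSON polygons load as lon/lat rings", {
  path <- withr::local_tempfile(fileext = ".geojson")
  writeLines('{"type":"FeatureCollection","features":[{"type":"Feature",
    "properties":{},"geometry":{"type":"Polygon","coordinates":
    [[[100.0,0.0],[100.1,0.0],[100.1,0.1],[100.0,0.1],[100.0,0.0]]]}}]}',
    path)
  rings <- read_geojson_polygons(path)
  expect_length(rings, 1)
  expect_equal(dim(rings[[1]]), c(5, 2))
  expect_equal(rings[[1]][1, ], c(lon = 100, lat = 0))
})
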