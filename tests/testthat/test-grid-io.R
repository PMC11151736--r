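test_that("ESRI ASCII grids round-trip through write/read", {
  # integer grid: exact; seeded real grid: to full precision
  g_int <- raster_grid(matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE),
                       cell_size = 5)
  p <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(g_int, p)
  back <- read_ascii_grid(p)
  expect_identical(back$values, g_int$values)
  expect_equal(back$cell_size, 5)
  expect_equal(back$values[1, 1], 1)

  set.seed(101)
  g_real <- raster_grid(matrix(rnorm(30) * 1e-4, 5, 6),
                        xll = 1200.5, yll = -40, cell_size = 5)
  write_ascii_grid(g_real, p)
  back <- read_ascii_grid(p)
  expect_equal(back$values, g_real$values, tolerance = 1e-12)
  expect_equal(back$xll, 1200.5)
  expect_equal(back$yll, -40)
})

test_that("nodata cells are excluded from arithmetic and written verbatim", {
  m <- matrix(c(1, 2, 3, 4, NA, 6, 7, 8, 9), 3, 3, byrow = TRUE)
  g <- raster_grid(m, nodata_value = -9999)
  expect_equal(grid_sum(g), 40)    # 45 minus the masked 5
  p <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(g, p)
  expect_match(paste(readLines(p), collapse = "\n"), "-9999")
  back <- read_ascii_grid(p)
  expect_true(is.na(back$values[2, 2]))
  expect_equal(grid_sum(back), 40)
})

test_that("malformed ESRI ASCII input fails with a pointed error", {
  p <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows two", "xllcorner 0", "yllcorner 0",
               "cellsize 5", "1 2", "3 4"), p)
  expect_error(read_ascii_grid(p), "header line 2")
  writeLines(c("ncols 2", "nrows 3", "xllcorner 0", "yllcorner 0",
               "cellsize 5", "1 2", "3 4"), p)
  expect_error(read_ascii_grid(p), "expected 3 data rows")
  writeLines(c("ncols 3", "nrows 2", "xllcorner 0", "yllcorner 0",
               "cellsize 5", "1 2 3", "4 5"), p)
  expect_error(read_ascii_grid(p), "row 2 has 2 values")
  expect_error(read_ascii_grid(tempfile()), "no such file")
})

test_that("header keys are case-insensitive and NODATA_value accepted", {
  p <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("NCOLS 2", "NROWS 2", "XLLCORNER 10", "YLLCORNER 20",
               "CELLSIZE 5", "NODATA_value -1", "1 -1", "3 4"), p)
  g <- read_ascii_grid(p)
  expect_true(is.na(g$values[1, 2]))
  expect_equal(g$nodata_value, -1)
  expect_equal(g$xll, 10)
})

test_that("weather CSV reader enforces series invariants", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("date,precip_mm,tavg_c", "2020-01-01,0,5",
               "2020-01-02,10,6", "2020-01-03,0,7"), p)
  w <- read_weather_csv(p)
  expect_s3_class(w, "weather_series")
  expect_equal(nrow(w), 3)
  expect_equal(w$precip_mm, c(0, 10, 0))

  writeLines(c("date,precip_mm,tavg_c", "2020-01-01,0,5",
               "2020-01-01,1,5"), p)
  expect_error(read_weather_csv(p), "duplicate date")
  writeLines(c("date,precip_mm,tavg_c", "2020-01-01,0,5",
               "2020-01-03,1,5"), p)
  expect_error(read_weather_csv(p), "2020-01-02")
  writeLines(c("date,precip_mm,tavg_c", "2020-01-01,-2,5"), p)
  expect_error(read_weather_csv(p), "non-negative")
})

test_that("a synthetic leap-year weather file has 366 rows", {
  p <- withr::local_tempfile(fileext = ".csv")
  write_weather_csv(make_weather(synth_spec(seed = 3), 2020), p)
  expect_equal(nrow(read_weather_csv(p)), 366)
})

test_that("config defaults carry the published parameter values", {
  cfg <- default_config()
  expect_equal(cfg$deposition$trwp, 100)
  expect_equal(cfg$deposition$cell_resolution, 5)
  expect_equal(cfg$deposition$tc_fraction, 0.02)
  expect_equal(cfg$deposition$cc_fraction, 0.38)
  expect_equal(cfg$deposition$alpha, 1.0)
  expect_equal(cfg$contaminant$koc, 11000)
  expect_equal(cfg$contaminant$molar_solubility, 0.000158)
  expect_equal(cfg$contaminant$molar_mass, 268.404)
  expect_equal(cfg$contaminant$k_max, 0.2207475)
  expect_equal(cfg$contaminant$log_kow, 2.745)
  expect_equal(cfg$lc50_threshold, 95)
  expect_equal(solubility_g_per_l(cfg$contaminant), 0.000158 * 268.404)
})

test_that("config loading merges overrides onto defaults and validates", {
  p <- withr::local_tempfile(fileext = ".json")
  writeLines('{"deposition": {"trwp": 200}}', p)
  cfg <- load_config(p)
  expect_equal(cfg$deposition$trwp, 200)
  expect_equal(cfg$deposition$cc_fraction, 0.38)   # untouched default

  writeLines('{"deposition": {"tc_fraction": 1.5}}', p)
  expect_error(load_config(p), "tc_fraction.*\\[0, 1\\]")
  writeLines('{"hydrology": {"field_capacity": 0.5, "porosity": 0.4}}', p)
  expect_error(load_config(p), "field_capacity")
  writeLines('{"lc50_threshold": -1}', p)
  expect_error(load_config(p), "lc50_threshold")
  writeLines('{"contaminant": {"direct_koc": false}}', p)
  expect_error(load_config(p), "not implemented")
})

test_that("config round-trips through write_config/load_config", {
  cfg <- default_config()
  cfg$deposition$trwp <- 123.456
  cfg$hydrology$foc_by_layer <- c(0.04, 0.02, 0.01, 0.003)
  p <- withr::local_tempfile(fileext = ".json")
  write_config(cfg, p)
  back <- load_config(p)
  expect_equal(unclass(back), unclass(validate_config(cfg)),
               tolerance = 1e-12)
})
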