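test_that("the synthetic DEM is pit-free with a single terminal at the outlet", {
  sp <- synth_spec(n_rows = 20, n_cols = 20, road_spacing = 5,
                   inlet_spacing = 5, seed = 11)
  dem <- make_dem(sp)
  expect_equal(fill_pits(dem)$values, dem$values)
  fl <- compute_d8(dem)
  term <- which(fl$direction == 0L & !is.na(fl$elev))
  expect_length(term, 1)
  expect_equal(term, rc_to_idx_test(20, sp$axis_col, 20))
  expect_error(synth_spec(slope_along = 0), "> 0")
})

test_that("land cover and traffic have the declared structure", {
  sp <- synth_spec(n_rows = 20, n_cols = 20, road_spacing = 5,
                   inlet_spacing = 5, seed = 11)
  lt <- make_landcover_and_traffic(sp, make_dem(sp))
  lc <- lt$land_cover$values
  # street rows at 5, 10, 15; stream column carved through them
  expect_equal(sort(unique(which(apply(lc == 1, 1, any)))), c(5, 10, 15))
  expect_true(all(lc[, sp$axis_col] == 5))
  # traffic defined exactly on road cells, within range, extremes present
  tr <- lt$traffic$values
  expect_equal(!is.na(tr), lc == 1)
  expect_true(all(tr[!is.na(tr)] >= 100 & tr[!is.na(tr)] <= 5000))
  expect_equal(max(tr, na.rm = TRUE), 5000)
  expect_equal(min(tr, na.rm = TRUE), 100)

  # determinism: the same seed reproduces the same grids
  lt2 <- make_landcover_and_traffic(sp, make_dem(sp))
  expect_identical(lt$land_cover$values, lt2$land_cover$values)
  expect_identical(lt$traffic$values, lt2$traffic$values)
})

test_that("the generated network passes validation on every seed tried", {
  for (seed in c(1, 2, 3)) {
    sp <- synth_spec(n_rows = 30, n_cols = 30, road_spacing = 6,
                     inlet_spacing = 4, seed = seed)
    ws <- make_watershed(sp)
    rep <- validate_network(ws$network, ws)
    expect_gt(rep$n_inlets, 0)
    expect_equal(rep$n_ms4 + rep$n_css, rep$n_inlets)
    # all MS4 outfalls land inside the delineation by construction
    expect_equal(rep$n_outfalls_non_contributing, 0)
    # inlets sit on road cells
    on_road <- ws$land_cover$values[cbind(ws$network$inlet_row,
                                          ws$network$inlet_col)] == 1
    expect_true(all(on_road))
  }
})

test_that("css_fraction extremes force the advertised routing", {
  sp0 <- synth_spec(n_rows = 30, n_cols = 30, road_spacing = 6,
                    inlet_spacing = 4, css_fraction = 0, seed = 4)
  expect_true(all(make_network(sp0,
    make_landcover_and_traffic(sp0, make_dem(sp0))$land_cover
  )$system_type == "MS4"))

  sp1 <- synth_spec(n_rows = 30, n_cols = 30, road_spacing = 6,
                    inlet_spacing = 4, css_fraction = 1, seed = 4)
  ws1 <- make_watershed(sp1)
  expect_true(all(ws1$network$system_type == "CSS"))
  # every masked street drains to the WWTP: a storm exports mass there only
  w <- constant_weather(10, precip = c(0, 0, 0, 20, rep(0, 6)))
  run1 <- run_simulation(ws1, w)
  expect_gt(run1$ledger$wwtp_export, 0)
  expect_equal(run1$ledger$stream_export, 0)

  # and with no CSS links the WWTP never sees mass or water
  ws0 <- make_watershed(sp0)
  run0 <- run_simulation(ws0, w)
  expect_equal(run0$ledger$wwtp_export, 0)
  expect_equal(sum(run0$series$wwtp_m3), 0)
})

test_that("the weather generator honors seasonality, seed and degeneracy", {
  sp <- synth_spec(seed = 33)
  w <- make_weather(sp, 2020)
  expect_equal(nrow(w), 366)
  dry_total <- sum(w$precip_mm[is_dry_season(w$date)])
  expect_lt(dry_total, 0.1 * sum(w$precip_mm))
  # summer warmer than winter
  expect_gt(mean(w$tavg_c[is_dry_season(w$date)]),
            mean(w$tavg_c[!is_dry_season(w$date)]))
  expect_identical(make_weather(sp, 2020), w)

  calm <- synth_spec(p_wet = 0, p_dry = 0, seed = 33)
  expect_true(all(make_weather(calm, 2021)$precip_mm == 0))
})

test_that("a written bundle reloads into an equivalent watershed", {
  sp <- synth_spec(n_rows = 24, n_cols = 24, road_spacing = 6,
                   inlet_spacing = 6, seed = 13)
  dir <- withr::local_tempdir()
  write_synth_bundle(sp, dir, year = 2021)
  expect_true(all(file.exists(file.path(dir,
    c("dem.asc", "land_cover.asc", "traffic.asc", "network.csv",
      "weather.csv", "config.json")))))
  ws_mem <- make_watershed(sp)
  dem <- read_ascii_grid(file.path(dir, "dem.asc"))
  lc <- read_ascii_grid(file.path(dir, "land_cover.asc"))
  ws_file <- watershed(dem, lc, read_ascii_grid(file.path(dir, "traffic.asc")),
                       read_network_csv(file.path(dir, "network.csv")),
                       pour_point = find_pour_point(dem, lc))
  expect_equal(ws_file$in_watershed, ws_mem$in_watershed)
  expect_equal(ws_file$depo_mask, ws_mem$depo_mask)
  expect_equal(ws_file$traffic$values, ws_mem$traffic$values,
               tolerance = 1e-12)
})
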