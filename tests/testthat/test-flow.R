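test_that("fill_pits raises a depression to its spill level and is idempotent", {
  plane <- south_plane(4, 4)
  expect_equal(fill_pits(plane)$values, plane$values)   # no pits to fill

  # 3x3 with the centre 1 m below all neighbors: raised to the lowest
  # neighbor level plus epsilon (spill through that neighbor)
  m <- matrix(5, 3, 3)
  m[2, 2] <- 4
  m[3, 2] <- 4.5   # lowest rim cell
  g <- raster_grid(m)
  f <- fill_pits(g)
  expect_equal(f$values[2, 2], 4.5 + 1e-6, tolerance = 1e-12)
  expect_true(all(f$values >= g$values))
  expect_equal(fill_pits(f)$values, f$values)

  expect_error(fill_pits(raster_grid(matrix(NA_real_, 2, 2))), "all nodata")
})

test_that("D8 directions follow steepest descent with the fixed tie order", {
  # plane tilted due south: every non-terminal cell points S
  fl <- compute_d8(south_plane(5, 4))
  dirs <- matrix(fl$direction, 5, 4)
  expect_true(all(dirs[1:4, ] == 3L))   # 3 = S in the E,SE,S,... order
  expect_true(all(dirs[5, ] == 0L))     # bottom row: terminals

  # equal drop to S and SE: S wins (its gradient is steeper because the
  # diagonal distance is longer)
  z <- matrix(c(9, 9, 9,
                9, 4, 9,
                9, 3, 3), 3, 3, byrow = TRUE)
  fl2 <- compute_d8(raster_grid(z))
  expect_equal(matrix(fl2$direction, 3, 3)[2, 2], 3L)

  # unfilled interior pit errors
  pit <- matrix(5, 3, 3); pit[2, 2] <- 1
  expect_error(compute_d8(raster_grid(pit)), "unfilled pit")
})

test_that("V-shaped valley routes hillslopes to the axis and axis south", {
  sp <- synth_spec(n_rows = 5, n_cols = 5, road_spacing = 2,
                   inlet_spacing = 2, seed = 1)
  fl <- compute_d8(make_dem(sp))
  dirs <- matrix(fl$direction, 5, 5)
  ax <- sp$axis_col
  expect_true(all(dirs[1:4, ax] == 3L))              # axis drains south
  expect_true(all(dirs[, ax - 1] %in% c(1L, 0L)))    # west bank points E
  expect_true(all(dirs[, ax + 1] %in% c(5L, 0L)))    # east bank points W
  # single terminal: the pour point at the south end of the axis
  expect_equal(which(fl$direction == 0L & !is.na(fl$elev)),
               (ax - 1L) * 5L + 5L)
})

test_that("topological order visits every cell before its successor", {
  for (seed in 1:3) {
    sp <- synth_spec(n_rows = 12, n_cols = 12, road_spacing = 3,
                     inlet_spacing = 3, seed = seed)
    fl <- compute_d8(fill_pits(make_dem(sp)))
    pos <- integer(length(fl$downstream))
    pos[fl$order] <- seq_along(fl$order)
    ok <- is.na(fl$downstream) | pos < pos[fl$downstream]
    expect_true(all(ok[!is.na(fl$elev)]))
  }
})

test_that("delineation follows D8 chains and pipe links", {
  # single-outlet tilted column: every cell drains to the pour point
  ws <- column_watershed(6)
  expect_true(all(ws$in_watershed))

  # two parallel valleys: pour point in valley A excludes valley B
  z <- cbind(seq(6, 1), seq(6, 1) + 10, seq(6, 1))  # cols 1,3 low; col 2 ridge
  dem <- raster_grid(z)
  fl <- compute_d8(dem)
  mask <- delineate(fl, c(6, 1))
  expect_true(all(mask[, 1]))
  expect_false(any(mask[, 3]))

  # a pipe from an inlet in valley B to valley A pulls B's catchment in
  net <- storm_network(3, 3, 4, 1, "MS4")
  mask2 <- delineate(fl, c(6, 1), net)
  expect_true(all(mask2[1:3, 3]))     # cells chaining into the inlet
  expect_false(any(mask2[4:6, 3]))    # below the inlet stays out
})

test_that("inlet-chained road mask follows the unbroken-chain rule", {
  # straight 5-cell road draining into an inlet at its foot: all 5 masked
  fl <- compute_d8(south_plane(7, 3))
  lc <- matrix(LC_PERV_CODE, 7, 3)
  lc[1:5, 2] <- LC_ROAD_CODE
  net <- storm_network(5, 2, 7, 2, "MS4")
  m <- upslope_of_inlet_mask(fl, raster_grid(lc), net)
  expect_equal(which(m), which(col(lc) == 2 & row(lc) <= 5))

  # identical road, no inlet anywhere: empty mask
  m0 <- upslope_of_inlet_mask(fl, raster_grid(lc), storm_network())
  expect_false(any(m0))

  # chain interrupted by one pervious cell above the inlet: upper cells out
  lc_gap <- lc
  lc_gap[3, 2] <- LC_PERV_CODE
  mg <- upslope_of_inlet_mask(fl, raster_grid(lc_gap), net)
  expect_true(all(mg[4:5, 2]))
  expect_false(any(mg[1:3, 2]))

  # parking lots and roofs are never masked even when chained
  lc_park <- lc
  lc_park[1:5, 2] <- LC_IMPERV_CODE
  expect_false(any(upslope_of_inlet_mask(fl, raster_grid(lc_park), net)))
})

test_that("validate_network reports counts and rejects bad networks", {
  sp <- synth_spec(n_rows = 30, n_cols = 30, road_spacing = 6,
                   inlet_spacing = 6, css_fraction = 0, seed = 5)
  ws <- make_watershed(sp)
  rep <- validate_network(ws$network, ws)
  expect_equal(rep$n_inlets, nrow(ws$network))
  expect_equal(rep$n_ms4 + rep$n_css, rep$n_inlets)
  expect_equal(rep$n_outfalls_contributing +
               rep$n_outfalls_non_contributing, rep$n_ms4)
  expect_equal(rep$n_outfalls_non_contributing, 0)

  dup <- storm_network(c(2, 2), c(3, 3), c(5, 6), c(3, 3), c("MS4", "MS4"))
  expect_error(validate_network(dup, ws), "duplicate inlet")
  off <- storm_network(2, 3, 500, 3, "MS4")
  expect_error(validate_network(off, ws), "off grid")
})

test_that("an outfall downstream of the pour point is flagged non-contributing", {
  # pour point mid-column: an MS4 outfall below it cannot contribute
  dem <- raster_grid(matrix(seq(8, 1), ncol = 1), cell_size = 5)
  lc <- raster_grid(matrix(c(rep(LC_ROAD_CODE, 7), LC_STREAM_CODE), ncol = 1))
  tr <- raster_grid(matrix(NA_real_, 8, 1))
  net <- storm_network(2, 1, 7, 1, "MS4")
  ws <- watershed(dem, lc, tr, net, pour_point = c(5, 1))
  rep <- validate_network(net, ws)
  expect_equal(rep$n_outfalls_non_contributing, 1)
  expect_equal(rep$non_contributing, 1L)
})
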