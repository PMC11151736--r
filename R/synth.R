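# Seeded synthetic watersheds: a V-shaped valley draining south to a single
# pour point, grid-pattern street rows chained into storm-drain inlets,
# MS4 outfalls at riparian or channel cells, an optional CSS share to the
# WWTP, and a wet/dry-season daily weather generator. Every structural
# feature the simulator assumes is present by construction, so all modules
# are testable without external GIS data.

#' Specification for a synthetic watershed
#'
#' Defaults describe the standard "demo-year" fixture: 100 x 100 cells at
#' 5 m (0.25 km2), street rows every 10 rows (the northernmost street
#' deliberately lacks inlets, exercising the deposition-mask rule), inlets
#' every 10 street cells, one max-traffic arterial row, a 20% CSS share,
#' and Pacific-Northwest seasonality (wet October-May, dry June-September).
#'
#' @param n_rows,n_cols grid size.
#' @param cell_size cell edge, m.
#' @param slope_along,slope_cross down-valley and cross-valley slopes (m/m,
#'   > 0). `slope_cross` must exceed `slope_along / (sqrt(2) - 1)` times
#'   nothing in particular; the defaults keep hillslope flow perpendicular
#'   to the valley so street rows align with D8 chains.
#' @param road_spacing street row interval, cells.
#' @param inlet_spacing inlet interval along a street, cells.
#' @param traffic_range `c(min, max)` vehicles/day on streets.
#' @param css_fraction share of inlets routed to the WWTP (CSS).
#' @param riparian_fraction share of MS4 outfalls delivering to a riparian
#'   pervious cell (the rest discharge directly to the channel).
#' @param roof_fraction,parking_fraction cover fractions for roofs and
#'   parking lots on non-street cells.
#' @param p_wet,p_dry daily storm probability by season.
#' @param rain_wet_mm,rain_dry_mm mean storm depth by season, mm.
#' @param temp_mean_c,temp_amp_c,temp_noise_sd_c temperature sinusoid
#'   (peaking August 1) and daily noise.
#' @param seed integer seed; all generator randomness derives from it.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(n_rows = 100, n_cols = 100, cell_size = 5,
                       slope_along = 0.01, slope_cross = 0.05,
                       road_spacing = 10, inlet_spacing = 10,
                       traffic_range = c(100, 5000),
                       css_fraction = 0.2, riparian_fraction = 0.5,
                       roof_fraction = 0.15, parking_fraction = 0.03,
                       p_wet = 0.45, p_dry = 0.01,
                       rain_wet_mm = 8, rain_dry_mm = 2,
                       temp_mean_c = 11, temp_amp_c = 7.5,
                       temp_noise_sd_c = 1.5, seed = 42L) {
  if (slope_along <= 0 || slope_cross <= 0)
    stop("slopes must be > 0", call. = FALSE)
  if (road_spacing < 2 || inlet_spacing < 1)
    stop("road_spacing must be >= 2 and inlet_spacing >= 1", call. = FALSE)
  if (any(c(css_fraction, riparian_fraction, p_wet, p_dry,
            roof_fraction, parking_fraction) < 0) ||
      any(c(css_fraction, riparian_fraction, p_wet, p_dry,
            roof_fraction, parking_fraction) > 1))
    stop("fractions and probabilities must lie in [0, 1]", call. = FALSE)
  if (traffic_range[2] < traffic_range[1])
    stop("traffic_range must be (min, max)", call. = FALSE)
  spec <- as.list(environment())
  spec$axis_col <- n_cols %/% 2L
  class(spec) <- c("synth_spec", "list")
  spec
}

#' Generate the synthetic valley DEM
#'
#' Elevation rises linearly up-valley (northward) and away from the central
#' stream axis, forming a V-shaped valley whose only flow terminal is the
#' pour point at the south end of the axis. Pit-free by construction.
#'
#' @param spec a [synth_spec()].
#' @return A [raster_grid()] of elevations (m).
#' @export
make_dem <- function(spec) {
  r <- matrix(seq_len(spec$n_rows), spec$n_rows, spec$n_cols)
  cc <- matrix(seq_len(spec$n_cols), spec$n_rows, spec$n_cols, byrow = TRUE)
  z <- (spec$n_rows - r) * spec$cell_size * spec$slope_along +
    abs(cc - spec$axis_col) * spec$cell_size * spec$slope_cross
  raster_grid(z, cell_size = spec$cell_size)
}

synth_road_rows <- function(spec) {
  seq(spec$road_spacing, spec$n_rows - 2L, by = spec$road_spacing)
}

#' Generate land cover and traffic for a synthetic watershed
#'
#' Street rows every `road_spacing` rows (interrupted by the stream
#' column), the valley axis coded stream, roofs and parking lots scattered
#' on remaining cells, everything else pervious. Traffic counts are drawn
#' uniformly from `traffic_range` per street cell; one arterial street row
#' (the middle one) carries the maximum count, and the northernmost street
#' carries the minimum at its west end.
#'
#' @param spec a [synth_spec()].
#' @param dem the DEM from [make_dem()] (shape reference).
#' @return list: `land_cover` ([raster_grid()] of codes), `traffic`
#'   ([raster_grid()], `NA` off-road).
#' @export
make_landcover_and_traffic <- function(spec, dem) {
  set.seed(spec$seed + 1L)
  nr <- spec$n_rows; nc <- spec$n_cols
  lc <- matrix(LC_PERVIOUS, nr, nc)
  rr <- synth_road_rows(spec)
  lc[rr, ] <- LC_ROAD
  lc[, spec$axis_col] <- LC_STREAM
  off_road <- which(lc == LC_PERVIOUS)
  n_roof <- round(spec$roof_fraction * length(off_road))
  if (n_roof) lc[sample(off_road, n_roof)] <- LC_ROOF
  off_road <- which(lc == LC_PERVIOUS)
  n_park <- round(spec$parking_fraction * length(off_road))
  if (n_park) lc[sample(off_road, n_park)] <- LC_IMPERV
  traffic <- matrix(NA_real_, nr, nc)
  road_cells <- which(lc == LC_ROAD)
  traffic[road_cells] <- stats::runif(length(road_cells),
                                      spec$traffic_range[1],
                                      spec$traffic_range[2])
  arterial <- rr[ceiling(length(rr) / 2)]
  traffic[arterial, lc[arterial, ] == LC_ROAD] <- spec$traffic_range[2]
  first_road_col <- which(lc[rr[1], ] == LC_ROAD)[1]
  traffic[rr[1], first_road_col] <- spec$traffic_range[1]
  list(land_cover = raster_grid(lc, cell_size = spec$cell_size),
       traffic = raster_grid(traffic, cell_size = spec$cell_size))
}

#' Generate the synthetic storm-sewer network
#'
#' Places inlets along every street row except the northernmost (left
#' inlet-free so that its street cells are excluded from the deposition
#' mask): one inlet on each street cell adjacent to the stream and further
#' inlets every `inlet_spacing` cells outward. A seeded share of inlets is
#' CSS (to the WWTP); MS4 inlets deliver either to a riparian pervious cell
#' one row south of the street beside the channel, or directly to the
#' channel cell of their street row.
#'
#' @param spec a [synth_spec()].
#' @param land_cover from [make_landcover_and_traffic()].
#' @param flow the `flow_field` (accepted for interface symmetry; inlet
#'   placement is purely geometric).
#' @return A `storm_network`.
#' @export
make_network <- function(spec, land_cover, flow = NULL) {
  set.seed(spec$seed + 2L)
  rr <- synth_road_rows(spec)
  inlet_rows <- rr[-1]
  ax <- spec$axis_col
  ir <- integer(0); ic <- integer(0)
  for (r in inlet_rows) {
    west <- seq(ax - 1L, 2L, by = -spec$inlet_spacing)
    east <- seq(ax + 1L, spec$n_cols - 1L, by = spec$inlet_spacing)
    cols <- c(west, east)
    cols <- cols[land_cover$values[cbind(r, cols)] == LC_ROAD]
    ir <- c(ir, rep(r, length(cols))); ic <- c(ic, cols)
  }
  n <- length(ir)
  css <- stats::runif(n) < spec$css_fraction
  riparian <- stats::runif(n) < spec$riparian_fraction
  dest_r <- ifelse(riparian, ir + 1L, ir)
  dest_c <- ifelse(riparian, ifelse(ic < ax, ax - 1L, ax + 1L), ax)
  # riparian target must be pervious; fall back to the channel when not
  rip_lc <- land_cover$values[cbind(dest_r, dest_c)]
  bad <- riparian & rip_lc != LC_PERVIOUS
  dest_r[bad] <- ir[bad]; dest_c[bad] <- ax
  dest_r[css] <- NA_integer_; dest_c[css] <- NA_integer_
  storm_network(ir, ic, dest_r, dest_c, ifelse(css, "CSS", "MS4"))
}

#' Generate a seeded daily weather year
#'
#' Wet-season (October-May) days rain with probability `p_wet` at
#' exponential mean depth `rain_wet_mm`; dry-season (June-September) days
#' with probability `p_dry` at mean `rain_dry_mm`. Temperature follows a
#' sinusoid peaking August 1 plus Gaussian noise. Deterministic under the
#' spec seed.
#'
#' @param spec a [synth_spec()].
#' @param year calendar year to generate.
#' @return A `weather_series` covering the full year.
#' @export
make_weather <- function(spec, year = 2020) {
  set.seed(spec$seed + 3L)
  dates <- seq(as.Date(sprintf("%d-01-01", year)),
               as.Date(sprintf("%d-12-31", year)), by = "day")
  nd <- length(dates)
  dry <- is_dry_season(dates)
  p <- ifelse(dry, spec$p_dry, spec$p_wet)
  mu <- ifelse(dry, spec$rain_dry_mm, spec$rain_wet_mm)
  storm <- stats::runif(nd) < p
  precip <- ifelse(storm, stats::rexp(nd, rate = 1 / mu), 0)
  doy <- as.integer(format(dates, "%j"))
  tavg <- spec$temp_mean_c +
    spec$temp_amp_c * cos(2 * pi * (doy - 213) / 365.25) +
    stats::rnorm(nd, 0, spec$temp_noise_sd_c)
  weather_series(dates, precip, tavg)
}

#' Build a complete synthetic watershed
#'
#' Convenience wrapper: DEM, land cover, traffic, network and the
#' [watershed()] assembly, under one seed.
#'
#' @param spec a [synth_spec()].
#' @param soil soil-column properties (see [watershed()]).
#' @return A `watershed`.
#' @export
make_watershed <- function(spec, soil = default_config()$hydrology) {
  dem <- make_dem(spec)
  lt <- make_landcover_and_traffic(spec, dem)
  net <- make_network(spec, lt$land_cover)
  watershed(dem, lt$land_cover, lt$traffic, net,
            pour_point = c(spec$n_rows, spec$axis_col), soil = soil)
}

#' Write a full synthetic input bundle to a directory
#'
#' Emits the ESRI ASCII grids (`dem.asc`, `land_cover.asc`, `traffic.asc`),
#' the weather CSV, the storm-sewer network CSV and a config JSON, i.e.
#' everything needed to re-run the simulation from files.
#'
#' @param spec a [synth_spec()].
#' @param dir output directory (created if missing).
#' @param year weather year.
#' @param config a `sim_config` to write alongside.
#' @return `dir`, invisibly.
#' @export
write_synth_bundle <- function(spec, dir, year = 2020,
                               config = default_config()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  dem <- make_dem(spec)
  lt <- make_landcover_and_traffic(spec, dem)
  net <- make_network(spec, lt$land_cover)
  write_ascii_grid(dem, file.path(dir, "dem.asc"))
  write_ascii_grid(lt$land_cover, file.path(dir, "land_cover.asc"))
  write_ascii_grid(lt$traffic, file.path(dir, "traffic.asc"))
  write_network_csv(net, file.path(dir, "network.csv"))
  write_weather_csv(make_weather(spec, year), file.path(dir, "weather.csv"))
  write_config(config, file.path(dir, "config.json"))
  invisible(dir)
}
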