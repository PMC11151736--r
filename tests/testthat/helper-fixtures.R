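# Shared fixtures, built in code. The demo-year run (the standard 100x100
# seeded fixture) is expensive (~10 s), so it is computed once per test
# session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

demo_spec <- function() synth_spec()   # the standard demo-year spec, seed 42

demo_watershed <- function() cached("demo_ws", make_watershed(demo_spec()))

demo_weather <- function() cached("demo_weather",
                                  make_weather(demo_spec(), 2020))

demo_run <- function() cached("demo_run", {
  run_simulation(demo_watershed(), demo_weather(), keep_daily_grids = TRUE)
})

# small tilted-plane watershed: single file column of cells draining south,
# optionally with storm-sewer links; land cover defaults to all-road
column_watershed <- function(n = 10, land = rep(LC_ROAD_CODE, n),
                             network = storm_network(),
                             traffic = rep(NA_real_, n)) {
  dem <- raster_grid(matrix(seq(n, 1), ncol = 1), cell_size = 5)
  lc <- raster_grid(matrix(land, ncol = 1), cell_size = 5)
  tr <- raster_grid(matrix(traffic, ncol = 1), cell_size = 5)
  watershed(dem, lc, tr, network, pour_point = c(n, 1))
}

LC_ROAD_CODE <- 1L
LC_ROOF_CODE <- 2L
LC_IMPERV_CODE <- 3L
LC_PERV_CODE <- 4L
LC_STREAM_CODE <- 5L

# plane tilted due south on an nr x nc grid (every cell's D8 direction = S)
south_plane <- function(nr, nc, cell = 5, drop = 1) {
  raster_grid(matrix(rep(seq(nr * drop, drop, by = -drop), nc), nr, nc),
              cell_size = cell)
}

constant_weather <- function(n, precip = 0, tavg = 15,
                             start = as.Date("2020-01-01")) {
  weather_series(seq(start, by = "day", length.out = n),
                 rep(precip, length.out = n), rep(tavg, length.out = n))
}

rc_to_idx_test <- function(r, c, nr) (c - 1) * nr + r

# independent oracle: solve M = C*Vw + Kd*Ms*C for the aqueous concentration
# by bisection on the mass-balance residual, then apply the solubility cap
# the same way the closed form states it
bisect_partition <- function(m, vw, ms, foc, params, iter = 200) {
  kd <- params$koc * foc
  if (vw + kd * ms <= 0) return(list(aqueous = 0, sorbed = m))
  f <- function(conc) conc * vw + kd * ms * conc - m
  lo <- 0
  hi <- max(m / max(vw + kd * ms, 1e-300), 1)
  while (f(hi) < 0) hi <- hi * 2
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  conc <- (lo + hi) / 2
  aq <- min(conc, solubility_g_per_l(params)) * vw
  aq <- min(aq, m)
  list(aqueous = aq, sorbed = m - aq)
}

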