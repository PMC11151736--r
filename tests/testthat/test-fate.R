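cpar <- default_config()$contaminant

test_that("closed-form partitioning matches the bisection oracle on 1000 seeded draws", {
  set.seed(4242)
  n <- 1000
  m <- 10^runif(n, -8, 1)
  vw <- 10^runif(n, -2, 4)
  ms <- 10^runif(n, -2, 3)
  foc <- runif(n, 0, 0.2)
  cf <- partition_layer(m, vw, ms, foc, cpar)
  for (i in seq_len(n)) {
    or <- bisect_partition(m[i], vw[i], ms[i], foc[i], cpar)
    expect_equal(cf$aqueous[i], or$aqueous, tolerance = 1e-10)
    expect_equal(cf$sorbed[i], or$sorbed, tolerance = 1e-10)
  }
})

test_that("partitioning honors the worked example and edge rules", {
  # foc 0.01 -> Kd 110; 1 g in 100 L + 9 kg soil: C = 1/1090 g/L
  p <- partition_layer(1, 100, 9, 0.01, cpar)
  expect_equal(p$aqueous, 100 / 1090, tolerance = 1e-12)
  expect_equal(p$sorbed, 1 - 100 / 1090, tolerance = 1e-12)
  # foc 0: all aqueous; no water: all sorbed
  expect_equal(partition_layer(1, 50, 9, 0, cpar)$aqueous, 1)
  expect_equal(partition_layer(1, 0, 9, 0.01, cpar)$sorbed, 1)
  # solubility cap: huge mass in little water
  pc <- partition_layer(100, 1, 0.001, 0, cpar)
  expect_equal(pc$aqueous, solubility_g_per_l(cpar) * 1)
  expect_equal(pc$aqueous + pc$sorbed, 100)
  expect_error(partition_layer(1, 0, 0, 0.1, cpar), "degenerate")
  expect_error(partition_layer(-1, 1, 1, 0.1, cpar), "out of range")
})

test_that("increasing foc never increases the aqueous fraction", {
  set.seed(7)
  for (i in 1:50) {
    m <- 10^runif(1, -6, 0); vw <- 10^runif(1, 0, 3)
    ms <- 10^runif(1, -1, 2)
    focs <- sort(runif(6, 0, 0.3))
    aq <- partition_layer(rep(m, 6), rep(vw, 6), rep(ms, 6), focs, cpar)$aqueous
    expect_true(all(diff(aq) <= 1e-15))
  }
})

test_that("wash-off is solubility-capped and otherwise complete", {
  # typical road loading: capacity dwarfs the store, everything washes off
  expect_equal(washoff(1e-6 * 25, 10, 25, cpar), 2.5e-5)
  # zero runoff: nothing moves
  expect_equal(washoff(1, 0, 25, cpar), 0)
  # contrived: 20 g on the cell, 1 L of runoff -> only S g dissolve
  s <- solubility_g_per_l(cpar)
  expect_equal(washoff(20, 1 / 25, 25, cpar), s)
  expect_equal(s, 0.0424, tolerance = 1e-3)
})

test_that("decay is first-order with temperature/moisture slow-down", {
  # optimal conditions over one half-life leave exactly half
  mod <- decay_modulation(25, 1, cpar)
  expect_equal(mod$f_t, 1); expect_equal(mod$f_w, 1)
  hl <- log(2) / cpar$k_max
  expect_equal(hl, 3.14, tolerance = 1e-6)
  expect_equal(mod$survival^hl, 0.5, tolerance = 1e-12)
  expect_equal(mod$survival, exp(-0.2207475), tolerance = 1e-12)
  expect_equal(mod$survival, 0.8019, tolerance = 1e-4)

  # colder and drier always decays slower
  expect_lt(decay_modulation(5, 1, cpar)$f_t,
            decay_modulation(25, 1, cpar)$f_t)
  expect_lt(decay_modulation(25, 0.3, cpar)$f_w, 1)
  # above-optimum temperature and saturation cap at the maximum rate
  expect_equal(decay_modulation(35, 2, cpar)$survival, exp(-cpar$k_max))

  aq <- matrix(1, 2, 4); sorb <- matrix(2, 2, 4)
  st <- decay_step(aq, sorb, 25, matrix(1, 2, 4), cpar)
  expect_equal(st$aq_g, aq * exp(-cpar$k_max))
  expect_equal(st$decayed, sum(aq + sorb) * (1 - exp(-cpar$k_max)))
  # k_max = 0: nothing decays
  c0 <- cpar; c0$k_max <- 0
  expect_equal(decay_step(aq, sorb, 25, matrix(1, 2, 4), c0)$decayed, 0)
  expect_error(decay_modulation(25, -1, cpar), ">= 0")
})

test_that("dry deposition accumulates linearly and the ledger closes", {
  # 30 dry days on the demo watershed: no export, no soil mass, surface
  # storage is exactly 30 x the daily deposition
  ws <- demo_watershed()
  run <- run_simulation(ws, constant_weather(30), keep_daily_grids = TRUE)
  s <- run$series
  expect_equal(sum(s$load_g), 0)
  expect_equal(run$ledger$stream_export, 0)
  expect_equal(run$ledger$soil_storage, 0)
  expect_equal(run$ledger$surface_storage, 30 * s$deposited_g[1],
               tolerance = 1e-12)
  expect_lt(run$ledger$residual, 1e-9)
  # per-cell: a max-traffic masked cell holds 30 x 1.52e-7 g/m2
  dep <- run$deposition$values
  mx <- which(dep == max(dep))[1]
  expect_equal(max(dep), 1.52e-7, tolerance = 1e-12)
  expect_equal(run$surface_daily[[30]][mx], 30 * 1.52e-7,
               tolerance = 1e-9)
})

test_that("aqueous mass advects with percolating water proportionally", {
  # one storm pushes dissolved mass through an MS4 outfall into a pervious
  # cell, then percolation carries the aqueous share downward
  land <- c(rep(LC_ROAD_CODE, 3), rep(LC_PERV_CODE, 6), LC_STREAM_CODE)
  net <- storm_network(3, 1, 6, 1, "MS4")
  tr <- rep(NA_real_, 10); tr[1:3] <- c(200, 500, 1000)
  ws <- column_watershed(10, land = land, network = net, traffic = tr)
  w <- constant_weather(5, precip = c(20, 0, 0, 0, 0))
  run <- run_simulation(ws, w)
  # all washed mass lands in the outfall cell's soil column, none in stream
  expect_equal(run$series$load_g, rep(0, 5))
  expect_equal(run$ledger$soil_storage + run$ledger$decayed,
               run$ledger$deposited - run$ledger$surface_storage,
               tolerance = 1e-12)
  aq <- run$final_state$aq_g; sorb <- run$final_state$sorb_g
  i6 <- rc_to_idx_test(6, 1, 10)
  expect_gt(sorb[i6, 1], 0)        # most mass sorbed in layer 1
  expect_gt(sum(aq[i6, ] + sorb[i6, ]), 0)
  off <- setdiff(seq_len(10), i6)
  expect_equal(sum(aq[off, ]) + sum(sorb[off, ]), 0)
})

test_that("mass_balance_check flags a broken ledger", {
  run <- demo_run()
  expect_lt(run$ledger$residual, 1e-9)
  broken <- run$ledger
  broken$stream_export <- broken$stream_export * 1.05
  expect_gt(mass_balance_check(broken), 1e-6)
})
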