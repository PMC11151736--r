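# The daily operator-split engine. Fixed order of operations each day:
#   1 deposit -> 2 rainfall partition (infiltration fills soil layer 1)
#   -> 3 evapotranspiration -> 4 wash-off -> 5 surface + pipe routing
#   -> 6 percolation + bottom-layer lateral flow (advecting aqueous mass)
#   -> 7 re-partition every layer -> 8 decay -> 9 ledger update and
#   conservation check. Changing output cadence never changes this
#   trajectory.

#' Run the daily 6PPD-Q fate-and-transport simulation
#'
#' Drives the full process chain over a daily weather series on a static
#' watershed: constant traffic-scaled deposition on inlet-chained street
#' cells, solubility-capped wash-off by runoff, same-day D8 and storm-sewer
#' routing to the pour point (or WWTP), sorbed/aqueous partitioning in a
#' four-layer soil column, downward and lateral aqueous advection, and
#' temperature/moisture-modulated first-order decay. A closed daily mass
#' balance is enforced: the run aborts if the relative residual ever
#' exceeds `tolerance`.
#'
#' @param ws a [watershed()].
#' @param weather a `weather_series`.
#' @param config a `sim_config` (see [default_config()]).
#' @param keep_daily_grids keep per-day surface and soil mass grids (g/m^2)
#'   for [hotspot_map()]; costs `2 * n_cells * n_days` doubles of memory.
#' @param tolerance relative mass/water balance tolerance (abort above it).
#' @return A `sim_run` object: `series` (daily data frame: date, precip_mm,
#'   discharge_m3, load_g, concentration_ng_l, zero_flow, wwtp_m3, wwtp_g,
#'   surface_storage_g, soil_storage_g), `ledger` (cumulative grams and the
#'   final residuals), `watershed`, `config`, and optionally
#'   `surface_daily` / `soil_daily` (list of matrices).
#' @export
run_simulation <- function(ws, weather, config = default_config(),
                           keep_daily_grids = FALSE, tolerance = 1e-9) {
  stopifnot(inherits(ws, "watershed"), inherits(weather, "weather_series"))
  config <- validate_config(config)
  pre <- prepare_routing(ws)
  n <- pre$n
  area <- pre$area
  hyd <- config$hydrology
  cpar <- config$contaminant
  # deposition is constant in time; traffic min-max scaling is confined to
  # the modeled watershed: the delineation plus inlet-chained streets whose
  # inlets divert to the WWTP (outside the topographic delineation but still
  # contributing deposition)
  traffic_in <- ws$traffic
  traffic_in$values[!(ws$in_watershed | ws$depo_mask)] <- NA_real_
  dep_grid <- if (any(ws$depo_mask) && any(!is.na(traffic_in$values))) {
    deposition_grid(config$deposition, traffic_in, ws$depo_mask)
  } else {   # no inlet-chained street with a count: nothing deposits
    raster_grid(matrix(0, ws$nr, ws$nc), cell_size = ws$cell_size)
  }
  dep_g <- as.vector(dep_grid$values) * area    # g per cell per day
  dep_total_day <- sum(dep_g)

  th <- hyd$soil_layer_thickness_m
  cap_mm <- hyd$porosity * th * 1000
  fc_mm <- hyd$field_capacity * th * 1000
  foc <- hyd$foc_by_layer
  soil_kg <- hyd$bulk_density_kg_m3 * th * area    # per cell, by layer
  soil_cells <- which(pre$has_soil)
  perv <- !is.na(pre$lc) & pre$lc == LC_PERVIOUS
  imp <- !is.na(pre$lc) & is_impervious_code(pre$lc)
  s_cap <- solubility_g_per_l(cpar)

  surface_g <- numeric(n)
  sw <- matrix(0, n, 4)      # soil water, mm
  aq <- matrix(0, n, 4)      # aqueous mass, g
  sorb <- matrix(0, n, 4)    # sorbed mass, g

  cum <- list(deposited = 0, decayed = 0, stream_export = 0,
              wwtp_export = 0, boundary_export = 0)
  cum_w <- list(precip = 0, discharge = 0, wwtp = 0, boundary = 0, et = 0)
  nd <- nrow(weather)
  out <- data.frame(
    date = weather$date, precip_mm = weather$precip_mm,
    discharge_m3 = numeric(nd), load_g = numeric(nd),
    concentration_ng_l = numeric(nd), zero_flow = logical(nd),
    wwtp_m3 = numeric(nd), wwtp_g = numeric(nd),
    surface_storage_g = numeric(nd), soil_storage_g = numeric(nd),
    deposited_g = numeric(nd), decayed_g = numeric(nd))
  surface_daily <- if (keep_daily_grids) vector("list", nd) else NULL
  soil_daily <- if (keep_daily_grids) vector("list", nd) else NULL
  dry <- is_dry_season(weather$date)

  for (d in seq_len(nd)) {
    p_mm <- weather$precip_mm[d]
    tavg <- weather$tavg_c[d]
    # 1. deposition on masked street cells
    surface_g <- surface_g + dep_g
    cum$deposited <- cum$deposited + dep_total_day
    # 2. rainfall partition; infiltration enters layer 1 immediately
    headroom1 <- cap_mm[1] - sw[, 1]
    gen <- generate_runoff(rep(p_mm, n), pre$lc, headroom1,
                           hyd$infiltration_capacity_mm)
    runoff_mm <- ifelse(pre$valid, gen$runoff_mm, 0)
    infil <- ifelse(pre$valid, gen$infiltration_mm, 0)
    sw[, 1] <- sw[, 1] + infil
    precip_vol <- p_mm / 1000 * area * sum(pre$valid)
    # 3. evapotranspiration from layer 1 of pervious cells
    et_mm <- if (dry[d]) hyd$et_dry_mm else hyd$et_wet_mm
    et_draw <- ifelse(perv, pmin(sw[, 1], et_mm), 0)
    sw[, 1] <- sw[, 1] - et_draw
    et_vol <- sum(et_draw) / 1000 * area
    # 4. wash-off from impervious surfaces
    dissolved <- numeric(n)
    wet_imp <- imp & runoff_mm > 0 & surface_g > 0
    if (any(wet_imp)) {
      dissolved[wet_imp] <- washoff(surface_g[wet_imp], runoff_mm[wet_imp],
                                    area, cpar)
      surface_g[wet_imp] <- surface_g[wet_imp] - dissolved[wet_imp]
    }
    # 5. same-day surface and pipe routing
    rt <- route_surface_internal(pre, runoff_mm, dissolved,
                                 headroom_mm = cap_mm[1] - sw[, 1])
    sw[, 1] <- sw[, 1] + rt$soil_add_mm
    aq[, 1] <- aq[, 1] + rt$soil_mass_g
    # 6a. percolation with proportional aqueous advection
    for (L in 1:3) {
      excess <- pmax(sw[, L] - fc_mm[L], 0)
      perc <- pmin(hyd$percolation_fraction * excess,
                   pmax(cap_mm[L + 1] - sw[, L + 1], 0))
      move <- perc > 0
      if (any(move)) {
        frac <- perc[move] / sw[move, L]
        m_mv <- aq[move, L] * frac
        sw[move, L] <- sw[move, L] - perc[move]
        sw[move, L + 1] <- sw[move, L + 1] + perc[move]
        aq[move, L] <- aq[move, L] - m_mv
        aq[move, L + 1] <- aq[move, L + 1] + m_mv
      }
    }
    # 6b. bottom-layer lateral flow: same-layer transfer downslope, or
    # baseflow where the successor is the channel or the pour point
    excess4 <- pmax(sw[, 4] - fc_mm[4], 0)
    lat <- hyd$lateral_fraction * excess4
    lat[!pre$has_soil] <- 0
    base_m3 <- 0; base_g <- 0
    if (any(lat > 0)) {
      frac4 <- ifelse(sw[, 4] > 0, lat / sw[, 4], 0)
      m_lat <- aq[, 4] * frac4
      sw[, 4] <- sw[, 4] - lat
      aq[, 4] <- aq[, 4] - m_lat
      to_soil <- lat > 0 & pre$lat_class == "soil"
      if (any(to_soil)) {
        sw[, 4] <- sw[, 4] + accum_at(n, pre$lat_target[to_soil],
                                      lat[to_soil])
        aq[, 4] <- aq[, 4] + accum_at(n, pre$lat_target[to_soil],
                                      m_lat[to_soil])
      }
      to_pour <- lat > 0 & pre$lat_class == "pour"
      base_m3 <- sum(lat[to_pour]) / 1000 * area
      base_g <- sum(m_lat[to_pour])
      to_bnd <- lat > 0 & pre$lat_class == "boundary"
      cum_w$boundary <- cum_w$boundary + sum(lat[to_bnd]) / 1000 * area
      cum$boundary_export <- cum$boundary_export + sum(m_lat[to_bnd])
      # lateral inflow may overfill a receiving bottom layer: push the
      # surplus upward through the column (water only)
      for (L in 4:2) {
        over <- pmax(sw[, L] - cap_mm[L], 0)
        sw[, L] <- sw[, L] - over
        sw[, L - 1] <- sw[, L - 1] + over
      }
      over1 <- pmax(sw[, 1] - cap_mm[1], 0)
      if (any(over1 > 0)) {
        sw[, 1] <- sw[, 1] - over1
        rt2 <- route_surface_internal(pre, over1, NULL,
                                      headroom_mm = numeric(n))
        rt$discharge_m3 <- rt$discharge_m3 + rt2$discharge_m3
        rt$wwtp_m3 <- rt$wwtp_m3 + rt2$wwtp_m3
        rt$boundary_m3 <- rt$boundary_m3 + rt2$boundary_m3
      }
    }
    # 7. equilibrium re-partition of every soil layer
    for (L in 1:4) {
      tot <- aq[soil_cells, L] + sorb[soil_cells, L]
      pp <- partition_layer(tot, sw[soil_cells, L] * area, soil_kg[L],
                            foc[L], cpar)
      aq[soil_cells, L] <- pp$aqueous
      sorb[soil_cells, L] <- pp$sorbed
    }
    # 8. decay of soil pools only
    wetness <- sweep(sw, 2, pmax(fc_mm, .Machine$double.eps), "/")
    dk <- decay_step(aq, sorb, tavg, wetness, cpar)
    aq <- dk$aq_g; sorb <- dk$sorb_g
    cum$decayed <- cum$decayed + dk$decayed
    # 9. ledger and conservation
    discharge <- rt$discharge_m3 + base_m3
    load <- rt$load_g + base_g
    cum$stream_export <- cum$stream_export + load
    cum$wwtp_export <- cum$wwtp_export + rt$wwtp_g
    cum$boundary_export <- cum$boundary_export + rt$boundary_g
    cum_w$precip <- cum_w$precip + precip_vol
    cum_w$discharge <- cum_w$discharge + discharge
    cum_w$wwtp <- cum_w$wwtp + rt$wwtp_m3
    cum_w$boundary <- cum_w$boundary + rt$boundary_m3
    cum_w$et <- cum_w$et + et_vol
    surf_store <- sum(surface_g)
    soil_store <- sum(aq) + sum(sorb)
    led <- c(cum, list(surface_storage = surf_store,
                       soil_storage = soil_store))
    resid <- mass_balance_check(led)
    if (resid > tolerance)
      stop(sprintf("mass balance violated on %s: relative residual %.3e",
                   weather$date[d], resid), call. = FALSE)
    water_store <- sum(sw) / 1000 * area
    w_resid <- abs(cum_w$precip - cum_w$discharge - cum_w$wwtp -
                   cum_w$boundary - cum_w$et - water_store) /
      max(cum_w$precip, .Machine$double.eps)
    if (cum_w$precip > 0 && w_resid > tolerance)
      stop(sprintf("water balance violated on %s: relative residual %.3e",
                   weather$date[d], w_resid), call. = FALSE)
    out$discharge_m3[d] <- discharge
    out$load_g[d] <- load
    out$wwtp_m3[d] <- rt$wwtp_m3
    out$wwtp_g[d] <- rt$wwtp_g
    out$surface_storage_g[d] <- surf_store
    out$soil_storage_g[d] <- soil_store
    out$deposited_g[d] <- dep_total_day
    out$decayed_g[d] <- dk$decayed
    if (keep_daily_grids) {
      surface_daily[[d]] <- matrix(surface_g / area, pre$nr)
      soil_daily[[d]] <- matrix((rowSums(aq) + rowSums(sorb)) / area, pre$nr)
    }
  }
  cs <- concentration_series(out$date, out$load_g, out$discharge_m3)
  out$concentration_ng_l <- cs$concentration_ng_l
  out$zero_flow <- cs$zero_flow
  ledger <- data.frame(deposited = cum$deposited, decayed = cum$decayed,
                       stream_export = cum$stream_export,
                       wwtp_export = cum$wwtp_export,
                       boundary_export = cum$boundary_export,
                       surface_storage = sum(surface_g),
                       soil_storage = sum(aq) + sum(sorb))
  ledger$residual <- mass_balance_check(ledger)
  structure(list(series = out, ledger = ledger, watershed = ws,
                 config = config, deposition = dep_grid,
                 surface_daily = surface_daily, soil_daily = soil_daily,
                 final_state = list(surface_g = surface_g, sw_mm = sw,
                                    aq_g = aq, sorb_g = sorb)),
            class = "sim_run")
}

#' @export
print.sim_run <- function(x, ...) {
  s <- x$series
  cat(sprintf("sim_run: %d days (%s to %s)\n", nrow(s), min(s$date),
              max(s$date)))
  cat(sprintf("  deposited %.4g g, stream export %.4g g, WWTP %.4g g, %s\n",
              x$ledger$deposited, x$ledger$stream_export,
              x$ledger$wwtp_export,
              sprintf("decayed %.4g g", x$ledger$decayed)))
  cat(sprintf("  mass-balance residual %.2e; peak concentration %.3g ng/L\n",
              x$ledger$residual, max(s$concentration_ng_l)))
  invisible(x)
}
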