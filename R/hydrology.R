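# Minimal daily bucket-and-route hydrology. Impervious cells shed all rain;
# pervious cells infiltrate up to a daily capacity into a 4-layer bucket
# column; above-field-capacity water percolates downward as a daily
# fraction and drains laterally from the bottom layer toward the stream.
# All surface and pipe transit completes within the day.

#' Partition daily rainfall into runoff and infiltration for one cell
#'
#' Impervious covers (road, roof, other impervious) and stream cells shed
#' the full depth as runoff. Pervious cells infiltrate up to the daily
#' infiltration capacity and the remaining headroom of soil layer 1; the
#' excess runs off (infiltration- or saturation-excess).
#'
#' @param precip_mm daily rainfall depth, mm (>= 0). Vectorised.
#' @param land_cover land-cover code per cell (see [LAND_COVER_CODES]).
#' @param headroom_mm remaining storage headroom of soil layer 1, mm.
#' @param capacity_mm daily infiltration capacity, mm/day.
#' @return list: `runoff_mm`, `infiltration_mm`.
#' @export
generate_runoff <- function(precip_mm, land_cover, headroom_mm,
                            capacity_mm) {
  if (any(precip_mm < 0)) stop("precip must be non-negative", call. = FALSE)
  known <- land_cover %in% LAND_COVER_CODES | is.na(land_cover)
  if (!all(known))
    stop("unknown land-cover code: ", land_cover[!known][1], call. = FALSE)
  perv <- !is.na(land_cover) & land_cover == LC_PERVIOUS
  infil <- ifelse(perv, pmin(precip_mm, capacity_mm, pmax(headroom_mm, 0)), 0)
  list(runoff_mm = precip_mm - infil, infiltration_mm = infil)
}

# Static routing structure derived once from a watershed: capture class of
# every cell (which inlet, the pour point, or the boundary, walking the D8
# chain and stopping at the first inlet or stream cell), pipe link tables,
# and subsurface lateral-flow targets.
prepare_routing <- function(ws) {
  nr <- ws$nr
  n <- nr * ws$nc
  lc <- as.vector(ws$land_cover$values)
  valid <- !is.na(ws$flow$elev)
  is_stream <- !is.na(lc) & lc == LC_STREAM
  link_of_cell <- rep(0L, n)
  net <- ws$network
  idx <- network_indices(net, nr)
  if (nrow(net)) link_of_cell[idx$inlet] <- seq_len(nrow(net))
  succ <- ws$flow$downstream
  pour <- ws$pour_index
  # capture class: k > 0 inlet link, 0 pour point, -1 off-grid boundary
  capture <- rep(NA_integer_, n)
  for (s in which(valid)) {
    if (!is.na(capture[s])) next
    path <- integer(0)
    i <- s
    repeat {
      if (!is.na(capture[i])) { res <- capture[i]; break }
      if (link_of_cell[i] > 0L) { res <- link_of_cell[i]; break }
      if (is_stream[i]) { res <- 0L; break }
      if (is.na(succ[i])) { res <- if (i == pour) 0L else -1L; break }
      path <- c(path, i)
      i <- succ[i]
    }
    capture[path] <- res
    if (is.na(capture[i])) capture[i] <- res
  }
  # subsurface lateral targets from the bottom layer: same-layer transfer to
  # the D8 successor, or baseflow where the successor is the channel/pour
  has_soil <- valid & !is_stream
  lat_target <- rep(NA_integer_, n)
  lat_class <- rep("none", n)  # soil | pour | boundary | none
  for (i in which(has_soil)) {
    s2 <- succ[i]
    if (is.na(s2)) {
      lat_class[i] <- if (i == pour) "pour" else "boundary"
    } else if (is_stream[s2]) {
      lat_class[i] <- "pour"
    } else {
      lat_class[i] <- "soil"
      lat_target[i] <- s2
    }
  }
  list(n = n, nr = nr, valid = valid, lc = lc, is_stream = is_stream,
       has_soil = has_soil, capture = capture, succ = succ, pour = pour,
       net = net, inlet_idx = idx$inlet, dest_idx = idx$dest,
       is_css = if (nrow(net)) net$system_type == "CSS" else logical(0),
       lat_target = lat_target, lat_class = lat_class,
       area = ws$cell_size^2)
}

# sum vals into an n-vector at (possibly duplicated) indices
accum_at <- function(n, index, vals) {
  out <- numeric(n)
  if (length(index)) {
    r <- rowsum(vals, index)
    out[as.integer(rownames(r))] <- r
  }
  out
}

# Same-day surface and pipe routing of water volumes (m^3) and an optional
# dissolved mass field (g). Runoff generated on each cell travels its D8
# chain until captured by an inlet, the stream (then the pour point), or the
# grid boundary. MS4 inlets deliver to their outfall cell: stream outfalls
# feed the channel, pervious outfalls infiltrate into soil layer 1 (water up
# to headroom, the full dissolved mass joins the layer-1 aqueous pool),
# their excess water continuing along the outfall cell's own capture chain.
# CSS inlets export to the WWTP. Returns grouped deliveries; `soil_add_mm`
# and `soil_mass_g` are per-cell additions for the caller to apply.
route_surface_internal <- function(pre, runoff_mm, mass_g = NULL,
                                   headroom_mm = NULL) {
  n <- pre$n
  area <- pre$area
  if (is.null(mass_g)) mass_g <- numeric(n)
  if (is.null(headroom_mm)) headroom_mm <- rep(Inf, n)
  vol <- runoff_mm / 1000 * area            # m^3 generated per cell
  cap <- pre$capture
  live <- which(vol > 0 | mass_g > 0)
  discharge <- sum(vol[live][cap[live] == 0L])
  load <- sum(mass_g[live][cap[live] == 0L])
  boundary_w <- sum(vol[live][cap[live] == -1L])
  boundary_m <- sum(mass_g[live][cap[live] == -1L])
  nl <- nrow(pre$net)
  pending_w <- numeric(nl); pending_m <- numeric(nl)
  if (nl) {
    sel <- live[cap[live] > 0L]
    if (length(sel)) {
      pending_w <- accum_at(nl, cap[sel], vol[sel])
      pending_m <- accum_at(nl, cap[sel], mass_g[sel])
    }
  }
  inlet_w <- pending_w; inlet_m <- pending_m   # first-pass interception
  wwtp_w <- 0; wwtp_m <- 0
  soil_add_mm <- numeric(n); soil_mass_g <- numeric(n)
  guard <- 0L
  repeat {
    k <- which(pending_w > 0 | pending_m > 0)
    if (!length(k)) break
    k <- k[1]
    w <- pending_w[k]; m <- pending_m[k]
    pending_w[k] <- 0; pending_m[k] <- 0
    guard <- guard + 1L
    if (guard > 10L * nl + 100L)
      stop("cycle detected in storm-sewer pipe routing", call. = FALSE)
    if (pre$is_css[k]) {
      wwtp_w <- wwtp_w + w; wwtp_m <- wwtp_m + m
      next
    }
    d <- pre$dest_idx[k]
    if (pre$is_stream[d] || d == pre$pour) {
      discharge <- discharge + w; load <- load + m
    } else if (!is.na(pre$lc[d]) && pre$lc[d] == LC_PERVIOUS) {
      head_m3 <- max(headroom_mm[d] - soil_add_mm[d], 0) / 1000 * area
      inf <- min(w, head_m3)
      soil_add_mm[d] <- soil_add_mm[d] + inf * 1000 / area
      soil_mass_g[d] <- soil_mass_g[d] + m
      excess <- w - inf
      if (excess > 0) {
        cd <- cap[d]
        if (cd == 0L) discharge <- discharge + excess
        else if (cd == -1L) boundary_w <- boundary_w + excess
        else { pending_w[cd] <- pending_w[cd] + excess
               inlet_w[cd] <- inlet_w[cd] + excess }
      }
    } else {
      # impervious outfall: water and mass continue along its capture chain
      cd <- cap[d]
      if (cd == 0L) { discharge <- discharge + w; load <- load + m }
      else if (cd == -1L) { boundary_w <- boundary_w + w
                            boundary_m <- boundary_m + m }
      else { pending_w[cd] <- pending_w[cd] + w
             pending_m[cd] <- pending_m[cd] + m
             inlet_w[cd] <- inlet_w[cd] + w
             inlet_m[cd] <- inlet_m[cd] + m }
    }
  }
  list(discharge_m3 = discharge, load_g = load,
       wwtp_m3 = wwtp_w, wwtp_g = wwtp_m,
       boundary_m3 = boundary_w, boundary_g = boundary_m,
       soil_add_mm = soil_add_mm, soil_mass_g = soil_mass_g,
       inlet_intercept_m3 = inlet_w, inlet_intercept_g = inlet_m)
}

#' Route a day's surface runoff (and optional dissolved load) to the outlet
#'
#' Convenience wrapper over the simulation engine's same-day surface and
#' storm-sewer routing for a single runoff field. See the details in the
#' returned components: pour-point discharge, WWTP export, off-watershed
#' boundary export, per-cell soil additions at pervious outfalls, and
#' per-link inlet interceptions.
#'
#' @param ws a [watershed()].
#' @param runoff_mm matrix of runoff depth generated per cell, mm.
#' @param mass_g optional matrix of dissolved mass leaving each cell, g.
#' @return list: `discharge_m3`, `load_g`, `wwtp_m3`, `wwtp_g`,
#'   `boundary_m3`, `boundary_g`, `soil_add_mm`, `soil_mass_g`,
#'   `inlet_intercept_m3`, `inlet_intercept_g`.
#' @export
route_surface <- function(ws, runoff_mm, mass_g = NULL) {
  pre <- prepare_routing(ws)
  route_surface_internal(pre, as.vector(runoff_mm),
                         if (!is.null(mass_g)) as.vector(mass_g))
}
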