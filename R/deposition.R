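# Daily 6PPD-Q road deposition: a fixed per-vehicle-corridor TRWP emission
# is converted to a per-cell areal rate, reduced to its 6PPD-Q content, and
# distributed over inlet-chained street cells in proportion to min-max
# scaled traffic counts. The same grid is applied every simulation day.

#' Convert TRWP emission from mg/km/day to g/m/day
#'
#' Pure unit conversion: mg to g (1e-3) and per-km to per-m (1e-3), so the
#' factor is 1e-6. 100 mg km^-1 day^-1 becomes 1e-4 g m^-1 day^-1.
#'
#' @param trwp tire road wear particle emission, mg km^-1 day^-1 (>= 0).
#' @return emission in g m^-1 day^-1.
#' @export
trwp_adj <- function(trwp) {
  if (any(trwp < 0)) stop("trwp must be non-negative", call. = FALSE)
  trwp * 1e-6
}

#' Spread linear TRWP emission over a grid cell's area
#'
#' The linear rate applies along the cell's road length (one cell
#' resolution), spread over the cell area: `adj * cell / cell^2 = adj / cell`.
#'
#' @param adj emission in g m^-1 day^-1 (from [trwp_adj()]).
#' @param cell_resolution cell edge, m (> 0).
#' @return areal emission, g m^-2 day^-1.
#' @export
trwp_pixel <- function(adj, cell_resolution) {
  if (any(cell_resolution <= 0))
    stop("cell_resolution must be > 0", call. = FALSE)
  adj * cell_resolution / cell_resolution^2
}

#' Maximum per-cell 6PPD-Q deposition rate
#'
#' Scales the areal TRWP rate by the 6PPD content of tire material
#' (`tc_fraction`), the 6PPD-to-6PPD-Q conversion fraction (`cc_fraction`)
#' and the calibration multiplier `alpha`. At the defaults the watershed
#' maximum is `2e-5 * 0.02 * 0.38 * 1 = 1.52e-7` g m^-2 day^-1.
#'
#' @param pixel areal TRWP rate, g m^-2 day^-1 (from [trwp_pixel()]).
#' @param params `deposition` block of a `sim_config`.
#' @return maximum 6PPD-Q deposition, g m^-2 day^-1.
#' @export
trwp_6ppdq <- function(pixel, params) {
  pixel * params$tc_fraction * params$cc_fraction * params$alpha
}

#' Min-max scale traffic counts over road cells
#'
#' Each road cell's count is scaled to \[0, 1\] against the minimum and
#' maximum counts across the road cells of the modeled watershed: the
#' lightest-traffic road maps to 0, the heaviest to 1. If all counts are
#' equal (including a single road cell) every scalar is 1, with a warning,
#' so that uniform traffic keeps full deposition rather than none.
#'
#' @param traffic [raster_grid()] of vehicles/day; `NA` on non-road cells.
#' @return A [raster_grid()] of unitless scalars in \[0, 1\].
#' @export
traffic_scalar <- function(traffic) {
  stopifnot_grid(traffic)
  v <- traffic$values
  if (!any(!is.na(v)))
    stop("traffic grid has no counted road cell", call. = FALSE)
  lo <- min(v, na.rm = TRUE); hi <- max(v, na.rm = TRUE)
  out <- traffic
  if (hi == lo) {
    warning("all traffic counts equal; traffic scalars set to 1")
    out$values <- ifelse(is.na(v), NA_real_, 1)
  } else {
    out$values <- (v - lo) / (hi - lo)
  }
  out
}

#' Daily 6PPD-Q deposition grid
#'
#' Composes the emission chain with traffic scaling on the inlet-chained
#' street mask: masked cells receive `trwp_6ppdq * traffic_scalar`, all
#' other cells (including unmasked roads and parking lots) receive exactly
#' zero. The grid is constant in time and applied each simulation day.
#'
#' @param params `deposition` block of a `sim_config`.
#' @param traffic [raster_grid()] of vehicles/day.
#' @param mask logical matrix from [upslope_of_inlet_mask()].
#' @return A [raster_grid()] of 6PPD-Q deposition, g m^-2 day^-1.
#' @export
deposition_grid <- function(params, traffic, mask) {
  stopifnot_grid(traffic)
  if (!identical(dim(traffic$values), dim(mask)))
    stop("traffic grid and mask dimensions differ", call. = FALSE)
  peak <- trwp_6ppdq(trwp_pixel(trwp_adj(params$trwp),
                                params$cell_resolution), params)
  sc <- traffic_scalar(traffic)$values
  out <- traffic
  dep <- matrix(0, nrow(sc), ncol(sc))
  sel <- mask & !is.na(sc)
  dep[sel] <- peak * sc[sel]
  out$values <- dep
  out$nodata_value <- -9999
  out
}

#' Deposition ledger table
#'
#' Per-cell account of the deposition computation on the masked street
#' cells, mirroring a deposition CSV export: cell coordinates, traffic
#' count, traffic scalar and daily deposition rate.
#'
#' @param params `deposition` block of a `sim_config`.
#' @param traffic [raster_grid()] of vehicles/day.
#' @param mask logical matrix from [upslope_of_inlet_mask()].
#' @return data frame: `row`, `col`, `traffic_count`, `traffic_scalar`,
#'   `deposition_g_m2_day`.
#' @export
deposition_table <- function(params, traffic, mask) {
  dep <- deposition_grid(params, traffic, mask)
  sc <- traffic_scalar(traffic)$values
  idx <- which(mask)
  nr <- nrow(mask)
  data.frame(row = idx_to_r(idx, nr), col = idx_to_c(idx, nr),
             traffic_count = as.vector(traffic$values)[idx],
             traffic_scalar = as.vector(sc)[idx],
             deposition_g_m2_day = as.vector(dep$values)[idx])
}
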