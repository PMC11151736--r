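# Contaminant process operations. All are vectorised over cells; the daily
# engine in simulate.R composes them. Masses are grams per cell, water in mm
# depth (1 mm on 1 m^2 = 1 L) unless a unit is spelled out.

#' Equilibrium linear-isotherm partitioning
#'
#' Splits a total mass between the aqueous and sorbed phases of a soil
#' volume assuming instantaneous linear sorption with `Kd = Koc * foc`
#' (L/kg). The aqueous concentration solves
#' `M = C * Vw + Kd * Ms * C`, giving `C = M / (Vw + Kd * Ms)`; the aqueous
#' concentration is additionally capped at the solubility `S`, any excess
#' held in the sorbed pool.
#'
#' @param total_mass total contaminant mass, g (>= 0). Vectorised.
#' @param water_volume_l water volume, L.
#' @param soil_mass_kg dry soil mass, kg.
#' @param foc soil organic-carbon fraction in \[0, 1\].
#' @param params `contaminant` block of a `sim_config`.
#' @return list with numeric `aqueous` and `sorbed` (g), same length as
#'   inputs.
#' @export
partition_layer <- function(total_mass, water_volume_l, soil_mass_kg, foc,
                            params) {
  if (any(total_mass < 0) || any(water_volume_l < 0) ||
      any(soil_mass_kg < 0) || any(foc < 0) || any(foc > 1))
    stop("partition_layer inputs out of range", call. = FALSE)
  if (any(total_mass > 0 & water_volume_l == 0 & soil_mass_kg == 0))
    stop("mass present with no water and no soil: degenerate state",
         call. = FALSE)
  kd <- params$koc * foc
  s_cap <- solubility_g_per_l(params)
  denom <- water_volume_l + kd * soil_mass_kg
  conc <- ifelse(denom > 0, total_mass / denom, 0)
  aqueous <- pmin(conc, s_cap) * water_volume_l
  aqueous <- pmin(aqueous, total_mass)
  list(aqueous = aqueous, sorbed = total_mass - aqueous)
}

#' Solubility-capped wash-off from an impervious surface
#'
#' The runoff volume dissolves surface mass up to its solubility:
#' `dissolved = min(surface_mass, S * runoff_volume)` with `S` in g/L and the
#' runoff volume in litres (`runoff_mm * area_m2`). At realistic road
#' loadings the cap almost never binds and the first storm removes the whole
#' accumulated store (first flush).
#'
#' @param surface_mass_g mass on the cell surface, g. Vectorised.
#' @param runoff_mm runoff depth leaving the cell, mm.
#' @param area_m2 cell area, m^2.
#' @param params `contaminant` block of a `sim_config`.
#' @return numeric: dissolved mass leaving the surface, g.
#' @export
washoff <- function(surface_mass_g, runoff_mm, area_m2, params) {
  if (any(runoff_mm < 0)) stop("runoff must be non-negative", call. = FALSE)
  capacity <- solubility_g_per_l(params) * runoff_mm * area_m2
  pmin(surface_mass_g, capacity)
}

#' Decay modulation scalars and daily survival factor
#'
#' First-order decay at rate `k_max` slowed by sub-optimal temperature and
#' moisture: `f_T = min(1, Q10^((T - T_opt)/10))` (Q10 = 2, optimum 25 C)
#' and `f_W = min(1, theta / theta_fc)`, the layer's water content relative
#' to field capacity. The daily survival factor is
#' `exp(-k_max * f_T * f_W)`; at optimal conditions the half-life is
#' `ln(2) / k_max` = 3.14 days at the default rate.
#'
#' @param tavg_c mean air temperature, deg C.
#' @param wetness layer water content as a fraction of field capacity
#'   (>= 0; capped at 1).
#' @param params `contaminant` block of a `sim_config`.
#' @return list: `f_t`, `f_w`, `survival` (all in \[0, 1\]).
#' @export
decay_modulation <- function(tavg_c, wetness, params) {
  if (any(wetness < 0)) stop("wetness must be >= 0", call. = FALSE)
  f_t <- pmin(1, params$q10^((tavg_c - params$t_opt_c) / 10))
  f_w <- pmin(1, wetness)
  list(f_t = f_t, f_w = f_w, survival = exp(-params$k_max * f_t * f_w))
}

#' Apply one day of decay to soil contaminant pools
#'
#' Multiplies every soil pool (aqueous and sorbed, all four layers) by the
#' survival factor of [decay_modulation()]. Mass on road surfaces does not
#' decay: the decay process is tied to soil temperature, moisture and
#' carbon conditions.
#'
#' @param aq_g,sorb_g cells x 4 matrices of layer masses, g.
#' @param tavg_c scalar mean air temperature, deg C.
#' @param wetness cells x 4 matrix of water content over field capacity.
#' @param params `contaminant` block of a `sim_config`.
#' @return list: updated `aq_g`, `sorb_g`, and `decayed` (total g lost).
#' @export
decay_step <- function(aq_g, sorb_g, tavg_c, wetness, params) {
  mod <- decay_modulation(tavg_c, wetness, params)
  if (any(mod$f_t < 0 | mod$f_t > 1) || any(mod$f_w < 0 | mod$f_w > 1))
    stop("decay modulation scalars outside [0, 1]", call. = FALSE)
  f <- mod$survival
  lost <- sum((aq_g + sorb_g) * (1 - f))
  list(aq_g = aq_g * f, sorb_g = sorb_g * f, decayed = lost)
}

#' Relative mass-balance residual of a simulation ledger
#'
#' `|deposited - decayed - stream - WWTP - boundary - storage| /
#' max(deposited, eps)`; the simulation engine aborts if this exceeds its
#' tolerance (1e-9) on any day.
#'
#' @param ledger list or one-row data frame with cumulative grams:
#'   `deposited`, `decayed`, `stream_export`, `wwtp_export`,
#'   `boundary_export`, `surface_storage`, `soil_storage`.
#' @return relative residual (unitless).
#' @export
mass_balance_check <- function(ledger) {
  resid <- ledger$deposited - ledger$decayed - ledger$stream_export -
    ledger$wwtp_export - ledger$boundary_export -
    ledger$surface_storage - ledger$soil_storage
  abs(resid) / max(ledger$deposited, .Machine$double.eps)
}
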