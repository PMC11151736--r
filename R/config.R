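#' Default simulation configuration
#'
#' Returns the full configuration with every parameter at its default.
#' Deposition block: tire road wear particle (TRWP) emission of 100 mg per km
#' driven per day, a 5-m cell, 2% of tire mass as 6PPD (`tc_fraction`), 38%
#' conversion of 6PPD to 6PPD-Q (`cc_fraction`, the midpoint of the 1-75%
#' theoretical range), calibration multiplier `alpha` = 1. Contaminant block:
#' Koc 11000 L/kg, molar solubility 1.58e-4 mol/L, molar mass 268.404 g/mol,
#' maximum decay rate 0.2207475 day^-1 (half-life 3.14 days at optimal
#' temperature and moisture), logKow 2.745 (metadata; Koc is specified
#' directly). Hydrology block: the minimal bucket-and-route scheme constants
#' (see the methods vignette).
#'
#' @return A nested list of class `sim_config`.
#' @export
default_config <- function() {
  cfg <- list(
    deposition = list(
      trwp = 100,              # mg km^-1 day^-1
      cell_resolution = 5,     # m
      tc_fraction = 0.02,      # fraction of tire mass that is 6PPD
      cc_fraction = 0.38,      # fraction of 6PPD transformed to 6PPD-Q
      alpha = 1.0              # calibration multiplier, unused (=1)
    ),
    contaminant = list(
      koc = 11000,             # L/kg
      molar_solubility = 0.000158,  # mol/L
      molar_mass = 268.404,    # g/mol
      k_max = 0.2207475,       # day^-1 at optimal conditions
      log_kow = 2.745,         # metadata only (direct_koc = TRUE)
      direct_koc = TRUE,
      q10 = 2,                 # temperature modulation Q10
      t_opt_c = 25             # decay optimum temperature, deg C
    ),
    hydrology = list(
      infiltration_capacity_mm = 50,   # pervious daily intake cap, mm/day
      percolation_fraction = 0.5,      # of above-field-capacity water, /day
      lateral_fraction = 0.1,          # bottom-layer lateral drainage, /day
      et_dry_mm = 2,                   # layer-1 draw Jun-Sep, mm/day
      et_wet_mm = 0.5,                 # layer-1 draw Oct-May, mm/day
      porosity = 0.45,
      field_capacity = 0.30,
      soil_layer_thickness_m = c(0.1, 0.2, 0.3, 0.4),
      foc_by_layer = c(0.05, 0.03, 0.01, 0.005),
      bulk_density_kg_m3 = 1300
    ),
    lc50_threshold = 95,       # ng/L, coho salmon LC50 for 6PPD-Q
    random_seed = 1L,
    output = list(dir = ".", cadence = "daily")
  )
  class(cfg) <- c("sim_config", "list")
  validate_config(cfg)
}

#' Load a simulation configuration from JSON
#'
#' Reads a JSON file holding any subset of the keys of [default_config()];
#' missing keys are filled with the defaults, present keys override them.
#' The merged configuration is validated before being returned.
#'
#' @param path path to a JSON config file, or `NULL` for pure defaults.
#' @return A validated `sim_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- unclass(default_config())
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
    user <- jsonlite::read_json(path, simplifyVector = TRUE)
    cfg <- merge_lists(cfg, user)
  }
  class(cfg) <- c("sim_config", "list")
  validate_config(cfg)
}

#' Write a configuration to JSON
#' @param config a `sim_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

merge_lists <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]])) {
      base[[k]] <- merge_lists(base[[k]], override[[k]])
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Validate a simulation configuration
#'
#' Checks ranges: all fractions in \[0, 1\], all rates and masses
#' non-negative, LC50 threshold positive, field capacity not above porosity.
#' Fails with the offending key named.
#'
#' @param config a `sim_config` list.
#' @return the config, invisibly classed, if valid.
#' @export
validate_config <- function(config) {
  fail <- function(key, why) stop(sprintf("config key '%s' %s", key, why),
                                  call. = FALSE)
  chk_frac <- function(key, v) {
    if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
      fail(key, "must lie in [0, 1]")
  }
  chk_pos <- function(key, v, strict = FALSE) {
    if (any(!is.finite(v)) || any(if (strict) v <= 0 else v < 0))
      fail(key, if (strict) "must be > 0" else "must be >= 0")
  }
  d <- config$deposition
  chk_pos("deposition.trwp", d$trwp)
  chk_pos("deposition.cell_resolution", d$cell_resolution, strict = TRUE)
  chk_frac("deposition.tc_fraction", d$tc_fraction)
  chk_frac("deposition.cc_fraction", d$cc_fraction)
  chk_frac("deposition.alpha", d$alpha)
  cc <- config$contaminant
  chk_pos("contaminant.koc", cc$koc)
  chk_pos("contaminant.molar_solubility", cc$molar_solubility)
  chk_pos("contaminant.molar_mass", cc$molar_mass, strict = TRUE)
  chk_pos("contaminant.k_max", cc$k_max)
  h <- config$hydrology
  chk_pos("hydrology.infiltration_capacity_mm", h$infiltration_capacity_mm)
  chk_frac("hydrology.percolation_fraction", h$percolation_fraction)
  chk_frac("hydrology.lateral_fraction", h$lateral_fraction)
  chk_pos("hydrology.et_dry_mm", h$et_dry_mm)
  chk_pos("hydrology.et_wet_mm", h$et_wet_mm)
  chk_frac("hydrology.porosity", h$porosity)
  chk_frac("hydrology.field_capacity", h$field_capacity)
  if (h$field_capacity > h$porosity)
    fail("hydrology.field_capacity", "must not exceed porosity")
  if (length(h$soil_layer_thickness_m) != 4L)
    fail("hydrology.soil_layer_thickness_m", "must have 4 layers")
  chk_pos("hydrology.soil_layer_thickness_m", h$soil_layer_thickness_m,
          strict = TRUE)
  if (length(h$foc_by_layer) != 4L)
    fail("hydrology.foc_by_layer", "must have 4 layers")
  chk_frac("hydrology.foc_by_layer", h$foc_by_layer)
  chk_pos("hydrology.bulk_density_kg_m3", h$bulk_density_kg_m3, strict = TRUE)
  if (!is.finite(config$lc50_threshold) || config$lc50_threshold <= 0)
    fail("lc50_threshold", "must be > 0")
  if (!isTRUE(cc$direct_koc))
    stop("direct_koc = FALSE (Koc estimation from logKow) is not implemented;",
         " supply koc directly", call. = FALSE)
  class(config) <- c("sim_config", "list")
  invisible(config)
}

#' Aqueous solubility of the contaminant in g/L
#'
#' Mass solubility derived from the molar solubility and molar mass:
#' `S = molar_solubility * molar_mass` (0.0424 g/L at the defaults). This is
#' the cap applied to dissolved-phase concentrations at wash-off and in soil.
#'
#' @param contaminant the `contaminant` block of a `sim_config`.
#' @return solubility in g/L.
#' @export
solubility_g_per_l <- function(contaminant) {
  contaminant$molar_solubility * contaminant$molar_mass
}

#' First-order decay rate from half-life, and back
#'
#' The maximum decay rate is a continuous first-order constant: a half-life
#' of `t` days gives `k = ln(2) / t` per day, and the default
#' `k = 0.2207475` day^-1 corresponds to a 3.14-day half-life at optimal
#' temperature and moisture.
#'
#' @param half_life_days half-life in days (> 0).
#' @return rate in day^-1.
#' @export
decay_rate_from_half_life <- function(half_life_days) {
  if (any(half_life_days <= 0)) stop("half-life must be > 0", call. = FALSE)
  log(2) / half_life_days
}

#' @rdname decay_rate_from_half_life
#' @param rate_per_day first-order rate in day^-1 (> 0).
#' @export
half_life_from_decay_rate <- function(rate_per_day) {
  if (any(rate_per_day <= 0)) stop("rate must be > 0", call. = FALSE)
  log(2) / rate_per_day
}

#' Midpoint of a theoretical conversion-fraction range
#'
#' The default 6PPD-to-6PPD-Q conversion fraction (`cc_fraction` = 0.38) is
#' the midpoint of the reported theoretical 1%-75% conversion range.
#'
#' @param low,high range endpoints as fractions (defaults 0.01 and 0.75).
#' @return the midpoint fraction.
#' @export
conversion_fraction_midpoint <- function(low = 0.01, high = 0.75) {
  (low + high) / 2
}
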