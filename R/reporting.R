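# Observables: pour-point concentration series, comparison against grab
# samples, LC50 exceedance flags, hotspot rasters, mass-balance summary.

#' Pour-point concentration series
#'
#' Converts daily stream load and discharge into ng/L:
#' `concentration = load_g * 1e9 / (discharge_m3 * 1e3)` on days with flow.
#' Zero-discharge days are reported as 0 ng/L and flagged `zero_flow`,
#' matching the undetectable dry-season condition rather than NaN.
#'
#' @param dates `Date` vector.
#' @param load_g daily 6PPD-Q load at the pour point, g/day.
#' @param discharge_m3 daily discharge, m^3/day.
#' @return A `pour_point_series` data frame: `date`, `discharge_m3`,
#'   `load_g`, `concentration_ng_l`, `zero_flow`.
#' @export
concentration_series <- function(dates, load_g, discharge_m3) {
  n <- length(dates)
  if (length(load_g) != n || length(discharge_m3) != n)
    stop("dates, loads and discharge are not aligned", call. = FALSE)
  zero <- discharge_m3 <= 0
  conc <- numeric(n)
  conc[!zero] <- load_g[!zero] * 1e9 / (discharge_m3[!zero] * 1e3)
  structure(data.frame(date = as.Date(dates), discharge_m3 = discharge_m3,
                       load_g = load_g, concentration_ng_l = conc,
                       zero_flow = zero),
            class = c("pour_point_series", "data.frame"))
}

#' Bundled observed 6PPD-Q grab samples
#'
#' The five single-day grab samples (ng/L) observed at the pour point
#' between October 2020 and April 2021, bundled as the package's reference
#' comparison fixture.
#'
#' @return data frame: `date`, `concentration_ng_l` (5 rows).
#' @export
observed_samples <- function() {
  p <- system.file("extdata", "observed_samples.csv", package = "tirewash")
  if (nzchar(p)) {
    df <- utils::read.csv(p, stringsAsFactors = FALSE)
    df$date <- as.Date(df$date)
    return(df)
  }
  data.frame(
    date = as.Date(c("2020-10-26", "2020-11-13", "2021-03-04",
                     "2021-03-18", "2021-04-29")),
    concentration_ng_l = c(6.63, 14.3, 27.4, 11.2, 1.71))
}

#' Compare a simulated series against observed grab samples
#'
#' Joins simulated daily-average concentrations to observed sample dates and
#' reports per-date absolute differences plus their maximum. Daily averages
#' against instantaneous grab samples is the intended comparison; no
#' sub-daily disaggregation is attempted.
#'
#' @param series a `pour_point_series`.
#' @param obs data frame with `date` and `concentration_ng_l`
#'   (default [observed_samples()]).
#' @return list: `table` (date, observed, simulated, abs_diff) and
#'   `max_abs_diff`.
#' @export
compare_observed <- function(series, obs = observed_samples()) {
  i <- match(as.Date(obs$date), as.Date(series$date))
  if (anyNA(i))
    stop("observed date(s) outside the simulated span: ",
         paste(obs$date[is.na(i)], collapse = ", "), call. = FALSE)
  tab <- data.frame(date = obs$date, observed = obs$concentration_ng_l,
                    simulated = series$concentration_ng_l[i])
  tab$abs_diff <- abs(tab$simulated - tab$observed)
  list(table = tab, max_abs_diff = max(tab$abs_diff))
}

#' Flag days at or above a toxicity threshold
#'
#' Inclusive comparison against the LC50 (default 95 ng/L for coho salmon):
#' a day exactly at the threshold is flagged, the protective convention.
#'
#' @param series a `pour_point_series`.
#' @param threshold ng/L (> 0).
#' @return `Date` vector of flagged days (possibly empty).
#' @export
exceedance_flags <- function(series, threshold = 95) {
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  series$date[series$concentration_ng_l >= threshold]
}

#' Time-aggregated contaminant hotspot map
#'
#' Per-cell mean (or max) mass over a date window, for the road-surface
#' compartment, the soil compartment, or their sum. Requires the run to
#' have kept daily grids (`keep_daily_grids = TRUE`).
#'
#' @param run a `sim_run`.
#' @param from,to window bounds (`Date`; defaults span the run).
#' @param compartment `"surface"`, `"soil"` or `"both"`.
#' @param stat `"mean"` or `"max"`.
#' @return A [raster_grid()] of g/m^2.
#' @export
hotspot_map <- function(run, from = NULL, to = NULL,
                        compartment = c("surface", "soil", "both"),
                        stat = c("mean", "max")) {
  compartment <- match.arg(compartment)
  stat <- match.arg(stat)
  if (is.null(run$surface_daily))
    stop("run was made with keep_daily_grids = FALSE", call. = FALSE)
  dts <- run$series$date
  if (is.null(from)) from <- min(dts)
  if (is.null(to)) to <- max(dts)
  sel <- which(dts >= as.Date(from) & dts <= as.Date(to))
  if (!length(sel)) stop("empty hotspot window", call. = FALSE)
  pick <- function(d) switch(compartment,
    surface = run$surface_daily[[d]],
    soil = run$soil_daily[[d]],
    both = run$surface_daily[[d]] + run$soil_daily[[d]])
  acc <- pick(sel[1])
  for (d in sel[-1]) {
    m <- pick(d)
    acc <- if (stat == "mean") acc + m else pmax(acc, m)
  }
  if (stat == "mean") acc <- acc / length(sel)
  g <- run$watershed$dem
  g$values <- acc
  g$nodata_value <- -9999
  g
}

#' Plain-text mass-balance summary
#'
#' @param run a `sim_run`.
#' @return character vector of report lines, invisibly; printed by default.
#' @export
mass_balance_summary <- function(run) {
  l <- run$ledger
  lines <- c(
    "6PPD-Q mass balance (g, cumulative over run)",
    sprintf("  deposited:        %.6e", l$deposited),
    sprintf("  decayed in soil:  %.6e", l$decayed),
    sprintf("  stream export:    %.6e", l$stream_export),
    sprintf("  WWTP export:      %.6e", l$wwtp_export),
    sprintf("  boundary export:  %.6e", l$boundary_export),
    sprintf("  surface storage:  %.6e", l$surface_storage),
    sprintf("  soil storage:     %.6e", l$soil_storage),
    sprintf("  relative residual: %.3e", l$residual))
  cat(lines, sep = "\n")
  invisible(lines)
}
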