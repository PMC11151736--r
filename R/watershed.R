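#' Land-cover codes
#'
#' Integer codes used in the land-cover grid: 1 road, 2 roof, 3 other
#' impervious (e.g. parking lot), 4 pervious, 5 stream channel. Roads, roofs
#' and other impervious cells shed all rainfall as runoff; only road cells in
#' the inlet-chained mask receive contaminant deposition.
#'
#' @format Named integer vector of length 5.
#' @export
LAND_COVER_CODES <- c(road = 1L, roof = 2L, impervious = 3L,
                      pervious = 4L, stream = 5L)

LC_ROAD <- 1L
LC_ROOF <- 2L
LC_IMPERV <- 3L
LC_PERVIOUS <- 4L
LC_STREAM <- 5L

is_impervious_code <- function(code) code %in% c(LC_ROAD, LC_ROOF, LC_IMPERV)

#' Read a storm-sewer network table
#'
#' CSV columns: `inlet_row`, `inlet_col`, `dest_row`, `dest_col`,
#' `system_type` (`MS4` or `CSS`). Rows and columns are 1-based from the
#' northwest corner. For `CSS` links the destination columns are blank: the
#' water and contaminant leave the watershed to the wastewater treatment
#' plant. For `MS4` links the destination is the outfall cell, re-entering
#' surface routing there.
#'
#' @param path path to the CSV file.
#' @return A `storm_network` data frame.
#' @export
read_network_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("inlet_row", "inlet_col", "dest_row", "dest_col", "system_type")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("network CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  storm_network(df$inlet_row, df$inlet_col, df$dest_row, df$dest_col,
                df$system_type)
}

#' Construct a storm-sewer network
#'
#' @param inlet_row,inlet_col inlet cell coordinates (1-based from NW).
#' @param dest_row,dest_col MS4 outfall cell coordinates; `NA` for CSS links.
#' @param system_type `"MS4"` or `"CSS"` per link.
#' @return A `storm_network` data frame.
#' @export
storm_network <- function(inlet_row = integer(0), inlet_col = integer(0),
                          dest_row = integer(0), dest_col = integer(0),
                          system_type = character(0)) {
  df <- data.frame(inlet_row = as.integer(inlet_row),
                   inlet_col = as.integer(inlet_col),
                   dest_row = suppressWarnings(as.integer(dest_row)),
                   dest_col = suppressWarnings(as.integer(dest_col)),
                   system_type = toupper(as.character(system_type)),
                   stringsAsFactors = FALSE)
  if (nrow(df) && !all(df$system_type %in% c("MS4", "CSS")))
    stop("system_type must be 'MS4' or 'CSS'", call. = FALSE)
  if (nrow(df) && any(df$system_type == "MS4" &
                      (is.na(df$dest_row) | is.na(df$dest_col))))
    stop("MS4 links require a destination cell", call. = FALSE)
  class(df) <- c("storm_network", "data.frame")
  df
}

#' Write a storm-sewer network table to CSV
#' @param network a `storm_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network_csv <- function(network, path) {
  utils::write.csv(as.data.frame(network), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

network_indices <- function(network, nr) {
  list(inlet = rc_to_idx(network$inlet_row, network$inlet_col, nr),
       dest = ifelse(is.na(network$dest_row), NA_integer_,
                     rc_to_idx(network$dest_row, network$dest_col, nr)))
}

#' Validate a storm-sewer network against a watershed
#'
#' Checks for duplicate inlet cells and off-grid destinations, and reports
#' counts of inlets, MS4 outfalls and CSS links, split by whether each
#' outfall contributes to the pour point (is inside the delineation) or not.
#'
#' @param network a `storm_network`.
#' @param watershed a [watershed()].
#' @return A list report: `n_inlets`, `n_ms4`, `n_css`,
#'   `n_outfalls_contributing`, `n_outfalls_non_contributing`,
#'   `non_contributing` (link row numbers).
#' @export
validate_network <- function(network, watershed) {
  nr <- nrow(watershed$dem$values); nc <- ncol(watershed$dem$values)
  if (nrow(network) == 0)
    return(list(n_inlets = 0L, n_ms4 = 0L, n_css = 0L,
                n_outfalls_contributing = 0L,
                n_outfalls_non_contributing = 0L,
                non_contributing = integer(0)))
  if (anyDuplicated(network[, c("inlet_row", "inlet_col")]))
    stop("duplicate inlet cell(s) in storm-sewer network", call. = FALSE)
  bad_in <- network$inlet_row < 1 | network$inlet_row > nr |
            network$inlet_col < 1 | network$inlet_col > nc
  if (any(bad_in))
    stop("inlet cell off grid at link ", which(bad_in)[1], call. = FALSE)
  ms4 <- network$system_type == "MS4"
  bad_out <- ms4 & (network$dest_row < 1 | network$dest_row > nr |
                    network$dest_col < 1 | network$dest_col > nc)
  if (any(bad_out))
    stop("MS4 destination off grid at link ", which(bad_out)[1],
         call. = FALSE)
  idx <- network_indices(network, nr)
  inside <- rep(FALSE, sum(ms4))
  if (any(ms4))
    inside <- watershed$in_watershed[idx$dest[ms4]]
  list(n_inlets = nrow(network),
       n_ms4 = sum(ms4),
       n_css = sum(!ms4),
       n_outfalls_contributing = sum(inside),
       n_outfalls_non_contributing = sum(!inside),
       non_contributing = which(ms4)[!inside])
}

#' Assemble the static simulation domain
#'
#' Bundles terrain, land cover, traffic, soils and the storm-sewer network;
#' fills DEM pits, derives the D8 flow field, delineates the watershed
#' draining to the pour point, and computes the inlet-chained road mask that
#' confines contaminant deposition.
#'
#' @param dem elevation [raster_grid()] (m).
#' @param land_cover [raster_grid()] of codes (see [LAND_COVER_CODES]).
#' @param traffic [raster_grid()] of vehicles/day on road cells (`NA`
#'   elsewhere).
#' @param network a `storm_network`.
#' @param pour_point `c(row, col)` of the watershed outlet.
#' @param soil list of soil-column properties: `porosity`, `field_capacity`
#'   (fractions, capacity <= porosity), `soil_layer_thickness_m` and
#'   `foc_by_layer` (4 values each), `bulk_density_kg_m3`. Defaults from
#'   [default_config()].
#' @return A `watershed` object.
#' @export
watershed <- function(dem, land_cover, traffic, network,
                      pour_point, soil = default_config()$hydrology) {
  stopifnot_grid(dem); stopifnot_grid(land_cover); stopifnot_grid(traffic)
  if (!same_shape(dem, land_cover) || !same_shape(dem, traffic))
    stop("dem, land_cover and traffic grids must have identical dimensions",
         call. = FALSE)
  nr <- nrow(dem$values); nc <- ncol(dem$values)
  if (pour_point[1] < 1 || pour_point[1] > nr ||
      pour_point[2] < 1 || pour_point[2] > nc)
    stop("pour point outside grid", call. = FALSE)
  lc <- land_cover$values
  codes <- stats::na.omit(unique(as.vector(lc)))
  if (!all(codes %in% LAND_COVER_CODES))
    stop("unknown land-cover code(s): ",
         paste(setdiff(codes, LAND_COVER_CODES), collapse = ", "),
         call. = FALSE)
  if (soil$field_capacity > soil$porosity)
    stop("field_capacity must not exceed porosity", call. = FALSE)
  dem_filled <- fill_pits(dem)
  flow <- compute_d8(dem_filled)
  in_ws <- delineate(flow, pour_point, network)
  depo_mask <- upslope_of_inlet_mask(flow, land_cover, network)
  structure(list(
    dem = dem, dem_filled = dem_filled, land_cover = land_cover,
    traffic = traffic, network = network,
    pour_point = as.integer(pour_point),
    pour_index = rc_to_idx(pour_point[1], pour_point[2], nr),
    flow = flow, in_watershed = in_ws, depo_mask = depo_mask,
    soil = soil, nr = nr, nc = nc, cell_size = dem$cell_size),
    class = "watershed")
}

#' @export
print.watershed <- function(x, ...) {
  lc <- as.vector(x$land_cover$values)
  cat(sprintf("watershed: %d x %d cells at %g m (%.3f km2 delineated)\n",
              x$nr, x$nc, x$cell_size,
              sum(x$in_watershed) * x$cell_size^2 / 1e6))
  cat(sprintf("  roads: %d cells (%d deposition-masked), streams: %d cells\n",
              sum(lc == LC_ROAD, na.rm = TRUE), sum(x$depo_mask),
              sum(lc == LC_STREAM, na.rm = TRUE)))
  cat(sprintf("  network: %d inlets (%d MS4, %d CSS); pour point (%d, %d)\n",
              nrow(x$network), sum(x$network$system_type == "MS4"),
              sum(x$network$system_type == "CSS"),
              x$pour_point[1], x$pour_point[2]))
  invisible(x)
}
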