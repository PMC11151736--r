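# Orchestration: file-based end-to-end runs, run manifests, and a small
# command-line interface (synth / validate / run).

#' Build a run manifest
#'
#' Records what went into a run: an MD5 of the configuration, MD5 checksums
#' of the input files, the seed, package version, simulated date span and
#' the output inventory. Written before a run and finalised after it.
#'
#' @param config a `sim_config`.
#' @param inputs character vector of input file paths.
#' @param dates `Date` vector of the simulated span.
#' @param outputs character vector of produced files (may be empty before
#'   the run finishes).
#' @return list of class `run_manifest`.
#' @export
run_manifest <- function(config, inputs = character(),
                         dates = as.Date(character()),
                         outputs = character()) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(config), tf, auto_unbox = TRUE, digits = NA)
  structure(list(
    config_md5 = unname(tools::md5sum(tf)),
    input_md5 = vapply(inputs, function(p) unname(tools::md5sum(p)), ""),
    seed = config$random_seed,
    package_version = as.character(utils::packageVersion("tirewash")),
    start_date = if (length(dates)) as.character(min(dates)) else NA,
    end_date = if (length(dates)) as.character(max(dates)) else NA,
    outputs = outputs), class = "run_manifest")
}

#' Run a simulation from an input bundle directory
#'
#' Loads `dem.asc`, `land_cover.asc`, `traffic.asc`, `network.csv`,
#' `weather.csv` and `config.json` from `dir` (the layout written by
#' [write_synth_bundle()]), runs the simulation, and writes the pour-point
#' series CSV, a mass-balance summary, the deposition grid, annual surface
#' and soil hotspot rasters and a JSON manifest into `out_dir`. Outputs are
#' bit-identical across reruns of the same bundle.
#'
#' @param dir input bundle directory.
#' @param out_dir output directory (created if missing).
#' @param keep_daily_grids forward to [run_simulation()] (needed for the
#'   hotspot rasters; on by default).
#' @return the `sim_run`, invisibly.
#' @export
run_bundle <- function(dir, out_dir, keep_daily_grids = TRUE) {
  paths <- file.path(dir, c("dem.asc", "land_cover.asc", "traffic.asc",
                            "network.csv", "weather.csv", "config.json"))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("input bundle incomplete; missing: ",
         paste(basename(missing), collapse = ", "), call. = FALSE)
  config <- load_config(paths[6])
  ws <- watershed(read_ascii_grid(paths[1]), read_ascii_grid(paths[2]),
                  read_ascii_grid(paths[3]), read_network_csv(paths[4]),
                  pour_point = find_pour_point(read_ascii_grid(paths[1]),
                                               read_ascii_grid(paths[2])),
                  soil = config$hydrology)
  weather <- read_weather_csv(paths[5])
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  run <- run_simulation(ws, weather, config,
                        keep_daily_grids = keep_daily_grids)
  outs <- c("pour_point.csv", "mass_balance.txt", "deposition.asc",
            "deposition.csv", "hotspot_surface.asc", "hotspot_soil.asc",
            "manifest.json")
  utils::write.csv(run$series, file.path(out_dir, "pour_point.csv"),
                   row.names = FALSE, quote = FALSE)
  if (any(ws$depo_mask)) {
    tr_in <- ws$traffic
    tr_in$values[!(ws$in_watershed | ws$depo_mask)] <- NA_real_
    utils::write.csv(deposition_table(config$deposition, tr_in, ws$depo_mask),
                     file.path(out_dir, "deposition.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  writeLines(utils::capture.output(mass_balance_summary(run)),
             file.path(out_dir, "mass_balance.txt"))
  write_ascii_grid(run$deposition, file.path(out_dir, "deposition.asc"))
  if (keep_daily_grids) {
    write_ascii_grid(hotspot_map(run, compartment = "surface"),
                     file.path(out_dir, "hotspot_surface.asc"))
    write_ascii_grid(hotspot_map(run, compartment = "soil"),
                     file.path(out_dir, "hotspot_soil.asc"))
  }
  man <- run_manifest(config, paths, weather$date, outs)
  jsonlite::write_json(unclass(man), file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(run)
}

#' Locate the pour point of a gridded domain
#'
#' The lowest stream cell of the land-cover grid (the outlet of the channel
#' chain); falls back to the lowest valid DEM cell when no stream cells
#' exist.
#'
#' @param dem elevation [raster_grid()].
#' @param land_cover land-cover [raster_grid()].
#' @return `c(row, col)`.
#' @export
find_pour_point <- function(dem, land_cover) {
  z <- dem$values
  stream <- !is.na(land_cover$values) & land_cover$values == LC_STREAM
  cand <- if (any(stream)) which(stream & !is.na(z)) else which(!is.na(z))
  i <- cand[which.min(z[cand])]
  c(idx_to_r(i, nrow(z)), idx_to_c(i, nrow(z)))
}

#' Command-line interface
#'
#' Subcommands:
#' \describe{
#'   \item{`synth --out DIR [--seed N] [--rows N] [--cols N] [--year Y]`}{
#'     write a synthetic input bundle.}
#'   \item{`validate --dir DIR`}{load a bundle, delineate, and report the
#'     storm-sewer network counts.}
#'   \item{`run --dir DIR --out DIR`}{run the simulation on a bundle and
#'     write all outputs.}
#' }
#' Exit status: 0 success, 1 validation failure, 2 conservation failure.
#'
#' @param args character vector (default: the command line).
#' @return exit code, invisibly.
#' @export
tirewash_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste("usage: tirewash <synth|validate|run> [options]",
                 "  synth    --out DIR [--seed N] [--rows N] [--cols N]",
                 "  validate --dir DIR",
                 "  run      --dir DIR --out DIR", sep = "\n")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opt <- parse_cli_opts(args[-1])
  code <- tryCatch({
    switch(cmd,
      synth = {
        spec <- synth_spec(
          n_rows = as.integer(opt_get(opt, "rows", 100)),
          n_cols = as.integer(opt_get(opt, "cols", 100)),
          seed = as.integer(opt_get(opt, "seed", 42)))
        write_synth_bundle(spec, opt_get(opt, "out"),
                           year = as.integer(opt_get(opt, "year", 2020)))
        message("bundle written to ", opt_get(opt, "out"))
        0L
      },
      validate = {
        dir <- opt_get(opt, "dir")
        config <- load_config(file.path(dir, "config.json"))
        dem <- read_ascii_grid(file.path(dir, "dem.asc"))
        lc <- read_ascii_grid(file.path(dir, "land_cover.asc"))
        ws <- watershed(dem, lc,
                        read_ascii_grid(file.path(dir, "traffic.asc")),
                        read_network_csv(file.path(dir, "network.csv")),
                        pour_point = find_pour_point(dem, lc),
                        soil = config$hydrology)
        rep <- validate_network(ws$network, ws)
        print(ws)
        message(sprintf("network: %d inlets, %d MS4 (%d contributing), %d CSS",
                        rep$n_inlets, rep$n_ms4,
                        rep$n_outfalls_contributing, rep$n_css))
        0L
      },
      run = {
        run_bundle(opt_get(opt, "dir"), opt_get(opt, "out"))
        0L
      },
      { message(usage); 1L })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("balance violated", conditionMessage(e))) 2L else 1L
  })
  invisible(code)
}

parse_cli_opts <- function(args) {
  opt <- list()
  i <- 1L
  while (i <= length(args)) {
    if (startsWith(args[i], "--")) {
      opt[[substring(args[i], 3)]] <- args[i + 1L]
      i <- i + 2L
    } else i <- i + 1L
  }
  opt
}

opt_get <- function(opt, key, default = NULL) {
  if (!is.null(opt[[key]])) return(opt[[key]])
  if (is.null(default)) stop("missing required option --", key, call. = FALSE)
  default
}
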