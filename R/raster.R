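#' Georeferenced raster grid
#'
#' The universal spatial container of the simulator: a numeric matrix with
#' row 1 the northernmost row, plus the georeferencing fields of the ESRI
#' ASCII grid format. Nodata cells are held as `NA` internally so they can
#' never leak into arithmetic; the sentinel is only materialised on write.
#'
#' @param values numeric matrix, row 1 = northernmost row. `NA` marks nodata.
#' @param xll,yll coordinates (m) of the grid's south-west corner.
#' @param cell_size cell edge length in metres (> 0).
#' @param nodata_value sentinel written to file for `NA` cells.
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, xll = 0, yll = 0, cell_size = 5,
                        nodata_value = -9999) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a single positive number", call. = FALSE)
  structure(
    list(values = values, xll = as.numeric(xll), yll = as.numeric(yll),
         cell_size = as.numeric(cell_size),
         nodata_value = as.numeric(nodata_value)),
    class = "raster_grid")
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' @export
as.matrix.raster_grid <- function(x, ...) x$values

#' @export
print.raster_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("raster_grid: %d rows x %d cols, cell %g m, llcorner (%g, %g)\n",
              d[1], d[2], x$cell_size, x$xll, x$yll))
  cat(sprintf("  values: [%g, %g], %d nodata cell(s)\n",
              suppressWarnings(min(x$values, na.rm = TRUE)),
              suppressWarnings(max(x$values, na.rm = TRUE)),
              sum(is.na(x$values))))
  invisible(x)
}

#' Cell area of a raster grid in square metres
#' @param grid a [raster_grid()].
#' @return `cell_size^2` (m^2).
#' @export
cell_area <- function(grid) grid$cell_size^2

stopifnot_grid <- function(grid, arg = deparse(substitute(grid))) {
  if (!inherits(grid, "raster_grid"))
    stop(sprintf("'%s' must be a raster_grid", arg), call. = FALSE)
  invisible(grid)
}

same_shape <- function(a, b) identical(dim(a$values), dim(b$values))

#' Read an ESRI ASCII grid
#'
#' Parses the standard six-line header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, `nodata_value`; keys case-insensitive, the nodata
#' line optional per the format) followed by whitespace-separated rows, north
#' first. Cells equal to the nodata sentinel come back as `NA`.
#'
#' @param path path to a `.asc` file.
#' @return A [raster_grid()].
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- list()
  i <- 1L
  while (i <= length(lines)) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (!(key %in% c("ncols", "nrows", "xllcorner", "yllcorner",
                     "cellsize", "nodata_value"))) break
    if (length(parts) != 2L || is.na(suppressWarnings(as.numeric(parts[2]))))
      stop(sprintf("malformed ESRI ASCII header line %d: '%s'", i, lines[i]),
           call. = FALSE)
    hdr[[key]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  miss <- setdiff(need, names(hdr))
  if (length(miss))
    stop("ESRI ASCII header missing key(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  body <- lines[i:length(lines)]
  if (length(body) != nr)
    stop(sprintf("expected %d data rows, found %d", nr, length(body)),
         call. = FALSE)
  vals <- lapply(body, function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]]))
  lens <- lengths(vals)
  if (any(lens != nc))
    stop(sprintf("data row %d has %d values, expected %d",
                 which(lens != nc)[1], lens[lens != nc][1], nc), call. = FALSE)
  m <- matrix(unlist(vals), nrow = nr, ncol = nc, byrow = TRUE)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  m[m == nodata] <- NA_real_
  raster_grid(m, xll = hdr$xllcorner, yll = hdr$yllcorner,
              cell_size = hdr$cellsize, nodata_value = nodata)
}

#' Write an ESRI ASCII grid
#'
#' Header keys are written lowercase in canonical order; `NA` cells are
#' written as the grid's nodata sentinel. Values round-trip exactly for
#' integers and to full double precision (17 significant digits) otherwise.
#'
#' @param grid a [raster_grid()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path) {
  stopifnot_grid(grid)
  d <- dim(grid$values)
  m <- grid$values
  m[is.na(m)] <- grid$nodata_value
  fmt_row <- function(r) paste(vapply(r, format_num, ""), collapse = " ")
  hdr <- c(
    sprintf("ncols %d", d[2]),
    sprintf("nrows %d", d[1]),
    sprintf("xllcorner %s", format_num(grid$xll)),
    sprintf("yllcorner %s", format_num(grid$yll)),
    sprintf("cellsize %s", format_num(grid$cell_size)),
    sprintf("nodata_value %s", format_num(grid$nodata_value)))
  body <- apply(m, 1L, fmt_row)
  ok <- tryCatch({
    writeLines(c(hdr, body), con = path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write grid to ", path, call. = FALSE)
  invisible(path)
}

format_num <- function(x) {
  if (is.na(x)) return("NA")
  if (x == round(x) && abs(x) < 1e15)
    return(format(x, scientific = FALSE, trim = TRUE, nsmall = 0))
  format(x, digits = 17, scientific = FALSE, trim = TRUE)
}

#' Sum of a grid's values, ignoring nodata
#' @param grid a [raster_grid()].
#' @return scalar sum over non-nodata cells.
#' @export
grid_sum <- function(grid) {
  stopifnot_grid(grid)
  sum(grid$values, na.rm = TRUE)
}
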