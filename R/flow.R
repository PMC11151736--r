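# D8 terrain routing: pit filling, flow directions, topological order.
# Cells are addressed by 1-based (row, col) from the northwest corner, or by
# the R column-major linear index into the value matrix.

# neighbor order fixes D8 tie-breaking: first maximal drop wins
D8_DR <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)   # E SE S SW W NW N NE
D8_DC <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
D8_NAMES <- c("E", "SE", "S", "SW", "W", "NW", "N", "NE")

rc_to_idx <- function(r, c, nr) (c - 1L) * nr + r
idx_to_r <- function(i, nr) (i - 1L) %% nr + 1L
idx_to_c <- function(i, nr) (i - 1L) %/% nr + 1L

#' Fill depressions in a DEM
#'
#' Priority-flood pit filling: water level rises from the grid boundary (and
#' from cells adjacent to nodata holes) inward, raising every cell to at
#' least the level of its lowest exit path plus a strictly increasing epsilon
#' (1e-6 m) across flats, so that every cell afterwards has a monotonically
#' strictly descending 8-neighbor path to the boundary.
#'
#' @param dem a [raster_grid()] of elevations (m).
#' @param eps elevation increment applied along flats (m).
#' @return A [raster_grid()] with `filled >= dem` everywhere.
#' @export
fill_pits <- function(dem, eps = 1e-6) {
  stopifnot_grid(dem)
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z); n <- nr * nc
  if (all(is.na(z))) stop("DEM is all nodata", call. = FALSE)
  filled <- as.vector(z)
  closed <- is.na(filled)
  # seed: valid cells on the outer edge or touching a nodata hole
  edge <- matrix(FALSE, nr, nc)
  edge[1, ] <- TRUE; edge[nr, ] <- TRUE; edge[, 1] <- TRUE; edge[, nc] <- TRUE
  seed <- (as.vector(edge) | touches_nodata(z)) & !closed
  pri <- rep(Inf, n)
  pri[seed] <- filled[seed]
  repeat {
    i <- which.min(pri)
    if (!is.finite(pri[i])) break
    lvl <- pri[i]
    pri[i] <- Inf
    if (closed[i]) next
    closed[i] <- TRUE
    filled[i] <- lvl
    r <- idx_to_r(i, nr); cc <- idx_to_c(i, nr)
    for (k in 1:8) {
      r2 <- r + D8_DR[k]; c2 <- cc + D8_DC[k]
      if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
      j <- rc_to_idx(r2, c2, nr)
      if (closed[j]) next
      cand <- max(filled[j], lvl + eps)
      if (cand < pri[j]) pri[j] <- cand
    }
  }
  out <- dem
  out$values <- matrix(filled, nr, nc)
  out
}

touches_nodata <- function(z) {
  nr <- nrow(z); nc <- ncol(z)
  bad <- is.na(z)
  if (!any(bad)) return(rep(FALSE, nr * nc))
  near <- matrix(FALSE, nr, nc)
  for (k in 1:8) {
    sh <- shift_matrix(bad, D8_DR[k], D8_DC[k], fill = FALSE)
    near <- near | sh
  }
  as.vector(near & !bad)
}

# shift a matrix so that entry (r,c) holds m[r+dr, c+dc]; out-of-grid = fill
shift_matrix <- function(m, dr, dc, fill = NA) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  r_lo <- max(1L, 1L - dr); r_hi <- min(nr, nr - dr)
  c_lo <- max(1L, 1L - dc); c_hi <- min(nc, nc - dc)
  if (r_lo > r_hi || c_lo > c_hi) return(out)
  rs <- r_lo:r_hi; cs <- c_lo:c_hi
  out[rs, cs] <- m[rs + dr, cs + dc]
  out
}

#' Compute D8 flow directions from a pit-filled DEM
#'
#' Each cell drains to the 8-neighbor with the steepest descent gradient
#' (elevation drop over distance; diagonal distance is `cell_size * sqrt(2)`).
#' Ties are broken deterministically in the fixed neighbor order E, SE, S,
#' SW, W, NW, N, NE. Cells with no lower neighbor must sit on the grid
#' boundary (or against a nodata hole); they are flow terminals. An interior
#' cell with no descent means the DEM was not pit-filled and is an error.
#'
#' @param dem a pit-filled [raster_grid()].
#' @return A `flow_field`: list with `downstream` (linear index of the
#'   successor, `NA` for terminals and nodata), `direction` (1-8 neighbor
#'   code, 0 terminal), `order` (topological order, every cell before its
#'   successor), `elev` (the elevations used), `nr`, `nc`, `cell_size`.
#' @export
compute_d8 <- function(dem) {
  stopifnot_grid(dem)
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z); n <- nr * nc
  best_grad <- matrix(-Inf, nr, nc)
  best_dir <- matrix(0L, nr, nc)
  for (k in 1:8) {
    dist <- dem$cell_size * if (D8_DR[k] != 0L && D8_DC[k] != 0L) sqrt(2) else 1
    nb <- shift_matrix(z, D8_DR[k], D8_DC[k], fill = NA)
    grad <- (z - nb) / dist
    sel <- !is.na(grad) & grad > best_grad   # strict: earlier order wins ties
    best_grad[sel] <- grad[sel]
    best_dir[sel] <- k
  }
  valid <- !is.na(as.vector(z))
  descending <- as.vector(best_grad) > 0 & valid
  on_edge <- as.vector(row(z) == 1L | row(z) == nr |
                       col(z) == 1L | col(z) == nc) | touches_nodata(z)
  stuck <- valid & !descending & !on_edge
  if (any(stuck))
    stop(sprintf("unfilled pit or flat at interior cell (row %d, col %d); %s",
                 idx_to_r(which(stuck)[1], nr), idx_to_c(which(stuck)[1], nr),
                 "run fill_pits() first"), call. = FALSE)
  downstream <- rep(NA_integer_, n)
  dir <- rep(0L, n)
  ii <- which(descending)
  kk <- as.vector(best_dir)[ii]
  downstream[ii] <- rc_to_idx(idx_to_r(ii, nr) + D8_DR[kk],
                              idx_to_c(ii, nr) + D8_DC[kk], nr)
  dir[ii] <- kk
  # successors are strictly lower, so decreasing elevation is a topo order
  vv <- which(valid)
  order_topo <- vv[order(as.vector(z)[vv], decreasing = TRUE)]
  structure(list(downstream = downstream, direction = dir, order = order_topo,
                 elev = as.vector(z), nr = nr, nc = nc,
                 cell_size = dem$cell_size),
            class = "flow_field")
}

# terminal cell of every chain under a successor map (with path compression);
# succ[i] = NA means i is its own terminal. Errors on cycles.
chain_terminal <- function(succ) {
  n <- length(succ)
  term <- rep(NA_integer_, n)
  for (s in seq_len(n)) {
    if (!is.na(term[s])) next
    path <- integer(0)
    i <- s
    steps <- 0L
    while (is.na(term[i]) && !is.na(succ[i])) {
      path <- c(path, i)
      i <- succ[i]
      steps <- steps + 1L
      if (steps > n) stop("cycle detected in flow/pipe successors",
                          call. = FALSE)
    }
    t_end <- if (is.na(succ[i])) i else term[i]
    term[path] <- t_end
    term[i] <- t_end
  }
  term
}

#' Delineate the watershed draining to a pour point
#'
#' Marks every cell whose successor chain reaches the pour point. Storm-sewer
#' links extend the chain: an MS4 inlet's successor is its outfall
#' destination cell, and a CSS inlet's chain ends at the wastewater treatment
#' plant (outside every delineation).
#'
#' @param flow a `flow_field` from [compute_d8()].
#' @param pour_point `c(row, col)` of the pour point.
#' @param network optional `storm_network` (see [read_network_csv()]).
#' @return Logical matrix mask (`TRUE` = drains to the pour point).
#' @export
delineate <- function(flow, pour_point, network = NULL) {
  nr <- flow$nr
  pp <- rc_to_idx(pour_point[1], pour_point[2], nr)
  if (is.na(flow$elev[pp])) stop("pour point is a nodata cell", call. = FALSE)
  succ <- flow$downstream
  is_css <- rep(FALSE, length(succ))
  if (!is.null(network) && nrow(network) > 0) {
    idx <- network_indices(network, nr)
    css <- network$system_type == "CSS"
    succ[idx$inlet[!css]] <- idx$dest[!css]
    is_css[idx$inlet[css]] <- TRUE
  }
  # a cell is in the watershed iff its chain visits the pour point (which
  # need not be a terminal); CSS inlets divert the chain to the WWTP
  n <- length(succ)
  status <- rep(0L, n)   # 0 unknown, 1 reaches pour, 2 does not
  status[pp] <- 1L
  for (s in which(!is.na(flow$elev))) {
    if (status[s] != 0L) next
    path <- integer(0)
    i <- s
    steps <- 0L
    repeat {
      if (status[i] != 0L) { res <- status[i]; break }
      if (is_css[i]) { res <- 2L; break }
      path <- c(path, i)
      if (is.na(succ[i])) { res <- 2L; break }
      i <- succ[i]
      steps <- steps + 1L
      if (steps > n) stop("cycle detected in flow/pipe successors",
                          call. = FALSE)
    }
    status[path] <- res
    if (status[i] == 0L) status[i] <- res
  }
  matrix(status == 1L & !is.na(flow$elev), flow$nr, flow$nc)
}

#' Road cells chained upslope of a storm-drain inlet
#'
#' Daily deposition is restricted to street cells that drain, through an
#' unbroken chain of street cells, into a storm-drain inlet: a road cell is
#' in the mask iff following D8 successors visits only road cells until an
#' inlet cell is reached. Roads that never reach an inlet, roads whose chain
#' is interrupted by any non-road cell, and all other impervious surfaces
#' (parking lots, roofs) are excluded.
#'
#' @param flow a `flow_field`.
#' @param land_cover a [raster_grid()] of land-cover codes (1 = road).
#' @param network a `storm_network`; its inlet cells anchor the chains.
#' @return Logical matrix mask over the grid.
#' @export
upslope_of_inlet_mask <- function(flow, land_cover, network) {
  nr <- flow$nr
  lc <- as.vector(land_cover$values)
  is_road <- !is.na(lc) & lc == LC_ROAD
  is_inlet <- rep(FALSE, length(lc))
  if (nrow(network) > 0)
    is_inlet[network_indices(network, nr)$inlet] <- TRUE
  succ <- flow$downstream
  status <- rep(0L, length(lc))   # 0 unknown, 1 reaches inlet, 2 does not
  for (s in which(is_road)) {
    if (status[s] != 0L) next
    path <- integer(0)
    i <- s
    res <- 2L
    repeat {
      if (!is_road[i]) { res <- 2L; break }
      if (status[i] != 0L) { res <- status[i]; break }
      if (is_inlet[i]) { res <- 1L; break }
      path <- c(path, i)
      if (is.na(succ[i])) { res <- 2L; break }
      i <- succ[i]
    }
    if (is_road[i] && status[i] == 0L) status[i] <- res
    status[path] <- res
  }
  matrix(status == 1L & is_road, flow$nr, flow$nc)
}
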