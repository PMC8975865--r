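#' Aggregate a grid to a coarser resolution
#'
#' Block-mean aggregation (the standard raster "Aggregate" behaviour):
#' every output cell is the mean of the non-nodata input cells in its
#' block; a fully-nodata block stays nodata. The target cell size must be
#' an integer multiple of the input cell size — resampling between
#' non-nested grids is out of scope. Partial blocks at the south/east
#' edges use the cells available.
#'
#' @param grid an [elev_grid()].
#' @param target_cell target cell size (m), an integer multiple of
#'   `grid$cell_size`.
#' @return an [elev_grid()] at the coarser resolution.
#' @export
aggregate_to_resolution <- function(grid, target_cell) {
  f <- target_cell / grid$cell_size
  if (abs(f - round(f)) > 1e-9 || round(f) < 1)
    stop("target_cell (", target_cell,
         ") is not an integer multiple of the grid cell size (",
         grid$cell_size, ")")
  f <- as.integer(round(f))
  if (f == 1L) return(grid)
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v)
  nro <- ceiling(nr / f); nco <- ceiling(nc / f)
  bi <- (seq_len(nr) - 1L) %/% f + 1L
  bj <- (seq_len(nc) - 1L) %/% f + 1L
  blk <- bi[row(v)] + (bj[col(v)] - 1L) * nro
  ok <- is.finite(v)
  sums <- rep(0, nro * nco); cnts <- rep(0L, nro * nco)
  s <- tapply(v[ok], blk[ok], sum)
  n <- tapply(rep(1L, sum(ok)), blk[ok], sum)
  sums[as.integer(names(s))] <- s
  cnts[as.integer(names(n))] <- n
  out <- matrix(NA_real_, nro, nco)
  has <- cnts > 0
  out[has] <- sums[has] / cnts[has]
  # origin: top-left (north-west) corner is preserved; with partial south
  # blocks the south edge extends, so recompute origin_y from the top
  top_y <- grid$origin_y + nr * grid$cell_size
  elev_grid(out, cell_size = target_cell, origin_x = grid$origin_x,
            origin_y = top_y - nro * target_cell, nodata = grid$nodata)
}

#' Fill nodata gaps from the nearest valid neighbour
#'
#' Every in-mask nodata cell takes the value of the Euclidean-nearest
#' in-mask non-nodata cell (pure nearest-neighbour, no averaging, so
#' carved channel walls are not smoothed). Equidistant donors are resolved
#' deterministically to the one with the smallest row index, then the
#' smallest column. Cells outside the mask are untouched.
#'
#' @param grid an [elev_grid()].
#' @param mask logical marsh/area mask aligned with `grid`.
#' @return an [elev_grid()] with no in-mask nodata.
#' @export
fill_nodata_nearest <- function(grid, mask) {
  check_aligned(grid, mask)
  donors <- mask & is.finite(grid$values)
  if (!any(donors))
    stop("cannot fill gaps: mask contains no non-nodata cell")
  holes <- mask & !is.finite(grid$values)
  if (!any(holes)) return(grid)
  ed <- edt_nearest_cpp(donors)
  v <- grid$values
  v[holes] <- grid$values[ed$index[holes]]
  out <- grid
  out$values <- v
  out
}

#' Delimit the marsh catchment below HAT
#'
#' The landward limit of the studied saltmarsh is the local Highest
#' Astronomical Tide: cells with `z < hat` are candidates, optionally
#' intersected with a boundary polygon (e.g. the seawall/seaward limits),
#' and the largest 8-connected region — the scheme's catchment — is kept.
#'
#' @param grid an [elev_grid()].
#' @param hat Highest Astronomical Tide (m, same datum as the grid).
#' @param boundary optional closed polygon, a two-column matrix of (x, y)
#'   vertices in grid coordinates; only cell centres inside it are kept.
#' @return logical marsh mask aligned with `grid`.
#' @export
crop_to_marsh <- function(grid, hat, boundary = NULL) {
  v <- grid$values
  cand <- is.finite(v) & v < hat
  if (!is.null(boundary)) {
    boundary <- as.matrix(boundary)
    xs <- cell_x(grid, col(v))
    ys <- cell_y(grid, row(v))
    inside <- point_in_polygon(as.vector(xs), as.vector(ys),
                               boundary[, 1], boundary[, 2])
    cand <- cand & matrix(inside, nrow(v), ncol(v))
  }
  if (!any(cand)) {
    rng <- range(v[is.finite(v)])
    stop(sprintf(
      "no cells below HAT = %.3f m (grid elevation range [%.3f, %.3f] m)",
      hat, rng[1], rng[2]))
  }
  lab <- label_components_cpp(cand)
  sizes <- tabulate(lab[lab > 0])
  lab == which.max(sizes)
}

#' Read a boundary polygon
#'
#' Either whitespace-delimited `x y` vertex pairs (one per line, ring
#' closed implicitly) or a JSON array of `[x, y]` pairs.
#'
#' @param path file path.
#' @return two-column matrix of vertex coordinates for [crop_to_marsh()].
#' @export
read_boundary <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (grepl("^\\s*\\[", paste(txt, collapse = ""))) {
    m <- jsonlite::fromJSON(paste(txt, collapse = "\n"))
    m <- as.matrix(m)
  } else {
    m <- as.matrix(utils::read.table(path, col.names = c("x", "y")))
  }
  if (ncol(m) != 2 || nrow(m) < 3)
    stop("boundary file must contain at least three x,y vertex pairs")
  m
}

# Even-odd ray-casting point-in-polygon test; points on an edge count as
# inside often enough for cell-centre cropping purposes.
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  if (vx[1] == vx[n] && vy[1] == vy[n]) { vx <- vx[-n]; vy <- vy[-n]; n <- n - 1L }
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Slope map in degrees (Horn 3x3 operator)
#'
#' The Horn finite-difference operator (the classic GIS "Slope" tool):
#' with the 3x3 window `a b c / d e f / g h i` (north row first),
#' `dz/dx = ((c + 2f + i) - (a + 2d + g)) / (8 s)` and
#' `dz/dy = ((g + 2h + i) - (a + 2b + c)) / (8 s)` for cell size `s`;
#' slope is `atan(sqrt(dz/dx^2 + dz/dy^2))` in degrees. Edge cells use
#' reflected padding; any window containing nodata yields nodata.
#'
#' @param grid an [elev_grid()] with at least 3x3 cells.
#' @return an [elev_grid()]-shaped object of class `slope_grid` whose
#'   values are slopes in degrees (0–90).
#' @export
compute_slope_degrees <- function(grid) {
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v)
  if (nr < 3 || nc < 3) stop("slope needs a grid of at least 3x3 cells")
  # reflected padding
  p <- rbind(v[2, ], v, v[nr - 1, ])
  p <- cbind(p[, 2], p, p[, nc - 1])
  w <- function(dr, dc) p[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  a <- w(-1, -1); b <- w(-1, 0); cc_ <- w(-1, 1)
  d <- w(0, -1);                 f <- w(0, 1)
  g <- w(1, -1);  h <- w(1, 0);  i <- w(1, 1)
  s8 <- 8 * grid$cell_size
  dzdx <- ((cc_ + 2 * f + i) - (a + 2 * d + g)) / s8
  dzdy <- ((g + 2 * h + i) - (a + 2 * b + cc_)) / s8
  slope <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  bad <- !is.finite(a) | !is.finite(b) | !is.finite(cc_) | !is.finite(d) |
    !is.finite(v) | !is.finite(f) | !is.finite(g) | !is.finite(h) |
    !is.finite(i)
  slope[bad] <- NA_real_
  out <- grid
  out$values <- slope
  class(out) <- c("slope_grid", "elev_grid")
  out
}
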