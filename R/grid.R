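#' Gridded elevation container
#'
#' An `elev_grid` is a light S3 wrapper around a numeric matrix of
#' elevations in metres (ODN-like vertical datum). Row 1 is the
#' northernmost row, matching the on-disk Esri ASCII grid order; column 1
#' is the westernmost column. Cells missing data are stored as `NA`
#' internally; the `nodata` sentinel is only used on disk.
#'
#' @param values numeric matrix of elevations (m); `NA` marks missing cells.
#' @param cell_size positive cell edge length (m).
#' @param origin_x,origin_y coordinates (m) of the *lower-left corner* of
#'   the grid (corner convention, not cell centre).
#' @param nodata sentinel written for missing cells on export.
#' @param max_abs plausibility bound on `|z|`; values beyond it are rejected.
#' @return an object of class `elev_grid`.
#' @export
elev_grid <- function(values, cell_size, origin_x = 0, origin_y = 0,
                      nodata = -9999,
                      max_abs = getOption("creekmorph.max_abs_elevation", 100)) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cell_size) || length(cell_size) != 1L || !is.finite(cell_size) ||
      cell_size <= 0)
    stop("cell_size must be a single positive number")
  finite <- values[is.finite(values)]
  if (length(finite) && max(abs(finite)) >= max_abs)
    stop("implausible elevation values (|z| >= ", max_abs,
         " m); check units or nodata sentinel")
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
         nodata = as.numeric(nodata)),
    class = "elev_grid")
}

#' @export
print.elev_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<elev_grid> %d x %d cells, %.6g m cell size\n",
              nrow(v), ncol(v), x$cell_size))
  cat(sprintf("  origin (lower-left corner): (%.3f, %.3f)\n",
              x$origin_x, x$origin_y))
  ok <- is.finite(v)
  if (any(ok))
    cat(sprintf("  elevation range: [%.3f, %.3f] m, %d nodata cells\n",
                min(v[ok]), max(v[ok]), sum(!ok)))
  else cat("  all cells nodata\n")
  invisible(x)
}

#' @export
dim.elev_grid <- function(x) dim(x$values)

n_rows <- function(grid) nrow(grid$values)
n_cols <- function(grid) ncol(grid$values)

#' Cell-centre coordinates
#'
#' x of column `j` and y of row `i` under the corner-origin, north-up
#' convention (row 1 = northernmost).
#' @param grid an `elev_grid`.
#' @param i,j row / column indices.
#' @return numeric vector of coordinates (m).
#' @export
cell_x <- function(grid, j) grid$origin_x + (j - 0.5) * grid$cell_size

#' @rdname cell_x
#' @export
cell_y <- function(grid, i) grid$origin_y + (n_rows(grid) - i + 0.5) * grid$cell_size

check_aligned <- function(grid, mask, what = "mask") {
  if (!is.logical(mask) || !is.matrix(mask))
    stop(what, " must be a logical matrix")
  if (!identical(dim(mask), dim(grid$values)))
    stop(what, " (", paste(dim(mask), collapse = "x"),
         ") is not aligned with the grid (",
         paste(dim(grid$values), collapse = "x"), ")")
  invisible(TRUE)
}

# ---- Esri ASCII grid dialect --------------------------------------------

#' Read an Esri ASCII grid
#'
#' Parses the `.asc` dialect produced by "Raster to ASCII" exports: a
#' header of `ncols`, `nrows`, `xllcorner`/`xllcenter`,
#' `yllcorner`/`yllcenter`, `cellsize` and optional `nodata_value`
#' (case-insensitive), followed by `nrows` whitespace-separated data rows,
#' north row first. Centre-referenced origins are normalised to the corner
#' convention (shift by `cellsize / 2`). A missing `nodata_value` defaults
#' to -9999.
#'
#' @param path file path.
#' @return an [elev_grid()].
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- list()
  i <- 1L
  while (i <= length(lines)) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (!(key %in% c("ncols", "nrows", "xllcorner", "xllcenter",
                     "yllcorner", "yllcenter", "cellsize", "nodata_value")))
      break
    if (length(parts) != 2L || is.na(suppressWarnings(as.numeric(parts[2]))))
      stop("malformed ASCII grid header at key '", parts[1], "' in ", path)
    hdr[[key]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  for (key in c("ncols", "nrows", "cellsize"))
    if (is.null(hdr[[key]]))
      stop("ASCII grid header missing required key '", key, "' in ", path)
  if (is.null(hdr$xllcorner) && is.null(hdr$xllcenter))
    stop("ASCII grid header missing required key 'xllcorner' in ", path)
  if (is.null(hdr$yllcorner) && is.null(hdr$yllcenter))
    stop("ASCII grid header missing required key 'yllcorner' in ", path)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  cs <- hdr$cellsize
  if (cs <= 0) stop("malformed ASCII grid header at key 'cellsize': must be > 0")
  ox <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else hdr$xllcenter - cs / 2
  oy <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else hdr$yllcenter - cs / 2
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  body <- lines[i:length(lines)]
  if (length(body) != nr)
    stop("ASCII grid has ", length(body), " data rows, header says ", nr)
  vals <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    row <- suppressWarnings(as.numeric(strsplit(trimws(body[r]), "\\s+")[[1]]))
    if (length(row) != nc || anyNA(row))
      stop("ASCII grid row ", r, " has ", length(row),
           " values, expected ", nc)
    vals[r, ] <- row
  }
  vals[vals == nodata] <- NA_real_
  elev_grid(vals, cell_size = cs, origin_x = ox, origin_y = oy, nodata = nodata)
}

#' Write an Esri ASCII grid
#'
#' Inverse of [read_ascii_grid()]; values are printed with `digits` decimal
#' places, so a read-back reproduces the grid at that printed precision.
#'
#' @param grid an [elev_grid()].
#' @param path output path.
#' @param digits decimal places for elevations (default 3).
#' @export
write_ascii_grid <- function(grid, path, digits = 3) {
  v <- grid$values
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(v)),
    paste("nrows", nrow(v)),
    paste("xllcorner", format(grid$origin_x, scientific = FALSE)),
    paste("yllcorner", format(grid$origin_y, scientific = FALSE)),
    paste("cellsize", format(grid$cell_size, scientific = FALSE)),
    paste("NODATA_value", format(grid$nodata, scientific = FALSE))), con)
  out <- v
  out[!is.finite(out)] <- grid$nodata
  txt <- apply(out, 1, function(row)
    paste(formatC(row, format = "f", digits = digits), collapse = " "))
  writeLines(txt, con)
  invisible(path)
}

# ---- XYZ dialect ---------------------------------------------------------

#' Export masked cells as XYZ text
#'
#' Writes one `x y z` line per masked, non-nodata cell with 3-decimal
#' coordinates of the cell centre, in row-major (north row first, west to
#' east) order, matching the site-map text dialect.
#'
#' @param grid an [elev_grid()].
#' @param mask logical matrix aligned with `grid`.
#' @param path output path.
#' @param digits decimal places (default 3).
#' @export
write_xyz <- function(grid, mask, path, digits = 3) {
  check_aligned(grid, mask)
  keep <- mask & is.finite(grid$values)
  if (!any(keep)) stop("empty mask: nothing to export as XYZ")
  idx <- which(t(keep))  # row-major order
  nc <- n_cols(grid)
  j <- (idx - 1L) %% nc + 1L
  i <- (idx - 1L) %/% nc + 1L
  z <- grid$values[cbind(i, j)]
  txt <- paste(formatC(cell_x(grid, j), format = "f", digits = digits),
               formatC(cell_y(grid, i), format = "f", digits = digits),
               formatC(z, format = "f", digits = digits))
  writeLines(txt, path)
  invisible(path)
}

#' Read XYZ text
#'
#' @param path file of whitespace-delimited `x y z` lines.
#' @return data frame with columns `x`, `y`, `z`.
#' @export
read_xyz <- function(path) {
  df <- utils::read.table(path, col.names = c("x", "y", "z"))
  df
}

#' Merge overlapping grid mosaics
#'
#' Tiles must share a cell size and be on the same cell lattice. The output
#' covers the union extent; where tiles overlap, the *last* grid in the
#' (lexically ordered, if named) list wins, and the number of overwritten
#' cells is reported via a message.
#'
#' @param grids list of [elev_grid()] tiles; if named, processed in lexical
#'   name order.
#' @return a single [elev_grid()].
#' @export
merge_grids <- function(grids) {
  stopifnot(length(grids) >= 1L)
  if (!is.null(names(grids)) && all(nzchar(names(grids))))
    grids <- grids[order(names(grids))]
  cs <- grids[[1]]$cell_size
  for (g in grids) {
    if (g$cell_size != cs) stop("mosaic tiles disagree on cell size")
    if (abs((g$origin_x - grids[[1]]$origin_x) / cs -
            round((g$origin_x - grids[[1]]$origin_x) / cs)) > 1e-6 ||
        abs((g$origin_y - grids[[1]]$origin_y) / cs -
            round((g$origin_y - grids[[1]]$origin_y) / cs)) > 1e-6)
      stop("mosaic tiles are not on a common cell lattice")
  }
  x0 <- min(vapply(grids, function(g) g$origin_x, 0))
  y0 <- min(vapply(grids, function(g) g$origin_y, 0))
  x1 <- max(vapply(grids, function(g) g$origin_x + n_cols(g) * cs, 0))
  y1 <- max(vapply(grids, function(g) g$origin_y + n_rows(g) * cs, 0))
  nc <- as.integer(round((x1 - x0) / cs))
  nr <- as.integer(round((y1 - y0) / cs))
  vals <- matrix(NA_real_, nr, nc)
  overwritten <- 0L
  for (g in grids) {
    joff <- as.integer(round((g$origin_x - x0) / cs))
    # row 1 is north: offset from the top of the union extent
    ioff <- as.integer(round((y1 - (g$origin_y + n_rows(g) * cs)) / cs))
    ii <- ioff + seq_len(n_rows(g)); jj <- joff + seq_len(n_cols(g))
    sub <- vals[ii, jj, drop = FALSE]
    new <- g$values
    overwritten <- overwritten + sum(is.finite(sub) & is.finite(new))
    sub[is.finite(new)] <- new[is.finite(new)]
    vals[ii, jj] <- sub
  }
  if (overwritten > 0)
    message("merge_grids: ", overwritten,
            " overlapping cells resolved last-tile-wins")
  elev_grid(vals, cell_size = cs, origin_x = x0, origin_y = y0,
            nodata = grids[[1]]$nodata)
}
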