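#' Specification of a synthetic marsh
#'
#' Parametric description of a marsh platform ringed by a seawall, with
#' one dendritic creek tree carved inward from each seawall breach. The
#' defaults emulate the situations the extraction workflow assumes: a
#' low-relief vegetated platform, creeks lying lower than the platform
#' with steep banks, lidar-like Gaussian vertical noise (sigma 0.15 m, the
#' nominal lidar vertical resolution) at 1 m cells, and optional nodata
#' speckle from residual water.
#'
#' Channel widths, depths and segment lengths are given per reverse
#' Strahler order (entry channel first) and must be non-increasing with
#' order. Tree geometry is deterministic given the spec: each channel
#' spawns `branching_factor` children on alternating sides at
#' `branch_angle` degrees, attached at fixed fractions of the parent
#' length chosen so the parent always remains the longest path from its
#' root — the generated orders are therefore the reverse-Strahler ground
#' truth by construction.
#'
#' @param n_rows,n_cols grid shape (cells).
#' @param cell_size cell size (m, default 1).
#' @param platform_elevation marsh platform elevation (m).
#' @param seawall_elevation seawall crest elevation (m).
#' @param wall_thickness seawall thickness (cells).
#' @param hat Highest Astronomical Tide (m); delimits the marsh.
#' @param breach_cols columns of the breach centres on the southern wall.
#' @param tree_depth number of reverse-Strahler orders (1..depth).
#' @param branching_factor children per channel.
#' @param widths,depths,lengths per-order channel width (m), depth below
#'   platform (m) and centreline length (m); non-increasing with order.
#' @param branch_angle branching angle off the parent direction (deg).
#' @param sinuosity_amplitude lateral sine amplitude (m, 0 = straight).
#' @param profile `"rectangular"` or `"parabolic"` cross-section.
#' @param noise_sigma vertical Gaussian noise sd (m, default 0.15).
#' @param nodata_fraction fraction of cells blanked to nodata.
#' @param seed RNG seed; fixed seed gives bit-identical output.
#' @return an object of class `marsh_spec`.
#' @export
marsh_spec <- function(n_rows = 420, n_cols = 420, cell_size = 1,
                       platform_elevation = 2.0, seawall_elevation = 5.0,
                       wall_thickness = 3, hat = 2.5,
                       breach_cols = NULL, tree_depth = 3,
                       branching_factor = 2,
                       widths = c(7, 5, 3), depths = c(1.2, 0.9, 0.6),
                       lengths = c(260, 80, 26), branch_angle = 45,
                       sinuosity_amplitude = 0,
                       profile = c("rectangular", "parabolic"),
                       noise_sigma = 0.15, nodata_fraction = 0, seed = 1) {
  profile <- match.arg(profile)
  if (is.null(breach_cols)) breach_cols <- round(n_cols / 2)
  if (length(widths) < tree_depth || length(depths) < tree_depth ||
      length(lengths) < tree_depth)
    stop("widths, depths and lengths must each have one value per order")
  if (any(diff(widths[seq_len(tree_depth)]) > 0) ||
      any(diff(depths[seq_len(tree_depth)]) > 0))
    stop("channel widths and depths must be non-increasing with order")
  if (noise_sigma < 0 || nodata_fraction < 0 || nodata_fraction >= 1)
    stop("invalid noise_sigma or nodata_fraction")
  structure(list(n_rows = n_rows, n_cols = n_cols, cell_size = cell_size,
                 platform_elevation = platform_elevation,
                 seawall_elevation = seawall_elevation,
                 wall_thickness = wall_thickness, hat = hat,
                 breach_cols = breach_cols, tree_depth = tree_depth,
                 branching_factor = branching_factor,
                 widths = widths, depths = depths, lengths = lengths,
                 branch_angle = branch_angle,
                 sinuosity_amplitude = sinuosity_amplitude,
                 profile = profile, noise_sigma = noise_sigma,
                 nodata_fraction = nodata_fraction, seed = seed),
            class = "marsh_spec")
}

# Build channel polylines recursively; coordinates are continuous
# (row, col) with row increasing southward. Returns a list of channels:
# list(order, poly (n x 2), width, depth, length_m).
build_tree <- function(spec, start, dir, order) {
  len_cells <- spec$lengths[order] / spec$cell_size
  s <- seq(0, len_cells, by = 0.25)
  amp <- spec$sinuosity_amplitude / spec$cell_size
  lat <- if (amp > 0) amp * sin(2 * pi * s / (len_cells / 2)) else rep(0, length(s))
  nrm <- c(dir[2], -dir[1])  # left normal
  poly <- cbind(start[1] + s * dir[1] + lat * nrm[1],
                start[2] + s * dir[2] + lat * nrm[2])
  arc <- sum(sqrt(diff(poly[, 1])^2 + diff(poly[, 2])^2)) * spec$cell_size
  ch <- list(list(order = order, poly = poly, width = spec$widths[order],
                  depth = spec$depths[order], length_m = arc))
  if (order < spec$tree_depth && spec$branching_factor >= 1) {
    fr <- seq(0.3, 0.5, length.out = spec$branching_factor)
    ang <- spec$branch_angle * pi / 180
    for (i in seq_len(spec$branching_factor)) {
      side <- if (i %% 2 == 1) 1 else -1
      f <- fr[i]
      # subtree longest path must stay shorter than the remaining parent
      child_path <- sum(spec$lengths[(order + 1):spec$tree_depth])
      if (child_path >= (1 - f) * spec$lengths[order])
        stop("marsh_spec: child subtree at order ", order + 1,
             " would outgrow its parent; shorten `lengths`")
      j <- start + f * len_cells * dir
      ca <- cos(side * ang); sa <- sin(side * ang)
      cdir <- c(dir[1] * ca - dir[2] * sa, dir[1] * sa + dir[2] * ca)
      ch <- c(ch, build_tree(spec, j, cdir, order + 1L))
    }
  }
  ch
}

#' Generate a synthetic marsh with known creek ground truth
#'
#' Builds the platform, seawall and breaches, carves the dendritic creek
#' trees (deterministic geometry), then applies Gaussian elevation noise
#' and nodata speckle. Everything structural is recorded pre-noise in the
#' ground-truth object.
#'
#' @param spec a [marsh_spec()].
#' @return list with `grid` (an [elev_grid()]), `marsh` (logical mask of
#'   the catchment below HAT, pre-noise), and `truth`: per-channel records
#'   (`order`, `width`, `depth`, `length_m`), `mask` (carved creek cells,
#'   pre-noise), `tcl_m`, `order_counts`, `dd_km_km2`, `marsh_area_m2`,
#'   and `config`, a [detection_config()] matched to the carved geometry.
#' @export
generate_marsh <- function(spec) {
  stopifnot(inherits(spec, "marsh_spec"))
  nr <- spec$n_rows; nc <- spec$n_cols; cs <- spec$cell_size
  z <- matrix(spec$platform_elevation, nr, nc)
  wt <- spec$wall_thickness
  z[c(seq_len(wt), (nr - wt + 1):nr), ] <- spec$seawall_elevation
  z[, c(seq_len(wt), (nc - wt + 1):nc)] <- spec$seawall_elevation
  channels <- list()
  for (bc in spec$breach_cols) {
    # entry channel runs due north from the southern wall
    channels <- c(channels,
                  build_tree(spec, start = c(nr, bc), dir = c(-1, 0),
                             order = 1L))
  }
  # carve: per channel, cells within width/2 of the centreline
  mask <- matrix(FALSE, nr, nc)
  for (ch in channels) {
    line <- matrix(FALSE, nr, nc)
    rr <- pmin(pmax(as.integer(round(ch$poly[, 1])), 1L), nr)
    cc <- pmin(pmax(as.integer(round(ch$poly[, 2])), 1L), nc)
    line[cbind(rr, cc)] <- TRUE
    ed <- edt_nearest_cpp(line)
    r_cells <- (ch$width / cs - 1) / 2
    band <- sqrt(ed$dist2) <= r_cells + 1e-9
    if (spec$profile == "rectangular") {
      bed <- spec$platform_elevation - ch$depth
      z[band] <- pmin(z[band], bed)
    } else {
      dfrac <- sqrt(ed$dist2[band]) / max(r_cells, 0.5)
      bed <- spec$platform_elevation - ch$depth * (1 - dfrac^2)
      z[band] <- pmin(z[band], bed)
    }
    mask <- mask | band
  }
  # marsh mask from the pre-noise surface
  pre <- elev_grid(z, cs, nodata = -9999)
  marsh <- crop_to_marsh(pre, spec$hat)
  if (!any(mask & marsh))
    stop("marsh_spec produced no creek cells inside the marsh")
  order_counts <- tabulate(vapply(channels, function(ch) ch$order, 0L),
                           nbins = spec$tree_depth)
  tcl <- sum(vapply(channels, function(ch) ch$length_m, 0))
  area_m2 <- sum(marsh) * cs^2
  truth <- list(
    channels = lapply(channels, function(ch)
      list(order = ch$order, width = ch$width, depth = ch$depth,
           length_m = ch$length_m, poly = ch$poly)),
    mask = mask, order_counts = order_counts, tcl_m = tcl,
    marsh_area_m2 = area_m2,
    dd_km_km2 = (tcl / 1000) / (area_m2 / 1e6),
    # s_thresh above the seawall-toe Horn slope (~56 deg for a 3 m wall at
    # 1 m cells) so embankment faces never enter the candidate set; the
    # carved channels are caught by the elevation term alone
    config = detection_config(
      z_thresh = spec$platform_elevation - min(spec$depths[seq_len(spec$tree_depth)]) / 2,
      s_thresh = 60, min_component_px = 10, max_repair_dist = 5,
      z_tolerance = 0.15))
  # noise + nodata speckle, seed-reproducible and isolated from the caller
  if (spec$noise_sigma > 0 || spec$nodata_fraction > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(spec$seed)
    if (spec$noise_sigma > 0)
      z <- z + matrix(stats::rnorm(nr * nc, 0, spec$noise_sigma), nr, nc)
    if (spec$nodata_fraction > 0) {
      gaps <- stats::runif(nr * nc) < spec$nodata_fraction
      z[gaps] <- NA_real_
    }
  }
  list(grid = elev_grid(z, cs, nodata = -9999), marsh = marsh, truth = truth)
}

#' Blank random cells to nodata
#'
#' Emulates data gaps from residual water: sets a random fraction of cells
#' to nodata, reproducibly for a given seed.
#'
#' @param grid an [elev_grid()].
#' @param gap_fraction fraction of cells to blank, in `[0, 1)`.
#' @param seed RNG seed.
#' @return the degraded [elev_grid()].
#' @export
degrade <- function(grid, gap_fraction, seed = 1) {
  if (gap_fraction < 0 || gap_fraction >= 1)
    stop("gap_fraction must be in [0, 1)")
  if (gap_fraction == 0) return(grid)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  v <- grid$values
  v[stats::runif(length(v)) < gap_fraction] <- NA_real_
  out <- grid
  out$values <- v
  out
}
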