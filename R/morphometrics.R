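#' Sinuous and straight length of a pixel path
#'
#' Sinuous length is the along-pixel length (orthogonal steps count
#' `cell_size`, diagonal steps `sqrt(2) * cell_size`); straight length is
#' the Euclidean distance between the endpoints, floored at one cell so
#' the sinuosity ratio of closed or near-closed paths stays finite.
#'
#' @param path n x 2 matrix of (row, col) pixel coordinates, n >= 2.
#' @param cell_size cell size (m).
#' @return list with `sinuous_length`, `straight_length`,
#'   `sinuosity_ratio` (all m or dimensionless, sinuosity >= 1 up to
#'   rounding of the straight-length floor).
#' @export
segment_geometry <- function(path, cell_size = 1) {
  if (NROW(path) < 2) stop("degenerate 1-pixel path has no geometry")
  dr <- diff(path[, 1]); dc <- diff(path[, 2])
  sinuous <- sum(sqrt(dr^2 + dc^2)) * cell_size
  n <- nrow(path)
  straight <- sqrt((path[n, 1] - path[1, 1])^2 +
                   (path[n, 2] - path[1, 2])^2) * cell_size
  straight <- max(straight, cell_size)
  list(sinuous_length = sinuous, straight_length = straight,
       sinuosity_ratio = sinuous / straight)
}

#' Junction angle between a tributary and its parent channel
#'
#' The angle between the chord of the tributary's first `fit_len` pixels
#' from the junction and the chord of the parent's *downstream* direction
#' from the junction (toward the mouth). A perpendicular T-join gives 90
#' degrees; a tributary doubling back along the parent's upstream course
#' approaches 180.
#'
#' @param child_path pixel path oriented to start at the junction.
#' @param parent_down_path parent pixel path from the junction toward the
#'   mouth.
#' @param fit_len chord length in pixels (default 5).
#' @return angle in degrees, in (0, 180].
#' @export
junction_angle <- function(child_path, parent_down_path, fit_len = 5) {
  chord <- function(p) {
    k <- min(fit_len + 1L, nrow(p))
    c(p[k, 2] - p[1, 2], -(p[k, 1] - p[1, 1]))  # (x, y), north positive
  }
  v1 <- chord(child_path); v2 <- chord(parent_down_path)
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) return(NA_real_)
  acos(pmin(1, pmax(-1, sum(v1 * v2) / (n1 * n2)))) * 180 / pi
}

#' Channel cross-section at a station
#'
#' A transect is cast through the station perpendicular to the local
#' centreline chord (fitted over `fit_len` pixels each way) and sampled at
#' `cell_size / 2` steps, midpoint convention, outward on both sides until
#' the sample leaves the creek mask. The bank level is the mean elevation
#' of the two first out-of-mask cells; width is the in-mask extent of the
#' transect; depth is bank level minus the minimum elevation met; area is
#' the midpoint-rule integral of `max(0, bank - z)` over the in-mask
#' samples.
#'
#' @param grid an [elev_grid()].
#' @param mask logical creek mask.
#' @param path oriented pixel path of the segment or channel.
#' @param station index into `path`.
#' @param fit_len chord fit length (px).
#' @param max_half_width_px give up (station skipped, `NA`s returned) if
#'   the transect runs this many pixels without leaving the mask or exits
#'   the grid first.
#' @return named numeric `c(width, depth, area)` in m / m / m^2, all `NA`
#'   if the transect is invalid at this station.
#' @export
cross_section <- function(grid, mask, path, station, fit_len = 5,
                          max_half_width_px = 200) {
  bad <- c(width = NA_real_, depth = NA_real_, area = NA_real_)
  n <- nrow(path)
  if (station < 1 || station > n) stop("station outside the pixel path")
  a <- max(1L, station - fit_len); b <- min(n, station + fit_len)
  dx <- path[b, 2] - path[a, 2]
  dy <- path[b, 1] - path[a, 1]
  nrm <- sqrt(dx^2 + dy^2)
  if (nrm == 0) return(bad)
  # normal in (row, col) space
  ndr <- dx / nrm; ndc <- -dy / nrm
  cs <- grid$cell_size
  step <- 0.5
  r0 <- path[station, 1]; c0 <- path[station, 2]
  nr <- nrow(mask); nc <- ncol(mask)
  side <- function(sgn) {
    t_in <- 0
    zs <- numeric(0)
    k <- 1L
    repeat {
      t <- (k - 0.5) * step
      rr <- as.integer(floor(r0 + sgn * t * ndr + 0.5))
      cc <- as.integer(floor(c0 + sgn * t * ndc + 0.5))
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) return(NULL)  # exits grid
      if (!mask[rr, cc])
        return(list(t_exit = t, z_exit = grid$values[rr, cc],
                    t_in = t_in, zs = zs))
      zs <- c(zs, grid$values[rr, cc])
      t_in <- t
      k <- k + 1L
      if (t > max_half_width_px) return(NULL)
    }
  }
  s1 <- side(1); s2 <- side(-1)
  if (is.null(s1) || is.null(s2)) return(bad)
  bank <- mean(c(s1$z_exit, s2$z_exit), na.rm = TRUE)
  if (!is.finite(bank)) return(bad)
  width <- (s1$t_in + s2$t_in + step) * cs
  zin <- c(s1$zs, s2$zs, grid$values[r0, c0])
  zin <- zin[is.finite(zin)]
  depth <- if (length(zin)) bank - min(zin) else NA_real_
  area <- sum(pmax(0, bank - c(s1$zs, s2$zs)), na.rm = TRUE) * step * cs
  c(width = width, depth = depth, area = area)
}

#' Mean cross-section statistics along a path
#'
#' Stations every `spacing` pixels, excluding `fit_len` pixels at each end
#' (around junctions, where transects would cut the confluence). Means are
#' over the stations with a valid transect.
#'
#' @inheritParams cross_section
#' @param spacing station spacing (px).
#' @return list `mean_width`, `mean_depth`, `mean_xs_area`, `n_stations`
#'   (valid stations); all-`NA` with `n_stations = 0` when no station fits
#'   or none is valid.
#' @export
segment_cross_stats <- function(grid, mask, path, spacing = 5, fit_len = 5) {
  n <- nrow(path)
  none <- list(mean_width = NA_real_, mean_depth = NA_real_,
               mean_xs_area = NA_real_, n_stations = 0L)
  lo <- fit_len + 1L; hi <- n - fit_len
  if (n <= spacing || lo > hi) {
    # short segment: fall back to its midpoint so narrow tributaries still
    # report a cross-section when geometry allows
    stations <- if (n >= 3L) as.integer(ceiling(n / 2)) else integer(0)
  } else {
    stations <- seq(lo, hi, by = spacing)
  }
  if (!length(stations)) return(none)
  xs <- vapply(stations, function(st)
    cross_section(grid, mask, path, st, fit_len = fit_len), numeric(3))
  ok <- is.finite(xs["area", ])
  if (!any(ok)) return(none)
  list(mean_width = mean(xs["width", ok]),
       mean_depth = mean(xs["depth", ok]),
       mean_xs_area = mean(xs["area", ok]),
       n_stations = sum(ok))
}

# Per-channel metric table used by order_stats and network_summary.
channel_metrics <- function(net, grid, mask, spacing = 5, fit_len = 5) {
  if (!length(net$channels)) return(NULL)
  mask <- unclass_mask(mask)
  rows <- lapply(net$channels, function(ch) {
    p <- channel_path(net, ch)
    geo <- segment_geometry(p, net$cell_size)
    xs <- segment_cross_stats(grid, mask, p, spacing = spacing,
                              fit_len = fit_len)
    ang <- NA_real_
    if (!is.na(ch$parent)) {
      par <- net$channels[[ch$parent]]
      pp <- channel_path(net, par)
      j <- which(pp[, 1] == p[1, 1] & pp[, 2] == p[1, 2])[1]
      if (!is.na(j) && j > 1)
        ang <- junction_angle(p, pp[j:1, , drop = FALSE], fit_len = fit_len)
    }
    data.frame(channel = ch$id, order = ch$order, parent = ch$parent,
               sinuous_length = geo$sinuous_length,
               straight_length = geo$straight_length,
               sinuosity = geo$sinuosity_ratio,
               junction_angle = ang,
               mean_width = xs$mean_width, mean_depth = xs$mean_depth,
               mean_xs_area = xs$mean_xs_area,
               head_row = ch$far_row, head_col = ch$far_col)
  })
  do.call(rbind, rows)
}

#' Per-order channel statistics
#'
#' Channels are merged chains of same-order segments. For each reverse
#' Strahler order: channel count, total and mean sinuous length,
#' bifurcation ratio `N(k+1) / N(k)` (reported on order k; `NA` for the
#' highest order), mean sinuosity, mean junction angle, mean width, depth
#' and cross-sectional area, plus the `area / depth^2` and
#' `width / depth` shape ratios.
#'
#' @param net an ordered network ([assign_reverse_strahler()]).
#' @param grid the [elev_grid()].
#' @param mask logical creek mask.
#' @param spacing,fit_len transect controls, see [segment_cross_stats()].
#' @return data frame, one row per order.
#' @export
order_stats <- function(net, grid, mask, spacing = 5, fit_len = 5) {
  cm <- channel_metrics(net, grid, mask, spacing = spacing,
                        fit_len = fit_len)
  if (is.null(cm)) return(NULL)
  orders <- sort(unique(cm$order))
  counts <- vapply(orders, function(k) sum(cm$order == k), 0L)
  rows <- lapply(seq_along(orders), function(i) {
    k <- orders[i]
    sub <- cm[cm$order == k, , drop = FALSE]
    wsum <- sum(sub$sinuous_length)
    data.frame(
      order = k,
      n_channels = nrow(sub),
      total_length = wsum,
      mean_length = mean(sub$sinuous_length),
      bifurcation_ratio = if (i < length(orders))
        counts[i + 1] / counts[i] else NA_real_,
      mean_sinuosity = mean(sub$sinuosity),
      mean_junction_angle = if (all(is.na(sub$junction_angle))) NA_real_
        else mean(sub$junction_angle, na.rm = TRUE),
      mean_width = mean(sub$mean_width, na.rm = TRUE),
      mean_depth = mean(sub$mean_depth, na.rm = TRUE),
      mean_xs_area = mean(sub$mean_xs_area, na.rm = TRUE))
  })
  out <- do.call(rbind, rows)
  out$area_over_depth2 <- out$mean_xs_area / out$mean_depth^2
  out$width_over_depth <- out$mean_width / out$mean_depth
  out
}

#' Overmarsh-path-length (unchanneled length) map
#'
#' Per-cell Euclidean distance (m) from every in-marsh cell to the nearest
#' creek-mask cell; creek cells are at distance 0, cells outside the marsh
#' are `NA`. The mean of this map over in-marsh non-creek cells is the
#' network's overmarsh path length.
#'
#' @param marsh logical marsh mask.
#' @param mask logical creek mask (must be non-empty).
#' @param cell_size cell size (m).
#' @return numeric matrix of distances (m).
#' @export
opl_map <- function(marsh, mask, cell_size = 1) {
  mask <- unclass_mask(mask)
  if (!any(mask)) stop("empty creek mask: overmarsh distances are undefined")
  ed <- edt_nearest_cpp(mask)
  out <- sqrt(ed$dist2) * cell_size
  out[!marsh] <- NA_real_
  out
}

#' Whole-network morphometric parameters
#'
#' Computes the standard creek-network record: drainage density DD
#' (total channel length / marsh area, km/km^2), overmarsh path length
#' OPL (mean distance of in-marsh non-creek cells to the creek system, m),
#' main channel length MCL (the order-1 channel connected to the largest
#' outlet, m), total channel length TCL (m), number of creeks NB (merged
#' channels, all orders), total mouth cross-sectional area CSA (m^2), main
#' channel mouth depth D (m), planform area PA (creek-mask area, m^2),
#' undermarsh tidal prism TP (creek volume below the local bank tops,
#' m^3), length-weighted mean sinuosity SR, main channel gradient MCG
#' (degrees, positive when the head lies above the mouth) and the mean
#' in-marsh elevation above Mean Water Spring.
#'
#' @param grid an [elev_grid()].
#' @param marsh logical marsh mask.
#' @param mask logical (repaired) creek mask.
#' @param net an ordered network with outlets.
#' @param tides optional [tidal_levels()]; without it the elevation above
#'   MWS is `NA`.
#' @param channel_table optional precomputed [channel_metrics()] table.
#' @return an object of class `network_metrics` (a named list).
#' @export
network_summary <- function(grid, marsh, mask, net, tides = NULL,
                            channel_table = NULL) {
  mask <- unclass_mask(mask)
  cs <- grid$cell_size
  area_m2 <- sum(marsh) * cs^2
  tcl <- sum(vapply(net$segments, function(s) s$length_m, 0))
  dd <- (tcl / 1000) / (area_m2 / 1e6)
  # OPL over in-marsh non-creek cells
  nonc <- marsh & !mask
  opl <- if (any(mask) && any(nonc)) {
    dm <- opl_map(marsh, mask, cs)
    mean(dm[nonc])
  } else 0
  cm <- if (is.null(channel_table)) channel_metrics(net, grid, mask) else
    channel_table
  main <- NULL
  if (!is.null(cm) && nrow(net$outlets)) {
    main_id <- which(vapply(net$channels, function(ch)
      ch$order == 1L && ch$root_node == net$outlets$node[1], TRUE))
    if (length(main_id)) main <- net$channels[[main_id[1]]]
  }
  mcl <- if (!is.null(main)) main$length_m else NA_real_
  nb <- length(net$channels)
  csa <- sum(net$outlets$mouth_area, na.rm = TRUE)
  d_mouth <- if (nrow(net$outlets)) net$outlets$mouth_depth[1] else NA_real_
  pa <- sum(mask) * cs^2
  # tidal prism: creek volume below the nearest bank-top elevation
  banks <- marsh & !mask
  tp <- NA_real_
  if (any(banks) && any(mask)) {
    ed <- edt_nearest_cpp(banks)
    cells <- which(mask)
    bank_ref <- grid$values[ed$index[cells]]
    z <- grid$values[cells]
    ok <- is.finite(bank_ref) & is.finite(z)
    tp <- sum(pmax(0, bank_ref[ok] - z[ok])) * cs^2
  }
  sr <- if (!is.null(cm) && nrow(cm))
    sum(cm$sinuosity * cm$sinuous_length) / sum(cm$sinuous_length) else
      NA_real_
  mcg <- NA_real_
  if (!is.null(main)) {
    p <- channel_path(net, main)
    z_mouth <- grid$values[p[1, 1], p[1, 2]]
    z_head <- grid$values[p[nrow(p), 1], p[nrow(p), 2]]
    if (is.finite(z_mouth) && is.finite(z_head) && mcl > 0)
      mcg <- atan((z_head - z_mouth) / mcl) * 180 / pi
  }
  zin <- grid$values[marsh]
  mean_elev <- mean(zin[is.finite(zin)])
  elev_mws <- if (!is.null(tides)) mean_elev - tides$mws else NA_real_
  if (is.null(tides))
    message("network_summary: no tidal levels supplied; ",
            "mean elevation above MWS omitted")
  structure(list(
    DD = dd, OPL = opl, MCL = mcl, TCL = tcl, NB = nb, CSA = csa,
    D = d_mouth, PA = pa, TP = tp, SR = sr, MCG = mcg,
    mean_elev_above_mws = elev_mws, catchment_area = area_m2),
    class = "network_metrics")
}

#' @export
print.network_metrics <- function(x, ...) {
  lab <- c(DD = "Drainage density (km/km^2)",
           OPL = "Overmarsh path length (m)",
           MCL = "Main channel length (m)",
           TCL = "Total channel length (m)",
           NB = "Number of creeks",
           CSA = "Total mouth cross-sectional area (m^2)",
           D = "Main channel mouth depth (m)",
           PA = "Planform area (m^2)",
           TP = "Undermarsh tidal prism (m^3)",
           SR = "Sinuosity ratio",
           MCG = "Main channel gradient (deg)",
           mean_elev_above_mws = "Mean elevation above MWS (m)",
           catchment_area = "Catchment area (m^2)")
  cat("<network_metrics>\n")
  for (nm in names(lab))
    cat(sprintf("  %-42s %s\n", lab[[nm]],
                ifelse(is.na(x[[nm]]), "NA", format(signif(x[[nm]], 6)))))
  invisible(x)
}

#' @export
as.data.frame.network_metrics <- function(x, ...) {
  data.frame(parameter = names(unclass(x)),
             value = unlist(x, use.names = FALSE))
}

#' Elevation change versus distance to the creeks
#'
#' Attributes vertical change between two co-registered epochs to creek
#' proximity: per in-marsh cell, `dz = z_t1 - z_t0`; cells that gained
#' elevation are binned by distance to the *most recent* (t1) creek
#' extent, cells that lost elevation by distance to the *initial* (t0)
#' extent, in bins of `bin` metres up to `max_dist`.
#'
#' @param grid_t0,grid_t1 co-registered [elev_grid()]s (same shape, cell
#'   size and origin).
#' @param marsh logical marsh mask.
#' @param mask_t0,mask_t1 creek masks at the two epochs.
#' @param max_dist maximum distance considered (m, default 20).
#' @param bin bin width (m, default 1).
#' @return data frame with `dist_lo`, `dist_hi`, `direction`
#'   (`"gain"`/`"loss"`), `mean_dz`, `n`.
#' @export
elevation_change_vs_distance <- function(grid_t0, grid_t1, marsh,
                                         mask_t0, mask_t1,
                                         max_dist = 20, bin = 1) {
  if (!identical(dim(grid_t0$values), dim(grid_t1$values)) ||
      grid_t0$cell_size != grid_t1$cell_size ||
      grid_t0$origin_x != grid_t1$origin_x ||
      grid_t0$origin_y != grid_t1$origin_y)
    stop("epoch grids are not co-registered")
  cs <- grid_t0$cell_size
  dz <- grid_t1$values - grid_t0$values
  ok <- marsh & is.finite(dz)
  d1 <- sqrt(edt_nearest_cpp(unclass_mask(mask_t1))$dist2) * cs
  d0 <- sqrt(edt_nearest_cpp(unclass_mask(mask_t0))$dist2) * cs
  edges <- seq(0, max_dist, by = bin)
  out <- list()
  for (i in seq_len(length(edges) - 1)) {
    lo <- edges[i]; hi <- edges[i + 1]
    gain <- ok & dz > 0 & d1 >= lo & d1 < hi
    loss <- ok & dz < 0 & d0 >= lo & d0 < hi
    out[[length(out) + 1]] <- data.frame(
      dist_lo = lo, dist_hi = hi, direction = "gain",
      mean_dz = if (any(gain)) mean(dz[gain]) else NA_real_,
      n = sum(gain))
    out[[length(out) + 1]] <- data.frame(
      dist_lo = lo, dist_hi = hi, direction = "loss",
      mean_dz = if (any(loss)) mean(dz[loss]) else NA_real_,
      n = sum(loss))
  }
  do.call(rbind, out)
}
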