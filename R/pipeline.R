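#' Run the full creek extraction and parametrisation workflow
#'
#' One call from elevation grid to ordered network and morphometrics:
#' optional marsh delimitation below HAT, gap filling, slope mapping,
#' threshold detection, noise filtering, fragment reconnection, thinning,
#' network building, outlet identification, reverse-Strahler ordering,
#' per-order statistics and the whole-network parameter record.
#'
#' @param grid an [elev_grid()].
#' @param cfg a [detection_config()]; `z_thresh` may be tidal-relative.
#' @param tides optional [tidal_levels()].
#' @param marsh optional precomputed marsh mask; if `NULL` it is derived
#'   with [crop_to_marsh()] from `hat` (or `tides$hat`).
#' @param hat HAT elevation (m) when `marsh` is `NULL` and no tides given.
#' @param boundary optional polygon passed to [crop_to_marsh()].
#' @param slope optional precomputed slope grid.
#' @param spacing,fit_len transect controls (px), see
#'   [segment_cross_stats()].
#' @return an object of class `creek_analysis`: the input pieces plus
#'   `masks` (raw/filtered/repaired), `skeleton`, `network`, `channels`
#'   (per-channel metric table), `order_stats` and `metrics`
#'   ([network_summary()]). If detection yields an empty mask the object
#'   carries empty results (`metrics = NULL`) and a warning is raised.
#' @export
creek_analysis <- function(grid, cfg, tides = NULL, marsh = NULL,
                           hat = NULL, boundary = NULL, slope = NULL,
                           spacing = 5, fit_len = 5) {
  stopifnot(inherits(grid, "elev_grid"), inherits(cfg, "detection_config"))
  if (is.null(marsh)) {
    if (is.null(hat)) {
      if (is.null(tides)) stop("need `marsh`, `hat` or `tides` to delimit the marsh")
      hat <- tides$hat
    }
    marsh <- crop_to_marsh(grid, hat, boundary)
  }
  check_aligned(grid, marsh, "marsh mask")
  if (any(marsh & !is.finite(grid$values)))
    grid <- fill_nodata_nearest(grid, marsh)
  if (is.null(slope)) slope <- compute_slope_degrees(grid)
  cfg$z_thresh <- resolve_z_thresh(cfg$z_thresh, tides)
  raw <- detect_creek_mask(grid, slope, marsh, cfg)
  out <- structure(list(grid = grid, marsh = marsh, cfg = cfg,
                        tides = tides, slope = slope,
                        masks = list(raw = raw, filtered = NULL,
                                     repaired = NULL),
                        skeleton = NULL, network = NULL, channels = NULL,
                        order_stats = NULL, metrics = NULL),
                   class = "creek_analysis")
  if (!any(raw)) return(out)
  filt <- filter_small_components(raw, cfg$min_component_px)
  out$masks$filtered <- filt
  if (!any(filt)) {
    warning("all creek components removed by the size filter")
    return(out)
  }
  rep_ <- reconnect_fragments(filt, cfg, cell_size = grid$cell_size)
  out$masks$repaired <- rep_
  skel <- skeletonize_mask(rep_)
  out$skeleton <- skel
  net <- build_network(skel, cell_size = grid$cell_size)
  if (!length(net$segments)) return(out)
  net <- identify_outlets(net, marsh, rep_, grid, fit_len = fit_len)
  net <- assign_reverse_strahler(net)
  out$network <- net
  out$channels <- channel_metrics(net, grid, rep_, spacing = spacing,
                                  fit_len = fit_len)
  out$order_stats <- order_stats(net, grid, rep_, spacing = spacing,
                                 fit_len = fit_len)
  out$metrics <- network_summary(grid, marsh, rep_, net, tides = tides,
                                 channel_table = out$channels)
  out
}

#' @export
print.creek_analysis <- function(x, ...) {
  cat("<creek_analysis>\n")
  cat(sprintf("  grid: %d x %d cells at %.6g m\n", nrow(x$grid$values),
              ncol(x$grid$values), x$grid$cell_size))
  cat(sprintf("  marsh area: %.0f m^2; creek planform: %.0f m^2\n",
              sum(x$marsh) * x$grid$cell_size^2,
              if (is.null(x$masks$repaired)) 0 else
                sum(x$masks$repaired) * x$grid$cell_size^2))
  if (!is.null(x$network)) print(x$network)
  if (is.null(x$metrics)) cat("  no network extracted\n")
  invisible(x)
}

#' @export
summary.creek_analysis <- function(object, ...) {
  print(object)
  if (!is.null(object$order_stats)) {
    cat("\nPer-order statistics:\n")
    print(object$order_stats, digits = 4, row.names = FALSE)
  }
  if (!is.null(object$metrics)) {
    cat("\n")
    print(object$metrics)
  }
  invisible(object)
}

#' Plot an extracted creek network
#'
#' Shaded elevation with the skeleton overlaid, coloured by reverse
#' Strahler order.
#'
#' @param x a [creek_analysis()] result.
#' @param ... passed to [graphics::image()].
#' @export
plot.creek_analysis <- function(x, ...) {
  v <- x$grid$values
  nr <- nrow(v); nc <- ncol(v)
  xs <- cell_x(x$grid, seq_len(nc))
  ys_asc <- sort(cell_y(x$grid, seq_len(nr)))
  graphics::image(xs, ys_asc, t(v[nr:1, , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "Terrain"),
                  xlab = "x (m)", ylab = "y (m)", useRaster = TRUE,
                  asp = 1, ...)
  if (!is.null(x$network) && length(x$network$segments)) {
    ords <- vapply(x$network$segments, function(s) s$order, 0L)
    kmax <- max(c(ords, 1L), na.rm = TRUE)
    pal <- grDevices::hcl.colors(max(kmax, 2L), "Dark 2")
    for (s in x$network$segments) {
      k <- if (is.na(s$order)) 1L else s$order
      graphics::lines(cell_x(x$grid, s$path[, 2]),
                      cell_y(x$grid, s$path[, 1]), col = pal[k], lwd = 2)
    }
    if (!is.null(x$network$outlets))
      graphics::points(cell_x(x$grid, x$network$outlets$col),
                       cell_y(x$grid, x$network$outlets$row),
                       pch = 21, bg = "white", cex = 1.2)
  }
  invisible(x)
}

#' Threshold sensitivity of the network parameters
#'
#' Re-runs the full extraction with the elevation threshold perturbed by
#' each offset (default -delta, 0, +delta with delta = `cfg$z_tolerance`,
#' 0.15 m) and reports, per network parameter, the mean, the sample
#' standard deviation over the runs (n - 1 denominator: only a handful of
#' runs contribute) and the standard deviation as a percentage of the
#' mean. Runs whose network comes out empty are excluded and counted in
#' the `excluded_runs` attribute.
#'
#' @inheritParams creek_analysis
#' @param delta threshold perturbation (m).
#' @param offsets offsets applied to the resolved `z_thresh`.
#' @return data frame with `parameter`, `symbol`, `mean`, `sd`, `sd_pct`;
#'   attribute `runs` holds the per-offset parameter values.
#' @export
threshold_sensitivity <- function(grid, cfg, tides = NULL, marsh = NULL,
                                  hat = NULL, boundary = NULL,
                                  delta = cfg$z_tolerance,
                                  offsets = c(-delta, 0, delta), ...) {
  zt0 <- resolve_z_thresh(cfg$z_thresh, tides)
  runs <- list()
  excluded <- 0L
  for (off in offsets) {
    cfg_i <- cfg
    cfg_i$z_thresh <- zt0 + off
    an <- suppressWarnings(
      creek_analysis(grid, cfg_i, tides = tides, marsh = marsh, hat = hat,
                     boundary = boundary, ...))
    if (is.null(an$metrics)) {
      excluded <- excluded + 1L
      message("threshold_sensitivity: offset ", format(off),
              " m produced an empty network; excluded")
      next
    }
    runs[[length(runs) + 1]] <- an$metrics
  }
  if (!length(runs)) stop("no sensitivity run produced a network")
  syms <- c("MWS", "DD", "OPL", "MCL", "TCL", "NB", "CSA", "D", "PA",
            "TP", "SR", "MCG")
  fields <- c(MWS = "mean_elev_above_mws", DD = "DD", OPL = "OPL",
              MCL = "MCL", TCL = "TCL", NB = "NB", CSA = "CSA", D = "D",
              PA = "PA", TP = "TP", SR = "SR", MCG = "MCG")
  labels <- c(MWS = "Mean elevation above MWS (m)",
              DD = "Drainage density (km/km^2)",
              OPL = "Overmarsh path length (m)",
              MCL = "Main channel length (m)",
              TCL = "Total channel length (m)",
              NB = "Number of creeks (no unit)",
              CSA = "Total mouth cross-sectional area (m^2)",
              D = "Main channel mouth depth (m)",
              PA = "Planform area (m^2)",
              TP = "Undermarsh tidal prism (creek volume) (m^3)",
              SR = "Sinuosity ratio (no unit)",
              MCG = "Main channel gradient (deg)")
  vals <- sapply(syms, function(s)
    vapply(runs, function(m) as.numeric(m[[fields[[s]]]]), 0))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1,
                                         dimnames = list(NULL, syms))
  out <- data.frame(
    parameter = unname(labels[syms]), symbol = syms,
    mean = apply(vals, 2, mean),
    sd = if (nrow(vals) > 1) apply(vals, 2, stats::sd) else NA_real_,
    row.names = NULL)
  out$sd_pct <- 100 * out$sd / abs(out$mean)
  attr(out, "runs") <- vals
  attr(out, "excluded_runs") <- excluded
  out
}

#' Run one site end to end and write the output bundle
#'
#' Per epoch writes the area XYZ map, the creek XYZ map, the ordered
#' skeleton XYC map, a per-order statistics CSV (Appendix-A style column
#' names) and the network parameter CSV. With `sensitivity = TRUE` a
#' threshold-sensitivity CSV is added; with `change_analysis = TRUE` (two
#' or more epochs required) an elevation-change-versus-creek-distance CSV
#' comparing first and last epoch. A deterministic run log records
#' thresholds and repair/transect events, so two runs with identical
#' inputs give byte-identical bundles.
#'
#' @param epochs list of [elev_grid()]s or character paths to Esri ASCII
#'   grids, in chronological order; names become epoch labels.
#' @param out_dir output directory (created if missing).
#' @param cfg a [detection_config()].
#' @param tides optional [tidal_levels()].
#' @param hat,boundary marsh delimitation, see [creek_analysis()].
#' @param sensitivity,change_analysis optional extra products.
#' @return invisibly, the list of per-epoch `creek_analysis` objects.
#' @export
run_site <- function(epochs, out_dir, cfg, tides = NULL, hat = NULL,
                     boundary = NULL, sensitivity = FALSE,
                     change_analysis = FALSE) {
  if (!length(epochs)) stop("config error: need at least one input epoch")
  if (change_analysis && length(epochs) < 2)
    stop("config error: change analysis requires at least two epochs")
  if (inherits(epochs, "elev_grid")) epochs <- list(epochs)
  labels <- names(epochs)
  if (is.null(labels) || !all(nzchar(labels)))
    labels <- sprintf("epoch%d", seq_along(epochs))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, paste0(...))
  analyses <- list()
  for (i in seq_along(epochs)) {
    g <- epochs[[i]]
    if (is.character(g)) g <- read_ascii_grid(g)
    lab <- labels[i]
    an <- withCallingHandlers(
      creek_analysis(g, cfg, tides = tides, hat = hat, boundary = boundary),
      warning = function(w) {
        note("[", lab, "] warning: ", conditionMessage(w))
        invokeRestart("muffleWarning")
      },
      message = function(m) {
        note("[", lab, "] ", sub("\n$", "", conditionMessage(m)))
        invokeRestart("muffleMessage")
      })
    analyses[[lab]] <- an
    note("[", lab, "] z_thresh=", format(an$cfg$z_thresh),
         " s_thresh=", format(cfg$s_thresh),
         " min_component_px=", cfg$min_component_px,
         " max_repair_dist=", format(cfg$max_repair_dist))
    write_xyz(an$grid, an$marsh, file.path(out_dir, paste0(lab, "_area.xyz")))
    if (!is.null(an$masks$repaired) && any(an$masks$repaired)) {
      write_xyz(an$grid, an$masks$repaired,
                file.path(out_dir, paste0(lab, "_creek.xyz")))
      write_xyc(an$network, an$grid,
                file.path(out_dir, paste0(lab, "_skeleton.xyc")))
      os <- an$order_stats
      if (!is.null(os)) {
        names(os) <- c("Reverse Strahler order", "Number of creeks per order",
                       "Total Length", "Mean Length", "Bifurcation Ratio",
                       "Mean Sinuosity", "Mean junction angle",
                       "Mean channel width", "Mean channel depth",
                       "Mean cross-sectional area", "A/D", "W/D")[
                         seq_len(ncol(os))]
        utils::write.csv(os, file.path(out_dir, paste0(lab, "_order_stats.csv")),
                         row.names = FALSE)
      }
      if (!is.null(an$metrics))
        utils::write.csv(as.data.frame(an$metrics),
                         file.path(out_dir, paste0(lab, "_network_metrics.csv")),
                         row.names = FALSE)
    } else {
      note("[", lab, "] empty creek mask: creek products skipped")
    }
  }
  if (sensitivity) {
    g1 <- epochs[[1]]
    if (is.character(g1)) g1 <- read_ascii_grid(g1)
    sens <- withCallingHandlers(
      threshold_sensitivity(g1, cfg, tides = tides, hat = hat,
                            boundary = boundary),
      message = function(m) {
        note("[sensitivity] ", sub("\n$", "", conditionMessage(m)))
        invokeRestart("muffleMessage")
      })
    utils::write.csv(sens, file.path(out_dir, "sensitivity.csv"),
                     row.names = FALSE)
  }
  if (change_analysis) {
    a0 <- analyses[[1]]; a1 <- analyses[[length(analyses)]]
    if (is.null(a0$masks$repaired) || is.null(a1$masks$repaired)) {
      note("[change] skipped: an epoch has no creek mask")
    } else {
      ch <- elevation_change_vs_distance(a0$grid, a1$grid, a0$marsh,
                                         a0$masks$repaired,
                                         a1$masks$repaired)
      utils::write.csv(ch, file.path(out_dir, "change_analysis.csv"),
                       row.names = FALSE)
    }
  }
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(analyses)
}
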