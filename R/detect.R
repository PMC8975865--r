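#' Detection thresholds
#'
#' The four user thresholds of the creek detection workflow, plus the
#' vertical tolerance used by the sensitivity analysis:
#' * `z_thresh` — elevation (m) at or below which a cell is a creek
#'   candidate. Either an absolute elevation or a character expression
#'   relative to a tidal level, e.g. `"mhwn - 0.3"` (resolved against the
#'   site's [tidal_levels()] by [resolve_z_thresh()]).
#' * `s_thresh` — slope (degrees) at or above which a cell counts as a
#'   creek edge.
#' * `min_component_px` — connected elements smaller than this many pixels
#'   are treated as noise and removed.
#' * `max_repair_dist` — maximum Euclidean length (m) of a repair bridge
#'   when reconnecting fragmented terminal channels.
#' * `z_tolerance` — elevation-threshold perturbation for sensitivity runs
#'   (default 0.15 m, the nominal lidar vertical resolution).
#'
#' @param z_thresh numeric elevation (m) or character expression.
#' @param s_thresh slope threshold in degrees, in (0, 90).
#' @param min_component_px minimum component size in pixels (>= 1).
#' @param max_repair_dist maximum bridge length (m, >= 0).
#' @param z_tolerance sensitivity perturbation (m, >= 0).
#' @return an object of class `detection_config`.
#' @export
detection_config <- function(z_thresh, s_thresh = 40, min_component_px = 10,
                             max_repair_dist = 10, z_tolerance = 0.15) {
  if (!is.numeric(s_thresh) || s_thresh <= 0 || s_thresh >= 90)
    stop("s_thresh must be in (0, 90) degrees")
  if (min_component_px < 1) stop("min_component_px must be >= 1")
  if (max_repair_dist < 0) stop("max_repair_dist must be >= 0")
  if (z_tolerance < 0) stop("z_tolerance must be >= 0")
  structure(list(z_thresh = z_thresh, s_thresh = s_thresh,
                 min_component_px = as.integer(min_component_px),
                 max_repair_dist = max_repair_dist,
                 z_tolerance = z_tolerance),
            class = "detection_config")
}

#' @export
print.detection_config <- function(x, ...) {
  cat("<detection_config>\n")
  zt <- if (is.character(x$z_thresh)) x$z_thresh else
    sprintf("%.3f m", x$z_thresh)
  cat("  z_thresh         ", zt, "\n")
  cat(sprintf("  s_thresh          %.1f deg\n", x$s_thresh))
  cat(sprintf("  min_component_px  %d px\n", x$min_component_px))
  cat(sprintf("  max_repair_dist   %.1f m\n", x$max_repair_dist))
  cat(sprintf("  z_tolerance       %.2f m\n", x$z_tolerance))
  invisible(x)
}

#' Read a detection configuration file
#'
#' Accepts either JSON (an object with the [detection_config()] field
#' names) or plain `key = value` text, e.g.:
#' ```
#' z_thresh = mhwn - 0.3
#' s_thresh = 40
#' min_component_px = 10
#' max_repair_dist = 10
#' ```
#'
#' @param path file path.
#' @return a [detection_config()].
#' @export
read_detection_config <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vals <- if (grepl("^\\s*\\{", paste(txt, collapse = ""))) {
    jsonlite::fromJSON(paste(txt, collapse = "\n"))
  } else {
    txt <- txt[grepl("=", txt)]
    keys <- trimws(sub("=.*", "", txt))
    out <- lapply(trimws(sub("^[^=]*=", "", txt)), function(v) {
      num <- suppressWarnings(as.numeric(v))
      if (is.na(num)) v else num
    })
    names(out) <- keys
    out
  }
  known <- c("z_thresh", "s_thresh", "min_component_px",
             "max_repair_dist", "z_tolerance")
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown detection_config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(vals$z_thresh)) stop("config file must set z_thresh")
  do.call(detection_config, vals)
}

#' Resolve an elevation threshold against tidal levels
#'
#' A numeric threshold is returned as-is. A character threshold must be of
#' the form `"<level>"`, `"<level> + x"` or `"<level> - x"` where
#' `<level>` is one of `hat, mhws, mhwn, mws, mlwn, mlws`
#' (case-insensitive).
#'
#' @param z_thresh numeric or character.
#' @param tides a [tidal_levels()] (required for character thresholds).
#' @return numeric elevation (m).
#' @export
resolve_z_thresh <- function(z_thresh, tides = NULL) {
  if (is.numeric(z_thresh)) return(z_thresh)
  expr <- tolower(gsub("\\s+", "", z_thresh))
  m <- regmatches(expr,
                  regexec("^(hat|mhws|mhwn|mws|mlwn|mlws)([+-][0-9.]+)?$", expr))[[1]]
  if (!length(m))
    stop("cannot parse z_thresh expression '", z_thresh,
         "'; expected e.g. 'mhwn - 0.3'")
  if (is.null(tides))
    stop("z_thresh '", z_thresh, "' is tidal-level relative but no tidal ",
         "levels were supplied")
  base <- tides[[m[2]]]
  off <- if (nzchar(m[3])) as.numeric(m[3]) else 0
  base + off
}

#' Detect the raw creek mask by elevation and slope thresholds
#'
#' A creek network is a connected feature lying lower than the rest of the
#' marsh, with its edges delimited by steeper slopes. Candidate cells are
#' in-marsh cells with `z <= z_thresh` *or* `slope >= s_thresh`; retained
#' components are the 8-connected candidate components that contain at
#' least one elevation-qualified cell, so purely slope-defined features
#' (seawall toes, embankment faces) are dropped.
#'
#' @param grid an [elev_grid()].
#' @param slope the matching slope grid from [compute_slope_degrees()].
#' @param marsh logical marsh mask.
#' @param cfg a [detection_config()] (with numeric `z_thresh`; use
#'   [resolve_z_thresh()] first for tidal-relative thresholds).
#' @return logical creek mask with attribute `provenance = "raw"`. An
#'   empty mask is returned with a warning, not an error: a site may
#'   genuinely lack creeks.
#' @export
detect_creek_mask <- function(grid, slope, marsh, cfg) {
  check_aligned(grid, marsh, "marsh mask")
  if (!identical(dim(slope$values), dim(grid$values)))
    stop("slope grid is not aligned with the elevation grid")
  zt <- cfg$z_thresh
  if (!is.numeric(zt))
    stop("cfg$z_thresh must be numeric here; resolve tidal-relative ",
         "thresholds with resolve_z_thresh()")
  z <- grid$values; s <- slope$values
  low <- marsh & is.finite(z) & z <= zt
  steep <- marsh & is.finite(s) & s >= cfg$s_thresh
  cand <- low | steep
  out <- matrix(FALSE, nrow(z), ncol(z))
  if (any(cand)) {
    lab <- label_components_cpp(cand)
    keep <- sort(unique(lab[low]))
    keep <- keep[keep > 0]
    if (length(keep)) out <- matrix(lab %in% keep, nrow(z), ncol(z))
  }
  if (!any(out))
    warning("creek detection produced an empty mask (no cell at or below ",
            "z_thresh = ", format(zt), " m)")
  structure(out, provenance = "raw")
}

#' Remove small connected elements
#'
#' Noise filtering: drops 8-connected components of the creek mask with
#' fewer than `min_component_px` pixels.
#'
#' @param mask logical creek mask.
#' @param min_component_px minimum surviving component size (px).
#' @return filtered logical mask, `provenance = "filtered"`.
#' @export
filter_small_components <- function(mask, min_component_px) {
  if (min_component_px <= 1L || !any(mask))
    return(structure(unclass_mask(mask), provenance = "filtered"))
  lab <- label_components_cpp(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_component_px)
  structure(matrix(lab %in% keep, nrow(mask), ncol(mask)),
            provenance = "filtered")
}

unclass_mask <- function(mask) {
  attributes(mask) <- list(dim = dim(mask))
  mask
}

#' Reconnect fragmented terminal channels
#'
#' The largest surviving component is taken as the trunk network. The
#' remaining fragments are attached iteratively, nearest first: a fragment
#' whose minimum pixel-to-network Euclidean distance is within
#' `cfg$max_repair_dist` is joined by rasterizing the straight segment
#' (Bresenham line) between the closest pixel pair, after which distances
#' are recomputed so later fragments may attach to earlier bridges.
#' Fragments beyond reach stay detached and are reported in the
#' `detached` attribute. Repair only ever adds pixels.
#'
#' @param mask filtered logical creek mask.
#' @param cfg a [detection_config()] (uses `max_repair_dist`, in metres).
#' @param cell_size cell size (m) used to convert pixel distances.
#' @return repaired logical mask, `provenance = "repaired"`, with
#'   attribute `detached` = number of fragments left unconnected.
#' @export
reconnect_fragments <- function(mask, cfg, cell_size = 1) {
  m <- unclass_mask(mask)
  lab <- label_components_cpp(m)
  ncomp <- max(lab)
  if (ncomp <= 1L)
    return(structure(m, provenance = "repaired", detached = 0L))
  sizes <- tabulate(lab[lab > 0])
  trunk_lab <- which.max(sizes)
  net <- lab == trunk_lab
  frag_ids <- setdiff(which(sizes > 0), trunk_lab)
  detached <- 0L
  repeat {
    if (!length(frag_ids)) break
    ed <- edt_nearest_cpp(net)
    # nearest fragment to the current network, deterministic tie-break
    best <- NULL
    for (fid in frag_ids) {
      cells <- which(lab == fid & m)
      d2 <- ed$dist2[cells]
      o <- order(d2, (cells - 1L) %% nrow(m) + 1L,
                 (cells - 1L) %/% nrow(m) + 1L)
      cell <- cells[o[1]]
      cand <- list(fid = fid, d2 = d2[o[1]], cell = cell,
                   r = (cell - 1L) %% nrow(m) + 1L,
                   c = (cell - 1L) %/% nrow(m) + 1L,
                   target = ed$index[cell])
      if (is.null(best) || cand$d2 < best$d2 ||
          (cand$d2 == best$d2 && (cand$r < best$r ||
                                  (cand$r == best$r && cand$c < best$c))))
        best <- cand
    }
    if (sqrt(best$d2) * cell_size > cfg$max_repair_dist) {
      detached <- length(frag_ids)
      break
    }
    nr <- nrow(m)
    r0 <- (best$cell - 1L) %% nr + 1L; c0 <- (best$cell - 1L) %/% nr + 1L
    r1 <- (best$target - 1L) %% nr + 1L; c1 <- (best$target - 1L) %/% nr + 1L
    bridge <- bresenham_cpp(r0, c0, r1, c1)
    m[cbind(bridge[, 1], bridge[, 2])] <- TRUE
    net <- net | (lab == best$fid)
    net[cbind(bridge[, 1], bridge[, 2])] <- TRUE
    frag_ids <- setdiff(frag_ids, best$fid)
  }
  if (detached > 0L)
    message("reconnect_fragments: ", detached,
            " fragment(s) beyond max_repair_dist left detached")
  structure(m, provenance = "repaired", detached = detached)
}

#' Thin the creek mask to a one-pixel centreline
#'
#' Topology-preserving morphological thinning (Zhang–Suen family with
#' sequential re-checking, see the package vignette): the skeleton is a
#' subset of the mask, one pixel wide (no 2x2 all-true block), with the
#' same number of 8-connected components.
#'
#' @param mask repaired logical creek mask.
#' @return logical skeleton grid.
#' @export
skeletonize_mask <- function(mask) {
  thin_skeleton_cpp(unclass_mask(mask))
}
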