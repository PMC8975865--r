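#' Six mean tidal levels for one site
#'
#' Container for the standard mean tidal levels, in metres relative to
#' Ordnance Datum Newlyn (or any common vertical datum): Highest
#' Astronomical Tide, Mean High Water Spring/Neap, Mean Water Spring, Mean
#' Low Water Neap/Spring. The physical ordering
#' `hat >= mhws >= mhwn >= mws >= mlwn >= mlws` is enforced.
#'
#' @param hat,mhws,mhwn,mws,mlwn,mlws levels (m).
#' @return an object of class `tidal_levels`.
#' @export
tidal_levels <- function(hat, mhws, mhwn, mws, mlwn, mlws) {
  lv <- c(hat = hat, mhws = mhws, mhwn = mhwn, mws = mws,
          mlwn = mlwn, mlws = mlws)
  if (anyNA(lv) || !all(is.finite(lv))) stop("tidal levels must be finite")
  if (any(diff(lv) > 1e-9))
    stop("tidal levels violate ordering hat >= mhws >= mhwn >= mws >= mlwn >= mlws")
  structure(as.list(lv), class = "tidal_levels")
}

#' @export
print.tidal_levels <- function(x, ...) {
  cat("<tidal_levels> (m):\n")
  for (nm in c("hat", "mhws", "mhwn", "mws", "mlwn", "mlws"))
    cat(sprintf("  %-4s %8.3f\n", toupper(nm), x[[nm]]))
  invisible(x)
}

#' Read a port table
#'
#' CSV with columns `name,x,y,hat,mhws,mhwn,mws,mlwn,mlws,cd_to_odn`:
#' planar site coordinates (same projected CRS as the grids), six levels
#' relative to Chart Datum, and the Chart Datum to Ordnance Datum offset.
#'
#' @param path CSV path.
#' @return data frame of port records.
#' @export
read_port_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "x", "y", "hat", "mhws", "mhwn", "mws", "mlwn", "mlws",
            "cd_to_odn")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("port table is missing column(s): ", paste(missing, collapse = ", "))
  df[need]
}

#' Convert a port's levels from Chart Datum to ODN
#'
#' Shifts all six levels by the port's `cd_to_odn` offset and validates the
#' tidal ordering afterwards.
#'
#' @param port one-row data frame (or list) with the port-table fields.
#' @return the port with levels in ODN and `cd_to_odn` set to 0.
#' @export
to_odn <- function(port) {
  off <- port$cd_to_odn
  if (is.null(off) || !is.finite(off)) stop("cd_to_odn must be finite")
  fields <- c("hat", "mhws", "mhwn", "mws", "mlwn", "mlws")
  for (f in fields) port[[f]] <- port[[f]] + off
  lv <- unlist(port[fields])
  if (any(diff(lv) > 1e-9))
    stop("tidal ordering violated after datum conversion at port '",
         port$name, "'")
  port$cd_to_odn <- 0
  port
}

#' Interpolate a site's tidal levels from surrounding ports
#'
#' Inverse-distance (power `power`, default 1) weighted mean over ports
#' within `radius` (default 30 km) of the site, in planar coordinates.
#' Ports are converted to ODN first. A port exactly at the site returns
#' its levels verbatim.
#'
#' @param site_xy numeric length-2 vector, site coordinates (m).
#' @param ports data frame of port records ([read_port_table()] layout).
#' @param radius search radius (m), default 30000.
#' @param power inverse-distance weighting power, default 1.
#' @return a [tidal_levels()].
#' @export
interpolate_tidal_levels <- function(site_xy, ports, radius = 30000,
                                     power = 1) {
  d <- sqrt((ports$x - site_xy[1])^2 + (ports$y - site_xy[2])^2)
  within <- which(d <= radius)
  if (!length(within))
    stop(sprintf(
      "no port within %.0f m of the site (nearest port '%s' at %.0f m)",
      radius, ports$name[which.min(d)], min(d)))
  fields <- c("hat", "mhws", "mhwn", "mws", "mlwn", "mlws")
  odn <- do.call(rbind, lapply(within, function(i) {
    p <- to_odn(as.list(ports[i, ]))
    unlist(p[fields])
  }))
  exact <- within[d[within] == 0]
  if (length(exact)) {
    lv <- odn[match(exact[1], within), ]
  } else {
    w <- 1 / d[within]^power
    lv <- colSums(odn * w) / sum(w)
  }
  do.call(tidal_levels, as.list(lv))
}
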