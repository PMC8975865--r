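# Brute-force oracles and fixture builders shared across the test files.
# Oracles are deliberately naive (all-pairs, explicit loops) so they stay
# independent of the package's implementations.

# all-pairs nearest-neighbour gap fill, tie-break smallest row then column
oracle_fill <- function(values, mask) {
  nr <- nrow(values); nc <- ncol(values)
  donors <- which(mask & is.finite(values))
  dr <- (donors - 1) %% nr + 1
  dc <- (donors - 1) %/% nr + 1
  out <- values
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j] || is.finite(values[i, j])) next
    d2 <- (dr - i)^2 + (dc - j)^2
    k <- order(d2, dr, dc)[1]
    out[i, j] <- values[dr[k], dc[k]]
  }
  out
}

# all-pairs distance map to the nearest creek cell (m)
oracle_distmap <- function(mask, cell_size = 1) {
  nr <- nrow(mask); nc <- ncol(mask)
  f <- which(mask)
  fr <- (f - 1) %% nr + 1
  fc <- (f - 1) %/% nr + 1
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc))
    out[i, j] <- sqrt(min((fr - i)^2 + (fc - j)^2)) * cell_size
  out
}

# 8-connected labelling by repeated flood fill
oracle_label8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j] || lab[i, j]) next
    nxt <- nxt + 1L
    stack <- list(c(i, j)); lab[i, j] <- nxt
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (di in -1:1) for (dj in -1:1) {
        ii <- p[1] + di; jj <- p[2] + dj
        if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
        if (mask[ii, jj] && !lab[ii, jj]) {
          lab[ii, jj] <- nxt
          stack[[length(stack) + 1]] <- c(ii, jj)
        }
      }
    }
  }
  lab
}

# block-mean aggregation by explicit loops
oracle_blockmean <- function(values, f) {
  nr <- nrow(values); nc <- ncol(values)
  nro <- ceiling(nr / f); nco <- ceiling(nc / f)
  out <- matrix(NA_real_, nro, nco)
  for (bi in seq_len(nro)) for (bj in seq_len(nco)) {
    ii <- ((bi - 1) * f + 1):min(bi * f, nr)
    jj <- ((bj - 1) * f + 1):min(bj * f, nc)
    blk <- values[ii, jj]
    if (any(is.finite(blk))) out[bi, bj] <- mean(blk[is.finite(blk)])
  }
  out
}

no_2x2 <- function(s) {
  nr <- nrow(s); nc <- ncol(s)
  !any(s[-nr, -nc] & s[-1, -nc] & s[-nr, -1] & s[-1, -1])
}

n_components <- function(mask) max(0L, max(oracle_label8(mask)))

# order a constructed skeleton on a flat grid with marsh everywhere;
# outlets arise where the mask touches the grid edge
order_skeleton <- function(skel, grid = NULL) {
  if (is.null(grid)) grid <- elev_grid(matrix(1, nrow(skel), ncol(skel)), 1)
  marsh <- matrix(TRUE, nrow(skel), ncol(skel))
  net <- build_network(skel)
  net <- identify_outlets(net, marsh, skel, grid)
  suppressMessages(assign_reverse_strahler(net))
}

channel_orders <- function(net) sort(vapply(net$channels, function(ch) ch$order, 0L))

test_tides <- function() tidal_levels(hat = 2.5, mhws = 2.2, mhwn = 1.5,
                                      mws = 0, mlwn = -1, mlws = -2)

# small marsh with one straight carved channel, used by several files:
# platform 2 m, channel bed `bed` m, `width_px` cells wide, entering from
# the south edge through a seawall breach
simple_channel_marsh <- function(nr = 80, nc = 60, bed = 1.0, width_px = 3,
                                 len = 60, noise_sigma = 0, seed = 1) {
  generate_marsh(marsh_spec(
    n_rows = nr, n_cols = nc, platform_elevation = 2, seawall_elevation = 5,
    wall_thickness = 2, hat = 2.5, tree_depth = 1,
    widths = width_px, depths = 2 - bed, lengths = len,
    noise_sigma = noise_sigma, seed = seed))
}
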