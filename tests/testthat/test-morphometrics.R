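# rectangular test channel: platform 2 m, bed `bed`, `w` columns wide,
# horizontal at row `row`; returns grid + mask + a straight path along it
rect_channel <- function(nr = 21, nc = 40, row = 11, w = 3, bed = 1) {
  v <- matrix(2, nr, nc)
  half <- (w - 1) / 2
  rows <- (row - half):(row + half)
  v[rows, ] <- bed
  mask <- matrix(FALSE, nr, nc); mask[rows, ] <- TRUE
  path <- cbind(row = rep(row, nc), col = seq_len(nc))
  list(grid = elev_grid(v, 1), mask = mask, path = path)
}

test_that("path geometry gives sinuous and straight lengths", {
  p <- cbind(5, 3:13)  # straight 11-pixel horizontal path
  g <- segment_geometry(p, 1)
  expect_equal(g$sinuous_length, 10)
  expect_equal(g$straight_length, 10)
  expect_equal(g$sinuosity_ratio, 1)

  # right-angle L with two 5-step arms
  p <- rbind(cbind(5, 1:6), cbind(6:10, 6))
  g <- segment_geometry(p, 1)
  expect_equal(g$sinuous_length, 10)
  expect_equal(g$straight_length, sqrt(50))
  expect_equal(g$sinuosity_ratio, 10 / sqrt(50))

  expect_error(segment_geometry(cbind(1, 1), 1), "degenerate")

  set.seed(8)
  for (k in 1:10) {
    # random monotone staircase path
    steps <- matrix(sample(c(0L, 1L), 40, replace = TRUE), ncol = 2)
    steps <- steps[rowSums(steps) > 0, , drop = FALSE]
    p <- apply(rbind(c(3, 3), steps), 2, cumsum)
    expect_gte(segment_geometry(p, 1)$sinuosity_ratio, 1 - 1e-12)
  }
})

test_that("junction angles follow the chord convention", {
  junc <- c(10, 10)
  parent_down <- cbind(10, 10:1)           # downstream due west
  t_child <- cbind(11:20, 10)              # due south: T-join
  expect_equal(junction_angle(t_child, parent_down), 90)

  back_child <- cbind(10, 10:20)           # doubling back along upstream
  expect_equal(junction_angle(back_child, parent_down), 180)

  diag_child <- cbind(10 - 0:8, 10 - 0:8)  # north-west diagonal
  # vector oracle: chords (-5, 5) vs (-5, 0) -> 45 degrees
  expect_equal(junction_angle(diag_child, parent_down), 45)
})

test_that("rectangular channel cross-sections recover width, depth, area", {
  ch <- rect_channel(w = 3, bed = 1)
  xs <- cross_section(ch$grid, ch$mask, ch$path, station = 20)
  expect_equal(unname(xs["width"]), 3, tolerance = 0.5 / 3)
  expect_equal(unname(xs["depth"]), 1, tolerance = 0.01)
  expect_equal(unname(xs["area"]), 3, tolerance = 0.1)
})

test_that("V-channel cross-section area is near the analytic triangle", {
  v <- matrix(2, 21, 40)
  v[11, ] <- 1.0; v[c(10, 12), ] <- 1.5
  mask <- v < 2
  g <- elev_grid(v, 1)
  path <- cbind(rep(11, 40), 1:40)
  xs <- cross_section(g, mask, path, station = 20)
  expect_equal(unname(xs["area"]), 2.0, tolerance = 0.1)  # 1/2 * 4 * 1
  expect_equal(unname(xs["depth"]), 1.0, tolerance = 0.01)
})

test_that("transects that exit the grid are flagged, not fabricated", {
  ch <- rect_channel(nr = 5, row = 3, w = 5, bed = 1)  # mask touches edges
  xs <- cross_section(ch$grid, ch$mask, ch$path, station = 20)
  expect_true(all(is.na(xs)))
})

test_that("segment cross statistics average valid stations", {
  ch <- rect_channel(w = 3, bed = 1)
  st <- segment_cross_stats(ch$grid, ch$mask, ch$path)
  expect_equal(st$mean_width, 3, tolerance = 0.2)
  expect_equal(st$mean_depth, 1, tolerance = 0.01)
  expect_equal(st$mean_xs_area, 3, tolerance = 0.1)

  # linearly deepening bed 0.5 -> 1.5: mean depth ~ 1.0
  nr <- 21; nc <- 60
  v <- matrix(2, nr, nc)
  bed <- seq(0.5, 1.5, length.out = nc)
  for (j in 1:nc) v[10:12, j] <- 2 - bed[j]
  mask <- v < 2
  path <- cbind(rep(11, nc), 1:nc)
  st <- segment_cross_stats(elev_grid(v, 1), mask, path)
  expect_equal(st$mean_depth, 1.0, tolerance = 0.05)

  # path shorter than the spacing: no station, reported as none
  short <- segment_cross_stats(ch$grid, ch$mask, ch$path[1:2, ], spacing = 5)
  expect_equal(short$n_stations, 0)
  expect_true(is.na(short$mean_width))
})

test_that("overmarsh distance map matches the brute-force oracle", {
  set.seed(17)
  mask <- matrix(runif(30 * 24) < 0.05, 30, 24)
  mask[1, 1] <- TRUE
  marsh <- matrix(TRUE, 30, 24)
  dm <- opl_map(marsh, mask, cell_size = 2)
  expect_identical(dm, oracle_distmap(mask, 2))

  # cell edge-adjacent to a creek cell is one cell size away
  m1 <- matrix(FALSE, 5, 5); m1[3, 3] <- TRUE
  dm1 <- opl_map(matrix(TRUE, 5, 5), m1, cell_size = 1)
  expect_equal(dm1[3, 4], 1)
  expect_equal(dm1[2, 2], sqrt(2))

  expect_error(opl_map(marsh, matrix(FALSE, 30, 24)), "empty creek mask")
})

test_that("network summary implements the parameter definitions", {
  syn <- simple_channel_marsh(nr = 100, nc = 60, len = 80)
  an <- creek_analysis(syn$grid, syn$truth$config, tides = test_tides(),
                       marsh = syn$marsh)
  m <- an$metrics
  area_km2 <- sum(syn$marsh) / 1e6
  expect_equal(m$DD, (m$TCL / 1000) / area_km2, tolerance = 1e-9)
  expect_lte(m$MCL, m$TCL + 1e-9)
  expect_equal(m$NB, 1)
  expect_equal(m$PA, sum(an$masks$repaired))
  expect_lte(m$PA, m$catchment_area)
  # OPL equals the mean of the distance map over non-creek marsh cells
  dm <- opl_map(syn$marsh, an$masks$repaired)
  expect_equal(m$OPL, mean(dm[syn$marsh & !an$masks$repaired]))
  # mean elevation above MWS: platform 2 m, MWS 0 m
  expect_equal(m$mean_elev_above_mws, mean(syn$grid$values[syn$marsh]) - 0)
  expect_gte(m$SR, 1)
  # creek covering the whole marsh -> OPL 0
  allmask <- syn$marsh
  m2 <- network_summary(syn$grid, syn$marsh, allmask, an$network,
                        tides = test_tides(), channel_table = an$channels)
  expect_equal(m2$OPL, 0)
})

test_that("main channel gradient follows the endpoint elevations", {
  # straight channel sloping up from mouth to head
  syn <- simple_channel_marsh(nr = 120, nc = 40, len = 100, bed = 1)
  g <- syn$grid
  # superimpose a gentle along-channel tilt on the carved bed
  tilt <- outer(seq(0.2, 0, length.out = nrow(g$values)), rep(1, 40))
  g$values <- g$values + tilt
  an <- creek_analysis(g, syn$truth$config, hat = 2.7, marsh = syn$marsh)
  m <- an$metrics
  main <- an$network$channels[[1]]
  p <- creekmorph:::channel_path(an$network, main)
  zm <- g$values[p[1, 1], p[1, 2]]
  zh <- g$values[p[nrow(p), 1], p[nrow(p), 2]]
  expect_equal(m$MCG, atan((zh - zm) / m$MCL) * 180 / pi)
  expect_gt(m$MCG, 0)  # head above mouth
})

test_that("geometry-only parameters ignore order relabelling", {
  syn <- generate_marsh(marsh_spec(n_rows = 200, n_cols = 200,
                                   lengths = c(120, 40, 14),
                                   noise_sigma = 0, seed = 5))
  an <- creek_analysis(syn$grid, syn$truth$config, hat = 2.5,
                       marsh = syn$marsh)
  net2 <- an$network
  for (i in seq_along(net2$segments))  # scramble orders
    net2$segments[[i]]$order <- ((net2$segments[[i]]$order + 1L) %% 3L) + 1L
  m2 <- network_summary(an$grid, syn$marsh, an$masks$repaired, net2,
                        channel_table = an$channels)
  m1 <- an$metrics
  for (f in c("DD", "OPL", "PA", "TCL"))
    expect_equal(m2[[f]], m1[[f]], info = f)
})

test_that("per-order statistics table is complete and coherent", {
  syn <- generate_marsh(marsh_spec(noise_sigma = 0, seed = 2))
  an <- creek_analysis(syn$grid, syn$truth$config, hat = 2.5,
                       marsh = syn$marsh)
  os <- an$order_stats
  expect_equal(os$order, 1:3)
  expect_true(all(os$n_channels > 0))
  expect_equal(os$bifurcation_ratio[1], os$n_channels[2] / os$n_channels[1])
  expect_true(is.na(os$bifurcation_ratio[3]))
  expect_equal(os$total_length, os$mean_length * os$n_channels)
  expect_true(all(os$mean_sinuosity >= 1))
  expect_true(all(os$mean_junction_angle[-1] > 0 &
                  os$mean_junction_angle[-1] < 180))
  expect_equal(os$width_over_depth, os$mean_width / os$mean_depth)
  expect_equal(os$area_over_depth2, os$mean_xs_area / os$mean_depth^2)
})

test_that("elevation change is attributed to the matching creek extent", {
  nr <- 40; nc <- 40
  marsh <- matrix(TRUE, nr, nc)
  m0 <- matrix(FALSE, nr, nc); m0[20, 5:35] <- TRUE
  m1 <- m0; m1[28, 5:35] <- TRUE  # a new creek appeared at t1
  g0 <- elev_grid(matrix(2, nr, nc), 1)

  # uniform accretion: all gains at 0.05, no losses
  g1 <- elev_grid(matrix(2.05, nr, nc), 1)
  tab <- elevation_change_vs_distance(g0, g1, marsh, m0, m1)
  gains <- tab[tab$direction == "gain" & tab$n > 0, ]
  expect_true(all(abs(gains$mean_dz - 0.05) < 1e-12))
  expect_true(all(tab$n[tab$direction == "loss"] == 0))

  # no change: all bins empty
  tab0 <- elevation_change_vs_distance(g0, g0, marsh, m0, m1)
  expect_true(all(tab0$n == 0))

  # step field: +0.1 within 5 m of the t1 creeks, else +0.02
  d1 <- oracle_distmap(m1)
  v1 <- matrix(2, nr, nc) + ifelse(d1 <= 5, 0.1, 0.02)
  tab <- elevation_change_vs_distance(g0, elev_grid(v1, 1), marsh, m0, m1)
  g <- tab[tab$direction == "gain" & tab$n > 0, ]
  expect_true(all(abs(g$mean_dz[g$dist_hi <= 5] - 0.1) < 1e-12))
  expect_true(all(abs(g$mean_dz[g$dist_lo >= 6] - 0.02) < 1e-12))

  expect_error(
    elevation_change_vs_distance(g0, elev_grid(matrix(2, 10, 10), 1),
                                 marsh, m0, m1),
    "co-registered")
})
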