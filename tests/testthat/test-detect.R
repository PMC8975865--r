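test_that("threshold detection separates a carved channel from the platform", {
  v <- matrix(2, 20, 20)
  v[9:11, ] <- 1                     # carved channel, bed 1 m
  g <- elev_grid(v, 1)
  s <- compute_slope_degrees(g)
  marsh <- matrix(TRUE, 20, 20)
  cfg <- detection_config(z_thresh = 1.5, s_thresh = 40,
                          min_component_px = 1, max_repair_dist = 0)
  m <- detect_creek_mask(g, s, marsh, cfg)
  expect_true(all(m[9:11, ]))
  expect_false(any(m[c(1:7, 13:20), ]))  # rows 8/12 may join as steep edges

  # platform entirely above threshold, gentle slopes -> empty mask + warning
  cfg2 <- detection_config(z_thresh = 0.5, s_thresh = 80,
                           min_component_px = 1, max_repair_dist = 0)
  expect_warning(m2 <- detect_creek_mask(g, s, marsh, cfg2), "empty")
  expect_false(any(m2))
})

test_that("slope-only components (seawall toes) are excluded", {
  v <- matrix(2, 20, 20)
  v[9:11, 1:10] <- 1                 # channel in the west
  v[2:4, 15:18] <- 8                 # steep isolated bump in the north-east
  g <- elev_grid(v, 1, max_abs = 100)
  s <- compute_slope_degrees(g)
  cfg <- detection_config(z_thresh = 1.5, s_thresh = 40,
                          min_component_px = 1, max_repair_dist = 0)
  m <- detect_creek_mask(g, s, matrix(TRUE, 20, 20), cfg)
  expect_true(any(m[9:11, 1:10]))
  expect_false(any(m[1:5, 14:19]))   # bump: steep but nowhere below z_thresh
})

test_that("raising the elevation threshold never shrinks the mask here", {
  syn <- simple_channel_marsh()
  s <- compute_slope_degrees(syn$grid)
  cfg_lo <- syn$truth$config; cfg_lo$z_thresh <- 1.4
  cfg_hi <- syn$truth$config; cfg_hi$z_thresh <- 1.8
  m_lo <- detect_creek_mask(syn$grid, s, syn$marsh, cfg_lo)
  m_hi <- detect_creek_mask(syn$grid, s, syn$marsh, cfg_hi)
  expect_true(all(m_hi[m_lo]))
})

test_that("small-component filtering matches the labelling oracle", {
  m <- matrix(FALSE, 10, 10)
  m[2:3, 2] <- TRUE                    # 3-px blob (with diagonal)
  m[3, 3] <- TRUE
  expect_false(any(filter_small_components(m, 10)))
  expect_equal(sum(filter_small_components(m, 1)), 3)

  set.seed(13)
  sp <- matrix(runif(900) < 0.25, 30, 30)
  filt <- filter_small_components(sp, 4)
  lab <- oracle_label8(sp)
  sizes <- tabulate(lab[lab > 0])
  expect_equal(n_components(filt), sum(sizes >= 4))
  expect_equal(sum(filt), sum(sizes[sizes >= 4]))
})

test_that("fragment reconnection bridges the closest pixel pair", {
  m <- matrix(FALSE, 9, 30)
  m[5, 2:11] <- TRUE
  m[5, 15:24] <- TRUE                 # 3-px gap at cols 12:14
  cfg <- detection_config(1, 40, 1, max_repair_dist = 5)
  r <- reconnect_fragments(m, cfg)
  expect_equal(n_components(r), 1)
  expect_true(all(r[5, 12:14]))       # bridge is exactly the gap pixels
  expect_equal(sum(r), sum(m) + 3)

  cfg1 <- detection_config(1, 40, 1, max_repair_dist = 1)
  r1 <- suppressMessages(reconnect_fragments(m, cfg1))
  expect_equal(sum(r1), sum(m))       # out of reach: unchanged
  expect_equal(attr(r1, "detached"), 1L)

  r2 <- reconnect_fragments(m[, 1:12], cfg)   # already connected
  expect_equal(sum(r2), sum(m[, 1:12]))
})

test_that("iterative repair lets fragments attach through earlier bridges", {
  m <- matrix(FALSE, 9, 40)
  m[5, 2:15] <- TRUE                  # trunk
  m[5, 19:23] <- TRUE                 # fragment A, 3 px from trunk
  m[5, 27:30] <- TRUE                 # fragment B, 3 px from A, 11 from trunk
  cfg <- detection_config(1, 40, 1, max_repair_dist = 4)
  r <- reconnect_fragments(m, cfg)
  expect_equal(n_components(r), 1)
  expect_true(all(r[5, 2:30]))
})

test_that("thinning produces one-pixel centrelines preserving topology", {
  rib <- matrix(FALSE, 20, 60)
  rib[9:11, 5:55] <- TRUE             # 3-px ribbon, length 51 cells
  sk <- skeletonize_mask(rib)
  expect_true(all(rib[sk]))           # skeleton subset of mask
  expect_true(no_2x2(sk))
  expect_equal(n_components(sk), 1)
  expect_true(abs(sum(sk) - 51) <= 2) # end-to-end length within 2 px

  line <- matrix(FALSE, 10, 30); line[4, 3:25] <- TRUE
  expect_identical(skeletonize_mask(line), line)  # already thin

  # annulus -> single closed loop, every pixel degree 2
  rg <- matrix(FALSE, 30, 30)
  for (i in 1:30) for (j in 1:30) {
    d <- sqrt((i - 15.5)^2 + (j - 15.5)^2)
    if (d >= 7 && d <= 10) rg[i, j] <- TRUE
  }
  sk <- skeletonize_mask(rg)
  expect_equal(n_components(sk), 1)
  deg <- creekmorph:::neighbour_count_cpp(sk)
  expect_true(all(deg[sk] == 2))
})

test_that("thinning preserves component counts on random speckle", {
  set.seed(3)
  blob <- matrix(runif(2500) < 0.4, 50, 50)
  sk <- skeletonize_mask(blob)
  expect_equal(n_components(sk), n_components(blob))
  expect_true(no_2x2(sk))
  expect_true(all(blob[sk]))
})

test_that("detection configs load from key=value text and JSON", {
  f <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("z_thresh = mhwn - 0.3", "s_thresh = 42",
               "min_component_px = 6", "max_repair_dist = 8"), f)
  cfg <- read_detection_config(f)
  expect_equal(cfg$z_thresh, "mhwn - 0.3")
  expect_equal(cfg$s_thresh, 42)
  expect_equal(cfg$min_component_px, 6L)

  j <- withr::local_tempfile(fileext = ".json")
  writeLines('{"z_thresh": 1.7, "s_thresh": 55}', j)
  cfg <- read_detection_config(j)
  expect_equal(cfg$z_thresh, 1.7)
  expect_equal(cfg$max_repair_dist, 10)  # default retained

  writeLines("z_thresh = 1\nbogus = 2", f)
  expect_error(read_detection_config(f), "unknown")
})
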