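# Constructed skeleton shapes. Masks that are not already one pixel wide
# are passed through skeletonize_mask() before graph building, as the
# pipeline does. Outlets arise where the shape touches the grid edge
# (marsh everywhere).

skel_line <- function() { m <- matrix(FALSE, 12, 24); m[6, 1:20] <- TRUE; m }

skel_y <- function() {
  m <- matrix(FALSE, 24, 24)
  m[12, 1:10] <- TRUE
  for (k in 1:7) { m[12 - k, 10 + k] <- TRUE; m[12 + k, 10 + k] <- TRUE }
  m
}

skel_comb <- function() {
  m <- matrix(FALSE, 20, 40)
  m[10, 1:30] <- TRUE
  m[11:16, 8] <- TRUE; m[11:16, 16] <- TRUE; m[11:16, 24] <- TRUE
  skeletonize_mask(m)
}

skel_h <- function() {
  m <- matrix(FALSE, 24, 24)
  m[4:20, 6] <- TRUE; m[4:20, 18] <- TRUE; m[12, 6:18] <- TRUE
  skeletonize_mask(m)
}

# symmetric perfect binary tree of `depth` levels: a horizontal root from
# the west edge, then diagonal arms halving in length at each fork. All
# sibling paths tie, so ordering exercises the deterministic tie-breaks.
# Under the pruning rule the per-order channel counts follow the
# recurrence N(d) = (1, sum of shifted N(d-1)..N(1)):
# depth 2 -> (1,1); depth 3 -> (1,2,1); depth 4 -> (1,3,3,1).
skel_btree <- function(depth) {
  m <- matrix(FALSE, 80, 45)
  alen <- c(NA, 16, 8, 4)
  grow <- function(r, c, k) {
    if (k > depth) return(invisible(NULL))
    for (s in c(-1, 1)) {
      for (i in seq_len(alen[k])) m[r + s * i, c + i] <<- TRUE
      grow(r + s * alen[k], c + alen[k], k + 1)
    }
  }
  m[40, 1:10] <- TRUE
  grow(40, 10, 2)
  m
}

skel_two_outlet <- function() {
  m <- matrix(FALSE, 30, 30)
  m[8, 1:20] <- TRUE
  m[22, 1:12] <- TRUE
  m
}

skel_cycle <- function() {
  m <- matrix(FALSE, 30, 30)
  m[15, 1:10] <- TRUE
  m[10:20, 10] <- TRUE; m[10:20, 20] <- TRUE
  m[10, 10:20] <- TRUE; m[20, 10:20] <- TRUE
  skeletonize_mask(m)
}

skel_l <- function() {
  m <- matrix(FALSE, 20, 20)
  m[10, 1:14] <- TRUE; m[3:10, 14] <- TRUE
  skeletonize_mask(m)
}

skel_double_y <- function() {
  m <- matrix(FALSE, 40, 40)
  m[20, 1:14] <- TRUE
  for (k in 1:6) { m[20 - k, 14 + k] <- TRUE; m[20 + k, 14 + k] <- TRUE }
  for (k in 1:4) { m[14 - k, 20 + k] <- TRUE; m[14 + k, 20 + k] <- TRUE }
  skeletonize_mask(m)
}

test_that("segment graphs enumerate nodes and chains correctly", {
  net <- build_network(skel_line())
  expect_equal(length(net$segments), 1)
  expect_equal(sum(net$nodes$type == "endpoint"), 2)
  expect_equal(sum(net$nodes$type == "junction"), 0)
  expect_equal(net$segments[[1]]$length_m, 19)

  net <- build_network(skel_y())
  expect_equal(length(net$segments), 3)
  expect_equal(sum(net$nodes$type == "junction"), 1)
  expect_equal(sum(net$nodes$type == "endpoint"), 3)

  net <- build_network(skel_h())
  expect_equal(length(net$segments), 5)
  expect_equal(sum(net$nodes$type == "junction"), 2)

  expect_warning(net <- build_network(matrix(FALSE, 5, 5)), "empty")
  expect_equal(length(net$segments), 0)

  # every skeleton pixel is accounted for by segments or nodes
  sk <- skel_double_y()
  net <- build_network(sk)
  covered <- matrix(FALSE, nrow(sk), ncol(sk))
  for (s in net$segments) covered[s$path] <- TRUE
  covered[cbind(net$nodes$row, net$nodes$col)] <- TRUE
  expect_true(all(covered[sk]))
})

test_that("outlets are found at marsh-boundary contacts, largest first", {
  sk <- skel_two_outlet()
  grid <- elev_grid(matrix(1, 30, 30), 1)
  # widen the mouths differently so the mouth areas differ
  mask <- sk
  mask[7:9, 1:20] <- TRUE    # 3 px wide, row 8 channel
  mask[21:23, 1:12] <- TRUE
  v <- matrix(2, 30, 30)
  v[mask] <- 0.5; v[7:9, 1:20] <- 0.2     # deeper mouth for row-8 channel
  grid <- elev_grid(v, 1)
  net <- build_network(sk)
  net <- identify_outlets(net, matrix(TRUE, 30, 30), mask, grid)
  expect_equal(nrow(net$outlets), 2)
  expect_equal(net$outlets$row[1], 8)     # larger mouth area first
  expect_gt(net$outlets$mouth_area[1], net$outlets$mouth_area[2])

  # no boundary contact -> error
  sk2 <- matrix(FALSE, 10, 10); sk2[5, 3:7] <- TRUE
  expect_error(
    identify_outlets(build_network(sk2), matrix(TRUE, 10, 10), sk2,
                     elev_grid(matrix(1, 10, 10), 1)),
    "no outlet")
})

test_that("entry channel is always order 1 across the skeleton library", {
  h_open <- skel_h(); h_open[12, 1:6] <- TRUE   # connect the H to the edge
  shapes <- list(line = skel_line(), y = skel_y(), comb = skel_comb(),
                 h = skeletonize_mask(h_open), l = skel_l(),
                 double_y = skel_double_y(),
                 bt2 = skel_btree(2), bt3 = skel_btree(3),
                 bt4 = skel_btree(4), two_outlet = skel_two_outlet(),
                 cycle = skel_cycle())
  for (nm in names(shapes)) {
    net <- order_skeleton(shapes[[nm]])
    ords <- vapply(net$channels, function(ch) ch$order, 0L)
    expect_true(any(ords == 1L), info = nm)
    expect_equal(sort(unique(ords)), seq_len(max(ords)), info = nm)
    # the order-1 channel is rooted at the largest outlet
    main <- net$channels[[which(ords == 1L)[1]]]
    expect_equal(main$root_node, net$outlets$node[1], info = nm)
    # total function: every tree segment ordered
    cyc <- attr(net, "cycle_segments")
    for (s in net$segments)
      if (!(s$id %in% cyc)) expect_false(is.na(s$order), info = nm)
  }
})

test_that("hand-traced orders match on the constructed shapes", {
  expect_equal(channel_orders(order_skeleton(skel_line())), 1L)
  expect_equal(channel_orders(order_skeleton(skel_y())), c(1L, 2L))
  expect_equal(channel_orders(order_skeleton(skel_l())), 1L)
  # comb: stem order 1, three teeth order 2
  expect_equal(channel_orders(order_skeleton(skel_comb())),
               c(1L, 2L, 2L, 2L))
  # double-Y: main stem plus a branch at each fork
  expect_equal(channel_orders(order_skeleton(skel_double_y())),
               c(1L, 2L, 2L))
  # two outlets: each component gets its own order-1 entry channel
  expect_equal(channel_orders(order_skeleton(skel_two_outlet())),
               c(1L, 1L))
  # perfect binary trees: hand-traced per-order channel counts
  expected <- list(`2` = c(1L, 1L), `3` = c(1L, 2L, 1L),
                   `4` = c(1L, 3L, 3L, 1L))
  for (d in 2:4) {
    net <- order_skeleton(skel_btree(d))
    ords <- vapply(net$channels, function(ch) ch$order, 0L)
    expect_equal(tabulate(ords), expected[[as.character(d)]], info = d)
  }
})

test_that("symmetric binary tree of 7 equal segments prunes as hand-traced", {
  # root + 2 + 4 segments, all equal length; pruning gives: order 1 takes
  # root + child + grandchild (3 segments); at the first junction the
  # sibling subtree yields an order-2 channel of 2 segments; at the second
  # junction the sibling leaf is an order-2 channel of 1 segment; the
  # remaining leaf under the first-junction subtree is order 3
  m <- matrix(FALSE, 60, 60)
  m[30, 1:9] <- TRUE                                   # root segment
  for (k in 1:8) { m[30 - k, 9 + k] <- TRUE; m[30 + k, 9 + k] <- TRUE }
  for (k in 1:4) {
    m[22 - k, 17 + k] <- TRUE; m[22 + k, 17 + k] <- TRUE
    m[38 - k, 17 + k] <- TRUE; m[38 + k, 17 + k] <- TRUE
  }
  net <- order_skeleton(skeletonize_mask(m))
  ords <- vapply(net$channels, function(ch) ch$order, 0L)
  nseg <- vapply(net$channels, function(ch) length(ch$segment_ids), 0L)
  expect_equal(sort(ords), c(1L, 2L, 2L, 3L))
  expect_equal(nseg[ords == 1], 3)
  expect_equal(sort(nseg[ords == 2]), c(1L, 2L))
  expect_equal(nseg[ords == 3], 1)
})

test_that("cycles are broken by dropping their shortest segment", {
  net <- order_skeleton(skel_cycle())
  expect_gte(length(attr(net, "cycle_segments")), 1)
  ords <- vapply(net$channels, function(ch) ch$order, 0L)
  expect_true(any(ords == 1))
})

test_that("ordering is deterministic across repeated runs", {
  for (rep in 1:2) {
    sk <- skel_btree(3)
    n1 <- order_skeleton(sk); n2 <- order_skeleton(sk)
    o1 <- vapply(n1$segments, function(s) s$order, 0L)
    o2 <- vapply(n2$segments, function(s) s$order, 0L)
    expect_identical(o1, o2)
  }
})

test_that("pruning recursion is self-consistent when the main stem is removed", {
  # remove the order-1 channel pixels from the skeleton; re-ordering each
  # remaining piece from its stump reproduces the original orders - 1
  sk <- skel_btree(3)
  net <- order_skeleton(sk)
  ords <- vapply(net$channels, function(ch) ch$order, 0L)
  main <- net$channels[[which(ords == 1L)]]
  sk2 <- sk
  p <- creekmorph:::channel_path(net, main)
  sk2[p] <- FALSE
  grid <- elev_grid(matrix(1, nrow(sk), ncol(sk)), 1)
  marsh <- matrix(TRUE, nrow(sk), ncol(sk))
  lab <- oracle_label8(sk2)
  for (comp in seq_len(max(lab))) {
    piece <- lab == comp
    if (sum(piece) < 3) next
    sub <- build_network(piece)
    if (!length(sub$segments)) next
    # root the piece at its pixel nearest the removed stem (its stump)
    ends <- sub$nodes[sub$nodes$degree <= 1, ]
    d2 <- outer(ends$row, p[, 1], "-")^2 + outer(ends$col, p[, 2], "-")^2
    stump <- ends$id[which.min(apply(d2, 1, min))]
    sub$outlets <- data.frame(node = stump, row = ends$row[ends$id == stump],
                              col = ends$col[ends$id == stump],
                              mouth_width = NA, mouth_depth = NA,
                              mouth_area = 1)
    sub <- suppressMessages(assign_reverse_strahler(sub))
    sub_orders <- sort(vapply(sub$channels, function(ch) ch$order, 0L))
    # compare with the original channels contained in this piece
    orig <- ords[vapply(net$channels, function(ch) {
      cp <- creekmorph:::channel_path(net, ch)
      all(piece[cp[-1, , drop = FALSE]])
    }, TRUE)]
    expect_equal(sub_orders, sort(orig) - 1L)
  }
})

test_that("ordered skeletons export as XYC text", {
  sk <- skel_y()
  net <- order_skeleton(sk)
  grid <- elev_grid(matrix(1, nrow(sk), ncol(sk)), 1)
  f <- withr::local_tempfile(fileext = ".xyc")
  write_xyc(net, grid, f)
  xyc <- utils::read.table(f, col.names = c("x", "y", "order"))
  expect_equal(nrow(xyc), sum(sk))
  expect_equal(sort(unique(xyc$order)), 1:2)
})
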