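#' Build the segment graph of a skeleton
#'
#' Converts a one-pixel-wide skeleton into a graph: nodes are skeleton
#' pixels with exactly one 8-neighbour (endpoints) or three or more
#' (junctions); segments are the maximal 8-connected pixel chains between
#' nodes. Every skeleton pixel belongs to a segment and/or is a node. A
#' component that is a pure cycle (no endpoint or junction) gets an
#' `anchor` node at its first pixel in row-major order so its loop is
#' representable; such components cannot be ordered.
#'
#' @param skel logical skeleton matrix (from [skeletonize_mask()]).
#' @param cell_size cell size (m), used for sinuous segment lengths.
#' @return an object of class `creek_network` with elements `nodes` (data
#'   frame: id, row, col, degree, type), `segments` (list; each has `id`,
#'   `path` (n x 2 matrix of row, col), `from`, `to`, `length_m`, `order`),
#'   `dim`, `cell_size`.
#' @export
build_network <- function(skel, cell_size = 1) {
  skel <- unclass_mask(skel)
  nr <- nrow(skel); nc <- ncol(skel)
  empty <- function() {
    warning("empty skeleton: returning an empty network")
    structure(list(nodes = data.frame(id = integer(), row = integer(),
                                      col = integer(), degree = integer(),
                                      type = character()),
                   segments = list(), dim = c(nr, nc),
                   cell_size = cell_size, outlets = NULL),
              class = "creek_network")
  }
  if (!any(skel)) return(empty())
  deg <- neighbour_count_cpp(skel)
  node_mat <- skel & (deg != 2L)
  # pure-cycle components: add an anchor node at the row-major first pixel
  lab <- label_components_cpp(skel)
  anchors <- integer(0)
  for (comp in seq_len(max(lab))) {
    cells <- which(lab == comp)
    if (!any(node_mat[cells])) {
      rows <- (cells - 1L) %% nr + 1L; cols <- (cells - 1L) %/% nr + 1L
      o <- order(rows, cols)
      anchors <- c(anchors, cells[o[1]])
    }
  }
  node_mat[anchors] <- TRUE
  node_cells <- which(t(node_mat))            # row-major discovery order
  jj <- (node_cells - 1L) %% nc + 1L
  ii <- (node_cells - 1L) %/% nc + 1L
  lin <- (jj - 1L) * nr + ii                  # column-major linear index
  node_id <- integer(nr * nc)
  node_id[lin] <- seq_along(lin)
  degv <- deg[cbind(ii, jj)]
  type <- ifelse(lin %in% anchors, "anchor",
                 ifelse(degv <= 1L, "endpoint", "junction"))
  nodes <- data.frame(id = seq_along(lin), row = ii, col = jj,
                      degree = degv, type = type,
                      stringsAsFactors = FALSE)

  nbr_of <- function(r, c) {
    rr <- r + c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    cc <- c + c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    rr <- rr[ok]; cc <- cc[ok]
    on <- skel[cbind(rr, cc)]
    cbind(rr[on], cc[on])
  }
  visited <- new.env(hash = TRUE, parent = emptyenv())
  vkey <- function(a, b) paste(a, b)
  segments <- list()
  sid <- 0L
  for (k in seq_len(nrow(nodes))) {
    r0 <- nodes$row[k]; c0 <- nodes$col[k]
    u <- (c0 - 1L) * nr + r0
    nb <- nbr_of(r0, c0)
    if (!nrow(nb)) next
    # deterministic neighbour order: by row, then col
    nb <- nb[order(nb[, 1], nb[, 2]), , drop = FALSE]
    for (q in seq_len(nrow(nb))) {
      qlin <- (nb[q, 2] - 1L) * nr + nb[q, 1]
      if (!is.null(visited[[vkey(u, qlin)]])) next
      path_r <- c(r0, nb[q, 1]); path_c <- c(c0, nb[q, 2])
      prev <- u; cur <- qlin
      while (!node_id[cur]) {
        cr <- (cur - 1L) %% nr + 1L; cc2 <- (cur - 1L) %/% nr + 1L
        nxt <- nbr_of(cr, cc2)
        nxtlin <- (nxt[, 2] - 1L) * nr + nxt[, 1]
        nxtlin <- nxtlin[nxtlin != prev]
        if (length(nxtlin) != 1L)
          stop("internal error: non-thin skeleton while tracing segments")
        prev <- cur; cur <- nxtlin
        path_r <- c(path_r, (cur - 1L) %% nr + 1L)
        path_c <- c(path_c, (cur - 1L) %/% nr + 1L)
      }
      visited[[vkey(u, qlin)]] <- TRUE
      visited[[vkey(cur, prev)]] <- TRUE
      sid <- sid + 1L
      path <- cbind(row = path_r, col = path_c)
      steps <- sqrt(diff(path_r)^2 + diff(path_c)^2)
      segments[[sid]] <- list(id = sid, path = path,
                              from = node_id[u], to = node_id[cur],
                              length_m = sum(steps) * cell_size,
                              order = NA_integer_, channel = NA_integer_,
                              mean_xs_area = NA_real_)
    }
  }
  structure(list(nodes = nodes, segments = segments, dim = c(nr, nc),
                 cell_size = cell_size, outlets = NULL),
            class = "creek_network")
}

#' @export
print.creek_network <- function(x, ...) {
  cat(sprintf("<creek_network> %d nodes (%d endpoints, %d junctions), %d segments\n",
              nrow(x$nodes), sum(x$nodes$type %in% c("endpoint", "outlet")),
              sum(x$nodes$type == "junction"), length(x$segments)))
  if (!is.null(x$outlets) && nrow(x$outlets))
    cat(sprintf("  %d outlet(s); largest mouth area %.2f m^2\n",
                nrow(x$outlets), x$outlets$mouth_area[1]))
  ords <- vapply(x$segments, function(s) s$order, 0L)
  if (length(ords) && any(!is.na(ords))) {
    tab <- table(factor(ords[!is.na(ords)]))
    cat("  reverse-Strahler segment counts:",
        paste(sprintf("order %s: %d", names(tab), as.integer(tab)),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Identify outlets and their mouth cross-sections
#'
#' Outlets are the creek mouths at the marsh boundary (seaward edge or
#' seawall breach). Creek-mask pixels that lie on the marsh-mask boundary
#' (8-adjacent to non-marsh or to the grid edge) form contact zones; for
#' each 8-connected contact zone the nearest degree-one network node is
#' typed `outlet` and assigned a mouth cross-section (width, depth, area)
#' measured on its incident segment. Outlets are ordered by mouth area,
#' largest first, ties by row then column.
#'
#' @param net a [build_network()] result.
#' @param marsh logical marsh mask.
#' @param mask logical (repaired) creek mask.
#' @param grid the [elev_grid()].
#' @param fit_len chord fit length in pixels for the mouth transect.
#' @return the network with `outlets` (data frame) filled in and outlet
#'   nodes retyped.
#' @export
identify_outlets <- function(net, marsh, mask, grid, fit_len = 5) {
  check_aligned(grid, marsh, "marsh mask")
  mask <- unclass_mask(mask)
  nr <- net$dim[1]; nc <- net$dim[2]
  boundary <- marsh_boundary(marsh)
  contact <- boundary & mask
  if (!any(contact))
    stop("no outlet found: the creek mask does not touch the marsh ",
         "boundary; the network cannot be ordered")
  zones <- label_components_cpp(contact)
  ends <- net$nodes[net$nodes$degree <= 1L, , drop = FALSE]
  if (!nrow(ends))
    stop("no endpoint node available to serve as an outlet")
  out_nodes <- integer(0)
  for (zid in seq_len(max(zones))) {
    cells <- which(zones == zid)
    zr <- (cells - 1L) %% nr + 1L; zc <- (cells - 1L) %/% nr + 1L
    d2 <- vapply(seq_len(nrow(ends)), function(k)
      min((ends$row[k] - zr)^2 + (ends$col[k] - zc)^2), 0)
    o <- order(d2, ends$row, ends$col)
    out_nodes <- c(out_nodes, ends$id[o[1]])
  }
  out_nodes <- sort(unique(out_nodes))
  net$nodes$type[net$nodes$id %in% out_nodes] <- "outlet"
  info <- lapply(out_nodes, function(nid) {
    seg <- incident_segments(net, nid)
    xs <- c(width = NA_real_, depth = NA_real_, area = NA_real_)
    if (length(seg)) {
      s <- net$segments[[seg[1]]]
      path <- orient_path_from(s, nid)
      station <- min(fit_len + 1L, max(2L, nrow(path) - 1L))
      cs <- cross_section(grid, mask, path, station, fit_len = fit_len)
      if (!is.na(cs["area"])) xs <- cs
    }
    nd <- net$nodes[net$nodes$id == nid, ]
    data.frame(node = nid, row = nd$row, col = nd$col,
               mouth_width = unname(xs["width"]),
               mouth_depth = unname(xs["depth"]),
               mouth_area = unname(xs["area"]))
  })
  outlets <- do.call(rbind, info)
  area_key <- ifelse(is.na(outlets$mouth_area), -Inf, outlets$mouth_area)
  outlets <- outlets[order(-area_key, outlets$row, outlets$col), ,
                     drop = FALSE]
  rownames(outlets) <- NULL
  net$outlets <- outlets
  net
}

#' Boundary cells of a mask
#'
#' In-mask cells with at least one 8-neighbour outside the mask or off the
#' grid.
#' @param marsh logical mask.
#' @return logical matrix.
#' @export
marsh_boundary <- function(marsh) {
  nr <- nrow(marsh); nc <- ncol(marsh)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- marsh
  allnb <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    allnb <- allnb & pad[2:(nr + 1) + dr, 2:(nc + 1) + dc]
  }
  marsh & !allnb
}

incident_segments <- function(net, node_id) {
  which(vapply(net$segments,
               function(s) s$from == node_id || s$to == node_id, TRUE))
}

# Return the segment's pixel path oriented to start at the given node.
orient_path_from <- function(seg, node_id) {
  if (seg$from == node_id) seg$path
  else seg$path[rev(seq_len(nrow(seg$path))), , drop = FALSE]
}

#' Assign reverse-Strahler orders by pruning
#'
#' Reverse-Strahler ordering classifies the entry channel as order 1 and
#' gives each tributary its parent's order plus one. Operationally, per
#' connected component: the order-1 channel is the longest sinuous path
#' from the component's largest outlet to any endpoint; that channel is
#' then pruned, and every tributary stump branching off it roots a
#' subnetwork whose own longest path from the junction becomes an
#' order-(k+1) channel, recursively, until all segments are consumed.
#' Path-length ties break by the larger length-weighted mean segment
#' cross-sectional area (when populated), then by the (row, col) of the
#' far endpoint. Cycles are broken beforehand by dropping the shortest
#' segment of each independent cycle (maximum spanning tree); dropped
#' segments are reported and keep `order = NA`. Components with no outlet
#' are left unordered and reported.
#'
#' @param net a network with outlets identified ([identify_outlets()]).
#' @return the network with per-segment orders, a `channels` list (merged
#'   same-order channels with `order`, `segment_ids`, `parent`,
#'   `length_m`), and bookkeeping attributes `cycle_segments` /
#'   `unordered_components`.
#' @export
assign_reverse_strahler <- function(net) {
  if (!length(net$segments)) {
    net$channels <- list()
    return(net)
  }
  if (is.null(net$outlets) || !nrow(net$outlets))
    stop("no outlets identified; run identify_outlets() first")
  edges <- do.call(rbind, lapply(net$segments, function(s)
    c(s$from, s$to, s$length_m, s$id)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2]),
    directed = FALSE,
    vertices = data.frame(name = net$nodes$id))
  igraph::E(g)$sid <- edges[, 4]
  igraph::E(g)$weight <- edges[, 3]
  # cycle breaking: maximum spanning forest drops each cycle's shortest edge
  cycle_sids <- integer(0)
  nco <- igraph::components(g)$no
  if (igraph::ecount(g) > igraph::vcount(g) - nco) {
    keep <- igraph::mst(g, weights = -igraph::E(g)$weight)
    cycle_sids <- setdiff(igraph::E(g)$sid, igraph::E(keep)$sid)
    message("assign_reverse_strahler: broke ", length(cycle_sids),
            " cycle segment(s) before ordering")
  }
  tree_sids <- setdiff(vapply(net$segments, function(s) s$id, 0L), cycle_sids)
  # check for a pure cycle with no endpoint at all
  if (!length(tree_sids) && length(cycle_sids))
    stop("network is a pure cycle with no endpoint; cannot be ordered")
  # adjacency over tree segments
  adj <- vector("list", nrow(net$nodes))
  for (sidx in tree_sids) {
    s <- net$segments[[sidx]]
    adj[[s$from]] <- rbind(adj[[s$from]], c(s$id, s$to))
    if (s$to != s$from)
      adj[[s$to]] <- rbind(adj[[s$to]], c(s$id, s$from))
  }
  comp <- igraph::components(g)$membership
  names(comp) <- igraph::V(g)$name
  node_comp <- comp[as.character(net$nodes$id)]

  seg_order <- rep(NA_integer_, length(net$segments))
  seg_channel <- rep(NA_integer_, length(net$segments))
  channels <- list()
  chid <- 0L

  seg_area <- vapply(net$segments, function(s)
    ifelse(is.na(s$mean_xs_area), 0, s$mean_xs_area), 0)
  seg_len <- vapply(net$segments, function(s) s$length_m, 0)

  # longest downward path from `node`, not using segment `from_sid`;
  # returns list(len, area (length-weighted), far_row, far_col, sids)
  longest_from <- function(node, from_sid) {
    nd <- net$nodes[node, ]
    best <- list(len = 0, area = 0, far_row = nd$row, far_col = nd$col,
                 sids = integer(0))
    inc <- adj[[node]]
    if (is.null(inc)) return(best)
    for (k in seq_len(nrow(inc))) {
      sid <- inc[k, 1]
      if (!is.na(from_sid) && sid == from_sid) next
      if (!is.na(seg_order[sid])) next  # already belongs to another channel
      sub <- longest_from(inc[k, 2], sid)
      len <- seg_len[sid] + sub$len
      tot_a <- seg_area[sid] * seg_len[sid] + sub$area * sub$len
      area <- if (len > 0) tot_a / len else 0
      cand <- list(len = len, area = area, far_row = sub$far_row,
                   far_col = sub$far_col, sids = c(sid, sub$sids))
      better <- cand$len > best$len + 1e-12 ||
        (abs(cand$len - best$len) <= 1e-12 &&
           (cand$area > best$area + 1e-12 ||
              (abs(cand$area - best$area) <= 1e-12 &&
                 (cand$far_row < best$far_row ||
                    (cand$far_row == best$far_row &&
                       cand$far_col < best$far_col)))))
      if (length(best$sids) == 0L && length(cand$sids) > 0L) better <- TRUE
      if (better && length(cand$sids)) best <- cand
    }
    best
  }

  assign_channel <- function(root, k, parent_ch, from_sid) {
    path <- longest_from(root, from_sid)
    if (!length(path$sids)) return(invisible(NULL))
    chid <<- chid + 1L
    this_ch <- chid
    channels[[this_ch]] <<- list(id = this_ch, order = k,
                                 segment_ids = path$sids,
                                 parent = parent_ch,
                                 length_m = path$len,
                                 root_node = root,
                                 far_row = path$far_row,
                                 far_col = path$far_col)
    seg_order[path$sids] <<- k
    seg_channel[path$sids] <<- this_ch
    # walk the channel's nodes and recurse into tributary stumps; segments
    # already assigned (the channel itself, earlier channels) are excluded
    node <- root
    for (sid in c(path$sids, NA_integer_)) {
      inc <- adj[[node]]
      for (j in seq_len(NROW(inc))) {
        if (!is.na(seg_order[inc[j, 1]])) next
        assign_channel(node, k + 1L, this_ch, NA_integer_)
      }
      if (is.na(sid)) break
      s <- net$segments[[sid]]
      node <- if (s$from == node) s$to else s$from
    }
    invisible(NULL)
  }

  ordered_comps <- integer(0)
  for (oi in seq_len(nrow(net$outlets))) {
    onode <- net$outlets$node[oi]
    ocomp <- node_comp[onode]
    if (ocomp %in% ordered_comps) next
    ordered_comps <- c(ordered_comps, ocomp)
    assign_channel(onode, 1L, NA_integer_, NA_integer_)
  }
  unordered <- setdiff(unique(node_comp), ordered_comps)
  # components that contain segments but no outlet
  has_segments <- unique(vapply(net$segments, function(s)
    node_comp[s$from], 0))
  unordered <- intersect(unordered, has_segments)
  if (length(unordered))
    message("assign_reverse_strahler: ", length(unordered),
            " component(s) without an outlet left unordered")
  for (i in seq_along(net$segments)) {
    net$segments[[i]]$order <- seg_order[i]
    net$segments[[i]]$channel <- seg_channel[i]
  }
  net$channels <- channels
  attr(net, "cycle_segments") <- cycle_sids
  attr(net, "unordered_components") <- length(unordered)
  net
}

# Ordered pixel path of a channel, junction-to-far-endpoint.
channel_path <- function(net, ch) {
  node <- ch$root_node
  out <- NULL
  for (sid in ch$segment_ids) {
    s <- net$segments[[sid]]
    p <- orient_path_from(s, node)
    out <- if (is.null(out)) p else rbind(out, p[-1, , drop = FALSE])
    node <- if (s$from == node) s$to else s$from
  }
  out
}

#' Export the ordered skeleton as XYC text
#'
#' One `x y order` line per skeleton pixel carrying a reverse-Strahler
#' order, row-major, 3-decimal cell-centre coordinates.
#'
#' @param net an ordered network.
#' @param grid the [elev_grid()] supplying the georeference.
#' @param path output path.
#' @export
write_xyc <- function(net, grid, path) {
  rows <- integer(0); cols <- integer(0); ords <- integer(0)
  for (s in net$segments) {
    if (is.na(s$order)) next
    rows <- c(rows, s$path[, 1]); cols <- c(cols, s$path[, 2])
    ords <- c(ords, rep(s$order, nrow(s$path)))
  }
  if (!length(rows)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  df <- data.frame(row = rows, col = cols, ord = ords)
  df <- df[!duplicated(df[c("row", "col")]), ]
  df <- df[order(df$row, df$col), ]
  writeLines(paste(formatC(cell_x(grid, df$col), format = "f", digits = 3),
                   formatC(cell_y(grid, df$row), format = "f", digits = 3),
                   df$ord), path)
  invisible(path)
}
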