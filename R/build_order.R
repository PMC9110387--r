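# Heuristic build-order reconstruction.
#
# Starting from each endpoint of the comb's curve skeleton (the medial
# tree), the walk moves toward decreasing geodesic travel cost from the
# substrate until a branch of the tree is reached; there the regional
# build direction (mean geodesic gradient) and gravity (cell tilt) are
# re-estimated and the walk continues. Reversing the walk gives a
# plausible construction timeline: the substrate-adjacent segment first,
# then children in order of increasing distance. Segment boundaries are
# skeleton nodes of degree >= 3 and, additionally, sharp bends of the
# skeleton (tangent turning beyond a threshold), which mark mid-build
# reorientations that a pure branch criterion cannot see.

#' Reconstruct a comb construction timeline
#'
#' @param skeleton a `curve_skeleton` (see [curve_skeleton()]).
#' @param geo a `geodesic_field` solved from the substrate.
#' @param cells optional `cell_set` with frames; enables per-segment
#'   gravity estimates.
#' @param plane_per_segment optional function `(cell_ids, cells) ->
#'   median_plane` or a single `median_plane` used for every segment;
#'   default fits a plane to each segment's cell base points.
#' @param bend_angle_deg tangent turn angle that splits a segment
#'   (default 45).
#' @param min_cells_gravity minimum cells for a segment gravity estimate;
#'   smaller segments inherit the parent's gravity and are flagged.
#' @return A `build_timeline`: data frame of segments in construction
#'   order with build direction, gravity, node spans, and flags.
#' @export
reconstruct_build_order <- function(skeleton, geo, cells = NULL,
                                    plane_per_segment = NULL,
                                    bend_angle_deg = 45,
                                    min_cells_gravity = 5) {
  nodes <- skeleton$nodes
  nn <- nrow(nodes)
  if (nn == 0) stopf("empty skeleton")
  tree <- skeleton$edges
  if (nrow(tree) != nn - 1) stopf("skeleton edges do not form a tree")
  nbrs <- vector("list", nn)
  for (e in seq_len(nrow(tree))) {
    a <- tree[e, 1]; b <- tree[e, 2]
    nbrs[[a]] <- c(nbrs[[a]], b)
    nbrs[[b]] <- c(nbrs[[b]], a)
  }
  deg <- lengths(nbrs)

  # skeleton nodes sit mid-comb (often in open cell space where u is
  # infinite), so sample the geodesic field at the nearest voxels with
  # finite travel cost
  node_u <- vapply(seq_len(nn), function(v) {
    ctr <- round((nodes[v, ] - geo$origin_mm) / geo$spacing_mm) + 1
    ctr <- pmin(pmax(ctr, 1), geo$dims)
    for (rad in c(1L, 2L, 4L, 8L, 16L, 32L)) {
      lo <- pmax(ctr - rad, 1)
      hi <- pmin(ctr + rad, geo$dims)
      block <- geo$u[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
      fin <- block[is.finite(block)]
      if (length(fin)) return(min(fin))
    }
    NA_real_
  }, numeric(1))
  if (all(is.na(node_u)))
    stopf("no skeleton node has a finite geodesic value")
  root <- which.min(node_u)
  if (node_u[root] > 0.05 * max(node_u, na.rm = TRUE))
    warnf("geodesic field does not appear rooted at the skeleton (min node u = %.3g)",
          node_u[root])

  # split nodes: branches, and sharp bends of the skeleton
  is_split <- deg >= 3
  for (v in which(deg == 2)) {
    nb <- nbrs[[v]]
    d1 <- normalize3(nodes[nb[1], ] - nodes[v, ])
    d2 <- normalize3(nodes[nb[2], ] - nodes[v, ])
    if (180 - angle_deg(d1, d2) > bend_angle_deg) is_split[v] <- TRUE
  }

  # walk the tree from the root; a split node joins the incoming segment
  # and each of its children starts a fresh one
  seg_of <- integer(nn)
  seg_parent <- integer(0)
  seg_nodes <- list()
  queue <- list(list(node = root, seg = NA_integer_,
                     parent_seg = NA_integer_))
  visited <- logical(nn)
  nseg <- 0L
  while (length(queue)) {
    item <- queue[[1]]
    queue <- queue[-1]
    v <- item$node
    if (visited[v]) next
    visited[v] <- TRUE
    seg <- item$seg
    if (is.na(seg)) {
      nseg <- nseg + 1L
      seg_parent[nseg] <- item$parent_seg
      seg_nodes[[nseg]] <- integer(0)
      seg <- nseg
    }
    seg_of[v] <- seg
    seg_nodes[[seg]] <- c(seg_nodes[[seg]], v)
    for (nb in nbrs[[v]]) {
      if (!visited[nb]) {
        if (is_split[v])
          queue <- c(queue, list(list(node = nb, seg = NA_integer_,
                                      parent_seg = seg)))
        else
          queue <- c(queue, list(list(node = nb, seg = seg,
                                      parent_seg = seg)))
      }
    }
  }

  seg_u <- vapply(seg_nodes, function(ns) mean(node_u[ns], na.rm = TRUE),
                  numeric(1))

  # construction order: topological from the root segment, siblings by
  # ascending mean geodesic value
  order_idx <- rep(NA_integer_, nseg)
  tie_flag <- logical(nseg)
  frontier <- which(is.na(seg_parent))
  nxt_order <- 0L
  while (length(frontier)) {
    o <- frontier[order(seg_u[frontier])]
    if (length(o) > 1) {
      du <- diff(sort(seg_u[frontier]))
      tie_flag[o[which(du < 1e-9) + 1]] <- TRUE
    }
    for (sg in o) {
      order_idx[sg] <- nxt_order
      nxt_order <- nxt_order + 1L
    }
    frontier <- which(seg_parent %in% frontier & is.na(order_idx))
  }

  # per-segment build direction: mean unit geodesic gradient over domain
  # voxels nearest to the segment's nodes
  assign_seg <- nearest_segment_voxels(geo, nodes, seg_of)
  build_dirs <- matrix(NA_real_, nseg, 3)
  for (sg in seq_len(nseg)) {
    reg <- assign_seg == sg & geo$domain_mask & is.finite(geo$u)
    if (sum(reg) >= 50) {
      bd <- build_direction(geo, array(reg, dim = geo$dims), region_id = sg)
      build_dirs[sg, ] <- bd$mean_gradient
    }
  }

  # per-segment gravity from cell tilt
  gravities <- matrix(NA_real_, nseg, 3)
  grav_flag <- logical(nseg)
  if (!is.null(cells)) {
    ctr <- cbind(cells$cells$centroid_x, cells$cells$centroid_y,
                 cells$cells$centroid_z)
    nearest_node <- apply_nearest(ctr, nodes)
    cell_seg <- seg_of[nearest_node]
    for (sg in seq_len(nseg)) {
      ids <- which(cell_seg == sg)
      ids <- intersect(ids, orientation_cells(cells))
      if (length(ids) >= min_cells_gravity) {
        sub <- subset_cell_set(cells, ids)
        plane <- segment_plane(plane_per_segment, sub, ids, cells)
        tg <- try(tilt_and_gravity(sub, plane,
                                   min_cells = min_cells_gravity),
                  silent = TRUE)
        if (!inherits(tg, "try-error")) gravities[sg, ] <- tg$gravity
      }
    }
    # inherit missing gravities from the parent segment
    for (sg in order(order_idx)) {
      if (anyNA(gravities[sg, ]) && !is.na(seg_parent[sg]) &&
          !anyNA(gravities[seg_parent[sg], ])) {
        gravities[sg, ] <- gravities[seg_parent[sg], ]
        grav_flag[sg] <- TRUE
      }
    }
  }

  segs <- data.frame(
    segment = seq_len(nseg),
    order = order_idx,
    parent = seg_parent,
    n_nodes = lengths(seg_nodes),
    mean_u = seg_u,
    build_dir_x = build_dirs[, 1], build_dir_y = build_dirs[, 2],
    build_dir_z = build_dirs[, 3],
    gravity_x = gravities[, 1], gravity_y = gravities[, 2],
    gravity_z = gravities[, 3],
    gravity_inherited = grav_flag,
    order_tie = tie_flag)
  segs <- segs[order(segs$order), ]
  rownames(segs) <- NULL
  structure(list(segments = segs, seg_nodes = seg_nodes, seg_of = seg_of,
                 skeleton = skeleton),
            class = "build_timeline")
}

# nearest skeleton node for each point (rows); returns node indices
apply_nearest <- function(pts, nodes) {
  n <- nrow(pts)
  out <- integer(n)
  chunk <- 20000L
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    block <- pts[s:e, , drop = FALSE]
    d2 <- outer(rowSums(block^2), rep(1, nrow(nodes))) -
      2 * block %*% t(nodes) +
      outer(rep(1, nrow(block)), rowSums(nodes^2))
    out[s:e] <- max.col(-d2, ties.method = "first")
  }
  out
}

# per-voxel segment assignment for domain voxels (0 elsewhere)
nearest_segment_voxels <- function(geo, nodes, seg_of) {
  dims <- geo$dims
  idx <- which(geo$domain_mask & is.finite(geo$u))
  assign <- integer(prod(dims))
  if (!length(idx)) return(array(assign, dim = dims))
  ijk <- arrayInd(idx, dims)
  world <- sweep(sweep(ijk - 1, 2, geo$spacing_mm, `*`), 2,
                 geo$origin_mm, `+`)
  nearest <- apply_nearest(world, nodes)
  assign[idx] <- seg_of[nearest]
  array(assign, dim = dims)
}

# restrict a cell_set to a subset of cell ids (renumbered)
subset_cell_set <- function(cells, ids) {
  keep <- cells$cells$id %in% ids
  tab <- cells$cells[keep, , drop = FALSE]
  old <- tab$id
  tab$id <- seq_len(nrow(tab))
  labels <- array(0L, dim = cells$dims)
  for (k in seq_along(old)) labels[cells$labels == old[k]] <- k
  structure(list(labels = labels, dims = cells$dims,
                 spacing_mm = cells$spacing_mm, origin_mm = cells$origin_mm,
                 cells = tab, frames = cells$frames[old],
                 base_points = if (!is.null(cells$base_points))
                   cells$base_points[old, , drop = FALSE] else NULL),
            class = "cell_set")
}

segment_plane <- function(plane_per_segment, sub, ids, cells) {
  if (inherits(plane_per_segment, "median_plane")) return(plane_per_segment)
  if (is.function(plane_per_segment)) return(plane_per_segment(ids, cells))
  suppressWarnings(median_plane(sub))
}

#' @export
print.build_timeline <- function(x, ...) {
  cat(sprintf("<build_timeline> %d segments\n", nrow(x$segments)))
  print(x$segments[, c("segment", "order", "parent", "n_nodes", "mean_u")])
  invisible(x)
}

#' Tabular and JSON report of a build timeline
#'
#' @param timeline a `build_timeline`.
#' @return A list: `table` (one row per segment, construction order) and
#'   `json` (a JSON string that parses back to the same table).
#' @export
timeline_report <- function(timeline) {
  tab <- timeline$segments
  json <- jsonlite::toJSON(tab, dataframe = "rows", digits = NA, na = "null")
  list(table = tab, json = as.character(json))
}
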