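# Individual cell extraction and tilt/gravity reconstruction.
#
# The negative space of a comb section -- the open cell interiors -- is
# the Boolean difference between the section's morphological closure
# (10-mm ball, wide enough to roof over cell mouths) and the section
# itself. Iterative opening severs the thin sheet that connects cell
# mouths until the connected-component count stabilizes; each component
# is one cell. Per-cell principal-component frames give the cell axis;
# cells tilt upward from the comb's median plane, so the mean in-plane
# projection of the axes points against gravity.

#' Extract individual cells from a comb section
#'
#' @param section a [signed_distance_volume] of the comb section.
#' @param closure_radius_mm ball radius for the closing step (default 10,
#'   large enough to roof over open cell mouths).
#' @param opening_step_mm radius increment of the iterative opening
#'   schedule (default: one voxel spacing).
#' @param max_opening_mm safety cap on the opening radius.
#' @param opening_radius_mm skip the automatic schedule and open with
#'   this fixed radius (useful for cropped comb regions whose clipped
#'   cells keep the component count from settling).
#' @param volume_filter drop connected components whose volume is
#'   outside `[volume_filter[1], volume_filter[2]]` times the median
#'   component volume -- these are closure artifacts (fillets around the
#'   comb's outer rim), not cells. `NULL` disables the filter.
#' @return A `cell_set`: integer label volume (0 = background), a
#'   per-cell table (centroid, voxel count, volume, boundary flag), base
#'   points (deepest voxel of each cell), and grid geometry. The number
#'   of filtered non-cell components is reported in `n_filtered`.
#' @export
extract_cells <- function(section, closure_radius_mm = 10,
                          opening_step_mm = NULL, max_opening_mm = 5,
                          volume_filter = c(0.25, 3),
                          opening_radius_mm = NULL) {
  stopifnot(is_sdf(section))
  h <- check_isotropic(section$spacing_mm, "cell extraction")
  step <- opening_step_mm %||% h
  closed <- sdf_close(section, structuring_ball(closure_radius_mm))
  neg <- sdf_boolean(closed, section, "subtract")
  if (!any(neg$distances < 0))
    stopf("no negative space: the section has no open cells")

  # opening schedule: increase the radius until the component count is
  # stable across consecutive radii; if the count never settles before
  # annihilation, fall back to the most persistent (modal) count
  # Opening on the redistanced difference needs one distance transform
  # per radius: the eroded set reads directly off the SDF (d < -r) and
  # the re-dilation is an EDT threshold. Equivalent to
  # crop(sdf_dilate(sdf_erode(neg, r), r)) but without intermediate
  # redistancing.
  open_mask <- function(r) {
    er <- neg$distances < -r
    if (!any(er)) return(NULL)
    edt_mm(er, neg$dims, neg$spacing_mm) <= r
  }
  if (!is.null(opening_radius_mm)) {
    m <- open_mask(opening_radius_mm)
    if (is.null(m))
      stopf("opening radius %.3g mm annihilates the negative space",
            opening_radius_mm)
    labels <- array(label_components_cpp(as.logical(m),
                                         as.integer(neg$dims), 6L),
                    dim = neg$dims)
    return(finish_cell_set(labels, section, closed, volume_filter,
                           opening_radius_mm, h))
  }
  counts <- integer(0)
  radii <- numeric(0)
  mask_list <- list()
  r <- 0
  best <- NULL
  repeat {
    r <- r + step
    if (r > max_opening_mm) break
    m <- open_mask(r)
    if (is.null(m)) break
    labs <- label_components_cpp(as.logical(m), as.integer(neg$dims), 6L)
    counts <- c(counts, max(labs))
    radii <- c(radii, r)
    mask_list[[length(counts)]] <- m
    n <- length(counts)
    if (n >= 2 && counts[n] == counts[n - 1] && counts[n] > 0) {
      best <- n - 1L
      break
    }
  }
  if (length(counts) == 0)
    stopf("opening annihilated the negative space before cells separated")
  if (is.null(best)) {
    # no consecutive agreement: take the most persistent (modal) count,
    # then the smallest radius showing it
    tab <- table(counts[counts > 0])
    modal <- as.integer(names(tab)[which.max(tab)])
    best <- which(counts == modal)[1]
  }
  labels <- array(label_components_cpp(as.logical(mask_list[[best]]),
                                       as.integer(neg$dims), 6L),
                  dim = neg$dims)
  finish_cell_set(labels, section, closed, volume_filter, radii[best], h)
}

# apply the component-volume filter and assemble the cell_set
finish_cell_set <- function(labels, section, closed, volume_filter,
                            r_open, h) {
  n_filtered <- 0L
  if (!is.null(volume_filter) && max(labels) > 2) {
    counts <- tabulate(labels[labels > 0], nbins = max(labels))
    med <- median(counts)
    keep <- which(counts >= volume_filter[1] * med &
                    counts <= volume_filter[2] * med)
    n_filtered <- max(labels) - length(keep)
    remap <- integer(max(labels))
    remap[keep] <- seq_along(keep)
    labels <- array(ifelse(labels > 0, remap[pmax(labels, 1L)], 0L),
                    dim = dim(labels))
  }
  out <- build_cell_set(labels, section, closed,
                        boundary_margin = as.integer(ceiling(r_open / h)) + 1L)
  out$n_filtered <- n_filtered
  out$opening_radius_mm <- r_open
  out
}

# assemble the cell_set bookkeeping from a label volume
build_cell_set <- function(labels, section, closed = NULL,
                           boundary_margin = 1L) {
  dims <- dim(labels)
  spacing <- section$spacing_mm
  origin <- section$origin_mm
  n_cells <- max(labels)
  if (n_cells == 0) stopf("no cells labeled")
  idx <- which(labels > 0)
  lab <- labels[idx]
  ijk <- arrayInd(idx, dims)
  world <- sweep(sweep(ijk - 1, 2, spacing, `*`), 2, origin, `+`)
  cx <- rowsum(world, lab) / as.vector(table(lab))
  nvox <- as.vector(table(lab))
  # cells whose voxels come within the boundary margin of the grid edge
  # were plausibly clipped by the section (the opening erodes components
  # away from the edge, hence the margin)
  m <- boundary_margin
  on_boundary <- ijk[, 1] <= m | ijk[, 1] > dims[1] - m |
    ijk[, 2] <= m | ijk[, 2] > dims[2] - m |
    ijk[, 3] <= m | ijk[, 3] > dims[3] - m
  btouch <- as.vector(rowsum(as.numeric(on_boundary), lab) > 0)

  # deepest voxel of each cell: farthest from the cell's own mouth (its
  # lumen voxels that border the exterior of the closed comb), measured
  # with a small per-cell distance transform over the cell's bounding box
  base_points <- NULL
  if (!is.null(closed)) {
    exterior <- closed$distances > 0
    if (any(exterior)) {
      cellmask <- labels > 0
      mouth <- array(FALSE, dims)
      for (axis in 1:3) for (dir in c(-1L, 1L)) {
        sl <- lapply(dims, seq_len)
        sl[[axis]] <- pmin(pmax(seq_len(dims[axis]) + dir, 1L), dims[axis])
        shifted <- do.call(`[`, c(list(exterior), sl))
        mouth <- mouth | (cellmask & shifted)
      }
      dref_global <- NULL
      base_points <- t(vapply(seq_len(n_cells), function(cid) {
        sel <- which(lab == cid)
        sub <- ijk[sel, , drop = FALSE]
        lo <- apply(sub, 2, min)
        hi <- apply(sub, 2, max)
        bdims <- hi - lo + 1L
        box_lab <- labels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] == cid
        box_mouth <- mouth[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] & box_lab
        if (any(box_mouth)) {
          dloc <- edt_mm(box_mouth, bdims, spacing)
          dloc[!box_lab] <- -1
          bi <- arrayInd(which.max(dloc), bdims) + lo - 1L
        } else {
          # enclosed cell (no mouth): fall back to the voxel farthest
          # from the closed comb's exterior
          if (is.null(dref_global))
            dref_global <<- edt_mm(exterior, dims, spacing)
          dv <- dref_global[idx[sel]]
          bi <- sub[which.max(dv), ]
        }
        origin + (bi - 1) * spacing
      }, numeric(3)))
    }
  }
  tab <- data.frame(id = seq_len(n_cells),
                    centroid_x = cx[, 1], centroid_y = cx[, 2],
                    centroid_z = cx[, 3],
                    n_voxels = nvox,
                    volume_mm3 = nvox * prod(spacing),
                    boundary_touch = btouch,
                    degenerate = NA,
                    has_frame = FALSE)
  structure(list(labels = labels, dims = dims, spacing_mm = spacing,
                 origin_mm = origin, cells = tab,
                 frames = vector("list", n_cells),
                 base_points = base_points),
            class = "cell_set")
}

#' @export
print.cell_set <- function(x, ...) {
  cat(sprintf("<cell_set> %d cells, %.3g mm^3 total\n",
              nrow(x$cells), sum(x$cells$volume_mm3)))
  invisible(x)
}

#' Per-cell principal-component frames
#'
#' Computes an orthonormal basis for each cell from the principal
#' components of its voxel positions, axes ordered by descending
#' variance. The first axis (the cell's long axis) is oriented to point
#' away from the median plane when one is supplied. Cells whose leading
#' variance ratio is below `degenerate_ratio` (near-spherical blobs) are
#' flagged; their frame is still orthonormal but its axis order is
#' arbitrary.
#'
#' @param cells a `cell_set`.
#' @param plane optional `median_plane` used to orient the principal
#'   axes.
#' @param min_voxels cells below this size keep an empty frame.
#' @param degenerate_ratio flag threshold on sd1/sd2.
#' @return The `cell_set` with `frames` populated (list of 3 x 3
#'   matrices, columns = axes).
#' @export
cell_frames <- function(cells, plane = NULL, min_voxels = 20,
                        degenerate_ratio = 1.2) {
  idx <- which(cells$labels > 0)
  lab <- cells$labels[idx]
  ijk <- arrayInd(idx, cells$dims)
  world <- sweep(sweep(ijk - 1, 2, cells$spacing_mm, `*`), 2,
                 cells$origin_mm, `+`)
  for (cid in cells$cells$id) {
    sel <- lab == cid
    if (sum(sel) < min_voxels) {
      cells$cells$degenerate[cid] <- NA
      next
    }
    P <- world[sel, , drop = FALSE]
    pc <- prcomp(P, center = TRUE)
    ax <- pc$rotation[, 1:3]
    # right-handed frame
    if (sum(cross3(ax[, 1], ax[, 2]) * ax[, 3]) < 0) ax[, 3] <- -ax[, 3]
    degen <- pc$sdev[1] / max(pc$sdev[2], 1e-12) < degenerate_ratio
    if (!is.null(plane) && !degen) {
      ctr <- colMeans(P)
      side <- sign(sum((ctr - plane$point) * plane$normal))
      if (side != 0 && sum(ax[, 1] * plane$normal) * side < 0) {
        ax[, 1] <- -ax[, 1]
        ax[, 2] <- -ax[, 2]  # keep the frame right-handed
      }
    }
    cells$frames[[cid]] <- ax
    cells$cells$degenerate[cid] <- degen
    cells$cells$has_frame[cid] <- TRUE
  }
  cells
}

#' Median plane of a comb section
#'
#' Least-squares plane through the cell base points (the deepest voxel of
#' each cell, farthest from the comb exterior), approximating the
#' interface where the basal sides of the two mirrored cell sheets meet.
#'
#' @param x a `cell_set` from [extract_cells()] (which records base
#'   points), or a [signed_distance_volume] (cells are extracted first
#'   with default parameters).
#' @param ... passed on to [extract_cells()] when `x` is a volume.
#' @return A `median_plane` with fields `point` (mm) and unit `normal`.
#' @export
median_plane <- function(x, ...) {
  if (is_sdf(x)) x <- extract_cells(x, ...)
  if (!inherits(x, "cell_set")) stopf("need a cell_set or an SDF section")
  bp <- x$base_points
  if (is.null(bp)) stopf("cell set carries no base points")
  # cells clipped by the section boundary have unreliable bases
  interior <- !x$cells$boundary_touch
  if (sum(interior) >= 3) bp <- bp[interior, , drop = FALSE]
  if (nrow(bp) < 3)
    stopf("need at least 3 cell base points to fit a plane")
  ctr <- colMeans(bp)
  sv <- svd(sweep(bp, 2, ctr))
  normal <- sv$v[, 3]
  lead <- which(abs(normal) > 1e-8)[1]
  if (normal[lead] < 0) normal <- -normal
  # warn when all cells open to the same side (single-sheet input)
  side <- sign((cbind(x$cells$centroid_x, x$cells$centroid_y,
                      x$cells$centroid_z) - matrix(ctr, nrow(x$cells), 3,
                                                   byrow = TRUE)) %*% normal)
  if (length(unique(side[side != 0])) < 2)
    warnf("all cells lie on one side of the fitted plane (single sheet?)")
  structure(list(point = ctr, normal = normalize3(normal)),
            class = "median_plane")
}

#' @export
print.median_plane <- function(x, ...) {
  cat(sprintf("<median_plane> point (%.2f, %.2f, %.2f), normal (%.3f, %.3f, %.3f)\n",
              x$point[1], x$point[2], x$point[3],
              x$normal[1], x$normal[2], x$normal[3]))
  invisible(x)
}

# usable cells for orientation statistics: framed, non-degenerate, not
# clipped by the section boundary
orientation_cells <- function(cells) {
  ok <- cells$cells$has_frame & !is.na(cells$cells$degenerate) &
    !cells$cells$degenerate & !cells$cells$boundary_touch
  which(ok)
}

#' Cell tilt and reconstructed gravity direction
#'
#' The tilt of a cell is the angle between its long axis and the median
#' plane normal (canonically about 13 degrees, pointing upward). Because
#' bees build honey-holding cells tilted against gravity, the direction
#' of gravity at construction time is recovered as the negated robust
#' mean (componentwise median, re-normalized) of the unit in-plane
#' projections of the cell axes.
#'
#' @param cells a `cell_set` with frames (see [cell_frames()]).
#' @param plane a `median_plane`.
#' @param min_cells minimum number of usable cells (default 5).
#' @return A list with `tilt_deg` (per usable cell), `mean_tilt_deg`,
#'   `gravity` (unit 3-vector), `cell_ids`.
#' @export
tilt_and_gravity <- function(cells, plane, min_cells = 5) {
  use <- orientation_cells(cells)
  if (length(use) < min_cells)
    stopf("only %d usable cells (need >= %d)", length(use), min_cells)
  n <- plane$normal
  axes <- t(vapply(use, function(cid) cells$frames[[cid]][, 1], numeric(3)))
  dots <- axes %*% n
  tilt <- rad2deg(acos(pmin(pmax(abs(dots), 0), 1)))
  proj <- axes - dots %*% t(n)
  plen <- sqrt(rowSums(proj^2))
  if (median(plen) < 0.05)
    stopf("tilt unresolvable: cell axes are perpendicular to the plane")
  unit_proj <- proj / plen
  up <- apply(unit_proj, 2, median)
  gravity <- -normalize3(up)
  list(tilt_deg = as.numeric(tilt), mean_tilt_deg = mean(tilt),
       gravity = gravity, cell_ids = use)
}

#' Per-cell size metrics
#'
#' Depth is the voxel extent along the cell's long axis; width is the
#' minimal caliper extent over directions perpendicular to that axis --
#' for a hexagonal cell this is the flat-to-flat width, the quantity
#' apiarists report as cell width. One voxel spacing is added to both
#' extents to account for voxel footprints. Volume is voxel count times
#' voxel volume.
#'
#' @param cells a `cell_set` with frames.
#' @param plane a `median_plane` (for the tilt column).
#' @param n_caliper_directions directions sampled for the width caliper.
#' @return A data frame: `id`, `width_mm`, `depth_mm`, `volume_mm3`,
#'   `tilt_deg`.
#' @export
cell_metrics <- function(cells, plane, n_caliper_directions = 90) {
  h <- check_isotropic(cells$spacing_mm)
  idx <- which(cells$labels > 0)
  lab <- cells$labels[idx]
  ijk <- arrayInd(idx, cells$dims)
  world <- sweep(sweep(ijk - 1, 2, cells$spacing_mm, `*`), 2,
                 cells$origin_mm, `+`)
  nvec <- plane$normal
  theta <- seq(0, pi, length.out = n_caliper_directions + 1)[-1]
  rows <- lapply(cells$cells$id, function(cid) {
    if (!cells$cells$has_frame[cid])
      return(data.frame(id = cid, width_mm = NA, depth_mm = NA,
                        volume_mm3 = cells$cells$volume_mm3[cid],
                        tilt_deg = NA))
    P <- world[lab == cid, , drop = FALSE]
    ax <- cells$frames[[cid]]
    t1 <- P %*% ax[, 1]
    depth <- diff(range(t1)) + h
    u <- P %*% ax[, 2]
    v <- P %*% ax[, 3]
    widths <- vapply(theta, function(a) {
      w <- u * cos(a) + v * sin(a)
      diff(range(w)) + h
    }, numeric(1))
    dotn <- abs(sum(ax[, 1] * nvec))
    data.frame(id = cid, width_mm = min(widths), depth_mm = depth,
               volume_mm3 = cells$cells$volume_mm3[cid],
               tilt_deg = rad2deg(acos(min(max(dotn, 0), 1))))
  })
  do.call(rbind, rows)
}
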