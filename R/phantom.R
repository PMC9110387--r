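# Deterministic synthetic comb phantoms.
#
# The generator voxelizes an idealized A. mellifera comb: double-sided
# sheets of hexagonal cells that meet at a median interface plane, with
# the field's canonical geometry as defaults (lumen edge 2.5 mm within
# the reported 2.25-2.75 mm range, wall thickness 0.75 mm, cell depth
# 10.5 mm within 10-11 mm, 13 degree upward cell tilt, 8.5 mm lobe
# spacing within 7-10 mm). Cells are sheared prisms: the hexagonal
# cross-section stays parallel to the median plane while the extrusion
# axis tilts upward, so cell mouths lie in the comb face. Hexagons are
# point-up with one vertex toward the substrate, which hangs the comb
# from a denser support slab at the top of the grid. Optional global
# warps (cylinder bend, saddle, L-bend, Y-branch) and material bands
# (wax, honey, substrate, a higher-density repair seam) complete the
# phantom. Every voxel is a pure function of the spec and seed, so the
# same spec generates bitwise-identical volumes.

#' Synthetic comb phantom specification
#'
#' @param cell_edge_mm hexagonal lumen edge length (mm).
#' @param wall_thickness_mm wax wall thickness between lumens (mm); also
#'   the thickness of the basal septum at the interface.
#' @param cell_depth_mm lumen depth along the cell axis projection onto
#'   the median-plane normal (mm).
#' @param tilt_deg upward tilt of the cell axis away from the
#'   median-plane normal (degrees).
#' @param lobe_spacing_mm center-to-center spacing of parallel lobes.
#' @param rows,cols lattice extent for `layout = "grid"`.
#' @param n_rings hex rings for `layout = "disc"` (4 rings = 37 cells).
#' @param layout `"grid"` (rows x cols parallelogram) or `"disc"`
#'   (centered hexagonal patch).
#' @param sides 2 for a double-sided sheet, 1 for a single-sided sheet
#'   on a backing septum.
#' @param n_lobes number of parallel comb lobes.
#' @param warp `"none"`, `"cylinder_bend"`, `"saddle"`, `"l_bend"`, or
#'   `"y_branch"`.
#' @param warp_amplitude bend radius in mm (cylinder), saddle coefficient
#'   in 1/mm, or hinge angle in degrees (l_bend / y_branch).
#' @param hinge_frac position of the warp hinge along the comb's
#'   vertical extent (0 = bottom, 1 = top; default 0.5).
#' @param spacing_mm isotropic voxel spacing.
#' @param densities physical densities in g/cm^3 for wax, honey,
#'   substrate, seam; normalized voxel values are density / 2 (the
#'   phantom's known calibration line).
#' @param honey_cell_fraction fraction of cells holding honey.
#' @param honey_fill_fraction per-cell lumen fill depth fraction.
#' @param honey_target_mm3 if set, fill cells base-up in seeded order to
#'   exactly this planted honey volume (overrides the fractions).
#' @param rim_mm width of the solid wax band between the outermost
#'   lumens and the comb's outer boundary.
#' @param seam_radius_mm if > 0, plant a spherical repair seam of
#'   `densities["seam"]` centered on the comb interface.
#' @param substrate include the support slab the comb hangs from.
#' @param substrate_thickness_mm slab thickness.
#' @param margin_mm air margin around the solid.
#' @param rng_seed seed for the honey-cell draw.
#' @return A `comb_phantom_spec`.
#' @export
comb_phantom_spec <- function(cell_edge_mm = 2.5, wall_thickness_mm = 0.75,
                              cell_depth_mm = 10.5, tilt_deg = 13,
                              lobe_spacing_mm = 8.5, rows = 4, cols = 5,
                              n_rings = 4, layout = c("grid", "disc"),
                              sides = 2, n_lobes = 1,
                              warp = c("none", "cylinder_bend", "saddle",
                                       "l_bend", "y_branch"),
                              warp_amplitude = 0, hinge_frac = 0.5,
                              spacing_mm = 0.2,
                              densities = c(wax = 0.93, honey = 1.4,
                                            substrate = 1.19, seam = 1.05),
                              honey_cell_fraction = 0,
                              honey_fill_fraction = 0.75,
                              honey_target_mm3 = NULL, rim_mm = 2,
                              seam_radius_mm = 0, substrate = TRUE,
                              substrate_thickness_mm = 2,
                              margin_mm = 2.5, rng_seed = 1) {
  layout <- match.arg(layout)
  warp <- match.arg(warp)
  spec <- list(cell_edge_mm = cell_edge_mm,
               wall_thickness_mm = wall_thickness_mm,
               cell_depth_mm = cell_depth_mm, tilt_deg = tilt_deg,
               lobe_spacing_mm = lobe_spacing_mm, rows = rows, cols = cols,
               n_rings = n_rings, layout = layout, sides = sides,
               n_lobes = n_lobes, warp = warp,
               warp_amplitude = warp_amplitude, hinge_frac = hinge_frac,
               spacing_mm = spacing_mm,
               densities = densities,
               honey_cell_fraction = honey_cell_fraction,
               honey_fill_fraction = honey_fill_fraction,
               honey_target_mm3 = honey_target_mm3, rim_mm = rim_mm,
               seam_radius_mm = seam_radius_mm, substrate = substrate,
               substrate_thickness_mm = substrate_thickness_mm,
               margin_mm = margin_mm, rng_seed = rng_seed)
  lens <- c(cell_edge_mm, wall_thickness_mm, cell_depth_mm, spacing_mm)
  if (any(lens <= 0)) stopf("all lengths must be positive")
  if (wall_thickness_mm < 2 * spacing_mm)
    stopf("insufficient resolution: wall (%.3g mm) thinner than 2 voxels",
          wall_thickness_mm)
  structure(spec, class = "comb_phantom_spec")
}

# selected lattice coordinates (i, j) for a spec
phantom_lattice <- function(spec) {
  e <- spec$cell_edge_mm
  t <- spec$wall_thickness_mm
  D <- sqrt(3) * e + t            # lumen center pitch
  u1 <- c(D, 0)
  u2 <- c(D / 2, D * sqrt(3) / 2)
  if (spec$layout == "grid") {
    g <- expand.grid(i = 0:(spec$cols - 1), j = 0:(spec$rows - 1))
    # stagger alternate rows back so the footprint is rectangular
    sel <- cbind(g$i - g$j %/% 2, g$j)
  } else {
    n <- spec$n_rings - 1
    g <- expand.grid(i = -n:n, j = -n:n)
    hexdist <- (abs(g$i) + abs(g$j) + abs(g$i + g$j)) / 2
    sel <- as.matrix(g[hexdist <= n, ])
  }
  raw <- cbind(sel[, 1] * u1[1] + sel[, 2] * u2[1],
               sel[, 2] * u2[2])
  shift <- -colMeans(raw)
  list(e = e, t = t, D = D, u1 = u1, u2 = u2, sel = sel,
       centers = sweep(raw, 2, shift, `+`), shift = shift,
       e_out = D / sqrt(3))
}

# point-up hexagon membership, centered at origin, edge `edge`
in_hex <- function(dy, dz, edge) {
  abs(dy) <= sqrt(3) * edge / 2 + 1e-12 &
    abs(dz) <= edge - abs(dy) / sqrt(3) + 1e-12
}

# Flat-frame evaluator: material id (0 air, 1 wax, 2 lumen-interior,
# 3 substrate), cell key and axial depth d for lumen voxels. The lumen
# interior is reported as id 2 so honey can be assigned afterwards;
# un-filled lumen becomes air.
phantom_flat_eval <- function(qx, qy, qz, spec, lat, geom) {
  n <- length(qx)
  mat <- integer(n)
  cellkey <- rep(NA_integer_, n)
  ddepth <- rep(NA_real_, n)

  if (spec$substrate) {
    sub <- qz > geom$sub_lo & qz <= geom$sub_hi &
      abs(qx) <= geom$sub_x & qy >= geom$sub_y[1] & qy <= geom$sub_y[2]
    mat[sub] <- 3L
  }
  d <- abs(qx)
  if (spec$sides == 1) d[qx < 0] <- Inf  # single-sided: no comb at x < 0
  inslab <- d <= geom$cap & mat == 0L
  if (!any(inslab)) return(list(mat = mat, cellkey = cellkey, d = ddepth))

  ii <- which(inslab)
  # lattice coordinates in the unshifted frame
  zz <- qz[ii] - d[ii] * geom$tan_tilt - lat$shift[2]
  yy <- qy[ii] - lat$shift[1]
  jf <- zz / lat$u2[2]
  iffrac <- (yy - jf * lat$u2[1]) / lat$u1[1]
  i0 <- floor(iffrac)
  j0 <- floor(jf)
  li <- rep(NA_integer_, length(ii))
  lj <- rep(NA_integer_, length(ii))
  dy <- rep(NA_real_, length(ii))
  dz <- rep(NA_real_, length(ii))
  for (off in list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))) {
    cand_i <- i0 + off[1]
    cand_j <- j0 + off[2]
    cy <- cand_i * lat$u1[1] + cand_j * lat$u2[1]
    cz <- cand_j * lat$u2[2]
    hit <- is.na(li) & in_hex(yy - cy, zz - cz, lat$e_out)
    li[hit] <- cand_i[hit]
    lj[hit] <- cand_j[hit]
    dy[hit] <- (yy - cy)[hit]
    dz[hit] <- (zz - cz)[hit]
  }
  # comb footprint: a solid rim band surrounds the outermost lumens
  # (footprint is tested in the recentered world frame)
  yw <- yy + lat$shift[1]
  zw <- zz + lat$shift[2]
  if (geom$foot_kind == "disc") {
    infoot <- yw^2 + zw^2 <= geom$foot_radius^2
  } else {
    infoot <- yw >= geom$foot_lo[1] & yw <= geom$foot_hi[1] &
      zw >= geom$foot_lo[2] & zw <= geom$foot_hi[2]
  }
  selkey <- geom$sel_keys
  key <- li * 100000L + lj
  incell <- !is.na(li) & key %in% selkey
  # cells are true prisms about the tilted axis: the cross-section
  # perpendicular to the axis is the regular hexagon, which in these
  # sheared (base-plane) coordinates is the hexagon with dz scaled by
  # cos(tilt); lumen depth is measured along the axis
  # the basal septum (|x| <= wall/2) stays solid: without that cut the
  # tilted prisms of the two mirrored sheets would meet through the
  # interface near the hexagon tops
  taxial <- d[ii] / geom$cos_tilt + dz * geom$sin_tilt
  lumen <- incell & in_hex(dy, dz * geom$cos_tilt, lat$e) &
    taxial > geom$t_base & taxial <= geom$t_base + geom$depth &
    d[ii] > geom$base_half
  wall <- infoot & !lumen
  mat[ii[wall]] <- 1L
  mat[ii[lumen]] <- 2L
  cellkey[ii[lumen]] <- key[lumen]
  ddepth[ii[lumen]] <- taxial[lumen]

  if (spec$seam_radius_mm > 0) {
    sm <- mat == 1L &
      (qx - geom$seam_center[1])^2 + (qy - geom$seam_center[2])^2 +
      (qz - geom$seam_center[3])^2 <= spec$seam_radius_mm^2
    mat[sm] <- 4L
  }
  list(mat = mat, cellkey = cellkey, d = ddepth)
}

# forward/inverse warp machinery; each warp yields a list of candidate
# inverse maps with validity predicates in flat coordinates
warp_forward <- function(spec, geom, p) {
  zc <- geom$hinge_z
  switch(spec$warp,
    none = p,
    cylinder_bend = {
      R <- spec$warp_amplitude
      phi <- (zc - p[, 3]) / R
      phi <- pmax(phi, 0)  # above the hinge stays flat
      cbind(R - (R - p[, 1]) * cos(phi), p[, 2], zc - (R - p[, 1]) * sin(phi))
    },
    saddle = {
      A <- spec$warp_amplitude
      cbind(p[, 1] + A * (p[, 2]^2 - (p[, 3] - zc)^2), p[, 2], p[, 3])
    },
    l_bend = {
      # rotate the lower half about the hinge line through the -x comb
      # face so the bent arm swings clear of the upper half
      b <- deg2rad(spec$warp_amplitude)
      hx <- geom$hinge_x
      lower <- p[, 3] < zc
      out <- p
      x <- p[lower, 1] - hx; z <- p[lower, 3] - zc
      out[lower, 1] <- hx + cos(b) * x + sin(b) * z
      out[lower, 3] <- zc - sin(b) * x + cos(b) * z
      out
    },
    y_branch = {
      stopf("y_branch has no single forward map; branches are sampled separately")
    })
}

# list of candidate inverse maps: each function(world n x 3) ->
# list(q = n x 3 flat coords, valid = logical)
warp_inverse_candidates <- function(spec, geom) {
  zc <- geom$hinge_z
  if (spec$warp == "none" || spec$warp == "saddle") {
    if (spec$warp == "none")
      return(list(function(w) list(q = w, valid = rep(TRUE, nrow(w)))))
    A <- spec$warp_amplitude
    return(list(function(w)
      list(q = cbind(w[, 1] - A * (w[, 2]^2 - (w[, 3] - zc)^2),
                     w[, 2], w[, 3]),
           valid = rep(TRUE, nrow(w)))))
  }
  if (spec$warp == "cylinder_bend") {
    R <- spec$warp_amplitude
    return(list(function(w) {
      above <- w[, 3] >= zc
      rw <- sqrt((w[, 1] - R)^2 + (w[, 3] - zc)^2)
      phi <- atan2(zc - w[, 3], R - w[, 1])
      q <- cbind(ifelse(above, w[, 1], R - rw), w[, 2],
                 ifelse(above, w[, 3], zc - R * phi))
      list(q = q, valid = above | phi >= 0)
    }))
  }
  rot_cand <- function(beta, hx) {
    b <- deg2rad(beta)
    function(w) {
      x <- w[, 1] - hx; z <- w[, 3] - zc
      qx <- hx + cos(b) * x - sin(b) * z
      qz <- zc + sin(b) * x + cos(b) * z
      list(q = cbind(qx, w[, 2], qz), valid = qz < zc)
    }
  }
  ident_cand <- function(w) list(q = w, valid = w[, 3] >= zc)
  if (spec$warp == "l_bend")
    return(list(ident_cand,
                rot_cand(spec$warp_amplitude, geom$hinge_x)))
  # y_branch: flat trunk above the hinge, two mirrored branches below.
  # The branch swinging toward -x pivots about the +x comb face (and
  # vice versa) so the branches clear each other as soon as possible.
  list(ident_cand, rot_cand(spec$warp_amplitude, -geom$hinge_x),
       rot_cand(-spec$warp_amplitude, geom$hinge_x))
}

#' Generate a synthetic comb phantom
#'
#' Voxelizes the comb described by a [comb_phantom_spec()] and returns
#' the normalized density volume together with the complete ground
#' truth: per-cell centers and axes, interface plane, planted gravity,
#' per-material voxel counts, planted honey volume, and (for branched
#' warps) the growth order of segments.
#'
#' @param spec a [comb_phantom_spec].
#' @return A list `volume` ([density_volume]) and `truth` (list).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "comb_phantom_spec"))
  h <- spec$spacing_mm
  lat <- phantom_lattice(spec)
  tau <- deg2rad(spec$tilt_deg)
  base_half <- spec$wall_thickness_mm / 2
  cap <- base_half + spec$cell_depth_mm * cos(tau)

  # flat-frame footprint extents (lumens plus the solid rim band)
  band <- lat$e_out + spec$rim_mm
  if (spec$layout == "disc") {
    foot_kind <- "disc"
    foot_radius <- max(sqrt(rowSums(lat$centers^2))) + band
    yr <- c(-1, 1) * foot_radius
    zr <- c(-1, 1) * foot_radius
    foot_lo <- foot_hi <- NULL
  } else {
    foot_kind <- "rect"
    foot_radius <- NULL
    foot_lo <- c(min(lat$centers[, 1]), min(lat$centers[, 2])) - band
    foot_hi <- c(max(lat$centers[, 1]), max(lat$centers[, 2])) + band
    yr <- c(foot_lo[1], foot_hi[1])
    zr <- c(foot_lo[2], foot_hi[2])
  }
  drift <- cap * tan(tau)
  geom <- list(cap = cap, base_half = base_half, tan_tilt = tan(tau),
               cos_tilt = cos(tau), sin_tilt = sin(tau),
               t_base = base_half / cos(tau), depth = spec$cell_depth_mm,
               foot_kind = foot_kind, foot_radius = foot_radius,
               foot_lo = foot_lo, foot_hi = foot_hi,
               sel_keys = lat$sel[, 1] * 100000L + lat$sel[, 2],
               sub_lo = zr[2] - 0.2,
               sub_hi = zr[2] + drift + spec$substrate_thickness_mm,
               sub_x = cap + 1, sub_y = yr + c(-1, 1),
               seam_center = c(0, mean(yr), mean(zr)),
               hinge_z = zr[1] + spec$hinge_frac * (zr[2] - zr[1]),
               hinge_x = -cap)

  # world bounding box via forward warp of flat bbox samples
  zmax <- if (spec$substrate) geom$sub_hi else zr[2] + drift
  flat_lo <- c(-cap, yr[1], zr[1])
  flat_hi <- c(cap, yr[2] + 1, zmax)
  gs <- as.matrix(expand.grid(x = seq(flat_lo[1], flat_hi[1], length.out = 9),
                              y = seq(flat_lo[2], flat_hi[2], length.out = 9),
                              z = seq(flat_lo[3], flat_hi[3], length.out = 17)))
  if (spec$warp == "y_branch") {
    b <- spec$warp_amplitude
    sp2 <- spec; sp2$warp <- "l_bend"
    w1 <- warp_forward(sp2, geom, gs)
    sp2$warp_amplitude <- -b
    geom2 <- geom; geom2$hinge_x <- -geom$hinge_x
    w2 <- warp_forward(sp2, geom2, gs)
    wpts <- rbind(w1, w2)
  } else {
    wpts <- warp_forward(spec, geom, gs)
  }
  m <- spec$margin_mm
  lo <- apply(wpts, 2, min) - m
  hi <- apply(wpts, 2, max) + m
  if (spec$n_lobes > 1) {
    span <- (spec$n_lobes - 1) * spec$lobe_spacing_mm / 2
    lo[1] <- lo[1] - span; hi[1] <- hi[1] + span
  }
  dims <- pmax(ceiling((hi - lo) / h) + 1L, 2L)
  origin <- lo
  xs <- origin[1] + (seq_len(dims[1]) - 1) * h
  ys <- origin[2] + (seq_len(dims[2]) - 1) * h
  zs <- origin[3] + (seq_len(dims[3]) - 1) * h
  n <- prod(dims)
  W <- cbind(rep(xs, times = dims[2] * dims[3]),
             rep(rep(ys, each = dims[1]), times = dims[3]),
             rep(zs, each = dims[1] * dims[2]))

  lobe_off <- (seq_len(spec$n_lobes) - (spec$n_lobes + 1) / 2) *
    spec$lobe_spacing_mm
  cands <- warp_inverse_candidates(spec, geom)
  mat <- integer(n)
  cellkey <- rep(NA_real_, n)
  ddepth <- rep(NA_real_, n)
  for (lb in seq_len(spec$n_lobes)) {
    for (ci in seq_along(cands)) {
      cand <- cands[[ci]](W)
      use <- which(cand$valid)
      if (!length(use)) next
      q <- cand$q[use, , drop = FALSE]
      ev <- phantom_flat_eval(q[, 1] - lobe_off[lb], q[, 2], q[, 3],
                              spec, lat, geom)
      better <- ev$mat > mat[use]
      tgt <- use[better]
      mat[tgt] <- ev$mat[better]
      cellkey[tgt] <- ifelse(is.na(ev$cellkey[better]), NA,
                             ev$cellkey[better] + (ci - 1) * 1e10 +
                               (lb - 1) * 1e12)
      ddepth[tgt] <- ev$d[better]
    }
  }

  # honey assignment inside lumens (mat == 2)
  honey_sel <- integer(0)
  lum <- which(mat == 2L)
  n_honey_planned <- 0
  if (length(lum)) {
    keys <- unique(cellkey[lum])
    target_vox <- NULL
    if (!is.null(spec$honey_target_mm3)) {
      target_vox <- round(spec$honey_target_mm3 / h^3)
    } else if (spec$honey_cell_fraction > 0) {
      n_cells_fill <- round(spec$honey_cell_fraction * length(keys))
    } else n_cells_fill <- 0
    ordkeys <- with_seed(spec$rng_seed, sample(keys))
    if (!is.null(target_vox)) {
      acc <- integer(0)
      for (k in ordkeys) {
        if (length(acc) >= target_vox) break
        vox <- lum[cellkey[lum] == k]
        vox <- vox[order(ddepth[vox])]
        need <- target_vox - length(acc)
        acc <- c(acc, vox[seq_len(min(need, length(vox)))])
      }
      honey_sel <- acc
    } else if (n_cells_fill > 0) {
      fillkeys <- ordkeys[seq_len(n_cells_fill)]
      for (k in fillkeys) {
        vox <- lum[cellkey[lum] == k]
        dmax <- geom$t_base + spec$honey_fill_fraction * spec$cell_depth_mm
        honey_sel <- c(honey_sel, vox[ddepth[vox] <= dmax])
      }
    }
    n_honey_planned <- length(honey_sel)
  }

  dens <- spec$densities
  vals <- numeric(n)
  vals[mat == 1L] <- dens[["wax"]] / 2
  vals[mat == 3L] <- dens[["substrate"]] / 2
  vals[mat == 4L] <- dens[["seam"]] / 2
  vals[honey_sel] <- dens[["honey"]] / 2
  vol <- density_volume(array(vals, dim = dims), h, origin)

  # ground truth ----------------------------------------------------------
  sides <- if (spec$sides == 2) c(1, -1) else 1
  cells <- do.call(rbind, lapply(seq_len(spec$n_lobes), function(lb) {
    do.call(rbind, lapply(sides, function(s) {
      tmid <- geom$t_base + spec$cell_depth_mm / 2
      ctr_flat <- cbind(s * tmid * cos(tau) + lobe_off[lb],
                        lat$centers[, 1],
                        lat$centers[, 2] + tmid * sin(tau))
      ax_flat <- c(s * cos(tau), 0, sin(tau))
      data.frame(lobe = lb, side = s, i = lat$sel[, 1], j = lat$sel[, 2],
                 x = ctr_flat[, 1], y = ctr_flat[, 2], z = ctr_flat[, 3],
                 ax = ax_flat[1], ay = ax_flat[2], az = ax_flat[3])
    }))
  }))
  if (spec$warp %in% c("l_bend", "cylinder_bend")) {
    wc <- warp_forward(spec, geom, as.matrix(cells[, c("x", "y", "z")]))
    if (spec$warp == "l_bend") {
      b <- deg2rad(spec$warp_amplitude)
      lower <- cells$z < geom$hinge_z
      axr <- cbind(cos(b) * cells$ax + sin(b) * cells$az, cells$ay,
                   -sin(b) * cells$ax + cos(b) * cells$az)
      cells[lower, c("ax", "ay", "az")] <- axr[lower, ]
    }
    cells[, c("x", "y", "z")] <- wc
  }
  gravity <- c(0, 0, -1)
  truth <- list(
    n_cells = nrow(cells), n_cells_per_side = nrow(lat$sel),
    cells = cells,
    interface_point = c(0, 0, mean(zr)), interface_normal = c(1, 0, 0),
    gravity = gravity, growth_axis = c(0, 0, -1),
    tilt_deg = spec$tilt_deg,
    lumen_width_mm = sqrt(3) * spec$cell_edge_mm,
    cell_depth_mm = spec$cell_depth_mm,
    material_voxels = c(air = sum(mat == 0L) + sum(mat == 2L) -
                          length(honey_sel),
                        wax = sum(mat == 1L),
                        honey = length(honey_sel),
                        substrate = sum(mat == 3L),
                        seam = sum(mat == 4L)),
    honey_mm3 = length(honey_sel) * h^3,
    seam_center = geom$seam_center,
    hinge_z = geom$hinge_z,
    calibration = c(slope = 2, intercept = 0),
    substrate_value = dens[["substrate"]] / 2,
    euler_characteristic = 2,
    spec = spec)
  if (spec$warp == "l_bend") {
    b <- deg2rad(spec$warp_amplitude)
    truth$segment_gravity <- list(upper = c(0, 0, -1),
                                  lower = c(-sin(b), 0, -cos(b)))
  }
  if (spec$warp == "y_branch") {
    truth$growth_order <- c("trunk", "branch_pos", "branch_neg")
  }
  list(volume = vol, truth = truth)
}
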