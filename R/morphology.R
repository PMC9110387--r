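# Morphological and Boolean operators on signed distance volumes.
#
# Dilation by a ball of radius r keeps the voxels whose signed distance is
# at most r (an outward offset of the level set); erosion keeps those
# strictly below -r (an inward offset, the dual of dilating the
# complement by a closed ball). Every operator re-establishes an exact
# signed distance field afterwards, so compositions do not accumulate
# level-set drift beyond one voxel.

#' Ball structuring element
#'
#' @param radius_mm ball radius in mm; must be at least one voxel spacing
#'   of the volume it is applied to.
#' @return An object of class `structuring_ball`.
#' @export
structuring_ball <- function(radius_mm) {
  if (radius_mm <= 0) stopf("ball radius must be positive")
  structure(list(radius_mm = radius_mm), class = "structuring_ball")
}

ball_radius <- function(ball) {
  if (inherits(ball, "structuring_ball")) ball$radius_mm
  else as.numeric(ball)
}

check_ball <- function(sdf, ball) {
  h <- check_isotropic(sdf$spacing_mm, "morphology")
  r <- ball_radius(ball)
  if (r < h - 1e-12)
    stopf("ball radius %.3g mm is smaller than the voxel spacing %.3g mm",
          r, h)
  list(h = h, r = r)
}

# extend the grid by n voxels of outside space on every face
pad_mask <- function(mask, n) {
  d <- dim(mask)
  out <- array(FALSE, dim = d + 2L * n)
  out[n + seq_len(d[1]), n + seq_len(d[2]), n + seq_len(d[3])] <- mask
  out
}

# re-establish an exact SDF from an inside mask on the (possibly padded)
# grid of `sdf`
redistance_mask <- function(mask, sdf, pad = 0L) {
  origin <- sdf$origin_mm - pad * sdf$spacing_mm
  sdf_from_mask(mask, sdf$spacing_mm, origin, sdf$iso_threshold)
}

#' Dilate a solid by a ball
#'
#' Offsets the zero level set outward by the ball radius. With
#' `auto_pad = TRUE` (default) the grid is grown by `ceil(r/h) + 2`
#' voxels per face so the dilated solid cannot overflow.
#'
#' @param sdf a [signed_distance_volume].
#' @param ball a [structuring_ball] (or radius in mm).
#' @param auto_pad grow the grid to accommodate the offset; if `FALSE`
#'   and the dilation reaches the grid boundary, an error is raised.
#' @return A [signed_distance_volume].
#' @export
sdf_dilate <- function(sdf, ball, auto_pad = TRUE) {
  p <- check_ball(sdf, ball)
  mask <- sdf$distances <= p$r
  pad <- if (auto_pad) as.integer(ceiling(p$r / p$h)) + 2L else 0L
  if (!auto_pad) {
    faces <- c(mask[1, , ], mask[dim(mask)[1], , ], mask[, 1, ],
               mask[, dim(mask)[2], ], mask[, , 1], mask[, , dim(mask)[3]])
    if (any(faces))
      stopf("dilation reaches the grid boundary; enable auto_pad")
    return(redistance_mask(mask, sdf, 0L))
  }
  # the offset solid extends into the padding: take the sub-voxel-aware
  # threshold on the original grid, united with the exact voxel-center
  # Minkowski ball computed on the padded grid
  inside <- pad_mask(sdf$distances < 0, pad)
  dil <- edt_mm(inside, dim(inside), sdf$spacing_mm) <= p$r
  dil[pad + seq_len(sdf$dims[1]), pad + seq_len(sdf$dims[2]),
      pad + seq_len(sdf$dims[3])] <- mask
  redistance_mask(dil, sdf, pad)
}

#' Erode a solid by a ball
#'
#' Offsets the zero level set inward by the ball radius: a voxel survives
#' only if the whole closed ball around it lies inside the solid. Eroding
#' past the medial axis annihilates the solid (an empty field, all
#' distances positive).
#'
#' @inheritParams sdf_dilate
#' @return A [signed_distance_volume] (possibly empty).
#' @export
sdf_erode <- function(sdf, ball) {
  p <- check_ball(sdf, ball)
  mask <- sdf$distances < -p$r
  if (!any(mask)) {
    # annihilated: positive distances everywhere, capped at grid diagonal
    d <- array(grid_diagonal(sdf$dims, sdf$spacing_mm), dim = sdf$dims)
    return(signed_distance_volume(d, sdf$spacing_mm, sdf$origin_mm,
                                  sdf$iso_threshold))
  }
  redistance_mask(mask, sdf, 0L)
}

# crop a (padded) SDF back onto a reference grid
crop_to_grid <- function(sdf, ref) {
  off <- round((ref$origin_mm - sdf$origin_mm) / sdf$spacing_mm)
  if (any(abs((ref$origin_mm - sdf$origin_mm) / sdf$spacing_mm - off) > 1e-6))
    stopf("grids are not aligned; cannot crop")
  idx <- lapply(1:3, function(a) off[a] + seq_len(ref$dims[a]))
  signed_distance_volume(sdf$distances[idx[[1]], idx[[2]], idx[[3]]],
                         ref$spacing_mm, ref$origin_mm, sdf$iso_threshold)
}

#' Morphological closing (dilate then erode)
#'
#' Fills gaps and concavities narrower than twice the ball radius; the
#' result is returned on the input grid.
#'
#' @inheritParams sdf_dilate
#' @return A [signed_distance_volume] on the grid of `sdf`.
#' @export
sdf_close <- function(sdf, ball) {
  p <- check_ball(sdf, ball)
  pad <- as.integer(ceiling(p$r / p$h)) + 2L
  # dilate on the padded grid (one EDT), sub-voxel aware in the window
  inside <- pad_mask(sdf$distances < 0, pad)
  dil <- edt_mm(inside, dim(inside), sdf$spacing_mm) <= p$r
  win <- lapply(seq_along(sdf$dims), function(a) pad + seq_len(sdf$dims[a]))
  dil[win[[1]], win[[2]], win[[3]]] <- sdf$distances <= p$r
  # erode the dilated set: interior depth must exceed the radius
  closed <- edt_mm(!dil, dim(dil), sdf$spacing_mm) > p$r
  closed <- closed[win[[1]], win[[2]], win[[3]]]
  if (!any(closed)) {
    d <- array(grid_diagonal(sdf$dims, sdf$spacing_mm), dim = sdf$dims)
    return(signed_distance_volume(d, sdf$spacing_mm, sdf$origin_mm,
                                  sdf$iso_threshold))
  }
  sdf_from_mask(closed, sdf$spacing_mm, sdf$origin_mm, sdf$iso_threshold)
}

#' Morphological opening (erode then dilate)
#'
#' Removes protrusions and bridges thinner than twice the ball radius;
#' the result is returned on the input grid.
#'
#' @inheritParams sdf_dilate
#' @return A [signed_distance_volume] on the grid of `sdf`.
#' @export
sdf_open <- function(sdf, ball) {
  p <- check_ball(sdf, ball)
  er <- sdf$distances < -p$r
  if (!any(er)) {
    d <- array(grid_diagonal(sdf$dims, sdf$spacing_mm), dim = sdf$dims)
    return(signed_distance_volume(d, sdf$spacing_mm, sdf$origin_mm,
                                  sdf$iso_threshold))
  }
  # re-dilating the eroded set cannot leave the original solid, so no
  # padding is needed
  opened <- edt_mm(er, sdf$dims, sdf$spacing_mm) <= p$r
  sdf_from_mask(opened, sdf$spacing_mm, sdf$origin_mm, sdf$iso_threshold)
}

#' Boolean combination of two signed distance volumes
#'
#' Pointwise min (union), max (intersection), or `max(d_a, -d_b)`
#' (subtraction), followed by redistancing so the output is again an
#' exact signed distance field of the combined solid.
#'
#' @param a,b [signed_distance_volume]s on the same grid.
#' @param op `"union"`, `"intersect"`, or `"subtract"` (a minus b).
#' @return A [signed_distance_volume].
#' @export
sdf_boolean <- function(a, b, op = c("union", "intersect", "subtract")) {
  op <- match.arg(op)
  stopifnot(is_sdf(a), is_sdf(b))
  if (!same_grid(a, b))
    stopf("grid mismatch: boolean operands must share dims/spacing/origin")
  d <- switch(op,
              union = pmin(a$distances, b$distances),
              intersect = pmax(a$distances, b$distances),
              subtract = pmax(a$distances, -b$distances))
  mask <- array(d < 0, dim = a$dims)
  if (!any(mask)) {
    dd <- array(grid_diagonal(a$dims, a$spacing_mm), dim = a$dims)
    return(signed_distance_volume(dd, a$spacing_mm, a$origin_mm,
                                  a$iso_threshold))
  }
  redistance_mask(mask, a, 0L)
}
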