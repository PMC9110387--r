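# Analytic reference shapes: exact signed distance fields (and meshes)
# sampled on voxel grids, used as oracles for curvature, geodesic, and
# morphology checks.

#' Analytic reference shapes
#'
#' Samples an exact signed distance field (no thresholding error) of a
#' simple solid on a regular grid, or builds an exact mesh for the
#' saddle height surface.
#'
#' @param kind `"ball"`, `"slab"`, `"cylinder_shell"`, `"saddle"`, or
#'   `"dumbbell"`.
#' @param spacing_mm isotropic voxel spacing.
#' @param radius_mm ball/cylinder radius, or dumbbell bell radius.
#' @param center_mm shape center.
#' @param half_extents_mm slab half extents (3-vector).
#' @param height_mm cylinder height.
#' @param thickness_mm shell wall thickness.
#' @param separation_mm center separation of the dumbbell bells.
#' @param neck_radius_mm dumbbell neck radius.
#' @param coeff saddle coefficient `a` in `z = a (x^2 - y^2)` (1/mm).
#' @param extent_mm half side length of the saddle patch.
#' @param margin_mm air margin added around the solid.
#' @return A [signed_distance_volume], or a [surface_mesh] for
#'   `kind = "saddle"`.
#' @export
analytic_shape <- function(kind = c("ball", "slab", "cylinder_shell",
                                    "saddle", "dumbbell"),
                           spacing_mm = 0.5, radius_mm = 10,
                           center_mm = c(0, 0, 0),
                           half_extents_mm = c(10, 10, 2),
                           height_mm = 40, thickness_mm = 1,
                           separation_mm = 25, neck_radius_mm = 2,
                           coeff = 0.05, extent_mm = 10, margin_mm = 2) {
  kind <- match.arg(kind)
  h <- spacing_mm
  grid_sdf <- function(lo, hi, fun) {
    dims <- ceiling((hi - lo) / h) + 1L
    xs <- lo[1] + (seq_len(dims[1]) - 1) * h
    ys <- lo[2] + (seq_len(dims[2]) - 1) * h
    zs <- lo[3] + (seq_len(dims[3]) - 1) * h
    X <- rep(xs, times = dims[2] * dims[3])
    Y <- rep(rep(ys, each = dims[1]), times = dims[3])
    Z <- rep(zs, each = dims[1] * dims[2])
    signed_distance_volume(array(fun(X, Y, Z), dim = dims), h, lo)
  }
  m <- margin_mm
  if (kind == "ball") {
    r <- radius_mm
    lo <- center_mm - r - m; hi <- center_mm + r + m
    return(grid_sdf(lo, hi, function(x, y, z)
      sqrt((x - center_mm[1])^2 + (y - center_mm[2])^2 +
             (z - center_mm[3])^2) - r))
  }
  if (kind == "slab") {
    b <- half_extents_mm
    lo <- center_mm - b - m; hi <- center_mm + b + m
    return(grid_sdf(lo, hi, function(x, y, z) {
      qx <- abs(x - center_mm[1]) - b[1]
      qy <- abs(y - center_mm[2]) - b[2]
      qz <- abs(z - center_mm[3]) - b[3]
      ox <- pmax(qx, 0); oy <- pmax(qy, 0); oz <- pmax(qz, 0)
      sqrt(ox^2 + oy^2 + oz^2) + pmin(pmax(qx, pmax(qy, qz)), 0)
    }))
  }
  if (kind == "cylinder_shell") {
    r <- radius_mm; th <- thickness_mm / 2; hh <- height_mm / 2
    lo <- center_mm - c(r + th, r + th, hh) - m
    hi <- center_mm + c(r + th, r + th, hh) + m
    return(grid_sdf(lo, hi, function(x, y, z) {
      rad <- sqrt((x - center_mm[1])^2 + (y - center_mm[2])^2)
      pmax(abs(rad - r) - th, abs(z - center_mm[3]) - hh)
    }))
  }
  if (kind == "dumbbell") {
    r <- radius_mm; s <- separation_mm / 2; rn <- neck_radius_mm
    lo <- center_mm - c(s + r, r, r) - m
    hi <- center_mm + c(s + r, r, r) + m
    return(grid_sdf(lo, hi, function(x, y, z) {
      xx <- x - center_mm[1]; yy <- y - center_mm[2]; zz <- z - center_mm[3]
      d1 <- sqrt((xx + s)^2 + yy^2 + zz^2) - r
      d2 <- sqrt((xx - s)^2 + yy^2 + zz^2) - r
      dn <- pmax(sqrt(yy^2 + zz^2) - rn, abs(xx) - s)
      pmin(d1, d2, dn)
    }))
  }
  # saddle: exact height-surface mesh z = coeff * (x^2 - y^2)
  xs <- seq(-extent_mm, extent_mm, by = h)
  nk <- length(xs)
  gx <- rep(xs, times = nk)
  gy <- rep(xs, each = nk)
  V <- cbind(gx, gy, coeff * (gx^2 - gy^2))
  idx <- function(i, j) (j - 1) * nk + i
  tris <- NULL
  i <- rep(seq_len(nk - 1), times = nk - 1)
  j <- rep(seq_len(nk - 1), each = nk - 1)
  tris <- rbind(cbind(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
                cbind(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1)))
  surface_mesh(V, tris)
}
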