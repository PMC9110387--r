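# Shared internal helpers: grid bookkeeping, small vector algebra.

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

vnorm <- function(v) sqrt(sum(v^2))

normalize3 <- function(v) {
  n <- vnorm(v)
  if (n < 1e-300) return(c(0, 0, 0))
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# angle between two vectors in degrees, in [0, 180]
angle_deg <- function(a, b) {
  ca <- sum(normalize3(a) * normalize3(b))
  rad2deg(acos(max(-1, min(1, ca))))
}

check_isotropic <- function(spacing, what = "this operation") {
  if (diff(range(spacing)) > 1e-9 * max(spacing))
    stopf("%s requires isotropic voxel spacing (got %s)",
          what, paste(signif(spacing, 6), collapse = " x "))
  spacing[1]
}

# world coordinates of voxel centers along each axis (0-based index i at
# origin + i * spacing)
axis_coords <- function(dims, spacing, origin) {
  lapply(1:3, function(a) origin[a] + (seq_len(dims[a]) - 1) * spacing[a])
}

same_grid <- function(a, b, tol = 1e-9) {
  all(a$dims == b$dims) &&
    all(abs(a$spacing_mm - b$spacing_mm) < tol) &&
    all(abs(a$origin_mm - b$origin_mm) < tol)
}

grid_diagonal <- function(dims, spacing) {
  sqrt(sum(((dims - 1) * spacing)^2))
}

# trilinear interpolation of a 3-D array at world points (n x 3 matrix),
# NA outside the grid
trilinear <- function(arr, dims, spacing, origin, pts) {
  pts <- matrix(pts, ncol = 3)
  fx <- (pts[, 1] - origin[1]) / spacing[1]
  fy <- (pts[, 2] - origin[2]) / spacing[2]
  fz <- (pts[, 3] - origin[3]) / spacing[3]
  i0 <- floor(fx); j0 <- floor(fy); k0 <- floor(fz)
  tx <- fx - i0; ty <- fy - j0; tz <- fz - k0
  ok <- i0 >= 0 & i0 <= dims[1] - 2 & j0 >= 0 & j0 <= dims[2] - 2 &
    k0 >= 0 & k0 <= dims[3] - 2
  out <- rep(NA_real_, nrow(pts))
  if (!any(ok)) return(out)
  i0 <- i0[ok]; j0 <- j0[ok]; k0 <- k0[ok]
  tx <- tx[ok]; ty <- ty[ok]; tz <- tz[ok]
  acc <- 0
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (if (dx) tx else 1 - tx) * (if (dy) ty else 1 - ty) *
      (if (dz) tz else 1 - tz)
    idx <- (k0 + dz) * dims[1] * dims[2] + (j0 + dy) * dims[1] + (i0 + dx) + 1
    acc <- acc + w * arr[idx]
  }
  out[ok] <- acc
  out
}

# trilinear interpolation restricted to valid voxels: invalid corners
# get zero weight and the result is renormalized; NA when no valid
# corner carries weight
trilinear_masked <- function(arr, valid, dims, spacing, origin, pts) {
  pts <- matrix(pts, ncol = 3)
  fx <- (pts[, 1] - origin[1]) / spacing[1]
  fy <- (pts[, 2] - origin[2]) / spacing[2]
  fz <- (pts[, 3] - origin[3]) / spacing[3]
  i0 <- pmin(pmax(floor(fx), 0), dims[1] - 2)
  j0 <- pmin(pmax(floor(fy), 0), dims[2] - 2)
  k0 <- pmin(pmax(floor(fz), 0), dims[3] - 2)
  tx <- pmin(pmax(fx - i0, 0), 1)
  ty <- pmin(pmax(fy - j0, 0), 1)
  tz <- pmin(pmax(fz - k0, 0), 1)
  acc <- 0
  wtot <- 0
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (if (dx) tx else 1 - tx) * (if (dy) ty else 1 - ty) *
      (if (dz) tz else 1 - tz)
    idx <- (k0 + dz) * dims[1] * dims[2] + (j0 + dy) * dims[1] + (i0 + dx) + 1
    ok <- valid[idx]
    w <- w * ok
    v <- arr[idx]
    v[!ok] <- 0
    acc <- acc + w * v
    wtot <- wtot + w
  }
  out <- acc / wtot
  out[wtot < 1e-9] <- NA_real_
  out
}

# evaluate an expression with a temporarily seeded RNG, restoring state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
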