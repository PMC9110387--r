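# Density-weighted geodesic distance.
#
# Travel cost u solves the eikonal equation |grad u| = 1/s with speed
# metric s > 0 (s = 1 gives plain Euclidean geodesic distance; s = local
# density makes travel through dense comb cheaper per unit cost, the
# weighting used to trace build direction from the substrate). The
# solver is first-order fast marching on the voxel grid, restricted to a
# domain mask (comb solid or a surface shell).

#' Solve the eikonal equation on a voxel domain
#'
#' @param domain a [signed_distance_volume] (domain = inside voxels) or a
#'   [density_volume] (domain = voxels with value above
#'   `domain_threshold`).
#' @param source seed voxels with `u = 0`: a logical array on the grid or
#'   an n x 3 matrix of 1-based voxel indices.
#' @param metric the speed field `s`: a positive scalar, a numeric array
#'   on the grid, or `"density"` to use the volume's density values
#'   clamped to `[1e-3, 1]` (only for density-volume domains).
#' @param domain_mask optional logical array overriding the domain.
#' @param domain_threshold density threshold defining the domain of a
#'   [density_volume] (default 0: any material).
#' @return A `geodesic_field` with the travel-cost array `u` (mm when
#'   `s = 1`; `Inf` on unreachable voxels), the masks, and a QC count of
#'   unreachable voxels.
#' @export
solve_eikonal <- function(domain, source, metric = 1, domain_mask = NULL,
                          domain_threshold = 0) {
  if (is_sdf(domain)) {
    grid <- domain
    mask <- domain_mask %||% (domain$distances < 0)
  } else if (is_density_volume(domain)) {
    grid <- domain
    mask <- domain_mask %||% (domain$values > domain_threshold)
  } else stopf("domain must be a signed_distance_volume or density_volume")
  h <- check_isotropic(grid$spacing_mm, "fast marching")
  dims <- grid$dims

  src <- as_voxel_mask(source, dims)
  if (!any(src)) stopf("empty source")
  if (!any(src & mask)) stopf("source lies entirely outside the domain")
  src <- src & mask

  if (identical(metric, "density")) {
    if (!is_density_volume(domain))
      stopf("metric \"density\" requires a density_volume domain")
    s <- pmin(pmax(domain$values, 1e-3), 1)
  } else if (is.numeric(metric) && length(metric) == 1) {
    if (metric <= 0) stopf("metric must be positive")
    s <- array(metric, dim = dims)
  } else {
    s <- metric
    if (!all(dim(s) == dims)) stopf("metric field has wrong dimensions")
    if (any(s[mask] <= 0)) stopf("metric must be positive on the domain")
  }

  u <- fast_marching_cpp(as.numeric(1 / s), as.logical(src),
                         as.logical(mask), as.integer(dims), h)
  u <- array(u, dim = dims)
  u[!mask] <- Inf
  structure(list(dims = dims, spacing_mm = grid$spacing_mm,
                 origin_mm = grid$origin_mm, u = u, source_mask = src,
                 metric_s = s, domain_mask = mask,
                 n_unreachable = sum(mask & is.infinite(u))),
            class = "geodesic_field")
}

#' @export
print.geodesic_field <- function(x, ...) {
  fin <- x$u[is.finite(x$u)]
  cat(sprintf(
    "<geodesic_field> %s voxels, %d reached (max u %.4g), %d unreachable\n",
    paste(x$dims, collapse = "x"), length(fin), max(fin), x$n_unreachable))
  invisible(x)
}

# logical mask from a logical array or an n x 3 index matrix
as_voxel_mask <- function(x, dims) {
  if (is.logical(x) || (is.array(x) && is.numeric(x) &&
                        all(x %in% c(0, 1)))) {
    x <- array(as.logical(x), dim = dims)
    return(x)
  }
  x <- matrix(as.integer(x), ncol = 3)
  m <- array(FALSE, dim = dims)
  m[x] <- TRUE
  m
}

#' Normalized gradient of a geodesic field
#'
#' Central differences where both axis neighbors are finite, one-sided at
#' the domain boundary, normalized to unit length. Voxels with no finite
#' neighbor on any axis get the zero vector and are flagged.
#'
#' @param field a `geodesic_field`.
#' @return A list with unit-vector component arrays `gx`, `gy`, `gz` and
#'   a logical `flagged` array marking isolated voxels.
#' @export
gradient_field <- function(field) {
  u <- field$u
  dims <- field$dims
  h <- field$spacing_mm
  comp <- function(axis) {
    n <- dims[axis]
    shift <- function(k) {
      idx <- lapply(dims, seq_len)
      idx[[axis]] <- pmin(pmax(seq_len(n) + k, 1), n)
      do.call(`[`, c(list(u), idx))
    }
    up <- shift(1L); dn <- shift(-1L)
    g <- array(NA_real_, dim = dims)
    both <- is.finite(up) & is.finite(dn)
    g[both] <- (up[both] - dn[both]) / (2 * h[axis])
    fwd <- !both & is.finite(up) & is.finite(u)
    g[fwd] <- (up[fwd] - u[fwd]) / h[axis]
    bwd <- !both & !fwd & is.finite(dn) & is.finite(u)
    g[bwd] <- (u[bwd] - dn[bwd]) / h[axis]
    g[is.na(g)] <- 0
    g
  }
  gx <- comp(1); gy <- comp(2); gz <- comp(3)
  len <- sqrt(gx^2 + gy^2 + gz^2)
  flagged <- is.finite(u) & len == 0
  len[len == 0] <- 1
  list(gx = gx / len, gy = gy / len, gz = gz / len, flagged = flagged)
}

#' Trace a steepest-descent path to the source
#'
#' Integrates the negative gradient of the travel-cost field from a start
#' voxel down to the source by small fixed steps (half a voxel), with
#' trilinear interpolation of the unit gradient. When `s = 1` the
#' polyline length approximates `u(start)`.
#'
#' @param field a `geodesic_field`.
#' @param start 1-based voxel index triple with finite `u`.
#' @return An n x 3 matrix of points (mm); attribute `truncated` is TRUE
#'   if the descent stagnated before reaching the source.
#' @export
trace_path <- function(field, start) {
  start <- as.integer(start)
  u0 <- field$u[start[1], start[2], start[3]]
  if (!is.finite(u0)) stopf("start voxel has infinite travel cost")
  h <- check_isotropic(field$spacing_mm)
  origin <- field$origin_mm
  p <- origin + (start - 1) * field$spacing_mm
  if (field$source_mask[start[1], start[2], start[3]])
    return(matrix(p, ncol = 3))
  g <- gradient_field(field)
  dims <- field$dims
  # interpolate only over voxels that carry meaningful gradients; near
  # the domain boundary the off-domain corners would otherwise drag the
  # direction toward zero
  valid <- field$domain_mask & is.finite(field$u) & !g$flagged
  step <- 0.5 * h
  max_steps <- ceiling(4 * grid_diagonal(dims, field$spacing_mm) / step)
  path <- matrix(NA_real_, max_steps + 1, 3)
  path[1, ] <- p
  n <- 1L
  truncated <- FALSE
  for (i in seq_len(max_steps)) {
    gv <- c(trilinear_masked(g$gx, valid, dims, field$spacing_mm, origin, p),
            trilinear_masked(g$gy, valid, dims, field$spacing_mm, origin, p),
            trilinear_masked(g$gz, valid, dims, field$spacing_mm, origin, p))
    if (anyNA(gv)) { truncated <- TRUE; break }
    nrm <- vnorm(gv)
    if (nrm < 1e-6) { truncated <- TRUE; break }
    dir <- gv / nrm
    # take the step, backing off when it would leave the domain (e.g.
    # cutting an obstacle corner)
    uv <- NA_real_
    s <- step
    for (try in 1:4) {
      cand <- p - s * dir
      uv <- trilinear_masked(field$u, valid, dims, field$spacing_mm,
                             origin, cand)
      if (!is.na(uv)) break
      s <- s / 2
    }
    if (is.na(uv)) {
      # smooth descent blocked (tight corner): fall back to one discrete
      # downhill voxel step
      vox <- pmin(pmax(round((p - origin) / field$spacing_mm) + 1, 1), dims)
      best <- NULL
      best_u <- field$u[vox[1], vox[2], vox[3]]
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        nb <- vox + c(dx, dy, dz)
        if (any(nb < 1) || any(nb > dims)) next
        un <- field$u[nb[1], nb[2], nb[3]]
        if (is.finite(un) && un < best_u) { best <- nb; best_u <- un }
      }
      if (is.null(best)) { truncated <- TRUE; break }
      cand <- origin + (best - 1) * field$spacing_mm
      uv <- best_u
    }
    p <- cand
    n <- n + 1L
    path[n, ] <- p
    if (uv < h) break
    vox <- round((p - origin) / field$spacing_mm) + 1
    if (all(vox >= 1) && all(vox <= dims) &&
        field$source_mask[vox[1], vox[2], vox[3]]) break
  }
  if (truncated)
    warnf("path truncated: gradient stagnated before reaching the source")
  out <- path[seq_len(n), , drop = FALSE]
  attr(out, "truncated") <- truncated
  out
}

#' Regional build direction from a geodesic field
#'
#' The comb's local build direction is the average direction of steepest
#' travel-cost increase away from the substrate. Unit gradient vectors
#' over the region are averaged and re-normalized; the dispersion
#' `1 - |mean unit vector|` is 0 for perfectly aligned growth and 1 for
#' isotropic growth.
#'
#' @param field a `geodesic_field` (typically solved from the substrate).
#' @param region voxel set (logical array or n x 3 index matrix); at
#'   least 50 voxels with finite travel cost.
#' @param region_id optional label carried into the report.
#' @return A `build_direction_report`: `mean_gradient` (unit 3-vector),
#'   `dispersion` in \[0, 1\], `n_voxels`.
#' @export
build_direction <- function(field, region, region_id = NA) {
  mask <- as_voxel_mask(region, field$dims) & field$domain_mask
  ok <- mask & is.finite(field$u)
  if (!any(ok)) stopf("region has no finite travel cost")
  if (sum(ok) < 50)
    stopf("region too small: %d voxels with finite travel cost (need >= 50)",
          sum(ok))
  g <- gradient_field(field)
  keep <- ok & !g$flagged
  m <- c(mean(g$gx[keep]), mean(g$gy[keep]), mean(g$gz[keep]))
  len <- vnorm(m)
  structure(list(region_id = region_id,
                 mean_gradient = if (len > 0) m / len else c(0, 0, 0),
                 dispersion = 1 - min(len, 1),
                 n_voxels = sum(keep)),
            class = "build_direction_report")
}

#' @export
print.build_direction_report <- function(x, ...) {
  cat(sprintf(
    "<build_direction> region %s: direction (%.3f, %.3f, %.3f), dispersion %.3f (n=%d)\n",
    x$region_id, x$mean_gradient[1], x$mean_gradient[2], x$mean_gradient[3],
    x$dispersion, x$n_voxels))
  invisible(x)
}
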