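# Bee-scale curvature estimation.
#
# At every surface point the local neighborhood -- a geodesic ball on the
# mesh whose radius defaults to 15 mm, the scale of an A. mellifera
# worker's tactile reach -- is expressed in a tangent frame and fitted
# with the quadratic height function f(x, y) = a x^2 + b y^2 + c xy +
# d x + e y (no constant term: the surface passes through the query
# point). Principal curvatures are the eigenvalues of the shape operator
# of this Monge patch, evaluated at the origin.

#' Fit a local quadric at a mesh vertex
#'
#' Collects all vertices within a mesh-geodesic ball (shortest path along
#' edges) of the query vertex, expresses them in a local frame with z
#' along the vertex normal, and least-squares fits
#' `z = a x^2 + b y^2 + c xy + d x + e y`.
#'
#' @param mesh a [surface_mesh].
#' @param vertex query vertex index (1-based).
#' @param radius_mm neighborhood radius along the surface.
#' @param frame_z optional unit 3-vector overriding the frame z axis
#'   (defaults to the area-weighted vertex normal).
#' @return Named numeric vector `c(a, b, c, d, e)`.
#' @export
fit_local_quadric <- function(mesh, vertex, radius_mm, frame_z = NULL) {
  nb <- mesh_geodesic_balls_cpp(nrow(mesh$vertices), mesh$edges,
                                edge_lengths(mesh), as.integer(vertex),
                                radius_mm)[[1]]
  nb <- setdiff(nb, vertex)
  if (length(nb) < 6)
    stopf("only %d neighbors within %.3g mm; need at least 6",
          length(nb), radius_mm)
  z_axis <- if (is.null(frame_z)) vertex_normals(mesh)[vertex, ] else frame_z
  fit <- quadric_fit(mesh$vertices[nb, , drop = FALSE],
                     mesh$vertices[vertex, ], z_axis)
  if (is.null(fit)) stopf("degenerate fit: neighborhood is rank deficient")
  fit
}

# local-frame least squares; returns c(a,b,c,d,e) or NULL when the normal
# equations are ill conditioned (condition number > 1e8)
quadric_fit <- function(neighbors, origin, z_axis) {
  z_axis <- normalize3(z_axis)
  ref <- if (abs(z_axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  t1 <- normalize3(cross3(z_axis, ref))
  t2 <- cross3(z_axis, t1)
  rel <- sweep(neighbors, 2, origin)
  x <- rel %*% t1
  y <- rel %*% t2
  z <- rel %*% z_axis
  X <- cbind(x^2, y^2, x * y, x, y)
  sv <- svd(X, nu = 0, nv = 0)$d
  if (sv[1] <= 0 || sv[1] / max(sv[length(sv)], 1e-300) > 1e8) return(NULL)
  beta <- qr.solve(X, z)
  setNames(as.numeric(beta), c("a", "b", "c", "d", "e"))
}

#' Curvatures from quadric coefficients
#'
#' Evaluates the shape operator of the Monge patch
#' `z = a x^2 + b y^2 + c xy + d x + e y` at the origin: the first
#' fundamental form from the gradient `(d, e)`, the second from the
#' Hessian `(2a, c; c, 2b)`. Principal curvatures are its eigenvalues,
#' the Gaussian curvature their product and the mean curvature their
#' average.
#'
#' @param a,b,c,d,e quadric coefficients.
#' @return Named vector `c(kappa1, kappa2, K, H)` with `kappa1 >= kappa2`.
#' @export
curvature_from_quadric <- function(a, b, c, d, e) {
  a <- unname(a); b <- unname(b); c <- unname(c)
  d <- unname(d); e <- unname(e)
  E <- 1 + d^2; F <- d * e; G <- 1 + e^2
  w <- sqrt(1 + d^2 + e^2)
  L <- 2 * a / w; M <- c / w; N <- 2 * b / w
  det1 <- E * G - F^2
  K <- (L * N - M^2) / det1
  H <- (E * N + G * L - 2 * F * M) / (2 * det1)
  disc <- max(H^2 - K, 0)
  k1 <- H + sqrt(disc)
  k2 <- H - sqrt(disc)
  c(kappa1 = k1, kappa2 = k2, K = k1 * k2, H = (k1 + k2) / 2)
}

#' Per-vertex curvature field of a surface mesh
#'
#' Fits a local quadric at every vertex (see [fit_local_quadric()]) and
#' converts it to principal, Gaussian, and mean curvatures, then applies
#' `smoothing_rounds` of neighbor-mean averaging. The local frame's z
#' axis points along the inward normal so that convex solids have
#' positive principal curvature. Vertices whose fit is degenerate (too
#' few neighbors or rank-deficient sampling) inherit the value of the
#' nearest valid vertex and are flagged in the `qc_degenerate` channel.
#'
#' @param mesh a [surface_mesh] (typically from [extract_mesh()]).
#' @param radius_mm sampling radius in mm; the default of 15 matches the
#'   body scale of an *A. mellifera* worker.
#' @param smoothing_rounds rounds of neighbor averaging of the curvature
#'   channels (default 2).
#' @return A `curvature_field`: the mesh plus per-vertex channels
#'   `kappa1`, `kappa2`, `gaussian_K`, `mean_H`, `qc_degenerate`.
#' @export
compute_curvature_field <- function(mesh, radius_mm = 15,
                                    smoothing_rounds = 2) {
  nv <- nrow(mesh$vertices)
  el <- edge_lengths(mesh)
  if (radius_mm < 3 * mean(el))
    stopf("radius %.3g mm is below 3x the mean edge length (%.3g mm)",
          radius_mm, mean(el))
  normals <- vertex_normals(mesh)
  balls <- mesh_geodesic_balls_cpp(nv, mesh$edges, el,
                                   seq_len(nv), radius_mm)
  k1 <- k2 <- rep(NA_real_, nv)
  degenerate <- logical(nv)
  for (v in seq_len(nv)) {
    nb <- setdiff(balls[[v]], v)
    if (length(nb) < 6) { degenerate[v] <- TRUE; next }
    # inward-pointing frame: convex solid => positive principal curvature
    fit <- quadric_fit(mesh$vertices[nb, , drop = FALSE],
                       mesh$vertices[v, ], -normals[v, ])
    if (is.null(fit)) { degenerate[v] <- TRUE; next }
    kk <- curvature_from_quadric(fit[1], fit[2], fit[3], fit[4], fit[5])
    k1[v] <- kk[1]; k2[v] <- kk[2]
  }
  if (all(degenerate)) stopf("no vertex admitted a valid quadric fit")
  if (any(degenerate)) {
    adj <- vertex_adjacency(mesh)
    k1 <- inherit_nearest(k1, adj)
    k2 <- inherit_nearest(k2, adj)
  }
  adj <- vertex_adjacency(mesh)
  for (round in seq_len(smoothing_rounds)) {
    k1 <- neighbor_mean(k1, adj)
    k2 <- neighbor_mean(k2, adj)
  }
  swap <- k2 > k1
  if (any(swap)) {
    tmp <- k1[swap]; k1[swap] <- k2[swap]; k2[swap] <- tmp
  }
  mesh$attributes$kappa1 <- k1
  mesh$attributes$kappa2 <- k2
  mesh$attributes$gaussian_K <- k1 * k2
  mesh$attributes$mean_H <- (k1 + k2) / 2
  mesh$attributes$qc_degenerate <- degenerate
  structure(list(mesh = mesh, kappa1 = k1, kappa2 = k2,
                 gaussian_K = k1 * k2, mean_H = (k1 + k2) / 2,
                 sample_radius_mm = radius_mm,
                 qc_degenerate = degenerate),
            class = "curvature_field")
}

#' @export
print.curvature_field <- function(x, ...) {
  cat(sprintf(
    "<curvature_field> %d vertices, radius %.3g mm, median K %.4g /mm^2\n",
    length(x$kappa1), x$sample_radius_mm, median(x$gaussian_K)))
  invisible(x)
}

# BFS fill of NA entries from the nearest (hop-wise) valid vertex
inherit_nearest <- function(vals, adj) {
  frontier <- which(!is.na(vals))
  while (anyNA(vals) && length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      nb <- adj[[v]]
      fill <- nb[is.na(vals[nb])]
      if (length(fill)) {
        vals[fill] <- vals[v]
        nxt <- c(nxt, fill)
      }
    }
    frontier <- nxt
  }
  vals
}

# one round of neighbor averaging (self included for stability)
neighbor_mean <- function(vals, adj) {
  out <- vals
  for (v in seq_along(vals)) {
    nb <- c(v, adj[[v]])
    out[v] <- mean(vals[nb])
  }
  out
}

#' Area-weighted curvature histogram
#'
#' Bins a per-vertex curvature channel, weighting each vertex by its
#' barycentric area (one third of incident triangle area), so that the
#' `area_fraction` column integrates to 1 over the surface.
#'
#' @param field a `curvature_field` from [compute_curvature_field()].
#' @param channel one of `"kappa1"`, `"kappa2"`, `"K"`, `"H"`.
#' @param bins number of equal-width bins.
#' @return A data frame with columns `bin_lo`, `bin_hi`, `count`,
#'   `area_fraction`.
#' @export
curvature_histogram <- function(field, channel = c("kappa1", "kappa2",
                                                   "K", "H"),
                                bins = 50) {
  channel <- match.arg(channel)
  vals <- switch(channel, kappa1 = field$kappa1, kappa2 = field$kappa2,
                 K = field$gaussian_K, H = field$mean_H)
  if (length(vals) == 0 || all(is.na(vals))) stopf("empty curvature field")
  w <- vertex_areas(field$mesh)
  rng <- range(vals)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5) * max(abs(rng[1]), 1e-6)
  edges <- seq(rng[1], rng[2], length.out = bins + 1)
  idx <- findInterval(vals, edges, rightmost.closed = TRUE)
  idx[idx < 1] <- 1; idx[idx > bins] <- bins
  count <- tabulate(idx, nbins = bins)
  wsum <- vapply(seq_len(bins), function(b) sum(w[idx == b]), numeric(1))
  data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
             count = count, area_fraction = wsum / sum(w))
}
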