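# Laplacian (manifold harmonic) analysis of comb surfaces.
#
# The Fiedler vector -- the eigenvector of the Laplace operator with the
# smallest nonzero eigenvalue -- orders a surface along its dominant
# extent; its quantile bands segment approximately planar comb lobes, and
# centroids of its isocontour components linked by a minimum spanning
# tree form a curve skeleton of the comb.

#' Build a mesh Laplace operator
#'
#' Either the cotangent Laplacian with lumped (barycentric) mass matrix
#' -- the standard discretization for manifold harmonics -- or the
#' uniform graph Laplacian (identity mass), which is also available for
#' meshes that carry only an edge list.
#'
#' @param mesh a [surface_mesh].
#' @param kind `"cotangent"` or `"graph"`.
#' @return A `laplace_operator` holding the sparse symmetric
#'   positive-semidefinite matrix `L`, the diagonal mass vector `mass`,
#'   and the mesh.
#' @export
build_laplacian <- function(mesh, kind = c("cotangent", "graph")) {
  kind <- match.arg(kind)
  nv <- nrow(mesh$vertices)
  if (kind == "graph") {
    e <- mesh$edges
    L <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                              x = -1, dims = c(nv, nv))
    Matrix::diag(L) <- -Matrix::rowSums(L)
    return(structure(list(L = L, mass = rep(1, nv), kind = kind,
                          mesh = mesh), class = "laplace_operator"))
  }
  T <- mesh$triangles
  if (nrow(T) == 0) stopf("cotangent Laplacian needs triangles")
  cnt <- edge_triangle_counts(T)
  bad <- names(cnt)[cnt > 2]
  if (length(bad))
    stopf("non-manifold edges (shared by >2 triangles): %s",
          paste(head(bad, 10), collapse = "; "))
  V <- mesh$vertices
  ii <- integer(0); jj <- integer(0); ww <- numeric(0)
  for (corner in 1:3) {
    k <- T[, corner]
    i <- T[, corner %% 3 + 1]
    j <- T[, (corner + 1) %% 3 + 1]
    u <- V[i, , drop = FALSE] - V[k, , drop = FALSE]
    v <- V[j, , drop = FALSE] - V[k, , drop = FALSE]
    dot <- rowSums(u * v)
    crs <- sqrt(pmax(rowSums(u * u) * rowSums(v * v) - dot^2, 1e-300))
    cot <- dot / crs
    ii <- c(ii, i); jj <- c(jj, j); ww <- c(ww, cot / 2)
  }
  W <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = c(ww, ww),
                            dims = c(nv, nv))
  L <- Matrix::Diagonal(x = Matrix::rowSums(W)) - W
  mass <- vertex_areas(mesh)
  mass[mass <= 0] <- min(mass[mass > 0])
  structure(list(L = L, mass = mass, kind = kind, mesh = mesh),
            class = "laplace_operator")
}

#' @export
print.laplace_operator <- function(x, ...) {
  cat(sprintf("<laplace_operator> %s, %d vertices\n", x$kind, nrow(x$L)))
  invisible(x)
}

#' Smallest eigenpairs of a Laplace operator
#'
#' Solves the (generalized) symmetric eigenproblem `L v = lambda M v` by
#' reduction with `M^(-1/2)` and a dense symmetric eigendecomposition,
#' returning the `k` smallest eigenpairs with eigenvectors orthonormal
#' under the mass inner product. Signs are fixed deterministically: the
#' first component of each vector exceeding `1e-8` in magnitude is made
#' positive.
#'
#' @param op a `laplace_operator`.
#' @param k number of eigenpairs, `2 <= k <=` vertex count.
#' @return A `spectral_basis` with `values` (ascending, >= 0 up to
#'   round-off) and `vectors` (n x k).
#' @export
eigenbasis <- function(op, k) {
  n <- nrow(op$L)
  if (k < 2 || k > n) stopf("k must be in [2, %d]", n)
  s <- 1 / sqrt(op$mass)
  A <- as.matrix(op$L) * outer(s, s)
  A <- (A + t(A)) / 2
  eig <- eigen(A, symmetric = TRUE)
  idx <- order(eig$values)[seq_len(k)]
  vals <- pmax(eig$values[idx], 0)
  vecs <- eig$vectors[, idx, drop = FALSE] * s
  # mass-orthonormalize and fix signs
  for (c in seq_len(k)) {
    nrm <- sqrt(sum(op$mass * vecs[, c]^2))
    vecs[, c] <- vecs[, c] / nrm
    lead <- which(abs(vecs[, c]) > 1e-8)[1]
    if (!is.na(lead) && vecs[lead, c] < 0) vecs[, c] <- -vecs[, c]
  }
  structure(list(values = vals, vectors = vecs, k = k, op = op,
                 mesh = op$mesh),
            class = "spectral_basis")
}

#' @export
print.spectral_basis <- function(x, ...) {
  cat(sprintf("<spectral_basis> %d eigenpairs, lambda_2 = %.4g\n",
              x$k, if (x$k >= 2) x$values[2] else NA))
  invisible(x)
}

fiedler_vector <- function(basis) basis$vectors[, 2]

#' Segment a mesh by Fiedler-value quantile bands
#'
#' Partitions vertices into `n_segments` equal-mass bins of the Fiedler
#' vector (contiguous value ranges), which on elongated comb isolates
#' approximately planar lobes. Each segment gets a principal plane: the
#' centroid and first two principal components of its member vertex
#' positions.
#'
#' @param basis a `spectral_basis` with at least 2 vectors.
#' @param n_segments number of segments (>= 2).
#' @return A `segment_set`: per-vertex `labels` (1..n, ordered by
#'   Fiedler value) and a per-segment list with `fiedler_range`,
#'   `centroid`, `axes` (3 x 2 orthonormal), `normal`.
#' @export
fiedler_segment <- function(basis, n_segments) {
  if (n_segments < 2) stopf("n_segments must be >= 2")
  f <- fiedler_vector(basis)
  edges <- quantile(f, probs = seq(0, 1, length.out = n_segments + 1),
                    names = FALSE)
  labels <- findInterval(f, edges, rightmost.closed = TRUE)
  labels[labels < 1] <- 1; labels[labels > n_segments] <- n_segments
  segs <- lapply(seq_len(n_segments), function(sg) {
    idx <- which(labels == sg)
    P <- basis$mesh$vertices[idx, , drop = FALSE]
    ctr <- colMeans(P)
    pc <- prcomp(P, center = TRUE)
    axes <- pc$rotation[, 1:2, drop = FALSE]
    list(fiedler_range = range(f[idx]), centroid = ctr, axes = axes,
         normal = normalize3(cross3(axes[, 1], axes[, 2])),
         n_vertices = length(idx))
  })
  structure(list(labels = labels, segments = segs, basis = basis),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("<segment_set> %d segments over %d vertices\n",
              length(x$segments), length(x$labels)))
  invisible(x)
}

# connected components of a vertex subset under mesh adjacency
subset_components <- function(adj, subset) {
  inset <- logical(length(adj))
  inset[subset] <- TRUE
  labels <- integer(length(adj))
  lab <- 0L
  for (s in subset) {
    if (labels[s] != 0L) next
    lab <- lab + 1L
    queue <- s
    labels[s] <- lab
    while (length(queue)) {
      v <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      nb <- adj[[v]]
      nb <- nb[inset[nb] & labels[nb] == 0L]
      labels[nb] <- lab
      queue <- c(queue, nb)
    }
  }
  split(subset, labels[subset])
}

# Prim's minimum spanning tree on a complete Euclidean graph; ties broken
# toward the lowest node index. O(n^2), for skeleton-sized node sets.
prim_mst <- function(points) {
  n <- nrow(points)
  if (n == 1) return(matrix(integer(0), ncol = 2))
  intree <- logical(n)
  dist <- rep(Inf, n)
  parent <- integer(n)
  intree[1] <- TRUE
  d0 <- sqrt(rowSums((points - matrix(points[1, ], n, 3, byrow = TRUE))^2))
  dist <- d0; dist[1] <- Inf
  parent[] <- 1L
  edges <- matrix(0L, n - 1, 2)
  for (it in seq_len(n - 1)) {
    cand <- which(!intree)
    v <- cand[which.min(dist[cand])]
    edges[it, ] <- c(parent[v], v)
    intree[v] <- TRUE
    dv <- sqrt(rowSums((points - matrix(points[v, ], n, 3,
                                        byrow = TRUE))^2))
    upd <- !intree & dv < dist
    dist[upd] <- dv[upd]
    parent[upd] <- v
  }
  edges
}

#' Curve skeleton from Fiedler isocontours
#'
#' Slices the Fiedler vector into `n_contours` uniform quantile bands,
#' takes the centroid of every connected band component (components with
#' fewer than 3 vertices are dropped with a warning), and links the
#' centroids with Prim's minimum spanning tree under Euclidean edge
#' weights. Node tangents point toward increasing Fiedler value.
#'
#' @param basis a `spectral_basis`.
#' @param n_contours number of isocontour bands (default 25).
#' @return A `curve_skeleton`: `nodes` (n x 3 mm), `fiedler` values,
#'   `edges` (tree), `tangents` (n x 3 unit vectors).
#' @export
curve_skeleton <- function(basis, n_contours = 25) {
  f <- fiedler_vector(basis)
  mesh <- basis$mesh
  edges_q <- quantile(f, probs = seq(0, 1, length.out = n_contours + 1),
                      names = FALSE)
  band <- findInterval(f, edges_q, rightmost.closed = TRUE)
  band[band < 1] <- 1; band[band > n_contours] <- n_contours
  adj <- vertex_adjacency(mesh)
  nodes <- NULL
  fvals <- numeric(0)
  dropped <- 0L
  for (b in seq_len(n_contours)) {
    comps <- subset_components(adj, which(band == b))
    for (cp in comps) {
      if (length(cp) < 3) { dropped <- dropped + 1L; next }
      nodes <- rbind(nodes, colMeans(mesh$vertices[cp, , drop = FALSE]))
      fvals <- c(fvals, mean(f[cp]))
    }
  }
  if (dropped > 0)
    warnf("dropped %d contour component(s) with fewer than 3 vertices",
          dropped)
  if (is.null(nodes) || nrow(nodes) == 0)
    stopf("no contour components survived")
  tree <- prim_mst(nodes)
  tangents <- skeleton_tangents(nodes, fvals, tree)
  structure(list(nodes = nodes, fiedler = fvals, edges = tree,
                 tangents = tangents),
            class = "curve_skeleton")
}

skeleton_tangents <- function(nodes, fvals, tree) {
  n <- nrow(nodes)
  tangents <- matrix(0, n, 3)
  nbrs <- vector("list", n)
  for (e in seq_len(nrow(tree))) {
    a <- tree[e, 1]; b <- tree[e, 2]
    nbrs[[a]] <- c(nbrs[[a]], b)
    nbrs[[b]] <- c(nbrs[[b]], a)
  }
  for (v in seq_len(n)) {
    nb <- nbrs[[v]]
    if (length(nb) == 0) next
    lo <- nb[which.min(fvals[nb])]
    hi <- nb[which.max(fvals[nb])]
    dir <- if (fvals[hi] >= fvals[v] && fvals[lo] <= fvals[v] && hi != lo)
      nodes[hi, ] - nodes[lo, ]
    else if (fvals[hi] >= fvals[v]) nodes[hi, ] - nodes[v, ]
    else nodes[v, ] - nodes[lo, ]
    tangents[v, ] <- normalize3(dir)
  }
  tangents
}

#' @export
print.curve_skeleton <- function(x, ...) {
  cat(sprintf("<curve_skeleton> %d nodes, %d edges, total length %.3g mm\n",
              nrow(x$nodes), nrow(x$edges),
              sum(sqrt(rowSums((x$nodes[x$edges[, 1], , drop = FALSE] -
                                  x$nodes[x$edges[, 2], , drop = FALSE])^2)))))
  invisible(x)
}

#' Oriented cross-section of a volume at a skeleton node
#'
#' Resamples the volume on the plane through a skeleton node whose normal
#' is the node tangent -- the plane that bisects comb cells together with
#' the interface. Bilinear (trilinear in 3-D) interpolation at the
#' volume's own pixel spacing; pixels falling outside the volume are 0
#' and flagged.
#'
#' @param vol a [density_volume].
#' @param skeleton a `curve_skeleton`.
#' @param node node index.
#' @param size_mm side length of the square section.
#' @return A numeric matrix (the section image) with attributes `center`,
#'   `normal`, `u`, `v` (the in-plane axes), and `oob` (TRUE if any pixel
#'   fell outside the volume).
#' @export
cross_section <- function(vol, skeleton, node, size_mm) {
  stopifnot(is_density_volume(vol))
  tangent <- skeleton$tangents[node, ]
  if (vnorm(tangent) == 0) stopf("node %d has no defined tangent", node)
  center <- skeleton$nodes[node, ]
  ref <- if (abs(tangent[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  uax <- normalize3(cross3(tangent, ref))
  vax <- cross3(tangent, uax)
  h <- check_isotropic(vol$spacing_mm, "cross-section resampling")
  r <- seq(-size_mm / 2, size_mm / 2, by = h)
  grid <- expand.grid(a = r, b = r)
  pts <- cbind(center[1] + grid$a * uax[1] + grid$b * vax[1],
               center[2] + grid$a * uax[2] + grid$b * vax[2],
               center[3] + grid$a * uax[3] + grid$b * vax[3])
  vals <- trilinear(vol$values, vol$dims, vol$spacing_mm, vol$origin_mm, pts)
  oob <- anyNA(vals)
  vals[is.na(vals)] <- 0
  img <- matrix(vals, nrow = length(r))
  attr(img, "center") <- center
  attr(img, "normal") <- tangent
  attr(img, "u") <- uax
  attr(img, "v") <- vax
  attr(img, "oob") <- oob
  img
}
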