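#' Triangle surface mesh
#'
#' A discretization of the comb boundary: vertex positions in mm,
#' triangles as 1-based vertex index triples, and named per-vertex
#' attribute channels (curvatures, eigenvectors, geodesic values, ...).
#'
#' @param vertices numeric n x 3 matrix of positions (mm).
#' @param triangles integer m x 3 matrix of vertex indices (may have zero
#'   rows for pure graph use, in which case `edges` must be supplied).
#' @param edges optional explicit edge list (m x 2); derived from
#'   triangles when absent.
#' @param attributes named list of per-vertex channels.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles = NULL, edges = NULL,
                         attributes = list()) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  nv <- nrow(vertices)
  if (is.null(triangles)) triangles <- matrix(integer(0), ncol = 3)
  triangles <- matrix(as.integer(triangles), ncol = 3)
  if (nrow(triangles) > 0) {
    if (min(triangles) < 1 || max(triangles) > nv)
      stopf("triangle indices out of range")
  } else if (is.null(edges)) {
    stopf("a mesh with no triangles needs an explicit edge list")
  }
  if (is.null(edges)) edges <- triangles_to_edges(triangles)
  edges <- matrix(as.integer(edges), ncol = 2)
  structure(list(vertices = vertices, triangles = triangles, edges = edges,
                 attributes = attributes),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d triangles, %d edges",
              nrow(x$vertices), nrow(x$triangles), nrow(x$edges)))
  if (length(x$attributes))
    cat(sprintf(", channels: %s", paste(names(x$attributes), collapse = ", ")))
  cat("\n")
  invisible(x)
}

# unique undirected edges of a triangle set
triangles_to_edges <- function(tri) {
  if (nrow(tri) == 0) return(matrix(integer(0), ncol = 2))
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

# per-edge triangle incidence count (non-manifold check)
edge_triangle_counts <- function(tri) {
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  table(key)
}

#' Extract the boundary surface of a signed distance volume
#'
#' Runs marching tetrahedra on the zero level set: vertices are placed by
#' linear interpolation along grid edges (world mm), triangles are wound
#' with outward (positive-distance side) normals, and degenerate
#' zero-area faces are removed.
#'
#' @param sdf a [signed_distance_volume].
#' @param level level set to extract (default 0, the boundary).
#' @return A [surface_mesh].
#' @export
extract_mesh <- function(sdf, level = 0) {
  stopifnot(is_sdf(sdf))
  d <- sdf$distances
  if (min(d) >= level || max(d) <= level)
    stopf("empty level set: the surface at %.3g does not intersect the grid",
          level)
  res <- marching_tets_cpp(as.numeric(d), as.integer(sdf$dims),
                           as.numeric(sdf$spacing_mm),
                           as.numeric(sdf$origin_mm), level)
  V <- res$vertices
  T <- res$triangles
  # weld coincident vertices (the level set can pass exactly through a
  # grid corner, in which case several grid edges emit the same point)
  key <- paste(round(V[, 1] / sdf$spacing_mm[1] * 1e6),
               round(V[, 2] / sdf$spacing_mm[2] * 1e6),
               round(V[, 3] / sdf$spacing_mm[3] * 1e6))
  first <- match(key, key)
  if (any(first != seq_along(first))) {
    uniq <- unique(first)
    remap0 <- integer(nrow(V))
    remap0[uniq] <- seq_along(uniq)
    V <- V[uniq, , drop = FALSE]
    T <- matrix(remap0[first[T]], ncol = 3)
  }
  # drop collapsed faces (repeated indices or numerically zero area)
  keep <- T[, 1] != T[, 2] & T[, 2] != T[, 3] & T[, 1] != T[, 3]
  T <- T[keep, , drop = FALSE]
  a <- triangle_areas(V, T)
  T <- T[a > 1e-12 * mean(sdf$spacing_mm)^2, , drop = FALSE]
  # drop unreferenced vertices
  used <- sort(unique(as.vector(T)))
  remap <- integer(nrow(V))
  remap[used] <- seq_along(used)
  surface_mesh(V[used, , drop = FALSE],
               matrix(remap[T], ncol = 3))
}

triangle_areas <- function(V, T) {
  if (nrow(T) == 0) return(numeric(0))
  a <- V[T[, 2], , drop = FALSE] - V[T[, 1], , drop = FALSE]
  b <- V[T[, 3], , drop = FALSE] - V[T[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Total surface area of a mesh
#' @param mesh a [surface_mesh].
#' @return Area in mm^2.
#' @export
mesh_area <- function(mesh) sum(triangle_areas(mesh$vertices, mesh$triangles))

# area-weighted per-vertex normals (unit), from incident triangle normals
vertex_normals <- function(mesh) {
  V <- mesh$vertices; T <- mesh$triangles
  a <- V[T[, 2], , drop = FALSE] - V[T[, 1], , drop = FALSE]
  b <- V[T[, 3], , drop = FALSE] - V[T[, 1], , drop = FALSE]
  fn <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])  # 2*area-weighted already
  N <- matrix(0, nrow(V), 3)
  for (c in 1:3) {
    for (col in 1:3) {
      acc <- rowsum(fn[, col], T[, c], reorder = FALSE)
      idx <- as.integer(rownames(acc))
      N[idx, col] <- N[idx, col] + acc
    }
  }
  len <- sqrt(rowSums(N^2))
  len[len == 0] <- 1
  N / len
}

# barycentric (1/3 incident triangle area) vertex areas
vertex_areas <- function(mesh) {
  ta <- triangle_areas(mesh$vertices, mesh$triangles)
  va <- numeric(nrow(mesh$vertices))
  for (c in 1:3) {
    acc <- rowsum(ta / 3, mesh$triangles[, c], reorder = FALSE)
    idx <- as.integer(rownames(acc))
    va[idx] <- va[idx] + acc
  }
  va
}

# vertex adjacency list from edges
vertex_adjacency <- function(mesh) {
  nv <- nrow(mesh$vertices)
  e <- mesh$edges
  adj <- vector("list", nv)
  both <- rbind(e, e[, 2:1])
  sp <- split(both[, 2], both[, 1])
  adj[as.integer(names(sp))] <- sp
  adj
}

edge_lengths <- function(mesh) {
  e <- mesh$edges
  sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                  mesh$vertices[e[, 2], , drop = FALSE])^2))
}

#' Euler characteristic of a mesh
#' @param mesh a [surface_mesh].
#' @return V - E + F.
#' @export
euler_characteristic <- function(mesh) {
  nrow(mesh$vertices) - nrow(mesh$edges) + nrow(mesh$triangles)
}

# connected components of mesh vertices (graph BFS); returns labels
mesh_components <- function(mesh) {
  adj <- vertex_adjacency(mesh)
  nv <- nrow(mesh$vertices)
  labels <- integer(nv)
  queue <- integer(nv)
  lab <- 0L
  for (s in seq_len(nv)) {
    if (labels[s] != 0L) next
    lab <- lab + 1L
    queue[1] <- s
    labels[s] <- lab
    head <- 1L; tail <- 1L
    while (head <= tail) {
      v <- queue[head]
      head <- head + 1L
      nb <- adj[[v]]
      nb <- nb[labels[nb] == 0L]
      if (length(nb)) {
        labels[nb] <- lab
        queue[(tail + 1L):(tail + length(nb))] <- nb
        tail <- tail + length(nb)
      }
    }
  }
  labels
}

#' Write a mesh as ASCII PLY
#'
#' Vertex order is preserved exactly; scalar attribute channels are
#' written as extra float vertex properties.
#'
#' @param mesh a [surface_mesh].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path) {
  nv <- nrow(mesh$vertices); nt <- nrow(mesh$triangles)
  scalars <- Filter(function(a) is.numeric(a) && length(a) == nv,
                    mesh$attributes)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nv),
               "property float x", "property float y", "property float z",
               sprintf("property float %s", names(scalars)),
               sprintf("element face %d", nt),
               "property list uchar int vertex_indices",
               "end_header"), con)
  vm <- cbind(mesh$vertices, do.call(cbind, unname(scalars)))
  writeLines(apply(vm, 1, function(r) paste(format(r, trim = TRUE,
                                                   digits = 9),
                                            collapse = " ")), con)
  if (nt > 0)
    writeLines(paste(3, mesh$triangles[, 1] - 1, mesh$triangles[, 2] - 1,
                     mesh$triangles[, 3] - 1), con)
  invisible(path)
}

#' Write a mesh as Wavefront OBJ
#' @param mesh a [surface_mesh].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  if (nrow(mesh$triangles) > 0)
    writeLines(sprintf("f %d %d %d", mesh$triangles[, 1],
                       mesh$triangles[, 2], mesh$triangles[, 3]), con)
  invisible(path)
}
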