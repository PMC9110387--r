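# Independent oracles used across the suite. These deliberately avoid
# the code paths they check: brute-force set operations for morphology,
# Kruskal for Prim, a dense generalized eigensolve for the spectral
# reduction, and graph shortest paths (igraph) for the eikonal solver.

# brute-force Minkowski dilation of a binary 3-D mask with a closed
# Euclidean ball of radius r (voxel units); the mask is padded so the
# offset cannot clip
minkowski_dilate <- function(mask, r, pad = ceiling(r) + 1) {
  dims <- dim(mask)
  big <- array(FALSE, dims + 2 * pad)
  big[pad + seq_len(dims[1]), pad + seq_len(dims[2]),
      pad + seq_len(dims[3])] <- mask
  off <- as.matrix(expand.grid(-ceiling(r):ceiling(r),
                               -ceiling(r):ceiling(r),
                               -ceiling(r):ceiling(r)))
  off <- off[rowSums(off^2) <= r^2, , drop = FALSE]
  out <- array(FALSE, dim(big))
  w <- which(big, arr.ind = TRUE)
  for (k in seq_len(nrow(off))) {
    sh <- sweep(w, 2, off[k, ], `+`)
    out[sh] <- TRUE
  }
  list(mask = out, pad = pad)
}

# erosion as the dual: keep voxels with no outside voxel within r
minkowski_erode <- function(mask, r) {
  dims <- dim(mask)
  off <- as.matrix(expand.grid(-ceiling(r):ceiling(r),
                               -ceiling(r):ceiling(r),
                               -ceiling(r):ceiling(r)))
  off <- off[rowSums(off^2) <= r^2, , drop = FALSE]
  out <- array(FALSE, dims)
  w <- which(mask, arr.ind = TRUE)
  keep <- rep(TRUE, nrow(w))
  for (k in seq_len(nrow(off))) {
    sh <- sweep(w, 2, off[k, ], `+`)
    inside <- sh[, 1] >= 1 & sh[, 1] <= dims[1] &
      sh[, 2] >= 1 & sh[, 2] <= dims[2] &
      sh[, 3] >= 1 & sh[, 3] <= dims[3]
    ok <- inside
    ok[inside] <- mask[sh[inside, , drop = FALSE]]
    keep <- keep & ok
  }
  out[w[keep, , drop = FALSE]] <- TRUE
  out
}

crop_pad <- function(big, pad, dims) {
  big[pad + seq_len(dims[1]), pad + seq_len(dims[2]),
      pad + seq_len(dims[3])]
}

# Kruskal MST total weight on a complete Euclidean graph
kruskal_weight <- function(points) {
  n <- nrow(points)
  pairs <- t(combn(n, 2))
  w <- sqrt(rowSums((points[pairs[, 1], , drop = FALSE] -
                       points[pairs[, 2], , drop = FALSE])^2))
  o <- order(w)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  total <- 0
  for (k in o) {
    a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
    if (a != b) {
      parent[a] <- b
      total <- total + w[k]
    }
  }
  total
}

# dense generalized eigensolve L v = lambda M v via solve(M) %*% L (an
# independent route from the package's symmetric M^{-1/2} reduction)
dense_eigen_oracle <- function(op, k) {
  A <- diag(1 / op$mass) %*% as.matrix(op$L)
  ev <- eigen(A)
  vals <- Re(ev$values)
  sort(vals)[seq_len(k)]
}

# voxel-grid shortest-path distances with a 26-neighbor igraph
grid_dijkstra <- function(mask, spacing, from_idx, to_idx = NULL) {
  stopifnot(requireNamespace("igraph", quietly = TRUE))
  dims <- dim(mask)
  id <- array(0L, dims)
  id[mask] <- seq_len(sum(mask))
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  w <- which(mask, arr.ind = TRUE)
  edges <- NULL
  weights <- NULL
  for (k in seq_len(nrow(off))) {
    sh <- sweep(w, 2, off[k, ], `+`)
    ok <- sh[, 1] >= 1 & sh[, 1] <= dims[1] &
      sh[, 2] >= 1 & sh[, 2] <= dims[2] &
      sh[, 3] >= 1 & sh[, 3] <= dims[3]
    ok[ok] <- mask[sh[ok, , drop = FALSE]]
    a <- id[w[ok, , drop = FALSE]]
    b <- id[sh[ok, , drop = FALSE]]
    keep <- a < b
    edges <- rbind(edges, cbind(a[keep], b[keep]))
    weights <- c(weights, rep(sqrt(sum(off[k, ]^2)) * spacing,
                              sum(keep)))
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$weight <- weights
  igraph::distances(g, v = id[from_idx],
                    to = if (is.null(to_idx)) igraph::V(g) else id[to_idx])
}

# random rotation matrix under the current RNG
random_rotation <- function() {
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

angle_between_deg <- function(a, b) {
  acos(min(1, max(-1, sum(a * b) / sqrt(sum(a^2) * sum(b^2))))) * 180 / pi
}
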