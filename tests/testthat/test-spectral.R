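test_that("graph Laplacian reproduces the path-graph spectrum", {
  pm <- surface_mesh(cbind(0:3, 0, 0), edges = cbind(1:3, 2:4))
  eb <- eigenbasis(build_laplacian(pm, "graph"), 4)
  expect_equal(eb$values, c(0, 2 - sqrt(2), 2, 2 + sqrt(2)),
               tolerance = 1e-10)
  # constant vector lies in the kernel
  L <- build_laplacian(pm, "graph")$L
  expect_lt(max(abs(as.vector(L %*% rep(1, 4)))), 1e-12)
})

test_that("cotangent Laplacian rows sum to zero and flags non-manifold", {
  m <- fixture("coarse_ball", function()
    extract_mesh(analytic_shape("ball", spacing_mm = 2, radius_mm = 6)))
  op <- build_laplacian(m, "cotangent")
  expect_lt(max(abs(Matrix::rowSums(op$L))), 1e-10)
  # duplicate a face onto an extra vertex: edge shared by 3 triangles
  bad <- surface_mesh(rbind(m$vertices, m$vertices[1, ] + c(0, 0, 5)),
                      rbind(m$triangles,
                            c(m$triangles[1, 1], m$triangles[1, 2],
                              nrow(m$vertices) + 1)))
  expect_error(build_laplacian(bad, "cotangent"), "non-manifold")
})

test_that("eigenpairs agree with a dense generalized eigensolve", {
  m <- fixture("coarse_ball", function()
    extract_mesh(analytic_shape("ball", spacing_mm = 2, radius_mm = 6)))
  expect_lt(nrow(m$vertices), 500)
  op <- build_laplacian(m, "cotangent")
  eb <- eigenbasis(op, 8)
  ref <- dense_eigen_oracle(op, 8)
  expect_equal(eb$values, ref, tolerance = 1e-8)
  # eigenvalues ascending, non-negative; Rayleigh quotients match
  expect_true(all(diff(eb$values) >= -1e-12))
  expect_true(all(eb$values >= -1e-10))
  for (k in 2:8) {
    v <- eb$vectors[, k]
    rq <- as.numeric(t(v) %*% (op$L %*% v)) / sum(op$mass * v^2)
    expect_lt(abs(rq - eb$values[k]), 1e-8 * max(1, eb$values[k]))
  }
  # mass-orthonormality
  G <- t(eb$vectors) %*% (eb$vectors * op$mass)
  expect_lt(max(abs(G - diag(8))), 1e-6)
})

test_that("sphere harmonics group with multiplicities 1, 3, 5", {
  m <- fixture("sphere_spec", function()
    extract_mesh(analytic_shape("ball", spacing_mm = 1.5, radius_mm = 10)))
  eb <- eigenbasis(build_laplacian(m, "cotangent"), 9)
  lam <- eb$values * 100  # scale by r^2
  expect_lt(lam[1], 0.05)
  expect_lt(diff(range(lam[2:4])) / mean(lam[2:4]), 0.05)
  expect_lt(diff(range(lam[5:9])) / mean(lam[5:9]), 0.05)
  expect_gt(mean(lam[5:9]) / mean(lam[2:4]), 2.5)  # 6 vs 2
})

test_that("a disconnected mesh has a two-dimensional kernel", {
  m <- fixture("coarse_ball", function()
    extract_mesh(analytic_shape("ball", spacing_mm = 2, radius_mm = 6)))
  nv <- nrow(m$vertices)
  two <- surface_mesh(rbind(m$vertices,
                            sweep(m$vertices, 2, c(30, 0, 0), `+`)),
                      rbind(m$triangles, m$triangles + nv))
  eb <- eigenbasis(build_laplacian(two, "cotangent"), 4)
  expect_lt(eb$values[2], 1e-8)
  expect_gt(eb$values[3], 1e-6)
})

test_that("Fiedler vector splits a dumbbell and orders a slab", {
  db <- fixture("dumbbell_mesh", function()
    extract_mesh(analytic_shape("dumbbell", spacing_mm = 1.2,
                                radius_mm = 6, separation_mm = 22,
                                neck_radius_mm = 1.5)))
  eb <- eigenbasis(build_laplacian(db, "cotangent"), 3)
  seg <- fiedler_segment(eb, 2)
  truth <- ifelse(db$vertices[, 1] < 0, 1, 2)
  tab <- table(seg$labels, truth)
  purity <- sum(apply(tab, 1, max)) / sum(tab)
  expect_gte(purity, 0.95)
  # per-segment principal planes are orthonormal
  for (sg in seg$segments) {
    expect_lt(max(abs(crossprod(sg$axes) - diag(2))), 1e-8)
  }
  expect_error(fiedler_segment(eb, 1), "n_segments")

  # slab: Fiedler is monotone along the longest axis
  slab <- extract_mesh(analytic_shape("slab", spacing_mm = 1,
                                      half_extents_mm = c(20, 5, 2)))
  ebs <- eigenbasis(build_laplacian(slab, "cotangent"), 2)
  f <- ebs$vectors[, 2]
  expect_gt(abs(cor(f, slab$vertices[, 1], method = "spearman")), 0.99)
})

test_that("Fiedler segmentation is invariant to rigid motions", {
  db <- fixture("dumbbell_mesh", function()
    extract_mesh(analytic_shape("dumbbell", spacing_mm = 1.2,
                                radius_mm = 6, separation_mm = 22,
                                neck_radius_mm = 1.5)))
  eb <- eigenbasis(build_laplacian(db, "cotangent"), 3)
  seg <- fiedler_segment(eb, 2)
  set.seed(2)
  R <- random_rotation()
  moved <- surface_mesh(db$vertices %*% t(R) + 5, db$triangles)
  ebm <- eigenbasis(build_laplacian(moved, "cotangent"), 3)
  segm <- fiedler_segment(ebm, 2)
  agree <- mean(seg$labels == segm$labels)
  expect_gt(max(agree, 1 - agree), 0.999)  # up to global label swap
})

test_that("Prim's MST matches Kruskal and handles canonical layouts", {
  # 3 collinear centroids: 2-edge path spanning the extremes
  pts <- cbind(c(0, 1, 2.5), 0, 0)
  tree <- combscan:::prim_mst(pts)
  expect_equal(nrow(tree), 2L)
  w <- sum(sqrt(rowSums((pts[tree[, 1], , drop = FALSE] -
                           pts[tree[, 2], , drop = FALSE])^2)))
  expect_equal(w, 2.5)
  # unit square: MST length 3
  sq <- cbind(c(0, 1, 0, 1), c(0, 0, 1, 1), 0)
  tr2 <- combscan:::prim_mst(sq)
  w2 <- sum(sqrt(rowSums((sq[tr2[, 1], , drop = FALSE] -
                            sq[tr2[, 2], , drop = FALSE])^2)))
  expect_equal(w2, 3)
  # 50 random instances: Prim weight equals Kruskal exactly
  set.seed(17)
  for (i in 1:50) {
    p <- matrix(runif(3 * sample(5:12, 1)), ncol = 3)
    tr <- combscan:::prim_mst(p)
    wp <- sum(sqrt(rowSums((p[tr[, 1], , drop = FALSE] -
                              p[tr[, 2], , drop = FALSE])^2)))
    expect_equal(wp, kruskal_weight(p), tolerance = 1e-12)
  }
})

test_that("curve skeletons are trees that follow elongated shapes", {
  slab <- extract_mesh(analytic_shape("slab", spacing_mm = 1,
                                      half_extents_mm = c(20, 5, 2)))
  eb <- eigenbasis(build_laplacian(slab, "cotangent"), 2)
  sk <- suppressWarnings(curve_skeleton(eb, 10))
  expect_equal(nrow(sk$edges), nrow(sk$nodes) - 1)
  # acyclic + connected: n-1 edges with all nodes reachable
  reach <- rep(FALSE, nrow(sk$nodes))
  reach[1] <- TRUE
  for (it in seq_len(nrow(sk$nodes))) {
    for (e in seq_len(nrow(sk$edges))) {
      if (reach[sk$edges[e, 1]]) reach[sk$edges[e, 2]] <- TRUE
      if (reach[sk$edges[e, 2]]) reach[sk$edges[e, 1]] <- TRUE
    }
  }
  expect_true(all(reach))
  # nodes march along x; tangents mostly +-x
  o <- order(sk$fiedler)
  expect_gt(abs(cor(sk$nodes[o, 1], seq_along(o))), 0.99)
  expect_gt(median(abs(sk$tangents[, 1])), 0.9)
})

test_that("cross-sections resample the volume on oriented planes", {
  b <- analytic_shape("ball", spacing_mm = 0.5, radius_mm = 8)
  vol <- density_volume(array(as.numeric(b$distances < 0), dim = b$dims),
                        0.5, b$origin_mm)
  sk <- list(nodes = matrix(c(0, 0, 0), 1), fiedler = 0,
             edges = matrix(integer(0), ncol = 2),
             tangents = matrix(c(0, 0, 1), 1))
  img <- cross_section(vol, sk, 1, 18)
  # disk of diameter 16 mm: area pi * 64 within a voxel band
  area <- sum(img > 0.5) * 0.25
  expect_lt(abs(area - pi * 64) / (pi * 64), 0.06)
  expect_false(attr(img, "oob"))
  # plane through empty space: zeros and flagged
  sk2 <- sk
  sk2$nodes <- matrix(c(100, 0, 0), 1)
  img2 <- cross_section(vol, sk2, 1, 10)
  expect_true(all(img2 == 0))
  expect_true(attr(img2, "oob"))
  # a comb section shows the wall lattice
  ph <- small_disc_phantom()
  skc <- list(nodes = matrix(c(0, 0, 0), 1), fiedler = 0,
              edges = matrix(integer(0), ncol = 2),
              tangents = matrix(c(0, 0, 1), 1))
  imgc <- cross_section(ph$volume, skc, 1, 14)
  wax_frac <- mean(abs(imgc - 0.465) < 0.05)
  expect_gt(wax_frac, 0.1)
  expect_lt(wax_frac, 0.9)
})
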