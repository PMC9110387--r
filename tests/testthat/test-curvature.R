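test_that("quadric coefficients convert to curvatures analytically", {
  expect_equal(unname(curvature_from_quadric(0, 0, 0, 0, 0)),
               c(0, 0, 0, 0))
  # paraboloid: I = identity, II = diag(2a, 2b)
  k <- curvature_from_quadric(0.05, 0.05, 0, 0, 0)
  expect_equal(unname(k), c(0.1, 0.1, 0.01, 0.1), tolerance = 1e-12)
  # tilted patch (d = 0.3): finite-difference fundamental-form oracle
  a <- 0.05; d <- 0.3
  f <- function(x, y) a * x^2 + d * x
  eps <- 1e-5
  fx <- (f(eps, 0) - f(-eps, 0)) / (2 * eps)
  fy <- (f(0, eps) - f(0, -eps)) / (2 * eps)
  fxx <- (f(eps, 0) - 2 * f(0, 0) + f(-eps, 0)) / eps^2
  fyy <- (f(0, eps) - 2 * f(0, 0) + f(0, -eps)) / eps^2
  fxy <- (f(eps, eps) - f(eps, -eps) - f(-eps, eps) + f(-eps, -eps)) /
    (4 * eps^2)
  E <- 1 + fx^2; Fq <- fx * fy; G <- 1 + fy^2
  w <- sqrt(1 + fx^2 + fy^2)
  L <- fxx / w; M <- fxy / w; N <- fyy / w
  K_ref <- (L * N - M^2) / (E * G - Fq^2)
  H_ref <- (E * N + G * L - 2 * Fq * M) / (2 * (E * G - Fq^2))
  k2 <- curvature_from_quadric(a, 0, 0, d, 0)
  expect_equal(unname(k2["K"]), K_ref, tolerance = 1e-6)
  expect_equal(unname(k2["H"]), H_ref, tolerance = 1e-6)
})

test_that("local quadric fitting recovers planted polynomial surfaces", {
  # noiseless samples of z = 0.05 x^2 on a grid patch
  mk_patch_mesh <- function(fz) {
    xs <- seq(-2, 2, by = 0.4)
    n <- length(xs)
    gx <- rep(xs, times = n)
    gy <- rep(xs, each = n)
    V <- cbind(gx, gy, fz(gx, gy))
    idx <- function(i, j) (j - 1) * n + i
    i <- rep(seq_len(n - 1), times = n - 1)
    j <- rep(seq_len(n - 1), each = n - 1)
    tris <- rbind(cbind(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
                  cbind(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1)))
    surface_mesh(V, tris)
  }
  center_vertex <- function(mesh) which.min(rowSums(mesh$vertices[, 1:2]^2))
  flat <- mk_patch_mesh(function(x, y) 0 * x)
  q0 <- fit_local_quadric(flat, center_vertex(flat), 1.5,
                          frame_z = c(0, 0, 1))
  expect_lt(max(abs(q0)), 1e-9)
  # the local tangent frame is an arbitrary rotation of world x/y, so
  # compare frame-independent quantities: the coefficient pair up to
  # rotation, and the curvatures
  parab <- mk_patch_mesh(function(x, y) 0.05 * x^2)
  qp <- fit_local_quadric(parab, center_vertex(parab), 1.5,
                          frame_z = c(0, 0, 1))
  expect_equal(sort(abs(c(qp["a"], qp["b"]))), c(0, 0.05),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_lt(max(abs(qp[c("c", "d", "e")])), 1e-6)
  kp <- curvature_from_quadric(qp[1], qp[2], qp[3], qp[4], qp[5])
  expect_equal(unname(kp[c("kappa1", "kappa2")]), c(0.1, 0),
               tolerance = 1e-6)
  sadd <- mk_patch_mesh(function(x, y) (x^2 - y^2) / 20)
  qs <- fit_local_quadric(sadd, center_vertex(sadd), 1.5,
                          frame_z = c(0, 0, 1))
  ks <- curvature_from_quadric(qs[1], qs[2], qs[3], qs[4], qs[5])
  expect_equal(unname(ks["K"]), -0.01, tolerance = 1e-6)
  expect_equal(unname(ks[c("kappa1", "kappa2")]), c(0.1, -0.1),
               tolerance = 1e-6)
  # collinear neighborhood is rank deficient
  line <- surface_mesh(cbind(seq(0, 3, by = 0.25), 0, 0),
                       edges = cbind(1:12, 2:13))
  expect_error(fit_local_quadric(line, 6, 2, frame_z = c(0, 0, 1)),
               "degenerate|rank")
})

test_that("curvature field matches analytic sphere, plane, and saddle", {
  cf <- fixture("sphere_curv", function()
    compute_curvature_field(ball_mesh(), radius_mm = 3))
  expect_lt(abs(median(cf$gaussian_K) - 0.01) / 0.01, 0.10)
  # convex solid with outward normals: positive principal curvatures
  expect_gt(median(cf$kappa1), 0)
  expect_gt(median(cf$kappa2), 0)
  # K = k1 k2 and H = (k1+k2)/2 hold exactly, with k1 >= k2
  expect_equal(cf$gaussian_K, cf$kappa1 * cf$kappa2)
  expect_equal(cf$mean_H, (cf$kappa1 + cf$kappa2) / 2)
  expect_true(all(cf$kappa1 >= cf$kappa2))

  # flat slab: interior vertices are flat
  slab <- extract_mesh(analytic_shape("slab", spacing_mm = 0.5,
                                      half_extents_mm = c(10, 10, 2)))
  cfs <- compute_curvature_field(slab, radius_mm = 3)
  interior <- abs(slab$vertices[, 1]) < 6 & abs(slab$vertices[, 2]) < 6 &
    abs(abs(slab$vertices[, 3]) - 2) < 0.1
  expect_lt(median(abs(cfs$gaussian_K[interior])), 1e-4)
  expect_lt(median(abs(cfs$mean_H[interior])), 1e-3)

  # saddle z = (x^2 - y^2)/20 near the origin: closed-form K
  sm <- saddle_mesh()
  cfx <- compute_curvature_field(sm, radius_mm = 3, smoothing_rounds = 0)
  r2 <- rowSums(sm$vertices[, 1:2]^2)
  near <- r2 < 4
  a <- 0.05
  K_true <- -4 * a^2 / (1 + 4 * a^2 * r2[near])^2
  expect_lt(median(abs(cfx$gaussian_K[near] - K_true)) / 0.01, 0.15)
})

test_that("curvature scales as 1/length under uniform scaling", {
  cf10 <- fixture("sphere_curv", function()
    compute_curvature_field(ball_mesh(), radius_mm = 3))
  m5 <- extract_mesh(analytic_shape("ball", spacing_mm = 0.25,
                                    radius_mm = 5))
  cf5 <- compute_curvature_field(m5, radius_mm = 1.5)
  expect_equal(median(cf5$kappa1) / median(cf10$kappa1), 2,
               tolerance = 0.05)
  expect_equal(median(cf5$gaussian_K) / median(cf10$gaussian_K), 4,
               tolerance = 0.1)
})

test_that("smoothing preserves the area-weighted mean within 1%", {
  cf0 <- compute_curvature_field(ball_mesh(), radius_mm = 3,
                                 smoothing_rounds = 0)
  cf3 <- compute_curvature_field(ball_mesh(), radius_mm = 3,
                                 smoothing_rounds = 3)
  w <- combscan:::vertex_areas(ball_mesh())
  m0 <- sum(w * cf0$kappa1) / sum(w)
  m3 <- sum(w * cf3$kappa1) / sum(w)
  expect_lt(abs(m3 - m0) / abs(m0), 0.01)
})

test_that("area-weighted histograms integrate to one", {
  cf <- fixture("sphere_curv", function()
    compute_curvature_field(ball_mesh(), radius_mm = 3))
  h <- curvature_histogram(cf, "kappa1", bins = 30)
  expect_equal(sum(h$area_fraction), 1)
  expect_equal(sum(h$count), length(cf$kappa1))
  # sphere kappa1 is unimodal at 1/r
  peak <- h$bin_lo[which.max(h$area_fraction)]
  expect_lt(abs(peak - 0.1), 0.02)
  # constant channel: single nonzero bin with fraction 1
  cfc <- cf
  cfc$kappa1 <- rep(0.3, length(cf$kappa1))
  hc <- curvature_histogram(cfc, "kappa1", bins = 10)
  expect_equal(sum(hc$area_fraction > 0), 1L)
  expect_equal(max(hc$area_fraction), 1)
})

test_that("a bent comb envelope has a heavier negative-curvature tail", {
  tail_mass <- function(warp, amp) {
    spec <- comb_phantom_spec(layout = "grid", rows = 8, cols = 7,
                              sides = 2, spacing_mm = 0.45,
                              wall_thickness_mm = 0.95, substrate = FALSE,
                              warp = warp, warp_amplitude = amp)
    ph <- generate_phantom(spec)
    env <- sdf_close(to_sdf(ph$volume, 0.2), structuring_ball(6))
    dm <- combscan:::decimate_for_spectral(extract_mesh(env), 1500)
    cf <- compute_curvature_field(dm, radius_mm = 15, smoothing_rounds = 2)
    w <- combscan:::vertex_areas(dm)
    sum(w[cf$kappa2 < -0.01]) / sum(w)
  }
  flat <- tail_mass("none", 0)
  bent <- tail_mass("cylinder_bend", 18)
  expect_gt(bent, flat + 0.02)
})
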