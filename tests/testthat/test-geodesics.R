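# a thin planar slab domain with a point source, shared across tests
slab_field <- function(metric = 1, spacing = 0.5, n = 71, src_idx = c(6, 6)) {
  dims <- c(n, n, 3)
  mask <- array(FALSE, dims)
  mask[, , 2] <- TRUE
  vol <- density_volume(array(0.6 * mask, dims), spacing, c(0, 0, 0))
  src <- array(FALSE, dims)
  src[src_idx[1], src_idx[2], 2] <- TRUE
  solve_eikonal(vol, src, metric = metric, domain_mask = mask)
}

test_that("eikonal solutions reach the Euclidean limit on a flat slab", {
  f <- slab_field()
  # target 30 mm away in-plane (24, 18)
  u <- f$u[6 + 48, 6 + 36, 2]
  expect_lt(abs(u - 30) / 30, 0.05)
  # inverse-speed scaling is exact
  f2 <- slab_field(metric = 0.5)
  expect_equal(f2$u[6 + 48, 6 + 36, 2] / u, 2, tolerance = 1e-12)
  expect_lt(abs(f2$u[6 + 48, 6 + 36, 2] - 60) / 60, 0.05)
})

test_that("the slab error shrinks when the spacing halves", {
  e1 <- abs(slab_field(spacing = 0.5)$u[6 + 48, 6 + 36, 2] - 30)
  # the same physical source/target at half the spacing
  f <- slab_field(spacing = 0.25, n = 141, src_idx = c(11, 11))
  e2 <- abs(f$u[11 + 96, 11 + 72, 2] - 30)
  expect_lt(e2 / e1, 0.75)
})

test_that("cylinder-shell geodesics match the unrolled closed form", {
  h <- 0.25
  cy <- analytic_shape("cylinder_shell", spacing_mm = h, radius_mm = 10,
                       height_mm = 46, thickness_mm = 1)
  shell <- cy$distances < 0
  vol <- density_volume(array(as.numeric(shell), dim = cy$dims), h,
                        cy$origin_mm)
  vs <- round((c(10, 0, -10) - cy$origin_mm) / h) + 1
  src <- array(FALSE, cy$dims)
  src[vs[1], vs[2], vs[3]] <- TRUE
  f <- solve_eikonal(vol, src & shell, metric = 1, domain_mask = shell)
  vt <- round((c(0, 10, 10) - cy$origin_mm) / h) + 1
  u <- f$u[vt[1], vt[2], vt[3]]
  expect_lt(abs(u - sqrt((5 * pi)^2 + 20^2)) / sqrt((5 * pi)^2 + 20^2),
            0.05)
})

test_that("eikonal preconditions and QC behave", {
  vol <- density_volume(array(0.6, c(8, 8, 8)), 1)
  expect_error(solve_eikonal(vol, array(FALSE, c(8, 8, 8))), "empty source")
  src <- array(FALSE, c(8, 8, 8)); src[4, 4, 4] <- TRUE
  expect_error(solve_eikonal(vol, src, metric = -1), "positive")
  # unreachable voxels counted
  mask <- array(TRUE, c(8, 8, 8))
  mask[4:5, , ] <- FALSE
  mask[4, 4, 4] <- TRUE  # isolated source plane barrier
  f <- solve_eikonal(vol, src, domain_mask = mask)
  expect_gt(f$n_unreachable, 0)
})

test_that("gradients are radial for a point source and planar for a wall", {
  vol <- density_volume(array(0.6, c(81, 81, 81)), 0.25)
  src <- array(FALSE, c(81, 81, 81)); src[41, 41, 41] <- TRUE
  f <- solve_eikonal(vol, src)
  g <- gradient_field(f)
  idx <- which(f$u > 2.5 & f$u < 8)
  ijk <- arrayInd(idx, f$dims)
  rad <- sweep(ijk, 2, c(41, 41, 41))
  rad <- rad / sqrt(rowSums(rad^2))
  gv <- cbind(g$gx[idx], g$gy[idx], g$gz[idx])
  ang <- acos(pmin(1, rowSums(rad * gv))) * 180 / pi
  expect_lt(mean(ang), 5)
  # planar source: constant direction
  srcp <- array(FALSE, c(81, 81, 81)); srcp[1, , ] <- TRUE
  fp <- solve_eikonal(vol, srcp)
  gp <- gradient_field(fp)
  core <- fp$u > 2
  expect_gt(mean(gp$gx[core]), 0.99)
})

test_that("gradient directions agree with a Dijkstra oracle", {
  skip_if_not_installed("igraph")
  set.seed(4)
  dims <- c(25, 25, 3)
  mask <- array(FALSE, dims); mask[, , 2] <- TRUE
  # punch a few holes to make the domain nontrivial
  holes <- cbind(sample(5:20, 15, TRUE), sample(5:20, 15, TRUE), 2)
  mask[holes] <- FALSE
  vol <- density_volume(array(0.6 * mask, dims), 1, c(0, 0, 0))
  src <- array(FALSE, dims); src[3, 3, 2] <- TRUE
  src <- src & mask
  f <- solve_eikonal(vol, src, domain_mask = mask)
  dref <- grid_dijkstra(mask, 1, src)
  dref_arr <- array(Inf, dims)
  dref_arr[mask] <- as.vector(dref)
  # triangle-ish check: u within discretization tolerance of graph dist
  fin <- is.finite(f$u) & is.finite(dref_arr) & f$u > 3
  expect_lt(median(abs(f$u[fin] - dref_arr[fin]) / dref_arr[fin]), 0.06)
})

test_that("steepest-descent paths return to the source", {
  f <- slab_field()
  p <- trace_path(f, c(6 + 48, 6 + 36, 2))
  expect_false(attr(p, "truncated"))
  len <- sum(sqrt(rowSums(diff(p)^2)))
  expect_lt(abs(len - 30) / 30, 0.10)
  # start on the source: single point
  p0 <- trace_path(f, c(6, 6, 2))
  expect_equal(nrow(p0), 1L)
})

test_that("paths detour around an obstacle like the graph oracle", {
  skip_if_not_installed("igraph")
  dims <- c(41, 31, 3)
  mask <- array(FALSE, dims); mask[, , 2] <- TRUE
  mask[18:22, 1:22, 2] <- FALSE  # slot
  vol <- density_volume(array(0.6 * mask, dims), 1, c(0, 0, 0))
  src <- array(FALSE, dims); src[5, 5, 2] <- TRUE
  f <- solve_eikonal(vol, src, domain_mask = mask)
  tgt <- c(36, 5, 2)
  p <- trace_path(f, tgt)
  len <- sum(sqrt(rowSums(diff(p)^2)))
  dref <- grid_dijkstra(mask, 1, src, matrix(tgt, 1))
  expect_lt(abs(len - dref[1, 1]) / dref[1, 1], 0.10)
})

test_that("metric monotonicity: faster medium never increases cost", {
  f1 <- slab_field(metric = 1)
  f05 <- slab_field(metric = 0.5)
  fin <- is.finite(f1$u)
  expect_true(all(f05$u[fin] >= f1$u[fin] - 1e-9))
})

test_that("build direction recovers the phantom growth axis", {
  ph <- fixture("grown_phantom", function()
    generate_phantom(comb_phantom_spec(layout = "disc", n_rings = 3,
                                       sides = 2, spacing_mm = 0.35)))
  v <- ph$volume
  src <- abs(v$values - ph$truth$substrate_value) < 1e-6
  f <- solve_eikonal(v, src, metric = "density")
  zw <- v$origin_mm[3] + (seq_len(v$dims[3]) - 1) * v$spacing_mm[3]
  reg <- array(FALSE, v$dims)
  reg[, , zw < quantile(zw, 0.33)] <- TRUE
  bd <- build_direction(f, reg & f$domain_mask & !src)
  expect_gt(sum(bd$mean_gradient * ph$truth$growth_axis), 0.95)
  expect_true(bd$dispersion >= 0 && bd$dispersion <= 1)
  # isotropically grown region: high dispersion
  b <- analytic_shape("ball", spacing_mm = 0.5, radius_mm = 8)
  bv <- density_volume(array(as.numeric(b$distances < 0), dim = b$dims),
                       0.5, b$origin_mm)
  ci <- round((c(0, 0, 0) - b$origin_mm) / 0.5) + 1
  srcb <- array(FALSE, b$dims); srcb[ci[1], ci[2], ci[3]] <- TRUE
  fb <- solve_eikonal(bv, srcb)
  bdb <- build_direction(fb, fb$domain_mask & !srcb)
  expect_gt(bdb$dispersion, 0.5)
  # region too small errors
  tiny <- array(FALSE, v$dims); tiny[1:3, 1, 1] <- TRUE
  expect_error(build_direction(f, tiny), "finite travel cost|too small")
})

test_that("mirrored regions of a symmetric phantom balance out", {
  ph <- fixture("grown_phantom", function()
    generate_phantom(comb_phantom_spec(layout = "disc", n_rings = 3,
                                       sides = 2, spacing_mm = 0.35)))
  v <- ph$volume
  src <- abs(v$values - ph$truth$substrate_value) < 1e-6
  f <- solve_eikonal(v, src, metric = "density")
  yw <- v$origin_mm[2] + (seq_len(v$dims[2]) - 1) * v$spacing_mm[2]
  left <- array(FALSE, v$dims); left[, yw < -2, ] <- TRUE
  right <- array(FALSE, v$dims); right[, yw > 2, ] <- TRUE
  bl <- build_direction(f, left & f$domain_mask & !src)
  br <- build_direction(f, right & f$domain_mask & !src)
  expect_lt(abs(bl$mean_gradient[2] + br$mean_gradient[2]), 0.05)
})
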