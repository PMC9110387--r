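test_that("dilation matches analytic ball volumes and preconditions", {
  # single-voxel seed dilated by 3 mm -> ball of volume 4/3 pi 27
  vol <- array(0, c(9, 9, 9))
  vol[5, 5, 5] <- 1
  s <- to_sdf(density_volume(vol, 0.25), 0.5)
  d <- sdf_dilate(s, structuring_ball(3))
  v_true <- 4 / 3 * pi * 27
  expect_lt(abs(sdf_volume(d) - v_true) / v_true, 0.05)
  expect_error(sdf_dilate(s, structuring_ball(0.1)), "smaller than")
})

test_that("erosion offsets analytic balls inward and can annihilate", {
  b5 <- analytic_shape("ball", spacing_mm = 0.25, radius_mm = 5)
  e <- sdf_erode(b5, structuring_ball(2))
  v3 <- 4 / 3 * pi * 27
  expect_lt(abs(sdf_volume(e) - v3) / v3, 0.1)
  b2 <- analytic_shape("ball", spacing_mm = 0.25, radius_mm = 2)
  gone <- sdf_erode(b2, structuring_ball(3))
  expect_equal(sdf_volume(gone), 0)
})

test_that("morphology is voxel-exact against brute-force Minkowski oracles", {
  r <- 2
  for (seed in 1:20) {
    fx <- random_sdf16(seed)
    # dilation
    dil <- sdf_dilate(fx$sdf, structuring_ball(r))
    ref <- minkowski_dilate(fx$mask, r)
    pad_pkg <- as.integer(ceiling(r)) + 2L
    got <- combscan:::crop_to_grid(dil, fx$sdf)$distances < 0
    ref_crop <- crop_pad(ref$mask, ref$pad, dim(fx$mask))
    expect_identical(as.vector(got), as.vector(ref_crop))
    # erosion
    ero <- sdf_erode(fx$sdf, structuring_ball(r))
    expect_identical(as.vector(ero$distances < 0),
                     as.vector(minkowski_erode(fx$mask, r)))
    # opening and closing
    op <- sdf_open(fx$sdf, structuring_ball(r))
    ref_open <- minkowski_dilate(minkowski_erode(fx$mask, r), r)
    expect_identical(as.vector(op$distances < 0),
                     as.vector(crop_pad(ref_open$mask, ref_open$pad,
                                        dim(fx$mask))))
    cl <- sdf_close(fx$sdf, structuring_ball(r))
    refd <- minkowski_dilate(fx$mask, r)
    refc <- minkowski_erode(refd$mask, r)
    expect_identical(as.vector(cl$distances < 0),
                     as.vector(crop_pad(refc, refd$pad, dim(fx$mask))))
  }
})

test_that("closing bridges gaps narrower than the ball diameter", {
  mk_cubes <- function(gap_vox) {
    a <- array(0, c(30, 12, 12))
    a[2:11, 2:11, 2:11] <- 1
    a[(12 + gap_vox):(21 + gap_vox), 2:11, 2:11] <- 1
    to_sdf(density_volume(a, 1), 0.5)
  }
  n_comp <- function(s) {
    max(combscan:::label_components_cpp(as.logical(s$distances < 0),
                                        as.integer(s$dims), 6L))
  }
  two <- mk_cubes(4)  # 4 mm gap
  expect_equal(n_comp(two), 2L)
  expect_equal(n_comp(sdf_close(two, structuring_ball(3))), 1L)
  expect_equal(n_comp(sdf_close(two, structuring_ball(1.5))), 2L)
})

test_that("opening a ball larger than the element leaves it unchanged", {
  b5 <- analytic_shape("ball", spacing_mm = 0.25, radius_mm = 5)
  op <- sdf_open(b5, structuring_ball(3))
  # differences confined to a sub-voxel surface band
  expect_lt(mean(xor(op$distances < 0, b5$distances < 0)), 0.03)
})

test_that("boolean operators obey set algebra", {
  fx <- random_sdf16(7)
  a <- fx$sdf
  expect_identical(as.vector(sdf_boolean(a, a, "intersect")$distances < 0),
                   as.vector(a$distances < 0))
  expect_equal(sdf_volume(sdf_boolean(a, a, "subtract")), 0)
  # voxel-exact set algebra on random pairs, all three ops
  for (seed in c(21, 22, 23)) {
    fy <- random_sdf16(seed)
    b <- fy$sdf
    expect_identical(as.vector(sdf_boolean(a, b, "union")$distances < 0),
                     as.vector(fx$mask | fy$mask))
    expect_identical(as.vector(sdf_boolean(a, b, "intersect")$distances < 0),
                     as.vector(fx$mask & fy$mask))
    expect_identical(as.vector(sdf_boolean(a, b, "subtract")$distances < 0),
                     as.vector(fx$mask & !fy$mask))
  }
  # disjoint balls on a common grid: union volume is additive
  h <- 0.5
  xs <- seq(-12, 12, by = h)
  n <- length(xs)
  X <- rep(xs, times = n * n)
  Y <- rep(rep(xs, each = n), times = n)
  Z <- rep(xs, each = n * n)
  d1 <- array(sqrt((X + 6)^2 + Y^2 + Z^2) - 4, c(n, n, n))
  d2 <- array(sqrt((X - 6)^2 + Y^2 + Z^2) - 4, c(n, n, n))
  b1 <- signed_distance_volume(d1, h, c(-12, -12, -12))
  b2 <- signed_distance_volume(d2, h, c(-12, -12, -12))
  u <- sdf_boolean(b1, b2, "union")
  expect_equal(sdf_volume(u), sdf_volume(b1) + sdf_volume(b2),
               tolerance = 0.01)
  # grid mismatch errors
  off <- signed_distance_volume(b1$distances, b1$spacing_mm,
                                b1$origin_mm + 0.1)
  expect_error(sdf_boolean(b1, off, "union"), "grid mismatch")
})

test_that("duality, monotonicity, and idempotence hold", {
  fx <- random_sdf16(9)
  r <- 2
  # duality: erosion = complement of dilating the complement
  comp <- to_sdf(density_volume(array(as.numeric(!fx$mask),
                                      dim = dim(fx$mask)), 1), 0.5)
  dil_comp <- combscan:::crop_to_grid(
    sdf_dilate(comp, structuring_ball(r)), comp)
  ero <- sdf_erode(fx$sdf, structuring_ball(r))
  expect_identical(as.vector(ero$distances < 0),
                   as.vector(!(dil_comp$distances <= 0) & fx$mask))
  # monotone: A subset B implies dilate(A) subset dilate(B)
  sub_mask <- fx$mask
  sub_mask[1:8, , ] <- FALSE
  if (any(sub_mask)) {
    subs <- to_sdf(density_volume(array(as.numeric(sub_mask),
                                        dim = dim(sub_mask)), 1), 0.5)
    dA <- combscan:::crop_to_grid(sdf_dilate(subs, structuring_ball(r)),
                                  subs)
    dB <- combscan:::crop_to_grid(sdf_dilate(fx$sdf, structuring_ball(r)),
                                  fx$sdf)
    expect_true(all(dB$distances[dA$distances < 0] < 0))
  }
  # volume ordering and idempotence (1-voxel band tolerance)
  op1 <- sdf_open(fx$sdf, structuring_ball(r))
  cl1 <- sdf_close(fx$sdf, structuring_ball(r))
  expect_lte(sdf_volume(op1), sdf_volume(fx$sdf))
  expect_gte(sdf_volume(cl1), sdf_volume(fx$sdf))
  op2 <- sdf_open(op1, structuring_ball(r))
  cl2 <- sdf_close(cl1, structuring_ball(r))
  expect_lt(mean(xor(op2$distances < 0, op1$distances < 0)), 0.02)
  expect_lt(mean(xor(cl2$distances < 0, cl1$distances < 0)), 0.02)
})
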