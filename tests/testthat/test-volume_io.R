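test_that("density volume validates its invariants", {
  v <- array(runif(8 * 8 * 8), dim = c(8, 8, 8))
  vol <- density_volume(v, 0.5, c(1, 2, 3))
  expect_equal(vol$dims, c(8L, 8L, 8L))
  expect_equal(vol$spacing_mm, rep(0.5, 3))
  expect_error(density_volume(v * 2, 0.5), "\\[0, 1\\]")
  expect_error(density_volume(v, -1), "positive")
  expect_error(density_volume(array(0.5, c(1, 8, 8)), 0.5), ">= 2")
})

test_that("signed distance of an analytic ball matches theory", {
  b <- ball_sdf()
  ci <- round((c(0, 0, 0) - b$origin_mm) / b$spacing_mm) + 1
  expect_equal(b$distances[ci[1], ci[2], ci[3]], -10)
  # voxelized route: binarize the ball and redistance
  vol <- density_volume(array(as.numeric(b$distances < 0), dim = b$dims),
                        b$spacing_mm, b$origin_mm)
  s <- to_sdf(vol, 0.5)
  expect_lt(abs(s$distances[ci[1], ci[2], ci[3]] + 10), 0.5)  # 1 voxel
  # probe 5 mm outside the surface
  pi15 <- round((c(0, 0, 5 + 10) - b$origin_mm) / b$spacing_mm) + 1
  pi15 <- pmin(pi15, b$dims)
  # use a probe that is inside the grid: 11.5 mm from center
  p <- round((c(11.5, 0, 0) - b$origin_mm) / b$spacing_mm) + 1
  expect_lte(abs(s$distances[p[1], p[2], p[3]] - 1.5), 0.5)  # 1 voxel
})

test_that("to_sdf equals a brute-force all-pairs distance transform", {
  fx <- random_sdf16(11)
  w_in <- which(fx$mask, arr.ind = TRUE)
  w_out <- which(!fx$mask, arr.ind = TRUE)
  ref <- array(0, dim = c(16, 16, 16))
  for (i in seq_len(nrow(w_out))) {
    p <- w_out[i, ]
    ref[p[1], p[2], p[3]] <- sqrt(min(colSums((t(w_in) - p)^2)))
  }
  for (i in seq_len(nrow(w_in))) {
    p <- w_in[i, ]
    ref[p[1], p[2], p[3]] <- -sqrt(min(colSums((t(w_out) - p)^2)))
  }
  expect_equal(as.vector(fx$sdf$distances), as.vector(ref),
               tolerance = 1e-12)
})

test_that("to_sdf rejects empty solids and bad thresholds", {
  vol <- density_volume(array(0.1, c(4, 4, 4)), 1)
  expect_error(to_sdf(vol, 0.5), "empty solid")
  expect_error(to_sdf(vol, 1.5), "iso_threshold")
})

test_that("SDF gradient magnitude is ~1 away from medial axis", {
  b <- ball_sdf()
  d <- b$distances
  h <- b$spacing_mm[1]
  gx <- (d[3:dim(d)[1], , ] - d[1:(dim(d)[1] - 2), , ]) / (2 * h)
  gy <- (d[, 3:dim(d)[2], ] - d[, 1:(dim(d)[2] - 2), ]) / (2 * h)
  gz <- (d[, , 3:dim(d)[3]] - d[, , 1:(dim(d)[3] - 2)]) / (2 * h)
  n <- dim(d) - 2
  gmag <- sqrt(gx[, 2:(n[2] + 1), 2:(n[3] + 1)]^2 +
                 gy[2:(n[1] + 1), , 2:(n[3] + 1)]^2 +
                 gz[2:(n[1] + 1), 2:(n[2] + 1), ]^2)
  core <- abs(d[2:(n[1] + 1), 2:(n[2] + 1), 2:(n[3] + 1)])
  sel <- core > 2 * h & core < 8  # away from center (medial axis) and band
  expect_lt(max(abs(gmag[sel] - 1)), 0.1)
})

test_that("binarize-redistance is idempotent to one voxel", {
  fx <- random_sdf16(3)
  s1 <- fx$sdf
  vol2 <- density_volume(array(as.numeric(s1$distances < 0),
                               dim = s1$dims), 1, c(0, 0, 0))
  s2 <- to_sdf(vol2, 0.5)
  expect_equal(as.vector(s1$distances), as.vector(s2$distances))
})

test_that("downsample pools block means", {
  vol <- density_volume(array(0.5, c(4, 4, 4)), 1)
  expect_identical(downsample(vol, 1), vol)
  d2 <- downsample(vol, 2)
  expect_equal(d2$dims, c(2L, 2L, 2L))
  expect_true(all(d2$values == 0.5))
  expect_equal(d2$spacing_mm, rep(2, 3))
  # checkerboard averages to exactly 0.5
  idx <- as.matrix(expand.grid(1:4, 1:4, 1:4))
  cb <- array((rowSums(idx) %% 2 == 0) * 1, c(4, 4, 4))
  dc <- downsample(density_volume(cb, 1), 2)
  expect_true(all(dc$values == 0.5))
  expect_error(downsample(vol, 5), "exceeds")
})

test_that("NRRD write/read round-trips geometry and values", {
  ph <- small_disc_phantom()
  path <- tempfile(fileext = ".nrrd")
  write_nrrd(ph$volume, path)
  back <- load_volume(path, format = "nrrd")
  expect_equal(back$dims, ph$volume$dims)
  expect_equal(back$spacing_mm, ph$volume$spacing_mm)
  expect_equal(back$origin_mm, ph$volume$origin_mm)
  expect_equal(back$values, ph$volume$values)
  unlink(path)
})

test_that("16-bit TIFF stacks load, normalize, and round-trip", {
  skip_if_not_installed("tiff")
  dir <- tempfile("stack_")
  dir.create(dir)
  set.seed(5)
  vals <- round(array(runif(16 * 12 * 5), c(16, 12, 5)) * 65535) / 65535
  for (k in 1:5)
    tiff::writeTIFF(t(vals[, , k]), file.path(dir, sprintf("s%03d.tif", k)),
                    bits.per.sample = 16)
  vol <- load_volume(dir, format = "tiff_stack", normalize = TRUE,
                     spacing_mm = 0.1)
  expect_equal(vol$dims, c(16L, 12L, 5L))
  expect_equal(max(vol$values), 1.0)
  # round trip within 16-bit quantization
  raw <- load_volume(dir, format = "tiff_stack", spacing_mm = 0.1)
  expect_lt(max(abs(raw$values - vals)), 1 / 65535 + 1e-12)
  # constant stack cannot be normalized
  dir2 <- tempfile("const_")
  dir.create(dir2)
  tiff::writeTIFF(matrix(0.25, 8, 8), file.path(dir2, "a.tif"),
                  bits.per.sample = 16)
  expect_error(load_volume(dir2, format = "tiff_stack", normalize = TRUE,
                           spacing_mm = 0.1), "degenerate range")
  # mixed slice shapes are a format error
  dir3 <- tempfile("mix_")
  dir.create(dir3)
  tiff::writeTIFF(matrix(0.5, 8, 8), file.path(dir3, "a.tif"))
  tiff::writeTIFF(matrix(0.5, 9, 8), file.path(dir3, "b.tif"))
  expect_error(load_volume(dir3, format = "tiff_stack", spacing_mm = 0.1),
               "mixed slice shapes")
  unlink(c(dir, dir2, dir3), recursive = TRUE)
})

test_that("mesh extraction reproduces analytic areas and topology", {
  m <- ball_mesh()
  expect_lt(abs(mesh_area(m) - 4 * pi * 100) / (4 * pi * 100), 0.05)
  expect_equal(euler_characteristic(m), 2)
  slab <- analytic_shape("slab", spacing_mm = 0.5,
                         half_extents_mm = c(10, 10, 2))
  ms <- extract_mesh(slab)
  a_true <- 2 * 20 * 20 + 4 * 20 * 4
  expect_lt(abs(mesh_area(ms) - a_true) / a_true, 0.05)
  # comb phantom: one closed component, no handles
  ph <- small_disc_phantom()
  mp <- extract_mesh(to_sdf(ph$volume, 0.2))
  expect_equal(euler_characteristic(mp), ph$truth$euler_characteristic)
  # empty level set errors
  expect_error(extract_mesh(signed_distance_volume(
    array(1, c(4, 4, 4)), 1)), "empty level set")
})

test_that("PLY and OBJ writers emit valid files", {
  m <- ball_mesh()
  ply <- tempfile(fileext = ".ply")
  obj <- tempfile(fileext = ".obj")
  write_ply(m, ply)
  write_obj(m, obj)
  head_ply <- readLines(ply, n = 4)
  expect_equal(head_ply[1], "ply")
  expect_match(head_ply[3], as.character(nrow(m$vertices)))
  lines_obj <- readLines(obj)
  expect_equal(sum(startsWith(lines_obj, "v ")), nrow(m$vertices))
  expect_equal(sum(startsWith(lines_obj, "f ")), nrow(m$triangles))
  unlink(c(ply, obj))
})

test_that("volumes can be rotated and cropped", {
  ph <- small_disc_phantom()
  R <- diag(3)
  rv <- rotate_volume(ph$volume, R)
  expect_equal(sum(rv$values > 0.2), sum(ph$volume$values > 0.2),
               tolerance = 0.01)
  cv <- crop_volume(ph$volume, c(-5, -5, -5), c(5, 5, 5))
  expect_true(all(cv$dims <= ph$volume$dims))
  expect_error(crop_volume(ph$volume, c(1e5, 0, 0), c(1e5 + 1, 1, 1)),
               "does not intersect")
})
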