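# Shared fixtures, built once per test run and cached. Every fixture is
# generated in code (analytic shapes or seeded phantoms); nothing is
# read from disk.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

ball_sdf <- function(spacing = 0.5, radius = 10) {
  fixture(sprintf("ball_%g_%g", spacing, radius), function()
    analytic_shape("ball", spacing_mm = spacing, radius_mm = radius))
}

ball_mesh <- function(spacing = 0.5, radius = 10) {
  fixture(sprintf("ballmesh_%g_%g", spacing, radius), function()
    extract_mesh(ball_sdf(spacing, radius)))
}

saddle_mesh <- function(spacing = 0.5) {
  fixture(sprintf("saddle_%g", spacing), function()
    analytic_shape("saddle", spacing_mm = spacing, coeff = 0.05,
                   extent_mm = 10))
}

# small double-sided comb disc (14 cells), the workhorse phantom
small_disc_phantom <- function() {
  fixture("small_disc", function()
    generate_phantom(comb_phantom_spec(layout = "disc", n_rings = 2,
                                       sides = 2, spacing_mm = 0.3,
                                       substrate = FALSE)))
}

small_disc_cells <- function() {
  fixture("small_disc_cells", function() {
    ph <- small_disc_phantom()
    s <- to_sdf(ph$volume, 0.2)
    cells <- extract_cells(s)
    plane <- median_plane(cells)
    list(sdf = s, cells = cell_frames(cells, plane), plane = plane)
  })
}

# regional workflow on the mid-build-rotation phantom: Fiedler split of
# the comb into two regions, per-region cell extraction, tilt/gravity
l_bend_gravities <- function() {
  fixture("l_bend_gravities", function() {
    spec <- comb_phantom_spec(layout = "grid", rows = 7, cols = 3,
                              sides = 2, spacing_mm = 0.35,
                              warp = "l_bend", warp_amplitude = 90)
    ph <- generate_phantom(spec)
    vm <- ph$volume
    vm$values[abs(vm$values - ph$truth$substrate_value) < 1e-6] <- 0
    dm <- combscan:::decimate_for_spectral(extract_mesh(to_sdf(vm, 0.2)),
                                           1000)
    seg <- fiedler_segment(eigenbasis(build_laplacian(dm, "graph"), 3), 2)
    gravs <- lapply(1:2, function(k) {
      vs <- dm$vertices[seg$labels == k, , drop = FALSE]
      lo <- apply(vs, 2, quantile, 0.02) - 1
      hi <- apply(vs, 2, quantile, 0.98) + 1
      cs <- extract_cells(to_sdf(crop_volume(vm, lo, hi), 0.2),
                          opening_radius_mm = 1.0)
      pl <- suppressWarnings(median_plane(cs))
      tilt_and_gravity(cell_frames(cs, pl), pl)$gravity
    })
    list(truth = ph$truth, gravities = gravs)
  })
}

# random binary 16^3 volume and its SDF, per seed
random_sdf16 <- function(seed, p = 0.08) {
  set.seed(seed)
  mask <- array(runif(16^3) < p, dim = c(16, 16, 16))
  list(mask = mask,
       sdf = to_sdf(density_volume(array(as.numeric(mask), dim = dim(mask)),
                                   1, c(0, 0, 0)), 0.5))
}
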