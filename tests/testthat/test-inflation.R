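test_that("energy is zero at rest and the volume term has its closed form", {
  tet <- tetra_mesh()
  mp0 <- material_params(pressure = 0, k_bend = 0)
  eg <- compute_energy(tet$vertices, tet, mp0)
  expect_equal(eg$energy, 0, tolerance = 1e-12)
  expect_lt(max(abs(eg$gradient)), 1e-12)
  # with pressure p the only nonzero term at rest is -p V
  p <- 0.37
  eg2 <- compute_energy(tet$vertices, tet, material_params(pressure = p,
                                                           k_bend = 0))
  expect_equal(eg2$energy, -p * TETRA_VOLUME, tolerance = 1e-12)
  cube <- make_primitive("cube")$mesh
  eg3 <- compute_energy(cube$vertices, cube,
                        material_params(k_stretch = 1e6, pressure = p,
                                        k_bend = 0))
  expect_equal(eg3$energy, -p * 1.0, tolerance = 1e-9)
})

test_that("analytic gradient matches central finite differences", {
  shp <- make_primitive("sphere", subdivisions = 1L, jitter = 0.2, seed = 7L)
  mesh <- shp$mesh    # 42 vertices, jittered
  mp <- material_params(k_stretch = 1, pressure = 0.3, k_bend = 0.05)
  set.seed(42)
  pos <- mesh$vertices + matrix(rnorm(3 * n_vertices(mesh), 0, 0.05), ncol = 3)
  eg <- compute_energy(pos, mesh, mp)
  h <- 1e-6
  g_fd <- matrix(0, nrow(pos), 3)
  for (i in seq_len(nrow(pos))) {
    for (k in 1:3) {
      pp <- pos; pp[i, k] <- pp[i, k] + h
      pm <- pos; pm[i, k] <- pm[i, k] - h
      g_fd[i, k] <- (compute_energy(pp, mesh, mp)$energy -
                       compute_energy(pm, mesh, mp)$energy) / (2 * h)
    }
  }
  expect_lt(max(abs(eg$gradient - g_fd)) / max(abs(g_fd)), 1e-5)
})

test_that("zero pressure at rest converges immediately to the input", {
  shp <- small_accordion()
  traj <- inflate(shp$mesh, material_params(pressure = 0, k_bend = 0,
                                            max_steps = 10L))
  expect_true(traj$converged)
  expect_identical(traj$n_steps, 0L)
  expect_identical(snapshot_mesh(traj)$vertices, shp$mesh$vertices)
})

test_that("descent is monotone, deterministic, and volume-increasing", {
  shp <- small_accordion()
  mp <- material_params(max_steps = 3000L, snapshot_stride = 25L)
  traj <- inflate(shp$mesh, mp)
  expect_true(all(diff(traj$energy_series) <= 0))
  expect_gt(enclosed_volume(snapshot_mesh(traj)),
            enclosed_volume(shp$mesh))
  traj2 <- inflate(shp$mesh, mp)
  expect_identical(traj$snapshots, traj2$snapshots)
  expect_identical(traj$energy_series, traj2$energy_series)
  # connectivity frozen across snapshots
  expect_identical(snapshot_mesh(traj, "first")$faces, shp$mesh$faces)
})

test_that("pinned vertices never move and open meshes demand a pinned rim", {
  shp <- make_furrowed_disk(n_rings = 10L, n_spokes = 16L)
  expect_error(inflate(shp$mesh, material_params(max_steps = 5L)), "pinned")
  mp <- material_params(pinned = shp$masks$boundary, max_steps = 800L)
  traj <- inflate(shp$mesh, mp)
  pin <- as.integer(shp$masks$boundary)
  expect_identical(snapshot_mesh(traj)$vertices[pin, ],
                   shp$mesh$vertices[pin, ])
})

test_that("near-inextensibility holds at the default stiffness/pressure ratio", {
  fixtures <- list(
    small_accordion(),
    make_yoshimura_cylinder(n_axial = 7L, n_circumferential = 10L),
    make_furrowed_disk(n_rings = 14L, n_spokes = 24L))
  pins <- list(NULL, NULL, "boundary")
  for (k in seq_along(fixtures)) {
    shp <- fixtures[[k]]
    traj <- inflate(shp$mesh, material_params(pinned = pins[[k]],
                                              max_steps = 30000L))
    rel <- abs(surface_area(snapshot_mesh(traj)) / surface_area(shp$mesh) - 1)
    expect_lt(rel, 0.05)
  }
})

test_that("the descent reaches the same minimum as an independent quasi-Newton solver", {
  shp <- make_primitive("sphere", subdivisions = 2L, jitter = 0.15, seed = 3L)
  mesh <- shp$mesh   # 162 vertices, noisy rest geometry
  mp <- material_params(pressure = 0.1, max_steps = 20000L)
  traj <- inflate(mesh, mp)
  expect_true(traj$converged)
  e_pkg <- traj$energy_series[length(traj$energy_series)]
  # independent minimizer: stats::optim L-BFGS-B on the same functional
  p <- traj$params
  fn <- function(x) compute_energy(matrix(x, ncol = 3), mesh, p)$energy
  gr <- function(x) as.numeric(compute_energy(matrix(x, ncol = 3), mesh, p)$gradient)
  opt <- stats::optim(as.numeric(mesh$vertices), fn, gr, method = "L-BFGS-B",
                      control = list(maxit = 2000L, factr = 1e4))
  expect_lt(abs(e_pkg - opt$value) / abs(opt$value), 1e-3)
})

test_that("inflating a noisy sphere restores near-perfect sphericity", {
  shp <- make_primitive("sphere", subdivisions = 3L, jitter = 0.1, seed = 11L)
  traj <- inflate(shp$mesh, material_params(pressure = 0.1, max_steps = 20000L))
  fin <- snapshot_mesh(traj)
  sph <- 36 * pi * enclosed_volume(fin)^2 / surface_area(fin)^3
  expect_gt(sph, 0.99)
})

test_that("correspondence mapping is the identity on vertex indices", {
  shp <- small_accordion()
  traj <- inflate(shp$mesh, material_params(max_steps = 500L))
  mask <- region_mask("distal",
                      which(snapshot_mesh(traj)$vertices[, 3] >
                              0.8 * max(snapshot_mesh(traj)$vertices[, 3])),
                      n_vertices(shp$mesh))
  back <- map_region(traj, mask, at_step = "first")
  expect_identical(as.integer(back), as.integer(mask))
  empty <- map_region(traj, region_mask("none", integer(0)), "last")
  expect_length(empty, 0L)
  expect_error(map_region(traj, mask, at_step = 99999L), "not recorded")
  # rewound positions come from the folded snapshot
  folded <- snapshot_mesh(traj, "first")
  expect_identical(folded$vertices[as.integer(back), ],
                   shp$mesh$vertices[as.integer(mask), ])
})
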