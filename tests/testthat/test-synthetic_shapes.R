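test_that("every generator emits a valid, deterministic mesh", {
  shapes <- list(
    sphere = make_primitive("sphere", subdivisions = 2L),
    cylinder = make_primitive("cylinder"),
    cone = make_primitive("cone"),
    cube = make_primitive("cube"),
    bent_tube = make_primitive("bent_tube", n_theta = 12L),
    accordion = make_accordion_cylinder(n_theta = 16L, n_axial = 32L),
    yoshimura = make_yoshimura_cylinder(),
    disk = make_furrowed_disk(n_rings = 12L, n_spokes = 20L),
    base = make_biased_base(n_theta = 12L, n_axial = 24L),
    plate = make_notched_plate(90, nx = 41L, ny = 9L),
    cap = make_cap_model(n_theta = 24L, n_phi = 32L))
  closed_chi2 <- c("sphere", "cylinder", "cone", "cube", "bent_tube",
                   "accordion", "yoshimura")
  for (nm in names(shapes)) {
    rep <- validate_mesh(shapes[[nm]]$mesh)
    expect_true(rep$manifold, label = paste(nm, "manifold"))
    expect_true(rep$oriented, label = paste(nm, "oriented"))
    if (nm %in% closed_chi2) {
      expect_true(rep$closed, label = paste(nm, "closed"))
      expect_identical(rep$euler_characteristic, 2L)
      expect_gt(enclosed_volume(shapes[[nm]]$mesh), 0)
    } else {
      expect_false(rep$closed)
    }
    for (msk in shapes[[nm]]$masks) {
      expect_true(all(msk >= 1 & msk <= n_vertices(shapes[[nm]]$mesh)))
    }
  }
  # bit-identical on regeneration
  expect_identical(make_cap_model(n_theta = 24L, n_phi = 32L)$mesh$vertices,
                   shapes$cap$mesh$vertices)
  expect_identical(make_accordion_cylinder(n_theta = 16L, n_axial = 32L)$mesh,
                   shapes$accordion$mesh)
})

test_that("accordion geometry stores the stated meridional arc length", {
  shp <- make_accordion_cylinder(radius = 2.5, folded_height = 1,
                                 n_pleats = 12L, pleat_slant_length = 0.25)
  expect_equal(shp$arc_length, 6)
  expect_equal(axial_extent(shp$mesh), 1, tolerance = 1e-9)
  # measured meridional arc along the phi = 0 vertex column
  mer <- as.integer(shp$masks$meridian)
  pts <- shp$mesh$vertices[mer, ]
  arc <- sum(sqrt(rowSums(diff(pts)^2)))
  expect_equal(arc, 6, tolerance = 1e-9)
  # degenerate single pleat with slant = height/2 is a plain cylinder
  degen <- make_accordion_cylinder(radius = 1, folded_height = 1,
                                   n_pleats = 1L, pleat_slant_length = 0.5,
                                   n_theta = 12L, n_axial = 8L)
  r <- sqrt(rowSums(degen$mesh$vertices[as.integer(degen$masks$wall), 1:2]^2))
  expect_lt(diff(range(r)), 1e-12)
  expect_error(make_accordion_cylinder(n_pleats = 2L, pleat_slant_length = 0.1,
                                       folded_height = 1), "fit")
})

test_that("yoshimura folding shortens the cylinder and keeps slant lengths", {
  shp <- make_yoshimura_cylinder(radius = 1, height = 3, n_axial = 9L,
                                 n_circumferential = 12L, fold_depth = 0.12)
  expect_lt(shp$folded_height, shp$unfolded_height)
  expect_lt(axial_extent(shp$mesh), 3)
  flat <- make_yoshimura_cylinder(fold_depth = 0)
  r <- sqrt(rowSums(flat$mesh$vertices[seq_len(10L * 12L), 1:2]^2))
  expect_lt(diff(range(r)), 1e-12)
  expect_error(make_yoshimura_cylinder(fold_depth = 0.9), "fold_depth")
})

test_that("disk furrow patterns carry their analytic signatures", {
  flat <- make_furrowed_disk(pattern = "full_circle", amplitude = 0)
  expect_lt(diff(range(flat$mesh$vertices[, 3])), 1e-12)
  fc0 <- furrow_field(flat$mesh, smoothing_params(n_iterations = 10L))
  expect_true(all(fc0$classes == "neutral"))

  # radial sign oracle from the generator formula
  dk <- make_furrowed_disk(pattern = "full_circle", n_furrows = 6L)
  fc <- furrow_field(dk$mesh, smoothing_params(n_iterations = 30L))
  vx <- dk$mesh$vertices
  spoke <- which(abs(vx[, 2]) < 1e-9 & vx[, 1] > 1e-9)
  spoke <- spoke[order(vx[spoke, 1])]
  r <- vx[spoke, 1]
  env <- abs(vx[spoke, 3])              # generator displacement magnitude
  strong <- which(env > 0.4 * 0.03)     # well inside the furrow band
  s_true <- sin(2 * pi * 6 * r)
  agree <- sign(fc$field[spoke[strong]]) == sign(s_true[strong])
  expect_gt(mean(agree), 0.95)

  semi <- make_furrowed_disk(pattern = "semicircle")
  fcs <- furrow_field(semi$mesh, smoothing_params(n_iterations = 30L))
  right <- furrow_density(fcs, semi$mesh, semi$masks$half_pos_x)
  left <- furrow_density(fcs, semi$mesh, semi$masks$half_neg_x)
  expect_lt(right, 0.05)
  expect_gt(left, 0.1)
})

test_that("doubling generator resolution changes surface area by under 1%", {
  a1 <- surface_area(make_accordion_cylinder(n_theta = 24L, n_axial = 64L)$mesh)
  a2 <- surface_area(make_accordion_cylinder(n_theta = 48L, n_axial = 128L)$mesh)
  expect_lt(abs(a2 - a1) / a1, 0.01)
  d1 <- surface_area(make_furrowed_disk(n_rings = 28L, n_spokes = 48L)$mesh)
  d2 <- surface_area(make_furrowed_disk(n_rings = 56L, n_spokes = 96L)$mesh)
  expect_lt(abs(d2 - d1) / d1, 0.01)
})

test_that("biased base bends dorsally, symmetric base does not, swap mirrors", {
  shp <- make_biased_base()
  traj <- inflate(shp$mesh, material_params(pinned = shp$masks$base_ring,
                                            max_steps = 30000L))
  bend <- bend_angle(centerline(snapshot_mesh(traj)))
  expect_gt(bend, 0)

  sym <- make_biased_base(n_ventral_furrows = 3L, n_dorsal_furrows = 3L)
  tsym <- inflate(sym$mesh, material_params(pinned = sym$masks$base_ring,
                                            max_steps = 30000L))
  expect_lt(abs(bend_angle(centerline(snapshot_mesh(tsym)))), 3)

  # swapping ventral and dorsal counts = reflecting the fixture in Y
  mir <- shp$mesh
  mir$vertices[, 2] <- -mir$vertices[, 2]
  mir$faces <- mir$faces[, c(1, 3, 2)]
  tmir <- inflate(mir, material_params(pinned = shp$masks$base_ring,
                                       max_steps = 30000L))
  bend_m <- bend_angle(centerline(snapshot_mesh(tmir)))
  expect_lt(abs(bend_m + bend) / abs(bend), 0.1)
  expect_error(make_biased_base(n_ventral_furrows = 1L, n_dorsal_furrows = 3L),
               ">=")
})

test_that("cap subregion masks cover distinct territory with a boundary ring", {
  shp <- make_cap_model(n_theta = 24L, n_phi = 32L)
  msk <- shp$masks
  expect_length(intersect(as.integer(msk$medial_tips),
                          as.integer(msk$lateral_tips)), 0L)
  expect_length(intersect(as.integer(msk$bottom_surface),
                          as.integer(msk$medial_tips)), 0L)
  expect_identical(as.integer(msk$base_ring),
                   boundary_vertices(shp$mesh))
  expect_gt(length(msk$medial_tips), 10L)
  expect_gt(length(msk$lateral_tips), 10L)
})
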