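test_that("axial extents of primitives are exact", {
  expect_equal(axial_extent(make_primitive("cube")$mesh), 1)
  cyl <- make_primitive("cylinder", radius = 1, height = 4)$mesh
  expect_equal(axial_extent(cyl), 4)
  expect_equal(axial_extent(cyl, axis = c(1, 0, 0)), 2, tolerance = 1e-9)
})

test_that("centerlines of straight and conical tubes lie on the axis", {
  cyl <- make_primitive("cylinder", radius = 1, height = 4)$mesh
  cl <- centerline(cyl, n_slices = 10L)
  expect_lt(max(abs(cl[, 1:2])), 1e-6)
  expect_equal(bend_angle(cl), 0, tolerance = 1e-6)
  cone <- make_primitive("cone", radius = 1, height = 3)$mesh
  clc <- centerline(cone, n_slices = 8L)
  expect_lt(max(abs(clc[, 1:2])), 1e-6)
})

test_that("quarter-torus slice centroids trace the generator circle", {
  tor <- make_primitive("torus_segment", radius = 0.4, major_radius = 2,
                        n_theta = 28L, capped = FALSE)$mesh
  cl <- centerline(tor, axis = c(0, 1, 1) / sqrt(2), n_slices = 12L)
  cl <- cl[3:(nrow(cl) - 2), ]   # end slabs are truncated by the open rims
  # least-squares circle in the Y-Z plane (the radius itself is poorly
  # conditioned on a short arc; the deviation from the fit is the check)
  A <- cbind(2 * cl[, 2], 2 * cl[, 3], 1)
  b <- cl[, 2]^2 + cl[, 3]^2
  sol <- qr.solve(A, b)
  R <- sqrt(sol[3] + sol[1]^2 + sol[2]^2)
  dev <- abs(sqrt((cl[, 2] - sol[1])^2 + (cl[, 3] - sol[2])^2) - R)
  expect_lt(max(dev), 0.02 * 2)
})

test_that("bend angle of a bent tube is +90 degrees, mirrored to -90", {
  bt <- make_primitive("bent_tube", radius = 0.4, major_radius = 2,
                       arm_length = 2, n_theta = 20L)$mesh
  ax <- c(0, 1, 1) / sqrt(2)
  cl <- centerline(bt, axis = ax, n_slices = 16L)
  cl <- cl[2:(nrow(cl) - 1), ]   # trim cap-contaminated end slabs
  expect_equal(bend_angle(cl), 90, tolerance = 5)
  mirrored <- bt
  mirrored$vertices[, 2] <- -mirrored$vertices[, 2]
  clm <- centerline(mirrored, axis = c(0, -1, 1) / sqrt(2), n_slices = 16L)
  clm <- clm[2:(nrow(clm) - 1), ]
  expect_equal(bend_angle(clm), -bend_angle(cl), tolerance = 1e-9)
})

test_that("branch counting matches an independent component oracle", {
  cyl <- make_primitive("cylinder")$mesh
  expect_identical(count_branches(cyl), 1L)
  # two disjoint cones on a plate
  cone <- make_primitive("cone", radius = 0.4, height = 2,
                         n_theta = 12L, n_axial = 10L)$mesh
  c1 <- cone; c1$vertices[, 1] <- c1$vertices[, 1] - 1
  c2 <- cone; c2$vertices[, 1] <- c2$vertices[, 1] + 1
  two <- triangle_mesh(rbind(c1$vertices, c2$vertices),
                       rbind(c1$faces, c2$faces + n_vertices(c1)))
  expect_identical(count_branches(two), 2L)
  skip_if_not_installed("igraph")
  pr <- two$vertices[, 3]
  thr <- min(pr) + 0.6 * diff(range(pr))
  keep <- which(pr > thr)
  g <- igraph::graph_from_edgelist(mesh_edges(two), directed = FALSE)
  sub <- igraph::induced_subgraph(g, keep)
  comp <- igraph::components(sub)
  expect_identical(count_branches(two),
                   sum(comp$csize >= 5L))
})

test_that("branch count is monotone in height fraction for cone-like shapes", {
  cone <- make_primitive("cone", radius = 1, height = 3)$mesh
  fr <- c(0.2, 0.4, 0.6, 0.8)
  counts <- vapply(fr, function(f) count_branches(cone, height_fraction = f),
                   integer(1))
  expect_true(all(diff(counts) >= 0 | counts[-1] == 0L))
  expect_true(all(counts == 1L))
})

test_that("groove angles recover machined notch angles within 3 degrees", {
  for (a in c(90, 120)) {
    np <- make_notched_plate(a)
    expect_equal(groove_angle(np$mesh), a, tolerance = 3)
  }
  # a smooth convex tube has no concave section vertex
  cyl <- make_primitive("cylinder")$mesh
  expect_true(is.na(groove_angle(cyl, slice_axis = c(0, 0, 1),
                                 slice_position = 2)))
  flat <- make_notched_plate(NULL)
  expect_true(is.na(groove_angle(flat$mesh)))
})

test_that("apex offset measures lateral tip displacement over the rim radius", {
  # oblique cone built directly: ring radius 1, apex offset 0.5 laterally
  th <- 2 * pi * (0:23) / 24
  verts <- rbind(cbind(cos(th), sin(th), 0), c(0.5, 0, 1))
  f <- cbind(25L, 1L + (0:23), 1L + (1:24) %% 24)
  cone <- triangle_mesh(verts, f[, c(1, 3, 2)])
  expect_equal(apex_offset(cone), 0.5, tolerance = 1e-9)
  upright <- cone
  upright$vertices[25, 1] <- 0
  expect_equal(apex_offset(upright), 0, tolerance = 1e-9)
  expect_error(apex_offset(make_primitive("cube")$mesh), "open mesh")
})

test_that("angle-deficit curvature satisfies Gauss-Bonnet exactly", {
  fixtures <- list(
    make_primitive("sphere", subdivisions = 2L)$mesh,
    make_primitive("cube")$mesh,
    make_accordion_cylinder(n_theta = 12L, n_axial = 24L)$mesh,
    make_yoshimura_cylinder()$mesh,
    corrugated_sphere(subdivisions = 2L))
  for (m in fixtures) {
    k <- discrete_gaussian_curvature(m)
    expect_lt(abs(sum(k$deficit) - 2 * pi * 2), 1e-9)
  }
})

test_that("a regular cylinder wall is exactly developable (zero curvature)", {
  cyl <- make_primitive("cylinder", radius = 1, height = 4,
                        n_theta = 24L, n_axial = 24L)$mesh
  k <- discrete_gaussian_curvature(cyl)
  wall <- which(abs(cyl$vertices[, 3]) > 1e-9 &
                  abs(cyl$vertices[, 3] - 4) > 1e-9 &
                  seq_len(n_vertices(cyl)) <= 24L * 25L)
  expect_lt(max(abs(k$deficit[wall])), 1e-12)
})

test_that("icosphere curvature approaches 1/r^2 under refinement", {
  ico <- make_primitive("sphere", subdivisions = 3L)$mesh
  k <- discrete_gaussian_curvature(ico)
  expect_equal(mean(k$curvature), 1, tolerance = 0.02)
})

test_that("extents are rigid-motion invariant and bend angle flips under Y-mirror", {
  shp <- make_biased_base(n_theta = 12L, n_axial = 20L)
  m <- shp$mesh
  a <- 0.7
  rot <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, byrow = TRUE)
  moved <- m
  moved$vertices <- m$vertices %*% t(rot) + matrix(c(5, -3, 2), n_vertices(m), 3,
                                                   byrow = TRUE)
  expect_equal(surface_area(moved), surface_area(m), tolerance = 1e-9)
  expect_equal(axial_extent(moved), axial_extent(m), tolerance = 1e-9)
})

test_that("measure_mesh assembles the morphometry report", {
  shp <- make_biased_base(n_theta = 12L, n_axial = 20L)
  rep <- measure_mesh(shp$mesh)
  expect_s3_class(rep, "morphometry_report")
  expect_equal(rep$axial_extent, axial_extent(shp$mesh))
  expect_identical(rep$branch_count, 1L)
  expect_false(is.na(rep$volume))
})
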