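test_that("a smooth sphere classifies as entirely neutral", {
  ico <- make_primitive("sphere", subdivisions = 3L)$mesh
  fc <- furrow_field(ico, smoothing_params(n_iterations = 10L))
  # depth stays below the mesh-resolution floor (2% of mean edge length)
  e <- mesh_edges(ico)
  el <- mean(sqrt(rowSums((ico$vertices[e[, 1], ] -
                             ico$vertices[e[, 2], ])^2)))
  expect_lt(max(abs(fc$field)), 0.02 * el)
  expect_true(all(fc$classes == "neutral"))
})

test_that("signed depth matches the analytic corrugation phase", {
  lam <- 0.2
  cp <- grid_plate(81, 21, 2, 1, function(x, y) 0.05 * sin(2 * pi * x / lam))
  fc <- furrow_field(cp, smoothing_params(n_iterations = 50L))
  inter <- setdiff(seq_len(n_vertices(cp)), boundary_vertices(cp))
  s_true <- sin(2 * pi * cp$vertices[, 1] / lam)
  sel <- inter[abs(s_true[inter]) > 0.5]
  expect_true(all(sign(fc$field[sel]) == sign(s_true[sel])))
})

test_that("furrow field is equivariant under rigid motions", {
  shp <- make_furrowed_disk(n_rings = 12L, n_spokes = 20L)
  sp <- smoothing_params(n_iterations = 15L)
  d0 <- furrow_field(shp$mesh, sp)$field
  a <- 0.9
  rot <- matrix(c(1, 0, 0,
                  0, cos(a), -sin(a),
                  0, sin(a), cos(a)), 3, byrow = TRUE)
  moved <- shp$mesh
  moved$vertices <- shp$mesh$vertices %*% t(rot) +
    matrix(c(-2, 7, 1), n_vertices(shp$mesh), 3, byrow = TRUE)
  d1 <- furrow_field(moved, sp)$field
  expect_lt(max(abs(d0 - d1)), 1e-9)
})

test_that("meridional ridge/valley alternation counts the pleats", {
  shp <- make_accordion_cylinder()
  fc <- furrow_field(shp$mesh, smoothing_params(n_iterations = 50L))
  mer <- as.integer(shp$masks$meridian)
  d <- fc$field[mer]
  d <- d[abs(d) > 0.02 * max(abs(d))]
  sign_changes <- sum(diff(sign(d)) != 0)
  expect_identical(sign_changes, 2L * 12L)
})

test_that("re-smoothing an already-smoothed mesh leaves far shallower furrows", {
  shp <- make_biased_base()
  sp <- smoothing_params(n_iterations = 50L)
  d1 <- max(abs(furrow_field(shp$mesh, sp)$field))
  d2 <- max(abs(furrow_field(hc_laplacian_smooth(shp$mesh, sp), sp)$field))
  expect_gt(d1 / d2, 5)
})

test_that("valley density is ventrally biased where furrows are ventrally biased", {
  shp <- make_biased_base()
  fc <- furrow_field(shp$mesh, smoothing_params(n_iterations = 50L))
  dv <- furrow_density(fc, shp$mesh, shp$masks$ventral)
  dd <- furrow_density(fc, shp$mesh, shp$masks$dorsal)
  expect_gt(dv, dd)
  # uniform accordion: ventral and dorsal valley fractions agree by symmetry
  acc <- make_accordion_cylinder()
  fca <- furrow_field(acc$mesh, smoothing_params(n_iterations = 50L))
  av <- furrow_density(fca, acc$mesh, acc$masks$ventral)
  ad <- furrow_density(fca, acc$mesh, acc$masks$dorsal)
  expect_lt(abs(av - ad) / av, 0.05)
  expect_error(furrow_density(fca, acc$mesh, region_mask("e", integer(0))),
               "empty")
  # a smooth sphere has no valleys anywhere
  ico <- make_primitive("sphere", subdivisions = 3L)
  fs <- furrow_field(ico$mesh, smoothing_params(n_iterations = 10L))
  expect_equal(furrow_density(fs, ico$mesh, ico$masks$ventral), 0)
})

test_that("masked furrow removal is nearly idempotent on the folded mesh", {
  shp <- make_biased_base()
  reg <- shp$masks$base
  sp <- smoothing_params(mask = reg, n_iterations = 50L)
  s1 <- hc_laplacian_smooth(shp$mesh, sp)
  s2 <- hc_laplacian_smooth(s1, sp)
  depth_in <- function(m) {
    max(abs(furrow_field(m, smoothing_params(n_iterations = 30L))$field[
      as.integer(reg)]))
  }
  c0 <- depth_in(shp$mesh); c1 <- depth_in(s1); c2 <- depth_in(s2)
  expect_lt(abs(c1 - c2), 0.2 * abs(c0 - c1))
})

test_that("removal with an empty region changes nothing, and reports are reproducible", {
  shp <- small_accordion()
  mp <- material_params(max_steps = 800L)
  rep0 <- remove_furrows(shp$mesh, region_mask("none", integer(0)),
                         smoothing_params(n_iterations = 10L), mp)
  for (nm in names(rep0$deltas)) {
    if (!is.na(rep0$deltas[[nm]])) expect_true(rep0$deltas[[nm]] == 0)
  }
  rep1 <- remove_furrows(shp$mesh, shp$masks$ventral,
                         smoothing_params(n_iterations = 10L), mp)
  rep2 <- remove_furrows(shp$mesh, shp$masks$ventral,
                         smoothing_params(n_iterations = 10L), mp)
  expect_identical(rep1$morphometry_smoothed, rep2$morphometry_smoothed)
  expect_identical(rep1$deltas, rep2$deltas)
})

test_that("removing the base furrows reduces the dorsal bend of the unfolded horn", {
  shp <- make_biased_base()
  rep <- remove_furrows(shp$mesh, shp$masks$base,
                        smoothing_params(n_iterations = 50L),
                        material_params(pinned = shp$masks$base_ring,
                                        max_steps = 30000L))
  b0 <- rep$morphometry_original$bend_angle
  b1 <- rep$morphometry_smoothed$bend_angle
  expect_gt(b0, 0)          # original bends dorsally
  expect_lt(abs(b1), abs(b0))   # furrow removal reduces the turn
})

test_that("removing the disk furrow patch lowers the inflated apex", {
  shp <- make_furrowed_disk(pattern = "semicircle")
  mp <- material_params(pinned = shp$masks$boundary, max_steps = 30000L)
  rep <- remove_furrows(shp$mesh, shp$masks$furrows,
                        smoothing_params(n_iterations = 50L), mp)
  h0 <- max(snapshot_mesh(rep$trajectory_original)$vertices[, 3])
  h1 <- max(snapshot_mesh(rep$trajectory_smoothed)$vertices[, 3])
  expect_lt(h1, h0)
  # outside region + feather the two folded meshes are identical
  w <- build_weights(shp$mesh, shp$masks$furrows, 2L)
  untouched <- which(w == 0)
  expect_identical(rep$smoothed_folded$vertices[untouched, ],
                   shp$mesh$vertices[untouched, ])
})
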