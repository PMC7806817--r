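test_that("zero weights give the exact identity", {
  shp <- small_accordion()
  w0 <- rep(0, n_vertices(shp$mesh))
  expect_identical(laplacian_step(shp$mesh, w0), shp$mesh$vertices)
})

test_that("a flat plate is a fixed point of the smoother", {
  p <- grid_plate(15, 9)
  sm <- hc_laplacian_smooth(p, smoothing_params(alpha = 0.3, beta = 0.7,
                                                n_iterations = 30L))
  expect_lt(max(abs(sm$vertices - p$vertices)), 1e-9)
  # interior vertices of a regular grid sit at their neighbour centroid:
  # one plain step moves them by strictly nothing
  w <- rep(1, n_vertices(p))
  stepped <- laplacian_step(p, w)
  inter <- setdiff(seq_len(n_vertices(p)), boundary_vertices(p))
  expect_lt(max(abs(stepped[inter, ] - p$vertices[inter, ])), 1e-12)
})

test_that("a single perturbed vertex returns to its neighbour centroid", {
  p <- grid_plate(9, 9)
  inter <- setdiff(seq_len(n_vertices(p)), boundary_vertices(p))
  i <- inter[10]
  p$vertices[i, 3] <- 0.37
  w <- numeric(n_vertices(p)); w[i] <- 1
  stepped <- laplacian_step(p, w)
  nb <- vertex_adjacency(p)[[i]]
  expect_equal(stepped[i, ], colMeans(p$vertices[nb, ]), tolerance = 1e-12)
  expect_identical(stepped[-i, ], p$vertices[-i, ])
})

test_that("corrugation amplitude decreases monotonically with iterations", {
  lam <- 0.2
  cp <- grid_plate(81, 21, 2, 1, function(x, y) 0.05 * sin(2 * pi * x / lam))
  inter <- setdiff(seq_len(n_vertices(cp)), boundary_vertices(cp))
  amps <- vapply(c(1L, 5L, 25L, 100L), function(k) {
    s <- hc_laplacian_smooth(cp, smoothing_params(n_iterations = k))
    diff(range(s$vertices[inter, 3]))
  }, numeric(1))
  expect_true(all(diff(amps) < 0))
})

test_that("HC correction shrinks volume far less than plain Laplacian", {
  corr <- corrugated_sphere()
  v0 <- enclosed_volume(corr)
  hc <- hc_laplacian_smooth(corr, smoothing_params(alpha = 0, beta = 0.5,
                                                   n_iterations = 50L))
  plain <- corr
  w <- rep(1, n_vertices(corr))
  for (k in 1:50) plain$vertices <- laplacian_step(plain, w)
  loss_hc <- abs(enclosed_volume(hc) - v0) / v0
  loss_plain <- abs(enclosed_volume(plain) - v0) / v0
  expect_lt(loss_hc, loss_plain)
  expect_lt(loss_hc, 0.1)
})

test_that("region-masked smoothing is bit-exact outside the mask (feather 0)", {
  shp <- make_biased_base(n_theta = 12L, n_axial = 24L)
  mask <- shp$masks$ventral
  sp <- smoothing_params(mask = mask, feather_width = 0L, n_iterations = 25L)
  sm <- hc_laplacian_smooth(shp$mesh, sp)
  outside <- setdiff(seq_len(n_vertices(shp$mesh)), as.integer(mask))
  expect_identical(sm$vertices[outside, ], shp$mesh$vertices[outside, ])
  expect_false(identical(sm$vertices[as.integer(mask), ],
                         shp$mesh$vertices[as.integer(mask), ]))
})

test_that("feathered weights ramp linearly over breadth-first rings", {
  cyl <- make_primitive("cylinder", radius = 1, height = 2,
                        n_theta = 10L, n_axial = 19L)$mesh
  mask <- region_mask("half", which(cyl$vertices[, 3] <= 1 + 1e-9),
                      n_vertices(cyl))
  w <- build_weights(cyl, mask, feather_width = 2L)
  expect_true(all(w[as.integer(mask)] == 1))
  # independent oracle: igraph shortest-path distances from the mask
  skip_if_not_installed("igraph")
  g <- igraph::graph_from_edgelist(mesh_edges(cyl), directed = FALSE)
  d <- igraph::distances(g, v = igraph::V(g), to = as.integer(mask))
  ring <- apply(d, 1, min)
  expected <- pmax(0, 1 - ring / 3)
  expect_equal(w, unname(expected), tolerance = 1e-12)
  expect_true(all(abs(w[ring == 1] - 2 / 3) < 1e-12))
  expect_true(all(abs(w[ring == 2] - 1 / 3) < 1e-12))
  expect_true(all(w[ring >= 3] == 0))
})

test_that("degenerate masks are handled explicitly", {
  tet <- tetra_mesh()
  expect_warning(w <- build_weights(tet, region_mask("empty", integer(0))),
                 "empty")
  expect_identical(w, rep(0, 4))
  expect_identical(build_weights(tet, NULL), rep(1, 4))
})

test_that("smoothing is deterministic and never touches connectivity", {
  shp <- small_accordion()
  sp <- smoothing_params(n_iterations = 20L)
  a <- hc_laplacian_smooth(shp$mesh, sp)
  b <- hc_laplacian_smooth(shp$mesh, sp)
  expect_identical(a$vertices, b$vertices)
  expect_identical(a$faces, shp$mesh$faces)
  expect_identical(n_vertices(a), n_vertices(shp$mesh))
})
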