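# Fixtures are built in code; no binary data anywhere.

tetra_mesh <- function() {
  triangle_mesh(
    rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
    rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3)),
    name = "tetrahedron")
}
TETRA_VOLUME <- 1 / 6
TETRA_AREA <- 1.5 + sqrt(3) / 2

# rectangular plate over [-lx/2, lx/2] x [0, ly], z = zfun(x, y)
grid_plate <- function(nx, ny, lx = 2, ly = 1, zfun = function(x, y) 0 * x) {
  xs <- seq(-lx / 2, lx / 2, length.out = nx)
  ys <- seq(0, ly, length.out = ny)
  g <- expand.grid(x = xs, y = ys)
  verts <- cbind(g$x, g$y, zfun(g$x, g$y))
  vid <- function(i, j) (j - 1L) * nx + i
  i <- rep(seq_len(nx - 1L), ny - 1L)
  j <- rep(seq_len(ny - 1L), each = nx - 1L)
  f <- rbind(cbind(vid(i, j), vid(i + 1L, j), vid(i, j + 1L)),
             cbind(vid(i + 1L, j), vid(i + 1L, j + 1L), vid(i, j + 1L)))
  triangle_mesh(verts, f, name = "plate")
}

# icosphere with a radial sinusoidal corrugation (latitude waves)
corrugated_sphere <- function(amplitude = 0.08, waves = 6, subdivisions = 3L) {
  m <- make_primitive("sphere", subdivisions = subdivisions)$mesh
  r <- sqrt(rowSums(m$vertices^2))
  colat <- acos(pmin(1, pmax(-1, m$vertices[, 3] / r)))
  m$vertices <- m$vertices * (1 + amplitude * sin(waves * colat))
  m$name <- "corrugated_sphere"
  m
}

# small, fast inflation fixtures for invariant tests
small_accordion <- function() {
  make_accordion_cylinder(n_pleats = 6L, pleat_slant_length = 0.25,
                          folded_height = 0.5, radius = 2,
                          n_theta = 16L, n_axial = 24L)
}
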