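# Seeded parametric generators of folded test surfaces. The real beetle
# primordium meshes are not publicly deposited, so every pipeline stage is
# exercised on synthetic folded meshes emulating the primordium's salient
# structures: accordion-pleated cylinders (stalk), ventrally biased
# circumferential furrows (base), concentric full/semicircle and parallel
# furrow patches on disks and domes (cap), and Yoshimura zigzag pleating.
# All furrows are sinusoidal displacements along local normals, which makes
# the ridge/valley sign oracles analytic. Generators are deterministic
# given their arguments (and seed, where jitter is requested).

smoothstep01 <- function(t) {
  t <- pmin(1, pmax(0, t))
  t * t * (3 - 2 * t)
}

# flip face windings if a closed mesh encloses negative volume
ensure_outward <- function(mesh) {
  rep <- validate_mesh(mesh)
  if (rep$closed && enclosed_volume(mesh) < 0)
    mesh$faces <- mesh$faces[, c(1L, 3L, 2L)]
  mesh
}

# Triangulated surface of revolution. `radii`, `heights`: profile nodes
# bottom to top; rings of n_theta vertices each; optional fan caps.
revolve_profile <- function(radii, heights, n_theta, cap_bottom = TRUE,
                            cap_top = TRUE, phase = NULL, name = "revolved") {
  nr <- length(radii)
  stopifnot(nr == length(heights), nr >= 2L, n_theta >= 3L)
  if (is.null(phase)) phase <- rep(0, nr)
  th <- 2 * pi * (seq_len(n_theta) - 1L) / n_theta
  verts <- do.call(rbind, lapply(seq_len(nr), function(i)
    cbind(radii[i] * cos(th + phase[i]), radii[i] * sin(th + phase[i]),
          heights[i])))
  vid <- function(i, j) (i - 1L) * n_theta + ((j - 1L) %% n_theta) + 1L
  faces <- vector("list", nr)
  for (i in seq_len(nr - 1L)) {
    j <- seq_len(n_theta)
    if (i %% 2L == 1L || all(phase == 0)) {
      faces[[i]] <- rbind(cbind(vid(i, j), vid(i, j + 1L), vid(i + 1L, j)),
                          cbind(vid(i, j + 1L), vid(i + 1L, j + 1L), vid(i + 1L, j)))
    } else {
      faces[[i]] <- rbind(cbind(vid(i, j), vid(i, j + 1L), vid(i + 1L, j + 1L)),
                          cbind(vid(i, j), vid(i + 1L, j + 1L), vid(i + 1L, j)))
    }
  }
  f <- do.call(rbind, faces)
  if (cap_bottom) {
    apex_b <- nrow(verts) + 1L
    verts <- rbind(verts, c(0, 0, heights[1]))
    j <- seq_len(n_theta)
    f <- rbind(f, cbind(apex_b, vid(1L, j + 1L), vid(1L, j)))
  }
  if (cap_top) {
    apex_t <- nrow(verts) + 1L
    verts <- rbind(verts, c(0, 0, heights[nr]))
    j <- seq_len(n_theta)
    f <- rbind(f, cbind(apex_t, vid(nr, j), vid(nr, j + 1L)))
  }
  ensure_outward(triangle_mesh(verts, f, name = name))
}

# centerline samples of a straight-arc-straight path in the Y-Z plane:
# proximal arm along +Z from z = -arm, quarter-ish arc of the given radius,
# distal arm along the end tangent. Returns list(points, tangents, normals).
path_arc <- function(major_radius, arc, arm_length, n_per_unit = 8L) {
  pts <- list(); tg <- list()
  if (arm_length > 0) {
    t <- seq(-arm_length, 0, length.out = max(2L, ceiling(arm_length * n_per_unit)))
    t <- t[-length(t)]
    for (z in t) { pts[[length(pts) + 1L]] <- c(0, 0, z)
                   tg[[length(tg) + 1L]] <- c(0, 0, 1) }
  }
  u <- seq(0, arc, length.out = max(3L, ceiling(arc * major_radius * n_per_unit)))
  for (ui in u) {
    pts[[length(pts) + 1L]] <- c(0, major_radius * (1 - cos(ui)),
                                 major_radius * sin(ui))
    tg[[length(tg) + 1L]] <- c(0, sin(ui), cos(ui))
  }
  if (arm_length > 0) {
    pe <- pts[[length(pts)]]; te <- tg[[length(tg)]]
    t <- seq(0, arm_length, length.out = max(2L, ceiling(arm_length * n_per_unit)))
    for (s in t[-1]) { pts[[length(pts) + 1L]] <- pe + s * te
                       tg[[length(tg) + 1L]] <- te }
  }
  list(points = do.call(rbind, pts), tangents = do.call(rbind, tg))
}

# triangulated tube of the given radius around a polyline path in the Y-Z
# plane (frame: x-axis plus the in-plane normal of the tangent)
tube_along_path <- function(path, radius, n_theta, capped, name) {
  th <- 2 * pi * (seq_len(n_theta) - 1L) / n_theta
  np <- nrow(path$points)
  verts <- do.call(rbind, lapply(seq_len(np), function(i) {
    tgt <- path$tangents[i, ]
    nrm <- c(0, tgt[3], -tgt[2])   # in-plane normal
    ctr <- path$points[i, ]
    do.call(rbind, lapply(th, function(t)
      ctr + radius * (cos(t) * c(1, 0, 0) + sin(t) * nrm)))
  }))
  vid <- function(i, j) (i - 1L) * n_theta + ((j - 1L) %% n_theta) + 1L
  f <- do.call(rbind, lapply(seq_len(np - 1L), function(i) {
    j <- seq_len(n_theta)
    rbind(cbind(vid(i, j), vid(i, j + 1L), vid(i + 1L, j)),
          cbind(vid(i, j + 1L), vid(i + 1L, j + 1L), vid(i + 1L, j)))
  }))
  if (capped) {
    apex1 <- nrow(verts) + 1L
    apex2 <- nrow(verts) + 2L
    verts <- rbind(verts,
                   path$points[1, ] - 0.5 * radius * path$tangents[1, ],
                   path$points[np, ] + 0.5 * radius * path$tangents[np, ])
    j <- seq_len(n_theta)
    f <- rbind(f, cbind(apex1, vid(1L, j + 1L), vid(1L, j)),
               cbind(apex2, vid(np, j), vid(np, j + 1L)))
  }
  ensure_outward(triangle_mesh(verts, f, name = name))
}

halves_masks <- function(mesh, tol = 1e-9) {
  y <- mesh$vertices[, 2]
  list(ventral = region_mask("ventral", which(y < -tol), n_vertices(mesh)),
       dorsal = region_mask("dorsal", which(y > tol), n_vertices(mesh)))
}

icosphere <- function(radius = 1, subdivisions = 3L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    midcache <- new.env(hash = TRUE)
    mid <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      hit <- midcache[[key]]
      if (!is.null(hit)) return(hit)
      p <- (v[a, ] + v[b, ]) / 2
      p <- p / sqrt(sum(p^2))
      v <<- rbind(v, p)
      id <- nrow(v)
      midcache[[key]] <- id
      id
    }
    newf <- matrix(0L, 0L, 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c <- f[i, 3]
      ab <- mid(a, b); bc <- mid(b, c); ca <- mid(c, a)
      newf <- rbind(newf, c(a, ab, ca), c(b, bc, ab), c(c, ca, bc),
                    c(ab, bc, ca))
    }
    f <- newf
  }
  ensure_outward(triangle_mesh(v * radius, f, name = "icosphere"))
}

#' Primitive analytic meshes
#'
#' Oracle fixtures for the morphometrics and smoothing operations: closed
#' icosphere, capped cylinder, cube, capped cone, a quarter-torus tube (a
#' tube around a circular arc from +Z toward +Y), and a bent tube
#' (straight run, arc, straight run — the generator-known bend-angle
#' fixture). Each primitive ships with standard region masks
#' (ventral/dorsal halves).
#'
#' @param kind one of `"sphere"`, `"cylinder"`, `"cube"`, `"cone"`,
#'   `"torus_segment"`.
#' @param radius sphere/cylinder/cone radius, or torus tube radius.
#' @param height cylinder/cone height.
#' @param major_radius torus centerline radius.
#' @param arc torus arc angle in radians (default `pi/2`: quarter torus).
#' @param arm_length straight run added before and after the arc
#'   (`bent_tube` only), giving clean proximal/distal directions for
#'   bend-angle measurements.
#' @param capped close tube ends with apex fans (`torus_segment`,
#'   `bent_tube`).
#' @param subdivisions icosphere subdivision level.
#' @param n_theta angular resolution; `n_axial` axial resolution.
#' @param jitter relative vertex position noise (uniform, `jitter *` mean
#'   edge length); `seed` makes it reproducible.
#' @param seed integer seed for `jitter`.
#' @return list with `mesh` (a [triangle_mesh()]) and `masks` (named list
#'   of [region_mask()]).
#' @export
#' @examples
#' cyl <- make_primitive("cylinder", radius = 1, height = 4)
#' axial_extent(cyl$mesh)
make_primitive <- function(kind = c("sphere", "cylinder", "cube", "cone",
                                    "torus_segment", "bent_tube"),
                           radius = 1, height = 4, major_radius = 2,
                           arc = pi / 2, arm_length = 1, capped = TRUE,
                           subdivisions = 3L,
                           n_theta = 24L, n_axial = 24L,
                           jitter = 0, seed = 1L) {
  kind <- match.arg(kind)
  mesh <- switch(kind,
    sphere = icosphere(radius, subdivisions),
    cylinder = revolve_profile(rep(radius, n_axial + 1L),
                               seq(0, height, length.out = n_axial + 1L),
                               n_theta, name = "cylinder"),
    cone = revolve_profile(seq(radius, radius * 1e-3, length.out = n_axial + 1L),
                           seq(0, height, length.out = n_axial + 1L),
                           n_theta, name = "cone"),
    cube = {
      v <- as.matrix(expand.grid(c(0, 1), c(0, 1), c(0, 1)))
      dimnames(v) <- NULL
      f <- rbind(
        c(1, 3, 2), c(2, 3, 4),   # z = 0
        c(5, 6, 7), c(6, 8, 7),   # z = 1
        c(1, 2, 5), c(2, 6, 5),   # y = 0
        c(3, 7, 4), c(4, 7, 8),   # y = 1
        c(1, 5, 3), c(3, 5, 7),   # x = 0
        c(2, 4, 6), c(4, 8, 6))   # x = 1
      ensure_outward(triangle_mesh(v, f, name = "cube"))
    },
    torus_segment = tube_along_path(
      path_arc(major_radius, arc, 0), radius, n_theta, capped, "torus_segment"),
    bent_tube = tube_along_path(
      path_arc(major_radius, arc, arm_length), radius, n_theta, capped,
      "bent_tube"))
  if (jitter > 0) {
    set.seed(seed)
    e <- mesh_edges(mesh)
    d <- mesh$vertices[e[, 1], ] - mesh$vertices[e[, 2], ]
    scale <- jitter * mean(sqrt(rowSums(d * d)))
    mesh$vertices <- mesh$vertices +
      matrix(stats::runif(3 * n_vertices(mesh), -scale, scale), ncol = 3)
  }
  list(mesh = mesh, masks = halves_masks(mesh))
}

#' Accordion-pleated capped cylinder (the stalk fixture)
#'
#' Cylinder whose meridional profile is a triangle wave of
#' `2 n_pleats` linear segments, each of slant length
#' `pleat_slant_length`, compressed into an axial span of `folded_height`:
#' straight circumferential pleats storing a meridional arc length of
#' `2 n_pleats * pleat_slant_length`. Inflating it recovers the stored
#' length as proximodistal elongation (arc length 6 with folded height 1
#' gives the six-fold elongation of the stalk). Rest lengths for inflation
#' are the mesh's own edge lengths.
#'
#' @param radius mean pleat radius. The pleat amplitude
#'   `sqrt(slant^2 - (h/2n)^2)/2` must stay well below the radius or
#'   unfolding would demand large hoop strain; the default radius 2.5 keeps
#'   the required strain near 5%.
#' @param folded_height axial span of the folded pleats.
#' @param n_pleats number of pleats.
#' @param pleat_slant_length slant length of each of the `2 n_pleats`
#'   segments; `2 n_pleats * slant >= folded_height` must hold.
#' @param n_theta angular vertex count.
#' @param n_axial requested axial ring count (rounded to a multiple of the
#'   segment count).
#' @return list with `mesh`, `masks` (`ventral`, `dorsal`, `meridian`: the
#'   phi = 0 vertex column, proximal to distal) and `arc_length` (the
#'   meridional arc length).
#' @export
make_accordion_cylinder <- function(radius = 2.5, folded_height = 1,
                                    n_pleats = 12L, pleat_slant_length = 0.25,
                                    n_theta = 24L, n_axial = 64L) {
  nseg <- 2L * n_pleats
  dz <- folded_height / nseg
  if (pleat_slant_length < dz - 1e-12)
    stop("pleats do not fit: need 2 * n_pleats * slant >= folded_height")
  amp <- sqrt(max(pleat_slant_length^2 - dz^2, 0)) / 2
  m <- max(1L, round(n_axial / nseg))
  node_r <- radius + amp * (-1)^(0:nseg)
  node_z <- dz * (0:nseg)
  radii <- numeric(0); heights <- numeric(0)
  for (k in seq_len(nseg)) {
    t <- seq(0, 1, length.out = m + 1L)[-(m + 1L)]
    radii <- c(radii, node_r[k] + t * (node_r[k + 1] - node_r[k]))
    heights <- c(heights, node_z[k] + t * (node_z[k + 1] - node_z[k]))
  }
  radii <- c(radii, node_r[nseg + 1L])
  heights <- c(heights, node_z[nseg + 1L])
  mesh <- revolve_profile(radii, heights, n_theta, name = "accordion_cylinder")
  masks <- halves_masks(mesh)
  nr <- length(radii)
  masks$meridian <- region_mask("meridian", ((seq_len(nr) - 1L) * n_theta) + 1L,
                                n_vertices(mesh))
  # the pleated wall proper: everything except the two cap apex vertices.
  # Stalk elongation is measured on the wall; the flat cap fans are just
  # closures and bulge freely under pressure.
  masks$wall <- region_mask("wall", seq_len(nr * n_theta), n_vertices(mesh))
  list(mesh = mesh, masks = masks,
       arc_length = nseg * pleat_slant_length)
}

# Polar disk grid with a central fan hole: rings span [inner_frac, 1] of
# the radius and the innermost ring fans to a single center vertex. This
# keeps edge lengths near-uniform (dense sub-rings near the center would
# otherwise throttle the descent step of the inflation solver).
polar_disk_grid <- function(outer_radius, n_rings, n_spokes,
                            inner_frac = 0.22) {
  th <- 2 * pi * (seq_len(n_spokes) - 1L) / n_spokes
  rr <- outer_radius * seq(inner_frac, 1, length.out = n_rings)
  verts <- rbind(c(0, 0, 0),
                 do.call(rbind, lapply(rr, function(r)
                   cbind(r * cos(th), r * sin(th), 0))))
  vid <- function(i, j) 1L + (i - 1L) * n_spokes + ((j - 1L) %% n_spokes) + 1L
  j <- seq_len(n_spokes)
  f <- cbind(1L, vid(1L, j), vid(1L, j + 1L))
  for (i in seq_len(n_rings - 1L)) {
    f <- rbind(f,
               cbind(vid(i, j), vid(i + 1L, j), vid(i, j + 1L)),
               cbind(vid(i + 1L, j), vid(i + 1L, j + 1L), vid(i, j + 1L)))
  }
  list(verts = verts, faces = f,
       outer_ring = vid(n_rings, j))
}

#' Furrowed drumhead disk (the simplified cap-furrow fixture)
#'
#' A flat disk with sinusoidal out-of-plane furrows, pinned at its boundary
#' ring for inflation. Patterns: `full_circle` (rings concentric with the
#' center: inflates to an upright cone, apex on the axis), `semicircle`
#' (half-rings occupying only the x < 0 half, open toward +x — the
#' "outwardly vacant" pattern, which inflates to an oblique cone whose
#' apex sits well off the axis along x), `parallel` (straight furrows,
#' crests running along y).
#'
#' @param outer_radius disk radius.
#' @param pattern `"full_circle"`, `"semicircle"`, or `"parallel"`.
#' @param n_furrows number of furrow periods across the patterned band.
#' @param amplitude half peak-to-trough furrow height.
#' @param n_rings,n_spokes polar grid resolution.
#' @return list with `mesh` and `masks` (`boundary` = outer pinned ring,
#'   `furrows` = patterned vertices, `half_pos_x`, `half_neg_x`).
#' @export
make_furrowed_disk <- function(outer_radius = 1,
                               pattern = c("full_circle", "semicircle", "parallel"),
                               n_furrows = 5L, amplitude = 0.03,
                               n_rings = 28L, n_spokes = 48L) {
  pattern <- match.arg(pattern)
  g <- polar_disk_grid(outer_radius, n_rings, n_spokes)
  x <- g$verts[, 1]; y <- g$verts[, 2]
  r <- sqrt(x^2 + y^2)
  R <- outer_radius
  wr <- smoothstep01((r / R - 0.28) / 0.12) * smoothstep01((0.92 - r / R) / 0.12)
  z <- switch(pattern,
    full_circle = amplitude * sin(2 * pi * n_furrows * r / R) * wr,
    semicircle = {
      wphi <- smoothstep01((-x / pmax(r, 1e-12)) / 0.25)
      amplitude * sin(2 * pi * n_furrows * r / R) * wr * wphi
    },
    parallel = amplitude * sin(pi * n_furrows * x / R) * wr)
  verts <- cbind(x, y, z)
  mesh <- triangle_mesh(verts, g$faces, name = paste0("furrowed_disk_", pattern))
  v <- n_vertices(mesh)
  masks <- list(
    boundary = region_mask("boundary", g$outer_ring, v),
    furrows = region_mask("furrows", which(abs(z) > 1e-4 * amplitude + 0 &
                                             wr > 0.05), v),
    half_pos_x = region_mask("half_pos_x", which(x > 1e-9), v),
    half_neg_x = region_mask("half_neg_x", which(x < -1e-9), v))
  list(mesh = mesh, masks = masks)
}

#' Yoshimura (zigzag) folded cylinder
#'
#' The diamond buckling pattern of an axially compressed cylinder: rings
#' with alternating half-cell angular offsets, alternate rings displaced
#' radially inward by `fold_depth`, and the axial spacing compressed so
#' each zigzag edge keeps the slant length it has on the uncompressed
#' cylinder of the requested `height`. The folded mesh is therefore
#' axially shorter than `height`, and inflation recovers the stored
#' developable length. Capped at both ends.
#'
#' @param radius cylinder radius.
#' @param height the unfolded (developable) cylinder height.
#' @param n_axial number of axial cells (>= 3).
#' @param n_circumferential diamonds around the circumference (>= 3).
#' @param fold_depth radial indentation of alternate rings; must be small
#'   against `radius` (the unfolding hoop strain is about
#'   `fold_depth / (2 radius)`).
#' @return list with `mesh`, `masks`, `unfolded_height` (= `height`) and
#'   `folded_height` (axial extent of the folded wall).
#' @export
make_yoshimura_cylinder <- function(radius = 1, height = 3, n_axial = 9L,
                                    n_circumferential = 12L, fold_depth = 0.12) {
  stopifnot(n_axial >= 3L, n_circumferential >= 3L, fold_depth >= 0)
  nc <- as.integer(n_circumferential)
  dz0 <- height / n_axial
  psi <- pi / nc                      # half-cell angular offset
  chord0 <- 2 * radius * sin(psi / 2)
  L0 <- sqrt(chord0^2 + dz0^2)        # slant edge on the uncompressed cylinder
  r_in <- radius - fold_depth
  h2 <- radius^2 + r_in^2 - 2 * radius * r_in * cos(psi)
  if (L0^2 <= h2)
    stop("fold_depth too large for this cell geometry: zigzag edges cannot fit")
  dzf <- sqrt(L0^2 - h2)
  radii <- ifelse((0:n_axial) %% 2L == 0L, radius, r_in)
  heights <- dzf * (0:n_axial)
  phase <- ((0:n_axial) %% 2L) * psi
  mesh <- revolve_profile(radii, heights, nc, phase = phase,
                          name = "yoshimura_cylinder")
  list(mesh = mesh, masks = halves_masks(mesh),
       unfolded_height = height, folded_height = dzf * n_axial)
}

#' Tube base with ventrally biased circumferential furrows
#'
#' The orientation-setting fixture: a tube along +Z, pinned at its proximal
#' ring, capped distally, with circumferential sinusoidal furrows whose
#' count differs between the ventral (-Y) and dorsal (+Y) halves, blended
#' smoothly across the lateral seams. More ventral furrows store more
#' meridional length ventrally, so inflation elongates the ventral side
#' more and bends the tube dorsally (positive [bend_angle()]); swapping
#' the counts mirrors the bend.
#'
#' @param radius tube radius.
#' @param length tube length along +Z.
#' @param n_ventral_furrows,n_dorsal_furrows furrow counts
#'   (`n_ventral >= n_dorsal >= 0`).
#' @param amplitude radial furrow amplitude.
#' @param n_theta,n_axial resolution.
#' @return list with `mesh` and `masks` (`ventral`, `dorsal`, `base` = all
#'   wall vertices, `base_ring` = proximal pinned ring).
#' @export
make_biased_base <- function(radius = 0.8, length = 2.5,
                             n_ventral_furrows = 5L, n_dorsal_furrows = 1L,
                             amplitude = 0.08, n_theta = 20L, n_axial = 48L) {
  if (n_ventral_furrows < n_dorsal_furrows || n_dorsal_furrows < 0)
    stop("need n_ventral_furrows >= n_dorsal_furrows >= 0")
  th <- 2 * pi * (seq_len(n_theta) - 1L) / n_theta
  zz <- seq(0, length, length.out = n_axial + 1L)
  wv <- (1 - sin(th)) / 2
  wd <- (1 + sin(th)) / 2
  verts <- do.call(rbind, lapply(seq_along(zz), function(i) {
    z <- zz[i]
    wz <- smoothstep01((z / length - 0.06) / 0.10) *
      smoothstep01((0.94 - z / length) / 0.10)
    dr <- amplitude * wz *
      (wv * sin(2 * pi * n_ventral_furrows * z / length) +
         wd * sin(2 * pi * n_dorsal_furrows * z / length))
    cbind((radius + dr) * cos(th), (radius + dr) * sin(th), z)
  }))
  vid <- function(i, j) (i - 1L) * n_theta + ((j - 1L) %% n_theta) + 1L
  nr <- length(zz)
  j <- seq_len(n_theta)
  f <- do.call(rbind, lapply(seq_len(nr - 1L), function(i)
    rbind(cbind(vid(i, j), vid(i, j + 1L), vid(i + 1L, j)),
          cbind(vid(i, j + 1L), vid(i + 1L, j + 1L), vid(i + 1L, j)))))
  apex <- nrow(verts) + 1L
  verts <- rbind(verts, c(0, 0, length + 0.4 * radius))
  f <- rbind(f, cbind(apex, vid(nr, j), vid(nr, j + 1L)))
  mesh <- triangle_mesh(verts, f, name = "biased_base")
  v <- n_vertices(mesh)
  masks <- halves_masks(mesh)
  masks$base <- region_mask("base", seq_len(nr * n_theta), v)
  masks$base_ring <- region_mask("base_ring", vid(1L, j), v)
  list(mesh = mesh, masks = masks)
}

#' Rectangular plate with a machined V-groove
#'
#' Oracle fixture for [groove_angle()]: a flat plate with an exact V-notch
#' of the stated opening angle running along y at x = 0.
#'
#' @param notch_angle opening angle in degrees, in (10, 170); `NULL` for a
#'   flat plate without a groove.
#' @param half_width half-width of the notch along x.
#' @param nx,ny grid resolution (nx is forced odd so a vertex line lies
#'   exactly on the groove apex).
#' @return list with `mesh` (open plate over `[-1, 1] x [0, 1]`) and
#'   `masks` (`notch`).
#' @export
make_notched_plate <- function(notch_angle = 90, half_width = 0.45,
                               nx = 81L, ny = 13L) {
  if (!is.null(notch_angle) && (notch_angle <= 10 || notch_angle >= 170))
    stop("notch_angle must lie in (10, 170) degrees")
  if (nx %% 2L == 0L) nx <- nx + 1L
  xs <- seq(-1, 1, length.out = nx)
  ys <- seq(0, 1, length.out = ny)
  zfun <- if (is.null(notch_angle)) function(x) 0 * x else {
    half <- notch_angle / 2 * pi / 180
    function(x) ifelse(abs(x) < half_width,
                       -(half_width - abs(x)) / tan(half), 0)
  }
  verts <- as.matrix(expand.grid(x = xs, y = ys))
  verts <- cbind(verts, zfun(verts[, 1]))
  dimnames(verts) <- NULL
  vid <- function(i, j) (j - 1L) * nx + i
  i <- rep(seq_len(nx - 1L), ny - 1L)
  j <- rep(seq_len(ny - 1L), each = nx - 1L)
  f <- rbind(cbind(vid(i, j), vid(i + 1L, j), vid(i, j + 1L)),
             cbind(vid(i + 1L, j), vid(i + 1L, j + 1L), vid(i, j + 1L)))
  mesh <- triangle_mesh(verts, f, name = "notched_plate")
  notch <- which(abs(verts[, 1]) < half_width)
  list(mesh = mesh,
       masks = list(notch = region_mask("notch", notch, n_vertices(mesh))))
}

#' Branched cap model (the constructed four-branch fixture)
#'
#' A mushroom-like dome over a pinned base ring combining the cap's four
#' mechanism ingredients: two tall lateral macro-lobes (present in the
#' folded macro shape), two medial concentric-semicircle furrow patches on
#' the upper surface (absent from the macro shape; the furrows alone build
#' these tips on inflation), and parallel dorsoventral furrows on the
#' bottom surface of the overhang that help lift the lobes. Inflating the
#' full model yields four distal branches; zeroing the medial furrow
#' amplitude (or all furrow amplitudes) leaves only the two macro lobes.
#'
#' This fixture is deliberately constructed: it demonstrates that the
#' mechanism decomposition (macro lateral tips + furrow-built medial tips
#' + differential top/bottom elongation) suffices to produce a four-branch
#' shape, not that it reproduces beetle anatomy.
#'
#' @param base_radius radius of the pinned base ring.
#' @param dome_radius radius of the underlying spherical dome.
#' @param z_squash vertical flattening factor applied to the macro dome.
#' @param lobe_amplitude radial bulge of the lateral lobes (fraction of
#'   `dome_radius`); `lobe_theta_deg`/`lobe_sigma_deg` place and size them.
#' @param medial_height fold depth scale of the telescoped concentric
#'   furrow stacks (0 flattens the furrows, leaving only the small macro
#'   prominence); `medial_n_furrows` nested folds in the stack;
#'   `medial_theta_deg` patch center colatitude; `medial_gamma_deg` patch
#'   angular radius; `medial_sign` +1 for outward stacks, -1 for
#'   invaginated pouches; `medial_bump` height of the small macro
#'   prominence under each stack.
#' @param apex_dimple central depression of the upper surface (the cap's
#'   central groove region between the medial tips).
#' @param y_squash dorsoventral narrowing of the macro dome.
#' @param bottom_amplitude amplitude of the parallel furrows on the bottom
#'   surface band; `bottom_n_furrows` periods across the band.
#' @param n_theta,n_phi colatitude/azimuth resolution.
#' @return list with `mesh`, `masks` (`medial_tips`, `lateral_tips`,
#'   `upper_surface`, `bottom_surface`, `base_ring`).
#' @export
make_cap_model <- function(base_radius = 0.85, dome_radius = 1,
                           z_squash = 0.55, y_squash = 0.65,
                           apex_dimple = 0.15,
                           lobe_amplitude = 2.36, lobe_theta_deg = 38,
                           lobe_sigma_deg = 12,
                           medial_height = 2.2, medial_n_furrows = 5L,
                           medial_sign = 1, medial_bump = 0.65,
                           medial_theta_deg = 40, medial_gamma_deg = 30,
                           bottom_amplitude = 0.03, bottom_n_furrows = 6L,
                           n_theta = 48L, n_phi = 64L) {
  R <- dome_radius
  if (base_radius >= R) stop("base_radius must be smaller than dome_radius")
  cc <- sqrt(R^2 - base_radius^2)
  theta_max <- acos(-cc / R)
  deg <- pi / 180
  # polar fan hole: starting the colatitude grid away from the pole keeps
  # azimuthal chords comparable to the radial spacing (see polar_disk_grid)
  theta_min <- 8 * deg
  th <- seq(theta_min, theta_max, length.out = n_theta)
  ph <- 2 * pi * (seq_len(n_phi) - 1L) / n_phi
  grid <- expand.grid(phi = ph, theta = th)
  theta <- grid$theta; phi <- grid$phi

  # macro lateral lobes (the two prong-like lateral tips) at phi = 0, pi
  wphi_lobe <- ((1 + cos(2 * phi)) / 2)^4
  wth_lobe <- exp(-((theta - lobe_theta_deg * deg)^2) /
                    (2 * (lobe_sigma_deg * deg)^2))
  lobe <- lobe_amplitude * wth_lobe * wphi_lobe
  # taper all modulation to zero near the base ring
  base_window <- smoothstep01((theta_max - theta) / (18 * deg))
  # central dimple: the upper surface between the medial tips sits lower
  # than the tips (the cap's central groove), keeping the apex out of the
  # distal super-level set
  dimple <- apex_dimple * exp(-(theta / (26 * deg))^2 / 2)
  r_mod <- R * (1 + (lobe - dimple) * base_window)

  # medial concentric-semicircle furrow patches at phi = +-pi/2.
  # Each patch is a telescoped cone: the tip cone of height medial_height
  # folded flat into nested conical frustums (a radial accordion whose
  # zigzag slope equals the cone slope, so hoop radii and meridional
  # lengths are preserved and eversion under pressure is isometric). On
  # the folded surface the stack reads as concentric circular ridges and
  # valleys; the azimuthal vacancy (shallower folds on the outward half,
  # the "outwardly vacant concentric semicircle") stores less length in
  # the outward meridians, so the everted tip is an oblique cone.
  u <- cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
  patch_disp <- numeric(length(theta))
  in_patch <- logical(length(theta))
  gmax <- medial_gamma_deg * deg
  tri_wave <- function(t, n) {   # n-period triangle wave over [0,1], in [0,1]
    x <- (t * n) %% 1
    1 - abs(2 * x - 1)
  }
  bump_disp <- numeric(length(theta))
  for (sgn in c(1, -1)) {
    ctr <- c(0, sgn * sin(medial_theta_deg * deg), cos(medial_theta_deg * deg))
    gam <- acos(pmin(1, pmax(-1, u %*% ctr)))
    inside <- gam < gmax
    in_patch <- in_patch | inside
    # small macro prominence under each furrow stack: after furrow removal
    # a much smaller medial tip remains (it no longer reaches the distal
    # super-level set), matching the observed removal phenotype
    bump_disp <- bump_disp +
      medial_bump * exp(-(gam / (0.45 * gmax))^2 / 2)
    if (!any(inside) || medial_height <= 0) next
    t <- gam[inside] / gmax
    # vacancy: full fold depth on the apex-facing half, reduced outward
    wsemi <- 0.3 + 0.7 * smoothstep01((u[inside, 3] - ctr[3]) / 0.10 + 0.5)
    rim <- smoothstep01((1 - t) / 0.15)   # blend into the dome at the rim
    patch_disp[inside] <- patch_disp[inside] +
      medial_sign * medial_height * wsemi * rim *
      tri_wave(t, medial_n_furrows) / (2 * medial_n_furrows)
  }

  # parallel dorsoventral furrows on the bottom surface of the overhang
  wth_bot <- smoothstep01((theta - 92 * deg) / (10 * deg)) *
    smoothstep01((theta_max - 6 * deg - theta) / (8 * deg))
  wphi_bot <- ((1 + cos(2 * phi)) / 2)^2
  bot <- bottom_amplitude *
    sin(2 * pi * bottom_n_furrows * sin(theta) * cos(phi)) * wth_bot * wphi_bot

  r_tot <- r_mod + (bump_disp + patch_disp + bot) * base_window
  pts <- cbind(r_tot * sin(theta) * cos(phi),
               r_tot * sin(theta) * sin(phi),
               cc + r_tot * cos(theta))
  # force the base ring row onto z = 0 at base_radius exactly
  last_row <- which(abs(theta - theta_max) < 1e-12)
  pts[last_row, 1] <- base_radius * cos(phi[last_row])
  pts[last_row, 2] <- base_radius * sin(phi[last_row])
  pts[last_row, 3] <- 0
  # anisotropic macro shape: narrow dorsoventrally, flattened distally --
  # the mushroom-umbrella silhouette of the folded cap
  pts[, 2] <- pts[, 2] * y_squash
  pts[, 3] <- pts[, 3] * z_squash

  vid <- function(i, j) (i - 1L) * n_phi + ((j - 1L) %% n_phi) + 1L
  j <- seq_len(n_phi)
  f <- do.call(rbind, lapply(seq_len(n_theta - 1L), function(i)
    rbind(cbind(vid(i, j), vid(i, j + 1L), vid(i + 1L, j + 1L)),
          cbind(vid(i, j), vid(i + 1L, j + 1L), vid(i + 1L, j)))))
  apex <- nrow(pts) + 1L
  pts <- rbind(pts, c(0, 0, z_squash * (cc + R)))
  f <- rbind(f, cbind(apex, vid(1L, j + 1L), vid(1L, j)))
  mesh <- triangle_mesh(pts, f, name = "cap_model")
  if (enclosed_volume(mesh, fan_close_boundary = TRUE) < 0)
    mesh$faces <- mesh$faces[, c(1L, 3L, 2L)]

  v <- n_vertices(mesh)
  lat <- which(c(lobe, 0) > 0.25 * max(lobe_amplitude, 1e-12))
  med <- setdiff(which(c(in_patch, FALSE)), lat)
  bots <- setdiff(which(c(wth_bot * wphi_bot, 0) > 0.15), union(lat, med))
  upper <- setdiff(which(c(theta, 0) < 92 * deg | seq_len(v) == apex),
                   Reduce(union, list(lat, med, bots)))
  masks <- list(
    medial_tips = region_mask("medial_tips", med, v),
    lateral_tips = region_mask("lateral_tips", lat, v),
    upper_surface = region_mask("upper_surface", upper, v),
    bottom_surface = region_mask("bottom_surface", bots, v),
    base_ring = region_mask("base_ring", vid(n_theta, j), v))
  list(mesh = mesh, masks = masks)
}
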