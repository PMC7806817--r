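#' Slice-centroid centerline of a tubular mesh
#'
#' Bins vertices into `n_slices` equal-thickness slabs along an axis and
#' returns the area-weighted centroid of each non-empty slab, a polyline
#' approximating the object's central axis (the input to [bend_angle()]).
#'
#' @param mesh a [triangle_mesh()]
#' @param axis slicing direction, default +Z (proximodistal).
#' @param n_slices number of slabs (>= 3).
#' @return numeric matrix (k x 3) of slab centroids, ordered along the
#'   axis; errors if fewer than 3 slabs are non-empty.
#' @export
centerline <- function(mesh, axis = c(0, 0, 1), n_slices = 12L) {
  stopifnot(n_slices >= 3L)
  axis <- axis / sqrt(sum(axis^2))
  pr <- as.numeric(mesh$vertices %*% axis)
  if (diff(range(pr)) <= 0) stop("mesh has no extent along the axis")
  br <- seq(min(pr), max(pr), length.out = n_slices + 1L)
  bin <- findInterval(pr, br, rightmost.closed = TRUE)
  w <- vertex_areas(mesh)
  nodes <- lapply(seq_len(n_slices), function(b) {
    ix <- which(bin == b)
    if (!length(ix) || sum(w[ix]) <= 0) return(NULL)
    colSums(mesh$vertices[ix, , drop = FALSE] * w[ix]) / sum(w[ix])
  })
  nodes <- do.call(rbind, nodes[!vapply(nodes, is.null, logical(1))])
  if (is.null(nodes) || nrow(nodes) < 3L)
    stop("fewer than 3 non-empty slices along the axis")
  nodes
}

ls_direction <- function(nodes) {
  # principal direction of a node set, oriented along increasing row order
  c0 <- colMeans(nodes)
  sv <- svd(sweep(nodes, 2, c0))
  dir <- sv$v[, 1]
  if (sum((nodes[nrow(nodes), ] - nodes[1, ]) * dir) < 0) dir <- -dir
  dir
}

#' Signed sagittal bend angle of a centerline
#'
#' Angle between the proximal segment direction (least-squares line through
#' the first 25% of nodes) and the distal segment direction (last 25%),
#' projected onto the sagittal Y-Z plane. Positive when the distal end is
#' tipped dorsally (+Y); the sign flips under a Y-mirror.
#'
#' @param nodes a [centerline()] polyline (k x 3, k >= 3).
#' @return angle in degrees in (-180, 180].
#' @export
bend_angle <- function(nodes) {
  n <- nrow(nodes)
  if (is.null(n) || n < 3L) stop("need at least 3 centerline nodes")
  k <- max(2L, ceiling(n * 0.25))
  u <- ls_direction(nodes[seq_len(k), , drop = FALSE])
  v <- ls_direction(nodes[(n - k + 1L):n, , drop = FALSE])
  uyz <- u[2:3]; vyz <- v[2:3]
  if (sqrt(sum(uyz^2)) < 1e-12 || sqrt(sum(vyz^2)) < 1e-12)
    stop("degenerate (axis-perpendicular) segment direction")
  # positive = rotation from the proximal direction toward +Y
  ang <- atan2(uyz[2] * vyz[1] - uyz[1] * vyz[2], sum(uyz * vyz))
  ang * 180 / pi
}

bfs_components <- function(adj, keep) {
  # connected components of the induced subgraph on `keep` (logical)
  v <- length(adj)
  comp <- integer(v)
  cid <- 0L
  for (s in which(keep)) {
    if (comp[s]) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      cur <- queue[[1]]
      queue <- queue[-1]
      nb <- adj[[cur]]
      nb <- nb[keep[nb] & comp[nb] == 0L]
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Count distal branches of a mesh
#'
#' Number of connected components of the vertex subgraph above a height
#' threshold along the axis — the branch count of the super-level set at
#' `height_fraction` of the axial span. Components smaller than
#' `min_component` vertices are discarded as noise.
#'
#' @param mesh a [triangle_mesh()]
#' @param axis height direction, default +Z.
#' @param height_fraction threshold in (0, 1) of the axial span; default
#'   0.6.
#' @param min_component minimum vertices for a component to count.
#' @return integer branch count (0 if nothing lies above the threshold).
#' @export
count_branches <- function(mesh, axis = c(0, 0, 1), height_fraction = 0.6,
                           min_component = 5L) {
  stopifnot(height_fraction > 0, height_fraction < 1)
  axis <- axis / sqrt(sum(axis^2))
  pr <- as.numeric(mesh$vertices %*% axis)
  thr <- min(pr) + height_fraction * (max(pr) - min(pr))
  keep <- pr > thr
  if (!any(keep)) return(0L)
  comp <- bfs_components(vertex_adjacency(mesh), keep)
  sizes <- table(comp[comp > 0L])
  sum(sizes >= min_component)
}

# Cross-section of a mesh with the plane {x : x . axis = position}:
# polyline chains of edge-plane intersection points, one segment per
# crossed face, linked through shared edges. Returns a list of chains;
# each chain is a list(points = k x 3 matrix, normals = k x 3 interpolated
# vertex normals, closed = logical).
cross_section <- function(mesh, axis = c(0, 1, 0), position = 0) {
  axis <- axis / sqrt(sum(axis^2))
  s <- as.numeric(mesh$vertices %*% axis) - position
  f <- mesh$faces
  vn <- vertex_normals(mesh)
  v <- n_vertices(mesh)

  edge_id <- function(i, j) (pmin(i, j) - 1) * v + pmax(i, j)
  seg_edges <- list()
  for (c1 in 1:3) {
    c2 <- if (c1 == 3L) 1L else c1 + 1L
    i <- f[, c1]; j <- f[, c2]
    crossed <- (s[i] > 0) != (s[j] > 0)
    seg_edges[[c1]] <- ifelse(crossed, edge_id(i, j), NA_real_)
  }
  em <- do.call(cbind, seg_edges)
  nc <- rowSums(!is.na(em))
  faces_cr <- which(nc == 2L)
  if (!length(faces_cr)) return(list())

  # intersection point on each crossed edge (computed once per edge)
  all_e <- unique(as.numeric(em[faces_cr, ]))
  all_e <- all_e[!is.na(all_e)]
  ei <- floor((all_e - 1) / v) + 1
  ej <- (all_e - 1) %% v + 1
  t <- s[ei] / (s[ei] - s[ej])
  pts <- (1 - t) * mesh$vertices[ei, , drop = FALSE] +
    t * mesh$vertices[ej, , drop = FALSE]
  nrm <- (1 - t) * vn[ei, , drop = FALSE] + t * vn[ej, , drop = FALSE]

  # face segments as pairs of edge ids -> chain through shared edges
  seg <- t(apply(em[faces_cr, , drop = FALSE], 1, function(r) r[!is.na(r)]))
  if (ncol(seg) != 2L) seg <- t(seg)
  seg <- matrix(match(as.numeric(seg), all_e), ncol = 2L)

  used <- logical(nrow(seg))
  incident <- split(rep(seq_len(nrow(seg)), 2L), as.vector(seg))
  chains <- list()
  for (s0 in seq_len(nrow(seg))) {
    if (used[s0]) next
    chain <- c(seg[s0, 1], seg[s0, 2])
    used[s0] <- TRUE
    repeat {   # extend forward
      tail_e <- chain[length(chain)]
      cand <- incident[[as.character(tail_e)]]
      cand <- cand[!used[cand]]
      if (!length(cand)) break
      nxt <- cand[1]
      used[nxt] <- TRUE
      other <- setdiff(seg[nxt, ], tail_e)
      if (!length(other)) break
      chain <- c(chain, other[1])
    }
    repeat {   # extend backward
      head_e <- chain[1]
      cand <- incident[[as.character(head_e)]]
      cand <- cand[!used[cand]]
      if (!length(cand)) break
      nxt <- cand[1]
      used[nxt] <- TRUE
      other <- setdiff(seg[nxt, ], head_e)
      if (!length(other)) break
      chain <- c(other[1], chain)
    }
    closed <- FALSE
    if (length(chain) > 2L && chain[1] == chain[length(chain)]) {
      chain <- chain[-length(chain)]
      closed <- TRUE
    }
    chains[[length(chains) + 1L]] <-
      list(points = pts[chain, , drop = FALSE],
           normals = nrm[chain, , drop = FALSE],
           closed = closed)
  }
  chains
}

polyline_point_at <- function(pts, arclen, s_target, closed = FALSE) {
  if (closed) s_target <- s_target %% arclen[length(arclen)]
  s_target <- min(max(s_target, 0), arclen[length(arclen)])
  i <- findInterval(s_target, arclen, rightmost.closed = TRUE)
  i <- min(max(i, 1L), nrow(pts) - 1L)
  t <- (s_target - arclen[i]) / (arclen[i + 1] - arclen[i])
  (1 - t) * pts[i, ] + t * pts[i + 1, ]
}

#' Interior angle of the central groove on a cross-section
#'
#' Extracts the cross-section polyline of the mesh at the plane normal to
#' `slice_axis` through `slice_position`, finds the deepest concave vertex
#' (the groove: the section point that turns toward the outward surface
#' normal and is most recessed along it), and returns the interior angle
#' between the two tangent chords taken 10% of the section arc length to
#' each side of the groove point.
#'
#' @param mesh a [triangle_mesh()]
#' @param slice_axis normal of the slicing plane, default +Y (a sagittal
#'   section for the package's axis convention).
#' @param slice_position plane offset along `slice_axis`; default the
#'   mid-position of the mesh.
#' @param turn_tol minimum turn (radians, toward the normal) for a section
#'   point to count as concave.
#' @return angle in degrees, or `NA_real_` when the section has no concave
#'   vertex (e.g. a smooth convex tube).
#' @export
groove_angle <- function(mesh, slice_axis = c(0, 1, 0), slice_position = NULL,
                         turn_tol = 1e-3) {
  slice_axis <- slice_axis / sqrt(sum(slice_axis^2))
  pr <- as.numeric(mesh$vertices %*% slice_axis)
  if (is.null(slice_position)) slice_position <- mean(range(pr))
  if (slice_position <= min(pr) || slice_position >= max(pr))
    stop("slicing plane does not intersect the mesh")
  span <- diff(range(pr))
  tries <- 0L
  while (any(abs(pr - slice_position) < 1e-9 * span) && tries < 20L) {
    slice_position <- slice_position + 1e-4 * span   # avoid vertex-on-plane
    tries <- tries + 1L
  }
  chains <- cross_section(mesh, slice_axis, slice_position)
  if (!length(chains)) return(NA_real_)
  # use the longest chain
  lens <- vapply(chains, function(ch) {
    d <- diff(ch$points)
    sum(sqrt(rowSums(d * d)))
  }, numeric(1))
  ch <- chains[[which.max(lens)]]
  pts <- ch$points
  k <- nrow(pts)
  if (k < 5L) return(NA_real_)
  seglen <- sqrt(rowSums(diff(pts)^2))
  arclen <- c(0, cumsum(seglen))
  total <- arclen[k]

  interior <- if (ch$closed) seq_len(k) else 2:(k - 1L)
  concavity <- rep(NA_real_, k)
  for (i in interior) {
    ip <- if (i == 1L) k else i - 1L
    ins <- if (i == k) 1L else i + 1L
    t1 <- pts[i, ] - pts[ip, ]
    t2 <- pts[ins, ] - pts[i, ]
    n1 <- sqrt(sum(t1^2)); n2 <- sqrt(sum(t2^2))
    if (n1 < 1e-12 || n2 < 1e-12) next
    turn <- t2 / n2 - t1 / n1
    concavity[i] <- sum(turn * ch$normals[i, ])   # > 0: bends toward outside
  }
  cand <- which(!is.na(concavity) & concavity > turn_tol)
  if (!length(cand)) return(NA_real_)
  nbar <- colMeans(ch$normals)
  nbar <- nbar / max(sqrt(sum(nbar^2)), 1e-12)
  depth <- as.numeric(pts[cand, , drop = FALSE] %*% nbar)
  g <- cand[which.min(depth)]     # most recessed along the mean normal

  off <- 0.1 * total
  pa <- polyline_point_at(pts, arclen, arclen[g] - off, ch$closed)
  pb <- polyline_point_at(pts, arclen, arclen[g] + off, ch$closed)
  va <- pa - pts[g, ]; vb <- pb - pts[g, ]
  na_ <- sqrt(sum(va^2)); nb_ <- sqrt(sum(vb^2))
  if (na_ < 1e-12 || nb_ < 1e-12) return(NA_real_)
  acos(min(1, max(-1, sum(va * vb) / (na_ * nb_)))) * 180 / pi
}

#' Apex offset of an inflated drumhead
#'
#' For an open mesh pinned at its boundary ring: the in-plane (lateral)
#' distance between the highest interior vertex and the boundary-ring
#' centroid, divided by the ring's mean radius. Near 0 for an upright cone
#' (axisymmetric furrows), large for the oblique cone produced by
#' one-sided (semicircular) furrow patterns.
#'
#' @param mesh an open [triangle_mesh()] with a single boundary ring.
#' @param up normal of the base plane, default +Z.
#' @return dimensionless offset.
#' @export
apex_offset <- function(mesh, up = c(0, 0, 1)) {
  up <- up / sqrt(sum(up^2))
  bv <- boundary_vertices(mesh)
  if (!length(bv)) stop("apex_offset needs an open mesh with a boundary ring")
  ring <- mesh$vertices[bv, , drop = FALSE]
  ctr <- colMeans(ring)
  rel <- sweep(ring, 2, ctr)
  rel_in <- rel - outer(as.numeric(rel %*% up), up)
  mean_radius <- mean(sqrt(rowSums(rel_in^2)))
  h <- as.numeric(sweep(mesh$vertices, 2, ctr) %*% up)
  interior <- setdiff(seq_len(n_vertices(mesh)), bv)
  if (!length(interior) || max(h[interior]) <= 0)
    stop("no interior vertices above the base plane")
  apex <- mesh$vertices[interior[which.max(h[interior])], ]
  d <- apex - ctr
  d_in <- d - sum(d * up) * up
  sqrt(sum(d_in^2)) / mean_radius
}

#' Discrete Gaussian curvature (angle deficit)
#'
#' `K_i = (2 pi - sum of incident face angles at i) / A_i` for interior
#' vertices and `(pi - sum) / A_i` for boundary vertices, with `A_i` the
#' barycentric vertex area ([vertex_areas()]). Exactly zero on the interior
#' wall of a regular triangulated cylinder (a developable surface), and the
#' total deficit of a closed mesh satisfies the combinatorial Gauss-Bonnet
#' identity `sum(deficit) = 2 pi chi`.
#'
#' @param mesh a [triangle_mesh()]
#' @return list with `curvature` (per-vertex, 1/length^2) and `deficit`
#'   (per-vertex angle deficit, radians).
#' @export
discrete_gaussian_curvature <- function(mesh) {
  v <- n_vertices(mesh)
  co <- face_corner_coords(mesh)
  ang <- function(p, q, r) {
    # angle at p in triangle (p, q, r)
    u <- q - p; w <- r - p
    cu <- row_norms(u); cw <- row_norms(w)
    acos(pmin(1, pmax(-1, rowSums(u * w) / (cu * cw))))
  }
  a1 <- ang(co$a, co$b, co$c)
  a2 <- ang(co$b, co$c, co$a)
  a3 <- ang(co$c, co$a, co$b)
  sums <- numeric(v)
  f <- mesh$faces
  angs <- list(a1, a2, a3)
  for (k in 1:3) {
    acc <- rowsum(angs[[k]], f[, k])
    idx <- as.integer(rownames(acc))
    sums[idx] <- sums[idx] + acc[, 1]
  }
  bv <- boundary_vertices(mesh)
  full <- rep(2 * pi, v)
  full[bv] <- pi
  deficit <- full - sums
  areas <- vertex_areas(mesh)
  if (any(areas <= 0))
    stop("zero-area vertex neighbourhood at vertex ",
         which(areas <= 0)[1])
  list(curvature = deficit / areas, deficit = deficit)
}

#' Morphometry of a mesh
#'
#' The named scalar measurements used to compare folded, unfolded and
#' furrow-removed variants: extents along the three body axes, signed
#' sagittal bend angle, distal branch count, surface area and (for closed
#' or fan-closable meshes) enclosed volume; optionally the central groove
#' angle of a stated cross-section and the apex offset of open drumhead
#' meshes.
#'
#' @param mesh a [triangle_mesh()]
#' @param axis proximodistal axis, default +Z.
#' @param branch_fraction height fraction for [count_branches()].
#' @param n_slices centerline slice count for [bend_angle()]; the bend
#'   angle is `NA` when a centerline cannot be formed.
#' @param groove optional list with elements `axis` and `position` naming
#'   the cross-section for [groove_angle()]; `NULL` skips it.
#' @param apex compute [apex_offset()] (only meaningful for open pinned
#'   meshes); default: automatic (open meshes only).
#' @return list of class `morphometry_report`.
#' @export
measure_mesh <- function(mesh, axis = c(0, 0, 1), branch_fraction = 0.6,
                         n_slices = 12L, groove = NULL, apex = NULL) {
  ext <- apply(mesh$vertices, 2, function(x) diff(range(x)))
  bend <- tryCatch(bend_angle(centerline(mesh, axis, n_slices)),
                   error = function(e) NA_real_)
  open_mesh <- length(boundary_vertices(mesh)) > 0
  if (is.null(apex)) apex <- open_mesh
  rep <- list(
    axial_extent = axial_extent(mesh, axis),
    lateral_extent = ext[1],
    dorsoventral_extent = ext[2],
    bend_angle = bend,
    branch_count = count_branches(mesh, axis, branch_fraction),
    area = surface_area(mesh),
    volume = tryCatch(enclosed_volume(mesh, fan_close_boundary = open_mesh),
                      error = function(e) NA_real_),
    groove_angle = if (!is.null(groove))
      groove_angle(mesh, groove$axis, groove$position) else NA_real_,
    apex_offset = if (isTRUE(apex))
      tryCatch(apex_offset(mesh), error = function(e) NA_real_)
      else NA_real_
  )
  structure(rep, class = "morphometry_report")
}

#' @export
print.morphometry_report <- function(x, ...) {
  cat("morphometry report\n")
  for (nm in names(x)) {
    val <- x[[nm]]
    cat(sprintf("  %-20s %s\n", nm,
                if (is.na(val)) "NA" else format(val, digits = 5)))
  }
  invisible(x)
}
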