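#' Construct a triangle surface mesh
#'
#' The single geometry carrier used throughout the package: vertex
#' coordinates plus oriented triangle connectivity. Faces are stored
#' counterclockwise when viewed from outside, so consistently oriented
#' closed meshes have positive [enclosed_volume()]. Indices are 1-based;
#' file formats that use 0-based indices are converted at the I/O boundary.
#'
#' @param vertices numeric matrix (V x 3) of vertex coordinates. The package
#'   convention is +Z = proximodistal axis (distal up), +Y = dorsal,
#'   +X = animal's left; lengths are dimensionless.
#' @param faces integer matrix (F x 3) of vertex indices, counterclockwise
#'   seen from outside.
#' @param name free-text mesh name.
#' @param attributes named list of per-vertex numeric fields (each of
#'   length V), e.g. a furrow depth field.
#' @return an object of class `triangle_mesh` with elements `vertices`,
#'   `faces`, `attributes`, `name`.
#' @seealso [validate_mesh()], [load_mesh()], [save_mesh()]
#' @export
#' @examples
#' tet <- triangle_mesh(
#'   rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
#'   rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3)),
#'   name = "tetrahedron"
#' )
#' enclosed_volume(tet)
triangle_mesh <- function(vertices, faces, name = "mesh", attributes = list()) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("`vertices` must have 3 columns")
  if (nrow(faces) > 0L && ncol(faces) != 3L) stop("`faces` must have 3 columns")
  if (nrow(faces) == 0L) faces <- matrix(integer(0), 0L, 3L)
  v <- nrow(vertices)
  if (nrow(faces) > 0L) {
    if (min(faces) < 1L || max(faces) > v)
      stop("face indices out of range 1..", v)
    if (any(faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
              faces[, 1] == faces[, 3]))
      stop("faces must not repeat a vertex")
  }
  if (length(attributes)) {
    bad <- vapply(attributes, function(a) length(a) != v, logical(1))
    if (any(bad))
      stop("attribute fields must have one value per vertex: ",
           paste(names(attributes)[bad], collapse = ", "))
  }
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  structure(
    list(vertices = vertices, faces = faces,
         attributes = attributes, name = as.character(name)[1]),
    class = "triangle_mesh"
  )
}

#' @export
print.triangle_mesh <- function(x, ...) {
  rep <- validate_mesh(x)
  cat(sprintf("triangle_mesh '%s': %d vertices, %d faces (%s, %s)\n",
              x$name, n_vertices(x), n_faces(x),
              if (rep$closed) "closed" else "open",
              if (rep$manifold && rep$oriented) "manifold, oriented"
              else "non-manifold or inconsistently oriented"))
  if (length(x$attributes))
    cat("  fields:", paste(names(x$attributes), collapse = ", "), "\n")
  invisible(x)
}

#' Number of vertices / faces of a mesh
#' @param mesh a [triangle_mesh()]
#' @return integer count
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' @rdname n_vertices
#' @export
n_faces <- function(mesh) nrow(mesh$faces)

# Directed half-edges, one row per face edge, in face winding order.
half_edges <- function(mesh) {
  f <- mesh$faces
  cbind(c(f[, 1], f[, 2], f[, 3]), c(f[, 2], f[, 3], f[, 1]))
}

# Integer key identifying an undirected edge.
edge_key <- function(e, v) {
  i <- pmin(e[, 1], e[, 2])
  j <- pmax(e[, 1], e[, 2])
  (as.numeric(i) - 1) * v + as.numeric(j)
}

#' Undirected edge list of a mesh
#'
#' @param mesh a [triangle_mesh()]
#' @return integer matrix (E x 2), each row one undirected edge with
#'   the smaller index first; rows unique and sorted.
#' @export
mesh_edges <- function(mesh) {
  he <- half_edges(mesh)
  i <- pmin(he[, 1], he[, 2])
  j <- pmax(he[, 1], he[, 2])
  keep <- !duplicated(edge_key(he, n_vertices(mesh)))
  e <- cbind(i[keep], j[keep])
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

#' Validate a triangle mesh
#'
#' Checks the structural invariants: manifoldness (every edge borders at
#' most two faces), orientation consistency (each interior edge is traversed
#' once in each direction by its two faces), closedness, and the Euler
#' characteristic V - E + F (2 for closed genus-0 surfaces). Degenerate
#' (zero-area) faces are reported, never repaired.
#'
#' @param mesh a [triangle_mesh()]
#' @param area_tol faces with area below this are reported as degenerate.
#' @return a list of class `mesh_validation`: logical `manifold`,
#'   `oriented`, `closed`; integer `n_vertices`, `n_edges`, `n_faces`,
#'   `euler_characteristic`; matrices `boundary_edges`,
#'   `nonmanifold_edges`, `misoriented_edges`; integer `degenerate_faces`.
#' @export
validate_mesh <- function(mesh, area_tol = 1e-12) {
  v <- n_vertices(mesh)
  he <- half_edges(mesh)
  key <- edge_key(he, v)
  tab <- table(key)
  counts <- as.integer(tab)
  ukey <- as.numeric(names(tab))
  ue <- cbind(floor((ukey - 1) / v) + 1, (ukey - 1) %% v + 1)
  storage.mode(ue) <- "integer"

  manifold <- all(counts <= 2L)
  boundary <- ue[counts == 1L, , drop = FALSE]
  nonmanifold <- ue[counts > 2L, , drop = FALSE]

  # orientation: among edges with exactly two incident faces, the two
  # half-edges must run in opposite directions
  dkey <- (as.numeric(he[, 1]) - 1) * v + as.numeric(he[, 2])
  dup_directed <- unique(dkey[duplicated(dkey)])
  mis <- if (length(dup_directed)) {
    cbind(floor((dup_directed - 1) / v) + 1, (dup_directed - 1) %% v + 1)
  } else matrix(integer(0), 0L, 2L)
  storage.mode(mis) <- "integer"
  oriented <- nrow(mis) == 0L

  deg <- which(face_areas(mesh) < area_tol)

  structure(list(
    manifold = manifold,
    oriented = oriented,
    closed = nrow(boundary) == 0L && manifold,
    n_vertices = v,
    n_edges = nrow(ue),
    n_faces = n_faces(mesh),
    euler_characteristic = v - nrow(ue) + n_faces(mesh),
    boundary_edges = boundary,
    nonmanifold_edges = nonmanifold,
    misoriented_edges = mis,
    degenerate_faces = as.integer(deg)
  ), class = "mesh_validation")
}

#' @export
print.mesh_validation <- function(x, ...) {
  cat(sprintf(
    "mesh validation: V=%d E=%d F=%d chi=%d | manifold=%s oriented=%s closed=%s\n",
    x$n_vertices, x$n_edges, x$n_faces, x$euler_characteristic,
    x$manifold, x$oriented, x$closed))
  if (nrow(x$boundary_edges)) cat("  boundary edges:", nrow(x$boundary_edges), "\n")
  if (nrow(x$nonmanifold_edges)) cat("  non-manifold edges:", nrow(x$nonmanifold_edges), "\n")
  if (nrow(x$misoriented_edges)) cat("  misoriented edges:", nrow(x$misoriented_edges), "\n")
  if (length(x$degenerate_faces)) cat("  degenerate faces:", length(x$degenerate_faces), "\n")
  invisible(x)
}

#' Vertex adjacency of a mesh
#'
#' @param mesh a [triangle_mesh()]
#' @return list of length V; element `i` is the sorted integer vector of
#'   neighbours of vertex `i`. Symmetric: `j %in% adj[[i]]` iff
#'   `i %in% adj[[j]]`.
#' @export
vertex_adjacency <- function(mesh) {
  e <- mesh_edges(mesh)
  v <- n_vertices(mesh)
  adj <- split(c(e[, 2], e[, 1]), factor(c(e[, 1], e[, 2]), levels = seq_len(v)))
  lapply(adj, function(x) sort(unique(as.integer(x))))
}

#' Boundary edges and vertices
#'
#' @param mesh a [triangle_mesh()]
#' @return `boundary_edges()`: integer matrix (B x 2); `boundary_vertices()`:
#'   sorted integer vector of vertices on the boundary (empty for closed
#'   meshes).
#' @export
boundary_edges <- function(mesh) {
  validate_mesh(mesh)$boundary_edges
}

#' @rdname boundary_edges
#' @export
boundary_vertices <- function(mesh) {
  sort(unique(as.integer(boundary_edges(mesh))))
}

face_corner_coords <- function(mesh) {
  f <- mesh$faces
  p <- mesh$vertices
  list(a = p[f[, 1], , drop = FALSE],
       b = p[f[, 2], , drop = FALSE],
       c = p[f[, 3], , drop = FALSE])
}

row_cross <- function(u, w) {
  cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
        u[, 3] * w[, 1] - u[, 1] * w[, 3],
        u[, 1] * w[, 2] - u[, 2] * w[, 1])
}

row_norms <- function(m) sqrt(rowSums(m * m))

# Unnormalized face normals (magnitude = 2 * area), outward for CCW faces.
face_normals_raw <- function(mesh) {
  co <- face_corner_coords(mesh)
  row_cross(co$b - co$a, co$c - co$a)
}

#' Per-face areas of a mesh
#' @param mesh a [triangle_mesh()]
#' @return numeric vector of length F
#' @export
face_areas <- function(mesh) {
  if (n_faces(mesh) == 0L) return(numeric(0))
  row_norms(face_normals_raw(mesh)) / 2
}

#' Total surface area of a mesh
#' @param mesh a [triangle_mesh()]
#' @return scalar area (length squared)
#' @export
surface_area <- function(mesh) sum(face_areas(mesh))

#' Per-vertex barycentric areas
#'
#' One third of the area of the incident faces, the standard vertex weight
#' for area-weighted averages and for normalizing angle-deficit curvature.
#'
#' @param mesh a [triangle_mesh()]
#' @return numeric vector of length V
#' @export
vertex_areas <- function(mesh) {
  a3 <- face_areas(mesh) / 3
  v <- n_vertices(mesh)
  out <- numeric(v)
  f <- mesh$faces
  for (k in 1:3) {
    acc <- rowsum(a3, f[, k])
    out[as.integer(rownames(acc))] <- out[as.integer(rownames(acc))] + acc[, 1]
  }
  out
}

#' Outward unit vertex normals
#'
#' Area-weighted average of incident face normals, normalized. Outward
#' provided the face winding is counterclockwise seen from outside.
#'
#' @param mesh a [triangle_mesh()]
#' @return numeric matrix (V x 3) of unit normals; rows of zero-area
#'   neighbourhoods are zero.
#' @export
vertex_normals <- function(mesh) {
  fn <- face_normals_raw(mesh)   # magnitude 2*area: area weighting built in
  v <- n_vertices(mesh)
  out <- matrix(0, v, 3L)
  f <- mesh$faces
  for (k in 1:3) {
    acc <- rowsum(fn, f[, k])
    idx <- as.integer(rownames(acc))
    out[idx, ] <- out[idx, ] + acc
  }
  nn <- row_norms(out)
  pos <- nn > 0
  out[pos, ] <- out[pos, ] / nn[pos]
  out
}

#' Signed enclosed volume of a mesh
#'
#' Divergence-theorem volume: one sixth of the sum over faces of the triple
#' product of the vertex position vectors. Positive for closed meshes with
#' outward (counterclockwise) winding; reversing all windings negates it
#' exactly.
#'
#' For open meshes the volume is undefined unless the boundary is closed by
#' the pinned-base convention: `fan_close_boundary = TRUE` closes each
#' boundary loop by a triangle fan to the loop's vertex centroid, the same
#' closure [inflate()] uses for drumhead-style fixtures with a pinned rim.
#'
#' @param mesh a [triangle_mesh()]
#' @param fan_close_boundary close boundary loops by centroid fans instead
#'   of raising an error on open meshes.
#' @return scalar volume (length cubed)
#' @export
enclosed_volume <- function(mesh, fan_close_boundary = FALSE) {
  rep <- validate_mesh(mesh)
  co <- face_corner_coords(mesh)
  vol <- sum(rowSums(co$a * row_cross(co$b, co$c))) / 6
  if (nrow(rep$boundary_edges)) {
    if (!fan_close_boundary) {
      stop("mesh is open (", nrow(rep$boundary_edges), " boundary edges, e.g. ",
           paste(rep$boundary_edges[1, ], collapse = "-"),
           "); use fan_close_boundary = TRUE for the pinned-base closure")
    }
    cl <- closure_fan_faces(mesh)
    p <- rbind(mesh$vertices, cl$centroids)
    a <- p[cl$faces[, 1], , drop = FALSE]
    b <- p[cl$faces[, 2], , drop = FALSE]
    cc <- p[cl$faces[, 3], , drop = FALSE]
    vol <- vol + sum(rowSums(a * row_cross(b, cc))) / 6
  }
  vol
}

# Fan-closure of all boundary loops: each directed boundary half-edge (i,j)
# (appearing once, in face winding order) is closed by the triangle
# (j, i, centroid) so the closed surface stays consistently oriented.
# Returns centroids (one per loop) and faces indexing centroids at V+1.. .
closure_fan_faces <- function(mesh) {
  v <- n_vertices(mesh)
  he <- half_edges(mesh)
  key <- edge_key(he, v)
  cnt <- table(key)
  single <- as.numeric(names(cnt)[cnt == 1L])
  bd <- he[key %in% single, , drop = FALSE]   # directed boundary half-edges
  if (nrow(bd) == 0L)
    return(list(centroids = matrix(0, 0, 3), faces = matrix(integer(0), 0, 3)))
  # group boundary half-edges into loops
  nxt <- integer(v)
  nxt[bd[, 1]] <- bd[, 2]
  loop_id <- integer(nrow(bd))
  starts <- bd[, 1]
  seen <- logical(v)
  lid <- 0L
  loops <- list()
  for (s in starts) {
    if (seen[s]) next
    lid <- lid + 1L
    cur <- s
    loop <- integer(0)
    repeat {
      loop <- c(loop, cur)
      seen[cur] <- TRUE
      cur <- nxt[cur]
      if (cur == s || cur == 0L || seen[cur] && cur != s) break
    }
    loops[[lid]] <- loop
  }
  centroids <- t(vapply(loops, function(ix)
    colMeans(mesh$vertices[ix, , drop = FALSE]), numeric(3)))
  faces <- do.call(rbind, lapply(seq_along(loops), function(k) {
    ix <- loops[[k]]
    cbind(nxt[ix], ix, v + k)   # (j, i, centroid)
  }))
  storage.mode(faces) <- "integer"
  list(centroids = centroids, faces = faces, loops = loops)
}

#' Named vertex-region mask
#'
#' A named subset of vertex indices — the unit of region-specific smoothing,
#' pinning and morphometry (cap/stalk/base, ventral/dorsal halves, cap
#' subregions, pinned boundary rings).
#'
#' @param name region name, e.g. `"ventral"`, `"cap"`, `"boundary"`.
#' @param indices integer vertex indices (1-based); duplicates dropped.
#' @param n_vertices optional vertex count of the parent mesh, used to
#'   range-check the indices.
#' @return integer vector of class `region_mask`, sorted and unique, with a
#'   `name` attribute.
#' @export
region_mask <- function(name, indices, n_vertices = NULL) {
  idx <- sort(unique(as.integer(indices)))
  if (length(idx) && idx[1] < 1L) stop("mask indices must be >= 1")
  if (!is.null(n_vertices) && length(idx) && max(idx) > n_vertices)
    stop("mask indices exceed vertex count ", n_vertices)
  structure(idx, name = as.character(name)[1], class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("region_mask '%s': %d vertices\n", attr(x, "name"), length(x)))
  invisible(x)
}

#' Read / write a region mask file
#'
#' Plain text, one vertex index per line, `#` comments allowed. Indices are
#' 0-based on disk (the convention of common mesh tooling) and converted to
#' the package's 1-based indices.
#'
#' @param path file path.
#' @param name region name; defaults to the file stem.
#' @return a [region_mask()]
#' @export
read_region_mask <- function(path, name = NULL) {
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  region_mask(name, as.integer(lines) + 1L)
}

#' @rdname read_region_mask
#' @param mask a [region_mask()]
#' @export
write_region_mask <- function(mask, path) {
  writeLines(c(sprintf("# region: %s", attr(mask, "name")),
               as.character(as.integer(mask) - 1L)), path)
  invisible(path)
}

#' Extent of a mesh along an axis
#'
#' Max minus min of the vertex projections onto a direction; the
#' proximodistal extent for the default +Z axis.
#'
#' @param mesh a [triangle_mesh()]
#' @param axis direction vector (normalized internally); default +Z.
#' @return scalar extent
#' @export
axial_extent <- function(mesh, axis = c(0, 0, 1)) {
  if (n_vertices(mesh) == 0L) stop("empty mesh")
  axis <- axis / sqrt(sum(axis^2))
  pr <- mesh$vertices %*% axis
  max(pr) - min(pr)
}
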