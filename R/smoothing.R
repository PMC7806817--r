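#' Smoothing parameters
#'
#' Parameters of the HC-modified Laplacian smoother ([hc_laplacian_smooth()]).
#' `alpha` weights the pull of the push-back correction toward the original
#' positions (0 = toward the previous iterate), `beta` splits the push-back
#' between a vertex and its neighbourhood mean; `beta = 1` with `alpha = 0`
#' reduces the scheme to repeated plain Laplacian steps. The defaults
#' (`alpha = 0`, `beta = 0.5`, 50 iterations) are the shrink-resistant
#' regime of the HC scheme.
#'
#' @param alpha weight in `[0, 1]` pulling the correction toward the
#'   entry positions.
#' @param beta HC correction weight in `[0, 1]`.
#' @param n_iterations number of smoothing iterations (>= 1).
#' @param mask optional [region_mask()]: only masked vertices are smoothed.
#' @param feather_width non-negative integer; number of breadth-first rings
#'   outside the mask over which the smoothing weight ramps linearly from
#'   full (inside) to zero (outside). See [build_weights()].
#' @return list of class `smoothing_params`
#' @export
smoothing_params <- function(alpha = 0, beta = 0.5, n_iterations = 50L,
                             mask = NULL, feather_width = 2L) {
  stopifnot(alpha >= 0, alpha <= 1, beta >= 0, beta <= 1,
            n_iterations >= 1, feather_width >= 0)
  structure(list(alpha = alpha, beta = beta,
                 n_iterations = as.integer(n_iterations),
                 mask = mask, feather_width = as.integer(feather_width)),
            class = "smoothing_params")
}

# Row-stochastic neighbour-averaging matrix. Interior vertices average all
# mesh neighbours; boundary vertices of open meshes average only their two
# boundary neighbours (1D smoothing along the boundary polyline, which
# prevents the rim of open fixtures from curling inward). Boundary corners
# (turn angle above `corner_deg`) and isolated vertices get a zero row:
# they are left unmoved, preserving the outline of plate fixtures.
averaging_matrix <- function(mesh, corner_deg = 30) {
  v <- n_vertices(mesh)
  e <- mesh_edges(mesh)
  i <- c(e[, 1], e[, 2])
  j <- c(e[, 2], e[, 1])
  bnd <- boundary_edges(mesh)
  bvert <- sort(unique(as.integer(bnd)))
  if (length(bvert)) {
    # restrict boundary rows to boundary edges
    bkey_i <- i %in% bvert
    on_bedge <- paste(pmin(i, j), pmax(i, j)) %in%
      paste(pmin(bnd[, 1], bnd[, 2]), pmax(bnd[, 1], bnd[, 2]))
    keep <- !bkey_i | on_bedge
    i <- i[keep]; j <- j[keep]
    # detect corners: boundary vertices whose two boundary neighbours are
    # not collinear with them
    nb <- split(j[i %in% bvert], i[i %in% bvert])
    corners <- vapply(names(nb), function(vv) {
      ns <- nb[[vv]]
      if (length(ns) != 2L) return(TRUE)   # irregular boundary: freeze
      p <- mesh$vertices[as.integer(vv), ]
      u1 <- mesh$vertices[ns[1], ] - p
      u2 <- mesh$vertices[ns[2], ] - p
      cosang <- sum(u1 * u2) / sqrt(sum(u1^2) * sum(u2^2))
      cosang > cos(pi * (180 - corner_deg) / 180)
    }, logical(1))
    frozen <- as.integer(names(nb))[corners]
    if (length(frozen)) {
      keep2 <- !(i %in% frozen)
      i <- i[keep2]; j <- j[keep2]
    }
  }
  m <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(v, v))
  deg <- Matrix::rowSums(m)
  scale <- ifelse(deg > 0, 1 / deg, 0)
  Matrix::Diagonal(v, scale) %*% m
}

#' Per-vertex smoothing weights from a region mask
#'
#' No mask: all weights 1. With a mask: 1 on masked vertices, 0 outside,
#' with a linear ramp over `feather_width` breadth-first rings outside the
#' mask boundary (ring `k` gets weight `1 - k / (feather_width + 1)`).
#'
#' @param mesh a [triangle_mesh()]
#' @param mask optional [region_mask()]
#' @param feather_width non-negative integer ring count.
#' @return numeric vector of length V in `[0, 1]`.
#' @export
build_weights <- function(mesh, mask = NULL, feather_width = 2L) {
  v <- n_vertices(mesh)
  if (is.null(mask)) return(rep(1, v))
  idx <- as.integer(mask)
  if (length(idx) && max(idx) > v) stop("mask indices exceed vertex count")
  if (!length(idx)) {
    warning("empty smoothing mask: all weights zero")
    return(rep(0, v))
  }
  w <- numeric(v)
  w[idx] <- 1
  if (feather_width > 0L) {
    adj <- vertex_adjacency(mesh)
    frontier <- idx
    visited <- logical(v)
    visited[idx] <- TRUE
    for (k in seq_len(feather_width)) {
      nxt <- unique(unlist(adj[frontier], use.names = FALSE))
      nxt <- nxt[!visited[nxt]]
      if (!length(nxt)) break
      w[nxt] <- 1 - k / (feather_width + 1)
      visited[nxt] <- TRUE
      frontier <- nxt
    }
  }
  w
}

#' One weighted Laplacian smoothing step
#'
#' Moves each vertex toward the mean of its neighbours:
#' `p_i = (1 - w_i) q_i + w_i mean(q_j, j in N(i))`. Connectivity is
#' untouched. Boundary vertices of open meshes average along the boundary
#' polyline only; isolated vertices are left unmoved with a warning.
#'
#' @param mesh a [triangle_mesh()]
#' @param weights per-vertex smoothing weight in `[0, 1]`, length V.
#' @param avg optional precomputed [averaging_matrix] (internal reuse).
#' @return numeric matrix (V x 3) of new positions.
#' @export
laplacian_step <- function(mesh, weights, avg = NULL) {
  v <- n_vertices(mesh)
  stopifnot(length(weights) == v, all(weights >= 0), all(weights <= 1))
  if (is.null(avg)) avg <- averaging_matrix(mesh)
  deg <- Matrix::rowSums(avg)
  mesh_deg <- tabulate(mesh_edges(mesh), nbins = v)
  if (any(mesh_deg == 0 & weights > 0))
    warning("isolated vertices left unmoved")
  q <- mesh$vertices
  m <- as.matrix(avg %*% q)
  m[deg == 0, ] <- q[deg == 0, , drop = FALSE]
  (1 - weights) * q + weights * m
}

#' HC-modified Laplacian smoothing
#'
#' Laplacian smoothing with the Vollmer-style "push-back" correction that
#' suppresses the global shrinkage of plain Laplacian filtering. Per
#' iteration, with `o` the positions at entry and `q` the current iterate:
#' a weighted Laplacian step gives `p`; the displacement
#' `b_i = p_i - (alpha o_i + (1 - alpha) q_i)` is then pushed back as
#' `p_i <- p_i - w_i (beta b_i + (1 - beta) mean(b_j, j in N(i)))`.
#' The push-back is scaled by the smoothing weight `w_i` so vertices with
#' weight zero are exactly immobile, which makes region-masked smoothing
#' local: outside the mask (plus feather ring) the mesh is bit-identical.
#'
#' The smoother is fully deterministic and never alters connectivity.
#'
#' @param mesh a [triangle_mesh()]
#' @param params a [smoothing_params()]
#' @return the smoothed [triangle_mesh()] (attributes and name preserved).
#' @export
#' @examples
#' shp <- make_accordion_cylinder(n_theta = 12, n_axial = 24)
#' sm <- hc_laplacian_smooth(shp$mesh, smoothing_params(n_iterations = 10))
#' surface_area(sm) < surface_area(shp$mesh)
hc_laplacian_smooth <- function(mesh, params = smoothing_params()) {
  stopifnot(inherits(params, "smoothing_params"))
  avg <- averaging_matrix(mesh)
  w <- build_weights(mesh, params$mask, params$feather_width)
  deg <- Matrix::rowSums(avg)
  o <- mesh$vertices
  q <- o
  work <- mesh
  for (it in seq_len(params$n_iterations)) {
    work$vertices <- q
    p <- laplacian_step(work, w, avg = avg)
    b <- p - (params$alpha * o + (1 - params$alpha) * q)
    mb <- as.matrix(avg %*% b)
    mb[deg == 0, ] <- 0
    q <- p - w * (params$beta * b + (1 - params$beta) * mb)
  }
  out <- mesh
  out$vertices <- q
  out
}
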