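#' Material and descent parameters for the unfolding simulation
#'
#' The unfolding simulator ([inflate()]) minimizes a membrane energy by
#' steepest descent: rest-length edge springs (stiffness `k_stretch`,
#' normalized by rest length), a small hinge term penalizing dihedral
#' deviation from flat (`k_bend`), and pressure-volume work `-p V` driving
#' expansion. `NULL` entries are resolved from the mesh at run time:
#'
#' * `pressure`: `0.05 * k_stretch / R_lat`, with `R_lat` half the larger
#'   lateral (X/Y) bounding-box extent. By the Laplace law the membrane
#'   strain of an inflated tube scales as `p R / k`, so this keeps strain
#'   near 5%: the surface unfolds rather than stretches.
#' * `k_bend`: `1e-4 * k_stretch * mean(l0^2)` — just enough to regularize
#'   crumpling without resisting unfolding.
#' * `step_size`: `0.1 * min(l0) / k_stretch`; the descent also adapts the
#'   step (backtracking halving on energy increase, mild growth after
#'   accepted steps).
#' * `grad_tol`: `5e-3 * pressure * mean(l0^2)` (a small fraction of the
#'   typical pressure force on one vertex), or `1e-8 * k_stretch` when
#'   `pressure = 0`.
#'
#' @param k_stretch edge spring stiffness (energy/length), > 0.
#' @param pressure internal pressure (energy/length^3), >= 0 or `NULL`.
#' @param k_bend hinge stiffness (energy) or `NULL`.
#' @param step_size descent step (length^2/energy) or `NULL`.
#' @param max_steps maximum descent steps.
#' @param grad_tol convergence threshold on the max per-vertex gradient
#'   magnitude, or `NULL`.
#' @param pinned vertices held immobile: a [region_mask()], the string
#'   `"boundary"` (pin all boundary vertices — required for open meshes),
#'   or `NULL`.
#' @param snapshot_stride record a trajectory snapshot every this many
#'   accepted descent steps (first and last are always kept).
#' @param lbfgs_memory L-BFGS memory depth of the descent (curvature pairs
#'   kept for the quasi-Newton search direction); `0` selects plain
#'   steepest descent with an adaptive step. Both use the same monotone
#'   backtracking line search, so the recorded energy series never
#'   increases either way.
#' @return list of class `material_params`
#' @export
material_params <- function(k_stretch = 1, pressure = NULL, k_bend = NULL,
                            step_size = NULL, max_steps = 50000L,
                            grad_tol = NULL, pinned = NULL,
                            snapshot_stride = 100L, lbfgs_memory = 8L) {
  stopifnot(k_stretch > 0, is.null(pressure) || pressure >= 0,
            is.null(step_size) || step_size > 0, max_steps >= 1,
            snapshot_stride >= 1)
  structure(list(k_stretch = k_stretch, pressure = pressure, k_bend = k_bend,
                 step_size = step_size, max_steps = as.integer(max_steps),
                 grad_tol = grad_tol, pinned = pinned,
                 snapshot_stride = as.integer(snapshot_stride),
                 lbfgs_memory = as.integer(lbfgs_memory)),
            class = "material_params")
}

# Hinges: one row (i, j, k, l) per interior edge; the face (i, j, k)
# traverses the edge i->j and the face (j, i, l) traverses j->i.
build_hinges <- function(mesh) {
  f <- mesh$faces
  v <- n_vertices(mesh)
  he <- half_edges(mesh)
  opp <- c(f[, 3], f[, 1], f[, 2])
  dkey <- (as.numeric(he[, 1]) - 1) * v + as.numeric(he[, 2])
  rkey <- (as.numeric(he[, 2]) - 1) * v + as.numeric(he[, 1])
  twin <- match(rkey, dkey)
  keep <- !is.na(twin) & he[, 1] < he[, 2]   # one hinge per interior edge
  h <- cbind(he[keep, 1], he[keep, 2], opp[keep], opp[twin[keep]])
  storage.mode(h) <- "integer"
  h
}

resolve_pinned <- function(mesh, pinned) {
  if (is.null(pinned)) return(integer(0))
  if (identical(pinned, "boundary")) return(boundary_vertices(mesh))
  as.integer(pinned)
}

# Assemble the simulator inputs: 0-based edges/hinges/faces, rest lengths
# from the mesh's own edge lengths, fan-closure faces with pinned centroid
# rows appended for open meshes, and the resolved parameter values.
build_sim_structures <- function(rest_mesh, params) {
  rep <- validate_mesh(rest_mesh)
  pinned_idx <- resolve_pinned(rest_mesh, params$pinned)
  if (!rep$closed) {
    bvert <- sort(unique(as.integer(rep$boundary_edges)))
    if (!all(bvert %in% pinned_idx))
      stop("open mesh: the enclosed volume is undefined unless every ",
           "boundary vertex is pinned (pass pinned = \"boundary\" or a ",
           "mask covering the boundary ring)")
  }
  v <- n_vertices(rest_mesh)
  e <- mesh_edges(rest_mesh)
  d <- rest_mesh$vertices[e[, 1], , drop = FALSE] -
    rest_mesh$vertices[e[, 2], , drop = FALSE]
  rest_len <- sqrt(rowSums(d * d))
  if (any(rest_len <= 0)) stop("zero-length edge in rest mesh")
  hinges <- build_hinges(rest_mesh)
  cl <- closure_fan_faces(rest_mesh)
  n_extra <- nrow(cl$centroids)
  vol_faces <- rbind(rest_mesh$faces, cl$faces)
  pos0 <- rbind(rest_mesh$vertices, cl$centroids)
  pinned <- logical(v + n_extra)
  pinned[pinned_idx] <- TRUE
  if (n_extra) pinned[(v + 1):(v + n_extra)] <- TRUE

  l0m <- mean(rest_len)
  ext <- apply(rest_mesh$vertices, 2, function(x) diff(range(x)))
  r_lat <- max(ext[1], ext[2]) / 2
  pressure <- if (is.null(params$pressure)) 0.05 * params$k_stretch / r_lat
    else params$pressure
  k_bend <- if (is.null(params$k_bend)) 1e-4 * params$k_stretch * mean(rest_len^2)
    else params$k_bend
  step_size <- if (is.null(params$step_size)) 0.1 * min(rest_len) / params$k_stretch
    else params$step_size
  grad_tol <- if (is.null(params$grad_tol)) {
    if (pressure > 0) 5e-3 * pressure * mean(rest_len^2)
    else 1e-8 * params$k_stretch
  } else params$grad_tol

  resolved <- params
  resolved$pressure <- pressure
  resolved$k_bend <- k_bend
  resolved$step_size <- step_size
  resolved$grad_tol <- grad_tol
  resolved$pinned <- region_mask("pinned", pinned_idx, v)

  list(pos0 = pos0, edges = e - 1L, rest_len = rest_len,
       hinges = hinges - 1L, vol_faces = vol_faces - 1L,
       pinned = pinned, n_extra = n_extra, params = resolved)
}

#' Membrane energy and its analytic gradient
#'
#' Evaluates the unfolding energy (springs + hinges - pressure * volume) at
#' arbitrary vertex positions against a rest mesh, together with the exact
#' analytic gradient. Gradient rows of pinned vertices are zero. For open
#' meshes the volume uses the pinned-boundary fan closure (see
#' [enclosed_volume()]).
#'
#' @param positions numeric matrix (V x 3) of current positions.
#' @param rest_mesh the [triangle_mesh()] defining connectivity and rest
#'   edge lengths.
#' @param params a [material_params()]
#' @return list with `energy` (scalar) and `gradient` (V x 3 matrix).
#' @export
compute_energy <- function(positions, rest_mesh, params = material_params()) {
  positions <- as.matrix(positions)
  if (nrow(positions) != n_vertices(rest_mesh) || ncol(positions) != 3L)
    stop("`positions` must be a ", n_vertices(rest_mesh), " x 3 matrix")
  s <- build_sim_structures(rest_mesh, params)
  pos <- positions
  if (s$n_extra) {
    # closure centroids recomputed from the (pinned) boundary loops
    cl <- closure_fan_faces(rest_mesh)
    cent <- t(vapply(cl$loops, function(ix)
      colMeans(positions[ix, , drop = FALSE]), numeric(3)))
    pos <- rbind(positions, cent)
  }
  out <- cpp_energy_grad(pos, s$edges, s$rest_len, s$hinges, s$vol_faces,
                         s$params$k_stretch, s$params$k_bend,
                         s$params$pressure, s$pinned)
  list(energy = out$energy,
       gradient = out$gradient[seq_len(n_vertices(rest_mesh)), , drop = FALSE])
}

#' Unfold a folded mesh by pressure-driven energy minimization
#'
#' Steepest-descent minimization of the membrane energy from the folded
#' rest state, emulating the balloon-like deployment of a folded epithelial
#' sheet under internal pressure. Connectivity is frozen, so every vertex
#' of the unfolded surface corresponds to the same index in the folded
#' surface; the recorded trajectory supports exact correspondence analysis
#' (see [map_region()]).
#'
#' The descent is deterministic: identical inputs give identical
#' trajectories. The recorded energy series is non-increasing by
#' construction (backtracking line halving). If the line search stalls the
#' run aborts with a warning advising a smaller `step_size`.
#'
#' @param rest_mesh the folded [triangle_mesh()]; also supplies the rest
#'   edge lengths.
#' @param params a [material_params()]
#' @return object of class `simulation_trajectory`: `snapshots` (list of
#'   V x 3 position matrices), `steps` (descent step of each snapshot),
#'   `energy_series`, `rest_mesh`, `params` (with resolved defaults),
#'   `converged`, `n_steps`.
#' @export
#' @examples
#' shp <- make_accordion_cylinder(n_pleats = 4, n_theta = 10, n_axial = 16)
#' traj <- inflate(shp$mesh, material_params(max_steps = 300))
#' axial_extent(snapshot_mesh(traj)) > axial_extent(shp$mesh)
inflate <- function(rest_mesh, params = material_params()) {
  s <- build_sim_structures(rest_mesh, params)
  p <- s$params
  out <- cpp_inflate(s$pos0, s$edges, s$rest_len, s$hinges, s$vol_faces,
                     p$k_stretch, p$k_bend, p$pressure, s$pinned,
                     p$step_size, p$max_steps, p$grad_tol, p$snapshot_stride,
                     p$lbfgs_memory)
  if (isTRUE(out$stalled))
    warning("descent line search stalled before reaching grad_tol; ",
            "consider a smaller step_size")
  v <- n_vertices(rest_mesh)
  snaps <- lapply(out$snapshots, function(m) m[seq_len(v), , drop = FALSE])
  structure(list(
    snapshots = snaps,
    steps = out$steps,
    energy_series = out$energies,
    rest_mesh = rest_mesh,
    params = p,
    converged = out$converged,
    n_steps = out$n_steps
  ), class = "simulation_trajectory")
}

#' @export
print.simulation_trajectory <- function(x, ...) {
  cat(sprintf(
    "simulation_trajectory: %d snapshots over %d steps (%s), energy %.6g -> %.6g\n",
    length(x$snapshots), x$n_steps,
    if (x$converged) "converged" else "max_steps reached",
    x$energy_series[1], x$energy_series[length(x$energy_series)]))
  invisible(x)
}

resolve_snapshot_index <- function(trajectory, at_step) {
  if (identical(at_step, "last")) return(length(trajectory$snapshots))
  if (identical(at_step, "first")) return(1L)
  i <- match(as.integer(at_step), trajectory$steps)
  if (is.na(i))
    stop("step ", at_step, " was not recorded; recorded steps: ",
         paste(utils::head(trajectory$steps, 3), collapse = ", "), " ... ",
         trajectory$steps[length(trajectory$steps)])
  i
}

#' Extract a snapshot of a trajectory as a mesh
#'
#' @param trajectory a [inflate()] result.
#' @param at_step `"last"`, `"first"`, or a recorded descent step number.
#' @return a [triangle_mesh()] with the snapshot positions and the frozen
#'   connectivity of the rest mesh.
#' @export
snapshot_mesh <- function(trajectory, at_step = "last") {
  i <- resolve_snapshot_index(trajectory, at_step)
  out <- trajectory$rest_mesh
  out$vertices <- trajectory$snapshots[[i]]
  out$name <- paste0(trajectory$rest_mesh$name, "_step", trajectory$steps[i])
  out
}

#' Map a region through the unfolding trajectory
#'
#' Correspondence between folded and unfolded states is exact because
#' connectivity is frozen: a region drawn on the inflated mesh is the same
#' vertex-index set on every snapshot, including the folded state
#' ("rewinding" the simulation). This returns the mask (identity on
#' indices) after validating it against the trajectory, so regions can be
#' transferred across snapshots and exported with any snapshot's positions.
#'
#' @param trajectory a [inflate()] result.
#' @param mask a [region_mask()] on the trajectory's mesh.
#' @param at_step snapshot to validate against (`"last"`, `"first"`, or a
#'   recorded step number); errors if out of range.
#' @return the same [region_mask()] (identical index set).
#' @export
map_region <- function(trajectory, mask, at_step = "first") {
  resolve_snapshot_index(trajectory, at_step)   # range check
  region_mask(attr(mask, "name"), as.integer(mask),
              n_vertices(trajectory$rest_mesh))
}
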