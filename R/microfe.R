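#' Micro-FE model specification
#'
#' Material and analysis constants for the voxel hexahedral model:
#' homogeneous isotropic linear elasticity (14.8 GPa, Poisson 0.3), a 1 mm
#' longitudinal compressive displacement for the stiffness case, a 1 N
#' distributed distal load for the strength case, failure when 2% of the
#' considered nodes exceed -10300 microstrain in compression (third
#' principal strain) or +8000 microstrain in tension (first principal
#' strain), with nodes within 10% of the model length of either extremity
#' excluded from the criterion.
#'
#' @param E Young's modulus, MPa (N/mm^2); default 14800 (= 14.8 GPa).
#' @param nu Poisson's ratio, in (0, 0.5).
#' @param applied_displacement compressive displacement, mm.
#' @param applied_load distributed compressive load, N.
#' @param end_exclusion_fraction axial fraction excluded at each extremity
#'   for the strain criterion.
#' @param failure_node_fraction fraction of considered nodes that must reach
#'   a critical strain.
#' @param eps_comp_limit compressive principal strain limit, microstrain
#'   (negative).
#' @param eps_tens_limit tensile principal strain limit, microstrain.
#' @param rtol conjugate-gradient relative residual tolerance.
#' @param maxit maximum CG iterations (default `10 * n_dof`, capped at 2e5).
#' @return An object of class `fe_model_spec`.
#' @export
fe_model_spec <- function(E = 14800, nu = 0.3, applied_displacement = 1,
                          applied_load = 1, end_exclusion_fraction = 0.10,
                          failure_node_fraction = 0.02,
                          eps_comp_limit = -10300, eps_tens_limit = 8000,
                          rtol = 1e-8, maxit = NULL) {
  stopifnot(E > 0, nu >= 0, nu < 0.5,
            end_exclusion_fraction > 0, end_exclusion_fraction < 0.5,
            failure_node_fraction > 0, failure_node_fraction < 1,
            eps_comp_limit < 0, eps_tens_limit > 0)
  structure(list(E = E, nu = nu,
                 applied_displacement = applied_displacement,
                 applied_load = applied_load,
                 end_exclusion_fraction = end_exclusion_fraction,
                 failure_node_fraction = failure_node_fraction,
                 eps_comp_limit = eps_comp_limit,
                 eps_tens_limit = eps_tens_limit,
                 rtol = rtol, maxit = maxit),
            class = "fe_model_spec")
}

# Trilinear shape-function derivative signs; local node order
# (0,0,0),(1,0,0),(1,1,0),(0,1,0),(0,0,1),(1,0,1),(1,1,1),(0,1,1)
hex_local_signs <- function() {
  rbind(c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1), c(-1, 1, -1),
        c(-1, -1, 1), c(1, -1, 1), c(1, 1, 1), c(-1, 1, 1))
}

hex_dN <- function(xi, eta, zeta) {
  s <- hex_local_signs()
  dN <- matrix(0, 8, 3)
  for (a in 1:8) {
    dN[a, 1] <- s[a, 1] * (1 + s[a, 2] * eta) * (1 + s[a, 3] * zeta) / 8
    dN[a, 2] <- s[a, 2] * (1 + s[a, 1] * xi) * (1 + s[a, 3] * zeta) / 8
    dN[a, 3] <- s[a, 3] * (1 + s[a, 1] * xi) * (1 + s[a, 2] * eta) / 8
  }
  dN
}

hex_B <- function(dNdx) {
  B <- matrix(0, 6, 24)
  for (a in 1:8) {
    c0 <- 3 * (a - 1)
    B[1, c0 + 1] <- dNdx[a, 1]
    B[2, c0 + 2] <- dNdx[a, 2]
    B[3, c0 + 3] <- dNdx[a, 3]
    B[4, c0 + 1] <- dNdx[a, 2]; B[4, c0 + 2] <- dNdx[a, 1]
    B[5, c0 + 2] <- dNdx[a, 3]; B[5, c0 + 3] <- dNdx[a, 2]
    B[6, c0 + 1] <- dNdx[a, 3]; B[6, c0 + 3] <- dNdx[a, 1]
  }
  B
}

elastic_D <- function(E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  D
}

#' Element stiffness matrix of the voxel hexahedron
#'
#' Isotropic linear-elastic 8-node hexahedron of edge `edge_mm`, integrated
#' with 2x2x2 Gauss quadrature (exact for the trilinear element). Computed
#' once per model and shared by all elements.
#'
#' @param E Young's modulus, MPa.
#' @param nu Poisson's ratio.
#' @param edge_mm element (voxel) edge length, mm.
#' @return 24x24 symmetric stiffness matrix (N/mm per mm displacement).
#' @export
element_stiffness <- function(E, nu, edge_mm) {
  if (nu >= 0.5) stop("Poisson's ratio must be below 0.5")
  D <- elastic_D(E, nu)
  g <- 1 / sqrt(3)
  h <- edge_mm
  detJ <- (h / 2)^3
  Ke <- matrix(0, 24, 24)
  for (xi in c(-g, g)) for (eta in c(-g, g)) for (zeta in c(-g, g)) {
    dNdx <- hex_dN(xi, eta, zeta) * (2 / h)
    B <- hex_B(dNdx)
    Ke <- Ke + t(B) %*% D %*% B * detJ
  }
  (Ke + t(Ke)) / 2
}

# Centroid strain-displacement matrix in physical units (1/mm)
hex_B_centroid <- function(edge_mm) {
  hex_B(hex_dN(0, 0, 0) * (2 / edge_mm))
}

#' Build a voxel hexahedral mesh
#'
#' Keeps the largest 6-connected component of the mask, converts each bone
#' voxel to an 8-node hexahedral element with shared nodes, and identifies
#' the proximal and distal node sets (mesh nodes on the lowest and highest
#' occupied z planes).
#'
#' @param mask a [bone_mask()].
#' @param spacing voxel spacing in micrometres (defaults to the mask's).
#' @return An object of class `voxel_mesh`: `elems` (n_elem x 8, 0-based
#'   compact node ids in the local order used by [element_stiffness()]),
#'   `node_ijk` (n_nodes x 3 integer grid coordinates), `edge_mm`,
#'   `proximal_nodes`, `distal_nodes` (1-based node indices),
#'   `distal_face_weights` (consistent uniform-pressure weights, per distal
#'   node), `n_nodes`, `n_elems`.
#' @export
build_mesh <- function(mask, spacing = NULL) {
  m <- as_mask_array(mask)
  if (sum(m) == 0) stop("mask is empty")
  if (is.null(spacing))
    spacing <- if (inherits(mask, "bone_mask")) mask$spacing else 10.4
  mk <- largest_component(bone_mask(m, spacing), connectivity = 6L)
  m <- mk$data
  d <- dim(m)
  idx <- which(m != 0)
  vox <- arrayInd(idx, d) - 1L # 0-based voxel coords
  nxn <- d[1] + 1L
  nyn <- d[2] + 1L
  node_lin <- function(ix, iy, iz)
    ix + as.numeric(nxn) * (iy + as.numeric(nyn) * iz) # double to avoid overflow
  off <- hex_local_signs()
  off <- (off + 1L) / 2L # corner offsets 0/1 per local node
  raw <- matrix(0, nrow(vox), 8)
  for (a in 1:8)
    raw[, a] <- node_lin(vox[, 1] + off[a, 1], vox[, 2] + off[a, 2],
                         vox[, 3] + off[a, 3])
  uids <- sort(unique(as.vector(raw)))
  elems <- matrix(match(raw, uids) - 1L, nrow(vox), 8)
  iz <- floor(uids / (as.numeric(nxn) * nyn))
  rem <- uids - iz * as.numeric(nxn) * nyn
  iy <- floor(rem / nxn)
  ix <- rem - iy * nxn
  node_ijk <- cbind(as.integer(ix), as.integer(iy), as.integer(iz))
  zmin <- min(node_ijk[, 3])
  zmax <- max(node_ijk[, 3])
  proximal <- which(node_ijk[, 3] == zmin)
  distal <- which(node_ijk[, 3] == zmax)
  # consistent uniform-pressure weights on the distal surface: each element
  # top face lying in the distal plane contributes one quarter to each of its
  # 4 face nodes
  w <- numeric(nrow(node_ijk))
  top_elems <- which(vox[, 3] == max(vox[, 3]))
  for (e in top_elems) {
    face_nodes <- elems[e, 5:8] + 1L # local nodes with zeta = +1
    w[face_nodes] <- w[face_nodes] + 0.25
  }
  structure(list(elems = elems, node_ijk = node_ijk,
                 edge_mm = spacing / 1000,
                 proximal_nodes = proximal, distal_nodes = distal,
                 distal_face_weights = w[distal],
                 n_nodes = nrow(node_ijk), n_elems = nrow(elems)),
            class = "voxel_mesh")
}

#' @export
print.voxel_mesh <- function(x, ...) {
  cat(sprintf("<voxel_mesh> %d elements, %d nodes, edge %.4g mm\n",
              x$n_elems, x$n_nodes, x$edge_mm))
  cat(sprintf("  proximal/distal surface nodes: %d / %d\n",
              length(x$proximal_nodes), length(x$distal_nodes)))
  invisible(x)
}

fe_default_maxit <- function(mesh, spec) {
  if (!is.null(spec$maxit)) return(as.integer(spec$maxit))
  as.integer(min(10 * 3 * mesh$n_nodes, 2e5))
}

#' Apparent compressive stiffness from the voxel FE model
#'
#' Proximal surface nodes are fully constrained; every distal surface node
#' is prescribed a longitudinal displacement of `applied_displacement` mm in
#' compression (transverse distal DOFs left free). The assembled system is
#' solved matrix-free by Jacobi-preconditioned conjugate gradients, and
#' stiffness is the magnitude of the summed longitudinal reactions at the
#' proximal surface divided by the applied displacement.
#'
#' @param mesh a [build_mesh()] result.
#' @param spec an [fe_model_spec()].
#' @return An object of class `fe_result` with `stiffness` (N/mm), solver
#'   iterations and residual, and the displacement field.
#' @export
solve_stiffness <- function(mesh, spec = fe_model_spec()) {
  Ke <- element_stiffness(spec$E, spec$nu, mesh$edge_mm)
  ndof <- 3L * mesh$n_nodes
  fixed <- rep(NA_real_, ndof)
  pz <- mesh$proximal_nodes
  fixed[3 * (pz - 1) + 1] <- 0
  fixed[3 * (pz - 1) + 2] <- 0
  fixed[3 * (pz - 1) + 3] <- 0
  dz <- mesh$distal_nodes
  fixed[3 * (dz - 1) + 3] <- -spec$applied_displacement
  f <- rep(0, ndof)
  sol <- fe_cg_cpp(mesh$elems, mesh$n_nodes, Ke, fixed, f, spec$rtol,
                   fe_default_maxit(mesh, spec))
  if (!sol$converged)
    stop(sprintf("CG did not converge (relative residual %.3g after %d iterations)",
                 sol$relres, sol$iterations))
  forces <- fe_forces_cpp(mesh$elems, mesh$n_nodes, Ke, sol$u)
  reaction_z <- sum(forces[3 * (pz - 1) + 3])
  structure(list(stiffness = abs(reaction_z) / spec$applied_displacement,
                 strength = NA_real_,
                 u = sol$u, iterations = sol$iterations,
                 residual = sol$relres, spec = spec,
                 n_nodes = mesh$n_nodes, n_elems = mesh$n_elems),
            class = "fe_result")
}

# principal strains per node (microstrain), z coordinates, and the subset of
# node indices considered by the failure criterion
fe_strain_field <- function(mesh, spec, u) {
  Bc <- hex_B_centroid(mesh$edge_mm)
  eps <- fe_nodal_strains_cpp(mesh$elems, mesh$n_nodes, Bc, u)
  pr <- principal_strains_cpp(eps) * 1e6 # microstrain
  z <- mesh$node_ijk[, 3] * mesh$edge_mm
  zr <- range(z)
  L <- diff(zr)
  lo <- zr[1] + spec$end_exclusion_fraction * L
  hi <- zr[2] - spec$end_exclusion_fraction * L
  considered <- which(z >= lo & z <= hi)
  list(principal = pr, considered = considered)
}

# safety factors of the considered nodes under the unit probe load
fe_lambda <- function(pr, considered, spec) {
  e1 <- pr[considered, 1]
  e3 <- pr[considered, 3]
  lam_c <- ifelse(e3 < 0, abs(spec$eps_comp_limit) / abs(e3), Inf)
  lam_t <- ifelse(e1 > 0, spec$eps_tens_limit / e1, Inf)
  pmin(lam_c, lam_t)
}

#' Criterion-based compressive strength from the voxel FE model
#'
#' Proximal surface fully constrained; a compressive probe load of
#' `applied_load` N is applied on the distal surface as a uniform pressure
#' (consistent nodal forces: face-area weighting). Element centroid strains
#' are volume-averaged to the nodes, principal strains computed, and nodes
#' within `end_exclusion_fraction` of the model length of either extremity
#' are excluded. Each node's safety factor is the load scale at which it
#' first exceeds -10300 microstrain in compression (third principal) or
#' +8000 microstrain in tension (first principal); the bone fails when
#' `failure_node_fraction` of the considered nodes have failed, so strength
#' is `applied_load` times the k-th smallest safety factor,
#' k = ceiling(fraction x N).
#'
#' @param mesh a [build_mesh()] result.
#' @param spec an [fe_model_spec()].
#' @return An `fe_result` with `strength` (N), the nodal principal strains
#'   (microstrain, considered nodes), solver diagnostics.
#' @export
solve_strength <- function(mesh, spec = fe_model_spec()) {
  Ke <- element_stiffness(spec$E, spec$nu, mesh$edge_mm)
  ndof <- 3L * mesh$n_nodes
  fixed <- rep(NA_real_, ndof)
  pz <- mesh$proximal_nodes
  fixed[3 * (pz - 1) + 1] <- 0
  fixed[3 * (pz - 1) + 2] <- 0
  fixed[3 * (pz - 1) + 3] <- 0
  f <- rep(0, ndof)
  w <- mesh$distal_face_weights
  f[3 * (mesh$distal_nodes - 1) + 3] <- -spec$applied_load * w / sum(w)
  sol <- fe_cg_cpp(mesh$elems, mesh$n_nodes, Ke, fixed, f, spec$rtol,
                   fe_default_maxit(mesh, spec))
  if (!sol$converged)
    stop(sprintf("CG did not converge (relative residual %.3g after %d iterations)",
                 sol$relres, sol$iterations))
  sf <- fe_strain_field(mesh, spec, sol$u)
  lam <- fe_lambda(sf$principal, sf$considered, spec)
  if (all(!is.finite(lam)))
    stop("zero strain field: no node can reach a critical strain")
  k <- ceiling(spec$failure_node_fraction * length(lam))
  lam_k <- sort(lam)[k]
  structure(list(stiffness = NA_real_,
                 strength = spec$applied_load * lam_k,
                 u = sol$u,
                 principal_ue = sf$principal[sf$considered, , drop = FALSE],
                 considered = sf$considered,
                 iterations = sol$iterations, residual = sol$relres,
                 spec = spec, n_nodes = mesh$n_nodes,
                 n_elems = mesh$n_elems),
            class = "fe_result")
}

#' @export
print.fe_result <- function(x, ...) {
  cat("<fe_result>\n")
  if (is.finite(x$stiffness))
    cat(sprintf("  apparent stiffness: %.6g N/mm\n", x$stiffness))
  if (is.finite(x$strength))
    cat(sprintf("  strength: %.6g N\n", x$strength))
  cat(sprintf("  %d elements, %d nodes; CG %d iterations, relres %.2e\n",
              x$n_elems, x$n_nodes, x$iterations, x$residual))
  invisible(x)
}
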