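# R-level surface of the centre-based mechanical model. The relaxation loop
# and spatial-hash neighbour search live in src/mechanics.cpp; a plain
# O(N^2) force summation is kept here as the reference implementation.

#' Overlap between two soft spheres
#'
#' `delta = R1 + R2 - ||r1 - r2||`; pairs interact only when the overlap
#' exceeds `L_overlap` (0 by default, so touching cells exert no force).
#'
#' @param p1,p2 Length-3 position vectors, um.
#' @param R1,R2 Radii, um.
#' @return Overlap in um (may be negative for separated cells).
#' @examples
#' pair_overlap(c(0, 0, 0), c(8, 0, 0), 5.5, 5.5)  # 3
#' @export
pair_overlap <- function(p1, p2, R1, R2) {
  R1 + R2 - sqrt(sum((p1 - p2)^2))
}

#' Linear repulsive force magnitude
#'
#' `F = k1 * delta` with the overlap converted to metres; non-positive
#' overlap gives zero force.
#'
#' @param delta Overlap, um (vectorised).
#' @param params An `nb_params` object.
#' @return Force magnitude, N.
#' @export
repulsion_force <- function(delta, params = load_parameters()) {
  ifelse(delta > params$L_overlap, params$k1 * delta * 1e-6, 0)
}

#' Net repulsive forces on every agent
#'
#' Sums pairwise repulsions along centre-centre axes over all neighbours
#' within the search radius; the sum is multiplied by `k2` for a mobile
#' agent whose neighbour count (including itself) exceeds `N_nghbr_max`
#' (contact inhibition). `method = "hash"` uses the spatial-hash search;
#' `method = "brute"` is the O(N^2) reference used as an oracle in tests.
#'
#' @param positions n x 3 matrix, um.
#' @param radii Radii, um.
#' @param mobile Logical mobility flags (default all `TRUE`).
#' @param params An `nb_params` object.
#' @param method `"hash"` or `"brute"`.
#' @return A list: `forces` (n x 3, N), `neigh_count` (including self),
#'   `total_overlap` (um, summed over interacting pairs).
#' @export
net_forces <- function(positions, radii, mobile = NULL,
                       params = load_parameters(),
                       method = c("hash", "brute")) {
  method <- match.arg(method)
  n <- nrow(positions)
  if (is.null(mobile)) mobile <- rep(TRUE, n)
  if (method == "hash") {
    return(.cpp_net_forces(positions, radii, mobile, params$k1, params$k2,
                           params$L_nghbr, as.integer(params$N_nghbr_max),
                           params$L_overlap))
  }
  F <- matrix(0, n, 3)
  ncount <- rep(1L, n)
  total <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      dvec <- positions[i, ] - positions[j, ]
      d <- sqrt(sum(dvec^2))
      if (d > params$L_nghbr) next
      ncount[i] <- ncount[i] + 1L
      delta <- radii[i] + radii[j] - d
      if (delta <= params$L_overlap) next
      total <- total + delta / 2
      F[i, ] <- F[i, ] + params$k1 * delta * 1e-6 * dvec / d
    }
    if (mobile[i] && ncount[i] > params$N_nghbr_max) F[i, ] <- F[i, ] * params$k2
  }
  list(forces = F, neigh_count = ncount, total_overlap = total)
}

#' Overdamped Euler displacement
#'
#' Per axis, the displacement over one force-resolution step is
#' `F * dt_mech / (mu * (1 + M))`, converted to um; `M` is the matrix
#' fraction of the agent's voxel and increases the effective viscosity.
#'
#' @param forces n x 3 matrix of net forces, N.
#' @param M Matrix fraction per agent (scalar or vector).
#' @param params An `nb_params` object.
#' @return n x 3 matrix of displacements, um.
#' @export
euler_step <- function(forces, M = 0, params = load_parameters()) {
  forces * params$dt_mech / (params$mu * (1 + M)) * 1e6
}

#' Reflect out-of-domain agents back inside
#'
#' An agent beyond the current cubic boundary has its overshoot reversed
#' and scaled by `k4` (1 um beyond a face lands 2 um inside it). The domain
#' itself may only grow up to `k3` times its initial side (enforced by the
#' engine's expansion rule).
#'
#' @param positions n x 3 matrix, um.
#' @param side Current domain side, um.
#' @param params An `nb_params` object.
#' @return The corrected position matrix.
#' @export
enforce_boundary <- function(positions, side, params = load_parameters()) {
  k4 <- params$k4
  refl <- function(x) {
    x <- ifelse(x < 0, pmin(k4 * (-x), side), x)
    ifelse(x > side, pmax(side - k4 * (x - side), 0), x)
  }
  out <- positions
  for (j in seq_len(ncol(positions))) out[, j] <- refl(positions[, j])
  out
}

#' Relax an agent configuration to mechanical equilibrium
#'
#' Repeats {net forces for all agents; Euler displacement; boundary
#' enforcement} until the largest per-agent displacement in an iteration
#' falls below the tolerance or the iteration cap is reached. The cap
#' defaults to one agent-hour of 36 s force-resolution steps (100).
#'
#' @param positions n x 3 matrix, um.
#' @param radii Radii, um.
#' @param mobile Logical mobility flags (default all `TRUE`).
#' @param side Current domain side, um.
#' @param M_arr Optional 3D array of per-voxel matrix fractions (default:
#'   matrix-free everywhere).
#' @param L_voxel Voxel side matching `M_arr`, um.
#' @param params An `nb_params` object.
#' @return A list: `positions`, `iters`, `max_step_disp` (largest
#'   single-iteration displacement, um), `net_disp` (per-agent total
#'   displacement, um), `neigh_count`, `total_overlap_first`,
#'   `total_overlap_last`.
#' @export
resolve <- function(positions, radii, mobile = NULL, side,
                    M_arr = NULL, L_voxel = 30, params = load_parameters()) {
  n <- nrow(positions)
  if (is.null(mobile)) mobile <- rep(TRUE, n)
  if (is.null(M_arr)) {
    M_vec <- numeric(0)
    dims <- c(1L, 1L, 1L)
  } else {
    if (length(dim(M_arr)) != 3) stop("M_arr must be a 3D array")
    M_vec <- as.numeric(M_arr)
    dims <- as.integer(dim(M_arr))
  }
  .cpp_resolve(positions, radii, mobile, M_vec, dims, L_voxel, side,
               params$k1, params$k2, params$mu, params$dt_mech,
               params$L_nghbr, as.integer(params$N_nghbr_max),
               params$L_overlap, params$k4,
               as.integer(params$mech_max_iters), params$mech_tol)
}
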