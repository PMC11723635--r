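# Continuous automaton: a cubic voxel grid holding per-voxel cell censuses
# and the matrix fraction, plus global (spatially uniform) oxygen and
# angiogenesis bookkeeping.

.count_names <- c("nb_total", "nb_apop", "nb_necro", "nb_living",
                  "sc_total", "sc_apop", "sc_necro", "sc_living",
                  "sc_matrix_producing", "cells_total")

#' Build an empty voxel grid
#'
#' The spatial domain is a cube; each axis is divided into
#' `ceiling(domain_side / L_voxel)` voxels so the physical domain is never
#' truncated. All per-voxel state (ten cell counts and the matrix fraction)
#' starts at zero; the global oxygen and angiogenesis scalars start at their
#' neutral values and are set properly by [initialise()].
#'
#' @param domain_side Side of the cubic domain, um.
#' @param L_voxel Voxel side, um (default 30).
#' @return An `nb_grid` object.
#' @examples
#' g <- build_grid(60, 30)   # 2 x 2 x 2 voxels
#' g$dims
#' @export
build_grid <- function(domain_side, L_voxel = 30) {
  if (!is.numeric(domain_side) || domain_side <= 0 || L_voxel <= 0) {
    stop("domain_side and L_voxel must be positive")
  }
  n <- as.integer(ceiling(domain_side / L_voxel))
  dims <- c(n, n, n)
  counts <- lapply(.count_names, function(nm) array(0L, dim = dims))
  names(counts) <- .count_names
  grid <- list(
    dims = dims,
    L_voxel = L_voxel,
    side = domain_side,
    counts = counts,
    M = array(0, dim = dims),
    necro_hits = array(0L, dim = dims),
    O2 = 1,
    O2_supply = 0,
    supply0 = 0,
    static_O2 = 1L,
    angiogenesis_progress = 1,
    ang_ref = 1,
    n_vegf_producers = 0L,
    O2_conversion = NA_real_
  )
  class(grid) <- "nb_grid"
  grid
}

# voxel index per agent (1-based linear index); half-open membership
# [i*L, (i+1)*L); the top face is closed so boundary agents stay countable.
.voxel_index <- function(grid, x, y, z) {
  L <- grid$L_voxel
  d <- grid$dims
  if (length(x) == 0L) return(integer(0))
  tol <- 1e-9 * max(1, grid$side)
  if (any(x < -tol | y < -tol | z < -tol |
          x > grid$side + tol | y > grid$side + tol | z > grid$side + tol)) {
    stop("agent position outside the domain: census inconsistency")
  }
  ix <- pmin(pmax(floor(x / L), 0), d[1] - 1)
  iy <- pmin(pmax(floor(y / L), 0), d[2] - 1)
  iz <- pmin(pmax(floor(z / L), 0), d[3] - 1)
  as.integer(1 + ix + d[1] * (iy + d[2] * iz))
}

#' Recompute the per-voxel census from the agent set
#'
#' Every voxel state becomes the exact census of the agents whose centre
#' lies in it. Matrix-producing Schwann cells are the living, non-hypoxic
#' Schwann agents.
#'
#' @param grid An `nb_grid`.
#' @param agents An `nb_agents` set (see [new_agents()]).
#' @return The grid with updated counts.
#' @export
rebuild_counts <- function(grid, agents) {
  dims <- grid$dims
  nvox <- prod(dims)
  idx <- .voxel_index(grid, agents$x, agents$y, agents$z)
  tab <- function(mask) {
    array(tabulate(idx[mask], nbins = nvox), dim = dims)
  }
  nb <- agents$type == 1L
  sc <- agents$type == 2L
  liv <- agents$status == 0L
  apo <- agents$status == 1L
  nec <- agents$status == 2L
  grid$counts$nb_total <- tab(nb)
  grid$counts$nb_apop <- tab(nb & apo)
  grid$counts$nb_necro <- tab(nb & nec)
  grid$counts$nb_living <- tab(nb & liv)
  grid$counts$sc_total <- tab(sc)
  grid$counts$sc_apop <- tab(sc & apo)
  grid$counts$sc_necro <- tab(sc & nec)
  grid$counts$sc_living <- tab(sc & liv)
  grid$counts$sc_matrix_producing <- tab(sc & liv & !agents$hypoxic)
  grid$counts$cells_total <- grid$counts$nb_total + grid$counts$sc_total
  grid
}

# sum of each voxel's six orthogonal neighbours (outside-grid voxels are 0)
.neigh_sums <- function(arr) {
  d <- dim(arr)
  out <- array(0, dim = d)
  shift <- function(axis, by) {
    res <- array(0, dim = d)
    if (axis == 1L) {
      if (by == 1L) res[1:(d[1] - 1), , ] <- arr[2:d[1], , ]
      else res[2:d[1], , ] <- arr[1:(d[1] - 1), , ]
    } else if (axis == 2L) {
      if (by == 1L) res[, 1:(d[2] - 1), ] <- arr[, 2:d[2], ]
      else res[, 2:d[2], ] <- arr[, 1:(d[2] - 1), ]
    } else {
      if (by == 1L) res[, , 1:(d[3] - 1)] <- arr[, , 2:d[3]]
      else res[, , 2:d[3]] <- arr[, , 1:(d[3] - 1)]
    }
    res
  }
  for (axis in 1:3) {
    if (d[axis] > 1L) out <- out + shift(axis, 1L) + shift(axis, -1L)
  }
  out
}

#' Juxtacrine + paracrine signal in a voxel's von Neumann neighbourhood
#'
#' The signal an agent in voxel `index` receives is the juxtacrine strength
#' times the source-cell count in its own voxel plus the (ten times weaker)
#' paracrine strength times the source-cell count summed over the up-to-six
#' orthogonally adjacent voxels. Living Schwann cells source the apoptotic
#' and differentiation signals felt by neuroblasts; living neuroblasts
#' source the proliferation signal felt by Schwann cells.
#'
#' @param grid An `nb_grid` with a current census.
#' @param index Voxel linear index (1-based) or a vector of them.
#' @param kind One of `"apoptotic_nb"`, `"differentiation_nb"`,
#'   `"proliferation_sc"`.
#' @param params An `nb_params` object.
#' @return Dimensionless signal, one value per index.
#' @export
neighbourhood_signal <- function(grid, index, kind, params = load_parameters()) {
  src <- switch(kind,
    apoptotic_nb = ,
    differentiation_nb = grid$counts$sc_living,
    proliferation_sc = grid$counts$nb_living,
    stop("unknown signal kind: ", kind)
  )
  R <- switch(kind,
    apoptotic_nb = c(params$R_jux_apop_nb, params$R_para_apop_nb),
    differentiation_nb = c(params$R_jux_diff_nb, params$R_para_diff_nb),
    proliferation_sc = c(params$R_jux_pro_sc, params$R_para_pro_sc)
  )
  nbr <- .neigh_sums(src)
  R[1] * src[index] + R[2] * nbr[index]
}

#' Update the global oxygen level and supply rate
#'
#' When `static_O2 == 1` the oxygen state is frozen (the uniform,
#' well-perfused assumption). Otherwise the dimensionless oxygen level
#' integrates the supply-minus-consumption balance through a
#' moles-to-dimensionless conversion factor (set at initialisation so that
#' supply = consumption gives exactly zero drift), is floored at zero, and
#' the supply rate relaxes toward the level set by angiogenesis progress on
#' the angiogenesis time scale.
#'
#' @param grid An `nb_grid`.
#' @param total_consumption Total oxygen consumption of all living agents,
#'   moles/h (non-negative).
#' @param params An `nb_params` object.
#' @return The updated grid.
#' @export
update_oxygen <- function(grid, total_consumption, params = load_parameters()) {
  if (total_consumption < 0) stop("total_consumption must be non-negative")
  if (grid$static_O2 == 1L) return(grid)
  conv <- grid$O2_conversion
  if (is.na(conv)) conv <- 0
  grid$O2 <- max(0, grid$O2 + (grid$O2_supply - total_consumption) * conv)
  target <- grid$supply0 * grid$angiogenesis_progress
  grid$O2_supply <- grid$O2_supply + (target - grid$O2_supply) / params$Tangc
  grid
}

#' Advance angiogenesis progress
#'
#' First-order relaxation of the (dimensionless) angiogenesis progress
#' toward a target proportional to the current number of VEGF-producing
#' neuroblastoma cells, with time scale `Tangc`. Frozen when
#' `static_O2 == 1`.
#'
#' @param grid An `nb_grid` with `n_vegf_producers` current.
#' @param params An `nb_params` object.
#' @return The updated grid.
#' @export
update_angiogenesis <- function(grid, params = load_parameters()) {
  if (grid$static_O2 == 1L) return(grid)
  target <- grid$n_vegf_producers / max(1, grid$ang_ref)
  grid$angiogenesis_progress <- grid$angiogenesis_progress +
    (target - grid$angiogenesis_progress) / params$Tangc
  grid
}

#' Advance extracellular-matrix production
#'
#' Per voxel, the matrix volume fraction M grows by the collagen output of
#' its matrix-producing Schwann cells over one hour, normalised by the voxel
#' volume, capped at 1.
#'
#' @param grid An `nb_grid` with a current census.
#' @param params An `nb_params` object.
#' @return The updated grid.
#' @export
update_matrix <- function(grid, params = load_parameters()) {
  inc <- grid$counts$sc_matrix_producing * params$R_collagen / params$L_voxel^3
  grid$M <- pmin(grid$M + inc, 1)   # first arg keeps the array dim
  grid
}

# Record hits of the necrotic signal: each necrotic agent, with probability
# P_necrois, deposits one hit in every voxel of its von Neumann
# neighbourhood (its own voxel and up to six orthogonal neighbours).
.necro_emission <- function(grid, agents, params) {
  dims <- grid$dims
  hits <- array(0L, dim = dims)
  nec <- which(agents$status == 2L)
  if (length(nec)) {
    emit <- nec[stats::runif(length(nec)) < params$P_necrois]
    if (length(emit)) {
      idx <- .voxel_index(grid, agents$x[emit], agents$y[emit], agents$z[emit])
      own <- array(tabulate(idx, nbins = prod(dims)), dim = dims)
      hits <- own + .neigh_sums(own)
    }
  }
  grid$necro_hits <- hits
  grid
}

# Expand the cubic domain to new_side (<= k3 * initial side, enforced by the
# caller); per-voxel state is copied into the lower corner of the new grid.
.grid_expand <- function(grid, new_side) {
  new <- build_grid(new_side, grid$L_voxel)
  d0 <- grid$dims
  new$M[1:d0[1], 1:d0[2], 1:d0[3]] <- grid$M
  for (nm in .count_names) {
    new$counts[[nm]][1:d0[1], 1:d0[2], 1:d0[3]] <- grid$counts[[nm]]
  }
  keep <- c("O2", "O2_supply", "supply0", "static_O2",
            "angiogenesis_progress", "ang_ref", "n_vegf_producers",
            "O2_conversion")
  new[keep] <- grid[keep]
  new
}

#' Write a grid snapshot as a delimited table
#'
#' One row per voxel: indices i, j, k (zero-based) followed by the ten count
#' components and the matrix fraction.
#'
#' @param grid An `nb_grid`.
#' @param path Output CSV path.
#' @return The snapshot data.frame, invisibly.
#' @export
write_grid_snapshot <- function(grid, path) {
  d <- grid$dims
  ijk <- expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1), k = 0:(d[3] - 1))
  tab <- cbind(ijk, as.data.frame(lapply(grid$counts, as.vector)),
               M = as.vector(grid$M))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
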