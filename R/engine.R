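# Simulation engine: configuration, initialisation, the hourly step loop,
# treatment application, and seeded ensemble execution.

.histologies <- c("NB", "GNB", "nodular_GNB", "intermixed_GNB", "GN",
                  "maturing_GN", "mature_GN")
.grades <- c("undifferentiated", "poorly_differentiated", "differentiating")

#' Expected initial agent count
#'
#' `round(volume * cellularity * rho)`: the number of cells that fit in the
#' matrix-free fraction of the domain at the tissue cell density.
#'
#' @param volume Domain volume, um^3.
#' @param cellularity Fraction of the domain accessible to cells, (0, 1\].
#' @param rho Cell density in matrix-free space, 1/um^3.
#' @return Integer cell count.
#' @examples
#' initial_cell_count(8e9, 0.8)   # ~6e5 cells in an 8 mm^3 tumour
#' @export
initial_cell_count <- function(volume, cellularity, rho = 9.39e-5) {
  if (volume <= 0) stop("volume must be positive")
  round(volume * cellularity * rho)
}

#' Schwann fraction and differentiation range from histology
#'
#' Maps a histological category (and, for neuroblastoma, its grade of
#' differentiation) to a uniformly drawn Schwann-cell fraction and the
#' range from which each neuroblast's degree of differentiation is drawn.
#' Composite categories (ganglioneuroblastoma, its nodular form, and
#' ganglioneuroma) recurse to an equally likely precise category; a
#' neuroblastoma without a stated grade draws one of the three grades
#' equally.
#'
#' @param histology One of `"NB"`, `"GNB"`, `"nodular_GNB"`,
#'   `"intermixed_GNB"`, `"GN"`, `"maturing_GN"`, `"mature_GN"`.
#' @param grade For `"NB"`: `"undifferentiated"`, `"poorly_differentiated"`
#'   or `"differentiating"`.
#' @return A list: `schwann_fraction` (drawn), `deg_diff_range` (length 2),
#'   `category` (the resolved precise category).
#' @export
histology_init <- function(histology, grade = "undifferentiated") {
  if (!histology %in% .histologies) stop("unknown histology: ", histology)
  pick <- function(x) x[[sample.int(length(x), 1)]]
  while (histology %in% c("GNB", "nodular_GNB", "GN")) {
    histology <- switch(histology,
      GNB = pick(c("nodular_GNB", "intermixed_GNB")),
      nodular_GNB = pick(c("NB", "intermixed_GNB", "maturing_GN")),
      GN = pick(c("maturing_GN", "mature_GN"))
    )
  }
  if (histology == "NB") {
    if (is.null(grade) || is.na(grade)) grade <- pick(.grades)
    if (!grade %in% .grades) stop("unknown grade: ", grade)
    spec <- switch(grade,
      undifferentiated = list(sc = c(0.05, 0.17), dd = c(0, 0)),
      poorly_differentiated = list(sc = c(0.17, 0.33), dd = c(0, 0.2)),
      differentiating = list(sc = c(0.33, 0.5), dd = c(0.2, 0.4))
    )
    cat_name <- paste0("NB_", grade)
  } else {
    spec <- switch(histology,
      intermixed_GNB = list(sc = c(0.5, 0.67), dd = c(0.4, 0.6)),
      maturing_GN = list(sc = c(0.67, 0.83), dd = c(0.6, 0.8)),
      mature_GN = list(sc = c(0.83, 0.95), dd = c(0.8, 1.0))
    )
    cat_name <- histology
  }
  list(schwann_fraction = stats::runif(1, spec$sc[1], spec$sc[2]),
       deg_diff_range = spec$dd,
       category = cat_name)
}

#' Assign subclones from a clonal composition
#'
#' Divides \[0, 1) into 24 subintervals with widths equal to the cumulative
#' composition; each agent draws u ~ U(0, 1) and joins the subclone of the
#' containing subinterval.
#'
#' @param n_agents Number of NB agents.
#' @param clonal_composition 24 non-negative fractions summing to 1.
#' @return Integer vector of subclone ids.
#' @export
assign_clones <- function(n_agents, clonal_composition) {
  if (length(clonal_composition) != 24 ||
      abs(sum(clonal_composition) - 1) > 1e-9 ||
      any(clonal_composition < 0)) {
    stop("clonal_composition must be 24 non-negative fractions summing to 1")
  }
  cum <- cumsum(clonal_composition)
  u <- stats::runif(n_agents)
  pmin(findInterval(u, cum, left.open = TRUE) + 1L, 24L)
}

#' Treatment schedules
#'
#' `treatment_none()` applies no inhibition. `treatment_chemo()` inhibits
#' the six chemotherapy targets (CHK1, JAB1, HIF, MYCN, telomerase, p53)
#' with the given probabilities during the active windows; the default
#' schedule mirrors two-week cycles over the 3024 h run. A drug
#' combination, `treatment_drug_combination()`, is a vector of 20
#' inhibition probabilities applied at every step.
#'
#' @param windows List of `c(start, end)` hour pairs during which
#'   chemotherapy is active.
#' @param probs Named inhibition probabilities on the six chemo targets.
#' @param combination 20 probabilities (in [gene_products()] order).
#' @return A `treatment_schedule` list.
#' @name treatments
NULL

.chemo_targets <- c("CHK1", "JAB1", "HIF", "MYCN", "TELOMERASE", "p53")

#' @rdname treatments
#' @export
treatment_none <- function() {
  structure(list(mode = "none"), class = "treatment_schedule")
}

#' @rdname treatments
#' @export
treatment_chemo <- function(windows = NULL,
                            probs = stats::setNames(rep(0.5, 6), .chemo_targets)) {
  if (is.null(windows)) {
    starts <- seq(0, 3024 - 336, by = 336)          # eight two-week cycles
    windows <- lapply(starts, function(s) c(s, s + 120))
  }
  if (!setequal(names(probs), .chemo_targets)) {
    stop("chemo probabilities must be named exactly: ",
         paste(.chemo_targets, collapse = ", "))
  }
  if (any(probs < 0 | probs > 1)) stop("chemo probabilities must be in [0,1]")
  structure(list(mode = "chemo", windows = windows, probs = probs),
            class = "treatment_schedule")
}

#' @rdname treatments
#' @export
treatment_drug_combination <- function(combination) {
  if (length(combination) != 20 || any(combination < 0 | combination > 1)) {
    stop("a drug combination is 20 probabilities in [0,1]")
  }
  structure(list(mode = "drug_combination",
                 combination = stats::setNames(as.numeric(combination),
                                               gene_products())),
            class = "treatment_schedule")
}

#' Inhibition vector active at time t
#'
#' @param schedule A `treatment_schedule`.
#' @param t Current hour.
#' @return A list: `inhibition` (named 20-vector) and `chemo_active` flag.
#' @export
apply_treatment <- function(schedule, t) {
  inh <- stats::setNames(rep(0, 20), gene_products())
  chemo <- FALSE
  if (schedule$mode == "chemo") {
    chemo <- any(vapply(schedule$windows,
                        function(w) t >= w[1] && t < w[2], logical(1)))
    if (chemo) inh[names(schedule$probs)] <- schedule$probs
  } else if (schedule$mode == "drug_combination") {
    inh <- schedule$combination
  }
  list(inhibition = inh, chemo_active = chemo)
}

#' Build a simulation configuration
#'
#' Defaults reproduce the reference study conditions: an 8 mm^3 cube at
#' cellularity 0.8 (about 6e5 agents), undifferentiated neuroblastoma
#' histology, a uniform 24-subclone composition, static uniform oxygen at
#' the reference scale, no treatment, and 3024 one-hour steps (the
#' induction-chemotherapy time scale). Reduced runs scale
#' `initial_volume` and `n_steps` down.
#'
#' @param n_steps Number of one-hour steps.
#' @param initial_volume Domain volume, um^3.
#' @param cellularity Fraction of the domain accessible to cells.
#' @param histology,grade Histological category/grade (see
#'   [histology_init()]).
#' @param schwann_fraction Optional explicit Schwann fraction (overrides
#'   histology).
#' @param deg_diff_range Optional explicit differentiation range.
#' @param clonal_composition 24 fractions summing to 1.
#' @param O2_init Initial dimensionless oxygen level.
#' @param static_O2 1 = frozen uniform oxygen; 0 = dynamic supply/consumption.
#' @param treatment A `treatment_schedule`.
#' @param seed Integer run seed.
#' @param params An `nb_params` object or a named list of overrides.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_steps = 3024, initial_volume = 8e9,
                              cellularity = 0.8, histology = "NB",
                              grade = "undifferentiated",
                              schwann_fraction = NULL,
                              deg_diff_range = NULL,
                              clonal_composition = rep(1 / 24, 24),
                              O2_init = 1, static_O2 = 1,
                              treatment = treatment_none(), seed = 1,
                              params = load_parameters()) {
  if (!inherits(params, "nb_params")) params <- load_parameters(params)
  if (cellularity <= 0 || cellularity > 1) stop("cellularity must be in (0,1]")
  if (abs(sum(clonal_composition) - 1) > 1e-9) {
    stop("clonal_composition must sum to 1")
  }
  structure(list(
    n_steps = n_steps, initial_volume = initial_volume,
    cellularity = cellularity, histology = histology, grade = grade,
    schwann_fraction = schwann_fraction, deg_diff_range = deg_diff_range,
    clonal_composition = clonal_composition, O2_init = O2_init,
    static_O2 = as.integer(static_O2), treatment = treatment,
    seed = as.integer(seed), params = params
  ), class = "simulation_config")
}

#' Reduced nominal benchmark configuration
#'
#' A desk-scale rendition of the default study conditions used to audit the
#' mechanical model: an undifferentiated neuroblastoma at cellularity 0.8
#' with the default parameter tables, static uniform oxygen at the
#' reference scale and no treatment, sized so the domain holds about
#' `n_agents` cells and run for `hours` one-hour steps.
#'
#' @param n_agents Approximate number of agents (sets the domain volume).
#' @param hours Number of one-hour steps.
#' @param seed Integer run seed.
#' @return A `simulation_config`.
#' @export
nominal_config <- function(n_agents = 5000, hours = 200, seed = 1) {
  params <- load_parameters()
  vol <- n_agents / (0.8 * params$rho)
  simulation_config(n_steps = hours, initial_volume = vol, cellularity = 0.8,
                    histology = "NB", grade = "undifferentiated",
                    O2_init = 1, static_O2 = 1, treatment = treatment_none(),
                    seed = seed, params = params)
}

#' Initialise a simulation state
#'
#' Creates the agents (count from [initial_cell_count()]; types, subclones
#' and differentiation from the histology and clonal composition), places
#' them uniformly at random in the cubic domain, relaxes the configuration
#' with the mechanical model, builds and censuses the voxel grid, and sets
#' the oxygen supply rate equal to the populations' initial consumption
#' rate (so the initial oxygen balance is exactly zero).
#'
#' @param config A `simulation_config`.
#' @return An `nb_state` list (`agents`, `grid`, `params`, `config`, `t`,
#'   bookkeeping fields).
#' @export
initialise <- function(config) {
  params <- config$params
  set.seed(config$seed)
  n_total <- initial_cell_count(config$initial_volume, config$cellularity,
                                params$rho)
  if (is.null(config$schwann_fraction)) {
    h <- histology_init(config$histology, config$grade)
    sc_frac <- h$schwann_fraction
    dd_range <- if (is.null(config$deg_diff_range)) h$deg_diff_range
                else config$deg_diff_range
  } else {
    sc_frac <- config$schwann_fraction
    dd_range <- if (is.null(config$deg_diff_range)) c(0, 0)
                else config$deg_diff_range
  }
  n_sc <- round(sc_frac * n_total)
  n_nb <- n_total - n_sc
  side <- config$initial_volume^(1 / 3)

  pos <- matrix(stats::runif(3 * n_total, 0, side), ncol = 3)
  type <- c(rep("NB", n_nb), rep("SC", n_sc))
  sub <- rep(NA_integer_, n_total)
  sub[seq_len(n_nb)] <- assign_clones(n_nb, config$clonal_composition)
  dd <- numeric(n_total)
  dd[seq_len(n_nb)] <- stats::runif(n_nb, dd_range[1], dd_range[2])
  agents <- new_agents(n_total, type = type,
                       subclone = ifelse(is.na(sub), 1L, sub),
                       position = pos, deg_diff = dd, params = params)
  agents$subclone <- sub

  rel <- resolve(cbind(agents$x, agents$y, agents$z), agents$radius,
                 side = side, params = params)
  agents$x <- rel$positions[, 1]
  agents$y <- rel$positions[, 2]
  agents$z <- rel$positions[, 3]
  agents$neigh_count <- rel$neigh_count

  grid <- build_grid(side, params$L_voxel)
  grid$static_O2 <- config$static_O2
  grid$O2 <- config$O2_init
  grid <- rebuild_counts(grid, agents)
  consumption <- sum(agents$status == 0L) * abs(params$RO20)
  grid$O2_supply <- consumption
  grid$supply0 <- consumption
  grid$angiogenesis_progress <- 1
  grid$ang_ref <- max(1, sum(agents$status == 0L & agents$type == 1L))
  grid$O2_conversion <- if (is.na(params$O2_conversion)) {
    1 / max(consumption * params$Tangc, .Machine$double.eps)
  } else params$O2_conversion

  structure(list(
    agents = agents, grid = grid, params = params, config = config,
    t = 0L, side0 = side, side = side, init_iters = rel$iters
  ), class = "nb_state")
}

# domain expansion: when the agent count exceeds the capacity of the
# matrix-free space at density rho, grow the cube (up to k3 x initial side)
.maybe_expand <- function(state) {
  params <- state$params
  capacity <- params$rho * state$config$cellularity * state$side^3
  n <- n_agents(state$agents)
  if (n > capacity && state$side < params$k3 * state$side0) {
    new_side <- min(params$k3 * state$side0,
                    state$side * (n / capacity)^(1 / 3))
    state$grid <- .grid_expand(state$grid, new_side)
    state$side <- new_side
  }
  state
}

#' Advance a simulation state by one hour
#'
#' Implements the fixed event order of one time step: neuroblast agents are
#' evaluated (sense; gene products; telomere maintenance; DNA;
#' differentiation; death and removal; cycle attempt; division), then
#' Schwann agents likewise (no gene products, no differentiation), then the
#' mechanical model is relaxed, and finally the continuous automaton is
#' updated (census, necrotic-signal emission, oxygen, angiogenesis,
#' matrix). All agents sense the census recorded at the end of the previous
#' step; daughters created mid-step are first evaluated in the next step.
#'
#' @param state An `nb_state`.
#' @return The advanced state, with `last_events` (birth/death/removal
#'   counters) and `last_mech` (relaxation diagnostics) attached.
#' @export
step <- function(state) {
  params <- state$params
  agents <- state$agents
  grid <- state$grid
  treatment <- apply_treatment(state$config$treatment, state$t)

  stim <- sense(agents, grid, treatment, params)
  agents <- update_gene_products(agents, stim, params)
  agents <- update_telomeres(agents, params)
  agents <- update_dna(agents, stim, params)
  agents <- update_differentiation(agents, stim, params)
  dth <- update_death(agents, stim, grid$O2, params)
  agents <- dth$agents
  # per-agent stimulus fields must follow the survivors
  surv <- match(agents$id, state$agents$id)
  stim2 <- stim
  for (nm in c("hypoxic", "nourished", "apop_signal_nb", "diff_signal_nb",
               "pro_signal_sc", "necrotic_signal_hits")) {
    stim2[[nm]] <- stim[[nm]][surv]
  }
  cyc <- attempt_cycle(agents, stim2, params)
  div <- divide_agents(cyc$agents, cyc$divide, params)
  agents <- div$agents

  state$agents <- agents
  state <- .maybe_expand(state)
  grid <- state$grid

  rel <- resolve(cbind(agents$x, agents$y, agents$z), agents$radius,
                 agents$mobile, side = state$side, M_arr = grid$M,
                 L_voxel = params$L_voxel, params = params)
  agents$x <- rel$positions[, 1]
  agents$y <- rel$positions[, 2]
  agents$z <- rel$positions[, 3]
  agents$neigh_count <- rel$neigh_count
  state$agents <- agents

  grid <- rebuild_counts(grid, agents)
  grid <- .necro_emission(grid, agents, params)
  consumption <- sum(agents$status == 0L) * abs(params$RO20)
  grid$n_vegf_producers <- sum(agents$type == 1L & agents$status == 0L &
                                 agents$gp[, "VEGF"])
  grid <- update_oxygen(grid, consumption, params)
  grid <- update_angiogenesis(grid, params)
  grid <- update_matrix(grid, params)
  state$grid <- grid

  state$t <- state$t + 1L
  state$last_events <- list(births = div$births, died = dth$events$died,
                            revived = dth$events$revived,
                            removed = dth$events$removed)
  state$last_mech <- rel
  state
}

# one summary row of the state
.series_row <- function(state, mech = NULL) {
  a <- state$agents
  nb <- a$type == 1L
  liv <- a$status == 0L
  per_sub <- tabulate(a$subclone[nb & liv], nbins = 24L)
  row <- data.frame(
    t = state$t,
    nb_living = sum(nb & liv), nb_apop = sum(nb & a$status == 1L),
    nb_necro = sum(nb & a$status == 2L),
    sc_living = sum(!nb & liv), sc_apop = sum(!nb & a$status == 1L),
    sc_necro = sum(!nb & a$status == 2L),
    mean_deg_diff = if (any(nb & liv)) mean(a$deg_diff[nb & liv]) else NA_real_,
    O2 = state$grid$O2, side = state$side,
    mech_iters = if (is.null(mech)) NA_integer_ else mech$iters,
    max_iter_disp = if (is.null(mech)) NA_real_ else mech$max_step_disp,
    max_hour_disp = if (is.null(mech)) NA_real_ else max(c(mech$net_disp, 0))
  )
  names(per_sub) <- paste0("nb_living_s", 1:24)
  cbind(row, as.data.frame(as.list(per_sub)))
}

#' Run one realisation of the stochastic process
#'
#' Initialises from the configuration (seeded) and iterates [step()] for
#' `n_steps` hours, recording the population time series, per-step
#' mechanics diagnostics and per-subclone event counters.
#'
#' @param config A `simulation_config`.
#' @return An `nb_run` list: `series` (data.frame, one row per step
#'   including step 0), `counters` (list of step x 25 matrices: births,
#'   died, revived, removed; columns 1..24 are subclones, 25 is Schwann),
#'   `final_state`, `config`.
#' @export
run <- function(config) {
  state <- initialise(config)
  rows <- vector("list", config$n_steps + 1L)
  rows[[1]] <- .series_row(state)
  counters <- list(births = NULL, died = NULL, revived = NULL, removed = NULL)
  cmat <- matrix(0L, nrow = config$n_steps, ncol = 25)
  counters <- list(births = cmat, died = cmat, revived = cmat, removed = cmat)
  for (k in seq_len(config$n_steps)) {
    state <- step(state)
    rows[[k + 1L]] <- .series_row(state, state$last_mech)
    for (nm in names(counters)) {
      counters[[nm]][k, ] <- state$last_events[[nm]]
    }
  }
  structure(list(series = do.call(rbind, rows), counters = counters,
                 final_state = state, config = config),
            class = "nb_run")
}

#' Run a seeded ensemble
#'
#' Independent realisations of one configuration with distinct seeds
#' (default 10 runs). The ensemble summary is the arithmetic mean of the
#' final per-subclone living NB counts and the final Schwann count.
#'
#' @param config A `simulation_config`.
#' @param n_runs Number of realisations.
#' @param seeds Integer seeds, one per run (default `config$seed + 0:(n-1)`).
#' @return An `nb_ensemble` list: `runs`, `mean_final_subclones` (24),
#'   `mean_final_sc`, `mean_final_nb_living`, `outcomes`.
#' @export
run_ensemble <- function(config, n_runs = 10, seeds = NULL) {
  if (is.null(seeds)) seeds <- config$seed + seq_len(n_runs) - 1L
  if (anyDuplicated(seeds)) warning("duplicate seeds in ensemble")
  runs <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    cfg <- config
    cfg$seed <- as.integer(seeds[i])
    runs[[i]] <- run(cfg)
  }
  finals <- t(vapply(runs, function(r) {
    last <- r$series[nrow(r$series), ]
    as.numeric(last[paste0("nb_living_s", 1:24)])
  }, numeric(24)))
  structure(list(
    runs = runs,
    mean_final_subclones = colMeans(finals),
    mean_final_sc = mean(vapply(runs, function(r)
      r$series$sc_living[nrow(r$series)], numeric(1))),
    mean_final_nb_living = mean(rowSums(finals)),
    outcomes = vapply(runs, classify_run, character(1))
  ), class = "nb_ensemble")
}

#' Write the run time series as a delimited table
#' @param x An `nb_run`.
#' @param path Output CSV path.
#' @return The series data.frame, invisibly.
#' @export
write_timeseries <- function(x, path) {
  utils::write.csv(x$series, path, row.names = FALSE)
  invisible(x$series)
}

#' Write the global run-state record as JSON
#' @param state An `nb_state`.
#' @param path Output JSON path.
#' @return The record, invisibly.
#' @export
write_run_state <- function(state, path) {
  rec <- list(
    t = state$t, side = state$side, side0 = state$side0,
    O2 = state$grid$O2, O2_supply = state$grid$O2_supply,
    angiogenesis_progress = state$grid$angiogenesis_progress,
    n_vegf_producers = state$grid$n_vegf_producers,
    n_agents = n_agents(state$agents), seed = state$config$seed
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(rec)
}
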