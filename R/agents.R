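# Neuroblastoma and Schwann cell agents. The agent set is a list of
# parallel vectors (one entry per agent) plus an n x 20 logical matrix of
# gene-product activity. All update operations are vectorised over agents;
# within one time step every agent senses the census recorded at the end of
# the previous step, so the vectorised update reproduces the serial
# evaluation order exactly (daughters created mid-step are not re-evaluated
# until the next step).
#
# Encodings: type 1 = neuroblast (NB), 2 = Schwann (SC);
# status 0 = living, 1 = apoptotic, 2 = necrotic;
# phase 1..4 = G1, S, G2, M; dna 0 = normal, 1 = damaged, 2 = unreplicated.

.phase_names <- c("G1", "S", "G2", "M")
.dna_names <- c("normal", "damaged", "unreplicated")
.status_names <- c("living", "apoptotic", "necrotic")

#' Create a set of cell agents
#'
#' Agents start at the beginning of G1 (phase clock 0, radius `L_cell / 2`),
#' with full-length telomeres, normal DNA, and all gene products inactive;
#' mutation flags are expanded from the subclone id via
#' [subclone_profile()]. Schwann agents carry no subclone, no degree of
#' differentiation, and no gene products.
#'
#' @param n Number of agents.
#' @param type `"NB"` or `"SC"` (recycled).
#' @param subclone Subclone id 1..24 for NB agents (recycled; ignored for SC).
#' @param position Optional n x 3 matrix of coordinates, um; defaults to the
#'   origin voxel corner region (all zeros).
#' @param deg_diff Initial degree of differentiation in \[0, 1\] (NB only).
#' @param phase,clock,telomere,dna,status,apop_timer Initial cellular state
#'   (recycled); see Details for encodings.
#' @param params An `nb_params` object.
#' @return An `nb_agents` object.
#' @export
new_agents <- function(n, type = "NB", subclone = 1L, position = NULL,
                       deg_diff = 0, phase = "G1", clock = 0,
                       telomere = NULL, dna = "normal", status = "living",
                       apop_timer = 0, params = load_parameters()) {
  if (is.null(telomere)) telomere <- params$N_telo_max
  if (is.null(position)) position <- matrix(0, nrow = n, ncol = 3)
  type_i <- rep_len(ifelse(type == "NB", 1L, 2L), n)
  sub <- rep_len(as.integer(subclone), n)
  sub[type_i == 2L] <- NA_integer_
  prof <- subclone_profile(ifelse(is.na(sub), 1L, sub))
  agents <- list(
    id = seq_len(n),
    type = type_i,
    subclone = sub,
    x = rep_len(position[, 1], n),
    y = rep_len(position[, 2], n),
    z = rep_len(position[, 3], n),
    radius = rep(params$L_cell / 2, n),
    mobile = rep(TRUE, n),
    neigh_count = rep(1L, n),
    phase = rep_len(match(phase, .phase_names), n),
    clock = rep_len(as.numeric(clock), n),
    deg_diff = ifelse(type_i == 1L, rep_len(as.numeric(deg_diff), n), 0),
    status = rep_len(match(status, .status_names) - 1L, n),
    apop_timer = rep_len(as.numeric(apop_timer), n),
    telomere = rep_len(as.integer(telomere), n),
    dna = rep_len(match(dna, .dna_names) - 1L, n),
    hypoxic = rep(FALSE, n),
    atp = rep(TRUE, n),
    MYCN_amp = prof$MYCN_amp & type_i == 1L,
    TERT_rearr = prof$TERT_rearr & type_i == 1L,
    ATRX_inact = prof$ATRX_inact & type_i == 1L,
    ALK_mut = (prof$ALK == "activated_amplified") & type_i == 1L,
    other_MAPK_mut = prof$other_MAPK_mut & type_i == 1L,
    p53_inact = prof$p53_inact & type_i == 1L,
    gp = matrix(FALSE, nrow = n, ncol = 20,
                dimnames = list(NULL, gene_products())),
    next_id = n + 1L
  )
  class(agents) <- "nb_agents"
  agents
}

#' Number of agents in a set
#' @param agents An `nb_agents` object.
#' @return Integer count.
#' @export
n_agents <- function(agents) length(agents$id)

# keep a subset of agents (used for removal)
.subset_agents <- function(agents, keep) {
  nid <- agents$next_id
  for (nm in names(agents)) {
    if (nm == "gp") agents$gp <- agents$gp[keep, , drop = FALSE]
    else if (nm != "next_id") agents[[nm]] <- agents[[nm]][keep]
  }
  agents$next_id <- nid
  agents
}

#' Build a stimulus bundle directly
#'
#' Convenience constructor for driving single update operations outside a
#' full simulation (signals and flags recycled to `n`).
#'
#' @param n Number of agents the bundle addresses.
#' @param hypoxic,nourished Logical state flags.
#' @param chemo_active Whether a chemotherapy window is active.
#' @param drug_inhibition Named 20-vector of per-product inhibition
#'   probabilities (default all zero).
#' @param apop_signal_nb,diff_signal_nb,pro_signal_sc Dimensionless signals.
#' @param necrotic_signal_hits Necrotic-signal hit counts.
#' @return A `stimuli` list.
#' @export
stimulus_bundle <- function(n, hypoxic = FALSE, nourished = TRUE,
                            chemo_active = FALSE,
                            drug_inhibition = NULL,
                            apop_signal_nb = 0, diff_signal_nb = 0,
                            pro_signal_sc = 0, necrotic_signal_hits = 0) {
  if (is.null(drug_inhibition)) {
    drug_inhibition <- stats::setNames(rep(0, 20), gene_products())
  }
  list(
    hypoxic = rep_len(hypoxic, n),
    nourished = rep_len(nourished, n),
    chemo_active = isTRUE(chemo_active),
    drug_inhibition = drug_inhibition,
    apop_signal_nb = rep_len(apop_signal_nb, n),
    diff_signal_nb = rep_len(diff_signal_nb, n),
    pro_signal_sc = rep_len(pro_signal_sc, n),
    necrotic_signal_hits = rep_len(necrotic_signal_hits, n)
  )
}

#' Sense the microenvironment
#'
#' Integrates, for every agent at once, the stimuli it perceives: whether it
#' is hypoxic (oxygen below the hypoxia fraction of the reference scale),
#' whether it is nourished (oxygen available, or glycolysis-only ATP above
#' the threshold), the juxtacrine/paracrine signals from its von Neumann
#' neighbourhood, the necrotic-signal hits in its voxel, and the active drug
#' inhibition vector.
#'
#' @param agents An `nb_agents` set.
#' @param grid An `nb_grid` with a current census.
#' @param treatment Output of [apply_treatment()] (default: no treatment).
#' @param params An `nb_params` object.
#' @return A `stimuli` list (see [stimulus_bundle()]).
#' @export
sense <- function(agents, grid, treatment = NULL, params = load_parameters()) {
  n <- n_agents(agents)
  if (is.null(treatment)) {
    treatment <- list(inhibition = stats::setNames(rep(0, 20), gene_products()),
                      chemo_active = FALSE)
  }
  hyp <- grid$O2 < params$hypoxia_frac
  nour <- if (grid$O2 > 0) TRUE else params$R_glycolysis >= params$atp_threshold
  idx <- .voxel_index(grid, agents$x, agents$y, agents$z)
  sc_nbr <- .neigh_sums(grid$counts$sc_living)
  nb_nbr <- .neigh_sums(grid$counts$nb_living)
  sc_own <- grid$counts$sc_living[idx]
  nb_own <- grid$counts$nb_living[idx]
  list(
    hypoxic = rep(hyp, n),
    nourished = rep(nour, n),
    chemo_active = isTRUE(treatment$chemo_active),
    drug_inhibition = treatment$inhibition,
    apop_signal_nb = params$R_jux_apop_nb * sc_own +
      params$R_para_apop_nb * sc_nbr[idx],
    diff_signal_nb = params$R_jux_diff_nb * sc_own +
      params$R_para_diff_nb * sc_nbr[idx],
    pro_signal_sc = params$R_jux_pro_sc * nb_own +
      params$R_para_pro_sc * nb_nbr[idx],
    necrotic_signal_hits = as.numeric(grid$necro_hits[idx])
  )
}

#' Update the 20-gene-product Bernoulli layer
#'
#' Each product becomes active this hour iff its regulatory conditions hold,
#' a Bernoulli trial at its expression level succeeds, and no inhibition
#' draw (from the active drug combination or chemotherapy) vetoes it.
#' Products whose conditions are violated are inactive this hour. The
#' conditional structure follows the mutation-dependent wiring of the
#' regulatory layer (see the methods vignette for the full rule table):
#' MYCN activity depends on MYCN amplification and ALK status; MAPK/RAS
#' activity on the mutation state of the pathway; p53 is disabled by the
#' inactivating mutation and damped by active MYCN in a MYCN-amplified cell;
#' CHK1/CDS1 respond to DNA state; p73, p21/p27, CDC25C, CAS, HIF targets,
#' ID2 and the telomere-maintenance flags follow their upstream regulators.
#' Only NB agents carry gene products; SC rows are untouched.
#'
#' @param agents An `nb_agents` set.
#' @param stimuli A `stimuli` list from [sense()] or [stimulus_bundle()].
#' @param params An `nb_params` object.
#' @return The agent set with an updated `gp` matrix and ATP flags.
#' @export
update_gene_products <- function(agents, stimuli, params = load_parameters()) {
  n <- n_agents(agents)
  live_nb <- agents$type == 1L & agents$status == 0L
  gp <- agents$gp
  inh <- stimuli$drug_inhibition
  bern <- function(p) stats::runif(n) < p
  draw <- function(name, eligible, prob) {
    eligible & bern(prob) & !bern(inh[[name]]) & live_nb
  }

  # upstream-to-downstream within the hour
  e_mycn <- ifelse(agents$MYCN_amp & agents$ALK_mut,
                   params$E_MYCN, params$E_MYCN_other)
  gp[, "MYCN"] <- draw("MYCN", TRUE, e_mycn)
  e_mr <- ifelse(agents$MYCN_amp, params$E_MR1,
                 ifelse(agents$ALK_mut | agents$other_MAPK_mut,
                        params$E_MR2, params$E_MR_wt))
  gp[, "MAPK_RAS"] <- draw("MAPK_RAS", TRUE, e_mr)
  gp[, "JAB1"] <- draw("JAB1", TRUE, params$E_JAB1)
  gp[, "HIF"] <- draw("HIF", stimuli$hypoxic, params$E_HIF)
  gp[, "BNIP3"] <- draw("BNIP3", gp[, "HIF"], params$E_BNIP3)
  gp[, "IAP2"] <- draw("IAP2", gp[, "HIF"], params$E_IAP2)
  gp[, "VEGF"] <- draw("VEGF", gp[, "HIF"], params$E_VEGF)
  e_p53 <- ifelse(agents$MYCN_amp & gp[, "MYCN"],
                  params$E_p53 / 2, params$E_p53)
  gp[, "p53"] <- draw("p53", !agents$p53_inact, e_p53)
  gp[, "CHK1"] <- draw("CHK1", agents$dna != 0L, params$E_CHK1)
  gp[, "p73"] <- draw("p73", gp[, "CHK1"], params$E_p73)
  gp[, "CDS1"] <- draw("CDS1", agents$dna == 2L, params$E_CDS1)
  gp[, "CDC25C"] <- draw("CDC25C", !gp[, "CHK1"] & !gp[, "CDS1"],
                         params$E_CDC25C)
  gp[, "p21"] <- draw("p21", gp[, "p53"], params$E_p21)
  gp[, "p27"] <- draw("p27", gp[, "p53"], params$E_p27)
  gp[, "BCL"] <- draw("BCL", !gp[, "BNIP3"], params$E_Bcl)
  gp[, "BAK_BAX"] <- draw("BAK_BAX", TRUE, params$E_BAX_BAK)
  gp[, "CAS"] <- draw("CAS",
                      (gp[, "p53"] | gp[, "p73"]) & !gp[, "BCL"] &
                        (gp[, "BAK_BAX"] | stimuli$apop_signal_nb > 0),
                      params$E_CAS)
  gp[, "ID2"] <- draw("ID2", gp[, "MYCN"], params$E_ID2)
  gp[, "TELOMERASE"] <- draw("TELOMERASE",
                             agents$TERT_rearr | gp[, "MYCN"], 1)
  gp[, "ALT"] <- draw("ALT", agents$ATRX_inact, 1)

  agents$gp <- gp
  agents$hypoxic <- stimuli$hypoxic
  agents$atp <- stimuli$nourished
  agents
}

#' Update DNA status
#'
#' Normal DNA is damaged with probability `P_DNA_h` per hour under hypoxia
#' and `P_DNA_c` during an active chemotherapy window in S phase, or becomes
#' unreplicated with `P_unrep_h` under hypoxia in S phase (damage takes
#' priority when both fire). NB agents repair impaired DNA in any hour in
#' which p53 or p73 is active; Schwann agents repair damaged and
#' unreplicated DNA with probabilities `P_DNA_r1` and `P_DNA_r2`.
#'
#' @inheritParams update_gene_products
#' @return The agent set with updated `dna`.
#' @export
update_dna <- function(agents, stimuli, params = load_parameters()) {
  n <- n_agents(agents)
  live <- agents$status == 0L
  dna <- agents$dna
  normal <- live & dna == 0L
  u <- stats::runif
  p_dam <- ifelse(stimuli$hypoxic, params$P_DNA_h, 0)
  p_dam <- p_dam + ifelse(stimuli$chemo_active & agents$phase == 2L,
                          (1 - p_dam) * params$P_DNA_c, 0)
  dam <- normal & u(n) < p_dam
  p_unr <- ifelse(stimuli$hypoxic & agents$phase == 2L,
                  params$P_unrep_h, params$P_unrep)
  unr <- normal & !dam & u(n) < p_unr
  dna[dam] <- 1L
  dna[unr] <- 2L
  # repair
  nb <- agents$type == 1L
  nb_fix <- live & nb & dna != 0L & (agents$gp[, "p53"] | agents$gp[, "p73"])
  dna[nb_fix] <- 0L
  sc <- agents$type == 2L
  sc_fix1 <- live & sc & dna == 1L & u(n) < params$P_DNA_r1
  sc_fix2 <- live & sc & dna == 2L & u(n) < params$P_DNA_r2
  dna[sc_fix1 | sc_fix2] <- 0L
  agents$dna <- dna
  agents
}

#' Advance differentiation
#'
#' Living NB agents differentiate at the hourly rate times the
#' Schwann-derived differentiation signal, capped at 1.
#'
#' @inheritParams update_gene_products
#' @return The agent set with updated `deg_diff`.
#' @export
update_differentiation <- function(agents, stimuli, params = load_parameters()) {
  m <- agents$type == 1L & agents$status == 0L
  agents$deg_diff[m] <- pmin(1, agents$deg_diff[m] +
                               params$R_diff * stimuli$diff_signal_nb[m])
  agents
}

# necrosis dose-response: entry probability per hour at oxygen concentration
# C (mmHg); calibrated so entry at CO2_50 equals the recovery probability
# and the two-state balance sits at 50% necrotic.
necrosis_probability <- function(C, params = load_parameters()) {
  pmin(1, 2 * params$P_necro_r / (1 + (C / params$CO2_50)^4))
}

#' Update death state (apoptosis, necrosis, removal)
#'
#' Living agents initiate apoptosis when CAS is active, with probability
#' `P_apop` when their DNA is damaged, or by a Bernoulli trial at the
#' Schwann-derived apoptotic signal (NB only); they initiate necrosis with
#' an oxygen-dependent hourly probability (50% steady-state necrotic at the
#' half-necrosis concentration) or through necrotic-signal hits. Apoptosis
#' reverts with `P_apop_r` per hour while the apoptosis clock is below
#' `T_apop`, after which it is irreversible; an apoptotic cell undergoes
#' secondary necrosis with `P_necro_2`; necrosis reverts with `P_necro_r`.
#' Apoptotic or necrotic agents are removed with `P_lysis` per hour.
#'
#' @inheritParams update_gene_products
#' @param O2 Global dimensionless oxygen level (on the reference scale).
#' @return A list: `agents` (survivors), `events` (per-subclone counts of
#'   living-to-dead transitions, dead-to-living reversions and removals,
#'   each a 25-vector: subclones 1..24 then Schwann).
#' @export
update_death <- function(agents, stimuli, O2, params = load_parameters()) {
  n <- n_agents(agents)
  u <- stats::runif
  status <- agents$status
  nb <- agents$type == 1L
  live <- status == 0L

  C <- O2 * params$CO2s
  p_nec <- necrosis_probability(C, params)
  p_sig <- 1 - (1 - params$P_necro_sig)^stimuli$necrotic_signal_hits
  go_nec <- live & (u(n) < p_nec | u(n) < p_sig)
  cas <- nb & agents$gp[, "CAS"]
  go_apop <- live & !go_nec &
    (cas |
       (agents$dna == 1L & u(n) < params$P_apop) |
       (nb & u(n) < pmin(1, stimuli$apop_signal_nb)))

  was_apop <- status == 1L
  was_nec <- status == 2L
  apop_revert <- was_apop & agents$apop_timer < params$T_apop &
    u(n) < params$P_apop_r
  apop_to_nec <- was_apop & !apop_revert & u(n) < params$P_necro_2
  nec_revert <- was_nec & u(n) < params$P_necro_r

  status[go_apop] <- 1L
  status[go_nec] <- 2L
  status[apop_revert | nec_revert] <- 0L
  status[apop_to_nec] <- 2L
  timer <- agents$apop_timer
  timer[was_apop & !apop_revert] <- timer[was_apop & !apop_revert] + 1
  timer[apop_revert | go_apop] <- 0
  agents$apop_timer <- timer
  agents$status <- status

  removed <- status != 0L & u(n) < params$P_lysis

  bucket <- as.integer(ifelse(nb, agents$subclone, 25L))
  count_by <- function(mask) tabulate(bucket[mask], nbins = 25L)
  events <- list(
    died = count_by(go_apop | go_nec),
    revived = count_by(apop_revert | nec_revert),
    removed = count_by(removed)
  )
  list(agents = .subset_agents(agents, !removed), events = events)
}

#' Hourly telomere maintenance
#'
#' If telomerase or the ALT pathway is active, the telomere count increases
#' by one with probability `P_telo_r`, capped at the maximum length.
#' (Division-time shortening is handled by [divide_agents()].)
#'
#' @param agents An `nb_agents` set.
#' @param params An `nb_params` object.
#' @return The agent set with updated telomeres.
#' @export
update_telomeres <- function(agents, params = load_parameters()) {
  n <- n_agents(agents)
  m <- agents$status == 0L & (agents$gp[, "TELOMERASE"] | agents$gp[, "ALT"]) &
    stats::runif(n) < params$P_telo_r
  agents$telomere[m] <- pmin(params$N_telo_max, agents$telomere[m] + 1L)
  agents
}

# radius from growth progress: volume doubles across G1 + G2
.cycle_radius <- function(phase, clock, params) {
  tg <- params$T_G1 + params$T_G2
  g <- ifelse(phase == 1L, pmin(clock, params$T_G1) / tg,
       ifelse(phase == 2L, params$T_G1 / tg,
       ifelse(phase == 3L, (params$T_G1 + pmin(clock, params$T_G2)) / tg, 1)))
  (params$L_cell / 2) * (1 + g)^(1 / 3)
}

#' Attempt cell-cycle progression
#'
#' With probability `P_cycle_nb * (1 - deg_diff)` (NB) or
#' `min(1, P_cycle_sc + proliferation signal)` (SC) the agent advances its
#' phase clock by one hour — never while hypoxic, ATP-starved, or dead.
#' Phase transitions at the phase-duration boundaries are gated by
#' checkpoints: G1 to S needs p21 and p27 inactive and telomeres above the
#' critical length (or active telomerase/ALT); S to G2 needs replicated DNA
#' and CDS1 inactive; G2 to M needs CDC25C active and undamaged DNA.
#' Schwann agents, which carry no gene products, face the DNA and telomere
#' conditions only. The radius interpolates so cell volume doubles across
#' G1 + G2; completing M flags the agent for division.
#'
#' @inheritParams update_gene_products
#' @return A list: `agents` (updated) and `divide` (logical flags).
#' @export
attempt_cycle <- function(agents, stimuli, params = load_parameters()) {
  n <- n_agents(agents)
  nb <- agents$type == 1L
  live <- agents$status == 0L
  p <- ifelse(nb, params$P_cycle_nb * (1 - agents$deg_diff),
              pmin(1, params$P_cycle_sc + stimuli$pro_signal_sc))
  adv <- live & !stimuli$hypoxic & stimuli$nourished & stats::runif(n) < p
  clock <- agents$clock
  phase <- agents$phase
  clock[adv] <- clock[adv] + 1

  dur <- c(params$T_G1, params$T_S, params$T_G2, params$T_M)
  at_end <- clock >= dur[phase]
  gp <- agents$gp
  telo_ok <- agents$telomere > params$N_telo_c |
    (nb & (gp[, "TELOMERASE"] | gp[, "ALT"]))
  pass_g1 <- telo_ok & (!nb | (!gp[, "p21"] & !gp[, "p27"]))
  pass_s <- agents$dna != 2L & (!nb | !gp[, "CDS1"])
  pass_g2 <- agents$dna != 1L & (!nb | gp[, "CDC25C"])

  tr1 <- live & phase == 1L & at_end & pass_g1
  tr2 <- live & phase == 2L & at_end & pass_s
  tr3 <- live & phase == 3L & at_end & pass_g2
  div <- live & phase == 4L & at_end
  clock[phase == 1L & at_end & !pass_g1] <- dur[1]   # hold at checkpoint
  clock[phase == 2L & at_end & !pass_s] <- dur[2]
  clock[phase == 3L & at_end & !pass_g2] <- dur[3]
  phase[tr1] <- 2L; clock[tr1] <- 0
  phase[tr2] <- 3L; clock[tr2] <- 0
  phase[tr3] <- 4L; clock[tr3] <- 0

  agents$phase <- phase
  agents$clock <- clock
  agents$radius <- .cycle_radius(phase, clock, params)
  list(agents = agents, divide = div)
}

#' Divide flagged agents
#'
#' Each dividing parent is reset to the start of G1 (radius `L_cell / 2`)
#' and spawns a daughter at distance `L_cell / 2` in a uniformly random
#' direction; the daughter inherits the parent's subclone, mutations and
#' degree of differentiation, and both telomeres shorten by one unit
#' (floored at zero). Overlap created by placement is resolved by the next
#' mechanics step.
#'
#' @param agents An `nb_agents` set.
#' @param divide Logical flags from [attempt_cycle()].
#' @param params An `nb_params` object.
#' @return A list: `agents` (with daughters appended) and `births`
#'   (25-vector of per-subclone birth counts, Schwann last).
#' @export
divide_agents <- function(agents, divide, params = load_parameters()) {
  idx <- which(divide)
  nb <- agents$type == 1L
  births <- tabulate(as.integer(ifelse(nb, agents$subclone, 25L))[idx],
                     nbins = 25L)
  if (!length(idx)) return(list(agents = agents, births = births))
  k <- length(idx)
  agents$phase[idx] <- 1L
  agents$clock[idx] <- 0
  agents$radius[idx] <- params$L_cell / 2
  agents$telomere[idx] <- pmax(0L, agents$telomere[idx] - 1L)

  dirm <- matrix(stats::rnorm(3 * k), ncol = 3)
  dirm <- dirm / pmax(sqrt(rowSums(dirm^2)), 1e-12)
  off <- dirm * params$L_cell / 2
  n0 <- n_agents(agents)
  for (nm in names(agents)) {
    if (nm %in% c("gp", "next_id")) next
    agents[[nm]] <- c(agents[[nm]], agents[[nm]][idx])
  }
  agents$gp <- rbind(agents$gp, agents$gp[idx, , drop = FALSE])
  d <- n0 + seq_len(k)
  agents$x[d] <- agents$x[idx] + off[, 1]
  agents$y[d] <- agents$y[idx] + off[, 2]
  agents$z[d] <- agents$z[idx] + off[, 3]
  agents$id[d] <- agents$next_id + seq_len(k) - 1L
  agents$next_id <- agents$next_id + k
  list(agents = agents, births = births)
}

#' Write the agent table as a delimited file
#'
#' One row per agent: id, type, subclone, coordinates, radius, phase,
#' degree of differentiation, telomere units, DNA status and state flags.
#'
#' @param agents An `nb_agents` set.
#' @param path Output CSV path.
#' @return The table, invisibly.
#' @export
write_agents <- function(agents, path) {
  tab <- data.frame(
    id = agents$id,
    type = c("NB", "SC")[agents$type],
    subclone = agents$subclone,
    x = agents$x, y = agents$y, z = agents$z,
    radius = agents$radius,
    phase = .phase_names[agents$phase],
    clock = agents$clock,
    deg_diff = agents$deg_diff,
    telomere = agents$telomere,
    dna = .dna_names[agents$dna + 1L],
    status = .status_names[agents$status + 1L],
    hypoxic = agents$hypoxic,
    atp = agents$atp,
    mobile = agents$mobile
  )
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
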