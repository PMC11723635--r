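# Deterministic generators of synthetic inputs and miniature scenarios so
# every layer is testable in milliseconds without running full simulations.
# All fixtures are pure functions of their arguments and seed.

#' Uniform random blob of agents
#'
#' `n` agents of one type placed uniformly in a cube, with default cellular
#' attributes; byte-identical for identical arguments and seed.
#'
#' @param n Number of agents.
#' @param box_side Cube side, um.
#' @param seed Integer seed.
#' @param type `"NB"` or `"SC"`.
#' @param subclone Subclone id for NB agents.
#' @param params An `nb_params` object.
#' @return An `nb_agents` set.
#' @export
make_agent_blob <- function(n, box_side = 100, seed = 1, type = "NB",
                            subclone = 1L, params = load_parameters()) {
  set.seed(seed)
  pos <- matrix(stats::runif(3 * n, 0, box_side), ncol = 3)
  if (n == 0) pos <- matrix(numeric(0), ncol = 3)
  new_agents(n, type = type, subclone = subclone, position = pos,
             params = params)
}

#' Synthetic ensemble-results table
#'
#' Per-run final states consistent with a requested outcome mix: regressed
#' runs end with zero living neuroblasts, differentiated runs with a mean
#' degree of differentiation of at least 0.9, progressing runs below it.
#' Initial and final four-clone fractional compositions each sum to one.
#' Intended for testing classification, enrichment and bootstrap code
#' without simulation.
#'
#' @param n_configs Number of ensembles (virtual tumours).
#' @param n_runs Runs per ensemble.
#' @param outcome_mix Named probabilities over
#'   `c("regression", "differentiation", "progression")`.
#' @param seed Integer seed.
#' @return A data.frame, one row per run: `config`, `run`, `outcome`,
#'   `final_living_nb`, `mean_deg_diff`, `init_frac_*` and `final_frac_*`
#'   for the four clones (WT, MA, TR, AI).
#' @export
make_ensemble_table <- function(n_configs, n_runs,
                                outcome_mix = c(regression = 0,
                                                differentiation = 0,
                                                progression = 1),
                                seed = 1) {
  stopifnot(abs(sum(outcome_mix) - 1) < 1e-9)
  set.seed(seed)
  n <- n_configs * n_runs
  outcome <- sample(names(outcome_mix), n, replace = TRUE,
                    prob = outcome_mix)
  final_nb <- ifelse(outcome == "regression", 0L,
                     as.integer(round(stats::runif(n, 200, 2000))))
  dd <- ifelse(outcome == "differentiation", stats::runif(n, 0.9, 1),
               stats::runif(n, 0, 0.85))
  simplex4 <- function(m) {
    g <- matrix(stats::rexp(4 * m), ncol = 4)
    g / rowSums(g)
  }
  init <- simplex4(n)
  fin <- simplex4(n)
  fin[outcome == "regression", ] <- 0
  clones <- c("WT", "MA", "TR", "AI")
  out <- data.frame(
    config = rep(seq_len(n_configs), each = n_runs),
    run = rep(seq_len(n_runs), times = n_configs),
    outcome = outcome,
    final_living_nb = final_nb,
    mean_deg_diff = ifelse(final_nb == 0, NA_real_, dd)
  )
  colnames(init) <- paste0("init_frac_", clones)
  colnames(fin) <- paste0("final_frac_", clones)
  cbind(out, init, fin)
}

#' Synthetic merged drug-trial dataset
#'
#' Two classes of 20-dimensional inhibition-probability vectors separated
#' along a planted unit direction by the stated separation (clipped to
#' \[0, 1\]), with labels attached — for testing whether the
#' PCA/cluster/silhouette pipeline recovers planted structure.
#'
#' @param n_eff,n_ineff Examples per class (>= 2 each).
#' @param separation Distance between class centres along the planted
#'   direction.
#' @param seed Integer seed.
#' @return A data.frame: 20 probability columns (named after
#'   [gene_products()]), `label` (`"effective"`/`"ineffective"`), and the
#'   planted direction as attribute `"direction"`.
#' @export
make_drug_dataset <- function(n_eff, n_ineff, separation = 1, seed = 1) {
  if (n_eff < 2 || n_ineff < 2) stop("need at least 2 examples per class")
  set.seed(seed)
  w <- stats::rnorm(20)
  w <- w / sqrt(sum(w^2))
  n <- n_eff + n_ineff
  x <- matrix(stats::runif(20 * n, 0.25, 0.75), ncol = 20)
  shift <- c(rep(separation / 2, n_eff), rep(-separation / 2, n_ineff))
  x <- x + outer(shift, w)
  x <- pmin(pmax(x, 0), 1)
  colnames(x) <- gene_products()
  out <- data.frame(x, check.names = FALSE)
  out$label <- c(rep("effective", n_eff), rep("ineffective", n_ineff))
  attr(out, "direction") <- w
  out
}
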