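# The four in-silico experiment designs and the bespoke analysis layer:
# Latin hypercube designs, outcome classification, enrichment, drug-trial
# labelling, the calibration metric, bootstrap confidence intervals, PCA,
# and Ward clustering with silhouette validation.

#' Latin hypercube design
#'
#' `n` near-random points in `d` dimensions on the unit hypercube: per
#' column, exactly one sample falls in each of the `n` equal strata
#' `[i/n, (i+1)/n)`, uniformly placed within its stratum, with strata
#' independently permuted per column.
#'
#' @param n Number of points.
#' @param d Number of dimensions.
#' @return An n x d matrix in \[0, 1).
#' @export
latin_hypercube <- function(n, d) {
  if (n < 1 || d < 1) stop("n and d must be at least 1")
  lhs::randomLHS(n, d)
}

#' Classify the outcome of one run
#'
#' A run that ends without living neuroblastoma cells has regressed; one
#' that ends with living neuroblasts at least 90% differentiated on average
#' has differentiated; any other run is progressing. Only cell counts are
#' considered, never volumes.
#'
#' @param final_living_nb Final living NB count, or an `nb_run` object.
#' @param mean_deg_diff Final mean degree of differentiation of living NB
#'   cells (ignored when a run object is given).
#' @return `"regression"`, `"differentiation"` or `"progression"`.
#' @export
classify_run <- function(final_living_nb, mean_deg_diff = NA_real_) {
  if (inherits(final_living_nb, "nb_run")) {
    last <- final_living_nb$series[nrow(final_living_nb$series), ]
    mean_deg_diff <- last$mean_deg_diff
    final_living_nb <- last$nb_living
  }
  if (final_living_nb == 0) return("regression")
  if (!is.na(mean_deg_diff) && mean_deg_diff >= 0.9) return("differentiation")
  "progression"
}

#' Classify an ensemble by strict majority
#'
#' The ensemble label is the outcome achieved by a strict majority (more
#' than half) of its runs; with no strict majority the ensemble is
#' unclassified.
#'
#' @param run_outcomes Character vector of per-run outcomes.
#' @return `"regression"`, `"differentiation"`, `"progression"` or
#'   `"unclassified"`.
#' @export
classify_ensemble <- function(run_outcomes) {
  if (!length(run_outcomes)) stop("need at least one run outcome")
  tab <- table(run_outcomes)
  top <- names(tab)[which.max(tab)]
  if (max(tab) > length(run_outcomes) / 2) top else "unclassified"
}

#' Clonal enrichment
#'
#' A clone's enrichment is its final fractional composition (living NB
#' agents in the clone over all living NB agents) divided by its initial
#' fractional composition. Undefined for an initially absent clone.
#'
#' @param initial_fraction,final_fraction Fractional compositions.
#' @return `final / initial`; `NA` with a warning where the initial
#'   fraction is zero.
#' @export
enrichment <- function(initial_fraction, final_fraction) {
  out <- ifelse(initial_fraction > 0, final_fraction / initial_fraction,
                NA_real_)
  if (any(initial_fraction == 0)) {
    warning("enrichment undefined for initially absent clones (NA)")
  }
  out
}

#' Label a drug combination by its endpoint
#'
#' Ineffective combinations leave more than 90% of the untreated baseline
#' alive; effective ones leave fewer than 1000 living neuroblasts (or,
#' for reduced-scale baselines, fewer than a 1e-3 fraction of the
#' baseline), including complete regression at zero. Anything between is
#' intermediate and excluded from the merged analysis dataset.
#'
#' @param final_mean_living_nb Mean final living NB count over the runs.
#' @param baseline Untreated (control) final living NB count.
#' @return `"effective"`, `"ineffective"` or `"intermediate"` (vectorised).
#' @export
label_drug_combination <- function(final_mean_living_nb, baseline) {
  if (any(baseline <= 0)) stop("baseline must be positive")
  cut_eff <- ifelse(baseline > 1e6, 1000, 1e-3 * baseline)
  ifelse(final_mean_living_nb > 0.9 * baseline, "ineffective",
         ifelse(final_mean_living_nb < cut_eff, "effective", "intermediate"))
}

#' Growth-curve calibration metric
#'
#' Residual sum of squares between simulated and observed cell-count
#' ratios at matched time points (the round-one tournament score).
#'
#' @param simulated_ratios,observed_ratios Equal-length numeric vectors of
#'   cell-count ratios (typically at 0, 24, 48, 72, 96, 168 h).
#' @return Sum of squared pairwise differences.
#' @export
calibration_rss <- function(simulated_ratios, observed_ratios) {
  if (length(simulated_ratios) != length(observed_ratios)) {
    stop("ratio sequences must have equal length")
  }
  sum((simulated_ratios - observed_ratios)^2)
}

#' Bootstrap percentile confidence interval
#'
#' Resamples the data `n_resamples` times, each time drawing
#' `resample_size` values with replacement and recording the statistic;
#' returns the mean of the resampled statistics with their 2.5% and 97.5%
#' percentiles.
#'
#' @param samples Numeric data.
#' @param resample_size Values drawn per resample.
#' @param n_resamples Number of resamples.
#' @param statistic `"mean"` or `"median"`.
#' @return Named vector: `point`, `lower`, `upper`.
#' @export
bootstrap_ci <- function(samples, resample_size = length(samples),
                         n_resamples = 100, statistic = c("mean", "median")) {
  if (!length(samples)) stop("samples must be non-empty")
  statistic <- match.arg(statistic)
  fn <- if (statistic == "mean") mean else stats::median
  stats <- vapply(seq_len(n_resamples), function(i) {
    fn(sample(samples, resample_size, replace = TRUE))
  }, numeric(1))
  q <- stats::quantile(stats, c(0.025, 0.975), names = FALSE)
  c(point = mean(stats), lower = q[1], upper = q[2])
}

#' Variance fraction of the first principal component
#'
#' Fraction of total variance carried by the leading principal component
#' of the column-centred (unscaled) data matrix.
#'
#' @param dataset An n x d numeric matrix, n > d >= 2.
#' @return Fraction in (0, 1\].
#' @export
pc1_variance_fraction <- function(dataset) {
  dataset <- as.matrix(dataset)
  if (ncol(dataset) < 2 || nrow(dataset) <= ncol(dataset)) {
    stop("need n > d >= 2")
  }
  if (all(apply(dataset, 2, stats::sd) == 0)) {
    stop("degenerate data: all columns constant")
  }
  pc <- stats::prcomp(dataset, center = TRUE, scale. = FALSE)
  pc$sdev[1]^2 / sum(pc$sdev^2)
}

#' Two-cluster Ward partition of a 1-D projection, with silhouette
#'
#' Agglomerative clustering (Ward criterion) of values projected on one
#' axis (typically the first principal component), cut at two clusters,
#' validated by the mean silhouette coefficient over all examples.
#'
#' @param projected Numeric vector (length >= 4, at least two distinct
#'   values).
#' @return A list: `labels` (1/2 per example), `mean_silhouette`.
#' @export
cluster_and_silhouette <- function(projected) {
  projected <- as.numeric(projected)
  if (length(projected) < 4) stop("need at least 4 examples")
  if (length(unique(projected)) < 2) stop("need at least two distinct values")
  d <- stats::dist(projected)
  labels <- stats::cutree(stats::hclust(d, method = "ward.D2"), k = 2)
  sil <- cluster::silhouette(labels, d)
  list(labels = as.integer(labels), mean_silhouette = mean(sil[, "sil_width"]))
}

#' Experiment design presets
#'
#' Templates for the four in-silico experiment designs built on the model:
#'
#' 1. **Clonal competition** — 1200 virtual tumours; Latin hypercube over
#'    the initial oxygen level (sampled over the dimensionless 272-3272
#'    range, normalised by its upper bound) and the Schwann fraction
#'    (0.05-0.5); per-agent random 24-subclone assignment; cellularity
#'    0.8; no treatment; 10 runs each.
#' 2. **Gene-expression sensitivity** — 1000 Latin hypercube profiles over
#'    six expression levels (MYCN, MR1, MR0, p53, p73, HIF); uniform
#'    composition; oxygen 0.24; Schwann fraction 0.28; 10 runs each.
#' 3. **Composition/microenvironment sensitivity** — 10 configurations:
#'    MYCN-amplified fraction in {0, 25, 50, 75, 100}% (remainder
#'    wild-type) crossed with oxygen {0.24, 1}; 100 runs each.
#' 4. **Drug-combination trials** — four single-clone tumours, 5000 Latin
#'    hypercube drug combinations of 20 inhibition probabilities each;
#'    Schwann fraction 0.11; cellularity 1; within each combination the 10
#'    runs take oxygen at 10 regular intervals between 0 and 1.
#'
#' `scale` multiplies the initial volume (and hence agent count) so the
#' designs can be exercised at desk scale; `n_steps` defaults to the full
#' 3024 h induction window.
#'
#' @param id Preset number 1-4.
#' @param scale Volume scale factor (1 = full scale, 8 mm^3).
#' @param n_steps Steps per run.
#' @return An `nb_experiment` list: design metadata, a `design` matrix
#'   where applicable, and `make_config(j, ...)` returning the j-th
#'   `simulation_config` (for preset 4: `make_config(j, clone)` with clone
#'   in `c("WT", "MA", "TR", "AI")`, plus run-level `O2_levels`).
#' @export
experiment_preset <- function(id, scale = 1, n_steps = 3024) {
  id <- as.integer(id)
  if (!id %in% 1:4) stop("preset id must be 1..4")
  vol <- 8e9 * scale
  base <- list(id = id, n_steps = n_steps, initial_volume = vol,
               scale = scale)
  if (id == 1L) {
    n_cfg <- 1200L
    design <- latin_hypercube(n_cfg, 2)
    colnames(design) <- c("O2", "sc_frac")
    design[, "O2"] <- (272 + design[, "O2"] * 3000) / 3272
    design[, "sc_frac"] <- 0.05 + design[, "sc_frac"] * 0.45
    out <- c(base, list(
      name = "clonal_competition", n_configs = n_cfg, n_runs = 10L,
      design = design,
      make_config = function(j, seed = j) {
        simulation_config(
          n_steps = n_steps, initial_volume = vol, cellularity = 0.8,
          schwann_fraction = design[j, "sc_frac"],
          clonal_composition = rep(1 / 24, 24),
          O2_init = design[j, "O2"], static_O2 = 1,
          treatment = treatment_none(), seed = seed)
      }))
  } else if (id == 2L) {
    n_cfg <- 1000L
    design <- latin_hypercube(n_cfg, 6)
    colnames(design) <- c("E_MYCN", "E_MR1", "E_MR2", "E_p53", "E_p73",
                          "E_HIF")
    out <- c(base, list(
      name = "gene_expression_sensitivity", n_configs = n_cfg, n_runs = 10L,
      design = design,
      make_config = function(j, seed = j) {
        simulation_config(
          n_steps = n_steps, initial_volume = vol, cellularity = 0.8,
          schwann_fraction = 0.28, clonal_composition = rep(1 / 24, 24),
          O2_init = 0.24, static_O2 = 1, treatment = treatment_none(),
          seed = seed, params = as.list(design[j, ]))
      }))
  } else if (id == 3L) {
    grid_design <- expand.grid(ma_fraction = c(0, 0.25, 0.5, 0.75, 1),
                               O2 = c(0.24, 1))
    out <- c(base, list(
      name = "composition_microenvironment", n_configs = 10L, n_runs = 100L,
      design = as.matrix(grid_design),
      make_config = function(j, seed = j) {
        ma <- grid_design$ma_fraction[j]
        comp <- numeric(24)
        comp[7:12] <- ma / 6                      # MYCN-amplified clone
        comp[1:6] <- (1 - ma) / 6                 # remainder wild-type
        simulation_config(
          n_steps = n_steps, initial_volume = vol, cellularity = 0.8,
          schwann_fraction = 0.28, clonal_composition = comp,
          O2_init = grid_design$O2[j], static_O2 = 1,
          treatment = treatment_none(), seed = seed)
      }))
  } else {
    n_cfg <- 5000L
    design <- latin_hypercube(n_cfg, 20)
    colnames(design) <- gene_products()
    clones <- c(WT = 1L, MA = 7L, TR = 13L, AI = 19L)
    out <- c(base, list(
      name = "drug_combination_trials", n_configs = n_cfg, n_runs = 10L,
      n_trials = 4L, design = design,
      O2_levels = seq(0, 1, length.out = 10),
      make_config = function(j, clone = "MA", seed = j, O2 = 1) {
        comp <- numeric(24)
        comp[clones[[clone]] + 0:5] <- 1 / 6
        simulation_config(
          n_steps = n_steps, initial_volume = vol, cellularity = 1,
          schwann_fraction = 0.11, clonal_composition = comp,
          O2_init = O2, static_O2 = 1,
          treatment = treatment_drug_combination(design[j, ]), seed = seed)
      }))
  }
  structure(out, class = "nb_experiment")
}

#' Total simulated hours of an experiment design
#'
#' Bookkeeping product: configurations times runs per configuration times
#' steps per run. For the drug-trial preset this is the figure for one of
#' its four single-clone trials; set `all_trials = TRUE` to count all four.
#'
#' @param preset An `nb_experiment` from [experiment_preset()].
#' @param all_trials Multiply by the number of trials, where applicable.
#' @return Total simulated agent-population hours of the design.
#' @export
design_simulated_hours <- function(preset, all_trials = FALSE) {
  trials <- if (all_trials && !is.null(preset$n_trials)) preset$n_trials else 1L
  as.numeric(preset$n_configs) * preset$n_runs * preset$n_steps * trials
}
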