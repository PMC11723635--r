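# a small, quick configuration with enough death events to exercise
# bookkeeping: high Schwann fraction drives the apoptotic signal
small_config <- function(n_steps = 10, seed = 1, static_O2 = 1, ...) {
  simulation_config(n_steps = n_steps,
                    initial_volume = 27000 * 160, cellularity = 1,
                    schwann_fraction = 0.3, O2_init = 1,
                    static_O2 = static_O2, seed = seed, ...)
}

test_that("initial cell counts match the printed study scales", {
  expect_equal(initial_cell_count(8e9, 0.8, 9.39e-5), 600960)
  expect_equal(initial_cell_count(8e9, 1.0, 9.39e-5), 751200)
  expect_equal(initial_cell_count(27000, 1.0, 9.39e-5), 3)
  expect_error(initial_cell_count(-1, 0.5), "positive")
})

test_that("histology categories map to their Schwann and maturity ranges", {
  set.seed(1)
  checks <- list(
    list("NB", "undifferentiated", c(0.05, 0.17), c(0, 0)),
    list("NB", "poorly_differentiated", c(0.17, 0.33), c(0, 0.2)),
    list("NB", "differentiating", c(0.33, 0.5), c(0.2, 0.4)),
    list("intermixed_GNB", NULL, c(0.5, 0.67), c(0.4, 0.6)),
    list("maturing_GN", NULL, c(0.67, 0.83), c(0.6, 0.8)),
    list("mature_GN", NULL, c(0.83, 0.95), c(0.8, 1.0))
  )
  for (ck in checks) {
    for (i in 1:20) {
      h <- histology_init(ck[[1]], ck[[2]])
      expect_gte(h$schwann_fraction, ck[[3]][1])
      expect_lte(h$schwann_fraction, ck[[3]][2])
      expect_equal(h$deg_diff_range, ck[[4]])
    }
  }
  expect_error(histology_init("lymphoma"), "unknown")
})

test_that("composite histologies recurse with equal likelihood", {
  set.seed(2)
  n <- 2000
  res <- vapply(seq_len(n), function(i) histology_init("GNB")$category,
                character(1))
  # GNB splits 50/50 between nodular (which recurses further) and intermixed
  n_inter_direct <- sum(res == "intermixed_GNB")
  # nodular recurses to NB / intermixed / maturing GN equally, so the direct
  # intermixed share is 1/2 + (1/2)(1/3) = 2/3
  p <- 2 / 3
  expect_lt(abs(n_inter_direct / n - p), 3 * sqrt(p * (1 - p) / n))
  expect_true(all(res %in% c("intermixed_GNB", "maturing_GN",
                             "NB_undifferentiated")))
})

test_that("clone assignment follows the cumulative composition", {
  set.seed(3)
  one <- numeric(24); one[7] <- 1
  expect_true(all(assign_clones(500, one) == 7L))
  comp <- rep(1 / 24, 24)
  ids <- assign_clones(24000, comp)
  counts <- tabulate(ids, 24)
  tol <- 3 * sqrt(24000 * (1 / 24) * (23 / 24))
  expect_true(all(abs(counts - 1000) <= tol))
  gaps <- rep(1 / 12, 24); gaps[seq(2, 24, 2)] <- 0
  expect_true(all(assign_clones(2000, gaps) %in% seq(1, 24, 2)))
  expect_error(assign_clones(10, rep(0.1, 24)), "summing to 1")
})

test_that("initialisation is seeded, censused, and oxygen-balanced", {
  cfg <- small_config()
  s1 <- initialise(cfg)
  s2 <- initialise(cfg)
  expect_identical(s1$agents$x, s2$agents$x)   # determinism contract
  expect_identical(s1$agents$subclone, s2$agents$subclone)

  n_req <- initial_cell_count(cfg$initial_volume, cfg$cellularity)
  expect_equal(n_agents(s1$agents), n_req)
  expect_equal(sum(s1$agents$type == 2L), round(0.3 * n_req))
  expect_equal(sum(s1$grid$counts$cells_total), n_req)
  expect_true(all(s1$agents$status == 0L))     # only living agents created

  # supply equals initial consumption, so dynamic oxygen starts balanced
  cfg0 <- small_config(static_O2 = 0)
  st <- initialise(cfg0)
  consumption <- sum(st$agents$status == 0L) * abs(st$params$RO20)
  expect_equal(st$grid$O2_supply, consumption)
  g2 <- update_oxygen(st$grid, consumption, st$params)
  expect_equal(g2$O2, st$grid$O2)
})

test_that("stepping an empty domain only advances the clock", {
  cfg <- simulation_config(n_steps = 3, initial_volume = 5000,
                           cellularity = 0.5, schwann_fraction = 0,
                           seed = 1)
  st <- initialise(cfg)
  expect_equal(n_agents(st$agents), 0)
  st2 <- step(st)
  expect_equal(st2$t, 1L)
  expect_equal(n_agents(st2$agents), 0)
})

test_that("runs are bitwise reproducible under a fixed seed", {
  cfg <- small_config(n_steps = 8)
  r1 <- run(cfg)
  r2 <- run(cfg)
  expect_identical(r1$series, r2$series)
  expect_identical(r1$counters, r2$counters)
  r3 <- run(small_config(n_steps = 8, seed = 2))
  expect_false(identical(r1$series$nb_living, r3$series$nb_living))
})

test_that("per-subclone bookkeeping balances births, deaths and reversions", {
  cfg <- small_config(n_steps = 15, seed = 4)
  r <- run(cfg)
  liv <- as.matrix(r$series[, paste0("nb_living_s", 1:24)])
  for (t in seq_len(cfg$n_steps)) {
    expected <- liv[t, ] + r$counters$births[t, 1:24] -
      r$counters$died[t, 1:24] + r$counters$revived[t, 1:24]
    expect_equal(unname(liv[t + 1, ]), unname(expected))
  }
  # Schwann totals balance through column 25
  sc_liv <- r$series$sc_living
  for (t in seq_len(cfg$n_steps)) {
    expect_equal(sc_liv[t + 1],
                 sc_liv[t] + r$counters$births[t, 25] -
                   r$counters$died[t, 25] + r$counters$revived[t, 25])
  }
  # something actually happened in this configuration
  expect_gt(sum(r$counters$died), 0)
})

test_that("census conservation holds after every step", {
  cfg <- small_config(n_steps = 0, seed = 5)
  st <- initialise(cfg)
  for (k in 1:10) {
    st <- step(st)
    a <- st$agents
    expect_equal(sum(st$grid$counts$nb_total), sum(a$type == 1L))
    expect_equal(sum(st$grid$counts$sc_total), sum(a$type == 2L))
  }
})

test_that("treatment schedules produce the right inhibition vectors", {
  none <- apply_treatment(treatment_none(), 100)
  expect_true(all(none$inhibition == 0))
  expect_false(none$chemo_active)

  chemo <- treatment_chemo(windows = list(c(0, 120), c(336, 456)),
                           probs = stats::setNames(rep(0.7, 6),
                                                   c("CHK1", "JAB1", "HIF",
                                                     "MYCN", "TELOMERASE",
                                                     "p53")))
  inside <- apply_treatment(chemo, 50)
  expect_true(inside$chemo_active)
  on_targets <- inside$inhibition[c("CHK1", "JAB1", "HIF", "MYCN",
                                    "TELOMERASE", "p53")]
  expect_true(all(on_targets == 0.7))
  expect_true(all(inside$inhibition[setdiff(gene_products(),
                                            names(on_targets))] == 0))
  outside <- apply_treatment(chemo, 200)
  expect_true(all(outside$inhibition == 0))

  combo <- treatment_drug_combination(seq(0, 0.95, length.out = 20))
  at_any_t <- apply_treatment(combo, 1234)
  expect_equal(unname(at_any_t$inhibition), seq(0, 0.95, length.out = 20))
  expect_error(treatment_drug_combination(rep(2, 20)), "probabilities")
  expect_error(treatment_chemo(probs = c(CHK1 = 0.5)), "named exactly")
})

test_that("ensembles average finals and flag duplicate seeds", {
  cfg <- small_config(n_steps = 5)
  e1 <- run_ensemble(cfg, n_runs = 1)
  last <- e1$runs[[1]]$series[nrow(e1$runs[[1]]$series), ]
  expect_equal(e1$mean_final_subclones,
               unname(unlist(last[paste0("nb_living_s", 1:24)])))
  expect_equal(e1$mean_final_nb_living, last$nb_living)

  e2 <- run_ensemble(cfg, n_runs = 2, seeds = c(11, 12))
  manual <- sapply(e2$runs, function(r) r$series$nb_living[nrow(r$series)])
  expect_equal(e2$mean_final_nb_living, mean(manual))
  expect_warning(run_ensemble(cfg, n_runs = 2, seeds = c(1, 1)), "duplicate")
})

test_that("run artefacts write as delimited tables and JSON", {
  cfg <- small_config(n_steps = 3)
  r <- run(cfg)
  f1 <- withr::local_tempfile(fileext = ".csv")
  write_timeseries(r, f1)
  back <- read.csv(f1)
  expect_equal(nrow(back), 4)
  expect_true(all(c("nb_living", "O2", "mech_iters") %in% names(back)))
  f2 <- withr::local_tempfile(fileext = ".json")
  write_run_state(r$final_state, f2)
  rec <- jsonlite::read_json(f2)
  expect_equal(rec$t, 3)
  expect_equal(rec$n_agents, n_agents(r$final_state$agents))
})
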