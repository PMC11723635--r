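test_that("sensing reports hypoxia, nourishment, signals and drugs", {
  params <- load_parameters()
  a <- new_agents(2, position = matrix(45, 2, 3))
  g <- census_grid(a, 90, params)
  g$O2 <- 1                                   # reference scale: 72 mmHg
  s <- sense(a, g, params = params)
  expect_false(any(s$hypoxic))
  expect_true(all(s$nourished))
  expect_true(all(s$drug_inhibition == 0))

  g$O2 <- 0                                   # anoxia: glycolysis-only ATP
  s0 <- sense(a, g, params = params)
  expect_true(all(s0$hypoxic))
  expect_false(any(s0$nourished))             # yield below the ATP threshold

  # one Schwann neighbour in-voxel drives the apoptotic signal
  sc <- new_agents(1, type = "SC", position = matrix(45, 1, 3))
  g2 <- census_grid(sc, 90, params)
  s2 <- sense(a, g2, params = params)
  expect_equal(s2$apop_signal_nb, rep(3.04e-2, 2))
})

test_that("gene products follow their regulators at expression level one", {
  params <- load_parameters(list(E_p53 = 1, E_p73 = 1, E_HIF = 1))
  # wild-type agent, normal DNA, normoxia: CHK1/CDS1 ineligible, CDC25C on
  a <- new_agents(5, subclone = 1L)
  s <- stimulus_bundle(5)
  a <- update_gene_products(a, s, params)
  expect_true(all(a$gp[, "JAB1"]))
  expect_false(any(a$gp[, "CHK1"]))
  expect_false(any(a$gp[, "CDS1"]))
  expect_true(all(a$gp[, "CDC25C"]))
  expect_true(all(a$gp[, "p21"]))             # p53 on (E_p53 = 1) -> p21/p27
  expect_false(any(a$gp[, "HIF"]))            # not hypoxic
  # without TERT rearrangement, telomerase tracks MYCN activity exactly
  expect_equal(a$gp[, "TELOMERASE"], a$gp[, "MYCN"])

  # damaged DNA flips the checkpoint machinery
  d <- new_agents(5, subclone = 1L, dna = "damaged")
  d <- update_gene_products(d, s, params)
  expect_true(all(d$gp[, "CHK1"]))
  expect_true(all(d$gp[, "p73"]))             # CHK1 upregulates p73
  expect_false(any(d$gp[, "CDC25C"]))         # CHK1 downregulates CDC25C

  # hypoxia enables the HIF arm
  h <- new_agents(5, subclone = 1L)
  h <- update_gene_products(h, stimulus_bundle(5, hypoxic = TRUE), params)
  expect_true(all(h$gp[, "HIF"]))
  expect_true(all(h$gp[, "BNIP3"]))
  expect_true(all(h$gp[, "VEGF"]))
  expect_false(any(h$gp[, "BCL"]))            # BNIP3 suppresses BCL
})

test_that("telomere-maintenance routes follow the mutation profile", {
  params <- load_parameters()
  s <- stimulus_bundle(200)
  tr <- new_agents(200, subclone = 13L)       # TERT-rearranged
  tr <- update_gene_products(tr, s, params)
  expect_true(all(tr$gp[, "TELOMERASE"]))
  expect_false(any(tr$gp[, "ALT"]))
  ai <- new_agents(200, subclone = 19L)       # ATRX-inactivated
  ai <- update_gene_products(ai, s, params)
  expect_true(all(ai$gp[, "ALT"]))
  # the MYCN route to telomerase remains open in the AI clone
  expect_equal(ai$gp[, "TELOMERASE"], ai$gp[, "MYCN"])
})

test_that("p53 stays off under every stimulus when the pathway is mutated", {
  params <- load_parameters(list(E_p53 = 1))
  set.seed(1)
  for (stim in list(stimulus_bundle(50),
                    stimulus_bundle(50, hypoxic = TRUE),
                    stimulus_bundle(50, apop_signal_nb = 0.5))) {
    a <- new_agents(50, subclone = 4L, dna = "damaged")  # p53-inactivated WT
    a <- update_gene_products(a, stim, params)
    expect_false(any(a$gp[, "p53"]))
  }
})

test_that("a full drug combination vetoes every product", {
  params <- load_parameters(list(E_p53 = 1, E_MYCN = 1, E_p73 = 1, E_HIF = 1))
  inh <- stats::setNames(rep(1, 20), gene_products())
  a <- new_agents(100, subclone = 8L, dna = "damaged")
  a <- update_gene_products(a, stimulus_bundle(100, hypoxic = TRUE,
                                               drug_inhibition = inh), params)
  expect_false(any(a$gp))
})

test_that("DNA dynamics: quiescent, chemo-gated, and repairable", {
  params <- load_parameters()
  # normal DNA, normoxia, no chemo: unchanged (spontaneous rate is zero)
  a <- new_agents(500)
  a <- update_dna(a, stimulus_bundle(500), params)
  expect_true(all(a$dna == 0L))
  # chemotherapy damages S-phase cells only
  p1 <- load_parameters(list(P_DNA_c = 1))
  b <- new_agents(100, phase = c("S", "G1"))
  b <- update_dna(b, stimulus_bundle(100, chemo_active = TRUE), p1)
  expect_true(all(b$dna[b$phase == 2L] == 1L))
  expect_true(all(b$dna[b$phase == 1L] == 0L))
  # an NB agent with active p53 repairs deterministically
  r <- new_agents(50, dna = "damaged")
  r$gp[, "p53"] <- TRUE
  r <- update_dna(r, stimulus_bundle(50), params)
  expect_true(all(r$dna == 0L))
  # certain hypoxic unreplication in S phase (damage switched off)
  p2 <- load_parameters(list(P_DNA_h = 0, P_unrep_h = 1))
  u <- new_agents(50, phase = "S")
  u <- update_dna(u, stimulus_bundle(50, hypoxic = TRUE), p2)
  expect_true(all(u$dna == 2L))
})

test_that("death transitions follow their gates", {
  # a healthy cell in abundant oxygen stays alive
  params <- load_parameters()
  set.seed(2)
  a <- new_agents(200)
  out <- update_death(a, stimulus_bundle(200), O2 = 1, params = params)
  expect_true(all(out$agents$status == 0L))
  expect_equal(sum(out$events$died), 0)

  # active CAS forces apoptosis; the apoptotic signal acts as a probability
  pq <- quiet_params()
  c1 <- new_agents(20)
  c1$gp[, "CAS"] <- TRUE
  out1 <- update_death(c1, stimulus_bundle(20), O2 = 1, params = pq)
  expect_true(all(out1$agents$status == 1L))
  c2 <- new_agents(20)
  out2 <- update_death(c2, stimulus_bundle(20, apop_signal_nb = 1), O2 = 1,
                       params = pq)
  expect_true(all(out2$agents$status == 1L))

  # reversion is possible only before the apoptosis clock runs out
  p_rev <- quiet_params(P_apop_r = 1)
  early <- new_agents(10, status = "apoptotic", apop_timer = 0)
  expect_true(all(update_death(early, stimulus_bundle(10), 1,
                               p_rev)$agents$status == 0L))
  late <- new_agents(10, status = "apoptotic", apop_timer = 3)
  expect_true(all(update_death(late, stimulus_bundle(10), 1,
                               p_rev)$agents$status == 1L))

  # secondary necrosis and removal
  p_nec2 <- quiet_params(P_necro_2 = 1)
  sec <- new_agents(10, status = "apoptotic", apop_timer = 3)
  expect_true(all(update_death(sec, stimulus_bundle(10), 1,
                               p_nec2)$agents$status == 2L))
  p_lys <- quiet_params(P_lysis = 1)
  mix <- new_agents(10, status = c("living", "necrotic"))
  outl <- update_death(mix, stimulus_bundle(10), 1, p_lys)
  expect_equal(n_agents(outl$agents), 5)            # dead agents removed
  expect_true(all(outl$agents$status == 0L))        # living never removed
  expect_equal(sum(outl$events$removed), 5)
})

test_that("necrotic signals can trigger necrosis in neighbours", {
  pq <- quiet_params(P_necro_sig = 1)
  a <- new_agents(20)
  out <- update_death(a, stimulus_bundle(20, necrotic_signal_hits = 1), 1, pq)
  expect_true(all(out$agents$status == 2L))
  out0 <- update_death(new_agents(20), stimulus_bundle(20), 1, pq)
  expect_true(all(out0$agents$status == 0L))
})

test_that("sustained exposure at the half-necrosis concentration yields ~50%", {
  # isolate the entry/recovery balance: no removal, no other death routes
  params <- quiet_params(P_necro_r = 0.99)
  set.seed(42)
  n <- 3000
  a <- new_agents(n)
  O2_half <- params$CO2_50 / params$CO2s
  s <- stimulus_bundle(n, hypoxic = TRUE, nourished = FALSE)
  frac <- numeric(60)
  for (t in 1:60) {
    a <- update_death(a, s, O2 = O2_half, params = params)$agents
    frac[t] <- mean(a$status == 2L)
  }
  expect_equal(mean(frac[20:60]), 0.5, tolerance = 0.05)
})

test_that("telomeres shorten on division, lengthen by maintenance, stay bounded", {
  params <- load_parameters(list(P_telo_r = 1))
  a <- new_agents(10, telomere = 60)
  a$gp[, "TELOMERASE"] <- TRUE
  a <- update_telomeres(a, params)
  expect_true(all(a$telomere == 60))          # capped at the maximum
  b <- new_agents(10, telomere = 30)
  b$gp[, "ALT"] <- TRUE
  expect_true(all(update_telomeres(b, params)$telomere == 31))
  # division decrements both parent and daughter
  d <- new_agents(1, telomere = 20, phase = "M", clock = 2)
  out <- divide_agents(d, TRUE, params)
  expect_equal(out$agents$telomere, c(19L, 19L))
  d40 <- divide_agents(new_agents(1, telomere = 40), TRUE, params)
  expect_equal(d40$agents$telomere, c(39L, 39L))
})

test_that("cycle checkpoints arrest and release as regulated", {
  params <- load_parameters(list(P_cycle_nb = 1))
  s <- stimulus_bundle(1)
  # p21 active at the G1 boundary blocks G1 -> S
  a <- new_agents(1, phase = "G1", clock = 11)
  a$gp[, "p21"] <- TRUE
  out <- attempt_cycle(a, s, params)
  expect_equal(out$agents$phase, 1L)
  expect_equal(out$agents$clock, 12)          # held at the boundary
  # clearing p21/p27 releases the checkpoint
  held <- out$agents
  held$gp[, "p21"] <- FALSE
  out2 <- attempt_cycle(held, s, params)
  expect_equal(out2$agents$phase, 2L)
  # short telomeres block G1 -> S unless a maintenance route is active
  t <- new_agents(1, phase = "G1", clock = 11, telomere = 10)
  expect_equal(attempt_cycle(t, s, params)$agents$phase, 1L)
  t$gp[, "TELOMERASE"] <- TRUE
  expect_equal(attempt_cycle(t, s, params)$agents$phase, 2L)
  # unreplicated DNA blocks S -> G2; damaged DNA blocks G2 -> M
  u <- new_agents(1, phase = "S", clock = 5, dna = "unreplicated")
  expect_equal(attempt_cycle(u, s, params)$agents$phase, 2L)
  g2 <- new_agents(1, phase = "G2", clock = 3, dna = "damaged")
  g2$gp[, "CDC25C"] <- TRUE
  expect_equal(attempt_cycle(g2, s, params)$agents$phase, 3L)
  # CDC25C is required for G2 -> M
  g2b <- new_agents(1, phase = "G2", clock = 3)
  expect_equal(attempt_cycle(g2b, s, params)$agents$phase, 3L)
  g2b$gp[, "CDC25C"] <- TRUE
  expect_equal(attempt_cycle(g2b, s, params)$agents$phase, 4L)
})

test_that("an unobstructed traversal takes the full 24 hours of progression", {
  params <- load_parameters(list(P_cycle_nb = 1))
  a <- new_agents(1)
  a$gp[, "CDC25C"] <- TRUE
  s <- stimulus_bundle(1)
  hours_to_divide <- NA
  for (h in 1:30) {
    out <- attempt_cycle(a, s, params)
    a <- out$agents
    a$gp[, "CDC25C"] <- TRUE
    if (out$divide) { hours_to_divide <- h; break }
  }
  expect_equal(hours_to_divide, 24)           # 12 + 6 + 4 + 2
})

test_that("differentiation damps cycling and hypoxia halts it", {
  params <- load_parameters(list(P_cycle_nb = 1))
  full <- new_agents(1, deg_diff = 1)
  out <- attempt_cycle(full, stimulus_bundle(1), params)
  expect_equal(out$agents$clock, 0)           # progression probability zero
  hyp <- new_agents(1)
  out2 <- attempt_cycle(hyp, stimulus_bundle(1, hypoxic = TRUE), params)
  expect_equal(out2$agents$clock, 0)
  starve <- attempt_cycle(new_agents(1), stimulus_bundle(1, nourished = FALSE),
                          params)
  expect_equal(starve$agents$clock, 0)
})

test_that("the radius doubles cell volume across G1 + G2", {
  params <- load_parameters()
  a <- new_agents(3, phase = c("G1", "S", "M"), clock = c(0, 0, 0))
  out <- attempt_cycle(a, stimulus_bundle(3), quiet_params())
  r <- out$agents$radius
  expect_equal(r[1], 5.5)
  expect_equal(r[2], 5.5 * (1 + 12 / 16)^(1 / 3))
  expect_equal(r[3], 5.5 * 2^(1 / 3))
  expect_true(all(r >= 5.5 & r <= 5.5 * 2^(1 / 3)))
})

test_that("division resets, inherits and places the daughter at L_cell/2", {
  params <- load_parameters()
  set.seed(9)
  a <- new_agents(1, subclone = 7L, phase = "M", clock = 2, deg_diff = 0.3,
                  position = matrix(50, 1, 3))
  a$radius <- 5.5 * 2^(1 / 3)
  out <- divide_agents(a, TRUE, params)
  b <- out$agents
  expect_equal(n_agents(b), 2)
  expect_equal(b$subclone, c(7L, 7L))         # clonal identity is heritable
  expect_equal(b$deg_diff, c(0.3, 0.3))
  expect_equal(b$phase, c(1L, 1L))
  expect_equal(b$radius, c(5.5, 5.5))
  d <- sqrt((b$x[1] - b$x[2])^2 + (b$y[1] - b$y[2])^2 + (b$z[1] - b$z[2])^2)
  expect_equal(d, 5.5)
  expect_equal(out$births[7], 1L)
  expect_false(b$id[1] == b$id[2])            # fresh id for the daughter
})

test_that("differentiation integrates the Schwann signal and saturates", {
  params <- load_parameters()
  a <- new_agents(1)
  expect_equal(update_differentiation(a, stimulus_bundle(1),
                                      params)$deg_diff, 0)
  s <- stimulus_bundle(1, diff_signal_nb = 5.21e-4)  # one in-voxel Schwann
  a2 <- update_differentiation(a, s, params)
  expect_equal(a2$deg_diff, 0.01 * 5.21e-4)
  near <- new_agents(1, deg_diff = 1 - 1e-9)
  big <- stimulus_bundle(1, diff_signal_nb = 10)
  expect_equal(update_differentiation(near, big, params)$deg_diff, 1)
})

test_that("a fully quiescent update is the identity", {
  pq <- quiet_params()
  set.seed(5)
  a <- make_agent_blob(50, box_side = 90, seed = 5)
  s <- stimulus_bundle(50)
  before <- agent_snapshot(a)
  b <- update_gene_products(a, s, pq)
  b <- update_telomeres(b, pq)
  b <- update_dna(b, s, pq)
  b <- update_differentiation(b, s, pq)
  b <- update_death(b, s, O2 = 1, params = pq)$agents
  cyc <- attempt_cycle(b, s, pq)
  b <- divide_agents(cyc$agents, cyc$divide, pq)$agents
  expect_equal(agent_snapshot(b), before)
})

test_that("telomere and differentiation stay within their bounds", {
  params <- load_parameters(list(P_telo_r = 1, P_cycle_nb = 1))
  set.seed(3)
  a <- make_agent_blob(100, box_side = 200, seed = 3)
  a$gp[, "TELOMERASE"] <- runif(100) < 0.5
  s <- stimulus_bundle(100, diff_signal_nb = 0.5)
  for (i in 1:30) {
    a <- update_telomeres(a, params)
    a <- update_differentiation(a, s, params)
    expect_true(all(a$telomere >= 0 & a$telomere <= 60))
    expect_true(all(a$deg_diff >= 0 & a$deg_diff <= 1))
  }
})

test_that("the agent table writer records the full state", {
  a <- make_agent_blob(10, seed = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_agents(a, f)
  back <- read.csv(f)
  expect_equal(nrow(back), 10)
  expect_true(all(back$type == "NB"))
  expect_true(all(back$status == "living"))
  expect_equal(back$telomere, rep(60, 10))
})
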