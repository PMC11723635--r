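# Parameter set with every stochastic gate closed: no cycling, death,
# repair, lengthening, signalling emission or gene expression. Used for
# fixed-point and isolation tests.
quiet_params <- function(...) {
  zeros <- list(
    P_necrois = 0, P_lysis = 0, P_unrep_h = 0, P_DNA_h = 0, P_DNA_c = 0,
    P_apop = 0, P_apop_r = 0, P_necro_2 = 0, P_necro_r = 0, P_telo_r = 0,
    P_cycle_nb = 0, P_cycle_sc = 0, P_DNA_r1 = 0, P_DNA_r2 = 0,
    P_necro_sig = 0,
    E_p53 = 0, E_MYCN = 0, E_MR1 = 0, E_MR2 = 0, E_p73 = 0, E_HIF = 0,
    E_CHK1 = 0, E_p21 = 0, E_p27 = 0, E_CDC25C = 0, E_CDS1 = 0, E_ID2 = 0,
    E_IAP2 = 0, E_BNIP3 = 0, E_JAB1 = 0, E_Bcl = 0, E_BAX_BAK = 0,
    E_CAS = 0, E_VEGF = 0, E_MYCN_other = 0, E_MR_wt = 0
  )
  over <- list(...)
  zeros[names(over)] <- over
  load_parameters(zeros)
}

# snapshot of the agent fields that a quiescent update must not touch
agent_snapshot <- function(a) {
  a[c("x", "y", "z", "radius", "phase", "clock", "deg_diff", "status",
      "apop_timer", "telomere", "dna", "gp")]
}

# a small grid censused from an agent set
census_grid <- function(agents, side, params = load_parameters()) {
  rebuild_counts(build_grid(side, params$L_voxel), agents)
}
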