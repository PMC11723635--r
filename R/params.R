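#' @useDynLib nbsim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats prcomp runif rnorm quantile cutree hclust dist sd
#' @importFrom utils write.csv read.csv
NULL

# Internal registry: every model constant with value, units and the printed
# table it comes from. Fields with source "model" are package-level choices
# that the printed tables do not pin down (all configurable).
.param_registry <- function() {
  row <- function(name, value, units, source) {
    list(name = name, value = value, units = units, source = source)
  }
  regs <- list(
    # spatially homogeneous variables
    row("CO2s",        72,         "mmHg",      "table2"),
    row("RO20",        -1.875e-13, "moles/h",   "table2"),
    row("Tangc",       100,        "h",         "table2"),
    row("P_necrois",   0.5768,     "1",         "table2"),
    row("P_lysis",     0.35,       "1",         "table2"),
    row("rho",         9.39e-5,    "1/um^3",    "table2"),
    # continuous automaton
    row("L_voxel",        30,      "um",        "table3"),
    row("R_jux_pro_sc",   3.74e-3, "1",         "table3"),
    row("R_jux_diff_nb",  5.21e-4, "1",         "table3"),
    row("R_jux_apop_nb",  3.04e-2, "1",         "table3"),
    row("R_para_pro_sc",  3.74e-4, "1",         "table3"),
    row("R_para_diff_nb", 5.21e-5, "1",         "table3"),
    row("R_para_apop_nb", 3.04e-3, "1",         "table3"),
    # both agent types
    row("L_cell",       11,      "um",  "table4"),
    row("T_G1",         12,      "h",   "table4"),
    row("T_S",          6,       "h",   "table4"),
    row("T_G2",         4,       "h",   "table4"),
    row("T_M",          2,       "h",   "table4"),
    row("R_glycolysis", 6.67e-2, "1",   "table4"),
    row("N_telo_max",   60,      "1",   "table4"),
    row("N_telo_c",     20,      "1",   "table4"),
    row("P_unrep",      0,       "1",   "table4"),
    row("P_unrep_h",    0.43,    "1",   "table4"),
    row("P_DNA_h",      0.77,    "1",   "table4"),
    row("P_DNA_c",      0.64,    "1",   "table4"),
    row("T_apop",       3,       "h",   "table4"),
    row("P_apop",       0.26,    "1",   "table4"),
    row("P_apop_r",     0.96,    "1",   "table4"),
    row("CO2_50",       1.2,     "mmHg","table4"),
    row("P_necro_2",    0.2,     "1",   "table4"),
    row("P_necro_r",    0.99,    "1",   "table4"),
    # neuroblastoma agents
    row("E_p53",     0.20, "1", "table5"),
    row("E_MYCN",    0.94, "1", "table5"),
    row("E_MR1",     0.38, "1", "table5"),
    row("E_MR2",     0.00, "1", "table5"),
    row("E_p73",     0.14, "1", "table5"),
    row("E_HIF",     0.59, "1", "table5"),
    row("E_CHK1",    1, "1", "table5"),
    row("E_p21",     1, "1", "table5"),
    row("E_p27",     1, "1", "table5"),
    row("E_CDC25C",  1, "1", "table5"),
    row("E_CDS1",    1, "1", "table5"),
    row("E_ID2",     1, "1", "table5"),
    row("E_IAP2",    1, "1", "table5"),
    row("E_BNIP3",   1, "1", "table5"),
    row("E_JAB1",    1, "1", "table5"),
    row("E_Bcl",     1, "1", "table5"),
    row("E_BAX_BAK", 1, "1", "table5"),
    row("E_CAS",     1, "1", "table5"),
    row("E_VEGF",    1, "1", "table5"),
    row("R_diff",     0.01, "1/h", "table5"),
    row("P_telo_r",   0.09, "1",   "table5"),
    row("P_cycle_nb", 0.05, "1",   "table5"),
    # Schwann agents
    row("P_cycle_sc", 0.03, "1",       "table6"),
    row("R_collagen", 0.71, "um^3/h",  "table6"),
    row("P_DNA_r1",   0.77, "1",       "table6"),
    row("P_DNA_r2",   0.89, "1",       "table6"),
    # mechanics
    row("L_overlap",   0,       "um",      "table7"),
    row("k1",          2.20e-3, "N/m",     "table7"),
    row("L_nghbr",     17.33,   "um",      "table7"),
    row("N_nghbr_max", 2,       "1",       "table7"),
    row("k2",          2,       "1",       "table7"),
    row("mu",          0.40,    "N*s/m",   "table7"),
    row("dt_mech",     36,      "s",       "table7"),
    row("k3",          1.26,    "1",       "table7"),
    row("k4",          2,       "1",       "table7"),
    # package-level choices (unprinted; see methods vignette)
    row("E_MR_wt",       0,    "1",  "model"),  # wild-type MAPK/RAS activity
    row("E_MYCN_other",  0.47, "1",  "model"),  # E_MYCN/2 without ALK mutation
    row("hypoxia_frac",  0.1,  "1",  "model"),  # hypoxic below this * CO2s
    row("atp_threshold", 0.1,  "1",  "model"),  # glycolysis-only ATP cut-off
    row("P_necro_sig",   0.1,  "1",  "model"),  # necrosis per signal hit
    row("O2_conversion", NA,   "1/(moles/h)/h", "model"), # NA = set at init
    row("mech_max_iters", 100,  "1",  "model"),
    row("mech_tol",       0.01, "um", "model")
  )
  regs
}

#' Model parameter registry
#'
#' Returns the full default parameter set of the multicellular neuroblastoma
#' model: the printed constants of the source model's parameter tables
#' (microenvironment, signalling, cell-agent, gene-expression and mechanical
#' constants) plus a small number of clearly marked package-level choices
#' (see the methods vignette). Defaults can be overridden through a flat
#' named list or a YAML file of `name: value` pairs.
#'
#' @param config `NULL` (all defaults), a named list of overrides, or the
#'   path to a flat YAML file of `name: value` pairs.
#' @return An object of class `nb_params`: a named list of parameter values.
#' @examples
#' p <- load_parameters()
#' p$P_lysis
#' load_parameters(list(T_G1 = 10))$T_G1
#' @export
load_parameters <- function(config = NULL) {
  reg <- .param_registry()
  params <- stats::setNames(
    lapply(reg, `[[`, "value"),
    vapply(reg, `[[`, "name", FUN.VALUE = character(1))
  )
  if (!is.null(config)) {
    if (is.character(config) && length(config) == 1L) {
      config <- yaml::read_yaml(config)
    }
    if (!is.list(config) || is.null(names(config)) || any(names(config) == "")) {
      stop("config must be a named list or the path to a flat YAML file")
    }
    unknown <- setdiff(names(config), names(params))
    if (length(unknown)) {
      stop("unknown parameter name(s): ", paste(unknown, collapse = ", "))
    }
    params[names(config)] <- config
  }
  params <- lapply(params, function(x) as.numeric(x))
  class(params) <- "nb_params"
  validate_parameters(params)
  params
}

# probability-valued fields checked for [0, 1]
.prob_fields <- c(
  "P_necrois", "P_lysis", "P_unrep", "P_unrep_h", "P_DNA_h", "P_DNA_c",
  "P_apop", "P_apop_r", "P_necro_2", "P_necro_r", "P_telo_r", "P_cycle_nb",
  "P_cycle_sc", "P_DNA_r1", "P_DNA_r2", "P_necro_sig",
  "E_p53", "E_MYCN", "E_MR1", "E_MR2", "E_p73", "E_HIF", "E_CHK1", "E_p21",
  "E_p27", "E_CDC25C", "E_CDS1", "E_ID2", "E_IAP2", "E_BNIP3", "E_JAB1",
  "E_Bcl", "E_BAX_BAK", "E_CAS", "E_VEGF", "E_MR_wt", "E_MYCN_other"
)
.positive_fields <- c(
  "CO2s", "Tangc", "L_voxel", "L_cell", "T_G1", "T_S", "T_G2", "T_M",
  "T_apop", "CO2_50", "rho", "k1", "mu", "dt_mech", "L_nghbr", "k3", "k4",
  "mech_max_iters", "mech_tol", "R_collagen", "R_glycolysis", "R_diff"
)

#' Validate a parameter set
#'
#' Checks that every probability lies in \[0, 1\], that durations, time
#' scales and physical constants are positive, and that each paracrine
#' signal strength is one tenth of its juxtacrine counterpart.
#'
#' @param params An `nb_params` object.
#' @return `params`, invisibly, if valid; otherwise an error naming the
#'   offending field.
#' @export
validate_parameters <- function(params) {
  for (f in .prob_fields) {
    v <- params[[f]]
    if (!is.na(v) && (v < 0 || v > 1)) {
      stop("parameter out of range [0,1]: ", f, " = ", v)
    }
  }
  for (f in .positive_fields) {
    v <- params[[f]]
    if (!is.na(v) && v <= 0) stop("parameter must be positive: ", f, " = ", v)
  }
  if (params$L_overlap < 0) stop("parameter must be non-negative: L_overlap")
  invisible(params)
}

#' Export the parameter registry as a table
#'
#' @param params An `nb_params` object (defaults if omitted); overridden
#'   values are reflected in the `value` column.
#' @param path Optional file path; if given, the table is written as CSV.
#' @return A data.frame with columns `name`, `value`, `units`, `source`.
#' @export
param_table <- function(params = load_parameters(), path = NULL) {
  reg <- .param_registry()
  tab <- data.frame(
    name = vapply(reg, `[[`, "name", FUN.VALUE = character(1)),
    value = vapply(reg, function(r) as.numeric(params[[r$name]]),
                   FUN.VALUE = numeric(1)),
    units = vapply(reg, `[[`, "units", FUN.VALUE = character(1)),
    source = vapply(reg, `[[`, "source", FUN.VALUE = character(1)),
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) utils::write.csv(tab, path, row.names = FALSE)
  tab
}

#' The 20 gene products of the regulatory layer
#'
#' Stable ordering used everywhere a 20-entry vector indexes gene products,
#' in particular drug-combination inhibition vectors: MYCN; the MAPK/RAS
#' pathway; JAB1; CHK1; ID2; IAP2; HIF; BNIP3; VEGF; p53; p73; p21; p27;
#' Bcl-2/Bcl-xL (BCL); Bak/Bax (BAK_BAX); CAS; CDS1; CDC25C; ALT; telomerase.
#'
#' @return Character vector of length 20.
#' @export
gene_products <- function() {
  c("MYCN", "MAPK_RAS", "JAB1", "CHK1", "ID2", "IAP2", "HIF", "BNIP3",
    "VEGF", "p53", "p73", "p21", "p27", "BCL", "BAK_BAX", "CAS", "CDS1",
    "CDC25C", "ALT", "TELOMERASE")
}

#' The 24-subclone population structure
#'
#' A neuroblastoma cell agent belongs to one of four clones — wild-type (WT,
#' ids 1-6), MYCN-amplified (MA, 7-12), TERT-rearranged (TR, 13-18) and
#' ATRX-inactivated (AI, 19-24). Within each clone, offsets 1-3 carry
#' {no MAPK/RAS mutation, ALK activation/amplification, another MAPK/RAS
#' mutation} with wild-type p53, and offsets 4-6 repeat those MAPK/RAS
#' states with the p53 pathway inactivated.
#'
#' @return A 24-row data.frame: `id`, `clone`, `mapk_state`, `p53_inact`.
#' @export
subclone_table <- function() {
  clones <- c("WT", "MA", "TR", "AI")
  mapk <- c("none", "ALK", "other")
  data.frame(
    id = 1:24,
    clone = rep(clones, each = 6),
    mapk_state = rep(rep(mapk, times = 2), times = 4),
    p53_inact = rep(rep(c(FALSE, TRUE), each = 3), times = 4),
    stringsAsFactors = FALSE
  )
}

#' Mutation profile of a subclone
#'
#' Expands a subclone id into the agent-level mutation flags. The three
#' clone-defining mutations (MYCN amplification, TERT rearrangement, ATRX
#' inactivation) are mutually exclusive.
#'
#' @param id Integer subclone id in 1..24 (vectorised).
#' @return A data.frame with one row per id: logical `MYCN_amp`,
#'   `TERT_rearr`, `ATRX_inact`, `other_MAPK_mut`, `p53_inact` and character
#'   `ALK` (`"wild_type"` or `"activated_amplified"`).
#' @examples
#' subclone_profile(7)$MYCN_amp  # TRUE: MA clone
#' @export
subclone_profile <- function(id) {
  if (any(is.na(id)) || any(id < 1) || any(id > 24) || any(id != round(id))) {
    stop("subclone id must be an integer in 1..24")
  }
  tab <- subclone_table()[id, , drop = FALSE]
  data.frame(
    id = tab$id,
    MYCN_amp = tab$clone == "MA",
    TERT_rearr = tab$clone == "TR",
    ATRX_inact = tab$clone == "AI",
    ALK = ifelse(tab$mapk_state == "ALK", "activated_amplified", "wild_type"),
    other_MAPK_mut = tab$mapk_state == "other",
    p53_inact = tab$p53_inact,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
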