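# Reference data for peptide chemistry: residue elemental compositions,
# stable-isotope masses/abundances, and the random-coil amide exchange
# calibration (poly-DL-alanine basis with side-chain inductive/steric
# factors, Bai/Connelly/Englander-style).

# Residue (amino acid minus water) elemental compositions, columns C,H,N,O,S.
RESIDUE_FORMULAS <- local({
  m <- rbind(
    G = c(2, 3, 1, 1, 0),
    A = c(3, 5, 1, 1, 0),
    S = c(3, 5, 1, 2, 0),
    P = c(5, 7, 1, 1, 0),
    V = c(5, 9, 1, 1, 0),
    T = c(4, 7, 1, 2, 0),
    C = c(3, 5, 1, 1, 1),
    L = c(6, 11, 1, 1, 0),
    I = c(6, 11, 1, 1, 0),
    N = c(4, 6, 2, 2, 0),
    D = c(4, 5, 1, 3, 0),
    Q = c(5, 8, 2, 2, 0),
    K = c(6, 12, 2, 1, 0),
    E = c(5, 7, 1, 3, 0),
    M = c(5, 9, 1, 1, 1),
    H = c(6, 7, 3, 1, 0),
    F = c(9, 9, 1, 1, 0),
    R = c(6, 12, 4, 1, 0),
    Y = c(9, 9, 1, 2, 0),
    W = c(11, 10, 2, 1, 0)
  )
  colnames(m) <- c("C", "H", "N", "O", "S")
  m
})

# Stable isotopes: mass (Da) and abundance per element, lightest first.
ISOTOPES <- list(
  C = list(mass = c(12, 13.00335484), abundance = c(0.9893, 0.0107)),
  H = list(mass = c(1.00782503, 2.01410178), abundance = c(0.999885, 0.000115)),
  N = list(mass = c(14.00307401, 15.00010890), abundance = c(0.99636, 0.00364)),
  O = list(mass = c(15.99491462, 16.99913176, 17.99915961),
           abundance = c(0.99757, 0.00038, 0.00205)),
  S = list(mass = c(31.97207100, 32.97145876, 33.96786690, 35.96708076),
           abundance = c(0.9499, 0.0075, 0.0425, 0.0001))
)

PROTON_MASS <- 1.00727646
# Mass added per H -> D substitution (2H minus 1H).
DEUTERIUM_SHIFT <- 1.00627675

#' Random-coil amide exchange calibration constants
#'
#' The poly-DL-alanine reference rate constants, side-chain
#' inductive/electrostatic factors and activation energies used by
#' [intrinsic_rates()]. The calibration is the widely used protium-into-D2O
#' ("HD") parameter set of the Englander laboratory methodology for
#' random-coil peptides (Bai, Milne, Mayne & Englander, Proteins 17:75-86,
#' 1993, with the commonly distributed spreadsheet revisions): reference
#' rates `log10 kA = 1.62` (per M per min), `log10 kB = 10.18` (per M per
#' min), `log10 kW = -1.5` (per min) at 293.15 K; D2O ion product
#' `pKD = 15.05`; activation energies 14, 17, 19 kcal/mol for the acid, base
#' and water channels. Side-chain factors are log10 multipliers: `lambda`
#' applies to a residue's own amide, `rho` to the following residue's amide.
#' Titratable side chains (Asp, Glu, His) carry protonated and deprotonated
#' factor pairs mixed at run time by the solution pD and the side-chain pK
#' (in D2O: Asp 4.48, Glu 4.93, His 7.42, C-terminal carboxyl 3.66).
#'
#' @format A list with elements `version`, `ref_temperature_K`, `log_kA`,
#'   `log_kB`, `log_kW`, `pKD`, `Ea_kcal` (named acid/base/water),
#'   `side_chain` (data frame of log10 lambda/rho factors per channel),
#'   `titratable` (pK and protonated-form factors), `terminal` (N- and
#'   C-terminal group factors).
#' @export
exchange_constants <- function() EXCHANGE_CONSTANTS

EXCHANGE_CONSTANTS <- local({
  # columns: acid lambda, acid rho, base lambda, base rho (log10 factors);
  # deprotonated forms for D/E, neutral form for H.
  sc <- rbind(
    A = c(0.00, 0.00, 0.00, 0.00),
    R = c(-0.59, -0.32, 0.08, 0.22),
    N = c(-0.58, -0.13, 0.49, 0.32),
    D = c(0.90, 0.58, -0.30, -0.18),
    C = c(-0.54, -0.46, 0.62, 0.55),
    E = c(-0.90, 0.31, -0.51, -0.15),
    Q = c(-0.47, -0.27, 0.06, 0.20),
    G = c(-0.22, 0.22, 0.27, 0.17),
    H = c(0.00, 0.00, -0.10, 0.14),
    I = c(-0.91, -0.59, -0.73, -0.23),
    L = c(-0.57, -0.13, -0.58, -0.21),
    K = c(-0.56, -0.29, -0.04, 0.12),
    M = c(-0.64, -0.28, -0.01, 0.11),
    F = c(-0.52, -0.43, -0.24, 0.06),
    P = c(NA, -0.19, NA, -0.24),  # trans proline; no amide of its own
    S = c(-0.44, -0.39, 0.37, 0.30),
    T = c(-0.79, -0.47, -0.07, 0.20),
    W = c(-0.40, -0.44, -0.41, -0.11),
    Y = c(-0.41, -0.37, -0.27, 0.05),
    V = c(-0.74, -0.30, -0.70, -0.14)
  )
  colnames(sc) <- c("acid_lambda", "acid_rho", "base_lambda", "base_rho")
  titr <- list(
    D = list(pK = 4.48, protonated = c(-0.90, -0.12, 0.69, 0.60)),
    E = list(pK = 4.93, protonated = c(-0.60, -0.27, 0.24, 0.39)),
    H = list(pK = 7.42, protonated = c(-0.80, -0.51, 0.80, 0.83))
  )
  list(
    version = "HD-polyDLA-1993r1",
    ref_temperature_K = 293.15,
    log_kA = 1.62,   # /M/min, acid channel
    log_kB = 10.18,  # /M/min, base channel
    log_kW = -1.5,   # /min, water channel
    pKD = 15.05,
    Ea_kcal = c(acid = 14, base = 17, water = 19),
    gas_constant_kcal = 1.9872e-3,
    side_chain = sc,
    titratable = titr,
    terminal = list(
      # Free N-terminal amine acts on residue 2's amide via rho;
      # C-terminal carboxylate acts on the last residue's amide via lambda.
      n_term = c(acid_rho = -1.32, base_rho = 1.62),
      c_term = c(acid_lambda = 0.96, base_lambda = -1.80),
      c_term_pK = 3.66,
      c_term_protonated = c(acid_lambda = 0.05, base_lambda = -1.80)
    )
  )
})
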