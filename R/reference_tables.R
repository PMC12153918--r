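#' Names of the 31 modeled milk fatty-acid traits
#'
#' The 31 FT-MIR-predicted fatty acids and fatty-acid groups used throughout
#' the pipeline, in canonical column order. Concentrations are expressed in
#' g/100 g fat after unit conversion (g/dL milk as predicted).
#'
#' @return Character vector of length 31.
#' @export
fa_trait_names <- function() {
  c("C4", "C6", "C8", "C10", "C12", "C14", "C14_1cis9", "C16", "C16_1",
    "C17", "C18", "C18_1trans", "C18_1cis9", "C18_1cis", "C18_2",
    "C18_2cis9cis12", "C18_2cis9trans11", "C18_3cis9cis12cis15",
    "SFA", "MUFA", "PUFA", "UFA", "SCFA", "MCFA", "LCFA", "BFA",
    "omega3", "omega6", "odd_FA", "trans_FA", "C18_1")
}

#' Names of the auxiliary FT-MIR phenotypes
#'
#' Six herd-level phenotypes predicted alongside the fatty acids: milk yield
#' (kg/day), energy balance, nitrogen-use efficiency, blood
#' beta-hydroxybutyrate (log mmol/L plasma), blood free fatty acids
#' (uEq/L plasma) and dry-matter intake (kg/day). Fat and protein
#' (g/dL milk) are carried as separate fields because the cleaning bounds
#' apply to them.
#'
#' @return Character vector of length 6.
#' @export
aux_trait_names <- function() {
  c("milk_yield", "energy_balance", "nitrogen_efficiency",
    "blood_BHB", "blood_FFA", "DMI")
}

#' Reference per-state trait means (Walloon bulk-tank population)
#'
#' Published per-cluster means of the 39 FT-MIR-predicted traits for the
#' seven herd states identified in routine Walloon (Belgian) bulk-tank milk
#' monitoring. Fatty acids are in g/100 g fat, fat and protein in g/dL milk.
#' These ship as the default state profiles for the synthetic generator.
#'
#' @return Numeric matrix, 7 states (rows `state1`..`state7`) by 39 traits.
#' @export
walloon_state_means <- function() {
  traits <- c(fa_trait_names(), "fat", "protein", aux_trait_names())
  m <- matrix(c(
    # state1  state2  state3  state4  state5  state6  state7
    2.78,   2.87,   2.49,   2.69,   2.55,   2.60,   2.50,   # C4
    1.82,   1.70,   1.46,   1.86,   1.70,   1.56,   1.84,   # C6
    1.16,   1.01,   0.88,   1.23,   1.11,   0.94,   1.26,   # C8
    2.53,   2.06,   1.78,   2.77,   2.51,   1.87,   3.06,   # C10
    3.15,   2.51,   2.30,   3.51,   3.13,   2.44,   3.78,   # C12
    11.13,  9.56,   9.05,   12.07,  10.55,  9.92,   11.90,  # C14
    1.01,   0.84,   1.00,   1.12,   1.05,   1.05,   1.09,   # C14_1cis9
    31.04,  27.16,  24.26,  34.38,  25.78,  30.01,  29.31,  # C16
    1.58,   1.69,   1.95,   1.59,   1.70,   1.92,   1.60,   # C16_1
    0.64,   0.66,   0.72,   0.61,   0.70,   0.66,   0.70,   # C17
    10.02,  11.48,  10.44,  9.04,   9.56,   9.93,   9.18,   # C18
    3.21,   3.71,   4.44,   2.50,   4.21,   3.13,   3.58,   # C18_1trans
    19.06,  23.82,  26.28,  16.56,  21.81,  23.26,  17.98,  # C18_1cis9
    20.61,  25.69,  28.17,  17.97,  23.39,  25.07,  19.27,  # C18_1cis
    2.12,   2.40,   2.42,   1.92,   2.39,   2.08,   2.28,   # C18_2
    1.28,   1.47,   1.20,   1.22,   1.20,   1.21,   1.26,   # C18_2cis9cis12
    0.46,   0.53,   0.63,   0.38,   0.63,   0.45,   0.57,   # C18_2cis9trans11
    0.72,   0.80,   1.38,   0.50,   1.33,   0.79,   1.08,   # C18_3cis9cis12cis15
    68.37,  63.15,  57.54,  71.93,  61.53,  64.06,  67.24,  # SFA
    27.38,  32.76,  36.15,  24.32,  30.99,  32.12,  26.20,  # MUFA
    3.46,   4.01,   4.60,   2.86,   4.56,   3.36,   4.19,   # PUFA
    30.91,  36.81,  40.92,  27.29,  35.65,  35.71,  30.40,  # UFA
    8.71,   7.92,   6.88,   9.06,   8.24,   7.35,   9.04,   # SCFA
    50.62,  44.07,  41.79,  55.53,  45.67,  48.20,  51.00,  # MCFA
    39.84,  47.81,  49.86,  34.80,  43.67,  44.21,  38.00,  # LCFA
    2.21,   2.20,   2.66,   2.11,   2.70,   2.26,   2.54,   # BFA
    0.59,   0.68,   0.77,   0.47,   0.76,   0.56,   0.70,   # omega3
    2.17,   2.48,   2.36,   1.95,   2.36,   2.03,   2.34,   # omega6
    3.74,   3.73,   4.29,   3.59,   4.34,   3.75,   4.26,   # odd_FA
    4.00,   4.58,   5.54,   3.16,   5.32,   3.88,   4.56,   # trans_FA
    23.85,  29.40,  32.28,  20.64,  27.24,  28.27,  22.49,  # C18_1
    4.11,   3.94,   4.01,   4.23,   4.10,   4.05,   4.25,   # fat
    3.44,   3.31,   3.43,   3.50,   3.50,   3.37,   3.55,   # protein
    26.87,  26.10,  22.45,  28.11,  24.49,  24.81,  25.52,  # milk_yield
    -2.75,  -5.40,  -8.50,  -1.43,  -7.40,  -4.83,  -4.04,  # energy_balance
    56.67,  56.29,  31.04,  58.10,  38.73,  41.78,  49.67,  # nitrogen_efficiency
    -0.81,  -0.74,  -0.71,  -0.87,  -0.73,  -0.77,  -0.79,  # blood_BHB
    526.90, 678.60, 714.60, 407.70, 590.40, 629.00, 520.30, # blood_FFA
    22.24,  19.93,  19.78,  23.51,  22.03,  20.84,  24.17   # DMI
  ), ncol = 7, byrow = TRUE,
  dimnames = list(traits, paste0("state", 1:7)))
  t(m)
}

#' Reference population standard deviations of the traits
#'
#' Published whole-population SDs of the 39 FT-MIR-predicted traits for the
#' Walloon dataset. Within-state dispersion in the synthetic generator is a
#' fraction of these population SDs (between-state spread must dominate the
#' within-state spread for the states to be separable).
#'
#' @return Named numeric vector of length 39.
#' @export
walloon_trait_sds <- function() {
  c(C4 = 0.19, C6 = 0.12, C8 = 0.10, C10 = 0.36, C12 = 0.44, C14 = 0.87,
    C14_1cis9 = 0.11, C16 = 3.25, C16_1 = 0.17, C17 = 0.05, C18 = 1.03,
    C18_1trans = 0.75, C18_1cis9 = 2.63, C18_1cis = 2.78, C18_2 = 0.22,
    C18_2cis9cis12 = 0.15, C18_2cis9trans11 = 0.10,
    C18_3cis9cis12cis15 = 0.33, SFA = 4.09, MUFA = 3.11, PUFA = 0.68,
    UFA = 3.57, SCFA = 0.60, MCFA = 3.95, LCFA = 4.12, BFA = 0.26,
    omega3 = 0.12, omega6 = 0.24, odd_FA = 0.35, trans_FA = 0.93,
    C18_1 = 3.08, fat = 0.34, protein = 0.19, milk_yield = 2.85,
    energy_balance = 3.36, nitrogen_efficiency = 14.12, blood_BHB = 0.09,
    blood_FFA = 131.57, DMI = 2.14)
}

#' Reference state-transition matrix (Walloon bulk-tank population)
#'
#' Published percentages of herds moving from one state at one bulk-tank
#' control to each state at the next control (1-3 days later) in the
#' Walloon population. Rows are the state at time t, columns the state at
#' time t + 1. Rows are renormalized to sum exactly to one (the printed
#' percentages carry rounding error of up to 0.01).
#'
#' @param as_probability Return row-stochastic probabilities (default) or
#'   the printed percentages.
#' @return 7 x 7 numeric matrix.
#' @export
walloon_transition_matrix <- function(as_probability = TRUE) {
  p <- matrix(c(
    65.63,  1.26,  0.09, 20.19,  5.97,  1.69,  5.17,
    40.24, 32.52,  2.32,  4.97, 10.86,  8.90,  0.20,
    2.78,  2.85, 55.75,  0.45, 23.67, 14.33,  0.17,
    22.02,  0.14,  0.01, 69.81,  0.43,  0.53,  7.06,
    20.68,  1.23,  2.25,  1.62, 64.65,  3.00,  6.56,
    24.01,  4.21,  6.55,  8.02, 13.18, 43.42,  0.62,
    19.83,  0.02,  0.01, 27.80,  5.54,  0.12, 46.68
  ), nrow = 7, byrow = TRUE,
  dimnames = list(paste0("state", 1:7), paste0("state", 1:7)))
  if (as_probability) p / rowSums(p) else p
}

#' Reference random-forest confusion matrix (Walloon subset)
#'
#' Published out-of-fold confusion matrix of the cross-validated random
#' forest predicting the 7 herd states from the 31 fatty acids on the
#' 27,322-record clustering subset. Rows are predicted states, columns
#' reference states.
#'
#' @return 7 x 7 integer matrix with `sum(x) == 27322`.
#' @export
walloon_rf_confusion <- function() {
  matrix(c(
    5781L, 122L,    0L,  279L,  100L,  113L,   59L,
    78L, 1651L,   24L,    0L,   30L,   57L,    0L,
    0L,   43L, 2979L,    0L,  105L,   72L,    0L,
    287L,    0L,    0L, 5875L,    0L,   36L,   46L,
    50L,   36L,  111L,    1L, 4001L,   48L,   62L,
    96L,   33L,   90L,   36L,   46L, 2623L,    8L,
    53L,    0L,    0L,   24L,   59L,    4L, 2204L
  ), nrow = 7, byrow = TRUE,
  dimnames = list(predicted = paste0("state", 1:7),
                  reference = paste0("state", 1:7)))
}
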