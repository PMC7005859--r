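# Monoisotopic mass bookkeeping shared by the whole package.
# Residue masses are the standard 20 amino-acid monoisotopic residue
# (i.e. dehydrated) masses in Da.

AA_RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

PROTON_MASS <- 1.007276
WATER_MASS <- 18.010565
PHOSPHO_MASS <- 79.96633
H3PO4_MASS <- 97.976896
# Monoisotopic isotope spacing used for envelope m/z grids.
NEUTRON_MASS <- 1.0033548

# Averagine model unit: average atomic composition per 111.1254 Da of peptide.
AVERAGINE_UNIT_MASS <- 111.1254
AVERAGINE_COMPOSITION <- c(C = 4.9384, H = 7.7583, N = 1.3577, O = 1.4773, S = 0.0417)

# Isotope abundance tables (M+0..M+2 per element, natural abundances).
ELEMENT_ISOTOPES <- list(
  C = c(0.9893, 0.0107),
  H = c(0.999885, 0.000115),
  N = c(0.99636, 0.00364),
  O = c(0.99757, 0.00038, 0.00205),
  S = c(0.9499, 0.0075, 0.0425, 0.0001)
)

#' Residue letters eligible for phosphorylation
#'
#' @return Character vector `c("S", "T", "Y")`.
#' @export
phospho_residues <- function() c("S", "T", "Y")
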