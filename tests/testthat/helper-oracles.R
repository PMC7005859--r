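# Independent oracles built from first principles (elemental compositions),
# deliberately not sharing code with the package's mass arithmetic.

oracle_elements <- c(
  C = 12, H = 1.0078250319, N = 14.0030740052, O = 15.9949146221,
  S = 31.97207069, P = 30.97376151
)

# residue formulas as element counts C,H,N,O,S
oracle_formulas <- list(
  G = c(2, 3, 1, 1, 0), A = c(3, 5, 1, 1, 0), S = c(3, 5, 1, 2, 0),
  P = c(5, 7, 1, 1, 0), V = c(5, 9, 1, 1, 0), T = c(4, 7, 1, 2, 0),
  C = c(3, 5, 1, 1, 1), L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
  N = c(4, 6, 2, 2, 0), D = c(4, 5, 1, 3, 0), Q = c(5, 8, 2, 2, 0),
  K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0), M = c(5, 9, 1, 1, 1),
  H = c(6, 7, 3, 1, 0), F = c(9, 9, 1, 1, 0), R = c(6, 12, 4, 1, 0),
  Y = c(9, 9, 1, 2, 0), W = c(11, 10, 2, 1, 0)
)

oracle_residue_mass <- function(aa) {
  f <- oracle_formulas[[aa]]
  unname(sum(f * oracle_elements[c("C", "H", "N", "O", "S")]))
}

oracle_phospho <- unname(oracle_elements["H"] + oracle_elements["P"] +
                           3 * oracle_elements["O"])
oracle_water <- unname(2 * oracle_elements["H"] + oracle_elements["O"])
oracle_proton <- 1.007276

# length-safe sampling of one element
pick_one <- function(x) x[sample.int(length(x), 1)]

# brute-force fragment m/z for one phospho placement
oracle_fragment_mz <- function(sequence, phospho_positions, series, index,
                               charge) {
  res <- strsplit(sequence, "")[[1]]
  masses <- vapply(res, oracle_residue_mass, numeric(1))
  masses[phospho_positions] <- masses[phospho_positions] + oracle_phospho
  neutral <- if (series == "b") {
    sum(masses[seq_len(index)])
  } else {
    sum(masses[(length(res) - index + 1):length(res)]) + oracle_water
  }
  (neutral + charge * oracle_proton) / charge
}

# random valid peptide with at least min_sty S/T/Y residues
random_test_peptide <- function(min_len = 5, max_len = 15, min_sty = 1) {
  repeat {
    len <- sample(min_len:max_len, 1)
    s <- paste0(sample(names(oracle_formulas), len, replace = TRUE),
                collapse = "")
    if (sum(strsplit(s, "")[[1]] %in% c("S", "T", "Y")) >= min_sty) return(s)
  }
}

# analytic averagine binomial check: expected M+1/M+0 from carbon count alone
oracle_m1_over_m0_carbon <- function(mass) {
  n_c <- 4.9384 * mass / 111.1254
  n_c * 0.0107 / 0.9893
}
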