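test_that("site candidate enumeration matches binomial coefficients", {
  expect_equal(nrow(enumerate_site_candidates(modified_peptide("TESTS", 1))), 4)
  expect_equal(nrow(enumerate_site_candidates(modified_peptide("TESTS", 2))), 6)
  expect_error(modified_peptide("AGLK", 1), "no valid site combination")
  expect_error(enumerate_site_candidates(modified_peptide("TESTS", 0)),
               "nothing to localize")

  # exhaustive check over synthetic S-runs: C(n, p) for n <= 8, p <= 4
  for (n in 1:8) {
    seqn <- paste0(strrep("S", n), "K")
    for (p in 1:min(n, 4)) {
      cands <- enumerate_site_candidates(modified_peptide(seqn, p))
      expect_equal(nrow(cands), choose(n, p))
      expect_equal(anyDuplicated(vapply(cands$positions, paste,
                                        character(1), collapse = ",")), 0)
    }
  }
})

test_that("candidate order is lexicographic by position tuple", {
  cands <- enumerate_site_candidates(modified_peptide("TESTS", 2))
  tuples <- do.call(rbind, cands$positions)
  ord <- order(tuples[, 1], tuples[, 2])
  expect_equal(ord, seq_len(nrow(tuples)))
})

test_that("fragment masses match the elemental-composition oracle", {
  # frozen spot checks, computed from the oracle
  frags <- theoretical_fragments(modified_peptide("ASK", 1), 2, charges = 1)
  y1 <- frags$mz[frags$series == "y" & frags$index == 1]
  b2 <- frags$mz[frags$series == "b" & frags$index == 2]
  expect_equal(y1, 147.1128, tolerance = 1e-4)
  expect_equal(b2, 239.0428, tolerance = 1e-4)

  set.seed(42)
  for (rep in seq_len(1000)) {
    seqp <- random_test_peptide(min_sty = 1)
    pep <- modified_peptide(seqp, 1)
    pos <- pick_one(pep$candidate_residues)
    frags <- theoretical_fragments(pep, pos, charges = sample(1:2, 1))
    j <- sample(nrow(frags), 1)
    expected <- oracle_fragment_mz(seqp, pos, frags$series[j], frags$index[j],
                                   frags$charge[j])
    expect_equal(frags$mz[j], expected, tolerance = 1e-4)
  }
})

test_that("b/y complementarity: paired neutral masses sum to precursor mass", {
  set.seed(7)
  for (rep in seq_len(20)) {
    seqp <- random_test_peptide(min_sty = 1)
    pep <- modified_peptide(seqp, 1)
    pos <- pick_one(pep$candidate_residues)
    frags <- theoretical_fragments(pep, pos, charges = 1)
    n <- nchar(seqp)
    total <- peptide_mass(pep)
    for (i in seq_len(n - 1)) {
      b <- frags$mz[frags$series == "b" & frags$index == i]
      y <- frags$mz[frags$series == "y" & frags$index == n - i]
      # singly protonated: (b - H) + (y - H) = neutral mass, so b + y = M + 2H
      expect_equal(b + y, total + 2 * 1.007276, tolerance = 1e-3)
    }
  }
})

test_that("unknown residues and invalid phospho placements are rejected", {
  expect_error(modified_peptide("ASBZK", 1), "unknown residue")
  expect_error(theoretical_fragments(modified_peptide("ASK", 1), 1),
               "phospho_count")
  expect_error(modified_peptide("ASK", 2), "no valid site combination")
})

test_that("neutral-loss fragments are flagged duplicates shifted by -H3PO4", {
  pep <- modified_peptide("ASTK", 1)
  plain <- theoretical_fragments(pep, 2, charges = 1)
  with_nl <- theoretical_fragments(pep, 2, charges = 1, neutral_loss = TRUE)
  nl <- dplyr::filter(with_nl, loss == "H3PO4")
  expect_true(all(nl$n_phospho > 0))
  for (i in seq_len(nrow(nl))) {
    parent <- plain$mz[plain$series == nl$series[i] & plain$index == nl$index[i]]
    expect_equal(parent - nl$mz[i], 97.976896, tolerance = 1e-5)
  }
})

test_that("site-determining table separates confirming and refuting masses", {
  pep <- modified_peptide("SASK", 1)
  tab <- site_determining_fragments(pep, charges = 1)

  b1_phos <- dplyr::filter(tab, abs(mz - 168.0056) < 1e-3)
  expect_equal(b1_phos$role[b1_phos$candidate == "S1"], "confirming")
  expect_equal(b1_phos$role[b1_phos$candidate == "S3"], "refuting")
  b1_bare <- dplyr::filter(tab, abs(mz - 88.0393) < 1e-3)
  expect_equal(b1_bare$role[b1_bare$candidate == "S1"], "refuting")
  expect_equal(b1_bare$role[b1_bare$candidate == "S3"], "confirming")

  # unique-mass count bounded by the summed per-candidate fragment counts
  cands <- enumerate_site_candidates(pep)
  per_cand <- sum(vapply(cands$positions, function(p) {
    nrow(theoretical_fragments(pep, p, charges = 1))
  }, numeric(1)))
  expect_lte(dplyr::n_distinct(tab$mass_id), per_cand)
})

test_that("single-candidate peptides yield only neutral masses", {
  pep <- modified_peptide("ASGLK", 1)
  tab <- site_determining_fragments(pep)
  expect_true(all(tab$role == "neutral"))
})

test_that("confirming/refuting annotation is antisymmetric", {
  set.seed(11)
  for (rep in seq_len(25)) {
    seqp <- random_test_peptide(min_sty = 2)
    pep <- modified_peptide(seqp, sample(1:2, 1))
    tab <- site_determining_fragments(pep)
    roles <- tidyr::pivot_wider(tab[, c("mass_id", "candidate", "role")],
                                names_from = "candidate", values_from = "role")
    mat <- as.matrix(roles[, -1])
    for (i in seq_len(nrow(mat))) {
      r <- mat[i, ]
      # a mass is either neutral for everyone or a confirm/refute split
      expect_true(all(r == "neutral") ||
                    (any(r == "confirming") && any(r == "refuting") &&
                       !any(r == "neutral")))
    }
  }
})

test_that("averagine envelopes are normalized with sensible shape", {
  env <- isotope_envelope(500, 1)
  expect_equal(sum(env$abundance), 1, tolerance = 1e-6)
  expect_true(all(env$abundance >= 0))
  expect_equal(which.max(env$abundance), 1)  # M+0 dominates at 500 Da

  # M+1/M+0 grows monotonically with mass (carbon count grows)
  masses <- seq(200, 4000, by = 200)
  ratios <- vapply(masses, function(m) {
    e <- isotope_envelope(m, 1)
    e$abundance[2] / e$abundance[1]
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
  # and tracks the carbon-binomial expectation within 15%
  expect_equal(ratios[5], oracle_m1_over_m0_carbon(masses[5]), tolerance = 0.15)

  expect_error(isotope_envelope(-5, 1), "> 0")
  expect_error(isotope_envelope(500, 0), "charge")
})

test_that("peptide mass includes water, fixed mods and phospho groups", {
  pep <- modified_peptide("ACDEK", 0,
                          fixed_mods = tibble::tibble(position = 2,
                                                      mass = 57.02146))
  res <- sum(vapply(c("A", "C", "D", "E", "K"), oracle_residue_mass,
                    numeric(1)))
  expect_equal(peptide_mass(pep), res + oracle_water + 57.02146,
               tolerance = 1e-4)
  pep2 <- modified_peptide("ASK", 1)
  expect_equal(peptide_mass(pep2),
               sum(vapply(c("A", "S", "K"), oracle_residue_mass, numeric(1))) +
                 oracle_water + oracle_phospho,
               tolerance = 1e-4, ignore_attr = TRUE)
})
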