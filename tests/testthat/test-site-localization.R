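# Build a tiny single-window run around one peptide for evidence tests.
evidence_fixture <- function(sequence = "SAAGLLEDSK", true_pos = 1,
                             abundance = 1e5, cv = 0, seed = 5,
                             scale = 1) {
  roster <- tibble::tibble(
    sequence = sequence, phospho_count = 1L,
    true_positions = list(as.integer(true_pos)),
    charge = 2L, rt = 100, abundance = abundance
  )
  cfg <- dia_sim_config(roster, cycle_time = 2, rt_max = 200,
                        elution_sigma = 5, intensity_cv = cv, seed = seed)
  sim <- simulate_dia_run(cfg)
  if (scale != 1) {
    sim$run$intensity <- lapply(sim$run$intensity, function(i) i * scale)
  }
  sim
}

localize_fixture <- function(sim, sequence = "SAAGLLEDSK", threshold = 0.75,
                             config = localization_config()) {
  pep <- modified_peptide(sequence, 1L)
  localize_precursor(sim$run, pep, 2L, build_window_scheme(),
                     threshold = threshold, config = config,
                     rt_range = c(50, 150))
}

test_that("candidate scores follow the confirm-minus-refute rule", {
  candidates <- tibble::tibble(
    candidate = c("A", "B"),
    positions = list(1L, 3L)
  )
  mass_table <- tibble::tibble(
    mass_id = c(1L, 1L, 2L, 2L, 3L, 3L),
    mz = c(100, 100, 200, 200, 300, 300),
    charge = 1L,
    candidate = rep(c("A", "B"), 3),
    role = c("confirming", "refuting",
             "confirming", "refuting",
             "refuting", "confirming")
  )
  evidence <- tibble::tibble(
    mass_id = 1:3, mz = c(100, 200, 300), charge = 1L,
    observed = TRUE, weight = c(0.8, 0.6, 0.3)
  )
  scores <- score_candidates(evidence, mass_table, candidates)
  expect_equal(scores$raw_score[scores$candidate == "A"], 0.8 + 0.6 - 0.3)
  expect_equal(scores$raw_score[scores$candidate == "B"], 0.3 - 1.4)
  # negative raw score floors to zero: A takes all the confidence
  expect_equal(scores$fractional_confidence, c(1, 0))
})

test_that("fractional confidences normalize raw scores and fall back to uniform", {
  candidates <- tibble::tibble(candidate = c("A", "B", "C"),
                               positions = list(1L, 2L, 3L))
  mass_table <- tibble::tibble(
    mass_id = rep(1:3, each = 3), mz = rep(c(100, 200, 300), each = 3),
    charge = 1L,
    candidate = rep(c("A", "B", "C"), 3),
    role = c("confirming", "refuting", "refuting",
             "refuting", "confirming", "refuting",
             "refuting", "refuting", "confirming")
  )
  evidence <- tibble::tibble(
    mass_id = 1:3, mz = c(100, 200, 300), charge = 1L,
    observed = TRUE, weight = c(2, 1, 1) / 2
  )
  # counteract refutation by scoring each mass alone: use three observed
  # confirming fragments with weights 2, 1, 1 and no refuting observations
  mass_table$role[mass_table$role == "refuting"] <- "neutral"
  scores <- score_candidates(evidence, mass_table, candidates)
  expect_equal(scores$fractional_confidence, c(0.5, 0.25, 0.25))

  none <- dplyr::mutate(evidence, observed = FALSE, weight = 0)
  uniform <- score_candidates(none, mass_table, candidates)
  expect_equal(uniform$fractional_confidence, rep(1 / 3, 3))
})

test_that("site confidences aggregate candidates and sum to phospho count", {
  pep1 <- modified_peptide("ASGLK", 1)  # single candidate
  single <- score_candidates(
    tibble::tibble(mass_id = integer(), mz = numeric(), charge = integer(),
                   observed = logical(), weight = numeric()),
    site_determining_fragments(pep1),
    enumerate_site_candidates(pep1)
  )
  tab1 <- site_confidences(single, pep1)
  expect_equal(tab1$confidence, 1)
  expect_true(tab1$class1)

  # fractional 0.5/0.25/0.25 at p = 1: nothing reaches Class I at 0.75
  pep3 <- modified_peptide("ASGSGTK", 1)
  cands <- enumerate_site_candidates(pep3)
  scores <- tibble::tibble(
    candidate = cands$candidate, positions = cands$positions,
    raw_score = c(2, 1, 1), fractional_confidence = c(0.5, 0.25, 0.25)
  )
  tab3 <- site_confidences(scores, pep3, threshold = 0.75)
  expect_false(any(tab3$class1))
  expect_equal(sum(tab3$confidence), 1)

  # p = 2 over three residues: residue confidences sum to 2
  pep2 <- modified_peptide("ASGSGTK", 2)
  cands2 <- enumerate_site_candidates(pep2)
  scores2 <- tibble::tibble(
    candidate = cands2$candidate, positions = cands2$positions,
    raw_score = 1, fractional_confidence = rep(1 / 3, 3)
  )
  expect_equal(sum(site_confidences(scores2, pep2)$confidence), 2,
               tolerance = 1e-9)
})

test_that("fragment evidence components behave at their anchors", {
  sim <- evidence_fixture(cv = 0)
  loc <- localize_fixture(sim)
  pep <- modified_peptide("SAAGLLEDSK", 1)
  mass_table <- site_determining_fragments(pep)
  ev <- score_fragment_evidence(mass_table, loc$peak_group, sim$run,
                                loc$window)
  obs <- dplyr::filter(ev, observed)
  expect_gt(nrow(obs), 0)
  # noiseless simulation at theoretical m/z: ppm error 0, correlation 1
  expect_true(all(obs$mass_accuracy_component > 0.999))
  expect_true(all(obs$xic_correlation_component > 0.99))
  # strongest fragment anchors the intensity component at 1
  expect_equal(max(obs$intensity_component), 1)
  # unobserved masses carry no weight
  expect_true(all(ev$weight[!ev$observed] == 0))
  expect_error(
    score_fragment_evidence(mass_table[0, ], loc$peak_group, sim$run,
                            loc$window),
    "empty"
  )
})

test_that("low-correlation fragments are removed as interference", {
  sim <- evidence_fixture(cv = 0)
  loc <- localize_fixture(sim)
  pep <- modified_peptide("SAAGLLEDSK", 1)
  mass_table <- site_determining_fragments(pep)
  # inject a flat interference trace exactly on one site-determining mass
  target <- mass_table$mz[mass_table$role == "confirming"][1]
  run2 <- sim$run
  is_w <- run2$ms_level == 2L & run2$window == loc$window
  run2$mz[is_w] <- lapply(run2$mz[is_w], function(m) sort(c(m, target)))
  run2$intensity[is_w] <- purrr::map2(
    run2$mz[is_w], run2$intensity[is_w],
    function(m, i) {
      out <- numeric(length(m))
      out[match(setdiff(seq_along(m), which(abs(m - target) < 1e-9)[1]),
                seq_along(m))] <- i
      out[which(abs(m - target) < 1e-9)[1]] <- 5e4
      out
    }
  )
  # rebuild a clean run where that mass is ONLY flat interference
  ev <- score_fragment_evidence(mass_table, loc$peak_group, run2, loc$window)
  flat <- dplyr::filter(ev, abs(mz - target) < 1e-6)
  expect_lt(flat$xic_correlation_component, 0.25)
  expect_equal(flat$weight, 0)
})

test_that("mirrored isomer evidence scores exactly 0.5/0.5", {
  roster <- tibble::tibble(
    sequence = c("SAAGLLEDSK", "SAAGLLEDSK"), phospho_count = 1L,
    true_positions = list(1L, 9L),
    charge = 2L, rt = 100, abundance = 1e5
  )
  # equal relative intensity for every fragment of both isomers and no noise:
  # the evidence for S1 and S9 is an exact mirror image
  cfg <- dia_sim_config(roster, cycle_time = 2, rt_max = 200,
                        elution_sigma = 5, intensity_cv = 0,
                        fragment_rel_range = c(1, 1), seed = 1)
  sim <- simulate_dia_run(cfg)
  loc <- localize_fixture(sim)
  conf <- sort(loc$sites$confidence)
  expect_equal(conf, c(0.5, 0.5), tolerance = 1e-9)
  expect_false(any(loc$sites$class1))
})

test_that("localization is invariant to a global intensity rescale", {
  sim <- evidence_fixture(cv = 0.05, seed = 9)
  loc1 <- localize_fixture(sim)
  sim_scaled <- sim
  sim_scaled$run$intensity <- lapply(sim$run$intensity, function(i) 17 * i)
  loc2 <- localize_fixture(sim_scaled)
  expect_equal(loc1$sites$confidence, loc2$sites$confidence, tolerance = 1e-9)
  expect_equal(loc2$quantity / loc1$quantity, 17, tolerance = 1e-6)
})

test_that("boosting a confirming fragment never lowers its site confidence", {
  sim <- evidence_fixture(cv = 0.05, seed = 13)
  pep <- modified_peptide("SAAGLLEDSK", 1)
  mass_table <- site_determining_fragments(pep)
  loc <- localize_fixture(sim)
  base_conf <- loc$sites$confidence[loc$sites$position == 1]
  # boost every confirming mass of candidate S1 by increasing factors
  s1_masses <- mass_table$mz[mass_table$candidate == "S1" &
                               mass_table$role == "confirming"]
  prev <- base_conf
  for (factor in c(2, 5)) {
    run_b <- sim$run
    is_w <- run_b$ms_level == 2L & run_b$window == loc$window
    run_b$intensity[is_w] <- purrr::map2(
      run_b$mz[is_w], run_b$intensity[is_w],
      function(m, i) {
        hit <- vapply(m, function(x) any(abs(x - s1_masses) < 0.005),
                      logical(1))
        i * ifelse(hit, factor, 1)
      }
    )
    sim_b <- sim
    sim_b$run <- run_b
    loc_b <- localize_fixture(sim_b)
    conf_b <- loc_b$sites$confidence[loc_b$sites$position == 1]
    expect_gte(conf_b, prev - 1e-9)
    prev <- conf_b
  }
})

test_that("localization strings round-trip through format and parse", {
  sites <- tibble::tibble(position = c(3L, 5L), residue = c("S", "S"),
                          confidence = c(0.75, 0.25), class1 = c(TRUE, FALSE))
  s <- format_localization_string("AASLSK", sites)
  expect_equal(s, "AAS(0.75)LS(0.25)K")
  parsed <- parse_localization_string(s)
  expect_equal(parsed, c(`3` = 0.75, `5` = 0.25))
})
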