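#' Simulate the mixed-species ratio benchmark
#'
#' Emulates a two-species dilution design: a constant background population
#' (ratio 1 in every condition) plus a regulated subpopulation whose
#' abundance is scaled by a known per-condition ratio over a 1:1 reference.
#' Intensities are log-normal with multiplicative replicate noise at the
#' stated coefficient of variation. The default ratio set
#' `{0.25, 0.5, 1.5, 2}` is the canonical four-condition benchmark.
#'
#' @param n_background Number of unregulated (background) features.
#' @param n_regulated Number of regulated features.
#' @param ratios Per-condition ratios of the regulated subpopulation over the
#'   reference (all > 0).
#' @param cv Replicate coefficient of variation (0 = noiseless).
#' @param replicates Replicates per condition.
#' @param seed Integer seed (fixes all randomness).
#' @param base_meanlog,base_sdlog Log-normal parameters of feature base
#'   intensities.
#' @return A list: `quant` (long tibble: `feature`, `species`, `condition`,
#'   `true_ratio`, `replicate`, `intensity`) and `truth` (tibble: `feature`,
#'   `species`, `regulated`).
#' @export
simulate_species_mix <- function(n_background = 1000L, n_regulated = 200L,
                                 ratios = c(0.25, 0.5, 1.5, 2), cv = 0.10,
                                 replicates = 3L, seed = NULL,
                                 base_meanlog = log(1e6), base_sdlog = 1) {
  if (any(ratios <= 0)) abort("`ratios` must be > 0")
  if (!is.null(seed)) set.seed(seed)
  n <- n_background + n_regulated
  features <- tibble(
    feature = sprintf("f%04d", seq_len(n)),
    species = rep(c("background", "regulated"), c(n_background, n_regulated)),
    base = rlnorm(n, base_meanlog, base_sdlog)
  )
  conditions <- tibble(
    condition = c("ref", sprintf("r%g", ratios)),
    true_ratio = c(1, ratios)
  )
  sdlog <- sqrt(log(1 + cv^2))
  quant <- tidyr::crossing(features, conditions,
                           replicate = seq_len(replicates)) %>%
    dplyr::mutate(
      scale = ifelse(.data$species == "regulated", .data$true_ratio, 1),
      noise = if (cv > 0) rlnorm(dplyr::n(), -sdlog^2 / 2, sdlog) else 1,
      intensity = .data$base * .data$scale * .data$noise
    ) %>%
    dplyr::select("feature", "species", "condition", "true_ratio",
                  "replicate", "intensity")
  list(
    quant = quant,
    truth = dplyr::mutate(
      dplyr::select(features, "feature", "species"),
      regulated = .data$species == "regulated"
    )
  )
}

#' Estimate per-feature fold changes against the reference condition
#'
#' For each feature, computes the ratio of its replicate-mean intensity in
#' every condition to its replicate-mean intensity in the reference.
#'
#' @param quant Long quantification tibble from [simulate_species_mix()]
#'   (columns `feature`, `condition`, `replicate`, `intensity`; extra columns
#'   are carried through).
#' @param reference Name of the reference condition (default `"ref"`).
#' @return A tibble: one row per feature x non-reference condition with
#'   `fold_change` plus carried-through annotation columns.
#' @export
estimate_fold_changes <- function(quant, reference = "ref") {
  keys <- intersect(c("species", "true_ratio"), names(quant))
  means <- quant %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(c("feature", keys, "condition")))) %>%
    dplyr::summarise(mean_intensity = mean(.data$intensity), .groups = "drop")
  ref <- means %>%
    dplyr::filter(.data$condition == reference) %>%
    dplyr::select("feature", ref_intensity = "mean_intensity")
  means %>%
    dplyr::filter(.data$condition != reference) %>%
    dplyr::inner_join(ref, by = "feature") %>%
    dplyr::mutate(fold_change = .data$mean_intensity / .data$ref_intensity)
}

#' Simulate the phosphosite stoichiometry benchmark
#'
#' Emulates a fixed-occupancy mixing design: for every site, a protein
#' abundance is drawn log-normal and each condition carries a known
#' fractional occupancy `a`. Measured intensities are
#' `P = alpha * a * T * noise`, `N = beta * (1 - a) * T * noise`,
#' `Q = T * noise`, with independent log-normal multiplicative noise at the
#' stated CV. The default occupancy grid `{1, 10, 50, 90, 99}%` is the
#' five-condition benchmark design.
#'
#' @param occupancies Per-condition true occupancies, all strictly inside
#'   (0, 1).
#' @param n_sites Number of simulated sites.
#' @param cv Coefficient of variation of the multiplicative noise.
#' @param replicates Replicates per condition.
#' @param alpha,beta Response factors of the phospho / non-phospho forms.
#' @param seed Integer seed.
#' @param protein_meanlog,protein_sdlog Log-normal parameters of protein
#'   abundances.
#' @return A list: `triplets` (long tibble: `site`, `condition`, `replicate`,
#'   `P`, `N`, `Q`) and `truth` (tibble: `condition`, `occupancy`).
#' @export
simulate_stoichiometry_benchmark <- function(occupancies = c(0.01, 0.10, 0.50, 0.90, 0.99),
                                             n_sites = 500L, cv = 0.10,
                                             replicates = 3L,
                                             alpha = 1, beta = 1, seed = NULL,
                                             protein_meanlog = log(1e7),
                                             protein_sdlog = 1) {
  if (any(occupancies <= 0 | occupancies >= 1)) {
    abort("occupancies must lie strictly inside (0, 1)")
  }
  if (!is.null(seed)) set.seed(seed)
  sites <- tibble(
    site = sprintf("s%04d", seq_len(n_sites)),
    protein_abundance = rlnorm(n_sites, protein_meanlog, protein_sdlog)
  )
  conditions <- tibble(
    condition = sprintf("c%d", seq_along(occupancies)),
    occupancy = occupancies
  )
  sdlog <- sqrt(log(1 + cv^2))
  noise <- function(n) if (cv > 0) rlnorm(n, -sdlog^2 / 2, sdlog) else rep(1, n)
  triplets <- tidyr::crossing(sites, conditions,
                              replicate = seq_len(replicates)) %>%
    dplyr::mutate(
      P = alpha * .data$occupancy * .data$protein_abundance * noise(dplyr::n()),
      N = beta * (1 - .data$occupancy) * .data$protein_abundance * noise(dplyr::n()),
      Q = .data$protein_abundance * noise(dplyr::n())
    ) %>%
    dplyr::select("site", "condition", "replicate", "P", "N", "Q")
  list(triplets = triplets, truth = conditions)
}

#' Configuration for the DIA run simulator
#'
#' @param roster Tibble with one row per precursor: `sequence`,
#'   `phospho_count`, `true_positions` (list-column of integer phospho
#'   positions), `charge`, `rt` (apex, seconds), `abundance`.
#' @param scheme Isolation-window scheme (default 48 x 14 Da, 1 Da overlap,
#'   from 350 Da).
#' @param cycle_time Scan-cycle duration in seconds (one MS1 plus a full
#'   window sweep per cycle).
#' @param rt_max Gradient length in seconds.
#' @param elution_sigma Gaussian elution peak width (s.d., seconds).
#' @param intensity_cv Multiplicative log-normal peak noise CV (0 = clean).
#' @param interference_density Expected number of interfering fragment peaks
#'   per isolation window over the run.
#' @param seed Integer seed fixing all randomness.
#' @return A list of class `dia_sim_config`.
#' @export
dia_sim_config <- function(roster, scheme = build_window_scheme(),
                           cycle_time = 3, rt_max = 300, elution_sigma = 5,
                           intensity_cv = 0.02, interference_density = 0,
                           fragment_rel_range = c(0.3, 1), seed = 1L) {
  stopifnot(all(c("sequence", "phospho_count", "true_positions", "charge",
                  "rt", "abundance") %in% names(roster)))
  structure(
    list(roster = roster, scheme = scheme, cycle_time = cycle_time,
         rt_max = rt_max, elution_sigma = elution_sigma,
         intensity_cv = intensity_cv,
         interference_density = interference_density,
         fragment_rel_range = fragment_rel_range, seed = seed),
    class = "dia_sim_config"
  )
}

#' Random phosphopeptide roster for simulations
#'
#' Draws tryptic-like peptides (length 8-14, C-terminal K/R) containing at
#' least two S/T/Y residues, each carrying one phospho group on a randomly
#' chosen true site, spread uniformly over the gradient.
#'
#' @param n Number of precursors.
#' @param seed Integer seed.
#' @param rt_range Retention-time range for apexes (seconds).
#' @param charge Precursor charge assigned to all peptides.
#' @return A roster tibble for [dia_sim_config()], including a
#'   `precursor_mz` column.
#' @export
random_phosphopeptide_roster <- function(n, seed = 1L, rt_range = c(40, 260),
                                         charge = 2L) {
  set.seed(seed)
  aa_pool <- c("A", "G", "L", "V", "E", "D", "P", "F", "N", "Q")
  sty <- phospho_residues()
  make_seq <- function() {
    len <- sample(8:14, 1)
    res <- sample(aa_pool, len - 1L, replace = TRUE)
    n_sty <- sample(2:3, 1)
    pos <- sort(sample(seq_len(len - 1L), n_sty))
    res[pos] <- sample(sty, n_sty, replace = TRUE)
    paste0(paste0(res, collapse = ""), sample(c("K", "R"), 1))
  }
  seqs <- replicate(n, make_seq())
  roster <- tibble(
    sequence = seqs,
    phospho_count = 1L,
    true_positions = purrr::map(seqs, function(s) {
      pep <- modified_peptide(s, 1L)
      sample(pep$candidate_residues, 1L)
    }),
    charge = charge,
    rt = runif(n, rt_range[1], rt_range[2]),
    abundance = rlnorm(n, log(1e5), 0.5)
  )
  roster$precursor_mz <- vapply(seq_len(n), function(i) {
    precursor_mz(modified_peptide(roster$sequence[i], 1L), charge)
  }, numeric(1))
  roster
}

#' Simulate a DIA run with known phosphosite ground truth
#'
#' Forward-models a centroided DIA acquisition: every roster precursor
#' contributes an averagine MS1 isotope envelope and the singly charged b/y
#' fragment peaks of its true site candidate (with random library-like
#' relative intensities) to the MS2 scans of its isolation window(s), shaped
#' by a Gaussian elution profile and multiplicative log-normal intensity
#' noise. Positional isomers are simulated by listing the same sequence twice
#' with different `true_positions` (identical `rt` = exact co-elution).
#' Optional interference adds random fragment masses with their own elution
#' profiles uniformly over each window.
#'
#' @param config A [dia_sim_config()].
#' @return A list: `run` (a [dia_run()]), `truth` (tibble: `sequence`,
#'   `charge`, `true_positions` string, `rt`, `abundance`, `precursor_mz`),
#'   and `roster` (the input roster with `precursor_mz`).
#' @export
simulate_dia_run <- function(config) {
  stopifnot(inherits(config, "dia_sim_config"))
  set.seed(config$seed)
  roster <- config$roster
  scheme <- config$scheme
  n_pep <- nrow(roster)
  roster$precursor_mz <- vapply(seq_len(n_pep), function(i) {
    pep <- modified_peptide(roster$sequence[i], roster$phospho_count[i])
    precursor_mz(pep, roster$charge[i])
  }, numeric(1))
  out_of_range <- roster$precursor_mz < min(scheme$lower) |
    roster$precursor_mz > max(scheme$upper)
  if (any(out_of_range)) {
    abort(paste0("precursor m/z outside the window scheme for: ",
                 paste(roster$sequence[out_of_range], collapse = ", ")))
  }
  cycles <- seq(0, config$rt_max, by = config$cycle_time)
  sdlog <- sqrt(log(1 + config$intensity_cv^2))
  noise <- function(n) {
    if (config$intensity_cv > 0) rlnorm(n, -sdlog^2 / 2, sdlog) else rep(1, n)
  }

  peak_tbl <- purrr::map_dfr(seq_len(n_pep), function(i) {
    pep <- modified_peptide(roster$sequence[i], roster$phospho_count[i])
    frags <- theoretical_fragments(pep, roster$true_positions[[i]], charges = 1L)
    rel <- runif(nrow(frags), config$fragment_rel_range[1],
                 config$fragment_rel_range[2])
    env <- isotope_envelope(peptide_mass(pep), roster$charge[i])
    env <- env[env$abundance > 0.01, ]
    gauss <- exp(-(cycles - roster$rt[i])^2 / (2 * config$elution_sigma^2))
    active <- which(gauss > 1e-3)
    if (length(active) == 0L) return(NULL)
    windows <- assign_windows(roster$precursor_mz[i], scheme)
    ms2 <- tidyr::crossing(
      tibble(cycle = active),
      tibble(mz = frags$mz, rel = rel)
    ) %>%
      dplyr::mutate(
        intensity = roster$abundance[i] * .data$rel * gauss[.data$cycle] *
          noise(dplyr::n())
      )
    ms2 <- tidyr::crossing(ms2, window = windows)
    ms1 <- tidyr::crossing(
      tibble(cycle = active),
      tibble(mz = env$mz, rel = env$abundance)
    ) %>%
      dplyr::mutate(
        intensity = roster$abundance[i] * .data$rel * gauss[.data$cycle] *
          noise(dplyr::n()),
        window = NA_integer_
      )
    dplyr::bind_rows(
      dplyr::select(ms1, "cycle", "window", "mz", "intensity"),
      dplyr::select(ms2, "cycle", "window", "mz", "intensity")
    )
  })

  if (config$interference_density > 0) {
    interference <- purrr::map_dfr(scheme$index, function(w) {
      k <- stats::rpois(1, config$interference_density)
      if (k == 0L) return(NULL)
      purrr::map_dfr(seq_len(k), function(j) {
        fmz <- runif(1, 150, 1300)
        apex <- runif(1, 0, config$rt_max)
        ab <- rlnorm(1, log(5e4), 0.5)
        gauss <- exp(-(cycles - apex)^2 / (2 * config$elution_sigma^2))
        active <- which(gauss > 1e-3)
        if (length(active) == 0L) return(NULL)
        tibble(cycle = active, window = w, mz = fmz,
               intensity = ab * gauss[active] * noise(length(active)))
      })
    })
    peak_tbl <- dplyr::bind_rows(peak_tbl, interference)
  }

  # assemble scans: every cycle has one MS1 scan and one MS2 scan per window
  scan_grid <- dplyr::bind_rows(
    tibble(cycle = seq_along(cycles), ms_level = 1L, window = NA_integer_),
    tidyr::crossing(cycle = seq_along(cycles), window = scheme$index) %>%
      dplyr::mutate(ms_level = 2L)
  ) %>%
    dplyr::arrange(.data$cycle, .data$ms_level, .data$window) %>%
    dplyr::mutate(scan = dplyr::row_number(), rt = cycles[.data$cycle])

  peak_tbl <- peak_tbl %>%
    dplyr::mutate(ms_level = ifelse(is.na(.data$window), 1L, 2L)) %>%
    dplyr::inner_join(scan_grid, by = c("cycle", "window", "ms_level"))
  peaks_by_scan <- split(peak_tbl[, c("mz", "intensity")], peak_tbl$scan)

  empty <- tibble(mz = numeric(), intensity = numeric())
  mz_list <- vector("list", nrow(scan_grid))
  int_list <- vector("list", nrow(scan_grid))
  for (s in seq_len(nrow(scan_grid))) {
    p <- peaks_by_scan[[as.character(s)]]
    if (is.null(p) || nrow(p) == 0L) {
      mz_list[[s]] <- numeric()
      int_list[[s]] <- numeric()
    } else {
      # merge peaks closer than 1 mDa (co-incident contributions sum)
      agg <- p %>%
        dplyr::arrange(.data$mz) %>%
        dplyr::mutate(cl = cumsum(c(1L, as.integer(diff(.data$mz) > 1e-3)))) %>%
        dplyr::group_by(.data$cl) %>%
        dplyr::summarise(
          mz2 = sum(.data$mz * .data$intensity) / sum(.data$intensity),
          intensity = sum(.data$intensity), .groups = "drop"
        )
      mz_list[[s]] <- agg$mz2
      int_list[[s]] <- agg$intensity
    }
  }

  run <- dia_run(
    scan = scan_grid$scan, ms_level = scan_grid$ms_level,
    rt = scan_grid$rt, window = scan_grid$window,
    mz = mz_list, intensity = int_list
  )
  truth <- roster %>%
    dplyr::mutate(
      true_positions = vapply(.data$true_positions, paste, character(1),
                              collapse = ";")
    ) %>%
    dplyr::select("sequence", "charge", "true_positions", "rt", "abundance",
                  "precursor_mz")
  list(run = run, truth = truth, roster = roster)
}

#' Benchmark site localization on a simulated DIA run
#'
#' Localizes every roster precursor of a [simulate_dia_run()] output and
#' compares the Class I calls against the generative ground truth.
#'
#' @param sim Output of [simulate_dia_run()].
#' @param threshold Class I cutoff (default 0.75).
#' @param config A [localization_config()].
#' @param rt_halfwidth Retention-time search half-window (seconds).
#' @return A list: `calls` (per Class I call: `sequence`, `called_position`,
#'   `true_position`, `correct`), `report` (full localization report),
#'   `correct_rate`, `error_rate`, `n_class1`.
#' @export
localization_benchmark <- function(sim, threshold = 0.75,
                                   config = localization_config(),
                                   rt_halfwidth = 45) {
  roster <- sim$roster
  scheme <- attr(sim$run, "scheme")
  if (is.null(scheme)) scheme <- build_window_scheme()
  calls <- purrr::map_dfr(seq_len(nrow(roster)), function(i) {
    pep <- modified_peptide(roster$sequence[i], roster$phospho_count[i])
    loc <- tryCatch(
      localize_precursor(sim$run, pep, roster$charge[i], scheme,
                         threshold = threshold, config = config,
                         rt_range = roster$rt[i] + c(-1, 1) * rt_halfwidth),
      error = function(e) NULL
    )
    if (is.null(loc)) return(NULL)
    class1 <- dplyr::filter(loc$sites, .data$class1)
    if (nrow(class1) == 0L) return(NULL)
    tibble(
      sequence = roster$sequence[i],
      called_position = class1$position,
      true_position = list(roster$true_positions[[i]]),
      correct = purrr::map2_lgl(class1$position, list(roster$true_positions[[i]]),
                                ~ .x %in% .y)
    )
  })
  n_class1 <- nrow(calls)
  correct_rate <- if (n_class1 > 0) mean(calls$correct) else NA_real_
  list(
    calls = calls,
    correct_rate = correct_rate,
    error_rate = 1 - correct_rate,
    n_class1 = n_class1
  )
}
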