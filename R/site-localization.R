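#' Localization scoring configuration
#'
#' Collects the tunable parameters of the site-localization score.
#'
#' @param sigma_ppm Width (ppm) of the Gaussian mass-accuracy component.
#' @param r_min Minimum XIC correlation against the peak-group consensus
#'   profile; fragments below it are treated as interference and their weight
#'   is forced to 0.
#' @param noise_floor_frac A fragment counts as observed only if its apex
#'   exceeds this fraction of the largest fragment apex in the peak group.
#' @param tolerance_ppm XIC extraction tolerance for evidence fragments.
#' @param combine How fragment-weight components are combined: `"product"`
#'   (default; any failing component vetoes the fragment) or `"mean"`.
#' @param use_isotope Include the isotope-pattern similarity component
#'   (requires resolved fragment isotope peaks in the data).
#' @param intensity_decades Dynamic range (in decades below the strongest
#'   fragment) over which the intensity component decays from 1 to 0.
#' @return A list of class `localization_config`.
#' @export
localization_config <- function(sigma_ppm = 10, r_min = 0.25,
                                noise_floor_frac = 0.01, tolerance_ppm = 20,
                                combine = c("product", "mean"),
                                use_isotope = FALSE,
                                intensity_decades = 3) {
  combine <- match.arg(combine)
  structure(
    list(
      sigma_ppm = sigma_ppm, r_min = r_min,
      noise_floor_frac = noise_floor_frac, tolerance_ppm = tolerance_ppm,
      combine = combine, use_isotope = use_isotope,
      intensity_decades = intensity_decades
    ),
    class = "localization_config"
  )
}

#' Score fragment-level localization evidence
#'
#' For every unique fragment mass of a positional-isomer candidate set,
#' extracts its XIC across the peak-group boundaries and computes the
#' fragment weight from four bounded components:
#'
#' * intensity: position of the fragment apex within the group's intensity
#'   dynamic range (1 for the strongest fragment, decaying by decade);
#' * mass accuracy: `exp(-(ppm / sigma_ppm)^2 / 2)` of the apex centroid;
#' * XIC correlation: Pearson correlation against the peak-group consensus
#'   profile; fragments with `r < r_min` are interference and forced to
#'   weight 0;
#' * optionally, isotope-pattern similarity of the observed M+0/M+1 ratio to
#'   the averagine expectation.
#'
#' The weight is the product (or mean) of the components clamped to [0, 1];
#' unobserved fragments have weight 0. All components are intensity-scale
#' invariant, so rescaling a run leaves localization unchanged.
#'
#' @param mass_table Unique-mass table from [site_determining_fragments()].
#' @param peak_group One row of [detect_peak_groups()] output.
#' @param run A [dia_run()].
#' @param window_index MS2 window to extract evidence from.
#' @param config A [localization_config()].
#' @return A tibble with one row per unique mass: `mass_id`, `mz`,
#'   `observed`, `apex_intensity`, `intensity_component`,
#'   `mass_accuracy_component`, `xic_correlation_component`,
#'   `isotope_component`, `weight`.
#' @export
score_fragment_evidence <- function(mass_table, peak_group, run, window_index,
                                    config = localization_config()) {
  masses <- dplyr::distinct(mass_table, .data$mass_id, .data$mz, .data$charge)
  if (nrow(masses) == 0L) abort("empty unique-mass table")
  profile <- peak_group$profile[[1]]
  scans <- select_scans(run, window_index, c(peak_group$left, peak_group$right))
  xm <- xic_matrix(scans, masses$mz, config$tolerance_ppm)
  ref <- approx_intensity(profile, scans$rt)

  apex_scan <- apply(xm, 2, which.max)
  apex_int <- apply(xm, 2, max)
  max_apex <- max(apex_int)
  if (max_apex <= 0) {
    return(dplyr::mutate(
      masses, observed = FALSE, apex_intensity = 0,
      intensity_component = 0, mass_accuracy_component = 0,
      xic_correlation_component = 0, isotope_component = 1, weight = 0
    ))
  }
  observed <- apex_int > config$noise_floor_frac * max_apex

  intensity_component <- clamp01(
    1 + log10(pmax(apex_int / max_apex, 1e-12)) / config$intensity_decades
  )

  ppm_err <- vapply(seq_len(nrow(masses)), function(j) {
    if (!observed[j]) return(NA_real_)
    centroid <- scan_centroid(scans[apex_scan[j], ], masses$mz[j], config$tolerance_ppm)
    if (is.na(centroid)) return(NA_real_)
    (centroid - masses$mz[j]) / masses$mz[j] * 1e6
  }, numeric(1))
  mass_accuracy_component <- ifelse(
    is.na(ppm_err), 0, exp(-(ppm_err / config$sigma_ppm)^2 / 2)
  )

  r <- apply(xm, 2, function(y) {
    if (sd(y) == 0 || sd(ref) == 0) return(0)
    suppressWarnings(cor(y, ref))
  })
  r[is.na(r)] <- 0

  isotope_component <- rep(1, nrow(masses))
  if (isTRUE(config$use_isotope)) {
    isotope_component <- vapply(seq_len(nrow(masses)), function(j) {
      if (!observed[j]) return(0)
      iso_similarity(scans[apex_scan[j], ], masses$mz[j], masses$charge[j],
                     config$tolerance_ppm)
    }, numeric(1))
  }

  comp <- cbind(
    intensity_component,
    mass_accuracy_component,
    clamp01(r),
    isotope_component
  )
  weight <- if (config$combine == "product") {
    apply(comp, 1, prod)
  } else {
    rowMeans(comp)
  }
  weight[!observed] <- 0
  weight[r < config$r_min] <- 0   # interference removal

  dplyr::mutate(
    masses,
    observed = observed,
    apex_intensity = apex_int,
    intensity_component = intensity_component,
    mass_accuracy_component = mass_accuracy_component,
    xic_correlation_component = r,
    isotope_component = isotope_component,
    weight = weight
  )
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# intensity-weighted centroid m/z of matched peaks in one scan
scan_centroid <- function(scan_row, target_mz, tolerance_ppm) {
  m <- scan_row$mz[[1]]
  i <- scan_row$intensity[[1]]
  tol <- target_mz * tolerance_ppm * 1e-6
  sel <- m >= target_mz - tol & m <= target_mz + tol & i > 0
  if (!any(sel)) return(NA_real_)
  sum(m[sel] * i[sel]) / sum(i[sel])
}

# similarity of observed M+1/M+0 ratio to the averagine expectation, in [0,1]
iso_similarity <- function(scan_row, mz, charge, tolerance_ppm) {
  i0 <- peak_intensity_at(scan_row, mz, tolerance_ppm)
  i1 <- peak_intensity_at(scan_row, mz + NEUTRON_MASS / charge, tolerance_ppm)
  if (i0 <= 0) return(0)
  neutral_mass <- mz * charge - charge * PROTON_MASS
  env <- isotope_envelope(neutral_mass, charge)
  expected <- env$abundance[2] / env$abundance[1]
  observed <- i1 / i0
  exp(-abs(log((observed + 1e-6) / (expected + 1e-6))))
}

peak_intensity_at <- function(scan_row, mz, tolerance_ppm) {
  m <- scan_row$mz[[1]]
  i <- scan_row$intensity[[1]]
  tol <- mz * tolerance_ppm * 1e-6
  sum(i[m >= mz - tol & m <= mz + tol])
}

#' Score site candidates from fragment evidence
#'
#' The raw score of a candidate is the sum of the weights of its observed
#' confirming fragments minus the sum of the weights of its observed refuting
#' fragments, floored at zero (a fractional confidence requires non-negative
#' mass). Fractional confidences are the floored scores normalized to sum to
#' one; if every candidate scores zero (no usable fragment evidence) the
#' confidence is uniform over candidates.
#'
#' @param evidence Output of [score_fragment_evidence()].
#' @param mass_table Unique-mass table from [site_determining_fragments()]
#'   (provides per-candidate roles).
#' @param candidates Candidate tibble from [enumerate_site_candidates()].
#' @return A tibble: `candidate`, `positions` (list), `raw_score`,
#'   `fractional_confidence`.
#' @export
score_candidates <- function(evidence, mass_table, candidates) {
  joined <- mass_table %>%
    dplyr::inner_join(
      dplyr::select(evidence, "mass_id", "observed", "weight"),
      by = "mass_id"
    )
  scores <- joined %>%
    dplyr::group_by(.data$candidate) %>%
    dplyr::summarise(
      raw_score = sum(.data$weight[.data$observed & .data$role == "confirming"]) -
        sum(.data$weight[.data$observed & .data$role == "refuting"]),
      .groups = "drop"
    ) %>%
    dplyr::mutate(floored = pmax(.data$raw_score, 0))
  out <- candidates %>%
    dplyr::left_join(scores, by = "candidate") %>%
    dplyr::mutate(
      raw_score = dplyr::coalesce(.data$raw_score, 0),
      floored = dplyr::coalesce(.data$floored, 0)
    )
  total <- sum(out$floored)
  out$fractional_confidence <- if (total > 0) {
    out$floored / total
  } else {
    rep(1 / nrow(out), nrow(out))
  }
  dplyr::select(out, "candidate", "positions", "raw_score", "fractional_confidence")
}

#' Per-residue site confidences and Class I calls
#'
#' The confidence of a residue is the sum of the fractional confidences of
#' all candidates that place a phospho group on it; residue confidences
#' therefore sum to the phospho count. Residues at or above `threshold` are
#' Class I sites (0.75 for library-based analysis; 0.99 is the recommended
#' cutoff for library-free analysis).
#'
#' @param candidate_scores Output of [score_candidates()].
#' @param peptide The [modified_peptide()] being localized.
#' @param threshold Class I confidence cutoff (default 0.75).
#' @return A tibble: `position`, `residue`, `confidence`, `class1`.
#' @export
site_confidences <- function(candidate_scores, peptide, threshold = 0.75) {
  positions <- peptide$candidate_residues
  conf <- vapply(positions, function(pos) {
    sum(candidate_scores$fractional_confidence[
      purrr::map_lgl(candidate_scores$positions, ~ pos %in% .x)
    ])
  }, numeric(1))
  tibble(
    position = positions,
    residue = peptide$residues[positions],
    confidence = conf,
    class1 = conf >= threshold
  )
}

#' Localize one precursor in a DIA run
#'
#' End-to-end localization of a single phosphopeptide precursor: enumerate
#' positional-isomer candidates, detect the precursor's peak group from its
#' library fragment XICs, score the unique site-determining fragment masses,
#' and convert candidate scores into per-residue site confidences.
#'
#' @param run A [dia_run()].
#' @param peptide A [modified_peptide()] with at least one variable phospho.
#' @param charge Precursor charge.
#' @param scheme Isolation-window scheme.
#' @param library_fragments Optional tibble (`fragment_mz`,
#'   `relative_intensity`) used for peak-group detection; defaults to the
#'   theoretical fragments of the first site candidate with equal weights.
#' @param threshold Class I cutoff.
#' @param config A [localization_config()].
#' @param rt_range Optional retention-time restriction in seconds.
#' @return A list of class `site_localization`: `peptide`, `charge`,
#'   `sites` (site-confidence table), `candidates` (candidate scores),
#'   `peak_group`, `quantity` (summed fragment areas of the chosen group),
#'   `window`. `NULL` if no peak group is found.
#' @export
localize_precursor <- function(run, peptide, charge, scheme,
                               library_fragments = NULL, threshold = 0.75,
                               config = localization_config(),
                               rt_range = NULL) {
  candidates <- enumerate_site_candidates(peptide)
  prec_mz <- precursor_mz(peptide, charge)
  windows <- assign_windows(prec_mz, scheme)
  if (length(windows) == 0L) {
    abort(sprintf("precursor m/z %.3f outside the window scheme", prec_mz))
  }
  w <- windows[1]
  if (is.null(library_fragments)) {
    th <- theoretical_fragments(peptide, candidates$positions[[1]], charges = 1L)
    library_fragments <- tibble(fragment_mz = th$mz, relative_intensity = 1)
  }
  scans <- select_scans(run, w, rt_range)
  if (nrow(scans) == 0L) abort(paste0("no scans for window ", w))
  xm <- xic_matrix(scans, library_fragments$fragment_mz, config$tolerance_ppm)
  xics <- purrr::map_dfr(seq_len(ncol(xm)), function(j) {
    tibble(fragment = paste0("f", j), rt = scans$rt, intensity = xm[, j])
  })
  lib_int <- setNames(library_fragments$relative_intensity,
                      paste0("f", seq_len(nrow(library_fragments))))
  groups <- detect_peak_groups(xics, lib_int)
  if (nrow(groups) == 0L) return(NULL)
  pg <- groups[1, ]
  mass_table <- site_determining_fragments(peptide, candidates)
  evidence <- score_fragment_evidence(mass_table, pg, run, w, config)
  cand_scores <- score_candidates(evidence, mass_table, candidates)
  sites <- site_confidences(cand_scores, peptide, threshold)
  # quantify on the best candidate's own theoretical masses so positional
  # isomers are measured on comparable fragment sets
  best <- cand_scores$candidate[which.max(cand_scores$fractional_confidence)]
  own <- mass_table$mass_id[mass_table$candidate == best &
                              mass_table$role != "refuting"]
  quantity <- sum(evidence$apex_intensity[evidence$observed &
                                            evidence$mass_id %in% own])
  structure(
    list(
      peptide = peptide, charge = charge, sites = sites,
      candidates = cand_scores, peak_group = pg,
      quantity = quantity, window = w
    ),
    class = "site_localization"
  )
}

#' @export
print.site_localization <- function(x, ...) {
  cat(sprintf("<site_localization> %s (%d+), p=%d\n",
              x$peptide$sequence, x$charge, x$peptide$phospho_count))
  print(x$sites)
  invisible(x)
}

#' @rdname localize_precursor
#' @param x A `site_localization` object.
#' @param ... Unused.
#' @method tidy site_localization
#' @export
tidy.site_localization <- function(x, ...) {
  dplyr::mutate(x$sites,
                sequence = x$peptide$sequence, charge = x$charge,
                .before = 1)
}

#' Localize every precursor of a spectral library in a run
#'
#' Applies [localize_precursor()] to each library entry and emits one report
#' row per precursor with the localization-probability string in the
#' `"AAS(0.75)LS(0.25)K"` dialect.
#'
#' @param run A [dia_run()].
#' @param roster Tibble with columns `sequence`, `phospho_count`, `charge`
#'   (one row per precursor), optionally `rt` (apex hint, seconds).
#' @param scheme Window scheme.
#' @param threshold Class I cutoff.
#' @param config A [localization_config()].
#' @param run_id Label for the `run` column of the report.
#' @param rt_halfwidth Retention-time half-window around the `rt` hint.
#' @return A tibble: `run`, `modified_sequence`, `charge`, `best_candidate`,
#'   `localization`, `class1`, `quantity`.
#' @export
localize_run <- function(run, roster, scheme, threshold = 0.75,
                         config = localization_config(), run_id = "run1",
                         rt_halfwidth = 60) {
  purrr::map_dfr(seq_len(nrow(roster)), function(i) {
    pep <- modified_peptide(roster$sequence[i], roster$phospho_count[i])
    rt_range <- if ("rt" %in% names(roster) && !is.na(roster$rt[i])) {
      roster$rt[i] + c(-1, 1) * rt_halfwidth
    } else {
      NULL
    }
    loc <- tryCatch(
      localize_precursor(run, pep, roster$charge[i], scheme,
                         threshold = threshold, config = config,
                         rt_range = rt_range),
      error = function(e) NULL
    )
    if (is.null(loc)) return(NULL)
    best <- loc$candidates$candidate[which.max(loc$candidates$fractional_confidence)]
    tibble(
      run = run_id,
      modified_sequence = roster$sequence[i],
      charge = roster$charge[i],
      best_candidate = best,
      localization = format_localization_string(pep$sequence, loc$sites),
      class1 = any(loc$sites$class1),
      quantity = loc$quantity
    )
  })
}

#' Format a per-residue probability string
#'
#' Inverse of [parse_localization_string()]: interleaves residue confidences
#' into the sequence as `"AAS(0.75)LS(0.25)K"`.
#'
#' @param sequence Peptide sequence.
#' @param sites Site-confidence tibble (`position`, `confidence`).
#' @param digits Digits to print per probability.
#' @return A single string.
#' @export
format_localization_string <- function(sequence, sites, digits = 3) {
  residues <- strsplit(sequence, "")[[1]]
  out <- residues
  for (i in seq_len(nrow(sites))) {
    pos <- sites$position[i]
    out[pos] <- paste0(out[pos],
                       "(", formatC(sites$confidence[i], digits = digits,
                                    format = "g"), ")")
  }
  paste0(out, collapse = "")
}
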