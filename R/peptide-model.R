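#' Construct a modified peptide
#'
#' A modified peptide bundles a plain amino-acid sequence with its fixed
#' modifications (position-anchored mass deltas, e.g. carbamidomethyl-C or
#' oxidized-M) and a count of variable phospho groups to be distributed over
#' the serine/threonine/tyrosine residues of the sequence. The positions that
#' can carry a phospho group (the candidate residues) are derived from the
#' sequence.
#'
#' @param sequence Uppercase amino-acid string using the standard 20 letters.
#' @param phospho_count Number of variable phospho groups on the peptide
#'   (`p >= 0`).
#' @param fixed_mods Data frame with columns `position` (1-based) and
#'   `mass` (delta in Da), or `NULL`.
#' @return An object of class `modified_peptide`: a list with elements
#'   `sequence`, `residues`, `phospho_count`, `candidate_residues` (1-based
#'   positions of S/T/Y) and `fixed_mods` (a tibble).
#' @examples
#' pep <- modified_peptide("TESTS", phospho_count = 1)
#' pep$candidate_residues
#' @export
modified_peptide <- function(sequence, phospho_count = 0L, fixed_mods = NULL) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) < 1L) {
    abort("`sequence` must be a single non-empty string")
  }
  residues <- strsplit(sequence, "")[[1]]
  unknown <- setdiff(residues, names(AA_RESIDUE_MASS))
  if (length(unknown) > 0L) {
    abort(paste0("unknown residue: ", paste(unique(unknown), collapse = ", ")))
  }
  if (phospho_count < 0L) abort("`phospho_count` must be >= 0")
  if (is.null(fixed_mods)) {
    fixed_mods <- tibble(position = integer(), mass = numeric())
  } else {
    fixed_mods <- as_tibble(fixed_mods)
    stopifnot(all(c("position", "mass") %in% names(fixed_mods)))
    if (any(fixed_mods$position < 1L | fixed_mods$position > length(residues))) {
      abort("fixed modification position outside peptide")
    }
  }
  candidate_residues <- which(residues %in% phospho_residues())
  if (phospho_count > length(candidate_residues)) {
    abort("no valid site combination: phospho count exceeds S/T/Y residues")
  }
  structure(
    list(
      sequence = sequence,
      residues = residues,
      phospho_count = as.integer(phospho_count),
      candidate_residues = candidate_residues,
      fixed_mods = fixed_mods
    ),
    class = "modified_peptide"
  )
}

#' @export
print.modified_peptide <- function(x, ...) {
  cat(sprintf(
    "<modified_peptide> %s  p=%d  STY at {%s}\n",
    x$sequence, x$phospho_count, paste(x$candidate_residues, collapse = ",")
  ))
  invisible(x)
}

#' Monoisotopic neutral mass of a modified peptide
#'
#' Sum of residue masses plus water plus fixed-modification deltas plus
#' `phospho_count` phospho groups.
#'
#' @param peptide A [modified_peptide()].
#' @return Neutral monoisotopic mass in Da.
#' @export
peptide_mass <- function(peptide) {
  stopifnot(inherits(peptide, "modified_peptide"))
  sum(AA_RESIDUE_MASS[peptide$residues]) + WATER_MASS +
    sum(peptide$fixed_mods$mass) + peptide$phospho_count * PHOSPHO_MASS
}

#' Precursor m/z of a modified peptide
#'
#' @param peptide A [modified_peptide()].
#' @param charge Positive integer charge state.
#' @return m/z in Da.
#' @export
precursor_mz <- function(peptide, charge) {
  stopifnot(charge >= 1L)
  (peptide_mass(peptide) + charge * PROTON_MASS) / charge
}

#' Enumerate positional-isomer site candidates
#'
#' Expands a peptide carrying `p` variable phospho groups into all
#' `choose(n_STY, p)` site candidates (distinct placements of the phospho
#' groups over the S/T/Y residues), in lexicographic order of the position
#' tuples. Co-isolated positional isomers are indistinguishable by precursor
#' mass, so this candidate set is the hypothesis space the localization score
#' discriminates between.
#'
#' @param peptide A [modified_peptide()] with `phospho_count >= 1`.
#' @return A tibble with one row per candidate: `candidate` (label such as
#'   `"S3"` or `"S3+T5"`), `positions` (list-column of integer position
#'   vectors).
#' @examples
#' enumerate_site_candidates(modified_peptide("TESTS", 1))
#' @export
enumerate_site_candidates <- function(peptide) {
  stopifnot(inherits(peptide, "modified_peptide"))
  p <- peptide$phospho_count
  if (p < 1L) abort("nothing to localize: peptide carries no variable phospho group")
  cand <- peptide$candidate_residues
  if (p > length(cand)) abort("no valid site combination")
  combos <- if (length(cand) == 1L) {
    list(cand)  # combn() would misread a scalar as seq_len(n)
  } else {
    combn(cand, p, simplify = FALSE)
  }
  # combn over a sorted vector is already lexicographic in the position tuple
  labels <- vapply(
    combos,
    function(pos) paste0(peptide$residues[pos], pos, collapse = "+"),
    character(1)
  )
  tibble(candidate = labels, positions = combos)
}

#' Theoretical b/y fragment ions of one site candidate
#'
#' Computes singly/doubly charged b- and y-ion m/z values for a specific
#' placement of the peptide's phospho groups. b1 ions are generated: the b1
#' ion of an N-terminal phospho residue is maximally site-determining.
#' Optionally adds H3PO4 neutral-loss (-97.976896 Da) duplicates of every
#' phospho-bearing fragment.
#'
#' @param peptide A [modified_peptide()].
#' @param phospho_positions Integer vector of phospho positions (subset of the
#'   peptide's candidate residues) with length equal to `phospho_count`.
#' @param charges Integer fragment charges to generate (default `c(1, 2)`).
#' @param neutral_loss If `TRUE`, emit -H3PO4 duplicates of phospho-bearing
#'   fragments (flagged in the `loss` column).
#' @return A tibble with columns `series` ("b"/"y"), `index`, `charge`,
#'   `loss` ("none"/"H3PO4"), `mz`, `n_phospho` (phospho groups carried by the
#'   fragment).
#' @examples
#' theoretical_fragments(modified_peptide("ASK", 1), phospho_positions = 2)
#' @export
theoretical_fragments <- function(peptide, phospho_positions,
                                  charges = c(1L, 2L), neutral_loss = FALSE) {
  stopifnot(inherits(peptide, "modified_peptide"))
  phospho_positions <- sort(as.integer(phospho_positions))
  if (length(phospho_positions) != peptide$phospho_count ||
      !all(phospho_positions %in% peptide$candidate_residues)) {
    abort("`phospho_positions` must be `phospho_count` positions drawn from the S/T/Y residues")
  }
  n <- length(peptide$residues)
  if (n < 2L) abort("peptide too short to fragment")
  per_residue <- unname(AA_RESIDUE_MASS[peptide$residues])
  delta <- numeric(n)
  if (nrow(peptide$fixed_mods) > 0L) {
    delta[peptide$fixed_mods$position] <- delta[peptide$fixed_mods$position] +
      peptide$fixed_mods$mass
  }
  delta[phospho_positions] <- delta[phospho_positions] + PHOSPHO_MASS
  masses <- per_residue + delta
  cum_b <- cumsum(masses)          # b_i neutral residue sum
  total <- cum_b[n]
  idx <- seq_len(n - 1L)
  phospho_in_prefix <- cumsum(seq_len(n) %in% phospho_positions)

  base <- dplyr::bind_rows(
    tibble(
      series = "b", index = idx,
      neutral = cum_b[idx],
      n_phospho = phospho_in_prefix[idx]
    ),
    tibble(
      series = "y", index = idx,
      neutral = total - cum_b[n - idx] + WATER_MASS,
      n_phospho = length(phospho_positions) - phospho_in_prefix[n - idx]
    )
  )
  out <- tidyr::crossing(base, charge = as.integer(charges)) %>%
    dplyr::mutate(loss = "none")
  if (isTRUE(neutral_loss)) {
    nl <- dplyr::filter(out, .data$n_phospho > 0L) %>%
      dplyr::mutate(neutral = .data$neutral - H3PO4_MASS, loss = "H3PO4")
    out <- dplyr::bind_rows(out, nl)
  }
  out %>%
    dplyr::mutate(mz = (.data$neutral + .data$charge * PROTON_MASS) / .data$charge) %>%
    dplyr::select("series", "index", "charge", "loss", "mz", "n_phospho") %>%
    dplyr::arrange(.data$series, .data$index, .data$charge, .data$loss)
}

#' Site-determining fragment table across positional isomers
#'
#' Pools the theoretical fragments of all site candidates of one peptide,
#' deduplicates fragment masses at `tol` Da, and annotates each unique mass
#' per candidate as `"confirming"` (in this candidate's theoretical set but
#' not in every candidate's), `"refuting"` (in at least one other candidate's
#' set but not this one's) or `"neutral"` (shared by all candidates, hence
#' carrying no localization information).
#'
#' By default neutral-loss ions are excluded from the evidence table: a
#' -H3PO4 ion localizes identically to its parent ion and would double-count.
#'
#' @param peptide A [modified_peptide()].
#' @param candidates Candidate tibble from [enumerate_site_candidates()]
#'   (defaults to enumerating all).
#' @param charges Fragment charges to include.
#' @param neutral_loss Include -H3PO4 ions as evidence (default `FALSE`).
#' @param tol Mass deduplication tolerance in Da.
#' @return A tibble in long form: `mass_id`, `mz`, `candidate`, `role`, plus
#'   `series`/`index`/`charge` of one representative ion for the mass.
#' @examples
#' pep <- modified_peptide("SASK", 1)
#' site_determining_fragments(pep)
#' @export
site_determining_fragments <- function(peptide,
                                       candidates = enumerate_site_candidates(peptide),
                                       charges = c(1L, 2L),
                                       neutral_loss = FALSE,
                                       tol = 1e-4) {
  if (nrow(candidates) == 0L) abort("empty candidate list")
  frags <- purrr::map2_dfr(
    candidates$candidate, candidates$positions,
    function(label, pos) {
      theoretical_fragments(peptide, pos, charges = charges,
                            neutral_loss = neutral_loss) %>%
        dplyr::mutate(candidate = label)
    }
  )
  # cluster masses: after sorting, a gap > tol starts a new unique mass
  ord <- order(frags$mz)
  mzs <- frags$mz[ord]
  cluster <- cumsum(c(1L, as.integer(diff(mzs) > tol)))
  frags$mass_id <- NA_integer_
  frags$mass_id[ord] <- cluster
  n_cand <- nrow(candidates)
  rep_ion <- frags %>%
    dplyr::group_by(.data$mass_id) %>%
    dplyr::summarise(
      mz = .data$mz[1],
      series = .data$series[1], index = .data$index[1],
      charge = .data$charge[1],
      holders = list(unique(.data$candidate)),
      .groups = "drop"
    )
  tidyr::crossing(rep_ion, candidate = candidates$candidate) %>%
    dplyr::mutate(
      n_holders = lengths(.data$holders),
      has = purrr::map2_lgl(.data$candidate, .data$holders, ~ .x %in% .y),
      role = dplyr::case_when(
        .data$n_holders == n_cand ~ "neutral",
        .data$has ~ "confirming",
        TRUE ~ "refuting"
      )
    ) %>%
    dplyr::select("mass_id", "mz", "series", "index", "charge", "candidate", "role") %>%
    dplyr::arrange(.data$mass_id, .data$candidate)
}

#' Averagine isotope envelope
#'
#' Approximates the isotope pattern of a peptide-like ion of given
#' monoisotopic mass using the averagine model: the mass is converted into a
#' fractional average atomic composition and element isotope distributions
#' are convolved. The first four isotopologues (M+0..M+3) are returned,
#' renormalized to sum to one.
#'
#' @param mass Neutral monoisotopic mass in Da (> 0).
#' @param charge Positive integer charge (sets the m/z spacing).
#' @return A tibble with columns `k` (0..3), `mz`, `abundance`.
#' @examples
#' isotope_envelope(1500, 2)
#' @export
isotope_envelope <- function(mass, charge = 1L) {
  if (!is.numeric(mass) || mass <= 0) abort("`mass` must be > 0")
  if (charge <= 0) abort("`charge` must be a positive integer")
  units <- mass / AVERAGINE_UNIT_MASS
  counts <- AVERAGINE_COMPOSITION * units
  dist <- 1
  for (el in names(counts)) {
    iso <- ELEMENT_ISOTOPES[[el]]
    n <- counts[[el]]
    # element distribution for fractional atom count: interpolate between
    # floor(n) and ceiling(n) self-convolutions
    el_dist_n <- function(k) {
      d <- 1
      if (k > 0) {
        # repeated-squaring style convolution, truncated to 8 terms
        base <- iso
        kk <- k
        acc <- 1
        while (kk > 0) {
          if (kk %% 2 == 1) acc <- head(convolve_dist(acc, base), 8)
          base <- head(convolve_dist(base, base), 8)
          kk <- kk %/% 2
        }
        d <- acc
      }
      d
    }
    lo <- el_dist_n(floor(n))
    hi <- el_dist_n(ceiling(n))
    w <- n - floor(n)
    len <- max(length(lo), length(hi))
    lo <- c(lo, rep(0, len - length(lo)))
    hi <- c(hi, rep(0, len - length(hi)))
    dist <- head(convolve_dist(dist, (1 - w) * lo + w * hi), 8)
  }
  ab <- dist[seq_len(min(4, length(dist)))]
  ab <- c(ab, rep(0, 4 - length(ab)))
  ab <- ab / sum(ab)
  tibble(
    k = 0:3,
    mz = (mass + charge * PROTON_MASS + (0:3) * NEUTRON_MASS) / charge,
    abundance = ab
  )
}

# discrete distribution convolution (polynomial product)
convolve_dist <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  }
  out
}
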