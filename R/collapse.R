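#' Parse a per-residue localization-probability string
#'
#' Parses the `"AAS(0.75)LS(0.25)K"` dialect in which each modified residue
#' is followed by its localization probability in parentheses.
#'
#' @param s A single localization string.
#' @return Named numeric vector: names are 1-based peptide positions, values
#'   probabilities in `[0, 1]`.
#' @examples
#' parse_localization_string("AAS(0.75)LS(0.25)K")
#' @export
parse_localization_string <- function(s) {
  if (length(s) != 1L || is.na(s)) abort("`s` must be a single string")
  if (stringr::str_count(s, stringr::fixed("(")) !=
      stringr::str_count(s, stringr::fixed(")"))) {
    abort(paste0("malformed localization string: ", s))
  }
  tokens <- stringr::str_match_all(s, "([A-Z])(\\(([0-9.eE+-]+)\\))?")[[1]]
  if (nrow(tokens) == 0L ||
      nchar(paste0(tokens[, 1], collapse = "")) != nchar(s)) {
    abort(paste0("malformed localization string: ", s))
  }
  probs <- suppressWarnings(as.numeric(tokens[, 4]))
  has <- !is.na(tokens[, 3]) & tokens[, 3] != ""
  if (any(has & is.na(probs))) {
    abort(paste0("malformed probability in: ", s))
  }
  if (any(probs[has] < 0 | probs[has] > 1)) {
    abort(paste0("probability outside [0, 1] in: ", s))
  }
  setNames(probs[has], which(has))
}

#' Collapse a precursor report to modification-specific peptides
#'
#' Charge states (and any other precursor-level split) of the same grouping
#' key are summed in linear intensity space per run; the summed quantity is
#' then log2-transformed. Grouping either by the modified sequence with an
#' assay-probability cutoff (`grouping = "assay_probability"`; rows below
#' `cutoff` are dropped first) or by modified sequence plus the localization
#' string (`grouping = "localized_sequence"`). Missing (sequence, run)
#' combinations stay missing — they are never zero-filled.
#'
#' @param rows Precursor report tibble with columns `run`,
#'   `modified_sequence`, `charge`, `quantity`, and `assay_probability` or
#'   `localization` depending on the grouping.
#' @param grouping Grouping mode (see above).
#' @param cutoff Cutoff on the grouping column (default 0 keeps everything).
#' @return A tibble with one row per group and run: grouping key columns,
#'   `run`, `quantity` (linear sum), `log2_quantity`, `n_precursors`.
#' @export
collapse_to_modified_peptides <- function(rows,
                                          grouping = c("assay_probability",
                                                       "localized_sequence"),
                                          cutoff = 0) {
  grouping <- match.arg(grouping)
  rows <- as_tibble(rows)
  if (grouping == "assay_probability") {
    stopifnot("assay_probability" %in% names(rows))
    rows <- dplyr::filter(rows, .data$assay_probability >= cutoff)
    keys <- "modified_sequence"
  } else {
    stopifnot("localization" %in% names(rows))
    keys <- c("modified_sequence", "localization")
  }
  out <- rows %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "run")))) %>%
    dplyr::summarise(
      quantity = sum(.data$quantity),
      n_precursors = dplyr::n(),
      .groups = "drop"
    ) %>%
    dplyr::mutate(log2_quantity = log2(.data$quantity))
  stopifnot(!anyDuplicated(out[, c(keys, "run")]))
  out
}

#' Collapse a precursor report to phosphosite level
#'
#' Explodes every phospho position whose localization probability passes
#' `cutoff` into a site key `(protein, protein position, multiplicity)` —
#' the multiplicity being the phospho count of the contributing peptide, kept
#' as part of the key in the MaxQuant `___1/___2/___3` convention. Protein
#' positions are 1-based: `peptide_start + peptide position - 1`. Per run,
#' quantities of all precursors contributing to a site are summed in linear
#' space and the best (maximum) localization probability is retained.
#'
#' @param rows Precursor report with columns `run`, `modified_sequence`,
#'   `charge`, `protein`, `peptide_start`, `localization`, `quantity`.
#' @param cutoff Localization-probability cutoff (default 0.75, Class I).
#' @return A tibble: `protein`, `position`, `residue`, `multiplicity`,
#'   `site_id`, `run`, `quantity`, `log2_quantity`, `best_probability`,
#'   `n_precursors`.
#' @export
collapse_to_sites <- function(rows, cutoff = 0.75) {
  rows <- as_tibble(rows)
  needed <- c("run", "modified_sequence", "protein", "peptide_start",
              "localization", "quantity")
  missing_cols <- setdiff(needed, names(rows))
  if (length(missing_cols) > 0L) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (any(is.na(rows$peptide_start))) {
    bad <- unique(rows$modified_sequence[is.na(rows$peptide_start)])
    abort(paste0("peptide_start missing for: ", paste(bad, collapse = ", ")))
  }
  exploded <- purrr::map_dfr(seq_len(nrow(rows)), function(i) {
    probs <- parse_localization_string(rows$localization[i])
    multiplicity <- length(probs)
    keep <- probs >= cutoff
    if (!any(keep)) return(NULL)
    pos_in_pep <- as.integer(names(probs)[keep])
    seq_chars <- strsplit(gsub("\\([0-9.eE+-]+\\)", "", rows$localization[i]),
                          "")[[1]]
    tibble(
      run = rows$run[i],
      protein = first_accession(rows$protein[i]),
      protein_all = rows$protein[i],
      position = rows$peptide_start[i] + pos_in_pep - 1L,
      residue = seq_chars[pos_in_pep],
      multiplicity = multiplicity,
      probability = unname(probs[keep]),
      quantity = rows$quantity[i]
    )
  })
  if (is.null(exploded) || nrow(exploded) == 0L) {
    return(tibble(
      protein = character(), position = integer(), residue = character(),
      multiplicity = integer(), site_id = character(), run = character(),
      quantity = numeric(), log2_quantity = numeric(),
      best_probability = numeric(), n_precursors = integer()
    ))
  }
  exploded %>%
    dplyr::group_by(.data$protein, .data$position, .data$residue,
                    .data$multiplicity, .data$run) %>%
    dplyr::summarise(
      quantity = sum(.data$quantity),
      best_probability = max(.data$probability),
      n_precursors = dplyr::n(),
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      log2_quantity = log2(.data$quantity),
      site_id = paste0(.data$protein, "_", .data$residue, .data$position,
                       "___", .data$multiplicity)
    ) %>%
    dplyr::select("protein", "position", "residue", "multiplicity", "site_id",
                  "run", "quantity", "log2_quantity", "best_probability",
                  "n_precursors")
}

first_accession <- function(x) sub(";.*$", "", x)

#' De-normalize or quantile-normalize a quantity table
#'
#' `mode = "denormalize"` divides each row's quantity by its run's
#' normalization factor (undoing software normalization so that raw-scale
#' quantities can be compared across acquisition methods);
#' `mode = "quantile"` quantile-normalizes quantities across runs so every
#' run shares the same sorted intensity distribution.
#'
#' @param table Long tibble with columns `run`, `quantity`, and a feature
#'   identifier column (`feature` by default).
#' @param factors Named numeric vector of per-run normalization factors
#'   (required for `mode = "denormalize"`; all > 0).
#' @param mode `"denormalize"` or `"quantile"`.
#' @param feature_col Name of the feature identifier column.
#' @return The table with `quantity` replaced accordingly.
#' @export
denormalize_and_requantile <- function(table, factors = NULL,
                                       mode = c("denormalize", "quantile"),
                                       feature_col = "feature") {
  mode <- match.arg(mode)
  table <- as_tibble(table)
  if (mode == "denormalize") {
    if (is.null(factors)) abort("`factors` required for denormalize mode")
    if (any(factors <= 0)) abort("normalization factors must be > 0")
    miss <- setdiff(unique(table$run), names(factors))
    if (length(miss) > 0L) {
      abort(paste0("no normalization factor for run(s): ",
                   paste(miss, collapse = ", ")))
    }
    return(dplyr::mutate(table,
                         quantity = .data$quantity / unname(factors[.data$run])))
  }
  wide <- tidyr::pivot_wider(
    table[, c(feature_col, "run", "quantity")],
    names_from = "run", values_from = "quantity"
  )
  mat <- as.matrix(wide[, -1, drop = FALSE])
  norm <- quantile_normalize_matrix(mat)
  long <- wide
  long[, -1] <- as.data.frame(norm)
  out <- tidyr::pivot_longer(long, -dplyr::all_of(feature_col),
                             names_to = "run", values_to = "quantity")
  extra <- setdiff(names(table), names(out))
  if (length(extra) > 0L) {
    out <- dplyr::left_join(
      out, dplyr::distinct(table[, c(feature_col, "run", extra)]),
      by = c(feature_col, "run")
    )
  }
  dplyr::filter(out, !is.na(.data$quantity))
}

# rank-based quantile normalization; missing entries stay missing
quantile_normalize_matrix <- function(mat) {
  ranks <- apply(mat, 2, rank, ties.method = "average", na.last = "keep")
  if (!anyNA(mat)) {
    # complete case: classic mean-of-sorted-columns reference
    ref <- rowMeans(apply(mat, 2, sort))
    out <- mat
    for (j in seq_len(ncol(mat))) {
      out[, j] <- stats::approx(seq_len(nrow(mat)), ref, xout = ranks[, j],
                                rule = 2)$y
    }
    return(out)
  }
  n_obs <- colSums(!is.na(mat))
  grid <- seq(0, 1, length.out = 101)
  ref <- rowMeans(vapply(seq_len(ncol(mat)), function(j) {
    quantile(mat[, j], probs = grid, na.rm = TRUE, names = FALSE, type = 7)
  }, numeric(length(grid))))
  out <- mat
  for (j in seq_len(ncol(mat))) {
    p <- (ranks[, j] - 1) / (n_obs[j] - 1)
    out[, j] <- stats::approx(grid, ref, xout = p, rule = 2)$y
  }
  out
}
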