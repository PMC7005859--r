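#' Parse a modified-sequence string
#'
#' Accepts the `"AAS(ph)LK"` dialect in which each phosphorylated residue is
#' followed by the tag `(ph)`.
#'
#' @param s A single modified-sequence string.
#' @return A list: `sequence` (plain string), `phospho_positions` (integer).
#' @export
parse_modified_sequence <- function(s) {
  tokens <- stringr::str_match_all(s, "([A-Z])(\\(ph\\))?")[[1]]
  if (nrow(tokens) == 0L || nchar(paste0(tokens[, 1], collapse = "")) != nchar(s)) {
    abort(paste0("malformed modified sequence: ", s))
  }
  list(
    sequence = paste0(tokens[, 2], collapse = ""),
    phospho_positions = which(!is.na(tokens[, 3]))
  )
}

#' Read and validate a spectral library TSV
#'
#' The library schema is one row per transition with columns `precursor_mz`,
#' `modified_sequence` (the `"AAS(ph)LK"` dialect), `charge`,
#' `fragment_series`, `fragment_index`, `fragment_charge`, `fragment_mz`,
#' `relative_intensity`, `rt`. Fragment m/z values are cross-checked against
#' the theoretical mass of the annotated ion; entries off by more than
#' 0.01 Da are kept with the recomputed m/z and a warning.
#'
#' @param path Path to a tab-separated library file.
#' @return A validated tibble in the same schema.
#' @export
read_spectral_library <- function(path) {
  lib <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(lib) == 0L) abort("empty spectral library")
  required <- c("precursor_mz", "modified_sequence", "charge",
                "fragment_series", "fragment_index", "fragment_charge",
                "fragment_mz", "relative_intensity", "rt")
  missing_cols <- setdiff(required, names(lib))
  if (length(missing_cols) > 0L) {
    abort(paste0("missing column: ", paste(missing_cols, collapse = ", ")))
  }
  theo <- vapply(seq_len(nrow(lib)), function(i) {
    parsed <- parse_modified_sequence(lib$modified_sequence[i])
    pep <- modified_peptide(parsed$sequence,
                            length(parsed$phospho_positions))
    fr <- theoretical_fragments(pep, parsed$phospho_positions,
                                charges = lib$fragment_charge[i])
    hit <- fr$mz[fr$series == lib$fragment_series[i] &
                   fr$index == lib$fragment_index[i] &
                   fr$charge == lib$fragment_charge[i] &
                   fr$loss == "none"]
    if (length(hit) == 0L) NA_real_ else hit[1]
  }, numeric(1))
  off <- !is.na(theo) & abs(theo - lib$fragment_mz) > 0.01
  if (any(off)) {
    warn(sprintf(
      "%d fragment m/z value(s) deviate > 0.01 Da from theory; recomputed",
      sum(off)
    ))
    lib$fragment_mz[off] <- theo[off]
  }
  lib
}

report_schemas <- list(
  precursor = c("run", "modified_sequence", "charge"),
  peptide = c("modified_sequence", "run", "quantity"),
  site = c("protein", "position", "multiplicity", "run", "quantity"),
  occupancy = c("site", "condition", "occupancy")
)

#' Write an analysis report as TSV
#'
#' Writes one of the four report levels (`precursor`, `peptide`, `site`,
#' `occupancy`) as a UTF-8 tab-separated file with a stable column order.
#' Re-reading with [read_report()] reproduces the values exactly.
#'
#' @param results A non-empty tibble containing at least the level's key
#'   columns.
#' @param level Report level.
#' @param path Output path.
#' @param overwrite Allow replacing an existing file.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, level = c("precursor", "peptide", "site",
                                            "occupancy"),
                         path, overwrite = FALSE) {
  level <- match.arg(level)
  if (is.null(results) || nrow(results) == 0L) abort("empty results")
  if (file.exists(path) && !overwrite) {
    abort(paste0("file exists (use overwrite = TRUE): ", path))
  }
  key <- report_schemas[[level]]
  missing_cols <- setdiff(key, names(results))
  if (length(missing_cols) > 0L) {
    abort(paste0("missing column(s) for ", level, " report: ",
                 paste(missing_cols, collapse = ", ")))
  }
  results <- dplyr::select(results, dplyr::all_of(key), dplyr::everything())
  readr::write_tsv(results, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read a run manifest
#'
#' A manifest lists the runs of an experiment: tab-separated columns
#' `run_id`, `path`, `condition`, `replicate`.
#'
#' @param path Manifest TSV path.
#' @param check_files Require that each referenced file exists.
#' @return A tibble with the four manifest columns.
#' @export
read_run_manifest <- function(path, check_files = TRUE) {
  m <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("run_id", "path", "condition", "replicate")
  missing_cols <- setdiff(required, names(m))
  if (length(missing_cols) > 0L) {
    abort(paste0("missing column: ", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(m$run_id)) abort("run ids must be unique")
  if (check_files) {
    absent <- m$path[!file.exists(m$path)]
    if (length(absent) > 0L) {
      abort(paste0("missing file(s): ", paste(absent, collapse = ", ")))
    }
  }
  m
}

#' Write a DIA run to mzML
#'
#' Serializes a [dia_run()] to centroided mzML (MS2 scans carry their
#' isolation-window bounds). Requires the mzR package.
#'
#' @param run A [dia_run()].
#' @param scheme The window scheme used (provides isolation bounds).
#' @param path Output path (`.mzML`).
#' @return `path`, invisibly.
#' @export
write_mzml <- function(run, scheme, path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    abort("the mzR package is required to write mzML")
  }
  n <- nrow(run)
  win_lower <- ifelse(is.na(run$window), NA_real_,
                      scheme$lower[match(run$window, scheme$index)])
  win_upper <- ifelse(is.na(run$window), NA_real_,
                      scheme$upper[match(run$window, scheme$index)])
  center <- (win_lower + win_upper) / 2
  hdr <- data.frame(
    seqNum = seq_len(n),
    acquisitionNum = seq_len(n),
    msLevel = run$ms_level,
    polarity = rep(1L, n),
    peaksCount = lengths(run$mz),
    totIonCurrent = vapply(run$intensity, sum, numeric(1)),
    retentionTime = run$rt,
    basePeakMZ = vapply(run$mz, function(m) if (length(m)) m[1] else 0, numeric(1)),
    basePeakIntensity = vapply(run$intensity, function(i) if (length(i)) max(i) else 0,
                               numeric(1)),
    collisionEnergy = ifelse(run$ms_level == 2L, 25, 0),
    ionisationEnergy = rep(0, n),
    lowMZ = vapply(run$mz, function(m) if (length(m)) min(m) else 0, numeric(1)),
    highMZ = vapply(run$mz, function(m) if (length(m)) max(m) else 0, numeric(1)),
    precursorScanNum = rep(0L, n),
    precursorMZ = ifelse(run$ms_level == 2L, center, 0),
    precursorCharge = rep(0L, n),
    precursorIntensity = rep(0, n),
    mergedScan = rep(0L, n),
    mergedResultScanNum = rep(0L, n),
    mergedResultStartScanNum = rep(0L, n),
    mergedResultEndScanNum = rep(0L, n),
    injectionTime = rep(0, n),
    filterString = rep(NA_character_, n),
    spectrumId = paste0("scan=", seq_len(n)),
    centroided = rep(TRUE, n),
    ionMobilityDriftTime = rep(NA_real_, n),
    isolationWindowTargetMZ = ifelse(run$ms_level == 2L, center, NA_real_),
    isolationWindowLowerOffset = ifelse(run$ms_level == 2L,
                                        center - win_lower, NA_real_),
    isolationWindowUpperOffset = ifelse(run$ms_level == 2L,
                                        win_upper - center, NA_real_),
    scanWindowLowerLimit = rep(NA_real_, n),
    scanWindowUpperLimit = rep(NA_real_, n),
    stringsAsFactors = FALSE
  )
  peaks <- purrr::map2(run$mz, run$intensity, ~ cbind(mz = .x, intensity = .y))
  mzR::writeMSData(peaks, path, header = hdr, outformat = "mzml")
  invisible(path)
}

#' Read an mzML file into a DIA run
#'
#' Reads centroided mzML via mzR and maps MS2 isolation-window bounds back
#' onto the supplied (or inferred) window scheme. Retention times are
#' converted to seconds.
#'
#' @param path mzML file path.
#' @param scheme Optional window scheme; if `NULL`, window indices are
#'   assigned by matching distinct isolation bounds in file order.
#' @return A [dia_run()].
#' @export
read_mzml <- function(path, scheme = NULL) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    abort("the mzR package is required to read mzML")
  }
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle))
  hdr <- mzR::header(handle)
  peaks <- mzR::peaks(handle)
  if (is.matrix(peaks)) peaks <- list(peaks)
  lower <- hdr$isolationWindowTargetMZ - hdr$isolationWindowLowerOffset
  upper <- hdr$isolationWindowTargetMZ + hdr$isolationWindowUpperOffset
  window <- rep(NA_integer_, nrow(hdr))
  is_ms2 <- hdr$msLevel == 2L
  if (any(is_ms2)) {
    if (is.null(scheme)) {
      key <- paste(round(lower, 4), round(upper, 4))
      uk <- unique(key[is_ms2])
      window[is_ms2] <- match(key[is_ms2], uk) - 1L
    } else {
      window[is_ms2] <- vapply(which(is_ms2), function(i) {
        j <- which(abs(scheme$lower - lower[i]) < 1e-3 &
                     abs(scheme$upper - upper[i]) < 1e-3)
        if (length(j) == 1L) scheme$index[j] else NA_integer_
      }, integer(1))
    }
  }
  dia_run(
    scan = hdr$seqNum, ms_level = hdr$msLevel, rt = hdr$retentionTime,
    window = window,
    mz = purrr::map(peaks, ~ as.numeric(.x[, 1])),
    intensity = purrr::map(peaks, ~ as.numeric(.x[, 2]))
  )
}
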