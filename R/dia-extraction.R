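#' Build a DIA isolation-window scheme
#'
#' Staggered fixed-width windows: window `i` (0-based) spans
#' `[start + i * (width - overlap), start + i * (width - overlap) + width]`.
#' The default arguments reproduce the acquisition scheme used throughout the
#' package's benchmarks: 48 windows of 14 Da with 1 Da overlap starting at
#' 350 Da. Window intervals are treated as closed on both ends so that a
#' precursor inside a 1-Da overlap region is assigned to both windows.
#'
#' @param start Lower bound of the first window (Da).
#' @param width Window width (Da).
#' @param overlap Overlap between adjacent windows (Da), `0 <= overlap < width`.
#' @param count Number of windows.
#' @return A tibble with columns `index` (0-based), `lower`, `upper`, `center`.
#' @examples
#' build_window_scheme()[1:2, ]
#' @export
build_window_scheme <- function(start = 350, width = 14, overlap = 1, count = 48) {
  if (overlap >= width) abort("`overlap` must be smaller than `width`")
  if (overlap < 0) abort("`overlap` must be >= 0")
  if (count < 1) abort("`count` must be >= 1")
  i <- seq_len(count) - 1L
  lower <- start + i * (width - overlap)
  tibble(
    index = i,
    lower = lower,
    upper = lower + width,
    center = lower + width / 2
  )
}

#' Assign a precursor m/z to isolation windows
#'
#' @param mz Precursor m/z values (vectorized).
#' @param scheme Window scheme from [build_window_scheme()].
#' @return For a single `mz`, an integer vector of window indices containing
#'   it (length 2 inside an overlap region, 0 if out of range); for several,
#'   a list of such vectors.
#' @export
assign_windows <- function(mz, scheme) {
  if (nrow(scheme) == 0L) abort("`scheme` must be non-empty")
  one <- function(m) scheme$index[m >= scheme$lower & m <= scheme$upper]
  if (length(mz) == 1L) one(mz) else lapply(mz, one)
}

#' Assemble a DIA run tibble
#'
#' The in-memory representation of a (real or simulated) DIA run: one row per
#' scan, with centroided peaks held in parallel list-columns. Retention times
#' are in seconds.
#'
#' @param scan Integer scan index (acquisition order).
#' @param ms_level 1 or 2.
#' @param rt Retention time in seconds.
#' @param window 0-based isolation-window index (`NA` for MS1 scans).
#' @param mz List of numeric vectors (strictly increasing within each scan).
#' @param intensity List of numeric vectors (non-negative, same lengths).
#' @return A `dia_run` tibble sorted by `rt` then `ms_level`.
#' @export
dia_run <- function(scan, ms_level, rt, window, mz, intensity) {
  run <- tibble(
    scan = as.integer(scan), ms_level = as.integer(ms_level),
    rt = as.numeric(rt), window = as.integer(window),
    mz = mz, intensity = intensity
  )
  if (any(run$ms_level == 2L & is.na(run$window))) {
    abort("MS2 scans must carry a window index")
  }
  bad <- purrr::map2_lgl(run$mz, run$intensity, function(m, i) {
    length(m) != length(i) || any(i < 0) || (length(m) > 1 && any(diff(m) <= 0))
  })
  if (any(bad)) abort("peak arrays must be sorted by m/z with non-negative intensities")
  run <- dplyr::arrange(run, .data$rt, .data$ms_level)
  class(run) <- c("dia_run", class(run))
  run
}

#' Extract an ion chromatogram (XIC)
#'
#' Sums peak intensities within a ppm tolerance of `target_mz` in every scan
#' of the requested kind, producing one grid point per scan. Scans without
#' signal contribute 0 (never a missing value), so XICs on the same window
#' share a common retention-time grid.
#'
#' @param run A [dia_run()] tibble.
#' @param target_mz Target m/z (Da).
#' @param tolerance_ppm Half-width of the extraction tolerance in ppm.
#' @param window_index 0-based MS2 window to extract from, or `NA` to extract
#'   from MS1 scans.
#' @param rt_range Optional `c(min, max)` retention-time filter in seconds.
#' @return A tibble with columns `rt`, `intensity`; attribute `target_mz`.
#' @export
extract_xic <- function(run, target_mz, tolerance_ppm = 20,
                        window_index = NA, rt_range = NULL) {
  scans <- select_scans(run, window_index, rt_range)
  if (nrow(scans) == 0L) {
    abort(paste0("no scans for window ", window_index))
  }
  tol <- target_mz * tolerance_ppm * 1e-6
  ints <- purrr::map2_dbl(scans$mz, scans$intensity, function(m, i) {
    sum(i[m >= target_mz - tol & m <= target_mz + tol])
  })
  out <- tibble(rt = scans$rt, intensity = ints)
  attr(out, "target_mz") <- target_mz
  out
}

select_scans <- function(run, window_index, rt_range = NULL) {
  scans <- if (is.na(window_index)) {
    dplyr::filter(run, .data$ms_level == 1L)
  } else {
    dplyr::filter(run, .data$ms_level == 2L, .data$window == .env$window_index)
  }
  if (!is.null(rt_range)) {
    scans <- dplyr::filter(scans, .data$rt >= rt_range[1], .data$rt <= rt_range[2])
  }
  scans
}

# Fast path: XICs for many targets over one scan subset.
# Returns matrix scans x targets.
xic_matrix <- function(scans, target_mz, tolerance_ppm = 20) {
  tol <- target_mz * tolerance_ppm * 1e-6
  lo <- target_mz - tol
  hi <- target_mz + tol
  t(vapply(seq_len(nrow(scans)), function(s) {
    m <- scans$mz[[s]]
    i <- scans$intensity[[s]]
    vapply(seq_along(target_mz), function(j) sum(i[m >= lo[j] & m <= hi[j]]), 0)
  }, numeric(length(target_mz))))
}

#' Detect and rank co-eluting peak groups
#'
#' Takes the fragment XICs of one precursor on a common retention-time grid,
#' smooths the summed trace (Savitzky-Golay, window 5, order 2), finds local
#' maxima above a noise floor, sets the group boundaries at the nearest local
#' minima, and scores each candidate peak group by
#' `0.5 * spectral contrast angle(fragment areas, library intensities) +
#'  0.5 * mean pairwise Pearson correlation of the fragment traces`
#' inside the boundaries. Groups are returned in descending score order, ties
#' broken toward earlier retention time.
#'
#' @param xics Long tibble with columns `fragment`, `rt`, `intensity` — all
#'   fragments on one grid (as produced by [extract_xic()] per fragment).
#' @param library_intensities Named numeric vector of library relative
#'   intensities (names matching `fragment`); `NULL` weights all equally.
#' @param noise_floor_frac Candidate apexes must exceed this fraction of the
#'   maximum of the summed trace (default 0.05).
#' @return A tibble of peak groups: `apex_rt`, `left`, `right`, `score`,
#'   `areas` (list of named per-fragment areas), `profile` (list of
#'   `rt`/`intensity` tibbles of the summed consensus trace). Empty for
#'   all-zero input.
#' @export
detect_peak_groups <- function(xics, library_intensities = NULL,
                               noise_floor_frac = 0.05) {
  wide <- tidyr::pivot_wider(
    xics, id_cols = "rt",
    names_from = "fragment", values_from = "intensity"
  ) %>% dplyr::arrange(.data$rt)
  rt <- wide$rt
  mat <- as.matrix(wide[, -1, drop = FALSE])
  total <- rowSums(mat)
  if (all(total == 0)) return(empty_peak_groups())
  sm <- smooth_trace(total)
  floor_level <- noise_floor_frac * max(sm)
  apex_idx <- which_local_maxima(sm)
  apex_idx <- apex_idx[sm[apex_idx] > floor_level]
  if (length(apex_idx) == 0L) return(empty_peak_groups())
  min_idx <- c(1L, which_local_minima(sm), length(sm))

  groups <- purrr::map_dfr(apex_idx, function(a) {
    left <- max(min_idx[min_idx < a])
    right <- min(min_idx[min_idx > a])
    sel <- left:right
    areas <- apply(mat[sel, , drop = FALSE], 2, function(y) pracma::trapz(rt[sel], y))
    sub <- mat[sel, , drop = FALSE]
    tibble(
      apex_rt = rt[a], left = rt[left], right = rt[right],
      score = peak_group_score(areas, sub, library_intensities),
      areas = list(areas),
      profile = list(tibble(rt = rt[sel], intensity = total[sel]))
    )
  })
  dplyr::arrange(groups, dplyr::desc(.data$score), .data$apex_rt)
}

empty_peak_groups <- function() {
  tibble(
    apex_rt = numeric(), left = numeric(), right = numeric(),
    score = numeric(), areas = list(), profile = list()
  )
}

smooth_trace <- function(y, n = 5L, p = 2L) {
  if (length(y) < n) return(y)
  as.numeric(signal::sgolayfilt(y, p = p, n = n))
}

which_local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer())
  which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
}

which_local_minima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer())
  which(y[2:(n - 1)] < y[1:(n - 2)] & y[2:(n - 1)] <= y[3:n]) + 1L
}

# 0.5 * normalized spectral contrast angle + 0.5 * mean pairwise trace Pearson
peak_group_score <- function(areas, traces, library_intensities) {
  if (is.null(library_intensities)) {
    library_intensities <- setNames(rep(1, length(areas)), names(areas))
  }
  lib <- library_intensities[names(areas)]
  sca <- spectral_contrast_angle(areas, lib)
  keep <- colSums(traces) > 0
  r_mean <- if (sum(keep) >= 2L) {
    cm <- suppressWarnings(cor(traces[, keep, drop = FALSE]))
    mean(cm[upper.tri(cm)], na.rm = TRUE)
  } else {
    0
  }
  if (is.nan(r_mean)) r_mean <- 0
  0.5 * sca + 0.5 * r_mean
}

# 1 - 2/pi * angle between non-negative vectors; 1 = identical shape
spectral_contrast_angle <- function(a, b) {
  if (sum(a) == 0 || sum(b) == 0) return(0)
  cs <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  1 - 2 * acos(pmin(pmax(cs, -1), 1)) / pi
}

#' Detect 3D MS1 features
#'
#' Per-scan 2D features (centroid peaks above an intensity threshold) are
#' connected across adjacent MS1 scans when their m/z values agree within a
#' ppm tolerance, allowing up to `gap_limit` missing scans; chains spanning
#' fewer than `min_span` scans are dropped. This is the precursor-side input
#' of library-free pseudo-DDA spectrum generation.
#'
#' @param run A [dia_run()] (only MS1 scans are used).
#' @param tolerance_ppm m/z match tolerance between scans (default 10).
#' @param intensity_threshold Minimum peak intensity to seed/extend a feature.
#' @param gap_limit Maximum consecutive missing scans inside a feature.
#' @param min_span Minimum number of member scans.
#' @return A tibble of features: `feature`, `mz` (intensity-weighted mean),
#'   `rt_start`, `rt_end`, `apex_rt`, `apex_intensity`, `scans` (list of scan
#'   indices), `profile` (list of `rt`/`intensity` tibbles).
#' @export
detect_3d_features <- function(run, tolerance_ppm = 10,
                               intensity_threshold = 0, gap_limit = 1L,
                               min_span = 3L) {
  ms1 <- dplyr::filter(run, .data$ms_level == 1L)
  if (nrow(ms1) == 0L) return(empty_features())
  active <- list()   # each: list(mz, rts, ints, scans, gap)
  done <- list()
  for (s in seq_len(nrow(ms1))) {
    pk_mz <- ms1$mz[[s]]
    pk_int <- ms1$intensity[[s]]
    keep <- pk_int > intensity_threshold
    pk_mz <- pk_mz[keep]; pk_int <- pk_int[keep]
    used <- rep(FALSE, length(pk_mz))
    if (length(active) > 0L) {
      extended <- logical(length(active))
      for (f in seq_along(active)) {
        feat <- active[[f]]
        tol <- feat$mz * tolerance_ppm * 1e-6
        hit <- which(!used & abs(pk_mz - feat$mz) <= tol)
        if (length(hit) > 0L) {
          j <- hit[which.max(pk_int[hit])]
          used[j] <- TRUE
          w <- sum(feat$ints)
          feat$mz <- (feat$mz * w + pk_mz[j] * pk_int[j]) / (w + pk_int[j])
          feat$rts <- c(feat$rts, ms1$rt[s])
          feat$ints <- c(feat$ints, pk_int[j])
          feat$scans <- c(feat$scans, ms1$scan[s])
          feat$gap <- 0L
          extended[f] <- TRUE
        } else {
          feat$gap <- feat$gap + 1L
        }
        active[[f]] <- feat
      }
      expired <- vapply(active, function(f) f$gap > gap_limit, logical(1))
      done <- c(done, active[expired])
      active <- active[!expired]
    }
    for (j in which(!used)) {
      active <- c(active, list(list(
        mz = pk_mz[j], rts = ms1$rt[s], ints = pk_int[j],
        scans = ms1$scan[s], gap = 0L
      )))
    }
  }
  done <- c(done, active)
  done <- purrr::keep(done, function(f) length(f$scans) >= min_span)
  if (length(done) == 0L) return(empty_features())
  purrr::imap_dfr(done, function(f, i) {
    a <- which.max(f$ints)
    tibble(
      feature = i, mz = f$mz,
      rt_start = min(f$rts), rt_end = max(f$rts),
      apex_rt = f$rts[a], apex_intensity = f$ints[a],
      scans = list(f$scans),
      profile = list(tibble(rt = f$rts, intensity = f$ints))
    )
  })
}

empty_features <- function() {
  tibble(
    feature = integer(), mz = numeric(), rt_start = numeric(),
    rt_end = numeric(), apex_rt = numeric(), apex_intensity = numeric(),
    scans = list(), profile = list()
  )
}

#' Build pseudo-DDA spectra from 3D features
#'
#' For each MS1 feature, extracts fragment XICs in the feature's isolation
#' window over its elution span and keeps fragment masses whose XIC Pearson
#' correlation with the feature's MS1 elution profile is at least `r_min`.
#' When several co-isolated features claim the same fragment mass in the same
#' window, the fragment is assigned to the feature it correlates with best.
#' The result is a DDA-like peak list (fragment m/z with apex intensities)
#' per precursor feature, searchable by a conventional engine.
#'
#' @param features Tibble from [detect_3d_features()].
#' @param run A [dia_run()] with MS2 scans.
#' @param scheme Window scheme from [build_window_scheme()].
#' @param tolerance_ppm Fragment m/z clustering/extraction tolerance.
#' @param r_min Minimum profile correlation (default 0.8).
#' @return A tibble: `feature`, `precursor_mz`, `apex_rt`, `window`, `peaks`
#'   (list of `mz`/`intensity` tibbles). Features with no correlated
#'   fragments are skipped.
#' @export
build_pseudo_spectra <- function(features, run, scheme,
                                 tolerance_ppm = 20, r_min = 0.8) {
  if (nrow(features) == 0L) return(empty_pseudo_spectra())
  cand <- purrr::map_dfr(seq_len(nrow(features)), function(i) {
    feat <- features[i, ]
    windows <- assign_windows(feat$mz, scheme)
    purrr::map_dfr(windows, function(w) {
      scans <- select_scans(run, w, c(feat$rt_start, feat$rt_end))
      if (nrow(scans) < 3L) return(NULL)
      frag_mz <- cluster_masses(unlist(scans$mz), tolerance_ppm)
      if (length(frag_mz) == 0L) return(NULL)
      xm <- xic_matrix(scans, frag_mz, tolerance_ppm)
      prof <- feat$profile[[1]]
      ref <- approx_intensity(prof, scans$rt)
      if (sd(ref) == 0) return(NULL)
      r <- apply(xm, 2, function(y) {
        if (sd(y) == 0) return(0)
        suppressWarnings(cor(y, ref))
      })
      r[is.na(r)] <- 0
      keep <- r >= r_min
      if (!any(keep)) return(NULL)
      tibble(
        feature = feat$feature, window = w,
        frag_mz = frag_mz[keep], r = r[keep],
        apex_intensity = apply(xm[, keep, drop = FALSE], 2, max)
      )
    })
  })
  if (nrow(cand) == 0L) return(empty_pseudo_spectra())
  # resolve contested fragments: within a window, a fragment mass goes to the
  # feature with the highest correlation
  cand <- cand %>%
    dplyr::mutate(mass_key = paste(.data$window,
                                   cluster_assign(.data$frag_mz, tolerance_ppm))) %>%
    dplyr::group_by(.data$mass_key) %>%
    dplyr::filter(.data$r == max(.data$r)) %>%
    dplyr::slice(1) %>%
    dplyr::ungroup()
  cand %>%
    dplyr::group_by(.data$feature, .data$window) %>%
    dplyr::summarise(
      peaks = list(dplyr::arrange(
        tibble(mz = frag_mz, intensity = apex_intensity), mz
      )),
      .groups = "drop"
    ) %>%
    dplyr::left_join(
      dplyr::select(features, "feature", precursor_mz = "mz", "apex_rt"),
      by = "feature"
    ) %>%
    dplyr::select("feature", "precursor_mz", "apex_rt", "window", "peaks")
}

empty_pseudo_spectra <- function() {
  tibble(
    feature = integer(), precursor_mz = numeric(), apex_rt = numeric(),
    window = integer(), peaks = list()
  )
}

# collapse a pool of observed m/z values into cluster centers at ppm scale
cluster_masses <- function(mz, tolerance_ppm) {
  mz <- sort(unique(mz))
  if (length(mz) == 0L) return(numeric())
  gaps <- diff(mz) > mz[-length(mz)] * tolerance_ppm * 1e-6
  cl <- cumsum(c(1L, as.integer(gaps)))
  as.numeric(tapply(mz, cl, mean))
}

# assign each value to a cluster id (same rule as cluster_masses)
cluster_assign <- function(mz, tolerance_ppm) {
  ord <- order(mz)
  s <- mz[ord]
  gaps <- diff(s) > s[-length(s)] * tolerance_ppm * 1e-6
  cl <- cumsum(c(1L, as.integer(gaps)))
  out <- integer(length(mz))
  out[ord] <- cl
  out
}

approx_intensity <- function(profile, rt) {
  stats::approx(profile$rt, profile$intensity, xout = rt, rule = 2)$y
}

#' Isolation-window transmission and centerness diagnostics
#'
#' For precursors observed in two half-window-shifted schemes, transmission
#' is the intensity at the window-extreme position divided by the intensity
#' at the centermost position, and centerness is the distance of the
#' precursor m/z from the window center divided by half the window width
#' (0 at the center, 1 at the edge). Together they describe signal
#' attenuation toward window edges and motivate overlapping windows.
#'
#' @param observations Tibble with columns `mz`, `window_lower`,
#'   `window_upper`, `intensity_extreme` (precursor measured near the window
#'   edge), `intensity_center` (same precursor measured centered).
#' @return Input tibble with `transmission` and `centerness` columns; rows
#'   with zero center intensity are dropped with a warning.
#' @export
window_diagnostics <- function(observations) {
  stopifnot(all(c("mz", "window_lower", "window_upper",
                  "intensity_extreme", "intensity_center") %in% names(observations)))
  bad <- observations$intensity_center == 0
  if (any(bad)) {
    warn(sprintf("dropping %d observation(s) with zero center intensity", sum(bad)))
    observations <- observations[!bad, ]
  }
  observations %>%
    dplyr::mutate(
      width = .data$window_upper - .data$window_lower,
      center = (.data$window_upper + .data$window_lower) / 2,
      transmission = .data$intensity_extreme / .data$intensity_center,
      centerness = abs(.data$mz - .data$center) / (.data$width / 2)
    ) %>%
    dplyr::select(-"width", -"center")
}
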