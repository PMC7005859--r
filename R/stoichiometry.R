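#' Closed-form two-condition phosphosite occupancy
#'
#' Given the between-condition ratios of the phosphopeptide (`x`), its
#' non-phosphorylated counterpart peptide (`y`) and the protein (`z`), the
#' fractional occupancies of the two conditions have the closed form
#' `a_B = (z - y) / (x - y)` and `a_A = x * (z - y) / (z * (x - y))`.
#' Estimates outside `[0, 1]` are clipped and flagged.
#'
#' @param x Phosphopeptide intensity ratio A/B (> 0).
#' @param y Counterpart-peptide intensity ratio A/B (> 0).
#' @param z Protein intensity ratio A/B (> 0).
#' @return A tibble with one row: `a_A`, `a_B`, `clipped`.
#' @examples
#' occupancy_two_condition(x = 1.5, y = 0.5, z = 1)
#' @export
occupancy_two_condition <- function(x, y, z) {
  if (any(c(x, y, z) <= 0)) abort("ratios must be > 0")
  if (isTRUE(all.equal(x, y))) abort("indeterminate occupancy: x = y")
  a_B <- (z - y) / (x - y)
  a_A <- x * (z - y) / (z * (x - y))
  clipped <- a_A < 0 || a_A > 1 || a_B < 0 || a_B > 1
  tibble(
    a_A = clamp01(a_A),
    a_B = clamp01(a_B),
    clipped = clipped
  )
}

#' Fill missing peptide intensities by linear-behavior extrapolation
#'
#' Peptide forms that map to the same underlying peptide group (charge
#' states, missed-cleavage variants) are assumed to behave linearly with each
#' other across samples. For each form with missing entries, the donor form
#' with the highest Pearson correlation over at least two shared log-scale
#' observations is chosen, a least-squares line is fitted in log space, and
#' missing entries are predicted from the donor. Entries that cannot be
#' filled stay missing.
#'
#' @param data Long tibble with columns `group` (peptide group id), `form`
#'   (peptide form id), `sample`, `intensity` (linear scale; `NA` = missing).
#' @return The input with missing intensities filled where possible and a
#'   logical `imputed` column.
#' @export
extrapolate_missing <- function(data) {
  data <- as_tibble(data)
  stopifnot(all(c("group", "form", "sample", "intensity") %in% names(data)))
  filled <- data %>%
    dplyr::group_by(.data$group) %>%
    dplyr::group_modify(~ extrapolate_group(.x)) %>%
    dplyr::ungroup()
  filled
}

extrapolate_group <- function(gdat) {
  wide <- tidyr::pivot_wider(gdat, id_cols = "sample", names_from = "form",
                             values_from = "intensity")
  samples <- wide$sample
  mat <- log2(as.matrix(wide[, -1, drop = FALSE]))
  forms <- colnames(mat)
  imputed <- matrix(FALSE, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  if (ncol(mat) >= 2L) {
    for (j in seq_len(ncol(mat))) {
      miss <- is.na(mat[, j])
      if (!any(miss)) next
      best <- NULL
      best_r <- -Inf
      for (k in seq_len(ncol(mat))) {
        if (k == j) next
        shared <- !is.na(mat[, j]) & !is.na(mat[, k])
        if (sum(shared) < 2L) next
        r <- if (sd(mat[shared, j]) == 0 || sd(mat[shared, k]) == 0) {
          1  # exactly proportional constant forms: perfect linear relation
        } else {
          suppressWarnings(cor(mat[shared, j], mat[shared, k]))
        }
        if (!is.na(r) && r > best_r) {
          best_r <- r
          best <- k
        }
      }
      if (is.null(best)) next
      shared <- !is.na(mat[, j]) & !is.na(mat[, best])
      fit <- stats::lm.fit(cbind(1, mat[shared, best, drop = FALSE]),
                           mat[shared, j])
      can_fill <- miss & !is.na(mat[, best])
      if (any(can_fill)) {
        pred <- fit$coefficients[1] + fit$coefficients[2] * mat[can_fill, best]
        mat[can_fill, j] <- pred
        imputed[can_fill, j] <- TRUE
      }
    }
  }
  out <- tibble(
    sample = rep(samples, times = ncol(mat)),
    form = rep(forms, each = nrow(mat)),
    intensity = 2^as.numeric(mat),
    imputed = as.logical(imputed)
  )
  out$intensity[is.na(as.numeric(mat))] <- NA_real_
  # preserve original row order/columns
  dplyr::left_join(
    dplyr::select(gdat, -"intensity"), out,
    by = c("form", "sample")
  )
}

#' Fit the label-free 3D multiple-regression occupancy model
#'
#' The 3DMM relates protein intensity to the phosphorylated and
#' non-phosphorylated forms of one site across all conditions and replicates
#' at once: `Q ~ alpha * P + beta * N`, a plane through the origin in
#' (P, N, Q) space, fitted by nonnegative least squares (response factors are
#' physical and cannot be negative). The occupancy of condition `i` is then
#' `a_i = alpha * P_i / (alpha * P_i + beta * N_i)` evaluated on
#' replicate-mean intensities, so the estimate is invariant to any common
#' rescaling of `(alpha, beta)`.
#'
#' @param data Tibble with columns `condition`, `P` (phosphopeptide
#'   intensity), `N` (counterpart non-phospho intensity), `Q` (protein
#'   intensity), all linear scale; one row per condition x replicate.
#'   Rows with any missing value are dropped.
#' @return An object of class `occupancy_fit` with elements `alpha`, `beta`,
#'   `occupancy` (tibble: `condition`, `occupancy`, `clipped`), `residuals`,
#'   `r_squared`, `degenerate`, `n_points`.
#' @examples
#' d <- tibble::tibble(condition = c("A", "B"), P = c(80, 20),
#'                     N = c(20, 80), Q = c(100, 100))
#' fit_3dmm(d)
#' @export
fit_3dmm <- function(data) {
  data <- as_tibble(data)
  stopifnot(all(c("condition", "P", "N", "Q") %in% names(data)))
  data <- dplyr::filter(data, !is.na(.data$P), !is.na(.data$N), !is.na(.data$Q))
  conds <- unique(data$condition)
  if (length(conds) < 2L) abort("insufficient conditions: need >= 2 with complete triplets")
  A <- cbind(P = data$P, N = data$N)
  fit <- pracma::lsqnonneg(A, data$Q)
  alpha <- fit$x[1]
  beta <- fit$x[2]
  resid <- data$Q - A %*% fit$x
  ss_tot <- sum((data$Q - mean(data$Q))^2)
  r2 <- if (ss_tot > 0) 1 - sum(resid^2) / ss_tot else NA_real_
  all_zero_n <- all(data$N == 0)
  means <- data %>%
    dplyr::group_by(.data$condition) %>%
    dplyr::summarise(P = mean(.data$P), N = mean(.data$N), .groups = "drop")
  denom <- alpha * means$P + beta * means$N
  occ <- ifelse(denom > 0, alpha * means$P / denom, NA_real_)
  if (all_zero_n) occ <- rep(1, nrow(means))
  clipped <- !is.na(occ) & (occ < 0 | occ > 1)
  occupancy <- tibble(
    condition = means$condition,
    occupancy = clamp01(occ),
    clipped = clipped
  )
  degenerate <- all_zero_n || alpha == 0 || beta == 0
  structure(
    list(
      alpha = alpha, beta = beta, occupancy = occupancy,
      residuals = as.numeric(resid), r_squared = r2,
      degenerate = degenerate, n_points = nrow(data)
    ),
    class = "occupancy_fit"
  )
}

#' @export
print.occupancy_fit <- function(x, ...) {
  cat(sprintf("<occupancy_fit> alpha=%.4g beta=%.4g R2=%.4f%s\n",
              x$alpha, x$beta, x$r_squared,
              if (x$degenerate) " [degenerate]" else ""))
  print(x$occupancy)
  invisible(x)
}

#' @rdname fit_3dmm
#' @param x An `occupancy_fit`.
#' @param ... Unused.
#' @method tidy occupancy_fit
#' @export
tidy.occupancy_fit <- function(x, ...) {
  x$occupancy
}

#' @rdname fit_3dmm
#' @method glance occupancy_fit
#' @export
glance.occupancy_fit <- function(x, ...) {
  tibble(
    alpha = x$alpha, beta = x$beta, r_squared = x$r_squared,
    degenerate = x$degenerate, n_points = x$n_points
  )
}

#' Fit the 3DMM per site over a triplet table
#'
#' Convenience wrapper applying [fit_3dmm()] to every site of a long triplet
#' table.
#'
#' @param triplets Tibble with columns `site`, `condition`, `P`, `N`, `Q`.
#' @return A tibble: `site`, `condition`, `occupancy`, `clipped`, `alpha`,
#'   `beta`, `degenerate`. Sites whose fit fails are omitted.
#' @export
fit_3dmm_by_site <- function(triplets) {
  triplets %>%
    dplyr::group_by(.data$site) %>%
    dplyr::group_modify(function(d, key) {
      fit <- tryCatch(fit_3dmm(d), error = function(e) NULL)
      if (is.null(fit)) return(tibble())
      dplyr::mutate(fit$occupancy, alpha = fit$alpha, beta = fit$beta,
                    degenerate = fit$degenerate)
    }) %>%
    dplyr::ungroup()
}
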