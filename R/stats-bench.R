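#' Filter features by minimum valid values per group
#'
#' Keeps features quantified in at least `min_valid` samples of at least one
#' treatment group (the standard "min. 3 valid values in at least one group"
#' filter applied before statistical testing).
#'
#' @param data Wide tibble: a `feature` column plus one numeric column per
#'   sample (`NA` = missing).
#' @param design Tibble with columns `sample`, `group`.
#' @param min_valid Minimum number of valid values required in some group.
#' @return The filtered tibble.
#' @export
filter_min_valid <- function(data, design, min_valid = 3L) {
  mat <- wide_to_matrix(data, design)
  groups <- split(design$sample, design$group)
  if (min_valid > max(lengths(groups))) {
    abort("`min_valid` exceeds the largest group size")
  }
  keep <- Reduce(`|`, lapply(groups, function(s) {
    rowSums(!is.na(mat[, s, drop = FALSE])) >= min_valid
  }))
  data[keep, , drop = FALSE]
}

wide_to_matrix <- function(data, design) {
  missing_samples <- setdiff(design$sample, names(data))
  if (length(missing_samples) > 0L) {
    abort(paste0("sample column(s) absent from data: ",
                 paste(missing_samples, collapse = ", ")))
  }
  mat <- as.matrix(data[, design$sample, drop = FALSE])
  rownames(mat) <- data$feature
  mat
}

#' Median-center samples and impute from a downshifted normal
#'
#' Subtracts each sample's median (so every sample median becomes 0), then
#' replaces missing entries with draws from
#' `Normal(mean_s - downshift * sd_s, width * sd_s)`, where `mean_s`/`sd_s`
#' are the observed mean and standard deviation of the sample after
#' centering. This emulates the standard proteomics treatment of
#' missing-not-at-random values as low-abundance observations. The defaults
#' (`width = 0.3`, `downshift = 1.8`) are the field-standard Perseus
#' settings. With a fixed seed the imputation is bit-reproducible.
#'
#' @param data Wide log2-intensity tibble (`feature` + sample columns).
#' @param design Tibble with columns `sample`, `group`.
#' @param width Imputation s.d. as a fraction of the sample s.d.
#' @param downshift Imputation mean shift in sample s.d. units.
#' @param seed Optional integer seed.
#' @param median_center Subtract sample medians first (default `TRUE`).
#' @return The data tibble, median-centered and with no missing entries.
#' @export
normalize_and_impute <- function(data, design, width = 0.3, downshift = 1.8,
                                 seed = NULL, median_center = TRUE) {
  mat <- wide_to_matrix(data, design)
  if (any(colSums(!is.na(mat)) < 2L)) {
    abort("every sample needs at least 2 valid values")
  }
  if (median_center) {
    med <- apply(mat, 2, median, na.rm = TRUE)
    mat <- sweep(mat, 2, med)
  }
  if (!is.null(seed)) set.seed(seed)
  for (j in seq_len(ncol(mat))) {
    miss <- is.na(mat[, j])
    if (!any(miss)) next
    m <- mean(mat[, j], na.rm = TRUE)
    s <- sd(mat[, j], na.rm = TRUE)
    mat[miss, j] <- rnorm(sum(miss), mean = m - downshift * s, sd = width * s)
  }
  out <- data
  out[, design$sample] <- as.data.frame(mat)
  out
}

#' s0-moderated SAM test with permutation FDR
#'
#' Two-class design: the d-score of feature `i` is
#' `d_i = (mean_1 - mean_2) / (s_i + s0)` with `s_i` the pooled standard
#' error. Multi-class design: an s0-moderated F-type statistic,
#' `sqrt(sum_k n_k (mean_k - mean)^2 / (K - 1)) / (s_i + s0)` with `s_i` the
#' pooled within-group standard deviation. The fudge factor `s0` damps the
#' statistic of low-variance features. q-values come from group-label
#' permutations: at each observed |d| threshold, the expected number of null
#' features exceeding it (mean over permutations) divided by the number of
#' observed features exceeding it, made monotone and capped at 1.
#'
#' @param data Wide log2 tibble (`feature` + sample columns), no missing
#'   values (run [normalize_and_impute()] first).
#' @param design Tibble with `sample`, `group` (2 or more groups, each with
#'   at least 2 samples).
#' @param s0 Fudge factor (default 0.1).
#' @param n_permutations Number of label permutations (default 250).
#' @param fdr Significance cutoff on the q-value (default 0.05).
#' @param seed Optional integer seed for the permutations.
#' @param z_score Z-score each feature before testing (multi-class
#'   convention; default `FALSE`).
#' @return An object of class `sam_test`: `result` tibble (`feature`,
#'   `statistic`, `q_value`, `significant`), plus the call parameters.
#' @export
sam_test <- function(data, design, s0 = 0.1, n_permutations = 250L,
                     fdr = 0.05, seed = NULL, z_score = FALSE) {
  mat <- wide_to_matrix(data, design)
  if (anyNA(mat)) abort("matrix contains missing values; impute first")
  groups <- factor(design$group)
  if (nlevels(groups) < 2L) abort("need at least two groups")
  if (any(table(groups) < 2L)) abort("every group needs >= 2 samples")
  if (n_permutations < 25L) warn("fewer than 25 permutations: q-values will be unstable")
  if (isTRUE(z_score)) {
    mat <- t(scale(t(mat)))
  }
  stat_fun <- if (nlevels(groups) == 2L) sam_d_two_class else sam_d_multi_class
  d_obs <- stat_fun(mat, groups, s0)
  if (!is.null(seed)) set.seed(seed)
  perm_stats <- vapply(seq_len(n_permutations), function(b) {
    stat_fun(mat, sample(groups), s0)
  }, numeric(nrow(mat)))
  perm_stats <- matrix(perm_stats, nrow = nrow(mat))
  q <- permutation_q_values(abs(d_obs), abs(perm_stats))
  result <- tibble(
    feature = if (!is.null(rownames(mat))) rownames(mat) else as.character(seq_len(nrow(mat))),
    statistic = unname(d_obs),
    q_value = unname(q),
    significant = q <= fdr
  )
  structure(
    list(result = result, s0 = s0, fdr = fdr,
         n_permutations = n_permutations, design = "sam",
         n_groups = nlevels(groups)),
    class = "sam_test"
  )
}

sam_d_two_class <- function(mat, groups, s0) {
  lev <- levels(groups)
  i1 <- groups == lev[1]
  i2 <- groups == lev[2]
  n1 <- sum(i1); n2 <- sum(i2)
  m1 <- rowMeans(mat[, i1, drop = FALSE])
  m2 <- rowMeans(mat[, i2, drop = FALSE])
  ss1 <- rowSums((mat[, i1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((mat[, i2, drop = FALSE] - m2)^2)
  si <- sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (n1 + n2 - 2))
  (m1 - m2) / (si + s0)
}

sam_d_multi_class <- function(mat, groups, s0) {
  lev <- levels(groups)
  K <- length(lev)
  n <- ncol(mat)
  overall <- rowMeans(mat)
  between <- 0
  within_ss <- 0
  for (g in lev) {
    sel <- groups == g
    ng <- sum(sel)
    mg <- rowMeans(mat[, sel, drop = FALSE])
    between <- between + ng * (mg - overall)^2
    within_ss <- within_ss + rowSums((mat[, sel, drop = FALSE] - mg)^2)
  }
  si <- sqrt(within_ss / (n - K))
  sqrt(between / (K - 1)) / (si + s0)
}

# expected false positives over observed positives at each |d| threshold
permutation_q_values <- function(abs_obs, abs_perm) {
  m <- length(abs_obs)
  ord <- order(abs_obs, decreasing = TRUE)
  sorted_perm <- sort(as.numeric(abs_perm))
  n_perm_total <- length(sorted_perm)
  b <- ncol(abs_perm)
  q <- numeric(m)
  # positives at threshold abs_obs[i]: rank among observed
  obs_sorted <- abs_obs[ord]
  for (r in seq_len(m)) {
    thr <- obs_sorted[r]
    exceed <- n_perm_total - findInterval(thr, sorted_perm, left.open = FALSE)
    fp <- exceed / b
    q[r] <- min(1, fp / r)
  }
  # enforce monotonicity (q non-decreasing with rank)
  q <- cummax(q)
  out <- numeric(m)
  out[ord] <- q
  out
}

#' @rdname sam_test
#' @param x A `sam_test` object.
#' @param ... Unused.
#' @method tidy sam_test
#' @export
tidy.sam_test <- function(x, ...) x$result

#' @rdname sam_test
#' @method glance sam_test
#' @export
glance.sam_test <- function(x, ...) {
  tibble(
    n_features = nrow(x$result),
    n_significant = sum(x$result$significant),
    s0 = x$s0, fdr = x$fdr, n_permutations = x$n_permutations,
    n_groups = x$n_groups
  )
}

#' @export
print.sam_test <- function(x, ...) {
  cat(sprintf("<sam_test> %d features, %d significant at q <= %g (s0 = %g)\n",
              nrow(x$result), sum(x$result$significant), x$fdr, x$s0))
  invisible(x)
}

#' ROC curve from d-scores
#'
#' Thresholds the absolute score and reports true/false-positive rates at
#' every threshold, plus the trapezoidal area under the curve.
#'
#' @param scores Numeric scores (e.g. SAM d-scores).
#' @param truth Logical (or 0/1) ground-truth labels, `TRUE` = positive.
#' @return An object of class `roc_curve`: `points` tibble (`threshold`,
#'   `tpr`, `fpr`) and `auc`.
#' @export
roc_from_scores <- function(scores, truth) {
  truth <- as.logical(truth)
  if (length(scores) != length(truth)) abort("`scores` and `truth` lengths differ")
  if (all(truth) || !any(truth)) abort("both classes must be present")
  s <- abs(scores)
  thresholds <- c(Inf, sort(unique(s), decreasing = TRUE))
  n_pos <- sum(truth)
  n_neg <- sum(!truth)
  pts <- purrr::map_dfr(thresholds, function(t) {
    call <- s >= t
    tibble(threshold = t,
           tpr = sum(call & truth) / n_pos,
           fpr = sum(call & !truth) / n_neg)
  })
  auc <- pracma::trapz(pts$fpr, pts$tpr)
  structure(list(points = pts, auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC = %.4f (%d thresholds)\n",
              x$auc, nrow(x$points)))
  invisible(x)
}

#' @rdname roc_from_scores
#' @param x A `roc_curve`.
#' @param ... Unused.
#' @method tidy roc_curve
#' @export
tidy.roc_curve <- function(x, ...) x$points

#' @rdname roc_from_scores
#' @method glance roc_curve
#' @export
glance.roc_curve <- function(x, ...) tibble(auc = x$auc)

#' Bias/variance decomposition of the mean squared error
#'
#' Reports `bias = |mean(estimates) - truth|`, the population variance of
#' the estimates, the classical `mse = bias^2 + variance` (which equals
#' `mean((estimate - truth)^2)`), and the additive summary `bias + variance`
#' used by the benchmark figures of quantification-accuracy comparisons.
#'
#' @param estimates Numeric vector of estimates (length >= 2).
#' @param truth The true value.
#' @return A tibble: `bias`, `variance`, `mse`, `bias_plus_variance`.
#' @export
mse_decomposition <- function(estimates, truth) {
  if (length(estimates) < 2L) abort("need at least 2 estimates")
  bias <- abs(mean(estimates) - truth)
  variance <- mean((estimates - mean(estimates))^2)
  tibble(
    bias = bias,
    variance = variance,
    mse = bias^2 + variance,
    bias_plus_variance = bias + variance
  )
}
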