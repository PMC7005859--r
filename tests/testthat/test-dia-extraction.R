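# Small run builders used across extraction tests.
gaussian_run <- function(frag_mz, apex_rt, sigma = 5, cycle = 2, rt_max = 200,
                         amplitudes = rep(1e5, length(frag_mz)), window = 0L) {
  rts <- seq(0, rt_max, by = cycle)
  mz_order <- order(frag_mz)
  dia_run(
    scan = seq_along(rts), ms_level = 2L, rt = rts,
    window = rep(window, length(rts)),
    mz = lapply(rts, function(r) frag_mz[mz_order]),
    intensity = lapply(rts, function(r) {
      (amplitudes * exp(-(r - apex_rt)^2 / (2 * sigma^2)))[mz_order]
    })
  )
}

test_that("window scheme reproduces the 48 x 14 Da / 1 Da overlap layout", {
  scheme <- build_window_scheme(350, 14, 1, 48)
  expect_equal(nrow(scheme), 48)
  expect_equal(c(scheme$lower[1], scheme$upper[1]), c(350, 364))
  expect_equal(c(scheme$lower[2], scheme$upper[2]), c(363, 377))
  expect_equal(scheme$upper[48], 975)
  expect_error(build_window_scheme(350, 14, 14, 48), "overlap")

  # zero overlap: adjacent windows share exactly the boundary point
  s0 <- build_window_scheme(350, 10, 0, 5)
  expect_equal(s0$upper[-5], s0$lower[-1])
})

test_that("precursors map to windows, doubly inside overlap regions", {
  scheme <- build_window_scheme(350, 14, 1, 48)
  expect_equal(assign_windows(363.5, scheme), c(0L, 1L))
  expect_equal(assign_windows(355, scheme), 0L)
  expect_equal(assign_windows(349, scheme), integer(0))
})

test_that("XIC extraction sums matching peaks and zero-fills absent signal", {
  run <- dia_run(
    scan = 1:3, ms_level = 2L, rt = c(10, 20, 30), window = c(0L, 0L, 0L),
    mz = list(c(500.000, 500.005), 500.000, numeric()),
    intensity = list(c(100, 50), 200, numeric())
  )
  x <- extract_xic(run, 500.000, tolerance_ppm = 20, window_index = 0L)
  expect_equal(x$intensity, c(150, 200, 0))  # 500.005 is 10 ppm away: summed
  x2 <- extract_xic(run, 500.02, tolerance_ppm = 20, window_index = 0L)
  expect_equal(x2$intensity, c(0, 0, 0))     # 40 ppm away
  expect_error(extract_xic(run, 500, window_index = 7L), "window 7")
})

test_that("XIC extraction is linear in spectrum intensity", {
  run <- gaussian_run(c(300.1, 450.2, 600.3), apex_rt = 100)
  scaled <- run
  scaled$intensity <- lapply(run$intensity, function(i) 3.7 * i)
  for (mz in c(300.1, 450.2, 600.3)) {
    a <- extract_xic(run, mz, window_index = 0L)
    b <- extract_xic(scaled, mz, window_index = 0L)
    expect_equal(b$intensity, 3.7 * a$intensity)
  }
})

test_that("peak groups recover Gaussian apexes and rank by score", {
  run <- gaussian_run(c(300.1, 450.2, 600.3), apex_rt = 100, cycle = 2)
  xics <- purrr::map_dfr(c(300.1, 450.2, 600.3), function(mz) {
    x <- extract_xic(run, mz, window_index = 0L)
    dplyr::mutate(x, fragment = paste0("f", mz))
  })
  groups <- detect_peak_groups(xics)
  expect_equal(nrow(groups), 1)
  expect_lte(abs(groups$apex_rt - 100), 2)  # within one grid step
  expect_true(groups$left < groups$apex_rt && groups$apex_rt < groups$right)
  expect_true(all(unlist(groups$areas) >= 0))

  # two baseline-separated peaks give two groups
  rts <- seq(0, 300, by = 2)
  two <- dia_run(
    scan = seq_along(rts), ms_level = 2L, rt = rts,
    window = rep(0L, length(rts)),
    mz = lapply(rts, function(r) 500.5),
    intensity = lapply(rts, function(r) {
      1e5 * (exp(-(r - 80)^2 / 50) + exp(-(r - 220)^2 / 50)) + 1
    })
  )
  x <- dplyr::mutate(extract_xic(two, 500.5, window_index = 0L),
                     fragment = "f1")
  g2 <- detect_peak_groups(x)
  expect_equal(nrow(g2), 2)
  expect_lte(min(abs(g2$apex_rt - 80)), 2)
  expect_lte(min(abs(g2$apex_rt - 220)), 2)

  # all-zero traces give an empty result
  zero <- dplyr::mutate(x, intensity = 0)
  expect_equal(nrow(detect_peak_groups(zero)), 0)
})

test_that("noiseless Gaussian apex is found within one grid step on fine grids", {
  for (cycle in c(1, 2)) {  # sigma = 5, grids finer than sigma / 2
    run <- gaussian_run(c(400.2, 500.3), apex_rt = 103.3, sigma = 5,
                        cycle = cycle)
    xics <- purrr::map_dfr(c(400.2, 500.3), function(mz) {
      dplyr::mutate(extract_xic(run, mz, window_index = 0L),
                    fragment = paste0("f", mz))
    })
    g <- detect_peak_groups(xics)
    expect_lte(abs(g$apex_rt[1] - 103.3), cycle)
  }
})

test_that("3D feature detection connects scans and honors gap/span rules", {
  # one species in 5 consecutive MS1 scans
  rts <- seq(0, 20, by = 2)
  present <- rts >= 4 & rts <= 12
  run <- dia_run(
    scan = seq_along(rts), ms_level = 1L, rt = rts,
    window = rep(NA_integer_, length(rts)),
    mz = lapply(present, function(p) if (p) 600.3 else numeric()),
    intensity = lapply(present, function(p) if (p) 1e5 else numeric())
  )
  feats <- detect_3d_features(run, min_span = 3)
  expect_equal(nrow(feats), 1)
  expect_equal(length(feats$scans[[1]]), 5)
  expect_equal(feats$mz[1], 600.3, tolerance = 1e-6)

  # a 2-scan gap with gap limit 1 splits the trace; 3+3 scans survive span 3
  present2 <- rts %in% c(0, 2, 4, 12, 14, 16)
  run2 <- dia_run(
    scan = seq_along(rts), ms_level = 1L, rt = rts,
    window = rep(NA_integer_, length(rts)),
    mz = lapply(present2, function(p) if (p) 600.3 else numeric()),
    intensity = lapply(present2, function(p) if (p) 1e5 else numeric())
  )
  feats2 <- detect_3d_features(run2, gap_limit = 1, min_span = 3)
  expect_equal(nrow(feats2), 2)

  # sub-threshold noise yields nothing
  run3 <- dia_run(
    scan = seq_along(rts), ms_level = 1L, rt = rts,
    window = rep(NA_integer_, length(rts)),
    mz = lapply(rts, function(r) 600.3),
    intensity = lapply(rts, function(r) 5)
  )
  expect_equal(nrow(detect_3d_features(run3, intensity_threshold = 10)), 0)
})

test_that("pseudo-spectra keep co-eluting fragments and drop flat interference", {
  scheme <- build_window_scheme(350, 14, 1, 48)
  rts <- seq(0, 120, by = 2)
  prec_mz <- 500.25
  frag_mz <- c(200.1, 350.2, 480.3, 610.4, 750.5)
  gauss <- exp(-(rts - 60)^2 / (2 * 25))
  ms1 <- tibble::tibble(
    scan = seq_along(rts), ms_level = 1L, rt = rts, window = NA_integer_,
    mz = lapply(seq_along(rts), function(i) prec_mz),
    intensity = lapply(seq_along(rts), function(i) 1e5 * gauss[i])
  )
  ms2 <- tibble::tibble(
    scan = length(rts) + seq_along(rts), ms_level = 2L, rt = rts,
    window = assign_windows(prec_mz, scheme)[1],
    mz = lapply(seq_along(rts), function(i) c(frag_mz, 900.9)),
    intensity = lapply(seq_along(rts), function(i) {
      c(5e4 * gauss[i] * c(1, 0.8, 0.6, 0.4, 0.2), 3e4)  # last is flat
    })
  )
  run <- dia_run(
    scan = c(ms1$scan, ms2$scan), ms_level = c(ms1$ms_level, ms2$ms_level),
    rt = c(ms1$rt, ms2$rt), window = c(ms1$window, ms2$window),
    mz = c(ms1$mz, ms2$mz), intensity = c(ms1$intensity, ms2$intensity)
  )
  feats <- detect_3d_features(run, intensity_threshold = 100)
  expect_equal(nrow(feats), 1)
  ps <- build_pseudo_spectra(feats, run, scheme)
  expect_equal(nrow(ps), 1)
  peaks <- ps$peaks[[1]]
  expect_equal(peaks$mz, frag_mz, tolerance = 1e-6)   # flat 900.9 excluded
  # intensities proportional to the generative pattern (common scale)
  rel <- peaks$intensity / max(peaks$intensity)
  expect_equal(rel, c(1, 0.8, 0.6, 0.4, 0.2), tolerance = 0.05)
})

test_that("co-isolated precursors with distinct shapes split their fragments", {
  scheme <- build_window_scheme(350, 14, 1, 48)
  rts <- seq(0, 160, by = 2)
  g1 <- exp(-(rts - 50)^2 / (2 * 25))
  g2 <- exp(-(rts - 110)^2 / (2 * 25))
  fr1 <- c(210.1, 320.2, 430.3)
  fr2 <- c(515.4, 620.5, 730.6)
  run <- dia_run(
    scan = seq_len(2 * length(rts)),
    ms_level = rep(c(1L, 2L), each = length(rts)),
    rt = rep(rts, 2),
    window = rep(c(NA_integer_, 11L), each = length(rts)),
    mz = c(
      lapply(seq_along(rts), function(i) c(500.10, 505.30)),
      lapply(seq_along(rts), function(i) c(fr1, fr2))
    ),
    intensity = c(
      lapply(seq_along(rts), function(i) c(1e5 * g1[i], 8e4 * g2[i])),
      lapply(seq_along(rts), function(i) c(5e4 * g1[i] * c(1, .7, .5),
                                           4e4 * g2[i] * c(1, .7, .5)))
    )
  )
  feats <- detect_3d_features(run, intensity_threshold = 100)
  expect_equal(nrow(feats), 2)
  ps <- build_pseudo_spectra(feats, run, scheme)
  expect_equal(nrow(ps), 2)
  got1 <- ps$peaks[[which(abs(ps$precursor_mz - 500.10) < 0.01)]]$mz
  got2 <- ps$peaks[[which(abs(ps$precursor_mz - 505.30) < 0.01)]]$mz
  expect_equal(sort(got1), fr1, tolerance = 1e-6)
  expect_equal(sort(got2), fr2, tolerance = 1e-6)
  expect_equal(length(intersect(round(got1, 3), round(got2, 3))), 0)
})

test_that("transmission and centerness follow their definitions", {
  obs <- tibble::tibble(
    mz = c(357, 350.5, 363.9, 356),
    window_lower = 350, window_upper = 364,
    intensity_extreme = c(800, 500, 300, 0),
    intensity_center = c(1000, 1000, 1000, 0)
  )
  expect_warning(out <- window_diagnostics(obs), "zero center")
  expect_equal(nrow(out), 3)
  expect_equal(out$transmission, c(0.8, 0.5, 0.3))
  expect_equal(out$centerness[1], 0)                   # at window center
  expect_equal(out$centerness[2], 6.5 / 7)             # near the lower edge
  expect_equal(out$centerness[3], 6.9 / 7, tolerance = 1e-9)
})
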