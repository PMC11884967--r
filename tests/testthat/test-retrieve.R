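test_that("ALS baseline handles flat input, peaks, and the stiff limit", {
  y <- rep(3.3, 200)
  expect_lt(max(abs(als_baseline(y, 100, 0.001) - 3.3)), 1e-8)

  # line + one positive Lorentzian: asymmetric baseline stays on the line
  x <- 1:400
  line <- 2 + 0.004 * x
  peak <- 1.5 / (1 + ((x - 200) / 12)^2)
  z <- als_baseline(line + peak, 1e6, 0.001)
  under <- x > 160 & x < 240
  expect_lt(max(abs(z[under] - line[under]) / line[under]), 0.02)

  # lam -> 1e12: curvature of the fit vanishes (approaches a straight line)
  z2 <- suppressWarnings(als_baseline(line + peak, 1e12, 0.001))
  expect_lt(max(abs(diff(z2, differences = 2))), 1e-6)
})

test_that("ALS asymmetry weights sit below positive excursions", {
  set.seed(12)
  y <- c(rep(0, 80), 5 * exp(-((1:40 - 20) / 6)^2), rep(0, 80)) + rnorm(200, 0, 0.01)
  z <- als_baseline(y, 1e4, 0.001)
  expect_lt(mean(z[90:110]), 1)   # does not climb into the peak
})

test_that("KK phase is null for identical inputs and locates weak resonances", {
  k <- 512
  ref <- rep(100, k)
  expect_equal(kk_phase(ref, ref), rep(0, k))
  expect_equal(bcars:::.dht(rep(5, 256)), rep(0, 256))

  ax <- small_axis(k)
  m <- susceptibility_model(list(lorentzian_mode(1200, 15, 0.1 * 15)), 1)
  icars <- Mod(chi3_spectrum(m, ax))^2 * 100
  phi <- kk_phase(icars, ref)
  truth_peak <- which.min(abs(as.numeric(ax) - 1200))
  expect_lte(abs(which.max(phi) - truth_peak), 1)
})

test_that("discrete Hilbert transform is an anti-involution on the padded domain", {
  set.seed(13)
  for (i in 1:5) {
    n <- 512
    y <- as.numeric(stats::filter(rnorm(n), rep(1 / 8, 8), circular = TRUE))
    y <- y - mean(y)
    h2 <- bcars:::.dht(bcars:::.dht(y))
    expect_lt(max(abs(h2 + y)), 1e-3)
  }
})

test_that("NRB-only retrieval is numerically zero", {
  ax <- small_axis(512)
  ref <- glass_reference(ax)
  res <- suppressWarnings(retrieve_raman(ref, ref, ax))
  expect_lt(max(abs(res$raman_like)), 1e-6)
})

test_that("error-corrected retrieval recovers weak-resonance ground truth", {
  ax <- default_axis(1024)
  ref <- glass_reference(ax)
  ci <- crop_idx(ax)
  set.seed(14)
  cors <- vapply(1:10, function(i) {
    m <- random_weak_model()
    icars <- Mod(chi3_spectrum(m, ax))^2 * default_excitation(ax)$s_curve *
      (0.8^2 / m$chi_nr^2 + 1)   # arbitrary positive scale; retrieval is ratio-based
    res <- suppressWarnings(retrieve_raman(icars, ref, ax))
    cor(res$raman_like[ci], raman_truth(m, ax)[ci])
  }, numeric(1))
  expect_gte(min(cors), 0.99)
})

test_that("error correction beats plain KK under a mismatched reference", {
  ax <- default_axis(1024)
  d <- as.numeric(ax)
  exc <- default_excitation(ax)
  ci <- crop_idx(ax)
  m <- susceptibility_model(list(lorentzian_mode(1003, 6, 0.1 * 6),
                                 lorentzian_mode(1440, 15, 0.12 * 15),
                                 lorentzian_mode(2934, 40, 0.3 * 40)), 1)
  icars <- Mod(chi3_spectrum(m, ax))^2 * exc$s_curve
  # reference with a smooth 10% spectral tilt (shape error, not just level)
  ref_true <- glass_reference(ax, chi_nr = 1)
  ref_bad <- ref_true * (1 + 0.1 * (d - min(d)) / diff(range(d)))
  truth <- raman_truth(m, ax)
  corrected <- suppressWarnings(retrieve_raman(icars, ref_bad, ax))
  plain <- retrieve_raman_uncorrected(icars, ref_bad, ax)
  r_corr <- cor(corrected$raman_like[ci], truth[ci])
  r_plain <- cor(plain[ci], truth[ci])
  expect_gte(r_corr, 0.98)
  expect_lt(r_plain, r_corr)
})

test_that("retrieved peaks scale linearly in the weak-resonance regime", {
  ax <- default_axis(1024)
  ref <- glass_reference(ax)
  exc <- default_excitation(ax)$s_curve
  base_modes <- list(lorentzian_mode(1003, 8, 0.04 * 8),
                     lorentzian_mode(1440, 15, 0.05 * 15))
  peak_heights <- vapply(c(1, 2), function(f) {
    mm <- susceptibility_model(lapply(base_modes, function(m)
      lorentzian_mode(m$center_cm1, m$hwhm_cm1, f * m$amplitude)), 1)
    icars <- Mod(chi3_spectrum(mm, ax))^2 * exc
    res <- suppressWarnings(retrieve_raman(icars, ref, ax))
    res$raman_like[which.min(abs(as.numeric(ax) - 1003))]
  }, numeric(1))
  expect_lt(abs(peak_heights[2] / peak_heights[1] - 2), 0.1)
})

test_that("retrieved spectra are continuous across region boundaries", {
  ax <- default_axis(1024)
  d <- as.numeric(ax)
  ref <- glass_reference(ax)
  m <- susceptibility_model(list(lorentzian_mode(1440, 60, 0.1 * 60),
                                 lorentzian_mode(2934, 80, 0.2 * 80)), 1)
  icars <- Mod(chi3_spectrum(m, ax))^2 * default_excitation(ax)$s_curve
  r <- suppressWarnings(retrieve_raman(icars, ref, ax))$raman_like
  for (b in c(1708, 2745)) {
    i <- which.min(abs(d - b))
    local_var <- median(abs(diff(r[(i - 12):(i + 12)])))
    expect_lt(abs(r[i + 1] - r[i]), 3 * max(local_var, 1e-9) + 1e-9)
  }
})

test_that("whole-image retrieval matches per-pixel ground truth and is deterministic", {
  ax <- default_axis(1024)
  models <- two_class_models()
  ph <- random_phantom(32, 32, c(A = 1, B = 1), models, seed = 17,
                       radius_range = c(4, 5))
  scn <- render_scene(ph, ax, noise = noise_off(seed = 17), jitter_sigma = 0.1)
  ref <- glass_reference(ax)
  ret1 <- retrieve_hsi(scn$image, ref)
  ret2 <- retrieve_hsi(scn$image, ref)
  expect_identical(ret1$cube, ret2$cube)

  ci <- crop_idx(ax)
  flat <- matrix(ret1$cube, 32 * 32, 1024)
  cellpx <- which(scn$mask$labels > 0)
  cors <- vapply(cellpx, function(px) {
    l <- scn$mask$labels[px]
    tr <- if (scn$nucleus[px]) scn$truth_cells[[l]]$nucleus
          else scn$truth_cells[[l]]$cytoplasm
    cor(flat[px, ci], tr[ci])
  }, numeric(1))
  expect_gte(median(cors), 0.99)

  # background-only scene retrieves to (near) zero everywhere
  empty <- scene_phantom(12, 12, list(), models$classes, models$background)
  sc0 <- render_scene(empty, ax, noise = noise_off(seed = 1))
  ret0 <- retrieve_hsi(sc0$image, ref)
  expect_lt(quantile(abs(ret0$cube), 0.99), 1e-6)
})

test_that("retrieval parameter validation catches bad regions and asymmetries", {
  expect_error(retrieval_params(asymmetry_by_region = c(fingerprint = 0,
                                                        silent = 0.01,
                                                        high_wavenumber = 1e-4)),
               "asymmetry")
  expect_error(retrieval_params(region_bounds_cm1 = rbind(fingerprint = c(500, 1700),
                                                          silent = c(1750, 2745),
                                                          high_wavenumber = c(2745, 4554))),
               "contiguous")
  expect_error(retrieve_raman(rep(1, 16), rep(1, 17), tiny_axis(16)), "mismatch")
})
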