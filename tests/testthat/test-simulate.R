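test_that("chi3 spectrum matches hand-evaluated closed forms", {
  ax <- tiny_axis(16)
  expect_equal(chi3_spectrum(susceptibility_model(list(), 1), ax),
               rep(complex(real = 1), 16))
  one <- susceptibility_model(list(lorentzian_mode(1000, 10, 5)), 0)
  expect_equal(chi3_spectrum(one, wavenumber_axis(c(1000, seq(1100, 4000, length.out = 15))))[1],
               complex(imaginary = 0.5))          # on resonance: i A / Gamma
  expect_equal(chi3_spectrum(one, wavenumber_axis(c(990, seq(1100, 4000, length.out = 15))))[1],
               5 / complex(real = 10, imaginary = -10))   # 0.25 + 0.25i
  expect_error(chi3_spectrum(one, numeric(0)), "empty axis")
})

test_that("Im chi3 is nonnegative for nonnegative amplitudes", {
  set.seed(11)
  ax <- small_axis(256)
  for (i in 1:25) {
    m <- random_weak_model(chi_nr = runif(1, 0.2, 2))
    expect_true(all(Im(chi3_spectrum(m, ax)) >= 0))
  }
})

test_that("CARS intensity has the dispersive line shape of coherent mixing", {
  # |chi_nr + A/(Omega - d - iG)|^2 peaks below Omega and dips above it
  fine <- wavenumber_axis(seq(900, 1100, length.out = 2001))
  m <- susceptibility_model(list(lorentzian_mode(1000, 10, 2)), 1)
  exc <- excitation_profile(rep(1, 2001))
  spec <- cars_intensity(chi3_spectrum(m, fine), exc, noise_off())
  expect_lt(as.numeric(fine)[which.max(spec)], 1000)
  expect_gt(as.numeric(fine)[which.min(spec)], 1000)
})

test_that("NRB-only intensity is flat at |chi_nr|^2 S + dark", {
  ax <- tiny_axis(16)
  exc <- excitation_profile(rep(2, 16))
  out <- cars_intensity(chi3_spectrum(susceptibility_model(list(), 3), ax),
                        exc, noise_off(dark_level = 7))
  expect_equal(out, rep(3^2 * 2 + 7, 16))
})

test_that("noise model variance matches expectation + read variance", {
  set.seed(21)
  chi <- complex(real = sqrt(500))      # expectation 500 + dark 100
  exc <- excitation_profile(1)
  ns <- noise_spec(read_sigma = 4, dark_level = 100, shot = TRUE,
                   cosmic_rate_per_image = 0)
  draws <- replicate(10000, cars_intensity(chi, exc, ns))
  expected_var <- 600 + 16
  expect_lt(abs(var(draws) / expected_var - 1), 0.05)
  expect_lt(abs(mean(draws) / 600 - 1), 0.01)
})

test_that("rendered phantoms honour geometry, determinism and ground truth", {
  ax <- small_axis(128)
  models <- two_class_models()
  # zero cells: all pixels at background expectation
  empty <- scene_phantom(16, 16, list(), models$classes, models$background)
  sc0 <- render_scene(empty, ax, noise = noise_off())
  expect_true(all(sc0$mask$labels == 0L))
  bg_expect <- Mod(chi3_spectrum(models$background, ax))^2 *
    default_excitation(ax)$s_curve
  expect_lt(max(abs(sweep(matrix(sc0$image$cube, 256, 128), 2, bg_expect))), 1e-9)

  # five disjoint elliptical cells: per-label areas match analytic rasters
  cells <- lapply(1:5, function(i)
    list(class_name = "A", center = c(8 + 12 * ((i - 1) %% 3), 10 + 20 * ((i - 1) %/% 3)),
         radii = c(5, 4), orientation = i / 3, nucleus_fraction = 0.3))
  ph <- scene_phantom(44, 52, cells, models$classes, models$background)
  sc <- render_scene(ph, ax, noise = noise_off())
  expect_equal(sort(unique(as.vector(sc$mask$labels))), 0:5)
  for (i in 1:5) {
    analytic <- sum(bcars:::.ellipse_mask(44, 52, cells[[i]]$center,
                                          cells[[i]]$radii, cells[[i]]$orientation))
    expect_equal(sum(sc$mask$labels == i), analytic)
  }

  # same seed, noise disabled: bit-identical cubes
  sc_a <- render_scene(ph, ax, noise = noise_off(seed = 5))
  sc_b <- render_scene(ph, ax, noise = noise_off(seed = 5))
  expect_identical(sc_a$image$cube, sc_b$image$cube)

  # overlap rejected at construction
  bad <- c(cells, list(list(class_name = "A", center = cells[[1]]$center + 1,
                            radii = c(5, 4), orientation = 0, nucleus_fraction = 0.3)))
  expect_error(scene_phantom(44, 52, bad, models$classes, models$background),
               "overlap")
})

test_that("cosmic-ray injection follows the configured Poisson rate", {
  ax <- tiny_axis(16)
  models <- two_class_models()
  ph <- scene_phantom(8, 8, list(), models$classes, models$background)
  rate <- 2
  n_inj <- vapply(1:100, function(i) {
    sc <- render_scene(ph, ax, noise = noise_spec(cosmic_rate_per_image = rate,
                                                  seed = i))
    nrow(sc$cosmic_pixels)
  }, numeric(1))
  se <- sqrt(rate / 100)
  expect_lt(abs(mean(n_inj) - rate), 3 * se)
})

test_that("class models differ exactly through the multiplied bands", {
  models <- two_class_models()
  ax <- default_axis(1024)
  diff_truth <- raman_truth(models$classes$B$cytoplasm, ax) -
    raman_truth(models$classes$A$cytoplasm, ax)
  mult <- c("669" = 1.3, "728" = 1.3, "784" = 1.15, "1095" = 1.15, "1575" = 1.15)
  expected <- rep(0, length(ax))
  for (m in models$classes$A$cytoplasm$modes) {
    key <- as.character(m$center_cm1)
    if (key %in% names(mult)) {
      extra <- susceptibility_model(list(lorentzian_mode(
        m$center_cm1, m$hwhm_cm1, (mult[[key]] - 1) * m$amplitude)),
        models$classes$A$cytoplasm$chi_nr)
      expected <- expected + raman_truth(extra, ax)
    }
  }
  expect_lt(max(abs(diff_truth - expected)), 1e-12)
})

test_that("default excitation is dead inside the gap and positive outside", {
  ax <- default_axis(1024)
  exc <- default_excitation(ax)
  d <- as.numeric(ax)
  inside <- d >= exc$gap[1] & d <= exc$gap[2]
  expect_lt(mean(exc$s_curve[inside]), 0.01 * mean(exc$s_curve[!inside]))
  expect_true(all(exc$s_curve >= 0))
  # CH-stretch discriminative bands remain excited
  expect_gt(exc$s_curve[which.min(abs(d - 2934))], 0.1 * max(exc$s_curve))
  expect_gt(exc$s_curve[which.min(abs(d - 3054))], 0.3 * max(exc$s_curve))
})
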