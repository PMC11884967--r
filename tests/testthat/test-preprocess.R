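test_that("dark subtraction clips at zero and is elementwise exact", {
  img <- const_image(4, 4, 16, value = 10, dark = 10)
  expect_true(all(subtract_dark(img)$cube == 0))

  img0 <- const_image(4, 4, 16, value = 7, dark = 0)
  expect_identical(subtract_dark(img0)$cube, img0$cube)

  set.seed(2)
  cube <- array(runif(4 * 4 * 16, 0, 20), c(4, 4, 16))
  dark <- runif(16, 0, 10)
  img2 <- hsi(cube, tiny_axis(16), instrument_meta(dark_spectrum = dark))
  out <- subtract_dark(img2)$cube
  darkcube <- array(rep(dark, each = 16), c(4, 4, 16))
  above <- cube >= darkcube
  expect_equal((out + darkcube)[above], cube[above])
  expect_true(all(out[!above] == 0))
  img2$meta$dark_spectrum <- NULL
  expect_error(subtract_dark(img2), "dark")
})

test_that("despike flags exactly the pixels above threshold and replaces by neighbours", {
  set.seed(5)
  cube <- array(100 + rnorm(8 * 8 * 16), c(8, 8, 16))
  img <- hsi(cube, tiny_axis(16), instrument_meta(dark_spectrum = rep(0, 16)))
  # one interior pixel at 12x the global mean
  img$cube[4, 5, ] <- 12 * mean(rowMeans(matrix(cube, 64, 16)))
  res <- despike(img, threshold_factor = 10)
  expect_equal(unname(res$report$flagged_pixels), matrix(c(4L, 5L), 1, 2))
  nb <- (img$cube[3, 5, ] + img$cube[5, 5, ] + img$cube[4, 4, ] + img$cube[4, 6, ]) / 4
  expect_equal(res$image$cube[4, 5, ], nb)
  # every unflagged pixel passes through bit-identical
  keep <- array(TRUE, dim(cube)); keep[4, 5, ] <- FALSE
  expect_identical(res$image$cube[keep], img$cube[keep])
})

test_that("uniform cubes are untouched and corner spikes use in-frame neighbours", {
  img <- const_image(6, 6, 16, value = 50, dark = 0)
  res <- despike(img)
  expect_equal(nrow(res$report$flagged_pixels), 0)
  expect_identical(res$image$cube, img$cube)

  img$cube[1, 1, ] <- 50 * 15
  res2 <- despike(img)
  expect_equal(unname(res2$report$flagged_pixels), matrix(c(1L, 1L), 1, 2))
  expect_equal(res2$image$cube[1, 1, ],
               (img$cube[2, 1, ] + img$cube[1, 2, ]) / 2)
})

test_that("despiking is idempotent on simulated scenes", {
  ax <- small_axis(128)
  models <- two_class_models()
  for (s in 1:5) {
    ph <- random_phantom(48, 48, c(A = 2, B = 2), models, seed = s,
                         radius_range = c(4, 5))
    sc <- render_scene(ph, ax, noise = noise_spec(cosmic_rate_per_image = 2,
                                                  cosmic_factor = 12, seed = s))
    once <- despike(sc$image)
    twice <- despike(once$image)
    expect_equal(nrow(twice$report$flagged_pixels), 0)
  }
})

test_that("a rank-1 smooth cube survives denoising exactly", {
  h <- 24; w <- 24; k <- 64
  smooth_map <- outer(dnorm(1:h, h / 2, 6), dnorm(1:w, w / 2, 6))
  spec <- 1 + sin(seq(0, 3, length.out = k))^2
  cube <- array(as.vector(smooth_map) %o% spec, c(h, w, k)) * 100
  img <- hsi(cube, tiny_axis(k), instrument_meta())
  res <- svd_denoise(img)
  expect_identical(res$report$kept_indices, 1L)
  expect_lt(max(abs(res$image$cube - cube)), 1e-10 * max(cube))
})

test_that("rank-3 smooth cubes keep exactly components 1:3; white noise keeps none", {
  set.seed(9)
  h <- 32; w <- 32; k <- 96
  maps <- list(outer(dnorm(1:h, 8, 5), dnorm(1:w, 8, 5)),
               outer(dnorm(1:h, 24, 6), dnorm(1:w, 20, 4)),
               outer(sin(seq(0, pi, length.out = h)), cos(seq(0, pi / 2, length.out = w))))
  specs <- list(dnorm(1:k, 20, 4), dnorm(1:k, 50, 8), dnorm(1:k, 75, 3))
  cube <- array(0, c(h, w, k))
  for (i in 1:3) cube <- cube + array(as.vector(maps[[i]]) %o% specs[[i]], c(h, w, k)) * 1e4
  noisy <- cube + array(rnorm(h * w * k, 0, 1e-3 * max(cube)), c(h, w, k))
  res <- svd_denoise(hsi(noisy, tiny_axis(k), instrument_meta()))
  expect_identical(res$report$kept_indices, 1:3)

  pure <- hsi(array(abs(rnorm(h * w * k)), c(h, w, k)), tiny_axis(k), instrument_meta())
  res2 <- svd_denoise(pure)
  # white-noise maps: every score hovers at the disc-area fraction
  expect_length(res2$report$kept_indices, 0)
  expect_false(is.null(res2$report$warning))
  expect_lt(max(res2$report$lowfreq_scores[-1]), 3 * res2$report$area_fraction)
})

test_that("discarded singular energy accounts for the reconstruction error", {
  set.seed(10)
  ax <- small_axis(128)
  ph <- random_phantom(30, 30, c(A = 1, B = 1), two_class_models(), seed = 3,
                       radius_range = c(4, 5))
  sc <- render_scene(ph, ax, noise = noise_spec(cosmic_rate_per_image = 0, seed = 3))
  res <- svd_denoise(sc$image)
  m <- t(matrix(sc$image$cube, 30 * 30, 128))
  sv <- res$report$singular_values
  # energy: sum sigma^2 equals the squared Frobenius norm (no centring)
  expect_equal(sum(sv^2), sum(m^2), tolerance = 1e-9)
  discarded <- setdiff(seq_along(sv), res$report$kept_indices)
  err <- sqrt(sum((sc$image$cube - res$image$cube)^2))
  expect_equal(err, sqrt(sum(sv[discarded]^2)), tolerance = 1e-6)
})

test_that("denoising never lowers the SNR of rendered phantoms", {
  ax <- small_axis(128)
  models <- two_class_models()
  for (s in 1:8) {
    ph <- random_phantom(30, 30, c(A = 1, B = 1), models, seed = s,
                         radius_range = c(4, 5))
    clean <- render_scene(ph, ax, noise = noise_off(dark_level = 0, seed = s))
    noisy <- render_scene(ph, ax, noise = noise_spec(dark_level = 0,
                                                     cosmic_rate_per_image = 0,
                                                     seed = s))
    den <- svd_denoise(noisy$image)
    err_in <- sum((noisy$image$cube - clean$image$cube)^2)
    err_out <- sum((den$image$cube - clean$image$cube)^2)
    expect_lte(err_out, err_in)
  }
})
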