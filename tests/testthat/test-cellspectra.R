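test_that("cell averaging is the exact per-label mean with geometry attached", {
  ax <- tiny_axis(16)
  cube <- array(0, c(4, 4, 16))
  s <- seq_len(16)
  cube[1, 1, ] <- s
  cube[2, 1, ] <- 3 * s                       # two-pixel cell: mean = 2 s
  cube[4, 4, ] <- 7
  labels <- matrix(0L, 4, 4)
  labels[1, 1] <- 1L; labels[2, 1] <- 1L; labels[4, 4] <- 2L
  img <- hsi(cube, ax, instrument_meta(step_um = 2))
  tab <- average_cells(img, label_mask(labels, 0L))
  expect_equal(tab$records[[1]]$values, 2 * s)
  expect_equal(tab$records[[2]]$values, rep(7, 16))
  expect_equal(tab$records[[1]]$area_px, 2)
  expect_equal(tab$records[[2]]$equivalent_diameter_um, 2 * sqrt(1 / pi) * 2)
})

test_that("averaged cells on noiseless phantoms match class ground truth", {
  ax <- default_axis(1024)
  models <- two_class_models()
  ph <- random_phantom(40, 40, c(A = 2, B = 2), models, seed = 51,
                       radius_range = c(4, 5))
  scn <- render_scene(ph, ax, noise = noise_off(seed = 51))
  ret <- retrieve_hsi(scn$image, glass_reference(ax))
  tab <- average_cells(ret, scn$mask,
                       setNames(as.list(scn$cells$class), scn$cells$label))
  ci <- crop_idx(ax)
  for (r in tab$records) {
    # exact simulator expectation of the cell mean: jitter-weighted mix of
    # this cell's own compartment ground-truth spectra over its pixels
    l <- r$mask_label
    px <- which(scn$mask$labels == l)
    w_nuc <- sum(scn$jitter[px][scn$nucleus[px]])
    w_cyt <- sum(scn$jitter[px][!scn$nucleus[px]])
    truth <- (w_cyt * scn$truth_cells[[l]]$cytoplasm +
                w_nuc * scn$truth_cells[[l]]$nucleus) / (w_cyt + w_nuc)
    expect_gte(cor(r$values[ci], truth[ci]), 0.995)
  }
})

test_that("Pearson QC keeps faithful spectra and removes degraded ones", {
  ax <- tiny_axis(64)
  set.seed(52)
  base <- dnorm(1:64, 20, 4) + 0.5 * dnorm(1:64, 45, 6) + 0.01
  ref <- spectrum_record("ref", base, ax)
  # identical record: rho exactly 1, kept
  r_same <- spectrum_record("same", base, ax)
  # white noise: rho ~ 0, removed
  r_noise <- spectrum_record("noise", runif(64), ax)
  # constructed rho just below threshold: removed
  noise <- rnorm(64); noise <- residuals(lm(noise ~ base))
  target <- 0.990
  alpha <- sd(base) / sd(noise) * sqrt(1 / target^2 - 1)
  r_low <- spectrum_record("low", base + alpha * noise, ax)
  expect_equal(cor(r_low$values, base), target, tolerance = 1e-9)
  tab <- cell_spectrum_table(list(r_same, r_noise, r_low))
  out <- qc_filter(tab, ref, rho_min = 0.995)
  expect_equal(vapply(out$kept$records, `[[`, character(1), "id"), "same")
  expect_setequal(vapply(out$removed$records, `[[`, character(1), "id"),
                  c("noise", "low"))
  expect_equal(out$kept$records[[1]]$qc_rho, 1)
  # zero-variance spectrum: undefined correlation, removed and flagged
  flat_tab <- cell_spectrum_table(list(spectrum_record("flat", rep(2, 64), ax)))
  out2 <- qc_filter(flat_tab, ref)
  expect_length(out2$kept$records, 0)
  expect_true(is.na(out2$removed$records[[1]]$qc_rho))
})

test_that("EMSC recovers constructed coefficients and fixes scatter exactly", {
  ax <- tiny_axis(128)
  x <- as.numeric(ax)
  xs <- 2 * (x - min(x)) / (max(x) - min(x)) - 1
  m <- dnorm(1:128, 40, 6) + 0.4 * dnorm(1:128, 90, 10) + 0.05
  # identity
  fit0 <- emsc_correct(m, m, axis = ax)
  expect_equal(fit0$fit$b, 1, tolerance = 1e-9)
  expect_lt(max(abs(fit0$fit$c)), 1e-9)
  expect_lt(max(abs(fit0$corrected - m)), 1e-9)
  # s = 2 m + 0.3 + 0.1 x  -> b = 2, corrected = m
  s <- 2 * m + 0.3 + 0.1 * xs
  fit <- emsc_correct(s, m, axis = ax)
  expect_equal(fit$fit$b, 2, tolerance = 1e-8)
  expect_lt(max(abs(fit$corrected - m)), 1e-8)
  # idempotence and scale invariance
  once <- emsc_correct(s, m, axis = ax)$corrected
  twice <- emsc_correct(once, m, axis = ax)$corrected
  expect_lt(max(abs(twice - once)), 1e-8)
  scaled <- emsc_correct(3.7 * s, m, axis = ax)$corrected
  expect_lt(max(abs(scaled - once)), 1e-8)
  # degree-5 polynomial contamination is removed to numerical precision
  contaminated <- 1.4 * m + 0.2 - 0.3 * xs + 0.15 * xs^3 - 0.05 * xs^5
  fit5 <- emsc_correct(contaminated, m, axis = ax, order = 5)
  expect_equal(fit5$fit$b, 1.4, tolerance = 1e-6)
  expect_lt(max(abs(fit5$corrected - m)), 1e-8)
})

test_that("matrix EMSC agrees with the per-spectrum fit", {
  ax <- tiny_axis(96)
  set.seed(53)
  m <- dnorm(1:96, 30, 5) + 0.02
  x <- t(replicate(4, runif(1, 0.5, 2) * m + rnorm(1, 0, 0.1) +
                      runif(1, -0.1, 0.1) * seq(-1, 1, length.out = 96)))
  mat <- bcars:::.emsc_matrix(x, m, ax, 5L)
  for (i in 1:4) {
    one <- emsc_correct(x[i, ], m, axis = ax)$corrected
    expect_lt(max(abs(mat[i, ] - one)), 1e-9)
  }
})

test_that("crop-normalize restricts to the window and scales to exactly 0..1", {
  ax <- default_axis(1024)
  set.seed(54)
  v <- runif(1024)
  out <- crop_normalize(v, axis = ax)
  expect_equal(min(out), 0)
  expect_equal(max(out), 1)
  expect_length(out, sum(as.numeric(ax) <= 3142))   # all samples are >= 500
  # record already spanning 0..1 on the window is unchanged
  rec <- spectrum_record("r", out, attr(out, "axis"))
  out2 <- crop_normalize(rec, lo = 500, hi = 3142)
  expect_equal(out2$values, as.numeric(out))
  expect_error(crop_normalize(rep(1, 1024), axis = ax), "zero range")
  expect_error(crop_normalize(v, axis = ax, lo = 5000, hi = 6000), "overlap")
})
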