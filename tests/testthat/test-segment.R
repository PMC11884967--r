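test_that("total intensity is the trapezoidal integral over the axis", {
  img <- const_image(4, 4, 16, value = 3)
  span <- max(img$axis) - min(img$axis)
  expect_equal(total_intensity_image(img), matrix(3 * span, 4, 4))

  img$cube[2, 3, ] <- img$cube[2, 3, ] * 10
  ti <- total_intensity_image(img)
  expect_equal(which(ti == max(ti)), 2 + (3 - 1) * 4)

  set.seed(31)
  img2 <- hsi(array(runif(4 * 4 * 16), c(4, 4, 16)), tiny_axis(16), instrument_meta())
  img3 <- img2; img3$cube <- 2 * img2$cube
  expect_equal(total_intensity_image(img3), 2 * total_intensity_image(img2))
})

test_that("fallback segmentation finds disjoint discs with accurate areas", {
  set.seed(32)
  h <- 80; w <- 80
  img <- matrix(rnorm(h * w, 10, 0.5), h, w)
  centers <- list(c(15, 15), c(15, 55), c(40, 35), c(65, 15), c(65, 60))
  r <- 7
  for (cc in centers) {
    mask <- bcars:::.ellipse_mask(h, w, cc, c(r, r), 0)
    img[mask] <- img[mask] + 30
  }
  lm <- segment_cells(img, segmentation_params(min_cell_area_px = 20,
                                               gaussian_sigma_px = 1.5))
  expect_equal(max(lm$labels), 5)
  areas <- tabulate(lm$labels[lm$labels > 0])
  analytic <- sum(bcars:::.ellipse_mask(h, w, centers[[1]], c(r, r), 0))
  expect_true(all(abs(areas - analytic) / analytic <= 0.10))
})

test_that("blank images yield empty masks and touching discs are split", {
  expect_warning(lm0 <- segment_cells(matrix(1, 20, 20)), "no cells|foreground")
  expect_equal(max(lm0$labels), 0)

  h <- 40; w <- 60
  img <- matrix(0, h, w)
  m1 <- bcars:::.ellipse_mask(h, w, c(20, 22), c(8, 8), 0)
  m2 <- bcars:::.ellipse_mask(h, w, c(20, 36), c(8, 8), 0)  # overlap by ~2 px
  img[m1 | m2] <- 10
  lm <- segment_cells(img, segmentation_params(min_cell_area_px = 20,
                                               gaussian_sigma_px = 1))
  expect_equal(max(lm$labels), 2)
})

test_that("segmentation of rendered phantoms overlaps ground truth (IoU >= 0.7)", {
  ax <- small_axis(128)
  models <- two_class_models()
  for (s in 1:3) {
    ph <- random_phantom(64, 64, c(A = 4, B = 4), models, seed = s)
    scn <- render_scene(ph, ax, noise = noise_spec(cosmic_rate_per_image = 0,
                                                   seed = s))
    img <- subtract_dark(scn$image)
    lm <- segment_cells(total_intensity_image(img))
    expect_equal(max(lm$labels), nrow(scn$cells))
    for (l in seq_len(nrow(scn$cells))) {
      truth_px <- scn$mask$labels == l
      seg_label <- as.integer(names(which.max(table(lm$labels[truth_px & lm$labels > 0]))))
      seg_px <- lm$labels == seg_label
      iou <- sum(truth_px & seg_px) / sum(truth_px | seg_px)
      expect_gte(iou, 0.7)
    }
    # labels contain no holes after the fill step
    for (l in seq_len(max(lm$labels))) {
      bin <- lm$labels == l
      expect_equal(sum(EBImage::fillHull(bin)), sum(bin))
    }
  }
})

test_that("background reference averages the largest non-cell region", {
  ax <- small_axis(128)
  models <- two_class_models()
  ph <- random_phantom(48, 48, c(A = 2), models, seed = 41)
  scn <- render_scene(ph, ax, noise = noise_spec(cosmic_rate_per_image = 0, seed = 41))
  img <- subtract_dark(scn$image)
  ref <- background_reference(img, scn$mask)
  expected <- Mod(chi3_spectrum(models$background, ax))^2 * default_excitation(ax)$s_curve
  n <- attr(ref, "n_pixels")
  se <- sqrt((expected + 100) / n) + 3 / sqrt(n)       # shot + read, per channel
  # compare excited channels only: unexcited ones carry the small positive
  # bias of zero-clipped dark-subtracted noise, not background signal
  live <- expected > 50
  expect_true(all(abs(ref - expected)[live] < 6 * se[live] + 1))

  # all-background mask: reference is the global mean spectrum
  allbg <- label_mask(matrix(0L, 48, 48), 0L)
  ref2 <- background_reference(img, allbg)
  expect_equal(as.numeric(ref2),
               colMeans(matrix(img$cube, 48 * 48, 128)))

  # two candidate regions: larger one wins, ties break to the lower id
  labs <- matrix(9L, 8, 8)
  labs[1:8, 1:3] <- 0L      # 24 px background region (left)
  labs[1:4, 6:8] <- 0L      # 12 px background region (right)
  mm <- label_mask(labs, 0L)
  im <- const_image(8, 8, 16, value = 1)
  im$cube[1:8, 1:3, ] <- 5
  ref3 <- background_reference(im, mm)
  expect_equal(as.numeric(ref3), rep(5, 16))
  expect_equal(attr(ref3, "n_pixels"), 24)
})
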