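#' Lorentzian vibrational mode
#'
#' One resonance of the third-order susceptibility:
#' `A / (center - delta - i*hwhm)` as a function of the Raman shift `delta`.
#'
#' @param center_cm1 Band centre (cm^-1).
#' @param hwhm_cm1 Half width at half maximum (cm^-1), > 0.
#' @param amplitude Mode amplitude, >= 0.  The on-resonance imaginary part is
#'   `amplitude / hwhm_cm1`.
#' @return A list of class `"lorentzian_mode"`.
#' @export
lorentzian_mode <- function(center_cm1, hwhm_cm1, amplitude) {
  if (hwhm_cm1 <= 0) stop("hwhm must be positive")
  if (amplitude < 0) stop("amplitude must be nonnegative")
  structure(list(center_cm1 = center_cm1, hwhm_cm1 = hwhm_cm1,
                 amplitude = amplitude), class = "lorentzian_mode")
}

#' Complex third-order susceptibility model
#'
#' chi3(delta) = chi_nr + sum_j A_j / (Omega_j - delta - i Gamma_j): a real
#' nonresonant level plus a sum of complex Lorentzian resonances.
#'
#' @param modes List of [lorentzian_mode()] objects (may be empty).
#' @param chi_nr Nonresonant susceptibility level, >= 0 and finite.
#' @return A list of class `"susceptibility_model"`.
#' @export
susceptibility_model <- function(modes = list(), chi_nr = 1) {
  if (!is.finite(chi_nr) || chi_nr < 0) stop("chi_nr must be finite and nonnegative")
  stopifnot(all(vapply(modes, inherits, logical(1), "lorentzian_mode")))
  structure(list(modes = modes, chi_nr = chi_nr), class = "susceptibility_model")
}

#' Evaluate a susceptibility model on a wavenumber axis
#'
#' @param model [susceptibility_model()].
#' @param axis [wavenumber_axis()] (or plain numeric shifts).
#' @return Complex vector chi3(delta), same length as `axis`.  Its imaginary
#'   part is nonnegative whenever all amplitudes are.
#' @export
chi3_spectrum <- function(model, axis) {
  if (length(axis) == 0L) stop("empty axis")
  delta <- as.numeric(axis)
  chi <- rep(complex(real = model$chi_nr, imaginary = 0), length(delta))
  for (m in model$modes) {
    chi <- chi + m$amplitude / complex(real = m$center_cm1 - delta,
                                       imaginary = -m$hwhm_cm1)
  }
  chi
}

#' Resonant-only imaginary spectrum of a model
#'
#' The Raman-like ground truth Im(chi_res)/chi_nr used by retrieval oracles.
#'
#' @inheritParams chi3_spectrum
#' @return Real vector Im(sum of modes)/chi_nr.
#' @export
raman_truth <- function(model, axis) {
  res <- chi3_spectrum(susceptibility_model(model$modes, chi_nr = 0), axis)
  Im(res) / model$chi_nr
}

#' Laser excitation profile
#'
#' Nonnegative spectral weights S(delta) describing the four-wave-mixing
#' excitation envelope, optionally with a dead window (`gap`) where S is
#' essentially zero (mean inside < 1% of mean outside).
#'
#' @param s_curve Nonnegative weights, length K.
#' @param gap Optional `c(lo, hi)` interval (cm^-1) of the dead window.
#' @param axis Axis the profile is defined on (required when `gap` is set).
#' @return A list of class `"excitation_profile"`.
#' @export
excitation_profile <- function(s_curve, gap = NULL, axis = NULL) {
  s_curve <- as.numeric(s_curve)
  if (any(s_curve < 0) || !all(is.finite(s_curve))) stop("S must be finite and nonnegative")
  if (!is.null(gap)) {
    if (is.null(axis)) stop("axis required to validate the gap")
    inside <- axis >= gap[1] & axis <= gap[2]
    if (any(inside) && mean(s_curve[inside]) >= 0.01 * mean(s_curve[!inside]))
      stop("mean excitation inside the gap must be < 1% of outside")
  }
  structure(list(s_curve = s_curve, gap = gap), class = "excitation_profile")
}

#' Default two-hump excitation profile
#'
#' A smooth envelope with a fingerprint hump and a CH-stretch hump and a
#' raised-cosine dead window over `gap` (by default 2000-3000 cm^-1), scaled
#' to `peak_counts` at its maximum.  This emulates the combined two/three
#' colour excitation of a supercontinuum-driven BCARS system without
#' modelling the pulses.  The default dead window ends at 2800 cm^-1 so the
#' CH-stretch bands near 2934 and 3054 cm^-1 remain excited, consistent with
#' their presence in measured cell spectra.
#'
#' @param axis [wavenumber_axis()].
#' @param gap Dead-window interval (cm^-1).
#' @param peak_counts Peak of S (counts for unit |chi|^2).
#' @return An [excitation_profile()].
#' @export
default_excitation <- function(axis, gap = c(2000, 2800), peak_counts = 2000) {
  d <- as.numeric(axis)
  s <- exp(-((d - 1150) / 650)^2) + 0.8 * exp(-((d - 3100) / 380)^2)
  # raised-cosine gate: 1 outside the gap, ~0 inside, 120 cm^-1 transitions
  w <- 120
  gate <- rep(1, length(d))
  gate[d >= gap[1] & d <= gap[2]] <- 0
  lo_edge <- d > gap[1] - w & d < gap[1]
  gate[lo_edge] <- 0.5 * (1 + cos(pi * (d[lo_edge] - (gap[1] - w)) / w))
  hi_edge <- d > gap[2] & d < gap[2] + w
  gate[hi_edge] <- 0.5 * (1 - cos(pi * (d[hi_edge] - gap[2]) / w))
  s <- s * gate
  s <- s / max(s) * peak_counts
  excitation_profile(s, gap = gap, axis = d)
}

#' Noise specification
#'
#' @param read_sigma Additive zero-mean Gaussian read noise (counts RMS).
#' @param dark_level Dark-current offset (counts).
#' @param shot Apply Poisson counting noise on the expected counts?
#' @param cosmic_rate_per_image Expected number of cosmic-ray pixels per image.
#' @param cosmic_factor Spike strength as a multiple of the global mean
#'   intensity (must exceed the despike threshold factor when testing despike).
#' @param seed Integer seed for the scene's shared pseudorandom stream.
#' @return A list of class `"noise_spec"`.
#' @export
noise_spec <- function(read_sigma = 3, dark_level = 100, shot = TRUE,
                       cosmic_rate_per_image = 0.5, cosmic_factor = 12,
                       seed = 1L) {
  stopifnot(read_sigma >= 0, dark_level >= 0, cosmic_rate_per_image >= 0,
            cosmic_factor >= 0)
  structure(list(read_sigma = read_sigma, dark_level = dark_level,
                 shot = isTRUE(shot),
                 cosmic_rate_per_image = cosmic_rate_per_image,
                 cosmic_factor = cosmic_factor, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Noise disabled, for deterministic renders
#' @inheritParams noise_spec
#' @return A `noise_spec` with shot, read and cosmic noise all off.
#' @export
noise_off <- function(dark_level = 0, seed = 1L) {
  noise_spec(read_sigma = 0, dark_level = dark_level, shot = FALSE,
             cosmic_rate_per_image = 0, seed = seed)
}

#' Expected and noisy CARS intensity for one susceptibility spectrum
#'
#' The noiseless expectation is `|chi|^2 * S + dark_level`; Poisson counting
#' noise is applied to the expectation when `shot` is on, then zero-mean
#' Gaussian read noise is added.  Uses the current R random stream.
#'
#' @param chi Complex susceptibility spectrum, length K.
#' @param excitation [excitation_profile()] with matching length.
#' @param noise [noise_spec()].
#' @return Numeric counts, length K, floored at zero.
#' @export
cars_intensity <- function(chi, excitation, noise = noise_off()) {
  s <- excitation$s_curve
  if (length(chi) != length(s)) stop("chi and excitation lengths must agree")
  expectation <- Mod(chi)^2 * s + noise$dark_level
  out <- if (noise$shot) rpois(length(expectation), expectation) else expectation
  if (noise$read_sigma > 0) out <- out + rnorm(length(out), 0, noise$read_sigma)
  pmax(as.numeric(out), 0)
}

#' Default wavenumber axis of the simulator
#'
#' K uniform samples over 500-4554 cm^-1 (the span of the biological
#' vibrational spectrum covered by a broadband CARS measurement).
#'
#' @param k Number of channels (default 1024, a typical CCD row).
#' @return A [wavenumber_axis()].
#' @export
default_axis <- function(k = 1024L) {
  wavenumber_axis(seq(500, 4554, length.out = k))
}

# Base vibrational bands of a fixed eukaryotic cell: nucleobases (669, 728,
# 784), phenylalanine (1003), PO2 (1095), amide III (1250), CH deformation
# (1320), CH2 scissor (1440), A/G ring (1575), amide I (1655), CH2/CH3
# stretch (2934), =CH stretch (3054).  Amplitudes chosen so peak
# Im(chi_res)/(chi_nr) stays in the weak-resonance regime (<~0.45).
.cell_bands <- function(compartment) {
  b <- data.frame(
    center = c(669, 728, 784, 853, 1003, 1095, 1250, 1320, 1440, 1575, 1655, 2934, 3054),
    hwhm   = c( 10,   8,  10,   9,    5,  15,  25,  15,  15,  12,  20,  40,  20),
    cyto   = c(0.04, 0.05, 0.05, 0.06, 0.10, 0.04, 0.06, 0.07, 0.12, 0.05, 0.10, 0.45, 0.12),
    nuc    = c(0.08, 0.10, 0.12, 0.05, 0.08, 0.10, 0.06, 0.06, 0.10, 0.09, 0.09, 0.35, 0.10))
  b$peak <- if (compartment == "cytoplasm") b$cyto else b$nuc
  b
}

#' Default two-class susceptibility models and discriminative bands
#'
#' Builds per-compartment (cytoplasm, nucleus) susceptibility models for two
#' cell classes that share all bands except amplitude multipliers applied to
#' class B at nucleic-acid-associated shifts: `x1.3` at 669 and 728 cm^-1 and
#' `x1.15` at 784, 1095 and 1575 cm^-1 (user-settable).  The background is
#' glass: no modes, nonresonant only.
#'
#' @param multipliers Named numeric vector: class-B amplitude multiplier per
#'   band centre (names are centres in cm^-1).
#' @param chi_nr_cell Nonresonant level inside cells.
#' @param chi_nr_glass Nonresonant level of the glass substrate.
#' @return List with `classes` (named list; per class a list with `cytoplasm`
#'   and `nucleus` models), `background` model, and `bands` (data.frame with
#'   `center` and `halfwidth` of the discriminative windows).
#' @export
two_class_models <- function(multipliers = c("669" = 1.3, "728" = 1.3,
                                             "784" = 1.15, "1095" = 1.15,
                                             "1575" = 1.15),
                             chi_nr_cell = 1.1, chi_nr_glass = 0.8) {
  build <- function(compartment, mult) {
    b <- .cell_bands(compartment)
    modes <- lapply(seq_len(nrow(b)), function(i) {
      key <- as.character(b$center[i])
      m <- if (key %in% names(mult)) mult[[key]] else 1
      lorentzian_mode(b$center[i], b$hwhm[i],
                      amplitude = m * b$peak[i] * b$hwhm[i] * chi_nr_cell)
    })
    susceptibility_model(modes, chi_nr = chi_nr_cell)
  }
  none <- setNames(numeric(0), character(0))
  ctrs <- as.numeric(names(multipliers))
  hw <- .cell_bands("cytoplasm")
  halfw <- vapply(ctrs, function(cc) {
    g <- hw$hwhm[match(cc, hw$center)]
    if (is.na(g)) 25 else max(25, 2.5 * g)
  }, numeric(1))
  list(classes = list(
         A = list(cytoplasm = build("cytoplasm", none),
                  nucleus = build("nucleus", none)),
         B = list(cytoplasm = build("cytoplasm", multipliers),
                  nucleus = build("nucleus", multipliers))),
       background = susceptibility_model(list(), chi_nr = chi_nr_glass),
       bands = data.frame(center = ctrs, halfwidth = halfw))
}

.ellipse_mask <- function(h, w, center, radii, orientation) {
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  dy <- yy - center[1]; dx <- xx - center[2]
  ct <- cos(orientation); st <- sin(orientation)
  u <- (dx * ct + dy * st) / radii[2]
  v <- (-dx * st + dy * ct) / radii[1]
  u^2 + v^2 <= 1
}

#' Scene phantom: cell layout plus per-class physics
#'
#' @param height,width Frame size in pixels.
#' @param cells List of cell descriptors: each a list with `class_name`,
#'   `center` (c(row, col)), `radii` (c(ry, rx) in px), `orientation`
#'   (radians), `nucleus_fraction` (area fraction of the nuclear ellipse).
#' @param class_models Named list (per class) of lists with `cytoplasm` and
#'   `nucleus` [susceptibility_model()]s.
#' @param background_model Glass [susceptibility_model()] (typically no modes).
#' @return A list of class `"scene_phantom"`.  Cells must lie inside the
#'   frame and must not overlap (checked at construction).
#' @export
scene_phantom <- function(height, width, cells, class_models, background_model) {
  stopifnot(height >= 2, width >= 2, length(class_models) >= 1)
  occupied <- matrix(FALSE, height, width)
  for (cl in cells) {
    stopifnot(cl$class_name %in% names(class_models))
    if (cl$center[1] - cl$radii[1] < 1 || cl$center[1] + cl$radii[1] > height ||
        cl$center[2] - cl$radii[2] < 1 || cl$center[2] + cl$radii[2] > width)
      stop("cell extends outside the frame")
    m <- .ellipse_mask(height, width, cl$center, cl$radii, cl$orientation)
    if (any(m & occupied)) stop("overlapping cells in phantom")
    occupied <- occupied | m
  }
  structure(list(height = height, width = width, cells = cells,
                 class_models = class_models,
                 background_model = background_model),
            class = "scene_phantom")
}

#' Random non-overlapping phantom
#'
#' Places elliptical cells of the requested classes by rejection sampling
#' with a minimum inter-cell gap.  Cell sizes default to immune-cell scale
#' (about 10-14 um diameter at 1 um per pixel).
#'
#' @param height,width Frame size (px).
#' @param class_counts Named integer vector: cells per class.
#' @param models Output of [two_class_models()] (or same structure).
#' @param radius_range Range of ellipse semi-axes (px).
#' @param gap_px Minimum clearance between cells (px).
#' @param nucleus_fraction Nuclear area fraction.
#' @param seed Integer seed.
#' @param max_tries Placement attempts per cell before giving up.
#' @return A [scene_phantom()].
#' @export
random_phantom <- function(height = 96, width = 96,
                           class_counts = c(A = 8, B = 8),
                           models = two_class_models(),
                           radius_range = c(5, 7), gap_px = 3,
                           nucleus_fraction = 0.3, seed = 1L,
                           max_tries = 4000) {
  set.seed(seed)
  cells <- list()
  occupied <- matrix(FALSE, height, width)
  classes <- rep(names(class_counts), class_counts)
  classes <- sample(classes)
  for (cn in classes) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      radii <- sort(runif(2, radius_range[1], radius_range[2]), decreasing = TRUE)
      cy <- runif(1, radii[1] + 1, height - radii[1] - 1)
      cx <- runif(1, radii[2] + 1, width - radii[2] - 1)
      th <- runif(1, 0, pi)
      grown <- .ellipse_mask(height, width, c(cy, cx), radii + gap_px, th)
      if (!any(grown & occupied)) {
        occupied <- occupied | grown
        cells[[length(cells) + 1L]] <- list(class_name = cn, center = c(cy, cx),
                                            radii = radii, orientation = th,
                                            nucleus_fraction = nucleus_fraction)
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("could not place all cells; enlarge the frame or shrink cells")
  }
  scene_phantom(height, width, cells, models$classes, models$background)
}

#' Render a synthetic BCARS scene
#'
#' Draws each pixel's susceptibility from its compartment's model with
#' per-pixel lognormal amplitude jitter (intra-cell heterogeneity), mixes it
#' coherently with the nonresonant background under the excitation envelope,
#' applies shot/read noise, and injects whole-spectrum cosmic-ray spikes.
#' All randomness comes from one stream seeded by `noise$seed`.
#'
#' @param phantom [scene_phantom()].
#' @param axis [wavenumber_axis()].
#' @param excitation [excitation_profile()]; default built from the axis.
#' @param noise [noise_spec()].
#' @param jitter_sigma Lognormal sigma of the per-pixel amplitude jitter
#'   (intra-cell heterogeneity: focus, thickness, local density).
#' @param cell_sigma Lognormal sigma of the per-cell, per-mode amplitude
#'   variability (inter-cell compositional differences: each cell draws its
#'   own concentration factor for every band, shared between its
#'   compartments).  This is what makes two cells of one class genuinely
#'   different spectra rather than scaled copies.  The default 0.02 is
#'   consistent with most cells passing a 0.995 Pearson quality threshold,
#'   as observed for fixed cells of one line.
#' @param nrb_sigma Lognormal sigma of the per-cell nonresonant level: the
#'   NRB differs from cell to cell (thickness, refractive environment), so
#'   the shared glass reference never matches any cell exactly and the
#'   error-corrected retrieval leaves per-cell residuals — as on a real
#'   slide.
#' @param nrb_tilt_sigma Standard deviation of a per-cell linear spectral
#'   tilt of the nonresonant level (electronic background slope).
#' @param meta [instrument_meta()] attached to the image (its dark spectrum
#'   is set to the flat `dark_level` of `noise`).
#' @return List with `image` (`bcars_hsi`), `mask` (ground-truth
#'   `label_mask`), `nucleus` (logical H x W map), `truth` (per-class list of
#'   `cytoplasm`/`nucleus`/`cell` population ground-truth Raman spectra
#'   Im(chi_res)/chi_nr), `truth_cells` (per-cell list with that cell's own
#'   `cytoplasm`/`nucleus` truth including its mode factors), `jitter`
#'   (H x W map, 1 on background), `cosmic_pixels` (matrix of injected
#'   row/col), and `cells` (data.frame of per-cell label, class, area).
#' @export
render_scene <- function(phantom, axis, excitation = NULL,
                         noise = noise_spec(), jitter_sigma = 0.1,
                         cell_sigma = 0.02, nrb_sigma = 0.02,
                         nrb_tilt_sigma = 0.02, meta = NULL) {
  h <- phantom$height; w <- phantom$width; k <- length(axis)
  if (is.null(excitation)) excitation <- default_excitation(axis)
  s <- excitation$s_curve
  if (length(s) != k) stop("excitation length must match axis")
  set.seed(noise$seed)

  # rasterize cells and compartments
  labels <- matrix(0L, h, w)
  nucleus <- matrix(FALSE, h, w)
  cell_rows <- list()
  for (i in seq_along(phantom$cells)) {
    cl <- phantom$cells[[i]]
    m <- .ellipse_mask(h, w, cl$center, cl$radii, cl$orientation)
    nm <- .ellipse_mask(h, w, cl$center, cl$radii * sqrt(cl$nucleus_fraction),
                        cl$orientation)
    labels[m] <- i
    nucleus[m & nm] <- TRUE
    cell_rows[[i]] <- data.frame(label = i, class = cl$class_name, area_px = sum(m))
  }

  # per-cell compositional variability: one lognormal factor per band centre,
  # shared between the cell's compartments (drawn in cell order)
  scale_model <- function(model, factors) {
    susceptibility_model(lapply(model$modes, function(mm) {
      f <- factors[[as.character(mm$center_cm1)]]
      lorentzian_mode(mm$center_cm1, mm$hwhm_cm1,
                      mm$amplitude * (if (is.null(f)) 1 else f))
    }), model$chi_nr)
  }
  cell_models <- vector("list", length(phantom$cells))
  truth_cells <- vector("list", length(phantom$cells))
  x_tilt <- (as.numeric(axis) - mean(range(axis))) / (diff(range(axis)) / 2)
  for (i in seq_along(phantom$cells)) {
    cm <- phantom$class_models[[phantom$cells[[i]]$class_name]]
    centers <- unique(c(vapply(cm$cytoplasm$modes, `[[`, numeric(1), "center_cm1"),
                        vapply(cm$nucleus$modes, `[[`, numeric(1), "center_cm1")))
    factors <- setNames(as.list(rlnorm(length(centers), 0, cell_sigma)),
                        as.character(centers))
    # per-cell NRB: level jitter and a mild linear spectral tilt
    g_i <- rlnorm(1, 0, nrb_sigma)
    t_i <- rnorm(1, 0, nrb_tilt_sigma)
    cyto_i <- scale_model(cm$cytoplasm, factors)
    nuc_i <- scale_model(cm$nucleus, factors)
    nrb_curve <- pmax(g_i * (1 + t_i * x_tilt), 0.1)
    cell_models[[i]] <- list(cytoplasm = cyto_i, nucleus = nuc_i,
                             nrb_profile = cyto_i$chi_nr * nrb_curve)
    truth_cells[[i]] <- list(cytoplasm = raman_truth(cyto_i, axis) / g_i,
                             nucleus = raman_truth(nuc_i, axis) / g_i,
                             factors = unlist(factors),
                             nrb_level = g_i, nrb_tilt = t_i)
  }

  # per-pixel jitter on resonant amplitudes (background fixed at 1)
  jitter <- matrix(1, h, w)
  cellpix <- which(labels > 0)
  if (length(cellpix)) jitter[cellpix] <- rlnorm(length(cellpix), 0, jitter_sigma)

  # expectation cube, channels x pixels, built per (cell, compartment) group
  n <- h * w
  expectation <- matrix(0, k, n)
  fill_group <- function(idx, model, a = model$chi_nr) {
    if (!length(idx)) return()
    res <- chi3_spectrum(susceptibility_model(model$modes, chi_nr = 0), axis)
    j <- jitter[idx]
    expectation[, idx] <<- s * a^2 + outer(s * (2 * a * Re(res)), j) +
      outer(s * (Mod(res)^2), j^2)
  }
  fill_group(which(labels == 0L), phantom$background_model)
  for (i in seq_along(phantom$cells)) {
    fill_group(which(labels == i & !nucleus), cell_models[[i]]$cytoplasm,
               a = cell_models[[i]]$nrb_profile)
    fill_group(which(labels == i & nucleus), cell_models[[i]]$nucleus,
               a = cell_models[[i]]$nrb_profile)
  }
  expectation <- expectation + noise$dark_level

  counts <- if (noise$shot) {
    matrix(rpois(length(expectation), expectation), k, n)
  } else expectation
  if (noise$read_sigma > 0)
    counts <- counts + matrix(rnorm(length(counts), 0, noise$read_sigma), k, n)

  cosmic_pixels <- matrix(integer(0), 0, 2)
  if (noise$cosmic_rate_per_image > 0) {
    n_spike <- rpois(1, noise$cosmic_rate_per_image)
    if (n_spike > 0) {
      px <- sample.int(n, min(n_spike, n))
      gm <- mean(colMeans(counts))
      counts[, px] <- counts[, px] + noise$cosmic_factor * gm
      cosmic_pixels <- cbind(row = ((px - 1L) %% h) + 1L,
                             col = ((px - 1L) %/% h) + 1L)
    }
  }
  counts <- pmax(counts, 0)
  cube <- array(as.numeric(t(counts)), c(h, w, k))

  if (is.null(meta)) meta <- instrument_meta()
  meta$dark_spectrum <- rep(noise$dark_level, k)

  truth <- lapply(phantom$class_models, function(cm) {
    cyto <- raman_truth(cm$cytoplasm, axis)
    nuc <- raman_truth(cm$nucleus, axis)
    f <- if (length(phantom$cells)) phantom$cells[[1]]$nucleus_fraction else 0.3
    list(cytoplasm = cyto, nucleus = nuc, cell = (1 - f) * cyto + f * nuc)
  })

  img <- hsi(cube, axis, meta,
             provenance = list(list(step = "simulate",
                                    params = list(seed = noise$seed,
                                                  jitter_sigma = jitter_sigma,
                                                  cell_sigma = cell_sigma))))
  list(image = img,
       mask = label_mask(labels, 0L),
       nucleus = nucleus,
       truth = truth,
       truth_cells = truth_cells,
       jitter = jitter,
       cosmic_pixels = cosmic_pixels,
       cells = if (length(cell_rows)) do.call(rbind, cell_rows)
               else data.frame(label = integer(0), class = character(0),
                               area_px = integer(0)))
}
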