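# Shared fixtures: everything is generated in code at test time.

tiny_axis <- function(k = 16) wavenumber_axis(seq(500, 4554, length.out = k))

small_axis <- function(k = 512) wavenumber_axis(seq(500, 4554, length.out = k))

# a minimal valid image: h x w x k cube of constant counts
const_image <- function(h = 4, w = 4, k = 16, value = 10, dark = 0) {
  hsi(array(value, c(h, w, k)), tiny_axis(k),
      instrument_meta(dark_spectrum = rep(dark, k)))
}

# weak-resonance model with modes restricted to excited, biologically banded
# regions (fingerprint 600-1655 up to amide I, CH stretch 2950-3120) at
# typical biological band widths (HWHM 5-18 cm^-1); the aggregate resonant
# peak is capped so Im(chi_res)/chi_nr <= 0.2 everywhere
random_weak_model <- function(chi_nr = 1) {
  n <- sample(1:4, 1)
  modes <- lapply(seq_len(n), function(j) {
    ctr <- if (runif(1) < 0.8) runif(1, 600, 1655) else runif(1, 2950, 3120)
    g <- runif(1, 5, 18)
    lorentzian_mode(ctr, g, runif(1, 0.05, 0.2) * g * chi_nr)
  })
  m <- susceptibility_model(modes, chi_nr)
  pk <- max(raman_truth(m, default_axis(1024)))
  if (pk > 0.2) m <- susceptibility_model(lapply(modes, function(mm)
    lorentzian_mode(mm$center_cm1, mm$hwhm_cm1, mm$amplitude * 0.2 / pk)), chi_nr)
  m
}

# glass reference intensity for an axis under the default excitation
glass_reference <- function(axis, chi_nr = 0.8) {
  Mod(chi3_spectrum(susceptibility_model(list(), chi_nr), axis))^2 *
    default_excitation(axis)$s_curve
}

crop_idx <- function(axis, lo = 500, hi = 3142) {
  which(as.numeric(axis) >= lo & as.numeric(axis) <= hi)
}

# independent Monte-Carlo p-value oracle for the chi-square proportion test
mc_chisq_p <- function(observed, ratio, n_sim = 40000, seed = 99) {
  set.seed(seed)
  n <- sum(observed)
  pr <- ratio / sum(ratio)
  e <- pr * n
  stat <- function(o) sum((o - e)^2 / e)
  s_obs <- stat(observed)
  sims <- stats::rmultinom(n_sim, n, pr)
  mean(apply(sims, 2, stat) >= s_obs - 1e-12)
}
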