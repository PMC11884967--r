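#' Fit a pixel-to-wavelength calibration polynomial
#'
#' Least-squares polynomial through located emission-line positions (e.g.
#' from a neon lamp), as used to wavelength-calibrate a spectrograph.
#'
#' @param pixel_positions Detector pixel positions of the lines.
#' @param known_lines_nm Reference wavelengths (nm) of the same lines.
#' @param order Polynomial order (>= 1); needs at least `order + 1` lines.
#' @return List of class `"wavelength_fit"` with `coefficients` (intercept
#'   first), `residual_rms_nm` and `order`.  Use [predict_wavelength()] to
#'   evaluate it.
#' @export
fit_wavelength <- function(pixel_positions, known_lines_nm, order = 2L) {
  order <- as.integer(order)
  if (order < 1L) stop("order must be >= 1")
  if (anyDuplicated(pixel_positions)) stop("duplicate pixel positions")
  if (length(pixel_positions) != length(known_lines_nm))
    stop("positions and wavelengths must have equal length")
  if (length(pixel_positions) < order + 1L)
    stop("underdetermined fit: need at least order + 1 lines")
  X <- outer(as.numeric(pixel_positions), 0:order, `^`)
  fit <- lm.fit(X, as.numeric(known_lines_nm))
  structure(list(coefficients = unname(coef(fit)),
                 residual_rms_nm = sqrt(mean(fit$residuals^2)),
                 order = order),
            class = "wavelength_fit")
}

#' Evaluate a wavelength calibration at pixel positions
#' @param fit A `"wavelength_fit"`.
#' @param pixel_positions Pixels to evaluate at.
#' @return Wavelengths (nm).
#' @export
predict_wavelength <- function(fit, pixel_positions) {
  drop(outer(as.numeric(pixel_positions), 0:fit$order, `^`) %*% fit$coefficients)
}

#' Convert wavelength to Raman shift
#'
#' `10^7 * (1/probe_nm - 1/lambda_nm)` in cm^-1.  Wavelengths below the probe
#' (anti-Stokes detection) give negative shifts; these are allowed but
#' flagged with a warning.
#'
#' @param lambda_nm Detected wavelength (nm), > 0.
#' @param probe_nm Probe wavelength (nm), > 0.
#' @return Raman shift(s) in cm^-1.
#' @export
to_raman_shift <- function(lambda_nm, probe_nm) {
  if (any(lambda_nm <= 0) || any(probe_nm <= 0)) stop("wavelengths must be positive")
  shift <- 1e7 * (1 / probe_nm - 1 / lambda_nm)
  if (any(shift < 0)) warning("negative Raman shift: wavelength below the probe")
  shift
}

#' Inverse of [to_raman_shift()]
#' @param shift_cm1 Raman shift (cm^-1).
#' @param probe_nm Probe wavelength (nm).
#' @return Wavelength (nm).
#' @export
from_raman_shift <- function(shift_cm1, probe_nm) {
  1 / (1 / probe_nm - shift_cm1 / 1e7)
}

#' Diffraction-limited spot size
#'
#' lambda / (2 NA) in nm — e.g. 770 nm at NA 1.2 gives about 321 nm.
#'
#' @param lambda_nm Wavelength (nm).
#' @param na Numerical aperture, > 0.
#' @return Diffraction limit (nm).
#' @export
diffraction_limit_nm <- function(lambda_nm, na) {
  if (any(na <= 0)) stop("NA must be positive")
  lambda_nm / (2 * na)
}
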