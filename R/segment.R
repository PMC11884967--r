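#' Segmentation parameters
#'
#' @param min_cell_area_px Minimum object area kept as a cell (px).
#' @param gaussian_sigma_px Pre-smoothing sigma for the classical fallback.
#' @param method `"fallback"` (classical watershed pipeline) or `"external"`
#'   (shell out to a pluggable segmenter such as Cellpose).
#' @param external_command Command template for the external method;
#'   `{input}` and `{output}` are replaced by an intensity TIFF path and the
#'   expected label-TIFF path.
#' @return List of class `"segmentation_params"`.
#' @export
segmentation_params <- function(min_cell_area_px = 20, gaussian_sigma_px = 1.5,
                                method = c("fallback", "external"),
                                external_command = NULL) {
  if (min_cell_area_px < 1) stop("min_cell_area_px must be >= 1")
  method <- match.arg(method)
  if (method == "external" && is.null(external_command))
    stop("external method needs a command template")
  structure(list(min_cell_area_px = min_cell_area_px,
                 gaussian_sigma_px = gaussian_sigma_px,
                 method = method, external_command = external_command),
            class = "segmentation_params")
}

#' Total-intensity image of a hyperspectral cube
#'
#' Trapezoidal integral of each pixel's spectrum over the wavenumber axis.
#'
#' @param image `bcars_hsi`.
#' @return H x W numeric matrix.
#' @export
total_intensity_image <- function(image) {
  ax <- as.numeric(image$axis)
  k <- length(ax)
  wts <- c(diff(ax)[1] / 2,
           (ax[3:k] - ax[1:(k - 2)]) / 2,
           diff(ax)[k - 1] / 2)
  d <- dim(image$cube)
  matrix(matrix(image$cube, d[1] * d[2], k) %*% wts, d[1], d[2])
}

#' Segment cells in a total-intensity image
#'
#' Classical fallback: Gaussian smooth, Otsu threshold, fill holes, remove
#' objects below the minimum area, then split touching objects by watershed
#' on the distance transform.  Labels run 1..N; everything else is
#' background (label 0).  An external segmenter can be plugged in via
#' `params$method = "external"`.
#'
#' @param intensity H x W numeric image.
#' @param params [segmentation_params()].
#' @return A [label_mask()].  An empty foreground yields a zero-label mask
#'   with a warning.
#' @export
segment_cells <- function(intensity, params = segmentation_params()) {
  if (!all(is.finite(intensity))) stop("intensity image must be finite")
  if (params$method == "external") return(.segment_external(intensity, params))
  rng <- range(intensity)
  if (rng[2] <= rng[1]) {
    warning("constant intensity image: no cells found")
    return(label_mask(matrix(0L, nrow(intensity), ncol(intensity)), 0L))
  }
  img <- (intensity - rng[1]) / (rng[2] - rng[1])
  sm <- EBImage::gblur(img, sigma = params$gaussian_sigma_px)
  thr <- EBImage::otsu(EBImage::Image(sm), range = range(sm))
  fg <- sm > thr
  if (!any(fg)) {
    warning("empty foreground after thresholding")
    return(label_mask(matrix(0L, nrow(intensity), ncol(intensity)), 0L))
  }
  fg <- EBImage::fillHull(fg)
  lab <- EBImage::watershed(EBImage::distmap(fg), tolerance = 1, ext = 1)
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(intensity), ncol(intensity))
  # drop small objects, relabel 1..N in order of first appearance
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= params$min_cell_area_px)
  relab <- integer(length(sizes))
  relab[keep] <- seq_along(keep)
  lab[lab > 0L] <- relab[lab[lab > 0L]]
  if (!any(lab > 0L)) warning("no object above the minimum cell area")
  label_mask(lab, 0L)
}

.segment_external <- function(intensity, params) {
  tin <- tempfile(fileext = ".tif"); tout <- tempfile(fileext = ".tif")
  rng <- range(intensity)
  sc <- if (rng[2] > rng[1]) (intensity - rng[1]) / (rng[2] - rng[1]) else intensity * 0
  tiff::writeTIFF(sc, tin, bits.per.sample = 16L)
  cmd <- gsub("{input}", tin, params$external_command, fixed = TRUE)
  cmd <- gsub("{output}", tout, cmd, fixed = TRUE)
  status <- system(cmd)
  if (status != 0L || !file.exists(tout)) stop("external segmenter failed")
  lab <- round(tiff::readTIFF(tout, as.is = TRUE))
  label_mask(matrix(as.integer(lab), nrow(lab), ncol(lab)), 0L)
}

#' Nonresonant-background reference spectrum from the segmented background
#'
#' Averages the raw (dark-subtracted, denoised) spectra over the
#' largest-area connected region that is not labelled as a cell — in a
#' typical scene, the glass coverslip.  Ties between equally large regions
#' break toward the lower region id.
#'
#' @param raw_image `bcars_hsi` the reference is taken from.
#' @param mask [label_mask()] on the same grid.
#' @return Numeric reference spectrum with attribute `n_pixels`.
#' @export
background_reference <- function(raw_image, mask) {
  d <- dim(raw_image$cube)
  if (any(dim(mask$labels) != d[1:2])) stop("mask grid does not match image")
  bg <- mask$labels == mask$background_label
  if (!any(bg)) stop("background region empty")
  comp <- matrix(as.integer(EBImage::imageData(EBImage::bwlabel(bg))), d[1], d[2])
  sizes <- tabulate(comp[comp > 0L])
  pick <- which.max(sizes)            # ties -> lowest id (which.max is first)
  sel <- which(comp == pick)
  flat <- matrix(raw_image$cube, d[1] * d[2], d[3])
  out <- colMeans(flat[sel, , drop = FALSE])
  attr(out, "n_pixels") <- length(sel)
  out
}
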