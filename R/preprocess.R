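#' Subtract the dark-current spectrum
#'
#' Removes the instrument dark spectrum from every pixel, clipping at zero.
#'
#' @param image `bcars_hsi` whose metadata carries a dark spectrum.
#' @return The dark-subtracted image with provenance appended.
#' @export
subtract_dark <- function(image) {
  dark <- image$meta$dark_spectrum
  if (is.null(dark)) stop("no dark spectrum in metadata")
  d <- dim(image$cube)
  image$cube <- pmax(image$cube - rep(dark, each = d[1] * d[2]), 0)
  add_provenance(image, "subtract_dark")
}

#' Remove cosmic-ray pixels by mean-intensity thresholding
#'
#' A pixel is flagged when its spectral mean exceeds `threshold_factor`
#' times the global average of pixel spectral means, and its whole spectrum
#' is replaced by the mean of its four nearest in-frame neighbours
#' (unflagged neighbours when available).  Unflagged pixels pass through
#' bit-identical.
#'
#' @param image `bcars_hsi` with H, W >= 2.
#' @param threshold_factor Detection threshold (default 10).
#' @return List with `image` (despiked) and `report` (flagged pixel
#'   coordinates, threshold, replacement method).
#' @export
despike <- function(image, threshold_factor = 10) {
  if (threshold_factor <= 1) stop("threshold factor must exceed 1")
  d <- dim(image$cube)
  h <- d[1]; w <- d[2]; k <- d[3]
  if (h < 2 || w < 2) stop("image too small to despike")
  flat <- matrix(image$cube, h * w, k)        # pixels x channels
  px_mean <- rowMeans(flat)
  flagged <- which(px_mean > threshold_factor * mean(px_mean))
  if (length(flagged) == h * w) stop("all pixels flagged: degenerate image")
  coords <- cbind(row = ((flagged - 1L) %% h) + 1L,
                  col = ((flagged - 1L) %/% h) + 1L)
  is_flagged <- logical(h * w)
  is_flagged[flagged] <- TRUE
  for (i in seq_along(flagged)) {
    r <- coords[i, 1]; cc <- coords[i, 2]
    nb <- rbind(c(r - 1, cc), c(r + 1, cc), c(r, cc - 1), c(r, cc + 1))
    nb <- nb[nb[, 1] >= 1 & nb[, 1] <= h & nb[, 2] >= 1 & nb[, 2] <= w, , drop = FALSE]
    nb_idx <- (nb[, 2] - 1L) * h + nb[, 1]
    good <- nb_idx[!is_flagged[nb_idx]]
    if (!length(good)) good <- nb_idx
    flat[flagged[i], ] <- colMeans(flat[good, , drop = FALSE])
  }
  image$cube <- array(flat, d)
  image <- add_provenance(image, "despike",
                          list(threshold_factor = threshold_factor,
                               n_flagged = length(flagged)))
  list(image = image,
       report = list(flagged_pixels = coords,
                     threshold_factor = threshold_factor,
                     replacement = "mean of 4 nearest in-frame neighbours"))
}

# Economy SVD of a K x N matrix with K << N via the K x K Gram matrix:
# eigen(M M') gives the left vectors and squared singular values; only the
# first nc right vectors are formed.  Much cheaper than a full SVD when only
# the leading components are inspected; all K singular values are returned
# so the energy accounting sum(sigma^2) = ||M||_F^2 stays exact.
.econ_svd <- function(m, nc) {
  gram <- tcrossprod(m)
  eig <- eigen(gram, symmetric = TRUE)
  d <- sqrt(pmax(eig$values, 0))
  u <- eig$vectors
  v <- crossprod(m, u[, seq_len(nc), drop = FALSE])
  for (i in seq_len(nc)) {
    if (d[i] > 0) v[, i] <- v[, i] / d[i]
  }
  list(d = d, u = u, v = v)
}

# low-frequency disc energy fraction of a mean-removed spatial map
.lowfreq_score <- function(map, radius) {
  h <- nrow(map); w <- ncol(map)
  f <- fft(map - mean(map))
  power <- Mod(f)^2
  fy <- pmin(0:(h - 1), h - (0:(h - 1)))
  fx <- pmin(0:(w - 1), w - (0:(w - 1)))
  d2 <- outer(fy^2, fx^2, `+`)
  inside <- d2 <= radius^2
  tot <- sum(power)
  if (tot == 0) return(list(score = 0, area_fraction = mean(inside)))
  list(score = sum(power[inside]) / tot, area_fraction = mean(inside))
}

#' Truncated-SVD denoising with Fourier singular-vector selection
#'
#' Unfolds the cube to a channels x pixels matrix and computes its SVD (no
#' mean centring, so the background component stays explicit).  Each spatial
#' (right) singular vector is reshaped to the image grid, mean-removed and
#' 2D-Fourier transformed; a component is kept when the fraction of its
#' spectral energy inside the centred low-frequency disc of radius
#' `lf_radius_fraction * min(H, W)` exceeds `score_multiplier` times the
#' disc's area fraction — i.e. when the map has genuine smooth spatial
#' structure rather than white noise.  The cube is reconstructed from the
#' kept components only.
#'
#' @param image `bcars_hsi`.
#' @param max_components Number of leading components evaluated.
#' @param lf_radius_fraction Disc radius as a fraction of `min(H, W)`.
#' @param score_multiplier Keep threshold as a multiple of the disc's area
#'   fraction.
#' @return List with `image` (denoised) and `report` (singular values,
#'   kept indices, per-component low-frequency scores, parameters, and a
#'   `warning` record when nothing was kept).
#' @export
svd_denoise <- function(image, max_components = 50, lf_radius_fraction = 1 / 8,
                        score_multiplier = 3) {
  d <- dim(image$cube)
  h <- d[1]; w <- d[2]; k <- d[3]
  m <- t(matrix(image$cube, h * w, k))        # channels x pixels
  nc <- min(max_components, k, h * w)
  sv <- .econ_svd(m, nc)
  # deterministic sign: largest-|.| element of each spectral vector positive
  for (i in seq_len(nc)) {
    s <- sign(sv$u[which.max(abs(sv$u[, i])), i])
    if (s < 0) { sv$u[, i] <- -sv$u[, i]; sv$v[, i] <- -sv$v[, i] }
  }
  radius <- lf_radius_fraction * min(h, w)
  # components with numerically zero singular value carry no energy and
  # their right vectors are unstable (0/0); they are never kept
  eligible <- sv$d[seq_len(nc)] > 1e-6 * sv$d[1]
  scores <- numeric(nc); area_fraction <- NA_real_
  for (i in seq_len(nc)) {
    if (!eligible[i]) next
    sc <- .lowfreq_score(matrix(sv$v[, i], h, w), radius)
    scores[i] <- sc$score
    area_fraction <- sc$area_fraction
  }
  kept <- which(scores > score_multiplier * area_fraction & eligible)
  warning_rec <- NULL
  if (length(kept)) {
    recon <- sv$u[, kept, drop = FALSE] %*%
      (sv$d[kept] * t(sv$v[, kept, drop = FALSE]))
  } else {
    recon <- matrix(0, k, h * w)
    warning_rec <- "no singular vectors passed the low-frequency criterion"
  }
  image$cube <- array(t(recon), d)
  image <- add_provenance(image, "svd_denoise",
                          list(max_components = max_components,
                               lf_radius_fraction = lf_radius_fraction,
                               score_multiplier = score_multiplier,
                               kept = kept))
  list(image = image,
       report = list(singular_values = sv$d, kept_indices = kept,
                     lowfreq_scores = scores, area_fraction = area_fraction,
                     params = list(max_components = max_components,
                                   lf_radius_fraction = lf_radius_fraction,
                                   score_multiplier = score_multiplier),
                     warning = warning_rec))
}
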