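#' Cell spectrum table
#'
#' A list of per-cell [spectrum_record()]s sharing one axis, with per-cell
#' area, equivalent diameter and source-image id attached to each record.
#'
#' @param records List of `spectrum_record` objects.
#' @return Object of class `"cell_spectrum_table"`.
#' @export
cell_spectrum_table <- function(records) {
  stopifnot(all(vapply(records, inherits, logical(1), "spectrum_record")))
  if (length(records) > 1L) {
    ax <- records[[1]]$axis
    for (r in records[-1])
      if (length(r$axis) != length(ax) || max(abs(r$axis - ax)) > 1e-9)
        stop("records must share one axis")
  }
  structure(list(records = records), class = "cell_spectrum_table")
}

#' @export
length.cell_spectrum_table <- function(x) length(x$records)

#' @export
print.cell_spectrum_table <- function(x, ...) {
  labs <- table(vapply(x$records, function(r) as.character(r$class_label), character(1)),
                useNA = "ifany")
  cat(sprintf("<cell_spectrum_table> %d cells (%s)\n", length(x$records),
              paste(names(labs), labs, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Spectra matrix and labels of a table
#' @param table `cell_spectrum_table`.
#' @return List with `x` (cells x channels matrix), `labels` (character),
#'   `ids`, `axis`.
#' @export
table_matrix <- function(table) {
  recs <- table$records
  if (!length(recs)) stop("empty table")
  list(x = do.call(rbind, lapply(recs, `[[`, "values")),
       labels = vapply(recs, function(r) as.character(r$class_label), character(1)),
       ids = vapply(recs, `[[`, character(1), "id"),
       axis = recs[[1]]$axis)
}

#' Average retrieved spectra over each segmented cell
#'
#' One mean spectrum per mask label, with area (px) and equivalent diameter
#' (`2 sqrt(area/pi) * step_um`) attached.
#'
#' @param retrieved Retrieved `bcars_hsi`.
#' @param mask [label_mask()] on the image grid.
#' @param class_labels Optional vector: class label per mask label.
#' @param source_image Identifier recorded on each record.
#' @return A [cell_spectrum_table()].
#' @export
average_cells <- function(retrieved, mask, class_labels = NULL,
                          source_image = "scene") {
  d <- dim(retrieved$cube)
  if (any(dim(mask$labels) != d[1:2])) stop("mask grid does not match image")
  labs <- sort(unique(mask$labels[mask$labels != mask$background_label]))
  flat <- matrix(retrieved$cube, d[1] * d[2], d[3])
  step_um <- retrieved$meta$step_um
  recs <- lapply(labs, function(l) {
    px <- which(mask$labels == l)
    if (!length(px)) stop("label with zero pixels")
    spectrum_record(sprintf("%s_cell_%03d", source_image, l),
                    colMeans(flat[px, , drop = FALSE]),
                    retrieved$axis,
                    class_label = if (is.null(class_labels)) NA_character_
                                  else as.character(class_labels[[as.character(l)]]),
                    area_px = length(px),
                    equivalent_diameter_um = 2 * sqrt(length(px) / pi) * step_um,
                    source_image = source_image,
                    mask_label = l)
  })
  cell_spectrum_table(recs)
}

#' Pick the default QC reference record
#'
#' The record with the highest spectral mean intensity — a proxy for the
#' highest-SNR cell in the dataset.
#'
#' @param table `cell_spectrum_table`.
#' @return A `spectrum_record`.
#' @export
qc_reference <- function(table) {
  means <- vapply(table$records, function(r) mean(r$values), numeric(1))
  table$records[[which.max(means)]]
}

#' Pearson quality-control filter
#'
#' Keeps a cell when its Pearson correlation with the reference spectrum is
#' at least `rho_min`; the correlation is stored on every record.  A
#' zero-variance spectrum has undefined correlation and is removed.
#'
#' @param table `cell_spectrum_table`.
#' @param reference A `spectrum_record` on the same axis.
#' @param rho_min Threshold (default 0.995).
#' @param window Optional `c(lo, hi)` shift window (cm^-1) the correlation
#'   is evaluated on.  The pipeline uses the analysis window (500-3142) so
#'   unexcited tail channels, which carry no information, cannot dominate
#'   the QC decision; `NULL` uses the full axis.
#' @return List with `kept` and `removed` tables.
#' @export
qc_filter <- function(table, reference = qc_reference(table), rho_min = 0.995,
                      window = NULL) {
  if (length(reference$values) != length(table$records[[1]]$values))
    stop("reference axis mismatch")
  sel <- if (is.null(window)) seq_along(reference$values)
         else which(as.numeric(reference$axis) >= window[1] &
                      as.numeric(reference$axis) <= window[2])
  if (!length(sel)) stop("QC window does not overlap the axis")
  keep <- logical(length(table$records))
  for (i in seq_along(table$records)) {
    v <- table$records[[i]]$values[sel]
    rho <- if (sd(v) == 0 || sd(reference$values[sel]) == 0) NA_real_
           else cor(v, reference$values[sel])
    table$records[[i]]$qc_rho <- rho
    keep[i] <- !is.na(rho) && rho >= rho_min
  }
  list(kept = cell_spectrum_table(table$records[keep]),
       removed = cell_spectrum_table(table$records[!keep]))
}

#' Extended multiplicative signal correction of one spectrum
#'
#' Least-squares fit `s = b * m + sum_k c_k P_k(x)` with `P_k` orthogonal
#' polynomials of degree 0..`order` on the axis rescaled to -1..1, then
#' `corrected = (s - sum_k c_k P_k) / b`.  Removes multiplicative scatter
#' and smooth additive baseline differences between spectra.
#'
#' @param values Numeric spectrum (or a `spectrum_record`).
#' @param mean_reference Reference spectrum `m`, same length.
#' @param axis [wavenumber_axis()] (taken from the record if given one).
#' @param order Polynomial order (default 5).
#' @return List with `corrected` (numeric or updated record) and `fit`
#'   (`b`, `c`, `residual_rms`).  Errors when `|b| < 1e-6`.
#' @export
emsc_correct <- function(values, mean_reference, axis = NULL, order = 5L) {
  rec <- NULL
  if (inherits(values, "spectrum_record")) {
    rec <- values; axis <- rec$axis; values <- rec$values
  }
  if (length(values) != length(mean_reference)) stop("reference length mismatch")
  if (order < 0) stop("order must be >= 0")
  x <- as.numeric(axis)
  x <- 2 * (x - min(x)) / (max(x) - min(x)) - 1
  P <- cbind(1, if (order >= 1) stats::poly(x, degree = order) else NULL)
  X <- cbind(m = mean_reference, P)
  fit <- lm.fit(X, values)
  b <- unname(coef(fit)[1])
  if (!is.finite(b) || abs(b) < 1e-6) stop("degenerate spectrum: EMSC b ~ 0")
  cc <- unname(coef(fit)[-1])
  poly_part <- drop(P %*% cc)
  corrected <- (values - poly_part) / b
  out_fit <- list(b = b, c = cc, residual_rms = sqrt(mean(fit$residuals^2)))
  if (!is.null(rec)) {
    rec$values <- corrected
    return(list(corrected = rec, fit = out_fit))
  }
  list(corrected = corrected, fit = out_fit)
}

# EMSC over the rows of a spectra matrix: one QR factorization of the
# shared design serves every spectrum.
.emsc_matrix <- function(x, mean_reference, axis, order = 5L) {
  t_ax <- as.numeric(axis)
  t_ax <- 2 * (t_ax - min(t_ax)) / (max(t_ax) - min(t_ax)) - 1
  P <- cbind(1, if (order >= 1) stats::poly(t_ax, degree = order) else NULL)
  X <- cbind(m = mean_reference, P)
  qrX <- qr(X)
  cf <- qr.coef(qrX, t(x))                     # (order + 2) x n
  b <- cf[1, ]
  if (any(!is.finite(b)) || any(abs(b) < 1e-6))
    stop("degenerate spectrum: EMSC b ~ 0")
  poly_part <- P %*% cf[-1, , drop = FALSE]    # K x n
  t((t(x) - poly_part) / rep(b, each = nrow(P)))
}

#' EMSC-correct every record of a table against a mean reference
#'
#' @param table `cell_spectrum_table`.
#' @param mean_reference Reference spectrum; defaults to the mean of all
#'   records in the table (cache it to reuse on unlabelled runs).
#' @param order Polynomial order.
#' @return List with `table` (corrected) and `mean_reference` (as used).
#' @export
emsc_table <- function(table, mean_reference = NULL, order = 5L) {
  tm <- table_matrix(table)
  if (is.null(mean_reference)) mean_reference <- colMeans(tm$x)
  corrected <- .emsc_matrix(tm$x, mean_reference, tm$axis, order)
  recs <- table$records
  for (i in seq_along(recs)) recs[[i]]$values <- corrected[i, ]
  list(table = cell_spectrum_table(recs), mean_reference = mean_reference)
}

#' Crop a spectrum to a shift window and min-max normalize
#'
#' Restricts to the channels whose shifts lie in the closed interval
#' `lo..hi`, then rescales to min 0 and max 1.
#'
#' @param values Numeric spectrum or a `spectrum_record`.
#' @param axis Axis (taken from the record if given one).
#' @param lo,hi Window bounds (cm^-1), default 500-3142.
#' @return Cropped, normalized spectrum (numeric with attribute `axis`, or
#'   an updated record).  Errors on a constant (zero-range) spectrum.
#' @export
crop_normalize <- function(values, axis = NULL, lo = 500, hi = 3142) {
  rec <- NULL
  if (inherits(values, "spectrum_record")) {
    rec <- values; axis <- rec$axis; values <- rec$values
  }
  idx <- which(axis >= lo & axis <= hi)
  if (!length(idx)) stop("crop window does not overlap the axis")
  v <- values[idx]
  rng <- range(v)
  if (rng[2] <= rng[1]) stop("constant spectrum: zero range")
  v <- (v - rng[1]) / (rng[2] - rng[1])
  new_axis <- wavenumber_axis(as.numeric(axis)[idx])
  if (!is.null(rec)) {
    rec$values <- v; rec$axis <- new_axis
    return(rec)
  }
  structure(v, axis = new_axis)
}

#' Crop and normalize every record in a table
#' @inheritParams crop_normalize
#' @param table `cell_spectrum_table`.
#' @return A cropped, normalized `cell_spectrum_table`.
#' @export
crop_normalize_table <- function(table, lo = 500, hi = 3142) {
  cell_spectrum_table(lapply(table$records, crop_normalize, lo = lo, hi = hi))
}
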