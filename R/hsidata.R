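#' Wavenumber axis
#'
#' A calibrated Raman-shift axis in cm^-1.  The axis must be strictly
#' increasing, finite, and hold at least 16 channels.
#'
#' @param shifts Numeric vector of Raman shifts (cm^-1).
#' @return A numeric vector of class `"wn_axis"`.
#' @export
wavenumber_axis <- function(shifts) {
  shifts <- as.numeric(shifts)
  if (length(shifts) < 16L) stop("wavenumber axis needs at least 16 channels")
  if (!all(is.finite(shifts))) stop("wavenumber axis must be finite")
  if (any(diff(shifts) <= 0)) stop("wavenumber axis must be strictly increasing")
  structure(shifts, class = "wn_axis")
}

#' Instrument metadata
#'
#' @param probe_wavelength_nm Narrowband probe wavelength (nm).
#' @param objective_na Numerical aperture of the excitation objective.
#' @param pixel_dwell_s Pixel dwell time (s).
#' @param step_um Raster step size (micrometres per pixel).
#' @param dark_spectrum Dark-current spectrum (counts), length K, or NULL.
#' @return A list of class `"instrument_meta"`.
#' @export
instrument_meta <- function(probe_wavelength_nm = 770, objective_na = 1.2,
                            pixel_dwell_s = 0.005, step_um = 1,
                            dark_spectrum = NULL) {
  if (probe_wavelength_nm <= 0) stop("probe wavelength must be positive")
  if (objective_na <= 0 || objective_na > 1.5) stop("objective NA must be in (0, 1.5]")
  if (pixel_dwell_s <= 0) stop("pixel dwell must be positive")
  structure(list(probe_wavelength_nm = probe_wavelength_nm,
                 objective_na = objective_na,
                 pixel_dwell_s = pixel_dwell_s,
                 step_um = step_um,
                 dark_spectrum = if (is.null(dark_spectrum)) NULL else as.numeric(dark_spectrum)),
            class = "instrument_meta")
}

#' Hyperspectral image container
#'
#' Bundles an H x W x K cube of counts with its wavenumber axis, instrument
#' metadata, and an append-only provenance record of processing steps.
#'
#' @param cube Numeric H x W x K array of nonnegative finite counts.
#' @param axis [wavenumber_axis()] of length K.
#' @param meta [instrument_meta()].
#' @param provenance List of processing-step records (appended by each stage).
#' @return An object of class `"bcars_hsi"`.
#' @export
hsi <- function(cube, axis, meta = instrument_meta(), provenance = list()) {
  if (length(dim(cube)) != 3L) stop("cube must be a 3D array")
  if (!all(is.finite(cube))) stop("cube must be finite")
  if (dim(cube)[3] != length(axis)) stop("axis length must match cube channels")
  if (!is.null(meta$dark_spectrum) && length(meta$dark_spectrum) != length(axis))
    stop("dark spectrum length must match axis")
  structure(list(cube = cube, axis = axis, meta = meta, provenance = provenance),
            class = "bcars_hsi")
}

#' @export
print.bcars_hsi <- function(x, ...) {
  d <- dim(x$cube)
  cat(sprintf("<bcars_hsi> %d x %d px, %d channels (%.0f-%.0f cm^-1), %d processing steps\n",
              d[1], d[2], d[3], min(x$axis), max(x$axis), length(x$provenance)))
  invisible(x)
}

#' Append a provenance record to an image
#'
#' @param x A `bcars_hsi`.
#' @param step Character step name.
#' @param params Named list of the step's parameters.
#' @return The image with one more provenance record.
#' @export
add_provenance <- function(x, step, params = list()) {
  x$provenance <- c(x$provenance, list(list(step = step, params = params)))
  x
}

#' Cell label mask
#'
#' Integer image on the cube's grid: 0 marks background candidates, 1..N
#' individual cells.
#'
#' @param labels Integer H x W matrix of nonnegative labels.
#' @param background_label Integer label treated as background (default 0).
#' @return An object of class `"label_mask"`.
#' @export
label_mask <- function(labels, background_label = 0L) {
  labels <- matrix(as.integer(round(labels)), nrow(labels), ncol(labels))
  if (any(labels < 0L)) stop("labels must be nonnegative")
  if (!any(labels == background_label)) stop("background label absent from mask")
  structure(list(labels = labels, background_label = as.integer(background_label)),
            class = "label_mask")
}

#' Single-spectrum record
#'
#' @param id Character identifier.
#' @param values Numeric spectrum, same length as `axis`.
#' @param axis [wavenumber_axis()].
#' @param class_label Optional class label.
#' @param qc_rho Optional Pearson QC correlation between -1 and 1.
#' @param ... Extra scalar fields (e.g. `area_px`, `equivalent_diameter_um`,
#'   `source_image`).
#' @return An object of class `"spectrum_record"`.
#' @export
spectrum_record <- function(id, values, axis, class_label = NA_character_,
                            qc_rho = NA_real_, ...) {
  values <- as.numeric(values)
  if (!all(is.finite(values))) stop("spectrum values must be finite")
  if (length(values) != length(axis)) stop("spectrum length must match axis")
  if (!is.na(qc_rho) && (qc_rho < -1 || qc_rho > 1)) stop("qc_rho must be in [-1, 1]")
  structure(c(list(id = as.character(id), values = values, axis = axis,
                   class_label = class_label, qc_rho = qc_rho), list(...)),
            class = "spectrum_record")
}

.write_bin <- function(x, path, what) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(x), con, size = if (what == "double") 8L else 4L,
           endian = "little")
}

.read_bin <- function(path, what, n) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, what = what, n = n,
          size = if (what == "double") 8L else 4L, endian = "little")
}

#' Write a scene container
#'
#' Writes an image (and optionally label masks) to a directory container:
#' `cube.bin` (float64, column-major H x W x K), `masks/<name>.bin` (int32),
#' and `manifest.json` holding dimensions, axis, instrument metadata and
#' provenance.  The round trip through [read_scene()] is bit-exact for the
#' cube, axis and labels.
#'
#' @param image A `bcars_hsi`.
#' @param path Directory to create/overwrite.
#' @param masks Optional named list of `label_mask` objects.
#' @return `path`, invisibly.
#' @export
write_scene <- function(image, path, masks = NULL) {
  stopifnot(inherits(image, "bcars_hsi"))
  if (!all(is.finite(image$cube))) stop("refusing to write non-finite cube")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  .write_bin(image$cube, file.path(path, "cube.bin"), "double")
  .write_bin(as.numeric(image$axis), file.path(path, "axis.bin"), "double")
  mask_names <- character(0)
  if (!is.null(masks)) {
    if (is.null(names(masks)) || any(names(masks) == ""))
      stop("masks must be a named list")
    dir.create(file.path(path, "masks"), showWarnings = FALSE)
    for (nm in names(masks)) {
      m <- masks[[nm]]
      stopifnot(inherits(m, "label_mask"))
      .write_bin(m$labels, file.path(path, "masks", paste0(nm, ".bin")), "integer")
    }
    mask_names <- names(masks)
  }
  manifest <- list(
    dims = dim(image$cube),
    axis = as.numeric(image$axis),
    meta = unclass(image$meta),
    provenance = image$provenance,
    masks = lapply(setNames(mask_names, mask_names), function(nm) {
      m <- masks[[nm]]
      list(dims = dim(m$labels), background_label = m$background_label)
    })
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a scene container written by [write_scene()]
#'
#' @param path Container directory.
#' @return List with elements `image` (`bcars_hsi`) and `masks` (named list of
#'   `label_mask`, possibly empty).
#' @export
read_scene <- function(path) {
  man <- jsonlite::read_json(file.path(path, "manifest.json"),
                             simplifyVector = FALSE)
  d <- as.integer(unlist(man$dims))
  cube <- array(.read_bin(file.path(path, "cube.bin"), "double", prod(d)), d)
  axis <- .read_bin(file.path(path, "axis.bin"), "double", d[3])
  meta <- man$meta
  dark <- if (is.null(meta$dark_spectrum)) NULL else as.numeric(unlist(meta$dark_spectrum))
  im <- hsi(cube, wavenumber_axis(axis),
            instrument_meta(meta$probe_wavelength_nm, meta$objective_na,
                            meta$pixel_dwell_s, meta$step_um, dark))
  if (length(man$provenance)) {
    im$provenance <- lapply(man$provenance, function(p)
      list(step = p$step, params = p$params))
  }
  masks <- list()
  for (nm in names(man$masks)) {
    md <- as.integer(unlist(man$masks[[nm]]$dims))
    lab <- matrix(.read_bin(file.path(path, "masks", paste0(nm, ".bin")),
                            "integer", prod(md)), md[1], md[2])
    masks[[nm]] <- label_mask(lab, man$masks[[nm]]$background_label)
  }
  list(image = im, masks = masks)
}

#' Export a label mask as 16-bit TIFF
#'
#' @param mask A `label_mask` with at most 65535 labels.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_mask_tiff <- function(mask, path) {
  stopifnot(inherits(mask, "label_mask"))
  if (max(mask$labels) > 65535L) stop("too many labels for 16-bit TIFF")
  tiff::writeTIFF(mask$labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Export spectrum records to a CSV table
#'
#' One row per record; columns `id`, `class_label`, `qc_rho`, any shared extra
#' scalar fields, then one column per Raman shift.  All records must share
#' one axis.  Values survive the round trip through [read_spectra_table()] to
#' 1e-9 relative.
#'
#' @param records List of [spectrum_record()] objects (may be empty, in which
#'   case a header-only table is written using `axis`).
#' @param path Output CSV file.
#' @param axis Axis used for an empty record list; ignored otherwise.
#' @return `path`, invisibly.
#' @export
export_spectra_table <- function(records, path, axis = NULL) {
  if (length(records) == 0L) {
    if (is.null(axis)) stop("axis required to write an empty table")
    df <- as.data.frame(matrix(numeric(0), 0, 3 + length(axis)))
    names(df) <- c("id", "class_label", "qc_rho", .axis_colnames(axis))
    write.csv(df, path, row.names = FALSE)
    return(invisible(path))
  }
  ax <- records[[1]]$axis
  for (r in records) {
    if (length(r$axis) != length(ax) || max(abs(r$axis - ax)) > 1e-9)
      stop("all records must share one axis")
  }
  core <- c("id", "values", "axis", "class_label", "qc_rho")
  extras <- setdiff(names(records[[1]]), core)
  rows <- lapply(records, function(r) {
    base <- data.frame(id = r$id, class_label = r$class_label, qc_rho = r$qc_rho,
                       stringsAsFactors = FALSE)
    for (e in extras) base[[e]] <- if (is.null(r[[e]])) NA else r[[e]]
    cbind(base, as.data.frame(t(r$values)))
  })
  df <- do.call(rbind, rows)
  names(df) <- c("id", "class_label", "qc_rho", extras, .axis_colnames(ax))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

.axis_colnames <- function(axis) sprintf("wn_%s", format(as.numeric(axis), digits = 12, trim = TRUE, scientific = FALSE))

#' Read a spectra table written by [export_spectra_table()]
#'
#' @param path CSV file.
#' @return List of `spectrum_record` objects.
#' @export
read_spectra_table <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  wn_cols <- grep("^wn_", names(df))
  if (nrow(df) == 0L) return(list())
  ax <- wavenumber_axis(as.numeric(sub("^wn_", "", names(df)[wn_cols])))
  extras <- setdiff(names(df)[-wn_cols], c("id", "class_label", "qc_rho"))
  lapply(seq_len(nrow(df)), function(i) {
    rec <- spectrum_record(df$id[i], as.numeric(df[i, wn_cols]), ax,
                           class_label = as.character(df$class_label[i]),
                           qc_rho = df$qc_rho[i])
    for (e in extras) rec[[e]] <- df[[e]][i]
    rec
  })
}
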