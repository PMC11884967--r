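#!/usr/bin/env Rscript
# Step 3: build the labelled single-cell spectrum table.
#
# Averages the retrieved spectra inside every segmented cell of the
# labelled scenes, applies the Pearson quality filter (rho >= 0.995 against
# the highest-intensity cell), EMSC scatter correction against the mean
# cell spectrum, and the 500-3142 cm^-1 crop with min-max normalization.
# The table and the cached EMSC reference go to results/.

suppressPackageStartupMessages(library(bcars))

cfg <- default_config(seed = 1)
ret_dir <- "scratch/analysis/retrieved"
manifest <- read.csv("results/scene_manifest.csv")
labelled <- manifest[manifest$kind != "mixed", ]

tables <- list()
for (i in seq_len(nrow(labelled))) {
  id <- labelled$id[i]
  sc <- read_scene(file.path(ret_dir, id))
  # single-class scene: every segmented cell inherits the scene's class
  n_seg <- max(sc$masks$segmentation$labels)
  classes <- setNames(as.list(rep(labelled$kind[i], n_seg)), seq_len(n_seg))
  tables[[i]] <- average_cells(sc$image, sc$masks$segmentation, classes,
                               source_image = id)
}
raw_table <- cell_spectrum_table(unlist(lapply(tables, `[[`, "records"),
                                        recursive = FALSE))
qc <- qc_filter(raw_table, rho_min = cfg$cellspectra$rho_min,
                window = c(cfg$cellspectra$crop_lo, cfg$cellspectra$crop_hi))
emsc <- emsc_table(qc$kept, order = cfg$cellspectra$emsc_order)
final <- crop_normalize_table(emsc$table, cfg$cellspectra$crop_lo,
                              cfg$cellspectra$crop_hi)

export_spectra_table(final$records, "results/cell_spectra.csv")
write.csv(data.frame(shift = as.numeric(qc$kept$records[[1]]$axis)[
            seq_along(emsc$mean_reference)], reference = emsc$mean_reference),
          "results/emsc_reference.csv", row.names = FALSE)
labs <- table(vapply(final$records, `[[`, character(1), "class_label"))
cat(sprintf("cell table: %d kept (%s), %d removed by QC\n",
            length(final), paste(names(labs), labs, sep = "=", collapse = ", "),
            length(qc$removed)))
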