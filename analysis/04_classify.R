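#!/usr/bin/env Rscript
# Step 4: train and evaluate the random-forest classifier.
#
# Fits the 40-tree balanced forest on the labelled cell table, reports the
# out-of-bag score, 10-fold cross-validated balanced accuracy, and the Gini
# feature-importance spectrum; then evaluates single-pixel classification
# (pixels pooled from the labelled scenes, 90/10 stratified split).

suppressPackageStartupMessages(library(bcars))

cfg <- default_config(seed = 1)
table <- cell_spectrum_table(read_spectra_table("results/cell_spectra.csv"))

fit <- train_forest(table, n_trees = cfg$classify$n_trees, seed = cfg$seed)
cv <- crossval_balanced_accuracy(table, k = cfg$classify$cv_folds,
                                 n_trees = cfg$classify$n_trees,
                                 seed = cfg$seed)
cat(sprintf("forest: OOB accuracy %.3f, %d-fold CV balanced accuracy %.3f (sd %.3f)\n",
            fit$report$oob_score, cfg$classify$cv_folds, cv$mean, cv$sd))

ax <- table$records[[1]]$axis
imp <- data.frame(shift = as.numeric(ax), importance = fit$report$importance)
write.csv(imp, "results/feature_importance.csv", row.names = FALSE)
top5 <- imp$shift[order(imp$importance, decreasing = TRUE)[1:5]]
cat("top-5 importance channels (cm^-1):", paste(round(top5), collapse = ", "), "\n")

# single-pixel evaluation on the labelled scenes
manifest <- read.csv("results/scene_manifest.csv")
labelled <- manifest[manifest$kind != "mixed", ]
scenes <- lapply(seq_len(nrow(labelled)), function(i) {
  sc <- read_scene(file.path("scratch/analysis/retrieved", labelled$id[i]))
  n_seg <- max(sc$masks$segmentation$labels)
  list(image = sc$image, mask = sc$masks$segmentation,
       classes = setNames(as.list(rep(labelled$kind[i], n_seg)), seq_len(n_seg)))
})
ds <- single_pixel_dataset(scenes, cfg$cellspectra$crop_lo,
                           cfg$cellspectra$crop_hi, cfg$cellspectra$emsc_order)
spe <- single_pixel_eval(ds, cfg$classify$single_pixel_test_fraction,
                         grouped = cfg$classify$single_pixel_grouped,
                         n_trees = cfg$classify$n_trees, seed = cfg$seed)
cat(sprintf("single-pixel: %d spectra, test balanced accuracy %.3f\n",
            nrow(ds$x), spe$balanced_accuracy))

report <- list(oob_score = fit$report$oob_score,
               cv_mean = cv$mean, cv_sd = cv$sd, cv_per_fold = cv$per_fold,
               single_pixel_balanced_accuracy = spe$balanced_accuracy,
               n_cells = length(table), n_pixels = nrow(ds$x),
               top5_importance_shifts = top5)
jsonlite::write_json(report, "results/classifier_report.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
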