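#' Default pipeline configuration
#'
#' Every stage's parameters in one list.  Defaults equal the standard
#' analysis settings: despike threshold 10x, phase-retrieval region
#' asymmetries 0.001/0.01/0.0001 (smoothing 3e4 in channel units, see
#' [retrieval_params()]), Pearson QC threshold 0.995, EMSC order 5, crop
#' 500-3142 cm^-1, 40 trees, 0.5 decision threshold.
#'
#' @param mode One of `"simulate"`, `"labeled-train"`, `"mixed-predict"`,
#'   `"single-pixel"`.
#' @param seed Master seed.
#' @return Nested list of class `"pipeline_config"`.
#' @export
default_config <- function(mode = "simulate", seed = 1L) {
  structure(list(
    mode = mode,
    seed = as.integer(seed),
    simulate = list(n_scenes_per_class = 4L, n_mixed_scenes = 2L,
                    cells_per_scene = 16L, height = 96L, width = 96L,
                    k = 1024L, read_sigma = 3, dark_level = 100,
                    cosmic_rate_per_image = 0.5, cosmic_factor = 12,
                    jitter_sigma = 0.1, cell_sigma = 0.02,
                    nrb_sigma = 0.02, nrb_tilt_sigma = 0.02),
    despike = list(threshold_factor = 10),
    denoise = list(max_components = 50L, lf_radius_fraction = 1 / 8,
                   score_multiplier = 3),
    segment = list(min_cell_area_px = 20L, gaussian_sigma_px = 1.5,
                   method = "fallback"),
    retrieve = list(smoothing_lambda = 3e4,
                    asymmetry = c(fingerprint = 0.001, silent = 0.01,
                                  high_wavenumber = 1e-4),
                    pad_factor = 2),
    cellspectra = list(rho_min = 0.995, emsc_order = 5L,
                       crop_lo = 500, crop_hi = 3142),
    classify = list(n_trees = 40L, threshold = 0.5, cv_folds = 10L,
                    single_pixel_test_fraction = 0.1,
                    single_pixel_grouped = FALSE)
  ), class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' @param config A `pipeline_config` (plain lists are accepted).
#' @return The validated config, invisibly; errors on invalid settings.
#' @export
validate_config <- function(config) {
  cs <- config$cellspectra
  if (cs$rho_min < 0 || cs$rho_min > 1) stop("QC rho threshold must be in [0, 1]")
  if (cs$crop_lo >= cs$crop_hi) stop("crop window is empty")
  cl <- config$classify
  if (cl$threshold <= 0 || cl$threshold >= 1) stop("decision threshold must be in (0, 1)")
  if (cl$n_trees < 1) stop("need at least one tree")
  if (config$despike$threshold_factor <= 1) stop("despike factor must exceed 1")
  asym <- config$retrieve$asymmetry
  if (any(asym <= 0) || any(asym >= 1)) stop("asymmetry parameters must be in (0, 1)")
  if (!config$mode %in% c("simulate", "labeled-train", "mixed-predict", "single-pixel"))
    stop("unknown mode")
  invisible(config)
}

#' Load a configuration from YAML or JSON
#' @param path File ending in .yaml/.yml or .json.
#' @return A validated `pipeline_config` (defaults filled in).
#' @export
load_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_config()
  for (nm in names(raw)) {
    cfg[[nm]] <- if (is.list(raw[[nm]]) && is.list(cfg[[nm]]))
      modifyList(cfg[[nm]], raw[[nm]]) else raw[[nm]]
  }
  validate_config(cfg)
  cfg
}

.retrieval_params_from <- function(config) {
  retrieval_params(smoothing_lambda = config$retrieve$smoothing_lambda,
                   asymmetry_by_region = config$retrieve$asymmetry,
                   pad_factor = config$retrieve$pad_factor)
}

#' Preprocess and retrieve one raw scene
#'
#' The fixed stage order: despike, dark subtraction, SVD denoising,
#' total-intensity imaging, segmentation, background NRB reference
#' extraction, per-pixel error-corrected KK retrieval.
#'
#' @param raw `bcars_hsi` of counts.
#' @param config `pipeline_config`.
#' @return List with `retrieved` (`bcars_hsi`), `mask` (segmentation),
#'   `reference` (NRB spectrum), `intensity` (total-intensity image),
#'   `despike_report`, `denoise_report`.
#' @export
process_scene <- function(raw, config = default_config()) {
  ds <- despike(raw, config$despike$threshold_factor)
  img <- subtract_dark(ds$image)
  dn <- svd_denoise(img, config$denoise$max_components,
                    config$denoise$lf_radius_fraction,
                    config$denoise$score_multiplier)
  intensity <- total_intensity_image(dn$image)
  mask <- segment_cells(intensity,
                        segmentation_params(config$segment$min_cell_area_px,
                                            config$segment$gaussian_sigma_px))
  ref <- background_reference(dn$image, mask)
  retrieved <- retrieve_hsi(dn$image, as.numeric(ref), .retrieval_params_from(config))
  list(retrieved = retrieved, mask = mask, reference = ref,
       intensity = intensity, despike_report = ds$report,
       denoise_report = dn$report)
}

# majority ground-truth class per segmented label (mixed scenes)
.mask_classes <- function(seg_mask, truth_mask, truth_classes) {
  labs <- sort(unique(seg_mask$labels[seg_mask$labels != seg_mask$background_label]))
  out <- list()
  for (l in labs) {
    tl <- truth_mask$labels[seg_mask$labels == l]
    tl <- tl[tl != truth_mask$background_label]
    out[[as.character(l)]] <- if (!length(tl)) NA_character_
      else as.character(truth_classes[as.integer(names(which.max(table(tl))))])
  }
  out
}

#' Run the full synthetic two-class study
#'
#' Renders single-class labelled scenes and 1:1 mixed scenes with the
#' default phantom physics, processes every scene through the full chain,
#' builds the QC-filtered, EMSC-corrected, cropped and normalized cell
#' table, trains and cross-validates the forest, evaluates single-pixel
#' classification, predicts the mixture, and runs the mixture chi-square,
#' PCA-projection and size analyses.
#'
#' @param config `pipeline_config`.
#' @param progress Print stage timings?
#' @return A list with the labelled `table`, `fit` + `cv`, `single_pixel`
#'   results, `mixed` results (`predictions`, `chisq`, `projection`,
#'   `size`), per-scene diagnostics, and the PCA of the labelled table.
#' @export
run_study <- function(config = default_config(), progress = FALSE) {
  validate_config(config)
  sim <- config$simulate
  models <- two_class_models()
  axis <- default_axis(sim$k)
  excitation <- default_excitation(axis)
  say <- function(...) if (progress) message(sprintf(...))

  scene_specs <- list()
  for (i in seq_len(sim$n_scenes_per_class)) {
    scene_specs[[length(scene_specs) + 1L]] <- list(kind = "A", idx = i)
    scene_specs[[length(scene_specs) + 1L]] <- list(kind = "B", idx = i)
  }
  for (i in seq_len(sim$n_mixed_scenes))
    scene_specs[[length(scene_specs) + 1L]] <- list(kind = "mixed", idx = i)

  labeled_tables <- list()
  pixel_scenes <- list()
  mixed <- list()
  diagnostics <- list()
  for (si in seq_along(scene_specs)) {
    sp <- scene_specs[[si]]
    seed_i <- config$seed * 1000L + si
    counts <- switch(sp$kind,
                     A = c(A = sim$cells_per_scene, B = 0L),
                     B = c(A = 0L, B = sim$cells_per_scene),
                     mixed = c(A = sim$cells_per_scene %/% 2L,
                               B = sim$cells_per_scene - sim$cells_per_scene %/% 2L))
    phantom <- random_phantom(sim$height, sim$width, counts, models,
                              seed = seed_i)
    scene <- render_scene(phantom, axis, excitation,
                          noise_spec(sim$read_sigma, sim$dark_level, TRUE,
                                     sim$cosmic_rate_per_image,
                                     sim$cosmic_factor, seed = seed_i),
                          jitter_sigma = sim$jitter_sigma,
                          cell_sigma = sim$cell_sigma,
                          nrb_sigma = sim$nrb_sigma,
                          nrb_tilt_sigma = sim$nrb_tilt_sigma)
    proc <- process_scene(scene$image, config)
    say("scene %d/%d (%s): %d cells segmented", si, length(scene_specs),
        sp$kind, max(proc$mask$labels))
    truth_classes <- scene$cells$class
    classes <- .mask_classes(proc$mask, scene$mask, truth_classes)
    diagnostics[[si]] <- list(kind = sp$kind,
                              n_true = nrow(scene$cells),
                              n_segmented = max(proc$mask$labels),
                              kept_components = proc$denoise_report$kept_indices)
    if (sp$kind == "mixed") {
      mixed[[length(mixed) + 1L]] <-
        list(proc = proc, truth = scene, classes = classes, scene_id = si)
    } else {
      labeled_tables[[length(labeled_tables) + 1L]] <-
        average_cells(proc$retrieved, proc$mask, classes,
                      source_image = sprintf("scene%02d_%s", si, sp$kind))
      pixel_scenes[[length(pixel_scenes) + 1L]] <-
        list(image = proc$retrieved, mask = proc$mask, classes = classes)
    }
  }

  # labelled cell table: average -> QC -> EMSC -> crop -> normalize
  cs <- config$cellspectra
  all_records <- unlist(lapply(labeled_tables, `[[`, "records"), recursive = FALSE)
  all_records <- Filter(function(r) !is.na(r$class_label), all_records)
  table_raw <- cell_spectrum_table(all_records)
  qc <- qc_filter(table_raw, rho_min = cs$rho_min,
                  window = c(cs$crop_lo, cs$crop_hi))
  emsc <- emsc_table(qc$kept, order = cs$emsc_order)
  table <- crop_normalize_table(emsc$table, cs$crop_lo, cs$crop_hi)
  say("labelled cells: %d kept, %d removed by QC", length(qc$kept), length(qc$removed))

  cl <- config$classify
  fit <- train_forest(table, n_trees = cl$n_trees, seed = config$seed)
  cv <- crossval_balanced_accuracy(table, k = cl$cv_folds,
                                   n_trees = cl$n_trees, seed = config$seed)
  pca <- pca_fit(table)

  # single-pixel classification on the labelled scenes
  pixel_ds <- single_pixel_dataset(pixel_scenes, cs$crop_lo, cs$crop_hi,
                                   cs$emsc_order)
  sp_eval <- single_pixel_eval(pixel_ds, cl$single_pixel_test_fraction,
                               grouped = cl$single_pixel_grouped,
                               n_trees = cl$n_trees, seed = config$seed)
  say("single-pixel: %d pixels, balanced accuracy %.3f", nrow(pixel_ds$x),
      sp_eval$balanced_accuracy)

  # mixture evaluation
  mixed_out <- NULL
  if (length(mixed)) {
    mix_tables <- lapply(seq_along(mixed), function(i) {
      m <- mixed[[i]]
      average_cells(m$proc$retrieved, m$proc$mask, m$classes,
                    source_image = sprintf("mixed%02d", i))
    })
    mix_records <- unlist(lapply(mix_tables, `[[`, "records"), recursive = FALSE)
    mix_table_raw <- cell_spectrum_table(mix_records)
    mix_emsc <- emsc_table(mix_table_raw, mean_reference = emsc$mean_reference,
                           order = cs$emsc_order)
    mix_table <- crop_normalize_table(mix_emsc$table, cs$crop_lo, cs$crop_hi)
    preds <- predict_cells(fit, mix_table)
    counts <- table(factor(preds$predicted, levels = fit$report$levels))
    chisq <- chisq_proportions(as.numeric(counts), rep(1, length(counts)))
    proj_lab <- pca_project(pca, table)
    proj_mix <- pca_project(pca, mix_table, labels = preds$predicted)
    truth_mix <- table_matrix(mix_table)$labels
    areas <- split(vapply(mix_table$records, `[[`, numeric(1), "area_px"),
                   preds$predicted)
    size <- if (length(areas) == 2 && all(vapply(areas, length, integer(1)) >= 3))
      size_analysis(areas, step_um = 1) else NULL
    mixed_out <- list(predictions = preds, truth = truth_mix,
                      counts = counts, chisq = chisq,
                      projection = list(labeled = proj_lab, mixed = proj_mix),
                      size = size)
  }

  list(table = table, qc = qc, fit = fit, cv = cv, pca = pca,
       pixel_dataset_n = nrow(pixel_ds$x), single_pixel = sp_eval,
       pixel_axis = pixel_ds$axis, cropped_axis = table$records[[1]]$axis,
       mixed = mixed_out, diagnostics = diagnostics,
       emsc_reference = emsc$mean_reference)
}

#' Importance-localization check over repeated forest seeds
#'
#' Retrains the forest `n_seeds` times and reports, per run, whether all of
#' the top-`top_k` Gini-importance channels fall inside the generator's
#' discriminative bands.
#'
#' @param table Processed labelled `cell_spectrum_table`.
#' @param bands data.frame with `center` and `halfwidth` (cm^-1).
#' @param n_seeds Number of retrains.
#' @param top_k Channels inspected per run.
#' @param n_trees Trees per forest.
#' @return List with `fraction_in_band` (runs where all top-k channels are
#'   in-band) and the per-run logical vector.
#' @export
importance_band_check <- function(table, bands = two_class_models()$bands,
                                  n_seeds = 20L, top_k = 5L, n_trees = 40L) {
  tm <- table_matrix(table)
  ax <- as.numeric(tm$axis)
  in_band <- rep(FALSE, length(ax))
  for (i in seq_len(nrow(bands)))
    in_band <- in_band | abs(ax - bands$center[i]) <= bands$halfwidth[i]
  ok <- vapply(seq_len(n_seeds), function(s) {
    fit <- train_forest(tm$x, tm$labels, n_trees = n_trees, seed = s)
    top <- order(fit$report$importance, decreasing = TRUE)[seq_len(top_k)]
    all(in_band[top])
  }, logical(1))
  list(fraction_in_band = mean(ok), per_seed = ok)
}

#' Run the configured pipeline and write its artifacts
#'
#' Executes the synthetic study under `config` and writes containers,
#' tables, reports and a structured log into `outdir`.  Reruns with the
#' same config and seed produce byte-identical CSV/JSON reports.
#'
#' @param config `pipeline_config` (validated before execution).
#' @param outdir Output directory (created).
#' @return The [run_study()] result, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config = default_config(), outdir = tempfile("bcars_run_")) {
  validate_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  res <- run_study(config)
  export_spectra_table(res$table$records, file.path(outdir, "cell_spectra.csv"))
  report <- list(
    config = unclass(config),
    oob_score = res$fit$report$oob_score,
    cv_balanced_accuracy = list(mean = res$cv$mean, sd = res$cv$sd,
                                per_fold = res$cv$per_fold),
    single_pixel_balanced_accuracy = res$single_pixel$balanced_accuracy,
    n_cells = length(res$table),
    n_pixels = res$pixel_dataset_n,
    pc12_variance_fraction = sum(res$pca$explained_variance_fraction[1:2]),
    importance = res$fit$report$importance
  )
  if (!is.null(res$mixed)) {
    report$mixture <- list(counts = as.list(res$mixed$counts),
                           chi2 = res$mixed$chisq$chi2, p = res$mixed$chisq$p)
    write.csv(res$mixed$predictions, file.path(outdir, "mixed_predictions.csv"),
              row.names = FALSE)
  }
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log <- data.frame(stage = "run_study", seed = config$seed,
                    wall_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  write.csv(log, file.path(outdir, "log.csv"), row.names = FALSE)
  invisible(res)
}
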