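#' Balanced accuracy (mean of per-class recalls)
#'
#' @param truth Factor or character vector of true labels.
#' @param pred Predicted labels.
#' @return Balanced accuracy in 0..1.
#' @export
balanced_accuracy <- function(truth, pred) {
  truth <- as.character(truth); pred <- as.character(pred)
  mean(vapply(unique(truth), function(cl)
    mean(pred[truth == cl] == cl), numeric(1)))
}

.class_weights <- function(y) {
  tab <- table(y)
  w <- as.numeric(sum(tab) / (length(tab) * tab))
  names(w) <- names(tab)
  w
}

#' Train the random-forest cell classifier
#'
#' A 40-tree random forest with balanced class weighting (weights inversely
#' proportional to class frequencies), bootstrap per tree, unlimited depth
#' and sqrt(K) features per split.  Out-of-bag accuracy is computed from the
#' out-of-bag class-probability votes, and the Gini (impurity-decrease)
#' feature importance is normalized to sum to 1.
#'
#' @param table A `cell_spectrum_table` with class labels, or a numeric
#'   matrix (then supply `labels`).
#' @param labels Class labels when `table` is a matrix.
#' @param n_trees Number of trees (default 40).
#' @param seed Integer seed (fixed seed gives identical OOB and importance).
#' @return List of class `"forest_fit"` with `model` (ranger forest),
#'   `report` (n_trees, class weights, `oob_score`, normalized `importance`,
#'   seed, class levels) — at least 2 classes with >= 5 records each
#'   required.
#' @export
train_forest <- function(table, labels = NULL, n_trees = 40L, seed = 1L) {
  if (inherits(table, "cell_spectrum_table")) {
    tm <- table_matrix(table)
    x <- tm$x; labels <- tm$labels
  } else x <- table
  y <- factor(labels)
  if (nlevels(y) < 2L) stop("need at least 2 classes")
  if (any(table(y) < 5L)) stop("need at least 5 records per class")
  colnames(x) <- paste0("ch", seq_len(ncol(x)))
  df <- data.frame(x, check.names = FALSE)
  df$.class <- y
  model <- ranger::ranger(dependent.variable.name = ".class", data = df,
                          num.trees = n_trees, probability = TRUE,
                          importance = "impurity",
                          class.weights = .class_weights(y),
                          seed = seed, oob.error = TRUE)
  oob <- model$predictions                       # OOB class probabilities
  have <- rowSums(is.na(oob)) == 0
  oob_pred <- colnames(oob)[max.col(oob[have, , drop = FALSE], ties.method = "first")]
  imp <- model$variable.importance
  imp <- pmax(imp, 0)
  imp <- imp / sum(imp)
  structure(list(model = model,
                 report = list(n_trees = n_trees,
                               class_weights = .class_weights(y),
                               oob_score = mean(oob_pred == as.character(y)[have]),
                               importance = unname(imp),
                               seed = seed,
                               levels = levels(y),
                               n_features = ncol(x))),
            class = "forest_fit")
}

#' Stratified k-fold cross-validated balanced accuracy
#'
#' @param table `cell_spectrum_table` with labels, or matrix (+ `labels`).
#' @param labels Labels when a matrix is given.
#' @param k Folds (default 10); every class must have at least `k` records.
#' @param n_trees Trees per fold forest.
#' @param seed Seed controlling fold assignment and forests.
#' @return List with `mean`, `sd` and `per_fold` balanced accuracies.
#' @export
crossval_balanced_accuracy <- function(table, labels = NULL, k = 10L,
                                       n_trees = 40L, seed = 1L) {
  if (inherits(table, "cell_spectrum_table")) {
    tm <- table_matrix(table)
    x <- tm$x; labels <- tm$labels
  } else x <- table
  y <- factor(labels)
  if (any(table(y) < k)) stop("every class needs at least k records")
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  colnames(x) <- paste0("ch", seq_len(ncol(x)))
  per_fold <- vapply(seq_len(k), function(f) {
    tr <- fold != f
    df <- data.frame(x[tr, , drop = FALSE], check.names = FALSE)
    df$.class <- y[tr]
    m <- ranger::ranger(dependent.variable.name = ".class", data = df,
                        num.trees = n_trees,
                        class.weights = .class_weights(y[tr]),
                        seed = seed + f, oob.error = FALSE)
    pred <- predict(m, data.frame(x[!tr, , drop = FALSE], check.names = FALSE))$predictions
    balanced_accuracy(y[!tr], pred)
  }, numeric(1))
  list(mean = mean(per_fold), sd = sd(per_fold), per_fold = per_fold)
}

#' Predict class probabilities for cells
#'
#' Class probabilities are the weighted fraction of tree votes; a cell is
#' labelled with the class whose probability exceeds 0.5.  An exact 0.5 tie
#' is assigned to the second class alphabetically and flagged low
#' confidence.
#'
#' @param fit A `"forest_fit"`.
#' @param table `cell_spectrum_table` or matrix on the training axis.
#' @return data.frame with `id`, one probability column per class,
#'   `predicted`, and `low_confidence`.
#' @export
predict_cells <- function(fit, table) {
  ids <- NULL
  if (inherits(table, "cell_spectrum_table")) {
    tm <- table_matrix(table)
    x <- tm$x; ids <- tm$ids
  } else x <- table
  if (ncol(x) != fit$report$n_features) stop("axis/cropping mismatch with training")
  colnames(x) <- paste0("ch", seq_len(ncol(x)))
  prob <- predict(fit$model, data.frame(x, check.names = FALSE))$predictions
  stopifnot(max(abs(rowSums(prob) - 1)) < 1e-9)
  lev <- colnames(prob)
  top <- max.col(prob, ties.method = "last")     # 0.5 tie -> later class
  tie <- abs(prob[, 1] - 0.5) < 1e-12 & ncol(prob) == 2
  out <- data.frame(id = if (is.null(ids)) seq_len(nrow(prob)) else ids,
                    prob, check.names = FALSE)
  out$predicted <- lev[top]
  out$low_confidence <- tie
  out
}

#' Pool single-pixel spectra from retrieved scenes
#'
#' Every in-cell pixel inherits its cell's class label; background pixels
#' are excluded.  Each pixel spectrum is EMSC-corrected against the mean
#' pixel spectrum, cropped, and min-max normalized — the same treatment
#' applied to averaged cell spectra.
#'
#' @param scenes List of scenes, each a list with `image` (retrieved
#'   `bcars_hsi`), `mask` (`label_mask`), and `classes` (class label per
#'   mask label, named by label).
#' @param lo,hi Crop window (cm^-1).
#' @param emsc_order EMSC polynomial order.
#' @return List with `x` (pixels x channels matrix), `y` (class factor),
#'   `cell` (scene-qualified cell id per pixel), `axis`.
#' @export
single_pixel_dataset <- function(scenes, lo = 500, hi = 3142, emsc_order = 5L) {
  xs <- list(); ys <- list(); cells <- list()
  axis <- NULL
  for (si in seq_along(scenes)) {
    sc <- scenes[[si]]
    d <- dim(sc$image$cube)
    axis <- sc$image$axis
    flat <- matrix(sc$image$cube, d[1] * d[2], d[3])
    labs <- sort(unique(sc$mask$labels[sc$mask$labels != sc$mask$background_label]))
    for (l in labs) {
      px <- which(sc$mask$labels == l)
      if (!length(px)) stop("empty cell mask")
      xs[[length(xs) + 1L]] <- flat[px, , drop = FALSE]
      ys[[length(ys) + 1L]] <- rep(as.character(sc$classes[[as.character(l)]]),
                                   length(px))
      cells[[length(cells) + 1L]] <- rep(sprintf("s%d_c%d", si, l), length(px))
    }
  }
  x <- do.call(rbind, xs)
  corrected <- .emsc_matrix(x, colMeans(x), axis, emsc_order)
  idx <- which(as.numeric(axis) >= lo & as.numeric(axis) <= hi)
  cropped <- corrected[, idx, drop = FALSE]
  rng_lo <- apply(cropped, 1, min)
  rng_hi <- apply(cropped, 1, max)
  if (any(rng_hi <= rng_lo)) stop("constant pixel spectrum: zero range")
  out <- (cropped - rng_lo) / (rng_hi - rng_lo)
  list(x = out, y = factor(unlist(ys)), cell = unlist(cells),
       axis = wavenumber_axis(as.numeric(axis)[idx]))
}

#' Train/test evaluation of single-pixel classification
#'
#' Stratified split at pixel level (default, matching a simple 90/10
#' partition) or grouped by cell (`grouped = TRUE`, which avoids leaking
#' intra-cell correlation between train and test).
#'
#' @param dataset Output of [single_pixel_dataset()].
#' @param test_fraction Held-out fraction (default 0.1).
#' @param grouped Split by cell instead of by pixel?
#' @param n_trees Trees.
#' @param seed Seed (same seed gives identical split indices).
#' @return List with `balanced_accuracy`, `confusion`, `test_idx`, `fit`.
#' @export
single_pixel_eval <- function(dataset, test_fraction = 0.1, grouped = FALSE,
                              n_trees = 40L, seed = 1L) {
  y <- dataset$y
  set.seed(seed)
  if (grouped) {
    test <- logical(length(y))
    for (cl in levels(y)) {
      cells_cl <- unique(dataset$cell[y == cl])
      n_test <- max(1L, round(test_fraction * length(cells_cl)))
      test_cells <- sample(cells_cl, n_test)
      test[dataset$cell %in% test_cells] <- TRUE
    }
  } else {
    test <- logical(length(y))
    for (cl in levels(y)) {
      idx <- which(y == cl)
      test[sample(idx, max(1L, round(test_fraction * length(idx))))] <- TRUE
    }
  }
  fit <- train_forest(dataset$x[!test, , drop = FALSE], y[!test],
                      n_trees = n_trees, seed = seed)
  pred <- predict_cells(fit, dataset$x[test, , drop = FALSE])$predicted
  list(balanced_accuracy = balanced_accuracy(y[test], pred),
       confusion = table(truth = y[test], predicted = pred),
       test_idx = which(test),
       fit = fit)
}
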