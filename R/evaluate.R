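#' Principal-component model of a spectra table
#'
#' Mean-centred PCA with deterministic component signs (the
#' largest-magnitude loading of each component is made positive).
#'
#' @param table `cell_spectrum_table` or numeric matrix (rows = spectra).
#' @param n_components Components retained (default all).
#' @return List of class `"pca_model"`: `mean`, `components` (loadings in
#'   columns, orthonormal), `explained_variance`,
#'   `explained_variance_fraction`.
#' @export
pca_fit <- function(table, n_components = NULL) {
  x <- if (inherits(table, "cell_spectrum_table")) table_matrix(table)$x else table
  if (nrow(x) < 3L) stop("need at least 3 records for PCA")
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  nc <- min(if (is.null(n_components)) ncol(pc$rotation) else n_components,
            ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(nc), drop = FALSE]
  for (i in seq_len(nc)) {
    if (rot[which.max(abs(rot[, i])), i] < 0) rot[, i] <- -rot[, i]
  }
  ev <- pc$sdev^2
  structure(list(mean = pc$center,
                 components = rot,
                 explained_variance = ev[seq_len(nc)],
                 explained_variance_fraction = (ev / sum(ev))[seq_len(nc)]),
            class = "pca_model")
}

#' Project spectra on a fitted PC basis, with per-class 2D density estimates
#'
#' Scores are the centred spectra times the loadings.  When labels are
#' available, a Gaussian kernel density estimate over PC1-PC2 is computed
#' per class with Scott's-rule bandwidth.
#'
#' @param model A `"pca_model"`.
#' @param table `cell_spectrum_table` or matrix on the same axis/cropping.
#' @param labels Optional class labels (taken from the table if present).
#' @param kde_n Grid size of the density estimates.
#' @return List with `scores` (matrix), `labels`, and `kde` (per-class list
#'   of MASS::kde2d grids over PC1-PC2, NULL without labels).
#' @export
pca_project <- function(model, table, labels = NULL, kde_n = 50L) {
  if (inherits(table, "cell_spectrum_table")) {
    tm <- table_matrix(table)
    x <- tm$x
    if (is.null(labels)) labels <- tm$labels
  } else x <- table
  if (ncol(x) != length(model$mean)) stop("axis/cropping mismatch with the PCA model")
  scores <- sweep(x, 2, model$mean) %*% model$components
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  kde <- NULL
  if (!is.null(labels) && !all(is.na(labels)) && ncol(scores) >= 2) {
    scott <- function(v) sd(v) * length(v)^(-1 / 6)
    kde <- lapply(split(seq_along(labels), labels), function(idx) {
      if (length(idx) < 3) return(NULL)
      s <- scores[idx, 1:2, drop = FALSE]
      MASS::kde2d(s[, 1], s[, 2], n = kde_n,
                  h = c(max(scott(s[, 1]), 1e-9), max(scott(s[, 2]), 1e-9)))
    })
  }
  list(scores = scores, labels = labels, kde = kde)
}

#' Chi-square test of observed class counts against an expected ratio
#'
#' `chi2 = sum (O - E)^2 / E` with `E = ratio * total` and
#' `dof = classes - 1`; the p-value comes from the chi-square survival
#' function.
#'
#' @param observed_counts Nonnegative integer counts per class.
#' @param expected_ratio Expected proportions (normalized internally).
#' @return List with `chi2`, `p`, `dof`, `expected`.
#' @export
chisq_proportions <- function(observed_counts, expected_ratio) {
  o <- as.numeric(observed_counts)
  if (any(o < 0) || sum(o) <= 0) stop("counts must be nonnegative with positive total")
  r <- expected_ratio / sum(expected_ratio)
  e <- r * sum(o)
  if (any(e == 0)) stop("expected count of zero")
  chi2 <- sum((o - e)^2 / e)
  dof <- length(o) - 1L
  list(chi2 = chi2, p = pchisq(chi2, dof, lower.tail = FALSE), dof = dof,
       expected = e)
}

#' Cell-size analysis between two groups
#'
#' Computes the equivalent diameter of every cell from its mask area and
#' compares the two groups with a two-sided Mann-Whitney (Wilcoxon
#' rank-sum) test; a Welch t-test is available behind `parametric = TRUE`.
#'
#' @param areas_px List of two numeric vectors of per-cell areas (px), named
#'   by group.
#' @param step_um Pixel pitch (um).
#' @param parametric Use a Welch t-test instead of Mann-Whitney.
#' @return List with `summaries` (per-group n/mean/median diameter), `p`,
#'   `statistic`, `direction` (sign of median difference, group1 - group2),
#'   and `test`.
#' @export
size_analysis <- function(areas_px, step_um = 1, parametric = FALSE) {
  if (length(areas_px) != 2L) stop("exactly two groups required")
  if (any(vapply(areas_px, length, integer(1)) < 3L)) stop("group too small")
  diam <- lapply(areas_px, function(a) 2 * sqrt(a / pi) * step_um)
  ht <- if (parametric) t.test(diam[[1]], diam[[2]])
        else wilcox.test(diam[[1]], diam[[2]], exact = FALSE)
  summaries <- lapply(diam, function(d)
    list(n = length(d), mean_um = mean(d), median_um = median(d)))
  names(summaries) <- names(areas_px)
  list(summaries = summaries,
       p = ht$p.value,
       statistic = unname(ht$statistic),
       direction = sign(median(diam[[1]]) - median(diam[[2]])),
       test = if (parametric) "welch_t" else "mann_whitney")
}
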