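#' Random-forest classifier specification
#'
#' @param n_trees number of trees.
#' @param k_folds folds for stratified cross-validation.
#' @param class_weight `"inverse_frequency"` (weights inversely proportional
#'   to training-fold class frequencies) or `"none"`.
#' @param max_features split-candidate rule; `"sqrt"` (default) or an integer.
#' @param seed integer seed controlling fold assignment and forest growth.
#' @return a `classifier_spec` list.
#' @export
classifier_spec <- function(n_trees = 500, k_folds = 5,
                            class_weight = c("inverse_frequency", "none"),
                            max_features = "sqrt", seed = 0) {
  class_weight <- match.arg(class_weight)
  if (n_trees < 1) stop("'n_trees' must be >= 1")
  if (k_folds < 2) stop("'k_folds' must be >= 2")
  structure(list(n_trees = as.integer(n_trees), k_folds = as.integer(k_folds),
    class_weight = class_weight, max_features = max_features,
    seed = as.integer(seed)), class = "classifier_spec")
}

#' Stratified fold assignment
#'
#' Shuffles within each class and deals fold ids round-robin, so per-fold
#' class proportions match the global proportions to within one sample.
#'
#' @param labels class labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer fold id (1..k) per observation.
#' @export
stratified_folds <- function(labels, k, seed = 0) {
  labels <- as.factor(labels)
  counts <- table(labels)
  if (any(counts < k)) {
    small <- names(counts)[counts < k]
    stop(sprintf(
      "class(es) %s have fewer than %d members; use a smaller k_folds",
      paste(small, collapse = ", "), k
    ))
  }
  folds <- integer(length(labels))
  with_seed(derive_seed(seed, "folds"), {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      folds[idx] <- rep_len(seq_len(k), length(idx))[sample.int(length(idx))]
    }
  })
  folds
}

rf_class_weights <- function(labels, spec) {
  if (spec$class_weight == "none") return(NULL)
  tab <- table(labels)
  w <- as.numeric(sum(tab) / (length(tab) * tab))
  names(w) <- names(tab)
  w
}

rf_mtry <- function(p, spec) {
  if (identical(spec$max_features, "sqrt")) max(1L, floor(sqrt(p)))
  else min(p, max(1L, as.integer(spec$max_features)))
}

fit_rf <- function(scores, labels, spec, seed) {
  labels <- droplevels(as.factor(labels))
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  ranger::ranger(
    x = scores, y = labels,
    num.trees = spec$n_trees,
    mtry = rf_mtry(ncol(scores), spec),
    probability = TRUE,
    class.weights = rf_class_weights(labels, spec)[levels(labels)],
    seed = seed,
    num.threads = 1L
  )
}

rf_probabilities <- function(fit, scores, label_order) {
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  p <- predict(fit, data = scores, num.threads = 1L)$predictions
  p[, label_order, drop = FALSE]
}

# deterministic argmax: equal probabilities break toward the earlier label
rf_predict_class <- function(fit, scores, label_order) {
  p <- rf_probabilities(fit, scores, label_order)
  label_order[max.col(p, ties.method = "first")]
}

#' Stratified k-fold cross-validated classification
#'
#' For each fold the PCA transform is fit on the training spectra only (no
#' leakage), training spectra are projected and a class-weighted
#' probability random forest is grown; test-fold predictions are pooled into
#' one confusion matrix.
#'
#' @param spectra a preprocessed [spectra_matrix()] (pre-PCA space).
#' @param labels class label per cell.
#' @param spec a [classifier_spec()].
#' @param pca list of [pca_fit()] options (`variance_target`,
#'   `max_components`).
#' @return a `cv_result`: `accuracy`, `per_fold_accuracy`, `confusion`
#'   (true x predicted counts), `per_class_accuracy`, `label_order`, `folds`.
#' @export
cross_validate <- function(spectra, labels, spec = classifier_spec(),
                           pca = list(variance_target = 0.95,
                                      max_components = NULL)) {
  stopifnot(inherits(spectra, "spectra_matrix"))
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2L) stop("cross-validation requires at least 2 classes")
  folds <- stratified_folds(labels, spec$k_folds, seed = spec$seed)
  lab_order <- levels(labels)
  confusion <- matrix(0L, nlevels(labels), nlevels(labels),
    dimnames = list(true = lab_order, predicted = lab_order))
  per_fold <- numeric(spec$k_folds)
  for (f in seq_len(spec$k_folds)) {
    tr <- folds != f
    red <- pca_fit(subset_cells(spectra, tr),
      variance_target = pca$variance_target %||% 0.95,
      max_components = pca$max_components,
      fitted_on = sprintf("fold_%d_train", f))
    fit <- fit_rf(red$scores, labels[tr], spec,
      seed = derive_seed(spec$seed, paste0("rf_fold_", f)))
    te_scores <- pca_transform(red, subset_cells(spectra, !tr))
    pred <- rf_predict_class(fit, te_scores, lab_order)
    truth <- as.character(labels[!tr])
    per_fold[f] <- mean(pred == truth)
    for (i in seq_along(pred)) {
      confusion[truth[i], pred[i]] <- confusion[truth[i], pred[i]] + 1L
    }
  }
  structure(list(
    accuracy = sum(diag(confusion)) / sum(confusion),
    per_fold_accuracy = per_fold,
    confusion = confusion,
    per_class_accuracy = diag(confusion) / rowSums(confusion),
    label_order = lab_order,
    folds = folds,
    spec = spec
  ), class = "cv_result")
}

#' @exportS3Method base::print
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> pooled accuracy %.3f over %d folds\n",
    x$accuracy, length(x$per_fold_accuracy)))
  print(x$confusion)
  invisible(x)
}

#' Train a deployment classifier on reduced spectra
#'
#' @param scores PCA score matrix (n x k).
#' @param labels class label per row (at least two classes).
#' @param spec a [classifier_spec()].
#' @return a `raman_classifier` exposing per-class probabilities via
#'   [predict_probabilities()].
#' @export
train_final <- function(scores, labels, spec = classifier_spec()) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2L) stop("training requires at least 2 classes")
  fit <- fit_rf(as.matrix(scores), labels, spec,
    seed = derive_seed(spec$seed, "rf_final"))
  structure(list(fit = fit, label_order = levels(labels), spec = spec),
    class = "raman_classifier")
}

#' Per-class probabilities from a trained classifier
#'
#' @param classifier a `raman_classifier` from [train_final()].
#' @param scores PCA score matrix of new observations.
#' @return matrix of probabilities (rows sum to 1), columns in
#'   `classifier$label_order`.
#' @export
predict_probabilities <- function(classifier, scores) {
  stopifnot(inherits(classifier, "raman_classifier"))
  rf_probabilities(classifier$fit, as.matrix(scores), classifier$label_order)
}

#' Perturb spectra with a Voigt bump at one wavenumber
#'
#' Adds a peak-normalised Voigt profile centred at `w` to every spectrum
#' (`mode = "additive"`, the default), or zeroes the region within half a
#' FWHM of `w` (`mode = "mask"`). The default amplitude rule scales each
#' spectrum's bump by that spectrum's intensity standard deviation across the
#' window.
#'
#' @param spectra a [spectra_matrix()] (pre-PCA space).
#' @param w perturbation centre (cm^-1); must lie inside the grid.
#' @param fwhm bump width (cm^-1).
#' @param amplitude `"per_spectrum_sd"`, or a scalar / per-cell numeric
#'   vector of bump amplitudes.
#' @param mode `"additive"` or `"mask"`.
#' @return a perturbed `spectra_matrix`.
#' @export
perturb_wavenumber <- function(spectra, w, fwhm = 15,
                               amplitude = "per_spectrum_sd",
                               mode = c("additive", "mask")) {
  stopifnot(inherits(spectra, "spectra_matrix"))
  mode <- match.arg(mode)
  wn <- as.numeric(spectra$grid)
  if (w < wn[1L] || w > wn[length(wn)]) {
    stop(sprintf("perturbation centre %g cm^-1 lies outside the grid [%g, %g]",
      w, wn[1L], wn[length(wn)]))
  }
  x <- spectra$intensities
  if (mode == "mask") {
    x[, abs(wn - w) <= fwhm / 2] <- 0
    return(spectra_matrix(x, spectra$grid, cell_ids = spectra$cell_ids))
  }
  a <- if (identical(amplitude, "per_spectrum_sd")) {
    apply(x, 1L, sd)
  } else {
    rep_len(as.numeric(amplitude), nrow(x))
  }
  bump <- band_shape(raman_band(w, fwhm = fwhm), wn)
  spectra_matrix(x + outer(a, bump), spectra$grid, cell_ids = spectra$cell_ids)
}

#' Wavenumber importance by perturbation accuracy dropoff
#'
#' For each wavenumber on an evaluation grid, each cross-validation test fold
#' is perturbed with a Voigt bump ([perturb_wavenumber()]) in pre-PCA space,
#' projected through that fold's PCA transform, and reclassified;
#' `dropoff(w)` is the mean over folds of (unperturbed test accuracy minus
#' perturbed test accuracy). Negative dropoffs are reported, not clipped.
#'
#' Because the perturbation is additive and PCA projection is affine, the
#' perturbed scores equal `scores + a %o% (bump %*% t(loadings))`; the curve
#' is computed through that identity (it matches the explicit
#' perturb-then-project path to floating-point accuracy).
#'
#' @inheritParams cross_validate
#' @param perturb list: `fwhm` (default 15 cm^-1), `amplitude`
#'   (`"per_spectrum_sd"` or numeric), `grid_step` (evaluation spacing,
#'   cm^-1; default 2), `n_trees` (forest size for the per-fold importance
#'   forests, default 200 — the dropoff is an accuracy *difference* on the
#'   same folds and is stable with a smaller forest than the deployment
#'   classifier, at a fraction of the re-prediction cost).
#' @return an `importance_curve`: data.frame `wavenumber`, `dropoff`, `se`,
#'   with attributes `baseline_accuracy` and `config`.
#' @export
importance_curve <- function(spectra, labels, spec = classifier_spec(),
                             perturb = list(fwhm = 15,
                                            amplitude = "per_spectrum_sd",
                                            grid_step = 2, n_trees = 200),
                             pca = list(variance_target = 0.95,
                                        max_components = NULL)) {
  stopifnot(inherits(spectra, "spectra_matrix"))
  labels <- droplevels(as.factor(labels))
  fwhm <- perturb$fwhm %||% 15
  amplitude <- perturb$amplitude %||% "per_spectrum_sd"
  grid_step <- perturb$grid_step %||% 2
  spec <- `[[<-`(spec, "n_trees", as.integer(perturb$n_trees %||% 200))
  folds <- stratified_folds(labels, spec$k_folds, seed = spec$seed)
  lab_order <- levels(labels)
  wn <- as.numeric(spectra$grid)
  p <- length(wn)
  native_step <- attr(spectra$grid, "step")
  by_pts <- max(1L, as.integer(round(grid_step / native_step)))
  eval_idx <- seq(1L, p, by = by_pts)
  uniform <- diff(range(diff(wn))) < 1e-9
  offs <- if (uniform) {
    # single profile over signed offsets; slice per centre index
    band_shape(raman_band(wn[1L], fwhm = fwhm),
      wn[1L] + (seq_len(2L * p - 1L) - p) * native_step)
  } else {
    NULL
  }
  acc0 <- numeric(spec$k_folds)
  drop_mat <- matrix(NA_real_, spec$k_folds, length(eval_idx))
  for (f in seq_len(spec$k_folds)) {
    tr <- folds != f
    red <- pca_fit(subset_cells(spectra, tr),
      variance_target = pca$variance_target %||% 0.95,
      max_components = pca$max_components,
      fitted_on = sprintf("fold_%d_train", f))
    fit <- fit_rf(red$scores, labels[tr], spec,
      seed = derive_seed(spec$seed, paste0("rf_fold_", f)))
    test <- subset_cells(spectra, !tr)
    te_scores <- pca_transform(red, test)
    truth <- as.character(labels[!tr])
    acc0[f] <- mean(rf_predict_class(fit, te_scores, lab_order) == truth)
    a <- if (identical(amplitude, "per_spectrum_sd")) {
      apply(test$intensities, 1L, sd)
    } else {
      rep_len(as.numeric(amplitude), nrow(test$intensities))
    }
    for (j in seq_along(eval_idx)) {
      ci <- eval_idx[j]
      bump <- if (uniform) offs[(p - ci + 1L):(2L * p - ci)] else
        band_shape(raman_band(wn[ci], fwhm = fwhm), wn)
      delta <- as.numeric(bump %*% t(red$loadings))
      pert_scores <- te_scores + outer(a, delta)
      acc_w <- mean(rf_predict_class(fit, pert_scores, lab_order) == truth)
      drop_mat[f, j] <- acc0[f] - acc_w
    }
  }
  curve <- data.frame(
    wavenumber = wn[eval_idx],
    dropoff = colMeans(drop_mat),
    se = apply(drop_mat, 2L, sd) / sqrt(spec$k_folds)
  )
  structure(curve,
    baseline_accuracy = mean(acc0),
    config = list(fwhm = fwhm, amplitude = amplitude, grid_step = grid_step,
      k_folds = spec$k_folds),
    class = c("importance_curve", "data.frame")
  )
}
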