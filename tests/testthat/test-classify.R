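fast_spec <- function(...) classifier_spec(n_trees = 150, ...)

test_that("stratified folds preserve class proportions to within one sample", {
  labels <- rep(c("a", "b", "c"), times = c(40, 25, 11))
  folds <- stratified_folds(labels, 5, seed = 1)
  for (f in 1:5) {
    tab <- table(labels[folds == f])
    expect_true(all(abs(tab - table(labels) / 5) <= 1))
  }
  expect_error(stratified_folds(rep(c("a", "b"), c(3, 40)), 5), "smaller k")
})

test_that("two noiselessly separable classes are classified perfectly", {
  cohort <- cached_fixture("sep_small", two_class_cohort(
    n_per_class = 60, shift = 2,
    noise = noise_model(additive_noise_sd = 0.005, baseline_coeff_sd = 0,
      spike_rate = 0),
    cv = 0.05, seed = 21))
  pre <- preprocess_spectra(cohort$spectra, despike = FALSE)
  cv <- cross_validate(pre, cohort$metadata$sample_id, fast_spec())
  expect_equal(cv$accuracy, 1.0)
  # confusion identity: trace / total equals reported accuracy
  expect_equal(sum(diag(cv$confusion)) / sum(cv$confusion), cv$accuracy)
  expect_equal(unname(rowSums(cv$confusion)), as.vector(table(cohort$metadata$sample_id)))
})

test_that("training-set accuracy dominates CV accuracy on separable data and is deterministic", {
  cohort <- cached_fixture("sep_small", two_class_cohort(
    n_per_class = 60, shift = 2,
    noise = noise_model(additive_noise_sd = 0.005, baseline_coeff_sd = 0,
      spike_rate = 0),
    cv = 0.05, seed = 21))
  pre <- preprocess_spectra(cohort$spectra, despike = FALSE)
  red <- pca_fit(pre)
  fit1 <- train_final(red$scores, cohort$metadata$sample_id, fast_spec())
  p1 <- predict_probabilities(fit1, red$scores)
  expect_equal(unname(rowSums(p1)), rep(1, nrow(p1)), tolerance = 1e-9)
  train_acc <- mean(fit1$label_order[max.col(p1, "first")] ==
    cohort$metadata$sample_id)
  cv <- cross_validate(pre, cohort$metadata$sample_id, fast_spec())
  expect_gte(train_acc, cv$accuracy)
  fit2 <- train_final(red$scores, cohort$metadata$sample_id, fast_spec())
  expect_identical(p1, predict_probabilities(fit2, red$scores))
  expect_error(train_final(red$scores, rep("one", nrow(red$scores))),
    "at least 2")
})

test_that("perturbation is local, additive and vanishes at amplitude zero", {
  g <- wavenumber_grid()
  set.seed(2)
  sm <- spectra_matrix(matrix(runif(5 * length(g)), 5), g)
  expect_equal(perturb_wavenumber(sm, 1003, amplitude = 0)$intensities,
    sm$intensities, tolerance = 1e-12)
  pert <- perturb_wavenumber(sm, 1003, fwhm = 15, amplitude = 1)
  far <- abs(as.numeric(g) - 1003) > 5 * 15
  expect_lt(max(abs(pert$intensities[, far] - sm$intensities[, far])), 0.01)
  # two disjoint perturbations commute
  ab <- perturb_wavenumber(perturb_wavenumber(sm, 700, amplitude = 2), 1600,
    amplitude = 3)
  ba <- perturb_wavenumber(perturb_wavenumber(sm, 1600, amplitude = 3), 700,
    amplitude = 2)
  expect_equal(ab$intensities, ba$intensities, tolerance = 1e-12)
  expect_error(perturb_wavenumber(sm, 50), "outside")
})

test_that("the importance fast path equals explicit perturb-then-project", {
  cohort <- two_class_cohort(n_per_class = 30, seed = 31)
  pre <- preprocess_spectra(cohort$spectra, despike = FALSE)
  red <- pca_fit(pre)
  w <- 1003; fwhm <- 15
  a <- apply(pre$intensities, 1, sd)
  explicit <- pca_transform(red,
    perturb_wavenumber(pre, w, fwhm = fwhm, amplitude = a))
  bump <- voigt_profile(as.numeric(pre$grid), w,
    sigma = ramanresist:::voigt_params_from_fwhm(fwhm)$sigma,
    gamma = ramanresist:::voigt_params_from_fwhm(fwhm)$gamma)
  shortcut <- pca_transform(red, pre) +
    outer(a, as.numeric(bump %*% t(red$loadings)))
  expect_equal(explicit, shortcut, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("importance curve localises a planted discriminative band", {
  cohort <- cached_fixture("sep_imp", two_class_cohort(
    n_per_class = 80, shift = 1.5, seed = 51))
  pre <- preprocess_spectra(cohort$spectra, despike = FALSE)
  imp <- importance_curve(pre, cohort$metadata$sample_id,
    fast_spec(k_folds = 3),
    perturb = list(fwhm = 15, grid_step = 4))
  expect_equal(nrow(imp), length(seq(1, 1201, by = 4)))
  top <- imp$wavenumber[which.max(imp$dropoff)]
  expect_lt(abs(top - 1003), 10)
  # a quiet region far from every band carries no importance signal
  quiet <- imp$wavenumber > 1750
  expect_true(all(abs(imp$dropoff[quiet]) <=
    pmax(2 * imp$se[quiet], 0.02)))
})
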