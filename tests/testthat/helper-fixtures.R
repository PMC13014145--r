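# Fixtures are generated in code and cached for the duration of one test run,
# so several test files can share the heavier cohorts without regenerating.
.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- force(expr)
  .fixture_cache[[name]]
}

# two samples differing by a single planted band (log2 FC +1 at 1003 cm^-1)
two_class_cohort <- function(n_per_class = 200, shift = 1, band = "1003",
                             noise = noise_model(), cv = 0.15, seed = 42) {
  profile <- default_phenotype("melanoma", cv = cv)
  patients <- list(
    patient_spec("S-ref", list(list(profile = profile, fraction = 1)),
      c(drugX = "sensitive"), n_cells = n_per_class),
    patient_spec("S-alt", list(list(profile = profile, fraction = 1)),
      c(drugX = "resistant"), n_cells = n_per_class)
  )
  effects <- list(drugX = treatment_effect("drugX",
    setNames(shift, band)))
  synth_cohort(patients, treatments = "untreated", effects = effects,
    noise = noise, seed = seed)
}

# exhaustive two-sided rank-sum p-value by enumerating all group assignments
wilcoxon_enum_oracle <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  r <- rank(pooled)
  obs <- sum(r[seq_len(na)])
  combos <- utils::combn(n, na)
  sums <- apply(combos, 2L, function(ix) sum(r[ix]))
  center <- na * (n + 1) / 2
  p <- 2 * min(mean(sums <= obs), mean(sums >= obs))
  min(p, 1)
}

# exact mini-patient likelihood by enumerating all ordered subsets
minipatient_enum_oracle <- function(probs, subset_size, threshold = 0.5) {
  grid <- as.matrix(expand.grid(rep(list(seq_along(probs)), subset_size)))
  mean(rowMeans(matrix(probs[grid], nrow(grid), subset_size)) > threshold)
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)

expect_spectra_equal <- function(x, y, tol = 1e-9) {
  expect_identical(x$cell_ids, y$cell_ids)
  expect_true(all(abs(as.numeric(x$grid) - as.numeric(y$grid)) < 1e-9))
  scale <- max(abs(y$intensities), 1e-12)
  expect_lt(max(abs(x$intensities - y$intensities)) / scale, tol)
}
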