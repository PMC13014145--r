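quiet_profile <- function(cv = 0) {
  b <- list(raman_band(1003, fwhm = 12))
  phenotype_profile("one_band", b, amplitudes = 1, cv = cv, baseline_level = 0)
}

no_noise <- noise_model(additive_noise_sd = 0, baseline_coeff_sd = 0,
  spike_rate = 0)

test_that("a noiseless single-band spectrum peaks at the band centre", {
  g <- wavenumber_grid()
  y <- synth_spectrum(quiet_profile(), noise = no_noise, grid = g)
  expect_equal(as.numeric(g)[which.max(y)], 1003)
  expect_equal(max(y), 1)
})

test_that("a +1 log2 shift exactly doubles the noiseless band intensity", {
  g <- wavenumber_grid()
  eff <- treatment_effect("drugX", c("1003" = 1))
  y0 <- synth_spectrum(quiet_profile(), noise = no_noise, grid = g)
  y1 <- synth_spectrum(quiet_profile(), effect = eff, noise = no_noise, grid = g)
  expect_equal(y1, 2 * y0, tolerance = 1e-12)
})

test_that("with jitter off, the median treated/untreated ratio is exactly 2^shift", {
  profile <- quiet_profile(cv = 0)
  patients <- list(
    patient_spec("S-ref", list(list(profile = profile, fraction = 1)),
      c(drugX = "sensitive"), n_cells = 50),
    patient_spec("S-alt", list(list(profile = profile, fraction = 1)),
      c(drugX = "resistant"), n_cells = 50)
  )
  cohort <- synth_cohort(patients,
    effects = list(drugX = treatment_effect("drugX", c("1003" = 0.75))),
    noise = no_noise, seed = 4)
  g <- as.numeric(cohort$spectra$grid)
  at <- which(g == 1003)
  ref <- cohort$metadata$sample_id == "S-ref"
  ratio <- median(cohort$spectra$intensities[!ref, at]) /
    median(cohort$spectra$intensities[ref, at])
  expect_equal(ratio, 2^0.75, tolerance = 1e-9)
})

test_that("the sample mean spectrum tracks the noiseless template", {
  g <- wavenumber_grid()
  profile <- default_phenotype("melanoma", cv = 0.15)
  template <- drop(synth_spectra(1,
    phenotype_profile(profile$name, profile$bands, profile$amplitudes,
      cv = 0, baseline_level = 0),
    noise = no_noise, grid = g))
  nm <- noise_model(additive_noise_sd = 0.02, baseline_coeff_sd = 0,
    spike_rate = 0)
  p0 <- phenotype_profile(profile$name, profile$bands, profile$amplitudes,
    cv = 0.15, baseline_level = 0)
  set.seed(11)
  draws <- synth_spectra(1000, p0, noise = nm, grid = g)
  m <- colMeans(draws)
  se <- apply(draws, 2, sd) / sqrt(nrow(draws))
  # mean amplitude jitter is 1, so the mean spectrum estimates the template;
  # clipping at zero biases only where the template is ~0, so test there too
  # with a tolerance of 3 SE plus a tiny clipping allowance
  expect_true(all(abs(m - template) <= 3 * se + 0.01))
})

test_that("cohorts are bit-identical for identical seeds", {
  a <- two_class_cohort(n_per_class = 30, seed = 9)
  b <- two_class_cohort(n_per_class = 30, seed = 9)
  expect_identical(a$spectra$intensities, b$spectra$intensities)
  expect_identical(a$metadata, b$metadata)
  c <- two_class_cohort(n_per_class = 30, seed = 10)
  expect_false(identical(a$spectra$intensities, c$spectra$intensities))
})

test_that("cohort bookkeeping: counts, labels and ground truth", {
  cohort <- two_class_cohort(n_per_class = 40)
  expect_equal(nrow(cohort$spectra$intensities), 80L)
  expect_setequal(metadata_drugs(cohort$metadata), "drugX")
  expect_identical(
    unique(cohort$metadata$drugX[cohort$metadata$sample_id == "S-alt"]),
    "resistant")
  expect_equal(cohort$ground_truth$effects$drugX$`1003`, 1)
})

test_that("unknown treatment arms are rejected", {
  p <- patient_spec("P1", list(list(profile = quiet_profile(), fraction = 1)),
    c(drugX = "sensitive"), n_cells = 5)
  expect_error(
    synth_cohort(list(p), treatments = c("untreated", "mystery_drug")),
    "mystery_drug")
})

test_that("patient spectrum counts respect the clinical clamp bounds", {
  set.seed(3)
  n <- sample_patient_cell_counts(500)
  expect_true(all(n >= 96 & n <= 1512))
  expect_gt(mean(n), 400)
  expect_lt(mean(n), 650)
})

test_that("subpopulation mixing fractions are recovered within a 99% CI", {
  profile_a <- default_phenotype("melanoma")
  profile_b <- default_phenotype("fibroblast_like")
  n <- 800
  p <- patient_spec("MIX",
    list(list(profile = profile_a, fraction = 0.7),
         list(profile = profile_b, fraction = 0.3)),
    c(drugX = "sensitive"), n_cells = n)
  cohort <- synth_cohort(list(p), effects = list(
    drugX = treatment_effect("drugX", numeric(0))), seed = 5)
  frac <- cohort$ground_truth$patients$MIX$subpop_counts[1] / n
  expect_lt(abs(frac - 0.7), 2.58 * sqrt(0.7 * 0.3 / n))
})

test_that("treated_only scope confines effects to matching treatment arms", {
  profile <- quiet_profile()
  p <- patient_spec("P1", list(list(profile = profile, fraction = 1)),
    c(drugX = "resistant"), n_cells = 40)
  eff <- list(drugX = treatment_effect("drugX", c("1003" = 1)))
  cohort <- synth_cohort(list(p), treatments = c("untreated", "drugX"),
    effects = eff, noise = no_noise, seed = 2,
    effect_scope = "treated_only")
  g <- as.numeric(cohort$spectra$grid)
  at <- which(g == 1003)
  treated <- cohort$metadata$treatment == "drugX"
  expect_equal(unique(cohort$spectra$intensities[treated, at]), 2)
  expect_equal(unique(cohort$spectra$intensities[!treated, at]), 1)
})
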