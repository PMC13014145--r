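test_that("fold change is zero for identical groups and log2(2) for a doubled band", {
  g <- wavenumber_grid(600, 650, 1)
  set.seed(4)
  base <- matrix(runif(20 * length(g), 0.5, 2), 20)
  a <- spectra_matrix(base, g)
  expect_true(all(median_log2_fc(a, a)$log2fc == 0))
  doubled <- base
  at <- 21
  doubled[, at] <- 2 * doubled[, at]
  b <- spectra_matrix(doubled, g)
  fc <- median_log2_fc(a, b, eps = 0)
  expect_equal(fc$log2fc[at], 1, tolerance = 1e-12)
  expect_lt(max(abs(fc$log2fc[-at])), 1e-6)
})

test_that("display values clip at +/-2 while raw log2 fold changes do not", {
  g <- wavenumber_grid(600, 602, 1)
  a <- spectra_matrix(matrix(1, 10, 3), g)
  b <- spectra_matrix(matrix(rep(c(10, 1, 0.1), each = 10), 10), g)
  fc <- median_log2_fc(a, b, eps = 0)
  expect_equal(fc$log2fc, c(log2(10), 0, -log2(10)), tolerance = 1e-9)
  expect_equal(fc$clipped_log2fc, c(2, 0, -2))
})

test_that("swapping group and reference negates the profile exactly", {
  g <- wavenumber_grid(600, 620, 1)
  set.seed(9)
  a <- spectra_matrix(matrix(runif(15 * 21, 0, 2), 15), g)
  b <- spectra_matrix(matrix(runif(15 * 21, 0, 3), 15), g)
  expect_equal(median_log2_fc(a, b)$log2fc, -median_log2_fc(b, a)$log2fc,
    tolerance = 1e-12)
})

test_that("rank-sum worked example: A=(1,2,3) vs B=(4,5,6)", {
  a <- matrix(c(1, 2, 3), ncol = 1)
  b <- matrix(c(4, 5, 6), ncol = 1)
  res <- wilcoxon_per_wavenumber(a, b)
  expect_equal(res$statistic, 6)    # rank sum of group A
  expect_equal(res$p, 0.1)          # exact: 2 * (1/20) * 1 ... enumerated below
  expect_equal(res$p, wilcoxon_enum_oracle(c(1, 2, 3), c(4, 5, 6)))
})

test_that("exact p-values match exhaustive enumeration for small groups", {
  set.seed(12)
  for (rep in 1:20) {
    na <- sample(3:8, 1); nb <- sample(3:8, 1)
    a <- round(rnorm(na), 3); b <- round(rnorm(nb, sample(c(0, 1), 1)), 3)
    if (anyDuplicated(c(a, b))) next
    got <- wilcoxon_per_wavenumber(matrix(a, ncol = 1), matrix(b, ncol = 1))$p
    expect_equal(got, wilcoxon_enum_oracle(a, b), tolerance = 1e-12)
  }
})

test_that("identical groups give p = 1 under midrank handling, constants are flagged", {
  x <- matrix(c(1, 1, 2, 2, 3, 3), ncol = 1)
  res <- wilcoxon_per_wavenumber(x, x)
  expect_equal(res$p, 1)
  const <- matrix(5, 4, 1)
  res2 <- wilcoxon_per_wavenumber(const, const)
  expect_true(res2$degenerate)
  expect_equal(res2$p, 1)
})

test_that("null p-values are approximately uniform and BH controls discoveries", {
  set.seed(33)
  n_wn <- 400
  a <- matrix(rnorm(25 * n_wn), 25)
  b <- matrix(rnorm(25 * n_wn), 25)
  res <- wilcoxon_per_wavenumber(a, b)
  expect_gt(suppressWarnings(stats::ks.test(res$p, "punif"))$p.value, 0.01)
  expect_lt(mean(res$q <= 0.05), 0.02)
})

test_that("highly variant selection recovers a planted band and merges duplicates", {
  cohort <- cached_fixture("sep_imp", two_class_cohort(
    n_per_class = 80, shift = 1.5, seed = 51))
  pre <- preprocess_spectra(cohort$spectra, despike = FALSE)
  ref <- cohort$metadata$sample_id == "S-ref"
  imp <- data.frame(wavenumber = as.numeric(pre$grid),
    dropoff = 0, se = 0)
  imp$dropoff[which.min(abs(imp$wavenumber - 1003))] <- 0.2
  tests <- wilcoxon_per_wavenumber(
    pre$intensities[ref, , drop = FALSE],
    pre$intensities[!ref, , drop = FALSE])
  mean_spec <- colMeans(pre$intensities)
  sel <- select_highly_variant(importance = imp, mean_spectrum = mean_spec,
    wn = as.numeric(pre$grid), tests = tests, k_top = 5)
  expect_true(any(abs(sel$wavenumber - 1003) <= 10))
  # the 1003 pick came from both criteria and appears once, tagged with both
  hit <- sel[abs(sel$wavenumber - 1003) <= 10, ]
  expect_equal(nrow(hit), 1L)
  expect_match(hit$source, "importance")
  expect_true(all(diff(sel$wavenumber) > 0))
  expect_error(
    select_highly_variant(importance = imp[0, ], mean_spectrum = NULL),
    "relax")
})

test_that("barcodes are zero against an identical reference and recover planted shifts", {
  g <- wavenumber_grid(600, 700, 1)
  set.seed(5)
  n <- 150
  base <- matrix(runif(2 * n * length(g), 0.5, 1.5), 2 * n)
  shifted <- base
  at <- which(as.numeric(g) == 650)
  shifted[(n + 1):(2 * n), at] <- 2 * shifted[(n + 1):(2 * n), at]
  sm <- spectra_matrix(rbind(base[1:n, ], shifted[(n + 1):(2 * n), ]), g)
  groups <- rep(c("ctrl_like", "shifted"), each = n)
  bc <- build_barcode(sm, groups, selection = c(650, 620),
    reference_cells = 1:n)
  expect_lt(max(abs(bc["ctrl_like", ])), 1e-9)  # same cells as the reference
  expect_equal(unname(bc["shifted", "650"]), 1, tolerance = 0.2)
  expect_lt(abs(bc["shifted", "620"]), 0.2)
})

test_that("likelihood strata use the 0.8 / 0.2 bounds", {
  s <- likelihood_strata(c(0.9, 0.8, 0.5, 0.2, 0.1))
  expect_identical(s, c("resistant_like", NA, NA, NA, "sensitive_like"))
})
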