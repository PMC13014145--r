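test_that("spectra CSV round-trips cell ids, grid and intensities", {
  g <- wavenumber_grid(600, 650, 1)
  set.seed(7)
  sm <- spectra_matrix(matrix(runif(5 * length(g), 0, 3), 5), g,
    cell_ids = sprintf("c%02d", 1:5))
  md <- cohort_metadata(data.frame(
    cell_id = sm$cell_ids, sample_id = "A", passage = 1,
    treatment = "untreated", drugX = "resistant"
  ), sm)
  dir <- withr::local_tempdir()
  paths <- write_spectra(sm, md, dir)
  back <- read_spectra(paths["spectra"])
  expect_spectra_equal(back, sm, tol = 1e-12)
  md2 <- read_metadata(paths["metadata"], back)
  expect_identical(md2$cell_id, sm$cell_ids)
  expect_identical(md2$drugX, rep("resistant", 5))
})

test_that("an empty spectra matrix round-trips as a header-only file", {
  g <- wavenumber_grid(600, 610, 1)
  sm <- spectra_matrix(matrix(numeric(0), 0, length(g)), g)
  dir <- withr::local_tempdir()
  paths <- write_spectra(sm, out_dir = dir)
  back <- read_spectra(paths["spectra"])
  expect_equal(nrow(back$intensities), 0L)
  expect_equal(as.numeric(back$grid), as.numeric(g))
})

test_that("reading onto a finer grid interpolates linearly and fixes shared points", {
  g2 <- wavenumber_grid(600, 700, 2)
  set.seed(1)
  sm <- spectra_matrix(matrix(runif(3 * length(g2)), 3), g2)
  dir <- withr::local_tempdir()
  paths <- write_spectra(sm, out_dir = dir)
  g1 <- wavenumber_grid(600, 700, 1)
  fine <- read_spectra(paths["spectra"], expected_grid = g1)
  expect_equal(ncol(fine$intensities), 101L)
  shared <- match(as.numeric(g2), as.numeric(g1))
  expect_equal(fine$intensities[, shared], unname(sm$intensities),
    tolerance = 1e-12, ignore_attr = TRUE)
  # midpoints are the mean of the flanking file points
  expect_equal(fine$intensities[, 2],
    (sm$intensities[, 1] + sm$intensities[, 2]) / 2,
    tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("interpolation onto the file's own grid is the identity", {
  g <- wavenumber_grid(600, 640, 2)
  set.seed(2)
  sm <- spectra_matrix(matrix(runif(2 * length(g)), 2), g)
  expect_spectra_equal(interpolate_spectra(sm, g), sm, tol = 1e-12)
})

test_that("grids outside the file's range are refused (no extrapolation)", {
  g <- wavenumber_grid(700, 900, 1)
  sm <- spectra_matrix(matrix(1, 1, length(g)), g)
  expect_error(interpolate_spectra(sm, wavenumber_grid(600, 800, 1)),
    "extrapolation")
})

test_that("invalid spectra inputs fail with the offending cell named", {
  g <- wavenumber_grid(600, 602, 1)
  expect_error(
    spectra_matrix(matrix(c(1, NaN, 3, 4, 5, 6), 2, byrow = TRUE), g,
      cell_ids = c("bad_cell", "ok")),
    "bad_cell.*601"
  )
  expect_error(
    spectra_matrix(matrix(1, 2, 3), g, cell_ids = c("dup", "dup")),
    "duplicate"
  )
  dir <- withr::local_tempdir()
  f <- file.path(dir, "bad.csv")
  writeLines(c("cell_id,600,601,602", "c1,1,oops,3"), f)
  expect_error(read_spectra(f), "c1.*601")
})

test_that("metadata validation enforces coverage, defaults and label constancy", {
  g <- wavenumber_grid(600, 605, 1)
  sm <- spectra_matrix(matrix(1, 3, length(g)), g, cell_ids = c("a", "b", "c"))
  # omitted drug column -> unknown labels
  md <- cohort_metadata(data.frame(cell_id = c("a", "b", "c"),
    sample_id = "S1"), sm, drugs = "drugZ")
  expect_identical(md$drugZ, rep("unknown", 3))
  # missing cell -> error
  expect_error(
    cohort_metadata(data.frame(cell_id = c("a", "b"), sample_id = "S1"), sm),
    "absent from metadata.*c"
  )
  # conflicting labels within a sample -> error naming sample and drug
  expect_error(
    cohort_metadata(data.frame(
      cell_id = c("a", "b", "c"), sample_id = "S1",
      drugX = c("resistant", "sensitive", "resistant")
    ), sm),
    "drugX.*S1"
  )
})
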