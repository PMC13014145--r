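#' Wavenumber grid for the biological fingerprint window
#'
#' A strictly increasing sequence of Raman shifts (cm^-1). The default covers
#' the biological fingerprint region 600-1800 cm^-1 at 1 cm^-1 spacing
#' (1201 points).
#'
#' @param lo,hi inclusive window bounds in cm^-1.
#' @param step nominal spacing in cm^-1 (used only when `values` is NULL).
#' @param values explicit wavenumber vector; overrides `lo`/`hi`/`step`
#'   construction but is still validated against them.
#' @return an object of class `wavenumber_grid`: a numeric vector with
#'   attributes `lo`, `hi`, `step`.
#' @examples
#' g <- wavenumber_grid()
#' length(g) # 1201
#' @export
wavenumber_grid <- function(lo = 600, hi = 1800, step = 1, values = NULL) {
  stop_if_not_scalar_number(lo, "lo")
  stop_if_not_scalar_number(hi, "hi")
  if (lo >= hi) stop("'lo' must be strictly less than 'hi'")
  if (is.null(values)) {
    stop_if_not_scalar_number(step, "step")
    if (step <= 0) stop("'step' must be positive")
    values <- seq(lo, hi, by = step)
  }
  values <- as.numeric(values)
  if (anyNA(values) || any(!is.finite(values))) {
    stop("wavenumber grid contains non-finite values")
  }
  if (any(diff(values) <= 0)) stop("wavenumber grid must be strictly increasing")
  if (values[1L] < lo || values[length(values)] > hi) {
    stop("grid values fall outside [lo, hi]")
  }
  structure(values,
    lo = lo, hi = hi,
    step = if (length(values) > 1L) median(diff(values)) else NA_real_,
    class = "wavenumber_grid"
  )
}

#' @exportS3Method base::print
print.wavenumber_grid <- function(x, ...) {
  cat(sprintf(
    "<wavenumber_grid> %d points, %.6g..%.6g cm^-1 (step ~%.4g)\n",
    length(x), x[1L], x[length(x)], attr(x, "step")
  ))
  invisible(x)
}

grids_equal <- function(a, b, tol = 1e-8) {
  length(a) == length(b) && all(abs(as.numeric(a) - as.numeric(b)) <= tol)
}

#' Single-cell Raman spectra matrix
#'
#' Bundles an intensity matrix (cells x wavenumbers) with unique cell ids and
#' its [wavenumber_grid()]. Intensities must be finite; validation pinpoints
#' the offending cell and wavenumber otherwise.
#'
#' @param intensities numeric matrix, one row per cell.
#' @param grid a [wavenumber_grid()] with as many points as `intensities`
#'   has columns.
#' @param cell_ids character vector of unique cell identifiers; defaults to
#'   rownames or `cell_0001`-style ids.
#' @return an object of class `spectra_matrix` with fields `intensities`,
#'   `grid`, `cell_ids`.
#' @export
spectra_matrix <- function(intensities, grid, cell_ids = NULL) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (!inherits(grid, "wavenumber_grid")) {
    grid <- wavenumber_grid(values = grid, lo = min(grid), hi = max(grid))
  }
  if (ncol(intensities) != length(grid)) {
    stop(sprintf(
      "intensity matrix has %d columns but grid has %d wavenumbers",
      ncol(intensities), length(grid)
    ))
  }
  if (is.null(cell_ids)) {
    cell_ids <- rownames(intensities) %||%
      sprintf("cell_%04d", seq_len(nrow(intensities)))
  }
  cell_ids <- as.character(cell_ids)
  if (length(cell_ids) != nrow(intensities)) {
    stop("length of cell_ids must equal the number of spectra rows")
  }
  if (anyDuplicated(cell_ids)) {
    dup <- unique(cell_ids[duplicated(cell_ids)])
    stop("duplicate cell ids: ", paste(head(dup, 5L), collapse = ", "))
  }
  bad <- which(!is.finite(intensities), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "non-finite intensity for cell '%s' at wavenumber %.6g cm^-1",
      cell_ids[bad[1L, 1L]], as.numeric(grid)[bad[1L, 2L]]
    ))
  }
  dimnames(intensities) <- list(cell_ids, format(as.numeric(grid), trim = TRUE))
  structure(
    list(intensities = intensities, grid = grid, cell_ids = cell_ids),
    class = "spectra_matrix"
  )
}

#' @exportS3Method base::print
print.spectra_matrix <- function(x, ...) {
  cat(sprintf(
    "<spectra_matrix> %d cells x %d wavenumbers (%.6g..%.6g cm^-1)\n",
    nrow(x$intensities), ncol(x$intensities),
    x$grid[1L], x$grid[length(x$grid)]
  ))
  invisible(x)
}

#' @exportS3Method base::dim
dim.spectra_matrix <- function(x) dim(x$intensities)

#' Subset a spectra matrix by cell
#'
#' @param spectra a [spectra_matrix()].
#' @param i logical, integer, or character (cell id) index.
#' @return a `spectra_matrix` with the selected cells.
#' @export
subset_cells <- function(spectra, i) {
  stopifnot(inherits(spectra, "spectra_matrix"))
  if (is.character(i)) i <- match(i, spectra$cell_ids)
  spectra_matrix(spectra$intensities[i, , drop = FALSE], spectra$grid,
    cell_ids = spectra$cell_ids[i]
  )
}
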