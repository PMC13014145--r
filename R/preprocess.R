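#' Crop spectra to the biological fingerprint window
#'
#' Retains wavenumbers with `lo <= w <= hi` (inclusive), preserving order.
#' Defaults to the 600-1800 cm^-1 fingerprint window.
#'
#' @param spectra a [spectra_matrix()].
#' @param lo,hi window bounds in cm^-1.
#' @return a cropped `spectra_matrix`.
#' @export
crop_fingerprint <- function(spectra, lo = 600, hi = 1800) {
  stopifnot(inherits(spectra, "spectra_matrix"))
  if (lo >= hi) stop("'lo' must be less than 'hi'")
  wn <- as.numeric(spectra$grid)
  keep <- which(wn >= lo & wn <= hi)
  if (length(keep) == 0L) {
    stop(sprintf("no wavenumbers in [%g, %g]; grid covers [%g, %g]",
      lo, hi, min(wn), max(wn)))
  }
  grid <- wavenumber_grid(lo = lo, hi = hi, values = wn[keep])
  spectra_matrix(spectra$intensities[, keep, drop = FALSE], grid,
    cell_ids = spectra$cell_ids)
}

#' Remove cosmic-ray spikes
#'
#' A point is treated as a spike when its residual against a running median
#' (window `width`) exceeds `k` times the median absolute deviation of the
#' spectrum's residuals; spikes are replaced by the running-median value.
#'
#' @param spectra a [spectra_matrix()].
#' @param width running-median window (odd integer).
#' @param k MAD multiplier.
#' @return a despiked `spectra_matrix`.
#' @export
despike_spectra <- function(spectra, width = 5, k = 8) {
  stopifnot(inherits(spectra, "spectra_matrix"))
  x <- spectra$intensities
  if (ncol(x) <= width) return(spectra)
  for (i in seq_len(nrow(x))) {
    med <- runmed(x[i, ], width, endrule = "median")
    resid <- x[i, ] - med
    s <- mad(resid)
    # noiseless spectra have zero MAD; fall back to a small fraction of the
    # largest residual so isolated spikes are still caught
    if (s == 0) s <- 1e-3 * max(abs(resid))
    if (s > 0) {
      hit <- resid > k * s
      if (any(hit)) x[i, hit] <- med[hit]
    }
  }
  spectra_matrix(x, spectra$grid, cell_ids = spectra$cell_ids)
}

#' Asymmetric least squares baseline correction
#'
#' Estimates a smooth fluorescence-like baseline per spectrum by iteratively
#' reweighted penalised least squares (Eilers-style asymmetric least squares:
#' second-difference smoothness penalty `lam`, asymmetry `p` down-weighting
#' points above the baseline) and subtracts it. Peaks are preserved; the
#' output may contain small negative residuals in peak-free regions.
#'
#' @param spectra a [spectra_matrix()].
#' @param lam smoothness penalty (`> 0`); larger values give stiffer baselines.
#' @param p asymmetry parameter in (0, 1); the weight of points above the
#'   baseline.
#' @param n_iter number of reweighting iterations.
#' @param return_baseline if TRUE, return the estimated baseline instead of
#'   the corrected spectra.
#' @return a baseline-corrected `spectra_matrix`.
#' @export
baseline_correct <- function(spectra, lam = 1e5, p = 0.01, n_iter = 10,
                             return_baseline = FALSE) {
  stopifnot(inherits(spectra, "spectra_matrix"))
  if (lam <= 0) stop("'lam' must be positive")
  if (p <= 0 || p >= 1) stop("'p' must lie strictly between 0 and 1")
  if (!all(is.finite(spectra$intensities))) stop("non-finite input intensities")
  base <- als_baseline_cpp(spectra$intensities, lam, p, as.integer(n_iter))
  out <- if (return_baseline) base else spectra$intensities - base
  spectra_matrix(out, spectra$grid, cell_ids = spectra$cell_ids)
}

#' Normalise spectra row-wise
#'
#' `"l2"`: each spectrum is scaled to unit Euclidean norm. `"area"`: negatives
#' are clipped to zero and each spectrum is scaled to unit sum.
#'
#' @param spectra a [spectra_matrix()].
#' @param method `"l2"` (default) or `"area"`.
#' @return a normalised `spectra_matrix`.
#' @export
normalize_spectra <- function(spectra, method = c("l2", "area")) {
  stopifnot(inherits(spectra, "spectra_matrix"))
  method <- match.arg(method)
  x <- spectra$intensities
  if (method == "area") {
    x[x < 0] <- 0
    nrm <- rowSums(x)
  } else {
    nrm <- sqrt(rowSums(x^2))
  }
  zero <- which(nrm == 0)
  if (length(zero) > 0L) {
    stop("cannot normalise all-zero spectrum for cell(s): ",
      paste(head(spectra$cell_ids[zero], 5L), collapse = ", "))
  }
  spectra_matrix(x / nrm, spectra$grid, cell_ids = spectra$cell_ids)
}

#' Standard preprocessing pipeline
#'
#' Despike -> crop to the fingerprint window -> asymmetric least squares
#' baseline correction -> row normalisation. Every downstream stage (PCA,
#' classification, differential analysis, clustering, resistance models)
#' consumes the output of this pipeline.
#'
#' @param spectra a raw [spectra_matrix()].
#' @param crop list with `lo`, `hi` (cm^-1).
#' @param baseline list with `lam`, `p`, `n_iter`; set to `NULL` to skip.
#' @param normalize `"l2"`, `"area"`, or `NULL` to skip.
#' @param despike logical; median-filter spike removal before baseline
#'   correction.
#' @return a preprocessed `spectra_matrix`.
#' @export
preprocess_spectra <- function(spectra,
                               crop = list(lo = 600, hi = 1800),
                               baseline = list(lam = 1e5, p = 0.01, n_iter = 10),
                               normalize = "l2",
                               despike = TRUE) {
  stopifnot(inherits(spectra, "spectra_matrix"))
  out <- spectra
  if (isTRUE(despike)) out <- despike_spectra(out)
  if (!is.null(crop)) out <- crop_fingerprint(out, crop$lo %||% 600, crop$hi %||% 1800)
  if (!is.null(baseline)) {
    out <- baseline_correct(out, lam = baseline$lam %||% 1e5,
      p = baseline$p %||% 0.01, n_iter = baseline$n_iter %||% 10)
  }
  if (!is.null(normalize)) out <- normalize_spectra(out, normalize)
  out
}
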