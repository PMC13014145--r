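col_medians <- function(x) apply(x, 2L, median)

#' Median log2 fold change per wavenumber
#'
#' Per-group medians are taken per wavenumber on the signed intensities,
#' negative medians are clipped to zero just before the ratio, and
#' `log2((median_B + eps) / (median_A + eps))` is reported (group B versus
#' reference A). Taking the median before clipping keeps the estimator
#' stable at empty wavenumbers, where baseline-corrected noise straddles
#' zero: the median of the signed residuals is a well-behaved ~0, whereas
#' the median of zero-clipped residuals sits exactly at the clipping edge
#' and flips erratically between 0 and the noise scale. A display copy
#' clipped to \[-2, +2\] is included, matching the conventional heatmap
#' colour-scale bounds.
#'
#' @param groupA reference [spectra_matrix()] (or intensity matrix).
#' @param groupB comparison group on the same grid.
#' @param eps pseudo-intensity guarding against near-zero medians; default
#'   2% of the global maximum intensity, which is of the order of the
#'   per-wavenumber noise floor left by baseline correction. At empty
#'   wavenumbers the zero-clipped noise median sits at the clipping edge, so
#'   a pseudo-intensity well below the noise floor cannot stabilise the
#'   ratio there.
#' @param group,reference identifiers recorded in the result.
#' @return a `fold_change_profile` data.frame: `wavenumber`, `log2fc`,
#'   `clipped_log2fc`.
#' @export
median_log2_fc <- function(groupA, groupB, eps = NULL,
                           group = "group", reference = "reference") {
  ga <- if (inherits(groupA, "spectra_matrix")) groupA$intensities else as.matrix(groupA)
  gb <- if (inherits(groupB, "spectra_matrix")) groupB$intensities else as.matrix(groupB)
  if (nrow(ga) == 0L || nrow(gb) == 0L) stop("both groups must be non-empty")
  if (ncol(ga) != ncol(gb)) stop("groups are not on the same wavenumber grid")
  wn <- if (inherits(groupA, "spectra_matrix")) as.numeric(groupA$grid) else
    seq_len(ncol(ga))
  if (is.null(eps)) eps <- 0.02 * max(ga, gb)
  la <- pmax(col_medians(ga), 0) + eps
  lb <- pmax(col_medians(gb), 0) + eps
  lfc <- log2(lb / la)
  structure(data.frame(
    wavenumber = wn,
    log2fc = lfc,
    clipped_log2fc = pmin(pmax(lfc, -2), 2)
  ), group = group, reference = reference, eps = eps,
  class = c("fold_change_profile", "data.frame"))
}

#' Wilcoxon rank-sum test per wavenumber
#'
#' Two-sided rank-sum test of group B against group A at every wavenumber,
#' with midrank tie handling; exact p-values are used for small tie-free
#' groups (both sizes below 50), the normal approximation with continuity
#' correction otherwise. Q-values are Benjamini-Hochberg adjusted across
#' wavenumbers within this contrast. A wavenumber that is constant across
#' both groups is recorded with `p = 1` and flagged degenerate.
#'
#' @inheritParams median_log2_fc
#' @param fdr_method multiple-testing correction passed to
#'   [stats::p.adjust()] (default `"BH"`).
#' @return data.frame: `wavenumber`, `statistic` (rank sum of group A), `p`,
#'   `q`, `degenerate`.
#' @export
wilcoxon_per_wavenumber <- function(groupA, groupB, fdr_method = "BH") {
  ga <- if (inherits(groupA, "spectra_matrix")) groupA$intensities else as.matrix(groupA)
  gb <- if (inherits(groupB, "spectra_matrix")) groupB$intensities else as.matrix(groupB)
  if (nrow(ga) < 2L || nrow(gb) < 2L) stop("both groups need at least 2 spectra")
  if (ncol(ga) != ncol(gb)) stop("groups are not on the same wavenumber grid")
  wn <- if (inherits(groupA, "spectra_matrix")) as.numeric(groupA$grid) else
    seq_len(ncol(ga))
  na <- nrow(ga)
  p_vals <- numeric(ncol(ga))
  stat <- numeric(ncol(ga))
  degen <- logical(ncol(ga))
  for (j in seq_len(ncol(ga))) {
    a <- ga[, j]; b <- gb[, j]
    r <- rank(c(a, b))  # midranks
    stat[j] <- sum(r[seq_len(na)])
    if (max(c(a, b)) == min(c(a, b))) {
      p_vals[j] <- 1
      degen[j] <- TRUE
    } else {
      ties <- anyDuplicated(c(a, b)) > 0L
      wt <- suppressWarnings(wilcox.test(a, b,
        exact = !ties && na < 50 && nrow(gb) < 50, correct = TRUE))
      p_vals[j] <- wt$p.value
    }
  }
  data.frame(
    wavenumber = wn,
    statistic = stat,
    p = p_vals,
    q = p.adjust(p_vals, method = fdr_method),
    degenerate = degen
  )
}

# local maxima with a simple prominence estimate: peak height minus the
# higher of the two flanking minima down to the nearest taller point
find_prominent_peaks <- function(y, min_prominence) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  is_max <- which(diff(sign(diff(y))) == -2) + 1L
  keep <- logical(length(is_max))
  for (k in seq_along(is_max)) {
    i <- is_max[k]
    l <- i; while (l > 1L && y[l - 1L] <= y[i]) l <- l - 1L
    left_min <- min(y[l:i])
    r <- i; while (r < n && y[r + 1L] <= y[i]) r <- r + 1L
    right_min <- min(y[i:r])
    prom <- y[i] - max(left_min, right_min)
    keep[k] <- prom >= min_prominence
  }
  is_max[keep]
}

#' Select highly variant wavenumbers
#'
#' Union of (1) the top-`k_top` wavenumbers of a perturbation importance
#' curve and (2) prominent peaks of the group-mean spectrum whose Wilcoxon
#' q-value passes `q_max`. Selections within one merge radius (default: the
#' perturbation FWHM) are merged to the strongest member. Each selected
#' wavenumber carries a provenance tag.
#'
#' @param importance an [importance_curve()] (or NULL to skip the importance route).
#' @param mean_spectrum numeric vector of the grand-mean spectrum on `wn`
#'   (or NULL to skip the peak route).
#' @param wn wavenumber vector matching `mean_spectrum`.
#' @param tests result of [wilcoxon_per_wavenumber()] (or NULL: peaks are not
#'   filtered on significance).
#' @param k_top number of importance wavenumbers to keep.
#' @param q_max FDR threshold for peak selection.
#' @param prominence_frac minimum peak prominence as a fraction of the
#'   maximum mean intensity.
#' @param merge_fwhm merge radius in cm^-1.
#' @return data.frame `wavenumber`, `source` (`importance` / `peak` /
#'   `importance+peak`), `score`.
#' @export
select_highly_variant <- function(importance = NULL, mean_spectrum = NULL,
                                  wn = NULL, tests = NULL, k_top = 10,
                                  q_max = 0.05, prominence_frac = 0.05,
                                  merge_fwhm = 15) {
  picks <- list()
  if (!is.null(importance)) {
    ord <- order(importance$dropoff, decreasing = TRUE)
    top <- head(ord, k_top)
    picks$importance <- data.frame(
      wavenumber = importance$wavenumber[top],
      source = rep("importance", length(top)),
      score = importance$dropoff[top]
    )
  }
  if (!is.null(mean_spectrum)) {
    if (is.null(wn)) stop("'wn' is required with 'mean_spectrum'")
    pk <- find_prominent_peaks(mean_spectrum,
      min_prominence = prominence_frac * max(mean_spectrum))
    if (!is.null(tests)) {
      qv <- tests$q[match(round(wn[pk], 6), round(tests$wavenumber, 6))]
      pk <- pk[!is.na(qv) & qv <= q_max]
    }
    if (length(pk) > 0L) {
      picks$peak <- data.frame(
        wavenumber = wn[pk],
        source = "peak",
        score = mean_spectrum[pk] / max(mean_spectrum)
      )
    }
  }
  if (length(picks) == 0L || sum(vapply(picks, nrow, integer(1L))) == 0L) {
    stop("no highly variant wavenumbers selected; relax k_top/q_max/prominence thresholds")
  }
  all <- do.call(rbind, picks)
  all <- all[order(-all$score), , drop = FALSE]
  merged <- all[0, ]
  for (i in seq_len(nrow(all))) {
    near <- which(abs(merged$wavenumber - all$wavenumber[i]) <= merge_fwhm)
    if (length(near) == 0L) {
      merged <- rbind(merged, all[i, ])
    } else if (!grepl(all$source[i], merged$source[near[1L]], fixed = TRUE)) {
      merged$source[near[1L]] <- paste(
        sort(unique(c(merged$source[near[1L]], all$source[i]))),
        collapse = "+")
    }
  }
  merged <- merged[order(merged$wavenumber), , drop = FALSE]
  rownames(merged) <- NULL
  if (nrow(merged) == 0L) {
    stop("no highly variant wavenumbers selected; relax k_top/q_max/prominence thresholds")
  }
  merged
}

#' Build a spectral barcode
#'
#' One row per group (sample, Leiden cluster, or resistance-likelihood
#' stratum), one column per selected wavenumber; each value is the median
#' log2 fold change of the group against the reference cells at that
#' wavenumber.
#'
#' @param spectra a preprocessed [spectra_matrix()].
#' @param groups character/factor vector: group of each cell (cells with `NA`
#'   are ignored).
#' @param selection data.frame from [select_highly_variant()], or a numeric
#'   vector of wavenumbers.
#' @param reference_cells logical or index vector naming the reference cells
#'   (e.g. pooled untreated cells).
#' @param eps pseudo-intensity (see [median_log2_fc()]).
#' @return a `spectral_barcode` matrix (groups x wavenumbers) with attribute
#'   `selection`.
#' @export
build_barcode <- function(spectra, groups, selection, reference_cells,
                          eps = NULL) {
  stopifnot(inherits(spectra, "spectra_matrix"))
  wanted <- if (is.data.frame(selection)) selection$wavenumber else as.numeric(selection)
  if (length(wanted) == 0L) stop("empty wavenumber selection")
  wn <- as.numeric(spectra$grid)
  cols <- vapply(wanted, function(w) which.min(abs(wn - w)), integer(1L))
  x <- spectra$intensities
  if (is.null(eps)) eps <- 0.02 * max(x)
  ref <- x[reference_cells, cols, drop = FALSE]
  if (nrow(ref) == 0L) stop("no reference cells")
  ref_med <- pmax(col_medians(ref), 0) + eps
  groups <- as.character(groups)
  glev <- sort(unique(groups[!is.na(groups)]))
  out <- matrix(NA_real_, length(glev), length(cols),
    dimnames = list(glev, format(wn[cols], trim = TRUE)))
  for (g in glev) {
    rows <- which(!is.na(groups) & groups == g)
    if (length(rows) == 0L) {
      warning("group '", g, "' has no cells; omitted")
      next
    }
    out[g, ] <- log2(
      (pmax(col_medians(x[rows, cols, drop = FALSE]), 0) + eps) / ref_med)
  }
  out <- out[rowSums(is.na(out)) < ncol(out), , drop = FALSE]
  structure(out, selection = selection, eps = eps,
    class = c("spectral_barcode", "matrix"))
}

#' Resistance-likelihood strata for barcode rows
#'
#' Labels cells `"resistant_like"` when their patient-level likelihood
#' exceeds `hi` (default 0.8), `"sensitive_like"` below `lo` (default 0.2),
#' `NA` otherwise.
#'
#' @param likelihood numeric vector of per-cell (patient-inherited)
#'   resistance likelihoods.
#' @param hi,lo strata bounds.
#' @return character vector of strata.
#' @export
likelihood_strata <- function(likelihood, hi = 0.8, lo = 0.2) {
  out <- rep(NA_character_, length(likelihood))
  out[likelihood > hi] <- "resistant_like"
  out[likelihood < lo] <- "sensitive_like"
  out
}
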