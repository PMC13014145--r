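RESERVED_META_COLS <- c("cell_id", "sample_id", "passage", "treatment")
LABEL_LEVELS <- c("resistant", "sensitive", "unknown")

#' Read a spectra CSV
#'
#' The expected layout is one header row (`cell_id` followed by wavenumbers as
#' decimal strings) and one row per cell. If `expected_grid` is supplied and
#' differs from the file's grid, spectra are linearly interpolated onto it;
#' extrapolation outside the file's range is refused.
#'
#' @param path path to a CSV file.
#' @param expected_grid optional [wavenumber_grid()] to interpolate onto.
#' @return a [spectra_matrix()].
#' @export
read_spectra <- function(path, expected_grid = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path, header = TRUE, sep = ",", data.table = FALSE)
  if (ncol(dt) < 2L || names(dt)[1L] != "cell_id") {
    stop("spectra CSV must start with a 'cell_id' column followed by wavenumbers")
  }
  wn <- suppressWarnings(as.numeric(names(dt)[-1L]))
  if (anyNA(wn)) stop("non-numeric wavenumber in header: ",
    names(dt)[-1L][which(is.na(wn))[1L]])
  cell_ids <- as.character(dt[[1L]])
  if (anyDuplicated(cell_ids)) {
    stop("duplicate cell ids in ", path, ": ",
      paste(head(unique(cell_ids[duplicated(cell_ids)]), 5L), collapse = ", "))
  }
  body <- dt[-1L]
  if (nrow(body) == 0L) {
    grid <- wavenumber_grid(lo = min(wn), hi = max(wn), values = wn)
    return(spectra_matrix(matrix(numeric(0), 0L, length(wn)), grid,
      cell_ids = character(0)))
  }
  nonnum <- !vapply(body, is.numeric, logical(1L))
  if (any(nonnum)) {
    j <- which(nonnum)[1L]
    col <- suppressWarnings(as.numeric(body[[j]]))
    i <- which(is.na(col))[1L] %||% 1L
    stop(sprintf(
      "non-numeric intensity for cell '%s' at wavenumber %s",
      cell_ids[i], names(body)[j]
    ))
  }
  mat <- as.matrix(body)
  bad <- which(!is.finite(mat), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "non-finite intensity for cell '%s' at wavenumber %.6g cm^-1",
      cell_ids[bad[1L, 1L]], wn[bad[1L, 2L]]
    ))
  }
  grid <- wavenumber_grid(lo = min(wn), hi = max(wn), values = wn)
  sm <- spectra_matrix(mat, grid, cell_ids = cell_ids)
  if (!is.null(expected_grid) && !grids_equal(sm$grid, expected_grid)) {
    sm <- interpolate_spectra(sm, expected_grid)
  }
  sm
}

#' Interpolate spectra onto a new wavenumber grid
#'
#' Linear interpolation; requesting wavenumbers outside the source grid is an
#' error (no extrapolation). Interpolating onto the spectra's own grid is the
#' identity.
#'
#' @param spectra a [spectra_matrix()].
#' @param grid target [wavenumber_grid()].
#' @return a `spectra_matrix` on `grid`.
#' @export
interpolate_spectra <- function(spectra, grid) {
  stopifnot(inherits(spectra, "spectra_matrix"))
  if (!inherits(grid, "wavenumber_grid")) {
    grid <- wavenumber_grid(values = grid, lo = min(grid), hi = max(grid))
  }
  src <- as.numeric(spectra$grid)
  tgt <- as.numeric(grid)
  if (min(tgt) < min(src) - 1e-9 || max(tgt) > max(src) + 1e-9) {
    stop(sprintf(
      "requested grid [%.6g, %.6g] extends beyond the file grid [%.6g, %.6g]; extrapolation is not supported",
      min(tgt), max(tgt), min(src), max(src)
    ))
  }
  out <- t(apply(spectra$intensities, 1L, function(y) {
    approx(src, y, xout = tgt, method = "linear", rule = 1)$y
  }))
  if (length(tgt) == 1L) out <- matrix(out, ncol = 1L)
  spectra_matrix(out, grid, cell_ids = spectra$cell_ids)
}

#' Read a per-cell metadata TSV
#'
#' Expected columns: `cell_id`, `sample_id`, optionally `passage` and
#' `treatment`; every remaining column is interpreted as a per-drug resistance
#' label column with values `resistant` / `sensitive` / `unknown` (missing or
#' empty entries become `"unknown"`). Every spectra cell must be covered, and
#' the label must be constant within each (sample, drug) pair.
#'
#' @param path path to a TSV file.
#' @param spectra the [spectra_matrix()] the metadata annotates.
#' @param drugs optional character vector of drugs; label columns absent from
#'   the file are filled with `"unknown"`.
#' @return a `cohort_metadata` data.frame (attribute `drugs` lists the label
#'   columns).
#' @export
read_metadata <- function(path, spectra, drugs = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- data.table::fread(path, header = TRUE, sep = "\t", data.table = FALSE,
    colClasses = list(character = "cell_id"))
  cohort_metadata(df, spectra, drugs = drugs)
}

#' Construct and validate cohort metadata
#'
#' @param df data.frame with at least `cell_id` and `sample_id`.
#' @inheritParams read_metadata
#' @return a validated `cohort_metadata` data.frame.
#' @export
cohort_metadata <- function(df, spectra = NULL, drugs = NULL) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in c("cell_id", "sample_id")) {
    if (!col %in% names(df)) stop("metadata is missing required column '", col, "'")
    df[[col]] <- as.character(df[[col]])
  }
  if (!"passage" %in% names(df)) df$passage <- NA_integer_
  if (!"treatment" %in% names(df)) df$treatment <- "untreated"
  df$treatment <- as.character(df$treatment)
  if (anyDuplicated(df$cell_id)) {
    stop("duplicate cell ids in metadata: ",
      paste(head(unique(df$cell_id[duplicated(df$cell_id)]), 5L), collapse = ", "))
  }
  label_cols <- setdiff(names(df), RESERVED_META_COLS)
  if (!is.null(drugs)) {
    for (d in setdiff(drugs, label_cols)) df[[d]] <- "unknown"
    label_cols <- union(label_cols, drugs)
  }
  for (d in label_cols) {
    v <- as.character(df[[d]])
    v[is.na(v) | v == ""] <- "unknown"
    bad <- setdiff(unique(v), LABEL_LEVELS)
    if (length(bad) > 0L) {
      stop(sprintf("invalid resistance label(s) for drug '%s': %s",
        d, paste(bad, collapse = ", ")))
    }
    df[[d]] <- v
    tab <- unique(df[v != "unknown", c("sample_id", d)])
    dup <- tab$sample_id[duplicated(tab$sample_id)]
    if (length(dup) > 0L) {
      stop(sprintf(
        "conflicting '%s' labels within sample(s): %s (the label must be constant per sample and drug)",
        d, paste(unique(dup), collapse = ", ")
      ))
    }
  }
  if (!is.null(spectra)) {
    missing <- setdiff(spectra$cell_ids, df$cell_id)
    if (length(missing) > 0L) {
      stop("cells present in spectra but absent from metadata: ",
        paste(head(missing, 5L), collapse = ", "),
        if (length(missing) > 5L) sprintf(" (and %d more)", length(missing) - 5L) else "")
    }
    df <- df[match(spectra$cell_ids, df$cell_id), , drop = FALSE]
    rownames(df) <- NULL
  }
  structure(df, drugs = label_cols, class = c("cohort_metadata", "data.frame"))
}

#' Drugs annotated in a metadata table
#' @param metadata a `cohort_metadata`.
#' @return character vector of drug label columns.
#' @export
metadata_drugs <- function(metadata) attr(metadata, "drugs")

#' Write spectra (and optionally metadata) to disk
#'
#' Writes `spectra.csv` (and `metadata.tsv`) under `out_dir` with full double
#' precision, so that `read_spectra(write_spectra(x))` reproduces `x` to
#' better than 1e-9 relative intensity.
#'
#' @param spectra a [spectra_matrix()].
#' @param metadata optional `cohort_metadata`.
#' @param out_dir output directory (created if needed).
#' @return named character vector of the files written.
#' @export
write_spectra <- function(spectra, metadata = NULL, out_dir) {
  stopifnot(inherits(spectra, "spectra_matrix"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  spath <- file.path(out_dir, "spectra.csv")
  df <- data.frame(cell_id = spectra$cell_ids, stringsAsFactors = FALSE)
  body <- as.data.frame(spectra$intensities)
  names(body) <- format(as.numeric(spectra$grid), trim = TRUE, digits = 15)
  data.table::fwrite(cbind(df, body), spath, sep = ",")
  paths <- c(spectra = spath)
  if (!is.null(metadata)) {
    mpath <- file.path(out_dir, "metadata.tsv")
    data.table::fwrite(as.data.frame(metadata), mpath, sep = "\t")
    paths <- c(paths, metadata = mpath)
  }
  paths
}
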