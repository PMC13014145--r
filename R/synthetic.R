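#' Define a Raman band
#'
#' @param center band center (cm^-1).
#' @param fwhm full width at half maximum (cm^-1).
#' @param shape line shape: `"voigt"` (default), `"gaussian"`, `"lorentzian"`.
#' @param assignment free-text biochemical assignment.
#' @param eta Lorentzian width fraction for `"voigt"` shapes.
#' @return a `raman_band` list.
#' @export
raman_band <- function(center, fwhm = 12, shape = "voigt", assignment = "", eta = 0.3) {
  stop_if_not_scalar_number(center, "center")
  stop_if_not_scalar_number(fwhm, "fwhm")
  if (fwhm <= 0) stop("'fwhm' must be positive")
  structure(list(center = center, fwhm = fwhm, shape = shape,
    assignment = assignment, eta = eta), class = "raman_band")
}

#' Default cellular band library
#'
#' Sharp fingerprint bands at literature assignments used throughout melanoma
#' and immune-cell Raman work (phenylalanine 1003/1606; nucleic acids
#' 667/748/780/1306/1337/1585; protein 748/1126/1337/1446/1585/1664; lipid
#' 1306/1446; melanin 1385/1580; tryptophan 750; carotenoid 1156 cm^-1), plus
#' broad amide/CH envelope bands that carry the diffuse spectral mass of a
#' real cell so that no single sharp band dominates the total spectral energy.
#' Sharp-band widths default to 12 cm^-1 FWHM, a typical condensed-phase
#' Raman linewidth.
#'
#' @return named list of [raman_band()] objects; names are the band centers.
#' @export
default_band_library <- function() {
  sharp <- list(
    raman_band(667,  assignment = "nucleic acid"),
    raman_band(748,  assignment = "nucleic acid / protein"),
    raman_band(750,  assignment = "tryptophan"),
    raman_band(780,  assignment = "nucleic acid"),
    raman_band(1003, assignment = "phenylalanine"),
    raman_band(1126, assignment = "protein"),
    raman_band(1156, assignment = "carotenoid"),
    raman_band(1306, assignment = "nucleic acid / lipid"),
    raman_band(1337, assignment = "nucleic acid / protein"),
    raman_band(1385, assignment = "melanin"),
    raman_band(1446, assignment = "protein / lipid"),
    raman_band(1580, assignment = "melanin"),
    raman_band(1585, assignment = "nucleic acid / protein"),
    raman_band(1606, assignment = "phenylalanine"),
    raman_band(1664, assignment = "protein (amide I)")
  )
  broad <- list(
    raman_band(855,  fwhm = 40, assignment = "protein CH / proline envelope"),
    raman_band(1095, fwhm = 60, assignment = "C-C / PO2- envelope"),
    raman_band(1260, fwhm = 50, assignment = "amide III envelope"),
    raman_band(1450, fwhm = 30, assignment = "CH deformation envelope"),
    raman_band(1660, fwhm = 45, assignment = "amide I envelope")
  )
  bands <- c(sharp, broad)
  names(bands) <- vapply(bands, function(b) format(b$center), character(1L))
  bands
}

#' Phenotype spectral profile
#'
#' A generative description of one cell phenotype: a band library with mean
#' peak amplitudes (a.u.), a per-cell multiplicative amplitude coefficient of
#' variation, and a mean fluorescence-like baseline level.
#'
#' @param name phenotype name.
#' @param bands named list of [raman_band()]s.
#' @param amplitudes numeric vector of mean peak amplitudes, one per band
#'   (recycled names from `bands` if unnamed).
#' @param cv per-cell lognormal amplitude coefficient of variation (scalar or
#'   per band). The lognormal jitter has mean 1, so `amplitudes` are the mean
#'   peak heights.
#' @param baseline_level mean fluorescence-like background amplitude (a.u.).
#' @return a `phenotype_profile` list.
#' @export
phenotype_profile <- function(name, bands, amplitudes, cv = 0.15,
                              baseline_level = 0.4) {
  stopifnot(length(bands) == length(amplitudes))
  amplitudes <- as.numeric(amplitudes)
  if (any(amplitudes < 0)) stop("band amplitudes must be non-negative")
  cv <- rep_len(as.numeric(cv), length(bands))
  if (any(cv < 0)) stop("'cv' must be non-negative")
  if (baseline_level < 0) stop("'baseline_level' must be non-negative")
  if (is.null(names(bands))) {
    names(bands) <- vapply(bands, function(b) format(b$center), character(1L))
  }
  names(amplitudes) <- names(bands)
  structure(list(name = name, bands = bands, amplitudes = amplitudes,
    cv = cv, baseline_level = baseline_level), class = "phenotype_profile")
}

#' Built-in phenotype profiles
#'
#' `"melanoma"`: melanin-bearing tumor-cell profile. `"fibroblast_like"`:
#' collagen/protein-rich, melanin-poor profile (the passage-drift phenotype).
#' `"macrophage"`: tryptophan- and nucleic-acid-elevated immune profile.
#' Amplitudes are package design choices on an arbitrary intensity scale; only
#' the band centers are literature values.
#'
#' @param name one of `"melanoma"`, `"fibroblast_like"`, `"macrophage"`.
#' @param cv per-cell amplitude coefficient of variation.
#' @return a [phenotype_profile()].
#' @export
default_phenotype <- function(name = c("melanoma", "fibroblast_like", "macrophage"),
                              cv = 0.15) {
  name <- match.arg(name)
  bands <- default_band_library()
  base <- c(
    "667" = 0.55, "748" = 0.75, "750" = 0.45, "780" = 0.65, "1003" = 0.60,
    "1126" = 0.60, "1156" = 0.50, "1306" = 0.70, "1337" = 0.75, "1385" = 0.45,
    "1446" = 1.00, "1580" = 0.60, "1585" = 0.65, "1606" = 0.55, "1664" = 0.85,
    "855" = 0.50, "1095" = 0.55, "1260" = 0.65, "1450" = 0.80, "1660" = 0.90
  )
  amp <- base[names(bands)]
  if (name == "fibroblast_like") {
    amp[c("1385", "1580")] <- c(0.15, 0.25)
    amp[c("855", "1260", "1446")] <- c(0.75, 0.85, 1.10)
    amp["780"] <- 0.50
  } else if (name == "macrophage") {
    amp[c("750", "780", "1337")] <- c(0.65, 0.80, 0.90)
    amp[c("1385", "1580")] <- c(0.10, 0.20)
  }
  phenotype_profile(name, bands, amp, cv = cv)
}

#' Treatment effect on band intensities
#'
#' Multiplicative band intensity changes (as log2 shifts) carried by the
#' surviving cells of resistant samples.
#'
#' @param drug drug name.
#' @param band_log2_shifts named numeric vector; names are band centers
#'   (matching band library names), values are log2 fold changes. An empty
#'   vector means no effect.
#' @return a `treatment_effect` list.
#' @export
treatment_effect <- function(drug, band_log2_shifts = numeric(0)) {
  shifts <- as.numeric(band_log2_shifts)
  names(shifts) <- names(band_log2_shifts)
  if (length(shifts) > 0L && (is.null(names(shifts)) || any(names(shifts) == ""))) {
    stop("band_log2_shifts must be a named vector (names = band centers)")
  }
  if (any(!is.finite(shifts))) stop("band_log2_shifts must be finite")
  structure(list(drug = drug, band_log2_shifts = shifts),
    class = "treatment_effect")
}

#' Measurement noise model
#'
#' @param additive_noise_sd Gaussian detector noise standard deviation (a.u.).
#' @param baseline_poly_degree degree of the random polynomial multiplying the
#'   fluorescence-like background.
#' @param baseline_coeff_sd standard deviation of the random polynomial
#'   coefficients (relative to the baseline level).
#' @param spike_rate expected cosmic-ray spikes per spectrum (Poisson).
#' @return a `noise_model` list.
#' @export
noise_model <- function(additive_noise_sd = 0.02, baseline_poly_degree = 3,
                        baseline_coeff_sd = 0.1, spike_rate = 0.02) {
  if (additive_noise_sd < 0) stop("'additive_noise_sd' must be non-negative")
  if (spike_rate < 0) stop("'spike_rate' must be non-negative")
  structure(list(
    additive_noise_sd = additive_noise_sd,
    baseline_poly_degree = as.integer(baseline_poly_degree),
    baseline_coeff_sd = baseline_coeff_sd,
    spike_rate = spike_rate
  ), class = "noise_model")
}

# n_bands x n_wavenumbers peak-normalised shape matrix
profile_shape_matrix <- function(profile, grid) {
  x <- as.numeric(grid)
  lo <- x[1L]; hi <- x[length(x)]
  centers <- vapply(profile$bands, `[[`, numeric(1L), "center")
  if (any(centers < lo | centers > hi)) {
    stop("band center(s) outside the wavenumber grid: ",
      paste(centers[centers < lo | centers > hi], collapse = ", "))
  }
  t(vapply(profile$bands, band_shape, numeric(length(x)), x = x))
}

# mean amplitudes after applying a treatment effect's log2 shifts
effective_amplitudes <- function(profile, effect = NULL) {
  amps <- profile$amplitudes
  if (!is.null(effect) && length(effect$band_log2_shifts) > 0L) {
    hit <- names(effect$band_log2_shifts)
    unknown <- setdiff(hit, names(amps))
    if (length(unknown) > 0L) {
      stop("effect targets band(s) absent from the profile: ",
        paste(unknown, collapse = ", "))
    }
    amps[hit] <- amps[hit] * 2^effect$band_log2_shifts
  }
  amps
}

#' Simulate a block of single-cell spectra from one phenotype
#'
#' Each spectrum is a sum over bands of (mean amplitude x per-cell lognormal
#' jitter x 2^effect-shift x peak-normalised band shape), plus a random
#' smooth polynomial baseline, Gaussian detector noise, and Poisson-count
#' cosmic-ray spikes (amplitude 10x the tallest band, one grid point wide);
#' negative values are clipped to zero. Draws from the current RNG state; use
#' [with_seed()]-style seeding (or `set.seed`) for reproducibility.
#'
#' @param n number of cells.
#' @param profile a [phenotype_profile()].
#' @param effect optional [treatment_effect()].
#' @param noise a [noise_model()].
#' @param grid a [wavenumber_grid()].
#' @param shapes optional precomputed [profile_shape_matrix] (internal reuse).
#' @return numeric matrix `n x length(grid)`.
#' @export
synth_spectra <- function(n, profile, effect = NULL, noise = noise_model(),
                          grid = wavenumber_grid(), shapes = NULL) {
  stopifnot(inherits(profile, "phenotype_profile"), n >= 0)
  p <- length(grid)
  if (n == 0L) return(matrix(numeric(0), 0L, p))
  if (is.null(shapes)) shapes <- profile_shape_matrix(profile, grid)
  amps <- effective_amplitudes(profile, effect)
  nb <- length(amps)
  sdlog <- sqrt(log(1 + profile$cv^2))
  jitter <- matrix(1, n, nb)
  pos <- sdlog > 0
  if (any(pos)) {
    jitter[, pos] <- exp(matrix(
      rnorm(n * sum(pos)), n, sum(pos)
    ) * rep(sdlog[pos], each = n) - rep(sdlog[pos]^2 / 2, each = n))
  }
  amat <- jitter * rep(amps, each = n)
  out <- amat %*% shapes
  if (profile$baseline_level > 0) {
    tt <- seq(0, 1, length.out = p)
    deg <- noise$baseline_poly_degree
    coef <- matrix(rnorm(n * deg, sd = noise$baseline_coeff_sd), n, deg)
    basis <- outer(tt, seq_len(deg), `^`)
    out <- out + profile$baseline_level * (1 + coef %*% t(basis))
  }
  if (noise$additive_noise_sd > 0) {
    out <- out + matrix(rnorm(n * p, sd = noise$additive_noise_sd), n, p)
  }
  if (noise$spike_rate > 0) {
    k <- rpois(n, noise$spike_rate)
    amp_spike <- 10 * max(profile$amplitudes)
    for (i in which(k > 0)) {
      out[i, sample.int(p, k[i], replace = TRUE)] <- amp_spike
    }
  }
  out[out < 0] <- 0
  out
}

#' Simulate a single spectrum
#'
#' @inheritParams synth_spectra
#' @return numeric intensity vector of length `length(grid)`.
#' @export
synth_spectrum <- function(profile, effect = NULL, noise = noise_model(),
                           grid = wavenumber_grid()) {
  drop(synth_spectra(1L, profile, effect, noise, grid))
}

#' Patient specification for cohort simulation
#'
#' @param patient_id unique identifier (e.g. `"PAT-52"`).
#' @param subpopulations list of `list(profile = <phenotype_profile>,
#'   fraction = <number>)`; fractions must sum to 1.
#' @param resistance_labels named character vector mapping drug ->
#'   `"resistant"`/`"sensitive"`.
#' @param n_cells number of spectra for this patient.
#' @param passage passage number recorded in metadata.
#' @return a `patient_spec` list.
#' @export
patient_spec <- function(patient_id, subpopulations, resistance_labels,
                         n_cells, passage = 0L) {
  fr <- vapply(subpopulations, `[[`, numeric(1L), "fraction")
  if (abs(sum(fr) - 1) > 1e-8) stop("subpopulation fractions must sum to 1")
  if (n_cells < 1) stop("'n_cells' must be >= 1")
  labels <- as.character(resistance_labels)
  names(labels) <- names(resistance_labels)
  bad <- setdiff(unique(labels), c("resistant", "sensitive"))
  if (length(bad) > 0L) stop("invalid resistance label(s): ", paste(bad, collapse = ", "))
  structure(list(patient_id = patient_id, subpopulations = subpopulations,
    resistance_labels = labels, n_cells = as.integer(n_cells),
    passage = as.integer(passage)), class = "patient_spec")
}

#' Simulate a multi-patient single-cell Raman cohort
#'
#' Generates spectra for every patient, assigns treatments, and plants
#' per-drug resistance signatures. Under the default `"all_cells"` scope a
#' resistant patient's cells all carry that drug's band shifts (the surviving
#' persister-state premise: resistance-linked biochemistry is present before
#' and after exposure); under `"treated_only"` the shift is applied only to
#' cells whose own treatment matches the drug. Sensitive patients' cells are
#' always drawn without shifts. Fully reproducible from `seed`.
#'
#' @param patients list of [patient_spec()]s with unique ids.
#' @param treatments character vector of treatment arms (each cell is assigned
#'   one, round-robin); must be `"untreated"` or a name of `effects`.
#' @param effects named list of [treatment_effect()]s, keyed by drug.
#' @param noise a [noise_model()].
#' @param grid a [wavenumber_grid()].
#' @param seed integer seed.
#' @param effect_scope `"all_cells"` (default) or `"treated_only"`.
#' @return list with elements `spectra` ([spectra_matrix()]), `metadata`
#'   (`cohort_metadata`), `ground_truth` (planted shifts, labels, counts).
#' @export
synth_cohort <- function(patients, treatments = "untreated",
                         effects = list(), noise = noise_model(),
                         grid = wavenumber_grid(), seed = 0,
                         effect_scope = c("all_cells", "treated_only")) {
  effect_scope <- match.arg(effect_scope)
  ids <- vapply(patients, `[[`, character(1L), "patient_id")
  if (anyDuplicated(ids)) stop("patient ids must be unique")
  unknown <- setdiff(treatments, c("untreated", names(effects)))
  if (length(unknown) > 0L) {
    stop("unknown drug(s) in treatments (no treatment_effect defined): ",
      paste(unknown, collapse = ", "))
  }
  drugs <- union(names(effects),
    unlist(lapply(patients, function(p) names(p$resistance_labels))))
  shape_cache <- new.env(parent = emptyenv())
  get_shapes <- function(profile) {
    key <- paste0(profile$name, "#", length(profile$bands))
    if (is.null(shape_cache[[key]])) {
      shape_cache[[key]] <- profile_shape_matrix(profile, grid)
    }
    shape_cache[[key]]
  }
  with_seed(seed, {
    blocks <- list()
    meta <- list()
    truth_patients <- list()
    for (pat in patients) {
      n <- pat$n_cells
      fr <- vapply(pat$subpopulations, `[[`, numeric(1L), "fraction")
      sub_idx <- sample.int(length(fr), n, replace = TRUE, prob = fr)
      treat <- rep(treatments, length.out = n)
      res_drugs <- names(pat$resistance_labels)[pat$resistance_labels == "resistant"]
      res_drugs <- intersect(res_drugs, names(effects))
      # which planted shifts does each cell carry
      cell_shift_key <- if (effect_scope == "all_cells") {
        rep(paste(sort(res_drugs), collapse = "\r"), n)
      } else {
        ifelse(treat %in% res_drugs, treat, "")
      }
      mat <- matrix(NA_real_, n, length(grid))
      for (s in unique(sub_idx)) {
        profile <- pat$subpopulations[[s]]$profile
        shapes <- get_shapes(profile)
        for (key in unique(cell_shift_key[sub_idx == s])) {
          sel <- which(sub_idx == s & cell_shift_key == key)
          eff <- if (nzchar(key)) {
            combined <- numeric(0)
            for (d in strsplit(key, "\r", fixed = TRUE)[[1L]]) {
              sh <- effects[[d]]$band_log2_shifts
              all_b <- union(names(combined), names(sh))
              combined <- setNames(
                ifelse(all_b %in% names(combined), combined[all_b], 0) +
                  ifelse(all_b %in% names(sh), sh[all_b], 0),
                all_b
              )
            }
            treatment_effect("combined", combined)
          } else {
            NULL
          }
          mat[sel, ] <- synth_spectra(length(sel), profile, eff, noise, grid,
            shapes = shapes)
        }
      }
      cell_ids <- sprintf("%s_c%04d", pat$patient_id, seq_len(n))
      blocks[[pat$patient_id]] <- mat
      md <- data.frame(
        cell_id = cell_ids, sample_id = pat$patient_id,
        passage = pat$passage, treatment = treat,
        stringsAsFactors = FALSE
      )
      for (d in drugs) {
        md[[d]] <- unname(pat$resistance_labels[d] %||% "unknown")
        md[[d]][is.na(md[[d]])] <- "unknown"
      }
      meta[[pat$patient_id]] <- md
      truth_patients[[pat$patient_id]] <- list(
        n_cells = n,
        subpop_fractions = fr,
        subpop_counts = tabulate(sub_idx, nbins = length(fr)),
        resistance_labels = as.list(pat$resistance_labels)
      )
    }
    intensities <- do.call(rbind, blocks)
    metadata <- cohort_metadata(do.call(rbind, meta), drugs = drugs)
    spectra <- spectra_matrix(intensities, grid,
      cell_ids = metadata$cell_id)
    ground_truth <- list(
      seed = seed,
      effect_scope = effect_scope,
      effects = lapply(effects, function(e) as.list(e$band_log2_shifts)),
      noise = unclass(noise),
      patients = truth_patients
    )
    list(spectra = spectra, metadata = metadata, ground_truth = ground_truth)
  })
}

#' Draw per-patient spectrum counts like a clinical Raman cohort
#'
#' Lognormal counts with mean about 522 spectra per patient, clamped to the
#' observed clinical range [96, 1512].
#'
#' @param n_patients number of patients.
#' @param mean_cells target mean count.
#' @param min_cells,max_cells clamp bounds.
#' @param sdlog lognormal shape parameter.
#' @return integer vector of counts (draws from the current RNG state).
#' @export
sample_patient_cell_counts <- function(n_patients, mean_cells = 522,
                                       min_cells = 96, max_cells = 1512,
                                       sdlog = 0.5) {
  raw <- rlnorm(n_patients, meanlog = log(mean_cells) - sdlog^2 / 2, sdlog = sdlog)
  pmin(pmax(as.integer(round(raw)), min_cells), max_cells)
}
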