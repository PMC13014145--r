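#' Mini-patient aggregation configuration
#'
#' A mini patient is a resampled subset of one patient's single-cell spectra;
#' per-spectrum classifier probabilities are aggregated within each subset
#' and the patient's resistance likelihood is the fraction of subsets called
#' resistant.
#'
#' @param n_mini number of mini patients per patient (default 25000).
#' @param subset_size spectra per mini patient (default 50; capped at the
#'   patient's spectrum count when sampling with replacement).
#' @param sampling `"with_replacement"` (default) or `"without_replacement"`.
#' @param aggregation `"mean_probability"` (default) or `"majority_vote"`.
#' @param spectrum_threshold probability cutoff applied inside a mini patient
#'   (default 0.5).
#' @param seed integer seed for the resampling.
#' @return a `mini_patient_config` list.
#' @export
mini_patient_config <- function(n_mini = 25000, subset_size = 50,
                                sampling = c("with_replacement",
                                             "without_replacement"),
                                aggregation = c("mean_probability",
                                                "majority_vote"),
                                spectrum_threshold = 0.5, seed = 0) {
  sampling <- match.arg(sampling)
  aggregation <- match.arg(aggregation)
  if (n_mini < 1) stop("'n_mini' must be >= 1")
  if (subset_size < 1) stop("'subset_size' must be >= 1")
  if (spectrum_threshold < 0 || spectrum_threshold > 1) {
    stop("'spectrum_threshold' must lie in [0, 1]")
  }
  structure(list(n_mini = as.integer(n_mini),
    subset_size = as.integer(subset_size), sampling = sampling,
    aggregation = aggregation, spectrum_threshold = spectrum_threshold,
    seed = as.integer(seed)), class = "mini_patient_config")
}

#' Patient resistance likelihood from per-spectrum probabilities
#'
#' Draws `n_mini` subsets of `subset_size` spectra, aggregates the
#' per-spectrum resistance probabilities within each subset (mean by
#' default), calls a subset resistant when its aggregate exceeds
#' `spectrum_threshold`, and returns the fraction of resistant subsets.
#' Reproducible from `config$seed`; subset indices depend only on the seed,
#' so raising any probability can never lower the likelihood. In the
#' degenerate case `subset_size = 1` with mean aggregation the likelihood is
#' computed analytically as the fraction of spectra above the threshold.
#'
#' @param probabilities per-spectrum resistance probabilities in \[0, 1\].
#' @param config a [mini_patient_config()].
#' @return list: `likelihood`, `n_spectra`, `subset_size`, and `distribution`
#'   (mean and quantiles of the subset aggregates).
#' @export
patient_likelihood <- function(probabilities, config = mini_patient_config()) {
  p <- as.numeric(probabilities)
  n <- length(p)
  if (n < 1L) stop("need at least one probability")
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  m <- config$subset_size
  if (config$sampling == "without_replacement" && m > n) {
    stop(sprintf(
      "subset_size (%d) exceeds the number of spectra (%d) when sampling without replacement",
      m, n))
  }
  m <- min(m, n)
  thr <- config$spectrum_threshold
  if (m == 1L && config$aggregation == "mean_probability") {
    agg_summary <- c(mean = mean(p),
      quantile(p, c(0.05, 0.25, 0.5, 0.75, 0.95)))
    return(list(likelihood = mean(p > thr), n_spectra = n, subset_size = 1L,
      exact = TRUE, distribution = agg_summary))
  }
  agg <- with_seed(derive_seed(config$seed, "mini_patients"), {
    if (config$sampling == "with_replacement") {
      idx <- matrix(sample.int(n, config$n_mini * m, replace = TRUE),
        config$n_mini, m)
    } else {
      idx <- t(vapply(seq_len(config$n_mini),
        function(i) sample.int(n, m, replace = FALSE), integer(m)))
    }
    if (config$aggregation == "mean_probability") {
      rowMeans(matrix(p[idx], config$n_mini, m))
    } else {
      rowMeans(matrix(p[idx] > thr, config$n_mini, m))
    }
  })
  calls <- if (config$aggregation == "mean_probability") agg > thr else agg > 0.5
  list(
    likelihood = mean(calls),
    n_spectra = n,
    subset_size = m,
    exact = FALSE,
    distribution = c(mean = mean(agg),
      quantile(agg, c(0.05, 0.25, 0.5, 0.75, 0.95)))
  )
}

#' Train a per-drug resistance model
#'
#' Every spectrum of a sample labelled for `drug` inherits that sample's
#' resistant/sensitive label; a PCA transform and a class-weighted
#' probability random forest are then fit on those training spectra only
#' (cells labelled `"unknown"` never enter training).
#'
#' @param spectra a preprocessed [spectra_matrix()].
#' @param metadata a `cohort_metadata` covering the spectra.
#' @param drug drug name (a metadata label column).
#' @param spec a [classifier_spec()].
#' @param pca list of [pca_fit()] options; components default to capturing
#'   95% of variance, capped at 50.
#' @param config a [mini_patient_config()].
#' @param decision_cutoff patient-level likelihood cutoff (default 0.5).
#' @return a `resistance_model`.
#' @export
train_resistance_model <- function(spectra, metadata, drug,
                                   spec = classifier_spec(),
                                   pca = list(variance_target = 0.95,
                                              max_components = 50),
                                   config = mini_patient_config(),
                                   decision_cutoff = 0.5) {
  stopifnot(inherits(spectra, "spectra_matrix"))
  if (!identical(metadata$cell_id, spectra$cell_ids)) {
    stop("metadata rows are not aligned with the spectra; rebuild with cohort_metadata(df, spectra)")
  }
  if (!drug %in% metadata_drugs(metadata)) {
    stop("no label column for drug '", drug, "' in metadata")
  }
  lab <- metadata[[drug]]
  keep <- which(lab %in% c("resistant", "sensitive"))
  if (length(keep) == 0L) stop("no labelled training spectra for drug '", drug, "'")
  y <- factor(lab[keep], levels = c("resistant", "sensitive"))
  if (nlevels(droplevels(y)) < 2L) {
    stop("training for drug '", drug,
      "' needs at least one resistant and one sensitive sample")
  }
  train <- subset_cells(spectra, keep)
  red <- pca_fit(train, variance_target = pca$variance_target %||% 0.95,
    max_components = pca$max_components %||% 50,
    fitted_on = paste0("resistance_training_", drug))
  classifier <- train_final(red$scores, y, spec)
  structure(list(
    drug = drug,
    pca = red,
    classifier = classifier,
    config = config,
    decision_cutoff = decision_cutoff,
    training_patients = sort(unique(metadata$sample_id[keep])),
    n_training_spectra = length(keep)
  ), class = "resistance_model")
}

#' @exportS3Method base::print
print.resistance_model <- function(x, ...) {
  cat(sprintf(
    "<resistance_model> drug '%s': %d training spectra from %d samples, %d PCs, cutoff %.2f\n",
    x$drug, x$n_training_spectra, length(x$training_patients),
    x$pca$n_components, x$decision_cutoff
  ))
  invisible(x)
}

#' Per-spectrum resistance probabilities
#'
#' @param model a `resistance_model`.
#' @param spectra preprocessed spectra on the model's wavenumber grid.
#' @return numeric vector: probability of the resistant class per spectrum.
#' @export
spectrum_probabilities <- function(model, spectra) {
  stopifnot(inherits(model, "resistance_model"))
  scores <- pca_transform(model$pca, spectra)
  unname(predict_probabilities(model$classifier, scores)[, "resistant"])
}

#' Determine a patient's resistance to one drug
#'
#' Runs the mini-patient aggregation on the patient's spectra and thresholds
#' the resulting likelihood at the model's decision cutoff: the label is
#' resistant iff likelihood is strictly greater than the cutoff (a tie is
#' called sensitive). Evaluating a training patient is refused unless
#' explicitly overridden, to keep determinations honest.
#'
#' @param model a `resistance_model`.
#' @param spectra the patient's preprocessed spectra.
#' @param patient_id patient identifier.
#' @param allow_training_patient set TRUE to evaluate a patient the model was
#'   trained on.
#' @return a `patient_call` list: `patient_id`, `drug`, `likelihood`,
#'   `label`, `n_spectra`, `distribution`.
#' @export
determine_resistance <- function(model, spectra, patient_id,
                                 allow_training_patient = FALSE) {
  stopifnot(inherits(model, "resistance_model"))
  if (patient_id %in% model$training_patients && !allow_training_patient) {
    stop("patient '", patient_id, "' is in the model's training set; ",
      "set allow_training_patient = TRUE to evaluate it anyway")
  }
  probs <- spectrum_probabilities(model, spectra)
  pl <- patient_likelihood(probs, model$config)
  structure(list(
    patient_id = patient_id,
    drug = model$drug,
    likelihood = pl$likelihood,
    label = if (pl$likelihood > model$decision_cutoff) "resistant" else "sensitive",
    cutoff = model$decision_cutoff,
    n_spectra = pl$n_spectra,
    distribution = pl$distribution
  ), class = "patient_call")
}

#' Optimise per-drug decision cutoffs
#'
#' Grid search over cutoffs 0.00, 0.01, ..., 1.00 maximising balanced
#' accuracy of the training calls (label = resistant iff likelihood >
#' cutoff); among ties the cutoff closest to 0.5 is returned (then the
#' smaller one). Drugs with only one true label keep the default 0.5 with a
#' warning, as does a drug whose best achievable balanced accuracy is at or
#' below chance.
#'
#' @param calls data.frame with columns `drug`, `likelihood`, `true_label`
#'   (`"resistant"`/`"sensitive"`).
#' @return named numeric vector of cutoffs per drug.
#' @export
optimize_cutoffs <- function(calls) {
  stopifnot(all(c("drug", "likelihood", "true_label") %in% names(calls)))
  grid <- seq(0, 1, by = 0.01)
  out <- c()
  for (d in unique(calls$drug)) {
    sub <- calls[calls$drug == d, ]
    is_res <- sub$true_label == "resistant"
    if (!any(is_res) || all(is_res)) {
      warning("drug '", d, "': only one true label; keeping cutoff 0.5")
      out[d] <- 0.5
      next
    }
    bacc <- vapply(grid, function(ct) {
      pred_res <- sub$likelihood > ct
      (mean(pred_res[is_res]) + mean(!pred_res[!is_res])) / 2
    }, numeric(1L))
    best <- which(bacc == max(bacc))
    pick <- best[order(abs(grid[best] - 0.5), grid[best])][1L]
    if (max(bacc) <= 0.5) {
      warning("drug '", d, "': best balanced accuracy is at or below chance (",
        round(max(bacc), 3), ")")
    }
    out[d] <- grid[pick]
  }
  out
}

#' Cohort-level resistance evaluation
#'
#' For every (patient, drug) pair with a known label, trains a per-drug model
#' on the remaining labelled patients (leave-one-patient-out; PCA and forest
#' refit per holdout, so the evaluated patient never leaks into training) or
#' on a fixed training split, then determines the held-out patient's
#' resistance. Pairs whose training set would retain fewer than two patients
#' or a single class are marked not evaluable and excluded from the accuracy
#' denominator.
#'
#' @param spectra preprocessed [spectra_matrix()].
#' @param metadata `cohort_metadata`.
#' @param drugs drugs to evaluate (default: all annotated).
#' @param protocol `"leave_one_patient_out"` (default) or `"fixed_split"`.
#' @param train_patients patient ids used for training under
#'   `"fixed_split"`.
#' @param spec a [classifier_spec()].
#' @param pca list of [pca_fit()] options.
#' @param config a [mini_patient_config()]; the resampling seed is varied
#'   deterministically per (drug, patient).
#' @param cutoffs optional named per-drug decision cutoffs (default 0.5).
#' @param match_treatment_arm if TRUE, each drug's model is trained and
#'   evaluated on the cells of that drug's own treatment arm
#'   (`metadata$treatment == drug`) — the standard persister-screening
#'   design, which isolates the drug's signature from whatever other
#'   resistances a patient carries. Default FALSE (use every labelled
#'   cell).
#' @param prob_override optional `function(n_spectra, drug, patient_id)`
#'   returning per-spectrum probabilities, replacing the trained classifier
#'   (null-harness hook for calibration experiments).
#' @return a `cohort_evaluation`: `calls` data.frame (patient, drug,
#'   n_spectra, likelihood, cutoff, label, true_label, correct, evaluable),
#'   `accuracy`, `per_drug_accuracy`, `likelihood_matrix`.
#' @export
evaluate_cohort <- function(spectra, metadata, drugs = NULL,
                            protocol = c("leave_one_patient_out", "fixed_split"),
                            train_patients = NULL,
                            spec = classifier_spec(),
                            pca = list(variance_target = 0.95,
                                       max_components = 50),
                            config = mini_patient_config(),
                            cutoffs = NULL,
                            match_treatment_arm = FALSE,
                            prob_override = NULL) {
  protocol <- match.arg(protocol)
  stopifnot(inherits(spectra, "spectra_matrix"))
  if (!identical(metadata$cell_id, spectra$cell_ids)) {
    stop("metadata rows are not aligned with the spectra; rebuild with cohort_metadata(df, spectra)")
  }
  drugs <- drugs %||% metadata_drugs(metadata)
  rows <- list()
  for (d in drugs) {
    lab <- metadata[[d]]
    in_arm <- if (match_treatment_arm) metadata$treatment == d else
      rep(TRUE, nrow(metadata))
    labelled <- lab %in% c("resistant", "sensitive") & in_arm
    pts <- sort(unique(metadata$sample_id[labelled]))
    eval_pts <- if (protocol == "fixed_split") {
      if (is.null(train_patients)) stop("'fixed_split' requires train_patients")
      setdiff(pts, train_patients)
    } else {
      pts
    }
    cutoff <- unname((cutoffs[d] %||% NA_real_))
    if (is.na(cutoff)) cutoff <- 0.5
    for (pt in eval_pts) {
      pt_cells <- which(metadata$sample_id == pt & in_arm)
      true_label <- lab[pt_cells][1L]
      tr_keep <- labelled & metadata$sample_id != pt
      if (protocol == "fixed_split") {
        tr_keep <- tr_keep & metadata$sample_id %in% train_patients
      }
      tr_pts <- unique(metadata$sample_id[tr_keep])
      tr_classes <- unique(lab[tr_keep])
      evaluable <- length(tr_pts) >= 2L &&
        all(c("resistant", "sensitive") %in% tr_classes)
      if (!evaluable) {
        message(sprintf(
          "(%s, %s): not evaluable (needs >= 2 training patients with both labels)",
          pt, d))
        rows[[length(rows) + 1L]] <- data.frame(
          patient = pt, drug = d, n_spectra = length(pt_cells),
          likelihood = NA_real_, cutoff = cutoff, label = NA_character_,
          true_label = true_label, correct = NA, evaluable = FALSE
        )
        next
      }
      probs <- if (!is.null(prob_override)) {
        prob_override(length(pt_cells), d, pt)
      } else {
        tr_meta_rows <- which(tr_keep)
        tr_meta <- metadata[tr_meta_rows, , drop = FALSE]
        attr(tr_meta, "drugs") <- metadata_drugs(metadata)
        model <- train_resistance_model(
          subset_cells(spectra, tr_meta_rows), tr_meta, d,
          spec = spec, pca = pca, config = config,
          decision_cutoff = cutoff
        )
        spectrum_probabilities(model, subset_cells(spectra, pt_cells))
      }
      cfg <- config
      cfg$seed <- derive_seed(config$seed, paste0("mp_", d, "_", pt))
      pl <- patient_likelihood(probs, cfg)
      label <- if (pl$likelihood > cutoff) "resistant" else "sensitive"
      rows[[length(rows) + 1L]] <- data.frame(
        patient = pt, drug = d, n_spectra = length(pt_cells),
        likelihood = pl$likelihood, cutoff = cutoff, label = label,
        true_label = true_label, correct = label == true_label,
        evaluable = TRUE
      )
    }
  }
  calls <- do.call(rbind, rows)
  rownames(calls) <- NULL
  ok <- calls$evaluable
  acc <- if (any(ok)) mean(calls$correct[ok]) else NA_real_
  per_drug <- vapply(split(calls[ok, ], calls$drug[ok]),
    function(x) mean(x$correct), numeric(1L))
  pts_all <- sort(unique(calls$patient))
  lm <- matrix(NA_real_, length(pts_all), length(drugs),
    dimnames = list(pts_all, drugs))
  for (i in seq_len(nrow(calls))) {
    lm[calls$patient[i], calls$drug[i]] <- calls$likelihood[i]
  }
  structure(list(calls = calls, accuracy = acc,
    per_drug_accuracy = per_drug, likelihood_matrix = lm),
    class = "cohort_evaluation")
}

#' @exportS3Method base::print
print.cohort_evaluation <- function(x, ...) {
  cat(sprintf("<cohort_evaluation> %d calls, %d evaluable, accuracy %.3f\n",
    nrow(x$calls), sum(x$calls$evaluable), x$accuracy))
  invisible(x)
}

#' Save / load a resistance model
#'
#' Round-trips through `saveRDS`; reloaded models give bit-identical
#' probabilities.
#'
#' @param model a `resistance_model`.
#' @param path file path (.rds).
#' @return `save_resistance_model` returns `path` invisibly;
#'   `load_resistance_model` returns the model.
#' @export
save_resistance_model <- function(model, path) {
  stopifnot(inherits(model, "resistance_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_resistance_model
#' @export
load_resistance_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "resistance_model"))
  model
}
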