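DEMO_DRUGS <- c("bemcentinib", "cabozantinib", "dabrafenib", "nivolumab",
  "nivolumab+relatlimab")

#' Planted per-drug treatment effects for the demonstration cohort
#'
#' Each drug's resistance signature shifts at least two bands by at least
#' 0.5 log2 units, placed on bands the melanoma Raman literature links to
#' the corresponding pathways where possible (e.g. carotenoid/protein 1156
#' gain after bemcentinib, protein losses at 748/750 after cabozantinib).
#' Three constraints keep the per-drug ground truth identifiable: the five
#' signatures use pairwise disjoint band sets (a patient resistant to
#' several drugs carries the sum of their signatures); overlapping band
#' pairs (748/750, 1660/1664) are shifted together within one drug rather
#' than split across drugs; and no signature sits on a band whose amplitude
#' differs between the melanoma and fibroblast-like profiles, which would
#' confound drug response with subpopulation mixture. Effect sizes are
#' package design choices; the source spectra are not public.
#'
#' @return named list of [treatment_effect()]s.
#' @export
demo_treatment_effects <- function() {
  list(
    "bemcentinib" = treatment_effect("bemcentinib",
      c("1156" = 0.9, "1606" = 0.7)),
    "cabozantinib" = treatment_effect("cabozantinib",
      c("748" = -0.9, "750" = -0.8, "1003" = -0.6)),
    "dabrafenib" = treatment_effect("dabrafenib",
      c("1126" = -0.9, "667" = -0.8)),
    "nivolumab" = treatment_effect("nivolumab",
      c("1306" = -0.8, "1337" = 0.8)),
    "nivolumab+relatlimab" = treatment_effect("nivolumab+relatlimab",
      c("1664" = -0.9, "1660" = -0.8, "1095" = 0.6))
  )
}

# Balanced response matrix with minimally correlated drug columns (every
# pair of drugs agrees on 4 or 5 of the 9 patients). Patients resistant to
# several drugs carry the sum of those signatures, so correlated label
# columns would let one drug's model free-ride on another drug's bands and
# confound the per-drug ground truth.
demo_label_matrix <- function() {
  labs <- matrix(c(
    "S", "S", "S", "R", "S",
    "S", "R", "R", "S", "R",
    "R", "R", "S", "R", "R",
    "R", "S", "R", "R", "R",
    "S", "S", "R", "S", "S",
    "S", "S", "S", "S", "R",
    "R", "R", "S", "S", "S",
    "R", "S", "R", "S", "S",
    "S", "R", "R", "R", "S"
  ), nrow = 9, byrow = TRUE,
  dimnames = list(sprintf("PAT-%02d", 1:9), DEMO_DRUGS))
  ifelse(labs == "R", "resistant", "sensitive")
}

#' Generate the nine-patient demonstration cohort
#'
#' A synthetic clinical cohort mirroring the structure of a melanoma
#' patient-screening study: nine patients (five nominally for training, four
#' for testing) across five drugs (bemcentinib, cabozantinib, dabrafenib,
#' nivolumab, nivolumab+relatlimab), per-patient spectrum counts drawn with
#' mean about 522 and clamped to \[96, 1512\], patient-specific
#' melanoma/fibroblast-like subpopulation mixtures, and planted per-drug
#' resistance signatures ([demo_treatment_effects()]). Cells are assigned
#' round-robin to an untreated arm plus one arm per drug, and signatures
#' are expressed in the surviving cells of a resistant patient's matching
#' treatment arm (persister screening design, `effect_scope =
#' "treated_only"`); resistance evaluation on this cohort therefore uses
#' `match_treatment_arm = TRUE` so each drug's model reads its own arm.
#'
#' @param seed integer seed; the cohort is fully reproducible from it.
#' @param out_dir optional directory; if given, writes `spectra.csv`,
#'   `metadata.tsv` and `ground_truth.json`.
#' @param zero_effects if TRUE, all planted effects are removed (null
#'   cohort for calibration experiments).
#' @param mean_cells,min_cells,max_cells per-patient spectrum count
#'   distribution.
#' @return list `spectra`, `metadata`, `ground_truth` (and `paths` when
#'   `out_dir` is given).
#' @export
demo_cohort <- function(seed = 0, out_dir = NULL, zero_effects = FALSE,
                        mean_cells = 522, min_cells = 96, max_cells = 1512) {
  labels <- demo_label_matrix()
  effects <- demo_treatment_effects()
  if (zero_effects) {
    effects <- lapply(effects, function(e) treatment_effect(e$drug, numeric(0)))
  }
  patients <- with_seed(derive_seed(seed, "demo_patients"), {
    n_cells <- sample_patient_cell_counts(nrow(labels),
      mean_cells = mean_cells, min_cells = min_cells, max_cells = max_cells)
    fib_frac <- round(runif(nrow(labels), 0, 0.35), 2)
    lapply(seq_len(nrow(labels)), function(i) {
      patient_spec(
        patient_id = rownames(labels)[i],
        subpopulations = list(
          list(profile = default_phenotype("melanoma"), fraction = 1 - fib_frac[i]),
          list(profile = default_phenotype("fibroblast_like"), fraction = fib_frac[i])
        ),
        resistance_labels = labels[i, ],
        n_cells = n_cells[i]
      )
    })
  })
  cohort <- synth_cohort(patients,
    treatments = c("untreated", DEMO_DRUGS),
    effects = effects,
    seed = derive_seed(seed, "demo_cohort"),
    effect_scope = "treated_only")
  cohort$ground_truth$training_patients <- rownames(labels)[1:5]
  cohort$ground_truth$testing_patients <- rownames(labels)[6:9]
  if (!is.null(out_dir)) {
    paths <- write_spectra(cohort$spectra, cohort$metadata, out_dir)
    gt_path <- file.path(out_dir, "ground_truth.json")
    jsonlite::write_json(cohort$ground_truth, gt_path, auto_unbox = TRUE,
      digits = NA, pretty = TRUE)
    cohort$paths <- c(paths, ground_truth = gt_path)
  }
  cohort
}

PIPELINE_STAGES <- c("simulate", "preprocess", "cluster", "evaluate")

#' Default pipeline configuration
#'
#' @param seed global seed.
#' @param out_dir output directory for pipeline artifacts.
#' @param ... named blocks overriding the defaults (`simulate`, `crop`,
#'   `baseline`, `normalize`, `pca`, `cluster`, `resistance`).
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 0, out_dir = tempfile("ramanresist_run_"), ...) {
  defaults <- list(
    seed = as.integer(seed),
    out_dir = out_dir,
    simulate = list(mean_cells = 522, min_cells = 96, max_cells = 1512),
    crop = list(lo = 600, hi = 1800),
    baseline = list(lam = 1e5, p = 0.01, n_iter = 10),
    normalize = "l2",
    pca = list(variance_target = 0.95, max_components = 50),
    cluster = list(k_neighbors = 15, resolution = 0.5, umap_pca_components = 50),
    classifier = list(n_trees = 500, k_folds = 5),
    resistance = list(n_mini = 25000, subset_size = 50,
      spectrum_threshold = 0.5, cutoff = 0.5)
  )
  structure(modifyList(defaults, list(...)), class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with any subset of the [run_config()] blocks.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read YAML configurations")
  }
  cfg <- yaml::read_yaml(path)
  do.call(run_config, c(list(seed = cfg$seed %||% 0,
    out_dir = cfg$out_dir %||% tempfile("ramanresist_run_")),
    cfg[setdiff(names(cfg), c("seed", "out_dir"))]))
}

config_checksum <- function(config) {
  # paths do not affect the scientific parameters
  config <- config[setdiff(sort(names(config)), "out_dir")]
  txt <- paste(deparse(config), collapse = "")
  v <- utf8ToInt(txt)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% .Machine$integer.max)
}

#' Run the end-to-end synthetic demonstration pipeline
#'
#' Executes the requested stages in order (`simulate` -> `preprocess` ->
#' `cluster` / `evaluate`), writes each stage's artifacts under
#' `config$out_dir`, and records a manifest JSON listing every output file
#' together with the package version, configuration checksum, and seed.
#' Stage dependencies are validated before any computation; partial outputs
#' are removed on failure. The run is idempotent for a fixed seed.
#'
#' @param config a [run_config()].
#' @param stages ordered subset of `c("simulate", "preprocess", "cluster",
#'   "evaluate")`.
#' @return the manifest, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config = run_config(),
                         stages = c("simulate", "preprocess", "evaluate")) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  deps <- list(simulate = character(0), preprocess = "simulate",
    cluster = "preprocess", evaluate = "preprocess")
  for (i in seq_along(stages)) {
    missing <- setdiff(deps[[stages[i]]], stages[seq_len(i - 1L)])
    if (length(missing) > 0L) {
      stop(sprintf("stage '%s' requires stage '%s' to run before it",
        stages[i], missing[1L]))
    }
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  manifest <- list(
    package = "ramanresist",
    version = as.character(utils::packageVersion("ramanresist")),
    seed = config$seed,
    config_checksum = config_checksum(config),
    stages = stages,
    outputs = list()
  )
  state <- new.env(parent = emptyenv())
  on_fail <- function(e) {
    unlink(written)
    stop("pipeline failed in stage execution: ", conditionMessage(e),
      call. = FALSE)
  }
  tryCatch({
    for (stage in stages) {
      if (stage == "simulate") {
        cohort <- demo_cohort(seed = config$seed,
          out_dir = file.path(config$out_dir, "cohort"),
          mean_cells = config$simulate$mean_cells,
          min_cells = config$simulate$min_cells,
          max_cells = config$simulate$max_cells)
        state$cohort <- cohort
        written <- c(written, unname(cohort$paths))
        manifest$outputs$simulate <- as.list(cohort$paths)
      } else if (stage == "preprocess") {
        state$pre <- preprocess_spectra(state$cohort$spectra,
          crop = config$crop, baseline = config$baseline,
          normalize = config$normalize)
        path <- file.path(config$out_dir, "preprocessed")
        p <- write_spectra(state$pre, state$cohort$metadata, path)
        written <- c(written, unname(p))
        manifest$outputs$preprocess <- as.list(p)
      } else if (stage == "cluster") {
        red <- pca_fit(state$pre,
          variance_target = config$pca$variance_target,
          max_components = config$cluster$umap_pca_components,
          fitted_on = "all_cells_exploratory")
        cl <- leiden_cluster(red$scores,
          k_neighbors = config$cluster$k_neighbors,
          resolution = config$cluster$resolution, seed = config$seed)
        comp <- cluster_composition(cl, state$cohort$metadata)
        cpath <- file.path(config$out_dir, "clusters.tsv")
        data.table::fwrite(as.data.frame(cl), cpath, sep = "\t")
        cmpath <- file.path(config$out_dir, "cluster_composition.csv")
        data.table::fwrite(comp, cmpath, sep = ",")
        written <- c(written, cpath, cmpath)
        manifest$outputs$cluster <- list(clusters = cpath,
          composition = cmpath)
      } else if (stage == "evaluate") {
        res <- evaluate_cohort(state$pre, state$cohort$metadata,
          spec = classifier_spec(n_trees = config$classifier$n_trees,
            k_folds = config$classifier$k_folds, seed = config$seed),
          pca = config$pca,
          match_treatment_arm = TRUE,
          config = mini_patient_config(
            n_mini = config$resistance$n_mini,
            subset_size = config$resistance$subset_size,
            spectrum_threshold = config$resistance$spectrum_threshold,
            seed = config$seed))
        epath <- file.path(config$out_dir, "calls.tsv")
        data.table::fwrite(res$calls, epath, sep = "\t")
        written <- c(written, epath)
        manifest$outputs$evaluate <- list(calls = epath,
          accuracy = res$accuracy)
        state$evaluation <- res
      }
    }
  }, error = on_fail)
  mpath <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(manifest)
}
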