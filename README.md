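# ramanresist

Single-cell Raman phenotyping and patient-level drug-resistance likelihood
determination.

## What this is for

Spontaneous Raman spectroscopy gives a label-free, non-destructive
biochemical profile of a single cell across the biological fingerprint
window (600–1800 cm⁻¹): nucleic-acid, protein, lipid and pigment bands in
one vector per cell. Treated tumor cells that survive short drug exposure
("persisters") carry early spectral signatures of later resistance, which
makes cohorts of patient-derived single-cell spectra candidates for
predicting a melanoma patient's response to targeted inhibitors
(bemcentinib, cabozantinib, dabrafenib) and immunotherapies (nivolumab,
nivolumab+relatlimab) directly from cultured cells.

`ramanresist` is an R implementation of that analysis chain for
spectroscopists and computational biologists:

* **spectra I/O** — cells × wavenumbers CSV plus per-cell metadata TSV,
  validated and interpolated onto a common grid;
* **preprocessing** — cosmic-ray despiking, fingerprint cropping,
  asymmetric-least-squares baseline correction (banded C++ solver), l2/area
  normalisation, PCA capturing ≥95% of variance;
* **classification** — stratified k-fold, class-weighted random forests
  with Voigt-perturbation wavenumber importance (accuracy-dropoff curves);
* **differential Raman "expression"** — per-wavenumber median log2 fold
  changes (heatmap-clipped at ±2), Wilcoxon rank-sum tests with
  Benjamini–Hochberg FDR, highly-variant wavenumber selection, and spectral
  barcodes by sample / Leiden cluster / likelihood stratum;
* **embedding & clustering** — UMAP on the top 50 PCs, Leiden communities
  (resolution 0.5) on a kNN graph, cluster × drug label composition;
* **resistance determination** — the two-stage *mini-patient* architecture:
  a per-drug random forest scores each spectrum, then 25,000 resampled
  subsets ("mini patients", default 50 spectra each) are aggregated; the
  **resistance likelihood** is the fraction of subsets whose mean
  probability exceeds 0.5, thresholded (default 0.5, per-drug optimisable)
  into a patient label, evaluated leave-one-patient-out;
* **synthetic cohorts** — a generator with literature band positions,
  Voigt line shapes, lognormal per-cell jitter, fluorescence baselines,
  cosmic-ray spikes, patient subpopulation mixtures and planted per-drug
  resistance signatures, providing ground truth for every stage.

The statistic at the core is, per patient and drug,

```
likelihood = (1/N) Σ_j 1[ mean_{i ∈ subset_j} P(resistant | spectrum_i) > 0.5 ],  N = 25000
```

with `P(resistant | spectrum)` from a PCA + random-forest model trained on
spectra of patients with known response.

## Worked example

```r
library(ramanresist)

# a synthetic clinical cohort: 9 patients x 5 drugs, known ground truth
cohort <- demo_cohort(seed = 7)
pre    <- preprocess_spectra(cohort$spectra)      # despike, crop, baseline, l2

# leave-one-patient-out resistance determination; each drug's model is
# trained and evaluated on that drug's own treatment arm (persister design)
res <- evaluate_cohort(pre, cohort$metadata, match_treatment_arm = TRUE)
res
#> <cohort_evaluation> 45 calls, 45 evaluable, accuracy 1.000
head(res$calls[, c("patient", "drug", "likelihood", "label", "true_label")], 3)
#>   patient        drug likelihood     label true_label
#> 1  PAT-01 bemcentinib          0 sensitive  sensitive
#> 2  PAT-02 bemcentinib          0 sensitive  sensitive
#> 3  PAT-03 bemcentinib          1 resistant  resistant
```

Every row is one (patient, drug) determination made with that patient held
out of training; `likelihood` near 1 means nearly all of the patient's
25,000 mini patients were called resistant, and `accuracy` is the fraction
of labelled pairs called correctly. On this synthetic cohort the planted
signatures are strong, so the determinations are confident; on real data
likelihoods nearer the cutoff flag borderline patients whose barcodes
deserve a second look (`build_barcode()`, `likelihood_strata()`).

Phenotype-level questions use the same preprocessed matrix:

```r
cv  <- cross_validate(pre, cohort$metadata$sample_id)   # patient discernibility
imp <- importance_curve(pre, cohort$metadata$sample_id) # which wavenumbers carry it
```

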