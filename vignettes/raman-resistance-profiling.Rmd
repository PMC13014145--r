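---
title: "Single-cell Raman phenotyping and patient resistance likelihood: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-cell Raman phenotyping and patient resistance likelihood: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ramanresist)
```

## The problem

Spontaneous Raman spectroscopy records the inelastic scattering spectrum of a
cell in the biological fingerprint window (600–1800 cm⁻¹), a label-free
readout dense in nucleic-acid, protein, lipid and pigment vibrational bands.
Treated single-cell spectra carry early biochemical signatures of
drug-tolerant persister states, which makes them candidates for predicting a
melanoma patient's resistance to targeted inhibitors and immunotherapies from
a dish of patient-derived cells, without sequencing or antibody panels.

`ramanresist` implements the full analysis chain for such data: spectra I/O
on a common wavenumber grid, preprocessing (despiking, baseline correction,
normalisation, PCA), random-forest phenotype classification with
perturbation-based wavenumber importance, differential Raman "expression"
(median log2 fold-change barcodes with Wilcoxon testing and FDR control),
UMAP/Leiden cluster composition analysis, and a two-stage *mini-patient*
aggregation scheme that turns per-spectrum resistance probabilities into a
patient-level resistance likelihood. Because no suitable single-cell Raman
cohort is publicly deposited, the package also ships a synthetic cohort
generator with known ground truth; every stage is validated against planted
signals and exhaustive small-case oracles.

## Spectral model and the synthetic generator

A synthetic spectrum is

$$ y(\nu) \;=\; \sum_b a_b \, J_b \, 2^{s_b} \, V_b(\nu) \;+\; B(\nu) \;+\;
\varepsilon(\nu) \;+\; \text{spikes}, $$

where $V_b$ is a peak-normalised Voigt profile (Gaussian ⊗ Lorentzian;
`voigt_profile()` evaluates the Faddeeva function with a continued-fraction
branch for the far wings), $a_b$ the band's mean peak amplitude, $J_b$ a
per-cell lognormal jitter with mean 1 (default CV 0.15, multiplicative
intensity variation between cells), $s_b$ a planted log2 shift,
$B$ a fluorescence-like cubic polynomial background with random
coefficients, $\varepsilon$ Gaussian detector noise (default SD 0.02 a.u.),
and spikes are Poisson-count cosmic-ray points (default rate 0.02 per
spectrum, amplitude 10× the tallest band, one grid point wide).

Only the band *centres* are literature values (phenylalanine 1003/1606,
nucleic acids 667/748/780/1306/1337/1585, protein 748/1126/1337/1446/1585/
1664, lipid 1306/1446, melanin 1385/1580, tryptophan 750, carotenoid 1156
cm⁻¹). Widths default to 12 cm⁻¹ FWHM — a typical condensed-phase Raman
linewidth — and amplitudes are package design choices. The library adds
broad amide/CH envelope bands (FWHM 30–60 cm⁻¹) so that, as in real cell
spectra, the total spectral energy is spread over many overlapping features
and no single sharp band dominates; this matters because per-spectrum
normalisation couples any one band's change into all other wavenumbers in
proportion to that band's energy share.

Peak height (not area) is the amplitude convention throughout, matching how
band intensities are read off heatmaps and barcodes.

**Resistance semantics.** Planted treatment effects are attached to the
cells of *resistant-labelled* patients, under one of two scopes. With
`effect_scope = "all_cells"` every cell of a resistant patient carries the
drug's band shifts — the strongest persister-state premise, useful for
single-drug studies. With `"treated_only"` the shifts appear only in cells
whose own treatment arm matches the drug, i.e. in the surviving persisters
of that exposure — the design a wet-lab persister screen actually realises.
The multi-drug demonstration cohort uses `"treated_only"`: under the
all-cells scope a patient resistant to several drugs carries the *sum* of
their signatures, so with nine patients and five drugs each drug's model
faces four binary nuisance signatures spanning up to sixteen combinations
across only eight training patients — the per-drug ground truth becomes
structurally unidentifiable and leave-one-patient-out calls invert
confidently, regardless of normalisation or forest settings. Restricting
expression to the matching arm (and training each drug's model on that arm,
`evaluate_cohort(match_treatment_arm = TRUE)`) isolates each drug's signal.

**What the generator does not emulate.** Instrument effects (wavelength
calibration error, CCD etaloning), melanin resonance-Raman saturation,
cell-cycle and batch structure, and spatially correlated noise. Passing
tests on this generator therefore demonstrate that the *analysis chain*
recovers what it assumes; they do not certify performance on any real
instrument's data.

## Preprocessing

The pipeline order is despike → crop → baseline → normalise; classification
and clustering consume its output.

* **Despiking**: a point whose residual against a width-5 running median
  exceeds 8× the MAD of the residuals is replaced by the running median
  (with a small-fraction fallback scale when the MAD is exactly zero, as in
  noiseless test spectra).
* **Crop**: inclusive 600–1800 cm⁻¹ fingerprint window, default 1 cm⁻¹
  grid (1201 points). The acquisition grid of real instruments varies;
  `read_spectra()` interpolates linearly onto a requested grid and refuses
  to extrapolate.
* **Baseline**: Eilers-style asymmetric least squares (second-difference
  penalty `lam = 1e5`, asymmetry `p = 0.01`, 10 reweighting iterations),
  solved in C++ with a banded LDLᵀ factorisation (O(n) per spectrum). The
  estimator commutes exactly with constant offsets and preserves peak
  heights to within a few percent on polynomial backgrounds; its smoothing
  length is roughly `lam`^(1/4) ≈ 18 cm⁻¹, which bounds how far a peak's
  influence bleeds into neighbouring baseline (relevant when interpreting
  fold changes near a strongly changed band — see below).
* **Normalisation**: `l2` by default (robust to the sign issues area
  normalisation inherits from baseline-corrected negatives); features enter
  PCA mean-centred but not z-scored.
* **PCA**: LAPACK SVD of the centred matrix; the number of components is
  the smallest capturing ≥ 95% of variance (configurable cap; resistance
  models cap at 50, and UMAP conventionally uses the top 50). Component
  signs are fixed by the largest-loading convention so results are
  deterministic.

## Classification and wavenumber importance

Phenotype and resistance classifiers are probability random forests
(`ranger`; 500 trees, √p split candidates) with class weights inversely
proportional to training-fold class frequencies, evaluated by stratified
k-fold cross-validation (default k = 5). The PCA transform is refit inside
every training fold — test spectra never influence the reduction. Tied
class probabilities break toward the earlier label, so predictions are
deterministic.

Wavenumber importance follows the perturbation (masking) logic: each test
fold is perturbed in *pre-PCA* space with an additive Voigt bump (default
FWHM 15 cm⁻¹, amplitude = that spectrum's intensity SD) centred at each
evaluation wavenumber (default every 2 cm⁻¹), projected through the fold's
PCA, and reclassified; the dropoff is the mean loss of accuracy. An
additive bump remains meaningful after normalisation (zeroing a normalised
channel would not); a masking mode is available. Because projection is
affine, the perturbed scores are computed as
`scores + a ⊗ (bump · loadingsᵀ)`, which equals the explicit
perturb-then-project path to floating-point accuracy and makes the full
curve tractable; the importance fold forests default to 200 trees, since
the dropoff is an accuracy *difference* on fixed folds and is stable with a
smaller forest than the deployment classifier.

## Differential Raman "expression" and barcodes

For a group versus a reference, the per-wavenumber statistic is
`log2((median_B + eps) / (median_A + eps))`, with a display copy clipped to
[−2, +2] (the conventional heatmap colour bounds). Two numerical choices
matter at wavenumbers with little signal:

* Medians are taken on the *signed* baseline-corrected intensities and
  clipped at zero just before the ratio. Clipping per-cell values first
  would place the median of an empty wavenumber exactly at the clipping
  edge, where it flips between 0 and the noise scale with tiny group
  differences.
* `eps` defaults to 2% of the maximum intensity — of the order of the
  per-wavenumber noise floor that baseline correction leaves behind. A
  pseudo-intensity far below the noise floor cannot stabilise ratios of
  near-zero medians (the blow-ups it exists to prevent).

Fold changes are computed on baseline-corrected, **unnormalised** spectra.
Per-spectrum normalisation rescales every wavenumber by the spectrum norm,
so a genuine change at one band leaks a spurious opposite-signed offset
into all others (≈ −0.06 log2 for a doubled band carrying ~4% of the
spectral energy here); unnormalised group medians estimate planted
multiplicative shifts unbiasedly under the generator's per-band jitter.
Classification and clustering still use normalised spectra.

When interpreting a fold-change profile around a strongly changed band,
note its *processed footprint*: the band profile itself (Voigt tails) plus
the baseline estimator's redistribution radius (~2× the ALS smoothing
length) — about ±75 cm⁻¹ under the defaults for a 12 cm⁻¹ band. The
package's recovery tests require planted shifts to be recovered within
±0.1 log2 at the band and no spurious |FC| ≥ 0.1 outside that footprint.

Hypothesis testing is a two-sided Wilcoxon rank-sum per wavenumber
(midranks for ties; exact p-values for tie-free groups under 50, normal
approximation with continuity correction otherwise), with
Benjamini–Hochberg q-values across wavenumbers within each contrast
(contrasts are not pooled). *Highly variant wavenumbers* are the union of
the top importance-dropoff wavenumbers and prominent mean-spectrum peaks
(prominence ≥ 5% of the maximum) passing `q ≤ 0.05`; picks within one
perturbation FWHM merge to the strongest member, and each selected
wavenumber carries a provenance tag. Barcodes are rows of median log2 fold
changes at the selected wavenumbers, grouped by sample, Leiden cluster, or
resistance-likelihood stratum (resistant-like > 0.8, sensitive-like < 0.2).
Which reference a barcode uses (pooled untreated cells by default) is
recorded in the output.

## Embedding and clustering

UMAP runs on the top 50 principal components (n_neighbors 15, min_dist 0.1,
single-threaded and seeded, hence reproducible); it is exploratory only —
no quantitative conclusion in the package depends on embedding geometry
beyond gross separation. Leiden community detection runs on an exact
k-nearest-neighbour graph (k = 15, Euclidean metric in PC space) at
resolution 0.5, with clusters relabelled 0..C−1 by decreasing size.
Cluster composition tables report resistant / sensitive / *unknown* label
proportions per (cluster, drug) — unknowns are kept explicit rather than
dropped, so denominators are auditable.

## Two-stage resistance determination

Stage one: for each drug, every spectrum of a labelled sample inherits the
sample's resistant/sensitive label, and a PCA + class-weighted random
forest is trained on labelled spectra only (unknowns excluded, never
imputed). Stage two: a patient's spectra are resampled into **mini
patients** — subsets of `subset_size` spectra (default 50, with
replacement; the subset size is a package choice, sized to give smooth
likelihoods even for the smallest clinical samples of ~96 spectra while
still letting heterogeneous subpopulations shift individual subsets). Each
mini patient aggregates its per-spectrum resistance probabilities (mean by
default; majority vote available) and is called resistant when the
aggregate exceeds 0.5; the **resistance likelihood** is the fraction of
resistant mini patients among 25,000, and the patient is labelled resistant
when the likelihood strictly exceeds the decision cutoff (default 0.5; a
tie is conservatively called sensitive). At 25,000 mini patients the
Monte-Carlo error is at most 3·√(0.25/25000) ≈ 0.0095 at 99% confidence,
and the estimator is validated against exhaustive enumeration whenever the
subset space is small enough to enumerate. Subset indices depend only on
the seed, so raising any per-spectrum probability can never lower the
likelihood; the degenerate `subset_size = 1` mean-aggregation case is
computed analytically as the fraction of spectra above the threshold.

Per-drug decision cutoffs can be optimised by a grid search (step 0.01)
maximising balanced accuracy on *training-patient* calls only, with ties
broken toward 0.5. Cohort evaluation is leave-one-patient-out by default:
PCA and forest are refit for every holdout, so the evaluated patient never
leaks into training (the package refuses to score a training patient
without an explicit override); (patient, drug) pairs whose training set
would retain fewer than two patients or one class are reported as not
evaluable and excluded from the accuracy denominator.

## The demonstration cohort

`demo_cohort()` generates the package's reference synthetic cohort: nine
patients (five nominally training, four testing) across bemcentinib,
cabozantinib, dabrafenib, nivolumab and nivolumab+relatlimab; per-patient
spectrum counts are lognormal with mean ≈ 522 clamped to [96, 1512]
(matching the scale of a real patient screening series); cells are
assigned round-robin to an untreated arm plus one arm per drug; each
patient mixes a melanoma profile with a fibroblast-like subpopulation
(0–35%, emulating passage drift); and each drug's resistance signature
shifts 2–3 bands by 0.5–0.9 log2 units on pathway-plausible assignments
(e.g. a carotenoid 1156 gain for bemcentinib, protein 748/750 losses for
cabozantinib). Three identifiability constraints govern the signature
design: the five band sets are pairwise disjoint (a multi-resistant
patient expresses several signatures); overlapping band pairs (748/750,
1660/1664) belong to a single drug rather than being split across two; and
no signature sits on a band whose amplitude differs between the melanoma
and fibroblast-like profiles, which would confound response with
subpopulation mixture. The label matrix is a computationally searched
balanced design — every drug has 4–5 resistant patients of 9, every pair
of drug columns agrees on only 4–5 patients (|r| ≈ 0.1), and both classes
survive any single-patient holdout: correlated label columns would let one
drug's model free-ride on another drug's bands, which defeats the point of
per-drug determination.

## Problem sizes and numerical conventions

The validation suite runs planted-band classification at 1000 spectra per
class, fold-change recovery at 1000 (tests) / 500 (documented invariant)
spectra per group, null calibrations over 600 wavenumbers and ≥ 50
replicates, and the end-to-end cohort at full demonstration size (~4700
spectra, 45 leave-one-patient-out models, 25,000 mini patients per call) —
sizes chosen so the whole suite completes comfortably on a single CPU.
Other conventions: strictly increasing grids with inclusive crop bounds;
linear interpolation only (no extrapolation); deterministic seeds derived
per stream (folds, forests, resampling) from one user seed; ties in
predicted class break by label order; likelihood ties at the cutoff call
sensitive; degenerate all-constant wavenumbers report p = 1 and are
flagged.

## Known limitations

* Binary resistance labels; no graded or longitudinal response modelling.
* The generator's effect sizes are order-of-magnitude choices — the source
  literature reports heatmaps, not numeric per-band shifts.
* ALS baseline correction redistributes intensity within ~tens of cm⁻¹ of
  strong peaks; fold changes inside that footprint conflate band and
  baseline effects.
* Mini-patient subset size and sampling scheme are conventions exposed in
  configuration, not empirically fitted values.
* Leiden runs on the kNN graph of PCA scores (standard single-cell
  practice); graph construction choices (k, metric) move cluster
  boundaries for borderline cells.
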