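---
title: "Methods: simulating and classifying single-cell SERS spectra of dendritic-cell maturation"
author: "sersdc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and classifying single-cell SERS spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its science: the generative model
behind the simulator, the classifier and its training recipe, the evaluation
and interpretation procedures, the numerical choices, and what the synthetic
experiments do and do not demonstrate about real data.

## The measurement being modelled

A label-free SERS acquisition of single dendritic cells produces, per cell,
tens of spectra: intensity versus Raman shift (cm⁻¹), with bands at
characteristic positions reflecting the cell's biochemical composition.
Mature and immature cells differ most prominently in the tryptophan band at
1623 cm⁻¹ — markedly stronger in mature cells — while the carbohydrate band
at 1025 cm⁻¹ is comparable between states, which motivates the
I(1623)/I(1025) ratio as a normalisation-free maturation marker. The package
treats a dataset as a `SersSpectra` object (a `SummarizedExperiment`): a
shared, uniformly spaced wavenumber axis; one intensity column per spectrum;
and per-spectrum metadata (cell id, label, optional acquisition time and
grid position).

## The synthetic-data generator

`generateDataset()` draws from an explicit hierarchical model:

$$ y_{c,r}(\nu) \;=\; b(\nu) \;+\; s_c \sum_{k} A_{c,k}\,
   \exp\!\Big(-4\ln 2\,\frac{(\nu - \mu_k)^2}{w_k^2}\Big) \;+\;
   \varepsilon_{c,r}(\nu), $$

for cell $c$, replicate spectrum $r$, bands $k$ with centres $\mu_k$ and
FWHM $w_k$; $s_c = \exp(\sigma_{\text{cell}} Z_c)$ is a log-normal per-cell
scale (modelling nanoparticle-uptake variation), $A_{c,k} = \max(0,\,
m_{k} + \text{sd}_k Z_{c,k})$ a per-cell, per-band amplitude around the
class profile mean $m_k$, $b(\nu)$ a small positive quadratic baseline
standing in for substrate background, and $\varepsilon$ i.i.d. Gaussian
noise per point. Replicates of one cell share $s_c$ and $A_{c,k}$ and differ
only in noise, producing the within-cell < between-cell variance hierarchy
of repeated single-cell acquisitions.

Defaults and their rationale:

* **Axis**: 600–1700 cm⁻¹ in 1015 uniform points. The range covers all ten
  catalogued bands; the length is forced by the classifier's printed layer
  shapes (a kernel-3, stride-1, unpadded convolution of a 1015-point input
  has length 1013).
* **Band catalogue**: 647, 826, 1000, 1018, 1025, 1161, 1206, 1444, 1562,
  1623 cm⁻¹ with conventional biomolecular assignments; Gaussian line shape
  with FWHM 12 cm⁻¹, a typical SERS bandwidth.
* **Class effect**: mature/immature amplitude ratio 3.0 at 1623 cm⁻¹, 1.15
  at 826 and 1161 cm⁻¹, 1.0 elsewhere. This is the package's choice of a
  "strong marker band plus mild secondary shifts" configuration: it makes
  the tryptophan band the dominant discriminator (so contribution analyses
  should recover it) while leaving the carbohydrate band class-neutral (so
  the 1623/1025 ratio is a meaningful marker).
* **Design**: 196 mature + 210 immature cells, 50 spectra per cell (20,300
  spectra), matching the scale of a realistic single-cell SERS study.
* **Cell effect** $\sigma_{\text{cell}} = 0.15$ and **noise sd** 0.02
  (relative to unit band amplitude): visible replicate scatter without
  overwhelming the class signal.
* **Immature amplitude means** (0.35–0.90 across bands) were chosen once to
  give a plausibly structured spectrum; they are fully configurable via
  `classProfile()`.

`generateTimecourse()` emulates live-cell monitoring under a maturation
stimulus: a treated arm whose profile interpolates linearly from immature
toward mature with per-time-point weights (default 0.6/0.85/1.0 at
2/4/6 h — most of the spectral response in place within 2 h, emulating a
fast-acting stimulus), and a control arm that stays immature. Cells keep
their identities and random effects across time points, so trajectories are
smooth in the progress weight; only the acquisition noise is redrawn.
`generateMappingGrid()` emulates 1 µm raster scanning of one cell: full
profile inside a central elliptical mask, baseline-only background outside.

What the generator does **not** emulate: cosmic-ray spikes, wavenumber
miscalibration, baseline drift between acquisitions, autofluorescence,
instrument-specific noise colour, and biological sub-populations. Passing
the simulation experiments therefore demonstrates that the pipeline is
correct and sensitive under its stated model, not that the headline
accuracies transfer to any particular instrument's data.

## Preprocessing

* **Normalisation** is per spectrum: min → 0, max → 1. The per-spectrum
  scope is the standard reading for single-cell work (it removes the
  per-cell intensity scale so cells are comparable) and makes the band
  ratio invariant to global rescaling of raw intensities. Constant spectra
  map to all zeros, the documented degenerate rule. The map is idempotent.
* **Per-cell averaging** is the arithmetic mean of a cell's replicates; the
  single-cell classifier trains on these averages (re-normalised, so inputs
  stay in 0–1).
* **Splitting** uses largest-remainder rounding of the 70/20/10 fractions
  (ties toward the earlier subset — deterministic), stratified by label by
  default, shuffled with a seed. With stratification the rounding is applied
  within each label stratum, so combined sizes can deviate by ±1 from the
  unstratified rounding. Granularity is `"cell"` by default — no cell's
  replicates are split across subsets, preventing within-cell leakage — with
  `"spectrum"` available to reproduce the population-level protocol in which
  individual spectra are assigned independently.

## The classifier and its training recipe

The CNN is: Conv1D (32 filters, kernel 3, stride 1, valid padding, ReLU) →
dropout → max-pool (2, stride 2) → flatten → dense 32 ReLU with an L2 weight
penalty → dense 1 sigmoid. Training: 50 epochs of mini-batch SGD, batch 32,
learning rate 0.01, momentum 0.9, binary cross-entropy, and a
reduce-on-plateau scheduler monitoring validation loss with patience 10 and
floor 1e-5. Where the recipe leaves a value open the package fixes it:

* dropout rate **0.25** and L2 coefficient **1e-4** (common defaults for
  small 1-D CNNs; both configurable);
* scheduler reduction factor **0.5** (halving is the customary step);
* weight initialisation: Glorot (fan-in/fan-out scaled) uniform draws from
  the run seed, biases zero;
* baselines for the architecture comparison: MLP = one 64-unit ReLU layer;
  DNN = three 128-unit ReLU layers with dropout 0.25; both end in one
  sigmoid unit. These are package conventions — the comparison experiment
  needs *some* fully connected reference points;
* class encoding: mature = 1, so sensitivity is mature-class recall;
* reported layer shapes are per sample; the mini-batch dimension (32) is
  not part of the shape report.

Numerical details: the engine (C++, Armadillo) computes in single precision,
the customary deep-learning precision; probabilities are clamped to
[1e-12, 1−1e-12] inside the cross-entropy; the plateau test is a strict
improvement of more than 1e-8; reported loss curves are the data term (the
L2 penalty enters gradients, not the printed loss); inference batches
spectra in chunks of 512. All randomness — initialisation, epoch shuffling,
dropout masks — flows from R's RNG, so a fixed seed reproduces a run on a
fixed platform; across BLAS builds reproducibility is statistical rather
than bit-exact.

Training requires both classes in the training set (error otherwise) and
warns if inputs are outside 0–1. Evaluation thresholds probabilities at 0.5;
a probability exactly at the threshold predicts the positive class
(documented tie rule). The ROC is computed over all score thresholds with
ties grouped; the trapezoidal AUC equals the pairwise-concordance
probability with ties counted ½ (property-tested). A single-class
evaluation set leaves the AUC undefined (`NA` with a warning); the
confusion-based metrics are still returned.

## Interpretation

Two contribution methods are provided because "read the final layer's
weights" is ambiguous for a model whose final layers see flattened pooled
features rather than wavenumbers:

* **Occlusion** (default): zero each band's ±6 cm⁻¹ window in every
  spectrum, record the drop in balanced accuracy, clip negative drops, and
  normalise to percent. This measures contribution to classification
  performance directly. Its percentages are unstable when the total drop is
  near zero (e.g. an uninformative model); in that case the report falls
  back to uniform shares.
* **Weight back-projection**: absolute final-layer weights propagated
  through the dense stack and the pooling/convolution index maps onto input
  wavenumbers, summed per band window, normalised to percent — the literal
  weight reading.

The band window ±6 cm⁻¹ matches the default FWHM of 12 cm⁻¹. The
tryptophan/carbohydrate ratio is computed per cell on normalised, per-cell
averaged spectra and compared between groups with a two-sided Welch t-test
by default (robust to unequal variances; the mature group's ratio variance
is visibly larger) or a Mann–Whitney test; a cell with non-positive
denominator intensity raises an explicit degenerate-ratio error. When both
groups have zero variance and equal means the statistic is 0 and p = 1.

## Pipeline and time-course

`runExperiment()` chains generate/load → normalise → (optional per-cell
averaging) → split → train → evaluate → interpret, logs one record per
stage, and persists every result table (split manifest, curves, metrics with
per-sample probabilities, contribution, ratio, config + md5) so each
reported number is recomputable from artifacts. The run seed overrides all
nested seeds, making one integer reproduce the whole run.

For the time-course, the per-time-point mode (default) trains one model per
acquisition time on that time point's own 70/20/10 split — matching a
protocol in which each time point is evaluated with its own
train/validation/test confusion matrix. Whether a single model should
instead serve all time points is genuinely open; a shared-model mode
(pooled training splits, per-time-point evaluation) is provided, and
neither is asserted as the canonical protocol.

## Problem sizes in the tests and acceptance script

The simulation experiments use the default class-effect structure
throughout, with cohort sizes chosen by the package to keep runs desk-scale:
the test suite trains on cohorts of roughly 200–1000 spectra; the
acceptance script uses 48+52 cells × 10 spectra for the multicell model,
24+26 cells × 8 spectra per time point for the time-course, and the full
196+210-cell design for the single-cell (per-cell averaged) model and the
ratio test. Stochastic quantities are reported as medians over 5 seeds.

## Known limitations

* The simulator's separability is set by configuration; the shipped
  defaults make the classes cleanly separable, so near-perfect metrics on
  synthetic data validate the machinery, not instrument performance.
* Occlusion contributions depend on the evaluation set and degrade to
  uniform shares for uninformative models; back-projection ignores input
  values entirely. They agree on the dominant band (property-tested) but
  not necessarily on the tail ranking.
* No baseline-correction or cosmic-ray stage is included: normalisation
  plus the learned features absorb the smooth synthetic baseline, and spike
  artefacts are out of the simulator's scope.
* Bit-exact reproducibility across BLAS implementations is not promised;
  seeds fix results on a given platform.
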