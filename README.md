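# sersdc

Label-free classification of dendritic-cell (DC) maturation from single-cell
surface-enhanced Raman spectroscopy (SERS) spectra, using a one-dimensional
convolutional neural network (CNN).

## The problem

Dendritic cells switch between an immature and a mature functional state, and
assessing that state per cell — ideally in real time, on living cells —
matters for vaccine and immunotherapy studies. Label-free SERS gives each
cell a vibrational fingerprint: band intensities at characteristic Raman
shifts (methionine 647 cm⁻¹, the O-P-O stretch of DNA 826 cm⁻¹,
phenylalanine 1000 cm⁻¹, carbohydrates 1025 cm⁻¹, tryptophan 1623 cm⁻¹,
among others) that shift with the cell's biochemistry. `sersdc` implements
the full analysis chain for such data:

* a **seeded hierarchical simulator** of single-cell SERS datasets —
  Gaussian bands on a smooth baseline, class-dependent band amplitudes,
  log-normal per-cell scale effects, per-spectrum noise, maturation
  time-courses and raster mapping grids — so every downstream stage is
  testable without access to an instrument;
* **preprocessing**: per-spectrum min-max normalisation to the 0–1 interval,
  per-cell averaging, pointwise *t* confidence bands, and leakage-aware
  train/validation/test splitting (70/20/10 by default, at spectrum or cell
  granularity, stratified, largest-remainder sizing);
* the **classifier**: Conv1D (32 filters, kernel 3, stride 1, no padding,
  ReLU) → dropout → max-pool (size 2, stride 2) → flatten → dense(32, ReLU,
  L2) → dense(1, sigmoid), trained for 50 epochs with mini-batch SGD
  (batch 32, learning rate 0.01, momentum 0.9) on binary cross-entropy with
  a reduce-on-plateau scheduler (patience 10, floor 1e-5). For a 1015-point
  spectrum the feature lengths are 1015 → 1013 → 506 and the convolution
  holds 32 × (3 + 1) = 128 parameters. DNN and MLP baselines are included
  for architecture comparison. The training engine is written in
  C++ (RcppArmadillo) and is fully seeded;
* **evaluation**: confusion matrix with *mature* as the positive class,
  accuracy, sensitivity TP/(TP+FN), specificity TN/(TN+FP), the full ROC
  and its trapezoidal AUC;
* **interpretation**: per-band percent contributions by occlusion or by
  back-projection of the final-layer weights, the per-cell
  tryptophan/carbohydrate intensity ratio I(1623)/I(1025) with a Welch (or
  Mann–Whitney) group test — the proposed spectral maturation marker — and
  band-channel mapping images;
* an end-to-end **pipeline** (`runExperiment`, `runTimecourse`,
  `compareAlgorithms`) with config files, per-stage logging, persisted
  artifacts, and a thin CLI (`inst/scripts/sersdc-cli.R`).

## Worked example

```r
library(sersdc)

cfg <- syntheticConfig(nCellsPerClass = c(mature = 30L, immature = 32L),
                       spectraPerCell = 10L, seed = 1L)
spectra <- generateDataset(cfg)
spectra
#> SersSpectra: 620 spectra x 1015 wavenumbers (600.0-1700.0 cm^-1)
#>   labels: immature=320, mature=300
#>   cells: 62

norm <- minmaxNormalize(spectra)
sets <- splitDataset(norm, splitSpec(unit = "spectrum", seed = 1L))
model <- buildModel("cnn", modelConfig(), inputLen = 1015L)
layerShapes(model)
#>           layer output_length channels params
#> 1         input          1015        1      0
#> 2        conv1d          1013       32    128
#> 3       dropout          1013       32      0
#> 4     maxpool1d           506       32      0
#> 5       flatten         16192        1      0
#> 6    dense_relu            32        1 518176
#> 7 dense_sigmoid             1        1     33

model <- trainModel(model, sets$train, sets$validation, trainConfig(seed = 1L))
evaluateModel(model, sets$test)
#> EvaluationReport (mature = positive)
#>   TP 30  FP 0  TN 32  FN 0
#>   accuracy 1.0000  sensitivity 1.0000  specificity 1.0000  AUC 1.0000

cells <- minmaxNormalize(averagePerCell(norm))
ratioStatistic(cells)
#> RatioReport: 1623 / 1025 cm^-1 band-intensity ratio
#>   mature 0.934 +/- 0.111 (n=30), immature 0.348 +/- 0.034 (n=32)
#>   Welch two-sample t-test (two-sided): statistic 27.848, p = 4.55e-25

pc <- peakContribution(model, sets$test)
pc[order(pc$rank)[1:3], ]
#>    center           assignment contribution rank
#> 10   1623           tryptophan          100    1
#> 1     647           methionine            0    2
#> 2     826 O-P-O stretch of DNA            0    2
```

The test-set confusion matrix is perfect here because the default simulated
class effect (a three-fold tryptophan-band amplitude ratio) makes the two
states cleanly separable; the ratio report shows the corresponding group
difference in the per-cell 1623/1025 marker, and the occlusion analysis
attributes the decision to the tryptophan band.

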