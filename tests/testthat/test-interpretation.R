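test_that("band intensities are window means on the axis", {
  wn <- tinyAxis()
  zero <- manualSpectra(matrix(0, 1015, 1), wn)
  expect_equal(unname(bandIntensity(zero, 1623)), 0)

  g <- exp(-4 * log(2) * ((wn - 1623) / 12)^2)  # unit-amplitude band
  ds <- manualSpectra(matrix(g, ncol = 1), wn)
  idx <- which(wn >= 1617 & wn <= 1629)
  expect_equal(unname(bandIntensity(ds, 1623, 6)), mean(g[idx]))
  expect_gte(unname(bandIntensity(ds, 1623, 6)), 0.7)
  expect_lte(unname(bandIntensity(ds, 1623, 6)), 1.0)

  # window spanning the whole axis equals the global mean
  expect_equal(unname(bandIntensity(ds, 1150, 1e6)), mean(g))
  expect_error(bandIntensity(ds, 3000, 6), "range error")
})

test_that("the 1623/1025 ratio separates the default classes", {
  ds <- generateDataset(tinyConfig(nMature = 30L, nImmature = 30L, spc = 5L,
                                   seed = 17L))
  cells <- minmaxNormalize(averagePerCell(minmaxNormalize(ds)))
  rr <- ratioStatistic(cells)
  expect_lt(rr$p.value, 1e-4)
  expect_gt(rr$groupMeans[["mature"]], rr$groupMeans[["immature"]])
  expect_equal(nrow(rr$ratios), 60)
  rw <- ratioStatistic(cells, test = "mann_whitney")
  expect_lt(rw$p.value, 1e-4)
})

test_that("the ratio statistic is invariant to global rescaling", {
  ds <- generateDataset(tinyConfig(seed = 19L))
  scaled <- ds
  SummarizedExperiment::assay(scaled, "intensity") <-
    SummarizedExperiment::assay(ds, "intensity") * 7.3
  r1 <- ratioStatistic(minmaxNormalize(averagePerCell(minmaxNormalize(ds))))
  r2 <- ratioStatistic(minmaxNormalize(averagePerCell(minmaxNormalize(scaled))))
  expect_equal(r1$ratios$ratio, r2$ratios$ratio, tolerance = 1e-9)
  expect_equal(r1$p.value, r2$p.value, tolerance = 1e-9)
})

test_that("identical groups give uniform p-values (null calibration)", {
  wn <- tinyAxis()
  g1623 <- exp(-4 * log(2) * ((wn - 1623) / 12)^2)
  g1025 <- exp(-4 * log(2) * ((wn - 1025) / 12)^2)
  pvals <- vapply(1:300, function(seed) {
    set.seed(seed)
    n <- 30
    M <- sapply(seq_len(n), function(i)
      abs(rnorm(1, 1, 0.2)) * g1623 + abs(rnorm(1, 1, 0.2)) * g1025)
    ds <- manualSpectra(M, wn, labels = rep(c("mature", "immature"),
                                            each = n / 2))
    ratioStatistic(ds)$p.value
  }, numeric(1))
  expect_gt(mean(pvals < 0.05), 0.02)   # about 5% significant under the null
  expect_lt(mean(pvals < 0.05), 0.09)
  expect_gt(mean(pvals), 0.4)           # roughly uniform
  expect_lt(mean(pvals), 0.6)
})

test_that("degenerate ratios are handled explicitly", {
  wn <- tinyAxis()
  g <- exp(-4 * log(2) * ((wn - 1623) / 12)^2) +
       exp(-4 * log(2) * ((wn - 1025) / 12)^2)
  M <- matrix(rep(g, 8), ncol = 8)
  ds <- manualSpectra(M, wn, labels = rep(c("mature", "immature"), each = 4))
  rr <- ratioStatistic(ds)
  expect_equal(rr$statistic, 0)
  expect_equal(rr$p.value, 1)

  M2 <- M; M2[, 3] <- 0  # a cell with no carbohydrate signal at all
  ds2 <- manualSpectra(M2, wn, labels = rep(c("mature", "immature"), each = 4))
  expect_error(ratioStatistic(ds2), "degenerate ratio.*s003")
})

test_that("peak contributions are percentages that find the marker band", {
  # generator in which ONLY the tryptophan band differs between classes
  profs <- defaultProfiles()
  profs$mature@bands$mean <- profs$immature@bands$mean
  profs$mature@bands$sd <- profs$immature@bands$sd
  i1623 <- which(profs$mature@bands$center == 1623)
  profs$mature@bands$mean[i1623] <- 3 * profs$immature@bands$mean[i1623]
  cfg <- syntheticConfig(profiles = profs,
                         nCellsPerClass = c(mature = 20L, immature = 20L),
                         spectraPerCell = 5L, seed = 23L)
  ds <- minmaxNormalize(generateDataset(cfg))
  sets <- splitDataset(ds, splitSpec(unit = "spectrum", seed = 1))
  m <- trainModel(buildModel("cnn", modelConfig(), 1015),
                  sets$train, sets$validation,
                  trainConfig(epochs = 25, seed = 1))
  for (method in c("occlusion", "weight_backprojection")) {
    cr <- peakContribution(m, sets$test, method = method)
    expect_equal(sum(cr$contribution), 100, tolerance = 1e-6)
    expect_true(all(cr$contribution >= 0))
    expect_equal(cr$center[cr$rank == 1], 1623)
    expect_equal(order(-cr$contribution)[1], which(cr$rank == 1))
  }
  expect_error(peakContribution(buildModel("mlp", modelConfig(), 1015),
                                sets$test), "state error")
})

test_that("label-shuffled models spread contribution across bands", {
  cfg <- tinyConfig(nMature = 15L, nImmature = 15L, spc = 4L, seed = 31L)
  shares <- vapply(1:5, function(seed) {
    ds <- minmaxNormalize(generateDataset(cfg))
    set.seed(seed)
    cd <- SummarizedExperiment::colData(ds)
    cd$label <- sample(cd$label)
    SummarizedExperiment::colData(ds) <- cd
    sets <- splitDataset(ds, splitSpec(unit = "spectrum", seed = seed))
    m <- trainModel(buildModel("mlp", modelConfig(), 1015),
                    sets$train, sets$validation,
                    trainConfig(epochs = 10, seed = seed))
    max(peakContribution(m, sets$test,
                         method = "weight_backprojection")$contribution)
  }, numeric(1))
  expect_lt(median(shares), 2 * 10)  # no band above twice the uniform share
})

test_that("occlusion and back-projection rank bands consistently", {
  rhos <- vapply(1:5, function(seed) {
    ds <- minmaxNormalize(generateDataset(
      tinyConfig(nMature = 12L, nImmature = 13L, spc = 6L, seed = seed)))
    sets <- splitDataset(ds, splitSpec(unit = "spectrum", seed = seed))
    m <- trainModel(buildModel("cnn", modelConfig(), 1015),
                    sets$train, sets$validation,
                    trainConfig(epochs = 25, seed = seed))
    occ <- peakContribution(m, sets$test, method = "occlusion")
    bp <- peakContribution(m, sets$test, method = "weight_backprojection")
    cor(occ$contribution, bp$contribution, method = "spearman")
  }, numeric(1))
  expect_gt(median(rhos), 0)
})

test_that("channel images map the grid faithfully", {
  cfg <- tinyConfig(seed = 3L)
  one <- generateMappingGrid(cfg, c(1L, 1L))
  img1 <- mapChannelImage(one, 1623)
  expect_equal(dim(img1), c(1L, 1L))
  expect_equal(img1[1, 1], unname(bandIntensity(one, 1623)))

  g <- generateMappingGrid(cfg, c(12L, 15L), "mature")
  img <- mapChannelImage(g, 1623)
  expect_equal(dim(img), c(12L, 15L))
  expect_false(anyNA(img))
  inc <- matrix(spectrumData(g)$in_cell[order(spectrumData(g)$x,
                                              spectrumData(g)$y)], 12, 15)
  expect_gt(mean(img[inc]), mean(img[!inc]))

  # constant spectrum field -> constant image
  flat <- manualSpectra(matrix(1, 1015, 4), tinyAxis())
  cd <- SummarizedExperiment::colData(flat)
  cd$x <- c(1, 2, 1, 2); cd$y <- c(1, 1, 2, 2)
  SummarizedExperiment::colData(flat) <- cd
  imgF <- mapChannelImage(flat, 1025)
  expect_equal(max(imgF) - min(imgF), 0)

  cd$x <- c(1, 1, 1, 2)  # duplicated position
  SummarizedExperiment::colData(flat) <- cd
  expect_error(mapChannelImage(flat, 1025), "integrity error")
})

test_that("probability heatmaps respect the threshold tie rule", {
  ev <- evaluationFromScores(c(0.99, 0.01), c("mature", "immature"))
  hm <- probabilityHeatmap(ev)
  expect_identical(hm$predicted[hm$probability == 0.99], "mature")
  expect_identical(hm$predicted[hm$probability == 0.01], "immature")
  tie <- evaluationFromScores(c(0.5, 0.5), c("mature", "immature"))
  expect_identical(probabilityHeatmap(tie)$predicted, c("mature", "mature"))
})
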