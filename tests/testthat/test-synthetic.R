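test_that("generated datasets follow the configured design", {
  cfg <- tinyConfig(nMature = 5L, nImmature = 7L, spc = 4L, seed = 11L)
  ds <- generateDataset(cfg)
  expect_s4_class(ds, "SersSpectra")
  expect_equal(nSpectra(ds), (5 + 7) * 4)
  expect_equal(length(wavenumbers(ds)), 1015)
  expect_equal(as.vector(table(spectrumLabels(ds))[c("mature", "immature")]),
               c(5 * 4, 7 * 4))
  expect_equal(length(unique(cellIds(ds))), 12)
  expect_true(all(table(cellIds(ds)) == 4))
  # defaults encode the full study design: 196 + 210 cells x 50 spectra
  def <- syntheticConfig()
  expect_equal(unname(def@nCellsPerClass), c(196L, 210L))
  expect_equal(def@spectraPerCell, 50L)
  expect_equal(sum(def@nCellsPerClass) * def@spectraPerCell, 20300)
})

test_that("generation is deterministic in the seed", {
  cfg <- tinyConfig(seed = 42L)
  a <- generateDataset(cfg)
  b <- generateDataset(cfg)
  expect_identical(SummarizedExperiment::assay(a, "intensity"),
                   SummarizedExperiment::assay(b, "intensity"))
  expect_identical(spectrumData(a), spectrumData(b))
  cfg2 <- tinyConfig(seed = 43L)
  expect_false(identical(SummarizedExperiment::assay(a, "intensity"),
                         SummarizedExperiment::assay(generateDataset(cfg2),
                                                     "intensity")))
})

test_that("noiseless degenerate configuration reproduces the class template", {
  profs <- defaultProfiles()
  for (p in names(profs)) profs[[p]]@bands$sd <- 0
  cfg <- syntheticConfig(profiles = profs,
                         nCellsPerClass = c(mature = 1L, immature = 1L),
                         spectraPerCell = 1L, cellScaleSd = 0, noiseSd = 0)
  ds <- generateDataset(cfg)
  M <- intensityMatrix(ds)
  for (cls in c("mature", "immature")) {
    got <- M[spectrumLabels(ds) == cls, ]
    expect_equal(unname(got), oracleTemplate(wavenumbers(ds), profs[[cls]]),
                 tolerance = 1e-12)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(syntheticConfig(axis = seq(600, 700, length.out = 5)),
               "at least 8 points")
  expect_error(syntheticConfig(nCellsPerClass = c(mature = 0L, immature = 5L)),
               "invalid config")
  expect_error(syntheticConfig(noiseSd = -1), "invalid config")
  expect_error(timecourseConfig(maturationProgress = c(0.5, 0.4, 1)),
               "non-decreasing")
  expect_error(timecourseConfig(timePointsH = numeric(0),
                                maturationProgress = numeric(0)),
               "at least one time point")
})

test_that("within-cell variability is smaller than between-cell variability", {
  cfg <- tinyConfig(nMature = 20L, nImmature = 20L, spc = 8L, seed = 2L,
                    cellScaleSd = 0.3, noiseSd = 0.02)
  ds <- generateDataset(cfg)
  v <- bandIntensity(ds, 1623)
  for (cls in c("mature", "immature")) {
    sel <- spectrumLabels(ds) == cls
    cellMeans <- tapply(v[sel], cellIds(ds)[sel], mean)
    withinVar <- mean(tapply(v[sel], cellIds(ds)[sel], var))
    expect_lt(withinVar, var(cellMeans))
  }
})

test_that("class separability grows with the 1623 amplitude effect", {
  # likelihood-ratio oracle under isotropic noise = nearest noiseless template
  errRate <- function(effect) {
    profs <- defaultProfiles(effect1623 = effect)
    cfg <- syntheticConfig(profiles = profs,
                           nCellsPerClass = c(mature = 40L, immature = 40L),
                           spectraPerCell = 2L, cellScaleSd = 0.1,
                           noiseSd = 0.3, seed = 7L)
    ds <- generateDataset(cfg)
    M <- intensityMatrix(ds)
    tm <- oracleTemplate(wavenumbers(ds), profs$mature)
    ti <- oracleTemplate(wavenumbers(ds), profs$immature)
    dM <- rowSums(sweep(M, 2, tm)^2)
    dI <- rowSums(sweep(M, 2, ti)^2)
    pred <- ifelse(dM < dI, "mature", "immature")
    mean(pred != spectrumLabels(ds))
  }
  errs <- vapply(c(1.02, 1.3, 3.0), errRate, numeric(1))
  expect_gt(errs[1], 0)             # nearly unseparable when the gap vanishes
  expect_true(all(diff(errs) <= 0)) # Bayes-style error falls as the gap grows
})

test_that("time-course datasets share cells and mature monotonically", {
  tc <- timecourseConfig(base = tinyConfig(nMature = 8L, nImmature = 8L,
                                           spc = 3L, seed = 5L))
  sets <- generateTimecourse(tc)
  expect_named(sets, c("2", "4", "6"))
  ids <- lapply(sets, function(d) sort(unique(cellIds(d))))
  expect_identical(ids[[1]], ids[[2]])
  expect_identical(ids[[1]], ids[[3]])
  treatedMean <- vapply(sets, function(d)
    mean(bandIntensity(d, 1623)[spectrumLabels(d) == "mature"]), numeric(1))
  expect_true(all(diff(treatedMean) >= 0))
  expect_true(all(vapply(sets, function(d)
    unique(spectrumData(d)$time_point_h), numeric(1)) == c(2, 4, 6)))
})

test_that("zero maturation progress makes the arms exchangeable", {
  tc <- timecourseConfig(base = tinyConfig(nMature = 30L, nImmature = 30L,
                                           spc = 2L, seed = 9L),
                         timePointsH = 2, maturationProgress = 0)
  d <- generateTimecourse(tc)[["2"]]
  v <- bandIntensity(minmaxNormalize(d), 1623)
  ht <- t.test(v[spectrumLabels(d) == "mature"],
               v[spectrumLabels(d) == "immature"])
  expect_gt(ht$p.value, 1e-3)  # no detectable treated/control difference
})

test_that("saturated progress keeps every time point at the mature profile", {
  tc <- timecourseConfig(base = tinyConfig(nMature = 12L, nImmature = 12L,
                                           spc = 3L, seed = 4L),
                         maturationProgress = c(1, 1, 1))
  sets <- generateTimecourse(tc)
  m1623 <- vapply(sets, function(d)
    mean(bandIntensity(d, 1623)[spectrumLabels(d) == "mature"]), numeric(1))
  expect_lt(diff(range(m1623)) / mean(m1623), 0.02)
})

test_that("mapping grids put the band signal inside the cell region", {
  cfg <- tinyConfig(seed = 3L)
  one <- generateMappingGrid(cfg, c(1L, 1L))
  expect_equal(nSpectra(one), 1L)
  expect_equal(spectrumData(one)[, c("x", "y")], data.frame(x = 1L, y = 1L))

  gm <- generateMappingGrid(cfg, c(20L, 20L), "mature")
  gi <- generateMappingGrid(cfg, c(20L, 20L), "immature")
  contrast <- function(g, center) {
    v <- bandIntensity(g, center)
    inc <- spectrumData(g)$in_cell
    mean(v[inc]) - mean(v[!inc])
  }
  expect_gt(contrast(gm, 1623), 0)
  expect_lt(contrast(gi, 1623), contrast(gm, 1623))
  # carbohydrate channel: both classes show a comparable cell/background step
  expect_gt(contrast(gi, 1025) / contrast(gm, 1025), 0.5)
  expect_lt(contrast(gi, 1025) / contrast(gm, 1025), 2)
  expect_error(generateMappingGrid(cfg, c(0L, 5L)), "invalid config")
})
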