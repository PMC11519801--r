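test_that("shape arithmetic matches brute-force window enumeration", {
  expect_equal(convOutputLength(1015, 3, 1), 1013L)
  expect_equal(convOutputLength(240, 1, 1), 240L)
  expect_equal(convOutputLength(10, 3, 2), 4L)
  expect_equal(poolOutputLength(1013, 2, 2), 506L)
  expect_equal(poolOutputLength(9, 1, 1), 9L)
  expect_equal(poolOutputLength(7, 2, 2), 3L)
  for (len in c(1, 5, 17, 40, 64)) {
    for (window in 1:8) {
      if (window > len) next
      for (stride in 1:4) {
        expect_equal(convOutputLength(len, window, stride),
                     bruteWindows(len, window, stride))
        expect_equal(poolOutputLength(len, window, stride),
                     bruteWindows(len, window, stride))
      }
    }
  }
  expect_error(convOutputLength(2, 3, 1), "shape error")
  expect_error(poolOutputLength(1, 2, 2), "shape error")
})

test_that("parameter counts equal the closed-form tally", {
  expect_equal(countConvParams(32, 3, 1), 128L)
  expect_equal(countConvParams(1, 1, 1), 2L)
  expect_equal(countConvParams(16, 5, 4), 336L)
  expect_equal(countConvParams(8, 3, 2, bias = FALSE), 48L)
})

test_that("the CNN layer-shape report reproduces the printed architecture", {
  m <- buildModel("cnn", modelConfig(), 1015)
  sh <- layerShapes(m)
  expect_equal(sh$output_length[sh$layer == "conv1d"], 1013L)
  expect_equal(sh$output_length[sh$layer == "maxpool1d"], 506L)
  expect_equal(sh$output_length[sh$layer == "flatten"], 506L * 32L)
  expect_equal(sh$params[sh$layer == "conv1d"], 128L)
  # independent per-layer closed-form tally
  expect_equal(sum(sh$params),
               32 * (3 + 1) + (506 * 32) * 32 + 32 + 32 + 1)
  expect_error(buildModel("rnn", modelConfig(), 1015), "config error")
  expect_error(buildModel("cnn", modelConfig(), 2), "shape error")
})

test_that("trapezoidal AUC equals the pairwise-concordance oracle", {
  ev <- evaluationFromScores(c(0.1, 0.4, 0.35, 0.8),
                             c("immature", "immature", "mature", "mature"))
  expect_equal(auc(ev), 0.75)  # brute force over all label pairs
  perfect <- evaluationFromScores(c(0.9, 0.8, 0.2, 0.1),
                                  rep(c("mature", "immature"), each = 2))
  expect_equal(auc(perfect), 1.0)

  set.seed(33)
  for (i in 1:20) {
    n <- sample(6:40, 1)
    labels <- sample(c("mature", "immature"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    scores <- round(runif(n), 1)  # coarse grid to force ties
    ev <- evaluationFromScores(scores, labels)
    expect_equal(auc(ev), concordanceAUC(scores, labels), tolerance = 1e-12)
    roc <- rocCurve(ev)
    expect_equal(c(roc$fpr[1], roc$tpr[1]), c(0, 0))
    expect_equal(c(roc$fpr[nrow(roc)], roc$tpr[nrow(roc)]), c(1, 1))
    expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
  }
})

test_that("trapezoidal AUC agrees with an independent library", {
  skip_if_not_installed("pROC")
  set.seed(44)
  labels <- sample(c("mature", "immature"), 60, replace = TRUE)
  scores <- runif(60) + 0.5 * (labels == "mature")
  ours <- auc(evaluationFromScores(scores, labels))
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores, levels = c("immature", "mature"),
    direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("confusion metrics follow their definitions", {
  labels <- c(rep("mature", 50), rep("immature", 50))
  scores <- c(rep(0.9, 49), 0.1, rep(0.2, 50))  # one missed mature cell
  ev <- evaluationFromScores(scores, labels)
  expect_equal(unname(confusionMatrix(ev)), c(49, 0, 50, 1))
  expect_equal(ev@sensitivity, 0.98)
  expect_equal(ev@specificity, 1.0)
  expect_equal(ev@accuracy, 0.99)
  expect_warning(ev1 <- evaluationFromScores(c(0.9, 0.8), c("mature", "mature")),
                 "AUC undefined")
  expect_true(is.na(auc(ev1)))
  expect_equal(ev1@accuracy, 1)
})

test_that("training on a separable toy problem reduces the loss monotonically", {
  wn <- seq(600, 740, length.out = 8)
  M <- cbind(c(0, 0, 0, 1, 1, 0, 0, 0), c(1, 1, 0, 0, 0, 0, 1, 1))
  M <- M[, rep(1:2, each = 16)]
  ds <- manualSpectra(M, wn, labels = rep(c("mature", "immature"), each = 16))
  m <- buildModel("mlp", modelConfig(), 8)
  fit <- trainModel(m, ds, ds, trainConfig(epochs = 15, seed = 2))
  h <- trainingHistory(fit)
  expect_true(all(diff(h$train_loss[-1]) < 1e-8))
  expect_equal(h$val_acc[15], 1)
})

test_that("the plateau scheduler decays the learning rate to its floor", {
  wn <- seq(600, 740, length.out = 8)
  set.seed(5)
  M <- matrix(runif(8 * 24), 8)
  labels <- rep(c("mature", "immature"), 12)
  ds <- manualSpectra(M, wn, labels = labels)
  # validation labels are flipped, so validation loss cannot keep improving
  # and the plateau scheduler has to fire repeatedly
  val <- manualSpectra(M, wn, labels = rev(labels))
  cfg <- trainConfig(epochs = 60, schedPatience = 2L, minLearningRate = 1e-5,
                     seed = 3)
  fit <- trainModel(buildModel("mlp", modelConfig(), 8), ds, val, cfg)
  lr <- trainingHistory(fit)$lr
  expect_true(all(diff(lr) <= 0))          # non-increasing trajectory
  expect_true(all(lr >= 1e-5 - 1e-15))     # floored at the minimum
  expect_equal(min(lr), 1e-5)              # the floor is actually reached
})

test_that("training is seeded and guards its preconditions", {
  ds <- minmaxNormalize(generateDataset(tinyConfig(seed = 21L)))
  sets <- splitDataset(ds, splitSpec(unit = "spectrum", seed = 1))
  cfg <- trainConfig(epochs = 3, seed = 9)
  m1 <- trainModel(buildModel("cnn", modelConfig(), 1015),
                   sets$train, sets$validation, cfg)
  m2 <- trainModel(buildModel("cnn", modelConfig(), 1015),
                   sets$train, sets$validation, cfg)
  expect_identical(trainingHistory(m1), trainingHistory(m2))
  expect_identical(predictProb(m1, sets$test), predictProb(m2, sets$test))

  onlyMature <- sets$train[, spectrumLabels(sets$train) == "mature"]
  expect_error(trainModel(buildModel("mlp", modelConfig(), 1015),
                          onlyMature, sets$validation, cfg),
               "single class")
  raw <- generateDataset(tinyConfig(seed = 21L))  # not normalised
  rawSets <- splitDataset(raw, splitSpec(unit = "spectrum", seed = 1))
  expect_warning(trainModel(buildModel("mlp", modelConfig(), 1015),
                            rawSets$train, rawSets$validation, cfg),
                 "minmaxNormalize")
})

test_that("predictions are probabilities and deterministic at inference", {
  ds <- minmaxNormalize(generateDataset(tinyConfig(seed = 22L)))
  sets <- splitDataset(ds, splitSpec(unit = "spectrum", seed = 2))
  m <- trainModel(buildModel("mlp", modelConfig(), 1015),
                  sets$train, sets$validation, trainConfig(epochs = 5, seed = 1))
  p <- predictProb(m, sets$test)
  expect_true(all(p > 0 & p < 1))
  dup <- sets$test[, c(1, 1)]
  colnames(dup) <- c("a", "b")
  pd <- predictProb(m, dup)
  expect_equal(unname(pd[1]), unname(pd[2]))
  short <- SersSpectra(matrix(runif(20), 10), seq(600, 700, length.out = 10))
  expect_error(predictProb(m, short), "shape error")
  expect_error(predictProb(buildModel("mlp", modelConfig(), 1015), sets$test),
               "state error")
})

test_that("random labels on pure noise train to chance accuracy", {
  wn <- tinyAxis()
  accs <- vapply(1:3, function(seed) {
    set.seed(seed + 100)
    M <- matrix(runif(1015 * 260), 1015)
    labels <- sample(rep(c("mature", "immature"), each = 130))
    ds <- manualSpectra(M, wn, labels = labels)
    sets <- splitDataset(ds, splitSpec(fractions = c(0.5, 0.3, 0.2),
                                       unit = "spectrum", seed = seed))
    fit <- trainModel(buildModel("mlp", modelConfig(), 1015),
                      sets$train, sets$validation,
                      trainConfig(epochs = 20, seed = seed))
    tail(trainingHistory(fit)$val_acc, 1)
  }, numeric(1))
  expect_lt(abs(median(accs) - 0.5), 0.05)
})

test_that("all three architectures run end-to-end on a toy set", {
  wn <- seq(600, 660, length.out = 4)
  M <- matrix(runif(40), 4)
  ds <- manualSpectra(M, wn, labels = rep(c("mature", "immature"), 5))
  for (arch in c("cnn", "dnn", "mlp")) {
    m <- trainModel(buildModel(arch, modelConfig(), 4), ds, ds,
                    trainConfig(epochs = 2, seed = 1))
    expect_length(predictProb(m, ds), 10)
  }
})
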