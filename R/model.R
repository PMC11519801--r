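#' @include AllClasses.R
NULL

#' Convolution / pooling output lengths and parameter counts
#'
#' Closed-form shape arithmetic for 1-D layers with valid (no) padding:
#' `floor((input_len - window) / stride) + 1` output positions, and
#' `filters * (kernel * in_channels + 1)` trainable parameters for a biased
#' convolution. For the reference architecture, a 1015-point spectrum gives a
#' 1013-long convolution output (32 filters, 128 parameters) and a 506-long
#' pooled output.
#'
#' @param inputLen input feature length.
#' @param kernel,poolSize window length.
#' @param stride window step.
#' @param filters,inChannels,bias parameter-count inputs.
#' @return an integer length or parameter count.
#' @export
convOutputLength <- function(inputLen, kernel, stride = 1L) {
  if (kernel > inputLen)
    stop("shape error: kernel (", kernel, ") exceeds input length (", inputLen, ")")
  if (kernel < 1 || stride < 1) stop("shape error: kernel and stride must be >= 1")
  as.integer((inputLen - kernel) %/% stride + 1L)
}

#' @rdname convOutputLength
#' @export
poolOutputLength <- function(inputLen, poolSize, stride = poolSize) {
  if (poolSize > inputLen)
    stop("shape error: pool size (", poolSize, ") exceeds input length (", inputLen, ")")
  as.integer((inputLen - poolSize) %/% stride + 1L)
}

#' @rdname convOutputLength
#' @export
countConvParams <- function(filters, kernel, inChannels = 1L, bias = TRUE) {
  stopifnot(filters >= 1, kernel >= 1, inChannels >= 1)
  as.integer(filters * (kernel * inChannels + as.integer(bias)))
}

# Architecture descriptor handed to the C++ engine.
.archSpec <- function(arch, config, inputLen) {
  switch(arch,
    cnn = list(input_len = as.integer(inputLen), conv = TRUE,
               filters = config@convFilters, kernel = config@convKernel,
               stride = config@convStride, pool = config@poolSize,
               pool_stride = config@poolStride,
               conv_dropout = config@dropoutRate,
               dense_sizes = c(config@denseUnits, 1L),
               dense_dropout = c(0, 0),
               dense_l2 = c(config@l2Coeff, 0)),
    dnn = list(input_len = as.integer(inputLen), conv = FALSE,
               filters = 0L, kernel = 0L, stride = 0L, pool = 0L,
               pool_stride = 0L, conv_dropout = 0,
               dense_sizes = c(128L, 128L, 128L, 1L),
               dense_dropout = c(0.25, 0.25, 0.25, 0),
               dense_l2 = c(0, 0, 0, 0)),
    mlp = list(input_len = as.integer(inputLen), conv = FALSE,
               filters = 0L, kernel = 0L, stride = 0L, pool = 0L,
               pool_stride = 0L, conv_dropout = 0,
               dense_sizes = c(64L, 1L),
               dense_dropout = c(0, 0),
               dense_l2 = c(0, 0)),
    stop("config error: unknown architecture '", arch,
         "' (use cnn, dnn or mlp)"))
}

#' Build a spectral classifier
#'
#' `"cnn"` is the reference architecture: Conv1D (ReLU) -> dropout ->
#' max-pool -> flatten -> dense ReLU layer with L2 penalty -> single sigmoid
#' unit. `"dnn"` (three 128-unit ReLU layers with dropout 0.25) and `"mlp"`
#' (one 64-unit ReLU layer) are fully connected baselines for the
#' architecture comparison; both end in one sigmoid unit. Weights are
#' initialised on first training with fan-in/fan-out scaled (Glorot) uniform
#' draws from the run seed.
#'
#' @param arch `"cnn"`, `"dnn"` or `"mlp"`.
#' @param config a [modelConfig()] (used by the CNN).
#' @param inputLen spectrum length the model accepts.
#' @return an untrained [SersModel-class]; inspect with [layerShapes()].
#' @export
buildModel <- function(arch = c("cnn", "dnn", "mlp"), config = modelConfig(),
                       inputLen = 1015L) {
  if (length(arch) > 1) arch <- arch[1]
  validObject(config)
  inputLen <- as.integer(inputLen)
  spec <- .archSpec(arch, config, inputLen)   # validates arch
  if (arch == "cnn" && config@convKernel > inputLen)
    stop("shape error: kernel exceeds input length")
  new("SersModel", arch = arch, inputLength = inputLen, config = config,
      params = list(), trained = FALSE,
      history = data.frame())
}

#' Per-layer shape and parameter report
#'
#' @param x a [SersModel-class].
#' @return `data.frame` with one row per layer: `layer`, `output_length`
#'   (feature-axis length, or unit count for dense layers), `channels`,
#'   `params`. Batch size is not part of the report; reported shapes are per
#'   sample.
#' @export
setGeneric("layerShapes", function(x) standardGeneric("layerShapes"))

#' @rdname layerShapes
setMethod("layerShapes", "SersModel", function(x) {
  cfg <- x@config
  L <- x@inputLength
  if (x@arch == "cnn") {
    lc <- convOutputLength(L, cfg@convKernel, cfg@convStride)
    lp <- poolOutputLength(lc, cfg@poolSize, cfg@poolStride)
    flat <- lp * cfg@convFilters
    data.frame(
      layer = c("input", "conv1d", "dropout", "maxpool1d", "flatten",
                "dense_relu", "dense_sigmoid"),
      output_length = c(L, lc, lc, lp, flat, cfg@denseUnits, 1L),
      channels = c(1L, cfg@convFilters, cfg@convFilters, cfg@convFilters,
                   1L, 1L, 1L),
      params = c(0L, countConvParams(cfg@convFilters, cfg@convKernel, 1L),
                 0L, 0L, 0L,
                 as.integer(flat * cfg@denseUnits + cfg@denseUnits),
                 as.integer(cfg@denseUnits + 1L)))
  } else {
    sizes <- .archSpec(x@arch, cfg, L)$dense_sizes
    ins <- c(L, utils::head(sizes, -1))
    acts <- c(rep("dense_relu", length(sizes) - 1), "dense_sigmoid")
    data.frame(
      layer = c("input", acts),
      output_length = c(L, sizes),
      channels = 1L,
      params = c(0L, as.integer(ins * sizes + sizes)))
  }
})

.asXY <- function(data, inputLen = NULL) {
  X <- intensityMatrix(data)
  if (!is.null(inputLen) && ncol(X) != inputLen)
    stop("shape error: dataset has ", ncol(X),
         " wavenumbers but the model expects ", inputLen)
  lab <- spectrumLabels(data)
  list(X = X, y = as.numeric(lab == "mature"), lab = lab)
}

#' Train a spectral classifier
#'
#' Runs mini-batch SGD with momentum on binary cross-entropy for
#' `config@epochs` epochs; after every epoch the validation loss is
#' monitored by a reduce-on-plateau scheduler (factor `schedFactor`,
#' patience `schedPatience`, floored at `minLearningRate`). The positive
#' class is `mature`. All randomness derives from `config@seed`, so a fixed
#' seed (and thread policy) reproduces the run.
#'
#' @param model an untrained or trained [SersModel-class] (training restarts
#'   from fresh seeded weights).
#' @param train,validation labelled, normalised [SersSpectra] sets; the
#'   training set must contain both classes.
#' @param config a [trainConfig()].
#' @return the trained [SersModel-class] carrying its training history
#'   (loss/accuracy curves and learning-rate trajectory); see
#'   [trainingHistory()].
#' @export
setGeneric("trainModel", function(model, train, validation,
                                  config = trainConfig())
  standardGeneric("trainModel"))

#' @rdname trainModel
setMethod("trainModel", "SersModel", function(model, train, validation,
                                              config = trainConfig()) {
  validObject(config)
  if (nSpectra(train) == 0 || nSpectra(validation) == 0)
    stop("training error: train and validation sets must be non-empty")
  tr <- .asXY(train, model@inputLength)
  va <- .asXY(validation, model@inputLength)
  if (length(unique(tr$y)) < 2)
    stop("training error: training set contains a single class")
  if (min(tr$X) < -1e-9 || max(tr$X) > 1 + 1e-9)
    warning("training input outside [0, 1]; did you forget minmaxNormalize()?")
  spec <- .archSpec(model@arch, model@config, model@inputLength)
  tc <- list(epochs = config@epochs, batch_size = config@batchSize,
             learning_rate = config@learningRate, momentum = config@momentum,
             sched_factor = config@schedFactor,
             sched_patience = config@schedPatience,
             min_learning_rate = config@minLearningRate)
  fit <- withSeed(config@seed, {
    params <- cpp_init_params(spec)
    cpp_train(tr$X, tr$y, va$X, va$y, spec, params, tc)
  })
  model@params <- fit$params
  model@trained <- TRUE
  model@history <- data.frame(
    epoch = seq_len(config@epochs), lr = fit$lr,
    train_loss = fit$train_loss, train_acc = fit$train_acc,
    val_loss = fit$val_loss, val_acc = fit$val_acc)
  model
})

#' Predict mature-class probabilities
#'
#' @param model a trained [SersModel-class].
#' @param data a [SersSpectra] on the model's axis length.
#' @return numeric vector of probabilities in (0, 1), named by spectrum id,
#'   in input order.
#' @export
setGeneric("predictProb", function(model, data) standardGeneric("predictProb"))

#' @rdname predictProb
setMethod("predictProb", "SersModel", function(model, data) {
  if (!model@trained) stop("state error: model is not trained")
  xy <- .asXY(data, model@inputLength)
  spec <- .archSpec(model@arch, model@config, model@inputLength)
  p <- as.numeric(cpp_predict(xy$X, spec, model@params))
  names(p) <- colnames(data)
  p
})

# ROC curve over all score thresholds; ties grouped. Returns points from
# (0,0) to (1,1), non-decreasing in both coordinates.
.rocCurve <- function(scores, positive) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yp <- positive[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(yp); fp <- cumsum(!yp)
  last <- !duplicated(grp, fromLast = TRUE)
  P <- sum(positive); N <- sum(!positive)
  data.frame(threshold = c(Inf, s[last]),
             fpr = c(0, fp[last] / max(N, 1)),
             tpr = c(0, tp[last] / max(P, 1)))
}

.trapezoidAUC <- function(roc)
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)

#' Evaluate a classifier on a labelled dataset
#'
#' Thresholds the predicted mature-class probabilities (ties predict the
#' positive class), tabulates the confusion matrix with mature as positive,
#' and computes accuracy, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, the full ROC curve and its trapezoidal AUC (equal to the
#' pairwise-concordance probability with ties counted 1/2). If only one class
#' is present the AUC is undefined and returned as `NA` with a warning.
#'
#' @param model a trained [SersModel-class].
#' @param data a labelled [SersSpectra] (labels `mature`/`immature`).
#' @param threshold decision threshold on the mature-class probability.
#' @return an [EvaluationReport-class].
#' @export
setGeneric("evaluateModel", function(model, data, threshold = 0.5)
  standardGeneric("evaluateModel"))

#' @rdname evaluateModel
setMethod("evaluateModel", "SersModel", function(model, data, threshold = 0.5) {
  lab <- spectrumLabels(data)
  if (any(lab == "unknown"))
    stop("evaluation requires labelled spectra (found 'unknown')")
  p <- predictProb(model, data)
  evaluationFromScores(p, lab, threshold)
})

#' Build an EvaluationReport from scores and labels
#'
#' The metric arithmetic behind [evaluateModel()], exposed so that persisted
#' probabilities can be re-evaluated without the model.
#'
#' @param scores mature-class probabilities.
#' @param labels character labels (`mature`/`immature`).
#' @param threshold decision threshold; ties predict mature.
#' @return an [EvaluationReport-class].
#' @export
evaluationFromScores <- function(scores, labels, threshold = 0.5) {
  pos <- labels == "mature"
  pred <- scores >= threshold
  cm <- c(TP = sum(pred & pos), FP = sum(pred & !pos),
          TN = sum(!pred & !pos), FN = sum(!pred & pos))
  sens <- if (sum(pos)) cm[["TP"]] / (cm[["TP"]] + cm[["FN"]]) else NaN
  spec <- if (sum(!pos)) cm[["TN"]] / (cm[["TN"]] + cm[["FP"]]) else NaN
  if (length(unique(labels)) < 2) {
    warning("AUC undefined: evaluation set contains a single class")
    roc <- data.frame(threshold = numeric(0), fpr = numeric(0),
                      tpr = numeric(0))
    auc <- NA_real_
  } else {
    roc <- .rocCurve(scores, pos)
    auc <- .trapezoidAUC(roc)
  }
  new("EvaluationReport",
      confusion = setNames(as.numeric(cm), names(cm)),
      accuracy = mean(pred == pos), sensitivity = sens, specificity = spec,
      auc = auc, roc = roc, probabilities = as.numeric(scores),
      trueLabels = as.character(labels), threshold = threshold)
}

#' Confusion-matrix accessors
#'
#' @param x an [EvaluationReport-class].
#' @return `confusionMatrix()`: named numeric (TP, FP, TN, FN);
#'   `rocCurve()`: the ROC points; `auc()`: the trapezoidal AUC.
#' @export
confusionMatrix <- function(x) setNames(x@confusion, c("TP", "FP", "TN", "FN"))

#' @rdname confusionMatrix
#' @export
rocCurve <- function(x) x@roc

#' @rdname confusionMatrix
#' @export
auc <- function(x) x@auc
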