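#' @include AllClasses.R
NULL

#' @export
setClass("RunConfig",
  representation(synthetic = "ANY", inputSpectra = "character",
                 spectraFormat = "character", arch = "character",
                 model = "ModelConfig", train = "TrainConfig",
                 split = "SplitSpec", perCell = "logical",
                 contributionMethod = "character", ratioBands = "numeric",
                 halfWindow = "numeric", outDir = "character",
                 seed = "integer"))

#' End-to-end experiment configuration
#'
#' Bundles the data source (a [syntheticConfig()] or a spectra file readable
#' by [readSpectra()]; exactly one), the split, architecture, model and
#' training settings, and the interpretation options. `seed` is the run
#' seed: it overrides the seeds of the nested synthetic, split and training
#' configurations so one integer reproduces the whole run.
#'
#' @param synthetic a [syntheticConfig()], or `NULL` when reading files.
#' @param inputSpectra path to a spectra file, or `NULL`.
#' @param spectraFormat dialect for `inputSpectra`.
#' @param arch `"cnn"`, `"dnn"` or `"mlp"`.
#' @param model a [modelConfig()].
#' @param train a [trainConfig()].
#' @param split a [splitSpec()].
#' @param perCell train on per-cell averaged spectra (the single-cell model)
#'   instead of individual spectra.
#' @param contributionMethod see [peakContribution()].
#' @param ratioBands numerator/denominator band centers for
#'   [ratioStatistic()].
#' @param halfWindow band half-window, cm^-1.
#' @param outDir directory for persisted artifacts, or `NULL` to keep the
#'   run in memory.
#' @param seed run seed.
#' @return a `RunConfig`.
#' @export
runConfig <- function(synthetic = syntheticConfig(), inputSpectra = NULL,
                      spectraFormat = "wide_csv", arch = "cnn",
                      model = modelConfig(), train = trainConfig(),
                      split = splitSpec(), perCell = FALSE,
                      contributionMethod = "occlusion",
                      ratioBands = c(1623, 1025), halfWindow = 6,
                      outDir = NULL, seed = 1L) {
  new("RunConfig", synthetic = synthetic,
      inputSpectra = as.character(inputSpectra %||% character(0)),
      spectraFormat = spectraFormat, arch = arch, model = model,
      train = train, split = split, perCell = perCell,
      contributionMethod = contributionMethod,
      ratioBands = as.numeric(ratioBands), halfWindow = as.numeric(halfWindow),
      outDir = as.character(outDir %||% character(0)), seed = as.integer(seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

setValidity("RunConfig", function(object) {
  hasSyn <- !is.null(object@synthetic)
  hasFile <- length(object@inputSpectra) == 1
  if (hasSyn == hasFile)
    return("exactly one data source (synthetic or inputSpectra) is required")
  if (hasSyn && !is(object@synthetic, "SyntheticConfig"))
    return("synthetic must be a SyntheticConfig")
  if (!object@arch %in% c("cnn", "dnn", "mlp"))
    return("arch must be cnn, dnn or mlp")
  if (length(object@ratioBands) != 2) return("ratioBands must have length 2")
  TRUE
})

# Column-concatenate datasets sharing one axis (spectrum ids must be unique).
.concatSpectra <- function(xs) {
  xs <- xs[vapply(xs, nSpectra, integer(1)) > 0]
  if (!length(xs)) stop("no spectra to concatenate")
  M <- do.call(cbind, lapply(xs, function(x)
    SummarizedExperiment::assay(x, "intensity")))
  meta <- do.call(rbind, lapply(xs, spectrumData))
  SersSpectra(M, wavenumbers(xs[[1]]), meta)
}

.stageLog <- function(stage, nin, nout)
  message(sprintf("[sersdc] %-12s in=%d out=%d", stage, nin, nout))

.loadRunData <- function(config) {
  if (!is.null(config@synthetic)) {
    syn <- config@synthetic
    syn@seed <- config@seed
    generateDataset(syn)
  } else {
    readSpectra(config@inputSpectra, config@spectraFormat)
  }
}

.evalSubsets <- function(model, sets, threshold) {
  out <- list()
  for (nm in names(sets))
    if (nSpectra(sets[[nm]]) > 0)
      out[[nm]] <- evaluateModel(model, sets[[nm]], threshold)
  out
}

.metricsList <- function(ev) {
  cm <- confusionMatrix(ev)
  list(TP = cm[["TP"]], FP = cm[["FP"]], TN = cm[["TN"]], FN = cm[["FN"]],
       accuracy = ev@accuracy, sensitivity = ev@sensitivity,
       specificity = ev@specificity, auc = ev@auc,
       probabilities = as.numeric(ev@probabilities),
       true_labels = ev@trueLabels)
}

.persistRun <- function(config, dataset, sets, model, evals, contrib, ratio,
                        outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  manifest <- do.call(rbind, lapply(names(sets), function(nm) {
    md <- spectrumData(sets[[nm]])
    data.frame(spectrum_id = md$spectrum_id, cell_id = md$cell_id,
               label = md$label, subset = nm)
  }))
  data.table::fwrite(manifest, file.path(outDir, "split_manifest.csv"))
  data.table::fwrite(trainingHistory(model), file.path(outDir, "curves.csv"))
  jsonlite::write_json(lapply(evals, .metricsList),
                       file.path(outDir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(contrib))
    data.table::fwrite(as.data.frame(contrib),
                       file.path(outDir, "contribution.csv"))
  if (!is.null(ratio)) {
    data.table::fwrite(ratio$ratios, file.path(outDir, "ratio.csv"))
    jsonlite::write_json(list(test = ratio$test, statistic = ratio$statistic,
                              p.value = ratio$p.value),
                         file.path(outDir, "ratio_test.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  cfgFile <- file.path(outDir, "run_config.json")
  writeRunConfig(config, cfgFile)
  unname(tools::md5sum(cfgFile))
}

#' Run the full classification experiment
#'
#' Executes generate/load -> normalise -> (optional per-cell averaging) ->
#' split -> train -> evaluate -> interpret, logging one record per stage.
#' When `outDir` is set, every result table is persisted in documented
#' plain-text formats (split manifest, training curves, per-subset metrics
#' with probabilities, contribution and ratio tables, and the run
#' configuration with its md5 as provenance).
#'
#' @param config a [runConfig()].
#' @return a [RunReport-class] with the dataset summary, the trained model,
#'   per-subset [EvaluationReport-class]s, the contribution and ratio
#'   reports, and provenance.
#' @export
runExperiment <- function(config) {
  validObject(config)
  dataset <- .loadRunData(config)
  .stageLog("load", 0L, nSpectra(dataset))
  norm <- minmaxNormalize(dataset)
  .stageLog("normalize", nSpectra(dataset), nSpectra(norm))
  work <- norm
  if (config@perCell) {
    work <- minmaxNormalize(averagePerCell(norm))
    .stageLog("average", nSpectra(norm), nSpectra(work))
  }
  split <- config@split
  split@seed <- config@seed
  sets <- splitDataset(work, split)
  .stageLog("split", nSpectra(work),
            sum(vapply(sets, nSpectra, integer(1))))
  tc <- config@train
  tc@seed <- config@seed
  model <- buildModel(config@arch, config@model, length(wavenumbers(work)))
  model <- trainModel(model, sets$train, sets$validation, tc)
  .stageLog("train", nSpectra(sets$train), nrow(trainingHistory(model)))
  evals <- .evalSubsets(model, sets, tc@decisionThreshold)
  .stageLog("evaluate", nSpectra(sets$test),
            length(evals))
  contrib <- tryCatch(
    peakContribution(model, sets$test, method = config@contributionMethod,
                     halfWindow = config@halfWindow),
    error = function(e) NULL)
  ratio <- tryCatch({
    cells <- if (config@perCell) work else minmaxNormalize(averagePerCell(norm))
    ratioStatistic(cells, config@ratioBands[1], config@ratioBands[2],
                   halfWindow = config@halfWindow)
  }, error = function(e) NULL)
  .stageLog("interpret", nSpectra(sets$test),
            (!is.null(contrib)) + (!is.null(ratio)))
  prov <- list(seed = config@seed, arch = config@arch,
               package_version = as.character(utils::packageVersion("sersdc")),
               r_version = R.version.string)
  if (length(config@outDir) == 1)
    prov$config_md5 <- .persistRun(config, dataset, sets, model, evals,
                                   contrib, ratio, config@outDir)
  lab <- spectrumLabels(dataset)
  new("RunReport",
      datasetSummary = list(
        n_spectra = nSpectra(dataset),
        n_cells = length(unique(stats::na.omit(cellIds(dataset)))),
        labels = as.list(table(lab)),
        n_wavenumbers = length(wavenumbers(dataset))),
      model = model, evaluations = evals, contribution = contrib,
      ratio = ratio, timecourse = list(), provenance = prov)
}

#' Run the time-course experiment
#'
#' Applies the training protocol at each acquisition time point of a
#' maturation time-course: by default one model per time point (normalise,
#' 70/20/10 split within the time point, train, evaluate); in
#' `mode = "shared"` a single model is trained on the pooled training splits
#' of all time points and evaluated on each time point's test split.
#'
#' @param config a [timecourseConfig()].
#' @param arch,model,train,split as in [runConfig()].
#' @param seed run seed, overriding nested seeds.
#' @param mode `"per_time_point"` or `"shared"`.
#' @param timePoints optional subset of hours to train/evaluate (the full
#'   time-course is still generated so cell trajectories are unchanged).
#' @return a [RunReport-class] whose `@timecourse` slot is a named list (one
#'   entry per hour) of `list(evaluation=, history=)`.
#' @export
runTimecourse <- function(config, arch = "cnn", model = modelConfig(),
                          train = trainConfig(), split = splitSpec(),
                          seed = 1L, mode = c("per_time_point", "shared"),
                          timePoints = NULL) {
  mode <- match.arg(mode)
  validObject(config)
  base <- config@base
  base@seed <- as.integer(seed)
  config@base <- base
  datasets <- generateTimecourse(config)
  if (!is.null(timePoints))
    datasets <- datasets[as.character(timePoints)]
  sets <- lapply(datasets, function(d) {
    lab <- spectrumLabels(d)
    if (length(unique(lab)) < 2)
      stop("design error: a time point lacks a treated or control arm")
    sp <- split
    sp@seed <- as.integer(seed)
    splitDataset(minmaxNormalize(d), sp)
  })
  tc <- train
  tc@seed <- as.integer(seed)
  L <- length(config@base@axis)
  out <- list()
  if (mode == "per_time_point") {
    for (nm in names(sets)) {
      m <- buildModel(arch, model, L)
      m <- trainModel(m, sets[[nm]]$train, sets[[nm]]$validation, tc)
      out[[nm]] <- list(
        evaluation = evaluateModel(m, sets[[nm]]$test, tc@decisionThreshold),
        history = trainingHistory(m))
      .stageLog(paste0("t=", nm, "h"), nSpectra(sets[[nm]]$train),
                nSpectra(sets[[nm]]$test))
    }
  } else {
    pooledTrain <- .concatSpectra(lapply(sets, `[[`, "train"))
    pooledVal <- .concatSpectra(lapply(sets, `[[`, "validation"))
    m <- buildModel(arch, model, L)
    m <- trainModel(m, pooledTrain, pooledVal, tc)
    for (nm in names(sets))
      out[[nm]] <- list(
        evaluation = evaluateModel(m, sets[[nm]]$test, tc@decisionThreshold),
        history = trainingHistory(m))
  }
  new("RunReport",
      datasetSummary = list(
        time_points_h = as.numeric(names(datasets)),
        n_spectra = vapply(datasets, nSpectra, integer(1))),
      model = if (mode == "shared") m else NULL,
      evaluations = list(), contribution = NULL, ratio = NULL,
      timecourse = out,
      provenance = list(seed = as.integer(seed), arch = arch, mode = mode))
}

#' Compare classifier architectures on identical data and split
#'
#' Normalises the dataset once, splits it once, then trains and evaluates
#' each requested architecture on exactly the same subsets.
#'
#' @param x a labelled [SersSpectra].
#' @param archs architectures to compare.
#' @param model,train,split as in [runConfig()].
#' @param seed run seed (overrides nested seeds).
#' @return `data.frame` with one row per architecture: accuracy,
#'   sensitivity, specificity, AUC on the test set, and the seed.
#' @export
compareAlgorithms <- function(x, archs = c("cnn", "dnn", "mlp"),
                              model = modelConfig(), train = trainConfig(),
                              split = splitSpec(), seed = 1L) {
  norm <- minmaxNormalize(x)
  sp <- split
  sp@seed <- as.integer(seed)
  sets <- splitDataset(norm, sp)
  tc <- train
  tc@seed <- as.integer(seed)
  L <- length(wavenumbers(x))
  rows <- lapply(archs, function(a) {
    m <- trainModel(buildModel(a, model, L), sets$train, sets$validation, tc)
    ev <- evaluateModel(m, sets$test, tc@decisionThreshold)
    data.frame(arch = a, accuracy = ev@accuracy, sensitivity = ev@sensitivity,
               specificity = ev@specificity, auc = ev@auc,
               seed = as.integer(seed))
  })
  do.call(rbind, rows)
}

# --- configuration files ----------------------------------------------------

#' Read / write run configurations as YAML or JSON
#'
#' A plain-mapping serialisation of [runConfig()] (nested `synthetic`,
#' `model`, `train`, `split` sections mirroring the constructor arguments;
#' the synthetic axis is stored as `min`/`max`/`points`). The format follows
#' the file extension (`.yaml`/`.yml` or `.json`).
#'
#' @param path configuration file.
#' @param config a [runConfig()].
#' @return `readRunConfig()` returns a [runConfig()]; `writeRunConfig()`
#'   returns `path` invisibly.
#' @export
readRunConfig <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  synRaw <- raw$synthetic
  syn <- if (is.null(synRaw) && !is.null(raw$input_spectra)) NULL else {
    ax <- synRaw$axis %||% list(min = 600, max = 1700, points = 1015)
    syntheticConfig(
      axis = seq(ax$min, ax$max, length.out = ax$points),
      profiles = defaultProfiles(effect1623 = synRaw$effect1623 %||% 3.0),
      nCellsPerClass = c(mature = synRaw$n_mature %||% 196L,
                         immature = synRaw$n_immature %||% 210L),
      spectraPerCell = synRaw$spectra_per_cell %||% 50L,
      cellScaleSd = synRaw$cell_scale_sd %||% 0.15,
      noiseSd = synRaw$noise_sd %||% 0.02,
      seed = synRaw$seed %||% 1L)
  }
  mc <- do.call(modelConfig, raw$model %||% list())
  tr <- do.call(trainConfig, raw$train %||% list())
  spRaw <- raw$split %||% list()
  sp <- splitSpec(
    fractions = unlist(spRaw$fractions %||% c(0.7, 0.2, 0.1)),
    unit = spRaw$unit %||% "cell",
    seed = spRaw$seed %||% 1L,
    shuffle = spRaw$shuffle %||% TRUE,
    stratify = spRaw$stratify %||% TRUE)
  runConfig(synthetic = syn, inputSpectra = raw$input_spectra,
            spectraFormat = raw$spectra_format %||% "wide_csv",
            arch = raw$arch %||% "cnn", model = mc, train = tr, split = sp,
            perCell = raw$per_cell %||% FALSE,
            contributionMethod = raw$contribution_method %||% "occlusion",
            ratioBands = unlist(raw$ratio_bands %||% c(1623, 1025)),
            halfWindow = raw$half_window %||% 6,
            outDir = raw$out_dir, seed = raw$seed %||% 1L)
}

#' @rdname readRunConfig
#' @export
writeRunConfig <- function(config, path) {
  syn <- config@synthetic
  obj <- list(
    seed = config@seed, arch = config@arch, per_cell = config@perCell,
    contribution_method = config@contributionMethod,
    ratio_bands = config@ratioBands, half_window = config@halfWindow,
    synthetic = if (is.null(syn)) NULL else list(
      axis = list(min = min(syn@axis), max = max(syn@axis),
                  points = length(syn@axis)),
      n_mature = syn@nCellsPerClass[["mature"]],
      n_immature = syn@nCellsPerClass[["immature"]],
      spectra_per_cell = syn@spectraPerCell,
      cell_scale_sd = syn@cellScaleSd, noise_sd = syn@noiseSd,
      seed = syn@seed),
    input_spectra = if (length(config@inputSpectra)) config@inputSpectra else NULL,
    spectra_format = config@spectraFormat,
    model = list(convFilters = config@model@convFilters,
                 convKernel = config@model@convKernel,
                 convStride = config@model@convStride,
                 dropoutRate = config@model@dropoutRate,
                 poolSize = config@model@poolSize,
                 poolStride = config@model@poolStride,
                 denseUnits = config@model@denseUnits,
                 l2Coeff = config@model@l2Coeff),
    train = list(epochs = config@train@epochs,
                 batchSize = config@train@batchSize,
                 learningRate = config@train@learningRate,
                 momentum = config@train@momentum,
                 schedFactor = config@train@schedFactor,
                 schedPatience = config@train@schedPatience,
                 minLearningRate = config@train@minLearningRate,
                 seed = config@train@seed,
                 decisionThreshold = config@train@decisionThreshold),
    split = list(fractions = as.list(config@split@fractions),
                 unit = config@split@unit, seed = config@split@seed,
                 shuffle = config@split@shuffle,
                 stratify = config@split@stratify))
  obj <- Filter(Negate(is.null), obj)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::write_yaml(obj, path)
  else jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE)
  invisible(path)
}
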