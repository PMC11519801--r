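#' @include sersdc-package.R
NULL

.allowedLabels <- c("mature", "immature", "unknown")

# ---------------------------------------------------------------------------
# SersSpectra: the central data container
# ---------------------------------------------------------------------------

#' SersSpectra: single-cell SERS spectra on a shared wavenumber axis
#'
#' `SersSpectra` extends [SummarizedExperiment::SummarizedExperiment] with a
#' fixed layout: one assay named `"intensity"` holding a wavenumber-by-spectrum
#' matrix, a `wavenumber` column in `rowData` (the shared Raman-shift axis in
#' cm^-1), and per-spectrum metadata in `colData` (`cell_id`, `label`,
#' optionally `time_point_h`, `x`, `y`, `in_cell`). Column names are the
#' spectrum identifiers and must be unique. The axis must be strictly
#' increasing with uniform spacing (relative tolerance 1e-9), as produced by a
#' dispersive spectrometer after interpolation to a common grid.
#'
#' @param intensities numeric matrix, one row per wavenumber and one column
#'   per spectrum (Bioconductor orientation: features in rows).
#' @param wavenumbers numeric vector of Raman shifts in cm^-1, one per row.
#' @param meta `data.frame` with one row per spectrum. Recognised columns:
#'   `spectrum_id` (unique; defaults to `colnames(intensities)` or generated
#'   ids), `cell_id`, `label` (one of `"mature"`, `"immature"`, `"unknown"`;
#'   missing labels are stored as `"unknown"`), `time_point_h`, `x`, `y`,
#'   `in_cell`.
#'
#' @return a `SersSpectra` object.
#' @export
#' @examples
#' wn <- seq(600, 1700, length.out = 50)
#' m <- matrix(runif(50 * 3), nrow = 50, dimnames = list(NULL, paste0("s", 1:3)))
#' ss <- SersSpectra(m, wn, data.frame(cell_id = c("c1", "c1", "c2"),
#'                                     label = c("mature", "mature", "immature")))
#' ss
setClass("SersSpectra", contains = "SummarizedExperiment")

#' @rdname SersSpectra-class
#' @export
SersSpectra <- function(intensities, wavenumbers, meta = NULL) {
  intensities <- as.matrix(intensities)
  n <- ncol(intensities)
  if (is.null(meta)) meta <- data.frame(row.names = seq_len(max(n, 0L)))
  meta <- as.data.frame(meta)
  if (nrow(meta) == 0L && n > 0L) meta <- data.frame(row.names = seq_len(n))
  ids <- if (!is.null(meta$spectrum_id)) as.character(meta$spectrum_id)
         else if (!is.null(colnames(intensities))) colnames(intensities)
         else sprintf("spectrum_%04d", seq_len(n))
  meta$spectrum_id <- NULL
  if (is.null(meta$cell_id)) meta$cell_id <- rep(NA_character_, n)
  if (is.null(meta$label)) meta$label <- rep("unknown", n)
  meta$label <- as.character(meta$label)
  meta$label[is.na(meta$label)] <- "unknown"
  colnames(intensities) <- ids
  cd <- S4Vectors::DataFrame(meta)
  rownames(cd) <- ids
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = intensities),
    rowData = S4Vectors::DataFrame(wavenumber = as.numeric(wavenumbers)),
    colData = cd)
  new("SersSpectra", se)
}

setValidity("SersSpectra", function(object) {
  wn <- SummarizedExperiment::rowData(object)$wavenumber
  if (is.null(wn)) return("rowData must contain a 'wavenumber' column")
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    return("assay 'intensity' is missing")
  if (length(wn) >= 2) {
    d <- diff(wn)
    if (any(d <= 0)) return("wavenumber axis must be strictly increasing")
    if (any(abs(d - d[1]) > 1e-9 * abs(d[1]) + 1e-12))
      return("wavenumber axis must be uniformly spaced (rel. tol. 1e-9)")
  }
  ids <- colnames(object)
  if (ncol(object) > 0 && (is.null(ids) || anyDuplicated(ids)))
    return(sprintf("spectrum ids must be unique (duplicated: %s)",
                   paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  lab <- SummarizedExperiment::colData(object)$label
  if (!is.null(lab) && length(lab) && !all(lab %in% .allowedLabels))
    return(sprintf("labels must be one of %s",
                   paste(.allowedLabels, collapse = "/")))
  TRUE
})

# ---------------------------------------------------------------------------
# Simulator configuration
# ---------------------------------------------------------------------------

#' @export
setClass("ClassProfile",
  representation(label = "character", bands = "data.frame",
                 baseline = "numeric"))

#' Per-class generative profile for the SERS simulator
#'
#' A `ClassProfile` describes how spectra of one maturation state are built:
#' a catalogue of Raman bands (Gaussian line shapes with per-band mean and
#' standard deviation of the peak amplitude) plus a smooth polynomial
#' baseline standing in for substrate background.
#'
#' @param label `"mature"` or `"immature"`.
#' @param bands `data.frame` with columns `center` (cm^-1), `fwhm` (cm^-1),
#'   `mean`, `sd` (amplitude mean / standard deviation, arbitrary units) and
#'   `assignment` (free text).
#' @param baseline numeric polynomial coefficients (intercept first),
#'   evaluated on the axis rescaled to `[0, 1]`.
#' @return a `ClassProfile`.
#' @export
classProfile <- function(label, bands, baseline = c(0.25, 0.15, -0.08)) {
  new("ClassProfile", label = label, bands = as.data.frame(bands),
      baseline = as.numeric(baseline))
}

setValidity("ClassProfile", function(object) {
  b <- object@bands
  need <- c("center", "fwhm", "mean", "sd")
  if (!all(need %in% names(b)))
    return(sprintf("bands must have columns %s", paste(need, collapse = ", ")))
  if (any(b$fwhm <= 0)) return("band fwhm must be > 0")
  if (any(b$mean < 0)) return("band amplitude means must be >= 0")
  if (any(b$sd < 0)) return("band amplitude sds must be >= 0")
  if (!object@label %in% c("mature", "immature"))
    return("label must be 'mature' or 'immature'")
  TRUE
})

#' @export
setClass("SyntheticConfig",
  representation(axis = "numeric", profiles = "list",
                 nCellsPerClass = "integer", spectraPerCell = "integer",
                 cellScaleSd = "numeric", noiseSd = "numeric",
                 seed = "integer"))

#' Configuration of the synthetic single-cell SERS dataset generator
#'
#' The generator emulates a label-free SERS acquisition of mature and
#' immature dendritic cells: each cell draws per-band peak amplitudes around
#' its class profile, multiplied by a log-normal per-cell scale effect
#' (nanoparticle-uptake variation); each of its replicate spectra is the cell
#' template plus i.i.d. Gaussian noise. Defaults mirror a study of 196 mature
#' and 210 immature cells with 50 spectra per cell (20,300 spectra) on a
#' 600-1700 cm^-1 axis of 1015 points.
#'
#' @param axis numeric wavenumber axis (cm^-1); default 1015 uniform points
#'   over 600-1700 cm^-1. Must have at least 8 points.
#' @param profiles named list with `mature` and `immature` [classProfile()]
#'   entries; default [defaultProfiles()].
#' @param nCellsPerClass integer vector `c(mature, immature)` cell counts.
#' @param spectraPerCell replicate spectra acquired per cell.
#' @param cellScaleSd standard deviation of the per-cell log-normal
#'   multiplicative scale effect.
#' @param noiseSd standard deviation of the additive per-point noise, on the
#'   scale of a unit-amplitude band.
#' @param seed integer seed; the generator is fully deterministic given the
#'   configuration.
#' @return a `SyntheticConfig`.
#' @export
syntheticConfig <- function(axis = seq(600, 1700, length.out = 1015),
                            profiles = defaultProfiles(),
                            nCellsPerClass = c(mature = 196L, immature = 210L),
                            spectraPerCell = 50L,
                            cellScaleSd = 0.15,
                            noiseSd = 0.02,
                            seed = 1L) {
  if (all(c("mature", "immature") %in% names(nCellsPerClass)))
    n <- setNames(as.integer(nCellsPerClass[c("mature", "immature")]),
                  c("mature", "immature"))
  else n <- setNames(as.integer(nCellsPerClass), c("mature", "immature"))
  new("SyntheticConfig", axis = as.numeric(axis), profiles = profiles,
      nCellsPerClass = n, spectraPerCell = as.integer(spectraPerCell),
      cellScaleSd = as.numeric(cellScaleSd), noiseSd = as.numeric(noiseSd),
      seed = as.integer(seed))
}

setValidity("SyntheticConfig", function(object) {
  if (length(object@axis) < 8)
    return("invalid config: axis must have at least 8 points")
  d <- diff(object@axis)
  if (any(d <= 0)) return("invalid config: axis must be strictly increasing")
  if (!all(c("mature", "immature") %in% names(object@profiles)))
    return("profiles must be a list with 'mature' and 'immature' entries")
  for (p in object@profiles) {
    ok <- validObject(p, test = TRUE)
    if (is.character(ok)) return(ok)
    if (any(p@bands$center < min(object@axis) | p@bands$center > max(object@axis)))
      return("invalid config: band center outside the wavenumber axis")
  }
  if (any(object@nCellsPerClass < 1L))
    return("invalid config: cell counts must be >= 1")
  if (object@spectraPerCell < 1L)
    return("invalid config: spectraPerCell must be >= 1")
  if (object@cellScaleSd < 0 || object@noiseSd < 0)
    return("invalid config: cellScaleSd and noiseSd must be >= 0")
  TRUE
})

#' @export
setClass("TimecourseConfig",
  representation(base = "SyntheticConfig", timePointsH = "numeric",
                 maturationProgress = "numeric"))

#' Configuration of the maturation time-course generator
#'
#' Emulates repeated live-cell SERS acquisition during stimulus-driven
#' maturation: a treated arm whose spectral profile moves from the immature
#' toward the mature profile according to `maturationProgress`, and a control
#' arm that stays immature throughout. Cell identities (and their random
#' effects) persist across time points.
#'
#' @param base a [syntheticConfig()]; its `mature`/`immature` profiles are the
#'   interpolation endpoints and its cell counts give the treated/control arm
#'   sizes.
#' @param timePointsH acquisition times in hours.
#' @param maturationProgress interpolation weight in `[0, 1]` per time point
#'   (0 = still immature, 1 = fully mature); must be non-decreasing.
#' @return a `TimecourseConfig`.
#' @export
timecourseConfig <- function(base = syntheticConfig(),
                             timePointsH = c(2, 4, 6),
                             maturationProgress = c(0.6, 0.85, 1.0)) {
  new("TimecourseConfig", base = base, timePointsH = as.numeric(timePointsH),
      maturationProgress = as.numeric(maturationProgress))
}

setValidity("TimecourseConfig", function(object) {
  if (length(object@timePointsH) < 1)
    return("invalid config: at least one time point is required")
  if (length(object@maturationProgress) != length(object@timePointsH))
    return("invalid config: one maturationProgress weight per time point")
  w <- object@maturationProgress
  if (any(w < 0 | w > 1)) return("invalid config: progress weights must lie in [0, 1]")
  if (is.unsorted(w)) return("invalid config: progress weights must be non-decreasing")
  TRUE
})

# ---------------------------------------------------------------------------
# Model / training / split configuration
# ---------------------------------------------------------------------------

#' @export
setClass("ModelConfig",
  representation(convFilters = "integer", convKernel = "integer",
                 convStride = "integer", dropoutRate = "numeric",
                 poolSize = "integer", poolStride = "integer",
                 denseUnits = "integer", l2Coeff = "numeric"))

#' CNN architecture hyper-parameters
#'
#' Defaults encode the reference spectral classifier: Conv1D with 32 filters,
#' kernel 3, stride 1, no padding, ReLU; dropout; max-pooling size 2 stride 2;
#' flatten; dense layer of 32 ReLU units with an L2 weight penalty; one
#' sigmoid output unit. The dropout rate (0.25) and L2 coefficient (1e-4) are
#' package defaults, configurable here.
#'
#' @param convFilters,convKernel,convStride convolution shape parameters.
#' @param dropoutRate dropout fraction in `[0, 1)` after the convolution.
#' @param poolSize,poolStride max-pooling window and stride.
#' @param denseUnits hidden fully connected width.
#' @param l2Coeff L2 penalty on the hidden dense weights.
#' @return a `ModelConfig`.
#' @export
modelConfig <- function(convFilters = 32L, convKernel = 3L, convStride = 1L,
                        dropoutRate = 0.25, poolSize = 2L, poolStride = 2L,
                        denseUnits = 32L, l2Coeff = 1e-4) {
  new("ModelConfig", convFilters = as.integer(convFilters),
      convKernel = as.integer(convKernel), convStride = as.integer(convStride),
      dropoutRate = as.numeric(dropoutRate), poolSize = as.integer(poolSize),
      poolStride = as.integer(poolStride), denseUnits = as.integer(denseUnits),
      l2Coeff = as.numeric(l2Coeff))
}

setValidity("ModelConfig", function(object) {
  if (object@dropoutRate < 0 || object@dropoutRate >= 1)
    return("dropoutRate must lie in [0, 1)")
  if (object@l2Coeff < 0) return("l2Coeff must be >= 0")
  if (any(c(object@convFilters, object@convKernel, object@convStride,
            object@poolSize, object@poolStride, object@denseUnits) < 1L))
    return("all shape parameters must be >= 1")
  TRUE
})

#' @export
setClass("TrainConfig",
  representation(epochs = "integer", batchSize = "integer",
                 learningRate = "numeric", momentum = "numeric",
                 schedFactor = "numeric", schedPatience = "integer",
                 minLearningRate = "numeric", seed = "integer",
                 decisionThreshold = "numeric"))

#' Training recipe
#'
#' Mini-batch stochastic gradient descent with momentum on binary
#' cross-entropy, with a reduce-on-plateau learning-rate scheduler monitoring
#' validation loss. Defaults: 50 epochs, batch size 32, learning rate 0.01,
#' momentum 0.9, patience 10, reduction factor 0.5 (package default), minimum
#' learning rate 1e-5.
#'
#' @param epochs,batchSize,learningRate,momentum SGD parameters.
#' @param schedFactor multiplicative learning-rate reduction on plateau.
#' @param schedPatience epochs without validation-loss improvement before a
#'   reduction.
#' @param minLearningRate floor for the scheduled learning rate.
#' @param seed RNG seed covering initialisation, shuffling and dropout.
#' @param decisionThreshold probability cut-off for the positive (mature)
#'   class; ties predict positive.
#' @return a `TrainConfig`.
#' @export
trainConfig <- function(epochs = 50L, batchSize = 32L, learningRate = 0.01,
                        momentum = 0.9, schedFactor = 0.5, schedPatience = 10L,
                        minLearningRate = 1e-5, seed = 1L,
                        decisionThreshold = 0.5) {
  new("TrainConfig", epochs = as.integer(epochs), batchSize = as.integer(batchSize),
      learningRate = as.numeric(learningRate), momentum = as.numeric(momentum),
      schedFactor = as.numeric(schedFactor), schedPatience = as.integer(schedPatience),
      minLearningRate = as.numeric(minLearningRate), seed = as.integer(seed),
      decisionThreshold = as.numeric(decisionThreshold))
}

setValidity("TrainConfig", function(object) {
  if (object@epochs < 1L) return("epochs must be >= 1")
  if (object@batchSize < 1L) return("batchSize must be >= 1")
  if (object@learningRate <= 0) return("learningRate must be > 0")
  if (object@minLearningRate > object@learningRate)
    return("minLearningRate must not exceed learningRate")
  if (object@schedFactor <= 0 || object@schedFactor > 1)
    return("schedFactor must lie in (0, 1]")
  TRUE
})

#' @export
setClass("SplitSpec",
  representation(fractions = "numeric", unit = "character", seed = "integer",
                 shuffle = "logical", stratify = "logical"))

#' Train/validation/test split specification
#'
#' @param fractions numeric `(train, validation, test)` fractions summing to 1
#'   (tolerance 1e-9); subset sizes follow largest-remainder rounding with
#'   ties broken toward the earlier subset.
#' @param unit `"cell"` (default; no cell's replicate spectra are split across
#'   subsets) or `"spectrum"` (replicates the population-level protocol).
#' @param seed shuffling seed.
#' @param shuffle randomly permute units before assignment.
#' @param stratify apply the rounding per label stratum to preserve class
#'   balance.
#' @return a `SplitSpec`.
#' @export
splitSpec <- function(fractions = c(train = 0.7, validation = 0.2, test = 0.1),
                      unit = c("cell", "spectrum"), seed = 1L, shuffle = TRUE,
                      stratify = TRUE) {
  unit <- match.arg(unit)
  f <- as.numeric(fractions)
  names(f) <- c("train", "validation", "test")
  new("SplitSpec", fractions = f, unit = unit, seed = as.integer(seed),
      shuffle = shuffle, stratify = stratify)
}

setValidity("SplitSpec", function(object) {
  f <- object@fractions
  if (length(f) != 3) return("fractions must have length 3")
  if (any(f < 0 | f > 1)) return("each fraction must lie in [0, 1]")
  if (abs(sum(f) - 1) > 1e-9) return("fractions must sum to 1 (tolerance 1e-9)")
  if (!object@unit %in% c("cell", "spectrum"))
    return("unit must be 'cell' or 'spectrum'")
  TRUE
})

# ---------------------------------------------------------------------------
# Model and report objects
# ---------------------------------------------------------------------------

#' @export
setClass("SersModel",
  representation(arch = "character", inputLength = "integer",
                 config = "ModelConfig", params = "list", trained = "logical",
                 history = "data.frame"))

#' @export
setClass("EvaluationReport",
  representation(confusion = "numeric", accuracy = "numeric",
                 sensitivity = "numeric", specificity = "numeric",
                 auc = "numeric", roc = "data.frame",
                 probabilities = "numeric", trueLabels = "character",
                 threshold = "numeric"))

setValidity("EvaluationReport", function(object) {
  cm <- object@confusion
  if (!all(c("TP", "FP", "TN", "FN") %in% names(cm)))
    return("confusion must be named TP/FP/TN/FN")
  if (abs(sum(cm) - length(object@probabilities)) > 0)
    return("confusion counts must sum to the evaluated sample count")
  rates <- c(object@accuracy, object@sensitivity, object@specificity)
  rates <- rates[is.finite(rates)]
  if (any(rates < 0 | rates > 1)) return("rates must lie in [0, 1]")
  TRUE
})

#' @export
setClass("RunReport",
  representation(datasetSummary = "list", model = "ANY", evaluations = "list",
                 contribution = "ANY", ratio = "ANY", timecourse = "list",
                 provenance = "list"))
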