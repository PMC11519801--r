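#' @include AllClasses.R
NULL

#' Accessors for SersSpectra
#'
#' `wavenumbers()` returns the shared Raman-shift axis (cm^-1);
#' `intensityMatrix()` the intensities as a spectra-by-wavenumber matrix (the
#' orientation consumed by the classifiers); `spectrumData()` the per-spectrum
#' metadata with a `spectrum_id` column; `spectrumLabels()` and `cellIds()`
#' the label and cell-id vectors; `nSpectra()` the number of spectra.
#'
#' @param x a [SersSpectra] object.
#' @return see description.
#' @name SersSpectra-accessors
#' @aliases wavenumbers intensityMatrix spectrumData spectrumLabels cellIds nSpectra
NULL

#' @rdname SersSpectra-accessors
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))

#' @rdname SersSpectra-accessors
#' @export
setGeneric("intensityMatrix", function(x) standardGeneric("intensityMatrix"))

#' @rdname SersSpectra-accessors
#' @export
setGeneric("spectrumData", function(x) standardGeneric("spectrumData"))

#' @rdname SersSpectra-accessors
#' @export
setGeneric("spectrumLabels", function(x) standardGeneric("spectrumLabels"))

#' @rdname SersSpectra-accessors
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))

#' @rdname SersSpectra-accessors
#' @export
setGeneric("nSpectra", function(x) standardGeneric("nSpectra"))

#' @rdname SersSpectra-accessors
setMethod("wavenumbers", "SersSpectra", function(x)
  as.numeric(SummarizedExperiment::rowData(x)$wavenumber))

#' @rdname SersSpectra-accessors
setMethod("intensityMatrix", "SersSpectra", function(x)
  t(SummarizedExperiment::assay(x, "intensity")))

#' @rdname SersSpectra-accessors
setMethod("spectrumData", "SersSpectra", function(x) {
  df <- as.data.frame(SummarizedExperiment::colData(x))
  data.frame(spectrum_id = colnames(x), df, row.names = NULL,
             check.names = FALSE)
})

#' @rdname SersSpectra-accessors
setMethod("spectrumLabels", "SersSpectra", function(x)
  as.character(SummarizedExperiment::colData(x)$label))

#' @rdname SersSpectra-accessors
setMethod("cellIds", "SersSpectra", function(x)
  as.character(SummarizedExperiment::colData(x)$cell_id))

#' @rdname SersSpectra-accessors
setMethod("nSpectra", "SersSpectra", function(x) ncol(x))

setMethod("show", "SersSpectra", function(object) {
  wn <- wavenumbers(object)
  lab <- spectrumLabels(object)
  cat(sprintf("SersSpectra: %d spectra x %d wavenumbers (%.1f-%.1f cm^-1)\n",
              ncol(object), nrow(object),
              if (length(wn)) min(wn) else NA, if (length(wn)) max(wn) else NA))
  if (length(lab))
    cat("  labels:", paste(sprintf("%s=%d", names(table(lab)), table(lab)),
                           collapse = ", "), "\n")
  nc <- length(unique(stats::na.omit(cellIds(object))))
  if (nc) cat(sprintf("  cells: %d\n", nc))
  invisible(NULL)
})

#' Training history of a fitted model
#'
#' @param x a trained [SersModel-class] object.
#' @return `data.frame` with per-epoch `epoch`, `lr`, `train_loss`,
#'   `train_acc`, `val_loss`, `val_acc`.
#' @export
setGeneric("trainingHistory", function(x) standardGeneric("trainingHistory"))

setMethod("trainingHistory", "SersModel", function(x) x@history)

setMethod("show", "SersModel", function(object) {
  cat(sprintf("SersModel <%s>, input length %d, %s\n", object@arch,
              object@inputLength,
              if (object@trained) "trained" else "untrained"))
  sh <- layerShapes(object)
  cat(sprintf("  %d layers, %d parameters\n", nrow(sh), sum(sh$params)))
  if (object@trained && nrow(object@history)) {
    h <- utils::tail(object@history, 1)
    cat(sprintf("  final epoch %d: val_loss %.4f, val_acc %.4f, lr %.2g\n",
                h$epoch, h$val_loss, h$val_acc, h$lr))
  }
  invisible(NULL)
})

setMethod("show", "EvaluationReport", function(object) {
  cm <- object@confusion
  cat("EvaluationReport (mature = positive)\n")
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n", cm["TP"], cm["FP"],
              cm["TN"], cm["FN"]))
  cat(sprintf("  accuracy %.4f  sensitivity %.4f  specificity %.4f  AUC %s\n",
              object@accuracy, object@sensitivity, object@specificity,
              ifelse(is.na(object@auc), "NA", sprintf("%.4f", object@auc))))
  invisible(NULL)
})

setMethod("show", "RunReport", function(object) {
  cat("RunReport\n")
  for (nm in names(object@evaluations)) {
    ev <- object@evaluations[[nm]]
    cat(sprintf("  %s: accuracy %.4f, AUC %s\n", nm, ev@accuracy,
                ifelse(is.na(ev@auc), "NA", sprintf("%.4f", ev@auc))))
  }
  if (length(object@timecourse))
    cat(sprintf("  time points: %s h\n",
                paste(names(object@timecourse), collapse = ", ")))
  invisible(NULL)
})
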