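#' @include AllClasses.R
NULL

.windowIdx <- function(axis, center, halfWindow) {
  idx <- which(axis >= center - halfWindow & axis <= center + halfWindow)
  if (!length(idx))
    stop(sprintf("range error: band window %.6g +/- %.6g outside the %.6g-%.6g cm^-1 axis",
                 center, halfWindow, min(axis), max(axis)))
  idx
}

#' Band intensity of spectra
#'
#' Mean intensity over the axis points within `center +/- halfWindow`, the
#' conventional read-out of one Raman band from a (normalised) spectrum. The
#' default half-window of 6 cm^-1 matches the default 12 cm^-1 FWHM line
#' width.
#'
#' @param x a [SersSpectra] or a numeric spectrum on `axis`.
#' @param center band position, cm^-1.
#' @param halfWindow half width of the averaging window, cm^-1.
#' @param axis wavenumber axis, required when `x` is a bare vector.
#' @return numeric vector of band intensities, one per spectrum.
#' @export
bandIntensity <- function(x, center, halfWindow = 6, axis = NULL) {
  if (is(x, "SersSpectra")) {
    axis <- wavenumbers(x)
    M <- SummarizedExperiment::assay(x, "intensity")
  } else {
    if (is.null(axis)) stop("axis is required for a bare spectrum")
    M <- matrix(as.numeric(x), ncol = 1)
  }
  idx <- .windowIdx(axis, center, halfWindow)
  colMeans(M[idx, , drop = FALSE])
}

#' Band-ratio maturation marker with a group test
#'
#' Computes, per cell, the ratio of the band intensity at `numerator` (by
#' default tryptophan, 1623 cm^-1) to that at `denominator` (carbohydrates,
#' 1025 cm^-1) on per-cell averaged, normalised spectra, and tests the
#' mature vs immature groups with a two-sided Welch t-test (default) or
#' Mann-Whitney U test. Because the ratio is computed on min-max normalised
#' spectra it is invariant to global rescaling of the raw intensities.
#'
#' @param x a labelled, per-cell averaged [SersSpectra] with both groups of
#'   size >= 2.
#' @param numerator,denominator band centers in cm^-1.
#' @param test `"welch_t"` or `"mann_whitney"`.
#' @param halfWindow band half-window, cm^-1.
#' @return a list of class `RatioReport`: `ratios` (data.frame `cell_id`,
#'   `label`, `ratio`), `groupMeans`, `groupSds`, `test`, `statistic`,
#'   `p.value`.
#' @export
ratioStatistic <- function(x, numerator = 1623, denominator = 1025,
                           test = c("welch_t", "mann_whitney"),
                           halfWindow = 6) {
  test <- match.arg(test)
  lab <- spectrumLabels(x)
  if (!all(lab %in% c("mature", "immature")))
    stop("ratioStatistic requires mature/immature labels")
  if (any(table(factor(lab, c("mature", "immature"))) < 2))
    stop("both groups need at least 2 cells")
  num <- bandIntensity(x, numerator, halfWindow)
  den <- bandIntensity(x, denominator, halfWindow)
  if (any(den <= 0)) {
    bad <- colnames(x)[den <= 0][1]
    stop("degenerate ratio: non-positive denominator intensity in cell ", bad)
  }
  ratio <- num / den
  g <- split(ratio, lab)
  if (test == "welch_t") {
    if (var(g$mature) + var(g$immature) == 0) {
      # degenerate: no variance in either group -> no evidence of difference
      stat <- 0; pv <- if (mean(g$mature) == mean(g$immature)) 1 else 0
    } else {
      ht <- t.test(g$mature, g$immature, var.equal = FALSE)
      stat <- unname(ht$statistic); pv <- ht$p.value
    }
    testName <- "Welch two-sample t-test (two-sided)"
  } else {
    ht <- suppressWarnings(wilcox.test(g$mature, g$immature))
    stat <- unname(ht$statistic); pv <- ht$p.value
    testName <- "Mann-Whitney U test (two-sided)"
  }
  structure(list(
    ratios = data.frame(cell_id = colnames(x), label = lab, ratio = ratio,
                        row.names = NULL),
    groupMeans = vapply(g, mean, numeric(1)),
    groupSds = vapply(g, sd, numeric(1)),
    numerator = numerator, denominator = denominator,
    test = testName, statistic = stat, p.value = pv), class = "RatioReport")
}

#' @export
print.RatioReport <- function(x, ...) {
  cat(sprintf("RatioReport: %g / %g cm^-1 band-intensity ratio\n",
              x$numerator, x$denominator))
  cat(sprintf("  mature %.3f +/- %.3f (n=%d), immature %.3f +/- %.3f (n=%d)\n",
              x$groupMeans[["mature"]], x$groupSds[["mature"]],
              sum(x$ratios$label == "mature"),
              x$groupMeans[["immature"]], x$groupSds[["immature"]],
              sum(x$ratios$label == "immature")))
  cat(sprintf("  %s: statistic %.3f, p = %.3g\n", x$test, x$statistic,
              x$p.value))
  invisible(x)
}

.balancedAccuracy <- function(scores, labels, threshold) {
  pos <- labels == "mature"
  pred <- scores >= threshold
  (mean(pred[pos]) + mean(!pred[!pos])) / 2
}

#' Band-level contribution of Raman peaks to the classifier
#'
#' Quantifies how much each catalogue band contributes to the model's
#' classification performance. `"occlusion"` (default) zeroes the
#' `+/- halfWindow` region of every spectrum one band at a time and records
#' the drop in balanced accuracy; negative drops are clipped to zero and
#' drops are normalised to percent. `"weight_backprojection"` reads the
#' literal trained weights instead: absolute final-layer weights are
#' propagated back through the dense stack and (for the CNN) through the
#' pooling/convolution index maps onto input wavenumbers, then summed per
#' band window and normalised to percent. Contributions are non-negative and
#' sum to 100.
#'
#' @param model a trained [SersModel-class].
#' @param data a labelled, normalised [SersSpectra] to score occlusions on.
#' @param catalog band catalogue (`center`, `assignment` columns).
#' @param method `"occlusion"` or `"weight_backprojection"`.
#' @param halfWindow band half-window, cm^-1.
#' @param threshold decision threshold for occlusion scoring.
#' @return a `data.frame` of class `ContributionReport`: `center`,
#'   `assignment`, `contribution` (percent), `rank`, with the method in
#'   `attr(, "method")`.
#' @export
peakContribution <- function(model, data, catalog = defaultBandCatalog(),
                             method = c("occlusion", "weight_backprojection"),
                             halfWindow = 6, threshold = 0.5) {
  method <- match.arg(method)
  if (!model@trained) stop("state error: model is not trained")
  axis <- wavenumbers(data)
  raw <- if (method == "occlusion")
    .occlusionScores(model, data, catalog, halfWindow, threshold)
  else
    .backprojectionScores(model, axis, catalog, halfWindow)
  raw <- pmax(raw, 0)
  contribution <- if (sum(raw) > 0) 100 * raw / sum(raw)
                  else rep(100 / length(raw), length(raw))
  out <- data.frame(center = catalog$center, assignment = catalog$assignment,
                    contribution = contribution)
  out$rank <- rank(-out$contribution, ties.method = "min")
  attr(out, "method") <- method
  class(out) <- c("ContributionReport", "data.frame")
  out
}

.occlusionScores <- function(model, data, catalog, halfWindow, threshold) {
  lab <- spectrumLabels(data)
  if (any(lab == "unknown")) stop("occlusion scoring requires labelled spectra")
  axis <- wavenumbers(data)
  base <- .balancedAccuracy(predictProb(model, data), lab, threshold)
  M0 <- SummarizedExperiment::assay(data, "intensity")
  vapply(seq_len(nrow(catalog)), function(i) {
    idx <- .windowIdx(axis, catalog$center[i], halfWindow)
    M <- M0
    M[idx, ] <- 0
    occ <- data
    SummarizedExperiment::assay(occ, "intensity") <- M
    base - .balancedAccuracy(predictProb(model, occ), lab, threshold)
  }, numeric(1))
}

.backprojectionScores <- function(model, axis, catalog, halfWindow) {
  p <- model@params
  W <- p$dense_W
  # chain of absolute dense weights, from the final unit backwards
  imp <- abs(W[[length(W)]])[, 1]
  if (length(W) > 1)
    for (l in rev(seq_len(length(W) - 1))) imp <- abs(W[[l]]) %*% imp
  imp <- as.numeric(imp)   # importance per dense-stack input feature
  cfg <- model@config
  L <- model@inputLength
  binImp <- numeric(L)
  if (model@arch == "cnn") {
    lc <- convOutputLength(L, cfg@convKernel, cfg@convStride)
    lp <- poolOutputLength(lc, cfg@poolSize, cfg@poolStride)
    # flat features are filter-major, so feature j sits at pooled position
    # (j-1) %% lp; aggregate importance per pooled position, then spread it
    # over the input bins its pooling/convolution windows cover
    wImp <- rowsum(imp, (seq_along(imp) - 1) %% lp)[, 1]
    for (w in 0:(lp - 1)) {
      convPos <- w * cfg@poolStride + seq_len(cfg@poolSize) - 1
      bins <- unique(unlist(lapply(convPos, function(p0)
        p0 * cfg@convStride + seq_len(cfg@convKernel))))
      bins <- bins[bins <= L]
      binImp[bins] <- binImp[bins] + wImp[[as.character(w)]] / length(bins)
    }
  } else {
    binImp <- imp
  }
  vapply(seq_len(nrow(catalog)), function(i)
    sum(binImp[.windowIdx(axis, catalog$center[i], halfWindow)]), numeric(1))
}

#' Render a band-intensity mapping image from a grid acquisition
#'
#' @param x a [SersSpectra] whose spectra carry `x`/`y` grid positions (as
#'   from [generateMappingGrid()]); duplicate positions are an integrity
#'   error.
#' @param center band position in cm^-1 (e.g. 1623 for tryptophan).
#' @param halfWindow band half-window, cm^-1.
#' @return numeric matrix (rows = y, cols = x) of band intensities; grid
#'   nodes without a spectrum are `NA`.
#' @export
mapChannelImage <- function(x, center, halfWindow = 6) {
  md <- spectrumData(x)
  if (is.null(md$x) || is.null(md$y) || any(is.na(md$x)) || any(is.na(md$y)))
    stop("mapping requires x/y positions on every spectrum")
  if (anyDuplicated(md[, c("x", "y")]))
    stop("integrity error: duplicated grid positions")
  v <- bandIntensity(x, center, halfWindow)
  ys <- sort(unique(md$y)); xs <- sort(unique(md$x))
  img <- matrix(NA_real_, length(ys), length(xs),
                dimnames = list(y = ys, x = xs))
  img[cbind(match(md$y, ys), match(md$x, xs))] <- v
  img
}

#' Probability heatmap of evaluated samples
#'
#' Arranges the per-sample mature-class probabilities of an evaluation with
#' their true and predicted labels, the layout used to display per-cell
#' classification outcomes. Probabilities at the threshold predict the
#' positive class.
#'
#' @param report an [EvaluationReport-class].
#' @return `data.frame` with `sample`, `probability`, `true`, `predicted`,
#'   ordered by true label then probability.
#' @export
probabilityHeatmap <- function(report) {
  pr <- report@probabilities
  pred <- ifelse(pr >= report@threshold, "mature", "immature")
  out <- data.frame(sample = seq_along(pr), probability = pr,
                    true = report@trueLabels, predicted = pred)
  out[order(out$true, -out$probability), , drop = FALSE]
}
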