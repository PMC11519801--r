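#' @include AllClasses.R
NULL

#' Per-spectrum min-max normalisation
#'
#' Linearly rescales every spectrum so its minimum maps to 0 and its maximum
#' to 1 (the 0-1 interval), making intensities comparable across cells and
#' acquisitions. Constant spectra (zero range) map to all zeros. The axis and
#' metadata are unchanged; the operation is idempotent.
#'
#' @param x a [SersSpectra]; intensities must be finite.
#' @return the normalised [SersSpectra].
#' @export
minmaxNormalize <- function(x) {
  stopifnot(is(x, "SersSpectra"))
  M <- SummarizedExperiment::assay(x, "intensity")
  if (ncol(M) == 0) return(x)
  if (!all(is.finite(M)))
    stop("validation error: non-finite intensity values")
  mins <- apply(M, 2, min)
  rng <- apply(M, 2, max) - mins
  M <- sweep(M, 2, mins, `-`)
  nz <- rng > 0
  M[, nz] <- sweep(M[, nz, drop = FALSE], 2, rng[nz], `/`)
  SummarizedExperiment::assay(x, "intensity") <- M
  x
}

#' Average replicate spectra per cell
#'
#' Computes the arithmetic mean spectrum of each cell over its replicate
#' acquisitions, the representation used for single-cell level
#' classification. The cell's label is inherited; conflicting labels within
#' one cell raise an integrity error.
#'
#' @param x a [SersSpectra] in which every spectrum has a `cell_id`.
#' @return a [SersSpectra] with one spectrum per distinct cell (spectrum id =
#'   cell id), in order of first appearance.
#' @export
averagePerCell <- function(x) {
  stopifnot(is(x, "SersSpectra"))
  cid <- cellIds(x)
  if (any(is.na(cid) | cid == ""))
    stop("integrity error: every spectrum needs a cell_id for per-cell averaging")
  lab <- spectrumLabels(x)
  byCell <- split(lab, cid)
  confl <- names(byCell)[vapply(byCell, function(v) length(unique(v)) > 1L,
                                logical(1))]
  if (length(confl))
    stop("integrity error: conflicting labels within cell(s) ",
         paste(confl, collapse = ", "))
  cells <- unique(cid)
  M <- SummarizedExperiment::assay(x, "intensity")
  grp <- factor(cid, levels = cells)
  A <- t(rowsum(t(M), grp) / as.vector(table(grp)))
  colnames(A) <- cells
  meta <- data.frame(spectrum_id = cells, cell_id = cells,
                     label = vapply(byCell[cells], `[`, character(1), 1),
                     stringsAsFactors = FALSE)
  tp <- SummarizedExperiment::colData(x)$time_point_h
  if (!is.null(tp)) meta$time_point_h <- vapply(split(tp, grp), `[`, numeric(1), 1)
  SersSpectra(A, wavenumbers(x), meta)
}

#' Pointwise confidence band for the mean spectrum
#'
#' Computes, at every wavenumber, the Student-t confidence interval for the
#' mean intensity across spectra — the shaded band conventionally drawn
#' around an averaged Raman spectrum.
#'
#' @param x a [SersSpectra] with at least 2 spectra.
#' @param level confidence level (default 0.95).
#' @return `data.frame` with columns `wavenumber`, `mean`, `lower`, `upper`.
#' @export
confidenceBand <- function(x, level = 0.95) {
  stopifnot(is(x, "SersSpectra"))
  n <- ncol(x)
  if (n < 2) stop("insufficient data: confidence band needs at least 2 spectra")
  M <- SummarizedExperiment::assay(x, "intensity")
  mu <- rowMeans(M)
  se <- sqrt(apply(M, 1, var) / n)
  tq <- qt(1 - (1 - level) / 2, df = n - 1)
  data.frame(wavenumber = wavenumbers(x), mean = mu,
             lower = mu - tq * se, upper = mu + tq * se)
}

# Largest-remainder apportionment of n units to fractions; ties toward the
# earlier subset.
.largestRemainder <- function(n, fractions) {
  quota <- n * fractions
  base <- floor(quota + 1e-9)
  left <- n - sum(base)
  if (left > 0) {
    rem <- quota - base
    ord <- order(-rem, seq_along(rem))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Split a dataset into train/validation/test subsets
#'
#' Partitions the dataset at the chosen granularity: `unit = "cell"`
#' guarantees that all replicate spectra of one cell land in the same subset
#' (no within-cell leakage); `unit = "spectrum"` assigns spectra
#' independently. Subset sizes follow largest-remainder rounding of the
#' fractions (ties toward the earlier subset); with `stratify = TRUE` the
#' rounding is applied within each label stratum, approximately preserving
#' class balance. Deterministic for a fixed seed.
#'
#' @param x a non-empty [SersSpectra].
#' @param spec a [splitSpec()].
#' @return named list of [SersSpectra]: `train`, `validation`, `test`.
#' @export
splitDataset <- function(x, spec = splitSpec()) {
  stopifnot(is(x, "SersSpectra"), is(spec, "SplitSpec"))
  validObject(spec)
  if (ncol(x) == 0) stop("cannot split an empty dataset")
  if (spec@unit == "cell") {
    cid <- cellIds(x)
    if (any(is.na(cid) | cid == ""))
      stop("unit='cell' requires a cell_id on every spectrum")
    units <- unique(cid)
    ulab <- vapply(split(spectrumLabels(x), factor(cid, levels = units)),
                   `[`, character(1), 1)
  } else {
    units <- colnames(x)
    ulab <- spectrumLabels(x)
  }
  strata <- if (spec@stratify) split(seq_along(units), ulab)
            else list(all = seq_along(units))
  assign <- integer(length(units))
  withSeed(spec@seed, {
    for (s in strata) {
      idx <- if (spec@shuffle) s[sample.int(length(s))] else s
      sizes <- .largestRemainder(length(idx), spec@fractions)
      assign[idx] <- rep(1:3, times = sizes)
    }
  })
  counts <- tabulate(assign, 3)
  empty <- which(spec@fractions > 0 & counts == 0)
  if (length(empty))
    stop(sprintf(
      "sizing error: subset '%s' (fraction %.3g) received 0 of %d %s units (sizes %s)",
      names(spec@fractions)[empty[1]], spec@fractions[empty[1]],
      length(units), spec@unit, paste(counts, collapse = "/")))
  pick <- function(k) {
    keep <- units[assign == k]
    if (spec@unit == "cell") x[, cellIds(x) %in% keep]
    else x[, colnames(x) %in% keep]
  }
  list(train = pick(1), validation = pick(2), test = pick(3))
}
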