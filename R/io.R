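#' @include AllClasses.R
NULL

.metaPathFor <- function(path)
  paste0(tools::file_path_sans_ext(path), "_meta.",
         tools::file_ext(path))

.metaCols <- c("cell_id", "label", "time_point_h", "x", "y", "in_cell")

#' Read spectra from plain-text files
#'
#' Two documented CSV/TSV dialects are supported. `wide`: the first column is
#' `wavenumber` and every further column one spectrum (column name =
#' spectrum id); per-spectrum metadata live in a sidecar table
#' `<path-sans-ext>_meta.<ext>` keyed by `spectrum_id` (columns `cell_id`,
#' `label`, and optionally `time_point_h`, `x`, `y`, `in_cell`). `long`: one
#' row per (spectrum, wavenumber) with columns `spectrum_id`, `wavenumber`,
#' `intensity` plus the metadata columns repeated. Missing labels are loaded
#' as `"unknown"`. Duplicated spectrum ids, ragged rows and a non-monotone
#' axis raise format errors naming the offending record.
#'
#' @param path file to read (`.csv` or `.tsv`; the separator is sniffed).
#' @param format `"wide_csv"` or `"long_csv"`.
#' @param metaPath sidecar metadata file for the wide dialect; defaults to
#'   the derived path. Ignored for the long dialect.
#' @return a validated [SersSpectra].
#' @export
readSpectra <- function(path, format = c("wide_csv", "long_csv"),
                        metaPath = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- tryCatch(data.table::fread(path, header = TRUE, fill = FALSE),
                 error = function(e)
                   stop("format error reading ", path, ": ",
                        conditionMessage(e), call. = FALSE))
  if (format == "wide_csv") .readWide(dt, path, metaPath) else .readLong(dt, path)
}

.checkAxis <- function(wn, where) {
  if (length(wn) >= 2 && any(diff(wn) <= 0)) {
    bad <- which(diff(wn) <= 0)[1] + 1
    stop(sprintf("format error in %s: wavenumber axis not strictly increasing at row %d (%.6g)",
                 where, bad, wn[bad]), call. = FALSE)
  }
}

.cleanLabels <- function(lab, where) {
  lab <- as.character(lab)
  lab[is.na(lab) | lab == ""] <- "unknown"
  bad <- setdiff(unique(lab), .allowedLabels)
  if (length(bad))
    stop(sprintf("format error in %s: invalid label(s) %s", where,
                 paste(bad, collapse = ", ")), call. = FALSE)
  lab
}

.readWide <- function(dt, path, metaPath) {
  if (names(dt)[1] != "wavenumber")
    stop("format error in ", path, ": first column must be 'wavenumber'",
         call. = FALSE)
  wn <- as.numeric(dt[[1]])
  .checkAxis(wn, path)
  ids <- names(dt)[-1]
  if (anyDuplicated(ids))
    stop(sprintf("format error in %s: duplicated spectrum_id %s", path,
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  M <- as.matrix(as.data.frame(dt)[, -1, drop = FALSE])
  storage.mode(M) <- "double"
  colnames(M) <- ids
  if (is.null(metaPath)) metaPath <- .metaPathFor(path)
  meta <- NULL
  if (file.exists(metaPath) && length(ids)) {
    md <- as.data.frame(data.table::fread(metaPath, header = TRUE))
    if (!"spectrum_id" %in% names(md))
      stop("format error in ", metaPath, ": missing spectrum_id column",
           call. = FALSE)
    if (anyDuplicated(md$spectrum_id))
      stop(sprintf("format error in %s: duplicated spectrum_id %s", metaPath,
                   paste(unique(md$spectrum_id[duplicated(md$spectrum_id)]),
                         collapse = ", ")), call. = FALSE)
    missing <- setdiff(ids, md$spectrum_id)
    if (length(missing))
      stop(sprintf("format error in %s: no metadata for spectrum_id %s",
                   metaPath, paste(utils::head(missing, 3), collapse = ", ")),
           call. = FALSE)
    meta <- md[match(ids, md$spectrum_id), , drop = FALSE]
    if (!is.null(meta$label)) meta$label <- .cleanLabels(meta$label, metaPath)
  }
  SersSpectra(M, wn, meta)
}

.readLong <- function(dt, path) {
  need <- c("spectrum_id", "wavenumber", "intensity")
  if (!all(need %in% names(dt)))
    stop("format error in ", path, ": long dialect needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (nrow(dt) == 0)
    return(SersSpectra(matrix(numeric(0), 0, 0), numeric(0)))
  ids <- unique(dt$spectrum_id)
  wn <- sort(unique(as.numeric(dt$wavenumber)))
  .checkAxis(wn, path)
  cnt <- table(dt$spectrum_id)
  if (length(unique(cnt)) > 1 || any(cnt != length(wn))) {
    bad <- names(cnt)[cnt != length(wn)][1]
    stop(sprintf("format error in %s: spectrum %s has %d rows, expected %d (duplicated spectrum_id or ragged spectrum)",
                 path, bad, cnt[[bad]], length(wn)), call. = FALSE)
  }
  M <- matrix(NA_real_, length(wn), length(ids), dimnames = list(NULL, ids))
  ii <- match(as.numeric(dt$wavenumber), wn)
  jj <- match(dt$spectrum_id, ids)
  if (anyDuplicated(cbind(ii, jj)))
    stop("format error in ", path, ": duplicated (spectrum_id, wavenumber) rows",
         call. = FALSE)
  M[cbind(ii, jj)] <- as.numeric(dt$intensity)
  have <- intersect(.metaCols, names(dt))
  meta <- as.data.frame(dt[match(ids, dt$spectrum_id),
                           c("spectrum_id", have), with = FALSE])
  if (!is.null(meta$label)) meta$label <- .cleanLabels(meta$label, path)
  SersSpectra(M, wn, meta)
}

#' Write spectra to plain-text files
#'
#' Inverse of [readSpectra()]; see there for the dialect definitions.
#' Column ordering is deterministic (axis order; spectra in container order)
#' and numbers are serialised with full round-trip precision.
#'
#' @param x a [SersSpectra].
#' @param path output file (`.csv` or `.tsv`).
#' @param format `"wide_csv"` or `"long_csv"`.
#' @param metaPath sidecar path for the wide dialect (default derived).
#' @return `path`, invisibly.
#' @export
writeSpectra <- function(x, path, format = c("wide_csv", "long_csv"),
                         metaPath = NULL) {
  stopifnot(is(x, "SersSpectra"))
  validObject(x)
  format <- match.arg(format)
  sep <- if (identical(tolower(tools::file_ext(path)), "tsv")) "\t" else ","
  M <- SummarizedExperiment::assay(x, "intensity")
  meta <- spectrumData(x)
  keep <- intersect(c("spectrum_id", .metaCols), names(meta))
  meta <- meta[, keep, drop = FALSE]
  if (format == "wide_csv") {
    dt <- data.table::data.table(wavenumber = wavenumbers(x))
    if (ncol(M)) for (j in seq_len(ncol(M))) dt[[colnames(M)[j]]] <- M[, j]
    data.table::fwrite(dt, path, sep = sep)
    if (is.null(metaPath)) metaPath <- .metaPathFor(path)
    data.table::fwrite(meta, metaPath, sep = sep)
  } else {
    n <- ncol(M); L <- nrow(M)
    dt <- data.table::data.table(
      spectrum_id = rep(colnames(M), each = L),
      wavenumber = rep(wavenumbers(x), n),
      intensity = as.vector(M))
    for (cc in setdiff(keep, "spectrum_id"))
      dt[[cc]] <- rep(meta[[cc]], each = L)
    data.table::fwrite(dt, path, sep = sep)
  }
  invisible(path)
}
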