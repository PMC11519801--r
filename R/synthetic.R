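#' @include AllClasses.R
NULL

#' Default Raman band catalogue
#'
#' The ten bands used throughout the package, with their conventional
#' biomolecular assignments: methionine (647 cm^-1), the O-P-O stretch of DNA
#' (826 cm^-1), phenylalanine (1000 cm^-1), the C-O stretch of ribose
#' (1018 cm^-1), carbohydrates (1025 cm^-1), C-C/C-N stretching of proteins
#' (1161 cm^-1), tyrosine (1206 cm^-1), fatty acids (1444 cm^-1), COO-
#' (1562 cm^-1) and tryptophan (1623 cm^-1). Line shapes are Gaussian with a
#' default FWHM of 12 cm^-1, a typical SERS bandwidth.
#'
#' @param fwhm full width at half maximum in cm^-1 applied to every band.
#' @return `data.frame` with columns `center`, `fwhm`, `assignment`.
#' @export
defaultBandCatalog <- function(fwhm = 12) {
  data.frame(
    center = c(647, 826, 1000, 1018, 1025, 1161, 1206, 1444, 1562, 1623),
    fwhm = fwhm,
    assignment = c("methionine", "O-P-O stretch of DNA", "phenylalanine",
                   "C-O stretch of ribose", "carbohydrates",
                   "C-C/C-N stretch of proteins", "tyrosine", "fatty acid",
                   "COO-", "tryptophan"),
    stringsAsFactors = FALSE)
}

#' Default mature/immature class profiles
#'
#' Amplitude means are arbitrary-unit peak heights of the immature state;
#' the mature state multiplies them by a class-effect ratio: 3.0 for the
#' tryptophan band at 1623 cm^-1 (the maturation marker, markedly stronger in
#' mature cells), 1.15 at 826 and 1161 cm^-1 (mild nucleic-acid/protein
#' shifts) and 1.0 elsewhere (in particular the carbohydrate band at
#' 1025 cm^-1, which is comparable between the states). Amplitude standard
#' deviations are 10% of the mean; both classes share a small positive
#' quadratic baseline.
#'
#' @param catalog band catalogue, see [defaultBandCatalog()].
#' @param effect1623 mature/immature amplitude ratio at 1623 cm^-1.
#' @return named list of two [classProfile()] objects (`mature`, `immature`).
#' @export
defaultProfiles <- function(catalog = defaultBandCatalog(), effect1623 = 3.0) {
  immMean <- c(`647` = 0.50, `826` = 0.60, `1000` = 0.90, `1018` = 0.70,
               `1025` = 0.85, `1161` = 0.55, `1206` = 0.45, `1444` = 0.75,
               `1562` = 0.40, `1623` = 0.35)
  ratio <- setNames(rep(1, nrow(catalog)), as.character(catalog$center))
  ratio["1623"] <- effect1623
  ratio[c("826", "1161")] <- 1.15
  key <- as.character(catalog$center)
  imm <- data.frame(center = catalog$center, fwhm = catalog$fwhm,
                    mean = unname(immMean[key]), sd = 0.1 * unname(immMean[key]),
                    assignment = catalog$assignment, stringsAsFactors = FALSE)
  mat <- imm
  mat$mean <- imm$mean * unname(ratio[key])
  mat$sd <- 0.1 * mat$mean
  list(mature = classProfile("mature", mat),
       immature = classProfile("immature", imm))
}

# Gaussian line-shape basis: wavenumbers x bands, unit peak height.
.bandBasis <- function(axis, centers, fwhm) {
  G <- matrix(0, length(axis), length(centers))
  for (j in seq_along(centers))
    G[, j] <- exp(-4 * log(2) * ((axis - centers[j]) / fwhm[j])^2)
  G
}

.baselineCurve <- function(axis, coeffs) {
  u <- (axis - min(axis)) / max(max(axis) - min(axis), .Machine$double.eps)
  drop(outer(u, seq_along(coeffs) - 1, `^`) %*% coeffs)
}

# Cell templates for one class: baseline + Gaussian bands with per-cell
# amplitudes mean + sd * zAmp, all scaled by exp(cellScaleSd * zScale).
.cellTemplates <- function(axis, profile, zScale, zAmp, cellScaleSd) {
  scale <- exp(cellScaleSd * zScale)
  amps <- pmax(profile@bands$mean + profile@bands$sd * zAmp, 0) # bands x cells
  amps <- sweep(amps, 2, scale, `*`)
  G <- .bandBasis(axis, profile@bands$center, profile@bands$fwhm)
  base <- .baselineCurve(axis, profile@baseline)
  G %*% amps + base
}

#' Generate a synthetic single-cell SERS dataset
#'
#' Draws `nCellsPerClass` cells per maturation state. Each cell receives a
#' log-normal multiplicative scale effect and per-band peak amplitudes
#' (truncated at zero); its replicate spectra are the resulting noiseless
#' template plus i.i.d. Gaussian noise. The hierarchy (cell effects shared by
#' a cell's replicates, noise independent per spectrum) reproduces the
#' within-cell vs between-cell variance structure of repeated single-cell
#' acquisitions. Fully deterministic for a fixed configuration.
#'
#' @param config a [syntheticConfig()].
#' @return a [SersSpectra] with `cell_id` and `label` metadata
#'   (`sum(nCellsPerClass) * spectraPerCell` spectra).
#' @export
#' @examples
#' cfg <- syntheticConfig(nCellsPerClass = c(mature = 3, immature = 4),
#'                        spectraPerCell = 2)
#' generateDataset(cfg)
generateDataset <- function(config) {
  validObject(config)
  withSeed(config@seed, .generateBody(config))
}

.generateBody <- function(config) {
  axis <- config@axis
  spc <- config@spectraPerCell
  mats <- list(); metas <- list()
  for (cls in c("mature", "immature")) {
    nc <- config@nCellsPerClass[[cls]]
    prof <- config@profiles[[cls]]
    nb <- nrow(prof@bands)
    zScale <- rnorm(nc)
    zAmp <- matrix(rnorm(nb * nc), nb, nc)
    tmpl <- .cellTemplates(axis, prof, zScale, zAmp, config@cellScaleSd)
    M <- tmpl[, rep(seq_len(nc), each = spc), drop = FALSE]
    if (config@noiseSd > 0)
      M <- M + matrix(rnorm(length(M), sd = config@noiseSd), nrow(M))
    cells <- sprintf("%s_c%03d", cls, seq_len(nc))
    meta <- data.frame(
      spectrum_id = sprintf("%s_s%02d", rep(cells, each = spc),
                            rep(seq_len(spc), nc)),
      cell_id = rep(cells, each = spc),
      label = cls, stringsAsFactors = FALSE)
    mats[[cls]] <- M; metas[[cls]] <- meta
  }
  SersSpectra(do.call(cbind, mats), axis, do.call(rbind, metas))
}

#' Generate a synthetic maturation time-course
#'
#' A treated arm (labelled `mature`) interpolates linearly from the immature
#' toward the mature profile according to `maturationProgress`; a control arm
#' (labelled `immature`) keeps the immature profile at every time point. Cell
#' identities and their random effects (scale and amplitude deviates) persist
#' across time points, so a cell's trajectory is smooth in the progress
#' weight; acquisition noise is drawn independently per time point.
#'
#' @param config a [timecourseConfig()].
#' @return named list of [SersSpectra], one per time point (names are the
#'   hours), each carrying `time_point_h` metadata.
#' @export
generateTimecourse <- function(config) {
  validObject(config)
  base <- config@base
  validObject(base)
  withSeed(base@seed, {
    axis <- base@axis
    spc <- base@spectraPerCell
    arms <- list(
      treated = list(n = base@nCellsPerClass[["mature"]], label = "mature"),
      control = list(n = base@nCellsPerClass[["immature"]], label = "immature"))
    nb <- nrow(base@profiles$immature@bands)
    eff <- lapply(arms, function(a)
      list(zScale = rnorm(a$n), zAmp = matrix(rnorm(nb * a$n), nb, a$n)))
    imm <- base@profiles$immature
    mat <- base@profiles$mature
    out <- vector("list", length(config@timePointsH))
    names(out) <- as.character(config@timePointsH)
    for (ti in seq_along(config@timePointsH)) {
      w <- config@maturationProgress[ti]
      interp <- imm
      interp@bands$mean <- imm@bands$mean + w * (mat@bands$mean - imm@bands$mean)
      interp@bands$sd <- imm@bands$sd + w * (mat@bands$sd - imm@bands$sd)
      interp@baseline <- imm@baseline + w * (mat@baseline - imm@baseline)
      profs <- list(treated = interp, control = imm)
      mats <- list(); metas <- list()
      for (arm in names(arms)) {
        nc <- arms[[arm]]$n
        tmpl <- .cellTemplates(axis, profs[[arm]], eff[[arm]]$zScale,
                               eff[[arm]]$zAmp, base@cellScaleSd)
        M <- tmpl[, rep(seq_len(nc), each = spc), drop = FALSE]
        if (base@noiseSd > 0)
          M <- M + matrix(rnorm(length(M), sd = base@noiseSd), nrow(M))
        cells <- sprintf("%s_c%03d", arm, seq_len(nc))
        metas[[arm]] <- data.frame(
          spectrum_id = sprintf("t%g_%s_s%02d", config@timePointsH[ti],
                                rep(cells, each = spc), rep(seq_len(spc), nc)),
          cell_id = rep(cells, each = spc),
          label = arms[[arm]]$label,
          time_point_h = config@timePointsH[ti], stringsAsFactors = FALSE)
        mats[[arm]] <- M
      }
      out[[ti]] <- SersSpectra(do.call(cbind, mats), axis, do.call(rbind, metas))
    }
    out
  })
}

#' Generate a synthetic Raman mapping grid
#'
#' Emulates raster acquisition across a single cell at 1 micrometre steps:
#' one spectrum per grid node with `x`/`y` metadata. Nodes inside a central
#' elliptical "cell" region (relative radius `cellRadius`) carry the full
#' class profile (with per-node amplitude jitter); peripheral nodes carry
#' the baseline background only.
#'
#' @param config a [syntheticConfig()]; its profile for `label` is used.
#' @param gridShape integer `c(rows, cols)`, both at least 1.
#' @param label `"mature"` or `"immature"`, the cell's state.
#' @param cellRadius cell radius as a fraction of the half grid extent.
#' @return a [SersSpectra] with `x`, `y`, `in_cell` metadata; interior nodes
#'   are labelled with `label`, peripheral ones `"unknown"`.
#' @export
generateMappingGrid <- function(config, gridShape = c(20L, 20L),
                                label = c("mature", "immature"),
                                cellRadius = 0.7) {
  validObject(config)
  label <- match.arg(label)
  gridShape <- as.integer(gridShape)
  if (length(gridShape) != 2 || any(is.na(gridShape)) || any(gridShape < 1L))
    stop("invalid config: gridShape must be two integers >= 1")
  withSeed(config@seed, {
    axis <- config@axis
    prof <- config@profiles[[label]]
    rows <- gridShape[1]; cols <- gridShape[2]
    pos <- expand.grid(y = seq_len(rows), x = seq_len(cols))
    cy <- (rows + 1) / 2; cx <- (cols + 1) / 2
    ry <- max(rows / 2 * cellRadius, 0.51)
    rx <- max(cols / 2 * cellRadius, 0.51)
    inside <- ((pos$y - cy) / ry)^2 + ((pos$x - cx) / rx)^2 <= 1
    n <- nrow(pos)
    nb <- nrow(prof@bands)
    base <- .baselineCurve(axis, prof@baseline)
    M <- matrix(base, length(axis), n)
    if (any(inside)) {
      ni <- sum(inside)
      scale <- exp(config@cellScaleSd * rnorm(1))  # one cell, one uptake effect
      amps <- pmax(prof@bands$mean + prof@bands$sd *
                     matrix(rnorm(nb * ni), nb, ni), 0) * scale
      G <- .bandBasis(axis, prof@bands$center, prof@bands$fwhm)
      M[, inside] <- M[, inside, drop = FALSE] + G %*% amps
    }
    if (config@noiseSd > 0)
      M <- M + matrix(rnorm(length(M), sd = config@noiseSd), nrow(M))
    meta <- data.frame(
      spectrum_id = sprintf("pos_y%03d_x%03d", pos$y, pos$x),
      cell_id = ifelse(inside, "cell_001", NA_character_),
      label = ifelse(inside, label, "unknown"),
      x = pos$x, y = pos$y, in_cell = inside, stringsAsFactors = FALSE)
    SersSpectra(M, axis, meta)
  })
}
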