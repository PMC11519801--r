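# Small, fast fixture builders shared across the suite.

tinyAxis <- function(n = 1015) seq(600, 1700, length.out = n)

tinyConfig <- function(nMature = 6L, nImmature = 6L, spc = 3L, seed = 1L, ...)
  syntheticConfig(nCellsPerClass = c(mature = nMature, immature = nImmature),
                  spectraPerCell = spc, seed = seed, ...)

# A labelled dataset built directly from a matrix (no generator involved).
manualSpectra <- function(M, wn = NULL, labels = NULL, cells = NULL) {
  if (is.null(wn)) wn <- seq(600, 1700, length.out = nrow(M))
  n <- ncol(M)
  SersSpectra(M, wn, data.frame(
    spectrum_id = sprintf("s%03d", seq_len(n)),
    cell_id = if (is.null(cells)) sprintf("c%03d", seq_len(n)) else cells,
    label = if (is.null(labels)) rep("unknown", n) else labels))
}

# Noiseless class template computed independently of the generator internals:
# polynomial baseline + sum of Gaussian bands at their mean amplitudes.
oracleTemplate <- function(axis, profile) {
  u <- (axis - min(axis)) / (max(axis) - min(axis))
  base <- rowSums(sapply(seq_along(profile@baseline),
                         function(k) profile@baseline[k] * u^(k - 1)))
  for (i in seq_len(nrow(profile@bands)))
    base <- base + profile@bands$mean[i] *
      exp(-4 * log(2) * ((axis - profile@bands$center[i]) /
                           profile@bands$fwhm[i])^2)
  base
}

# Brute-force sliding-window census used as the shape-arithmetic oracle.
bruteWindows <- function(len, window, stride) {
  count <- 0L
  start <- 1L
  while (start + window - 1L <= len) {
    count <- count + 1L
    start <- start + stride
  }
  count
}

# Pairwise-concordance AUC oracle (ties counted 1/2).
concordanceAUC <- function(scores, labels) {
  pos <- scores[labels == "mature"]
  neg <- scores[labels == "immature"]
  pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(pairs)
}
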