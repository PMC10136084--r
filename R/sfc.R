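#' Biased sample skewness
#'
#' The third central moment over the 3/2 power of the second, both with
#' divisor n: m3 / m2^(3/2). This biased form (no small-sample correction)
#' is the quantity correlated across epochs. A zero-variance input returns
#' 0 with attribute `degenerate = TRUE` rather than NaN.
#'
#' @param x numeric vector, length >= 3.
#' @return skewness value; attribute `degenerate` flags zero variance.
#' @export
sampleSkewness <- function(x) {
  n <- length(x)
  if (n < 3L) stopf("skewness needs at least 3 samples, got %d", n)
  d <- x - mean(x)
  m2 <- mean(d^2)
  if (m2 == 0) return(structure(0, degenerate = TRUE))
  structure(mean(d^3) / m2^1.5, degenerate = FALSE)
}

#' Skewness feature matrix
#'
#' Computes Y\[i, t\] = sample skewness of channel i's envelope samples in
#' epoch t, the N x T feature matrix whose rows are correlated across time.
#' Zero-variance epochs (constant envelope) get skewness 0 and are marked
#' in the degenerate mask.
#'
#' @param env an [EnvelopeEpochs-class].
#' @return a [SkewnessMatrix-class].
#' @export
skewnessMatrix <- function(env) {
  stopifnot(is(env, "EnvelopeEpochs"))
  d <- dim(env@values)
  N <- d[1L]; T <- d[2L]; L <- d[3L]
  if (T < 2L) stopf("need at least 2 epochs, got %d", T)
  if (L < 3L) stopf("epochs of %d samples are too short for skewness", L)
  Y <- matrix(0, N, T)
  degen <- matrix(FALSE, N, T)
  for (i in seq_len(N)) {
    xm <- matrix(env@values[i, , ], nrow = T)   # T x L
    mu <- rowMeans(xm)
    dd <- xm - mu
    m2 <- rowMeans(dd^2)
    m3 <- rowMeans(dd^3)
    zero <- m2 == 0
    Y[i, ] <- ifelse(zero, 0, m3 / pmax(m2, .Machine$double.xmin)^1.5)
    degen[i, ] <- zero
  }
  rownames(Y) <- env@channelNames
  new("SkewnessMatrix", Y = Y, channelNames = env@channelNames,
      degenerateMask = degen)
}

#' Spearman rank correlation of two series
#'
#' Pearson correlation of average ranks (tie-corrected); on tie-free input
#' this equals the classical 1 - 6 sum(d^2) / (T (T^2 - 1)). A constant
#' input has no rank ordering: the correlation is defined as 0 with a
#' warning.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return correlation in \[-1, 1\].
#' @export
spearmanRho <- function(x, y) {
  if (length(x) != length(y))
    stopf("length mismatch: %d vs %d", length(x), length(y))
  if (length(x) < 2L) stopf("need at least 2 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warnf("constant input: Spearman correlation defined as 0")
    return(0)
  }
  stats::cor(x, y, method = "spearman")
}

#' Rank-correlation adjacency matrix
#'
#' The functional network: Z\[i, j\] = |Spearman correlation| between the
#' skewness time series of channels i and j, diagonal forced to 0.
#' Channels whose skewness series is constant (degenerate) get zero edges,
#' with a warning naming them.
#'
#' @param Y a [SkewnessMatrix-class] or a plain N x T matrix.
#' @return an [AdjacencyMatrix-class].
#' @export
buildAdjacency <- function(Y) {
  nms <- if (is(Y, "SkewnessMatrix")) Y@channelNames else rownames(Y)
  Ym <- if (is(Y, "SkewnessMatrix")) Y@Y else as.matrix(Y)
  if (nrow(Ym) < 2L) stopf("need at least 2 channels, got %d", nrow(Ym))
  if (is.null(nms)) nms <- paste0("ch", seq_len(nrow(Ym)))
  constant <- apply(Ym, 1L, function(r) stats::sd(r) == 0)
  Z <- suppressWarnings(stats::cor(t(Ym), method = "spearman"))
  if (any(constant)) {
    warnf("degenerate channel(s) with constant skewness, edges set to 0: %s",
          paste(nms[constant], collapse = ", "))
    Z[constant, ] <- 0
    Z[, constant] <- 0
  }
  Z <- abs(Z)
  Z <- (Z + t(Z)) / 2          # remove float asymmetry
  Z[Z > 1] <- 1
  diag(Z) <- 0
  dimnames(Z) <- list(nms, nms)
  new("AdjacencyMatrix", Z = Z, channelNames = nms)
}

#' Node connectivity strength
#'
#' Per channel, the sum of its edge weights to all other channels (column
#' sums of Z; equal to row sums by symmetry). Bounded by N - 1.
#'
#' @param Z an [AdjacencyMatrix-class] or plain symmetric matrix.
#' @param patientId carried into the result.
#' @return a [StrengthVector-class].
#' @export
nodeStrength <- function(Z, patientId = "patient") {
  nms <- if (is(Z, "AdjacencyMatrix")) Z@channelNames else rownames(Z)
  Zm <- if (is(Z, "AdjacencyMatrix")) Z@Z else as.matrix(Z)
  s <- colSums(Zm)
  names(s) <- if (is.null(nms)) paste0("ch", seq_along(s)) else nms
  new("StrengthVector", s = s, patientId = patientId)
}

#' Direct per-band connectivity (comparison path)
#'
#' The conventional alternative to skewness-based connectivity: within each
#' epoch, pairwise |Spearman| across channels is computed on the filtered
#' samples themselves, and the per-epoch matrices are averaged over time.
#' Used for the low-frequency comparison bands and for the direct extension
#' to the high-frequency band.
#'
#' @param rec a band-filtered [BipolarRecording-class].
#' @param epochLen epoch length in seconds.
#' @return an [AdjacencyMatrix-class] (time-averaged).
#' @export
bandConnectivityDirect <- function(rec, epochLen = 1) {
  stopifnot(is(rec, "BipolarRecording"))
  L <- round(rec@fs * epochLen)
  T <- floor(ncol(rec@samples) / L)
  if (T < 1L) stopf("segment shorter than one epoch")
  N <- nrow(rec@samples)
  acc <- matrix(0, N, N)
  for (t in seq_len(T)) {
    seg <- rec@samples[, ((t - 1L) * L + 1L):(t * L), drop = FALSE]
    rk <- apply(seg, 1L, rank)               # L x N average ranks
    Zt <- suppressWarnings(abs(stats::cor(rk)))
    Zt[!is.finite(Zt)] <- 0
    acc <- acc + Zt
  }
  Z <- acc / T
  Z <- (Z + t(Z)) / 2
  Z[Z > 1] <- 1
  diag(Z) <- 0
  dimnames(Z) <- list(rec@pairNames, rec@pairNames)
  new("AdjacencyMatrix", Z = Z, channelNames = rec@pairNames)
}
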