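# Zero-phase spectral filtering machinery.
#
# Forward-backward application of a filter H is equivalent to a single
# zero-phase pass with response |H(w)|^2. We evaluate |H|^2 on the DFT grid
# of the (mirror-padded) signal and multiply in the frequency domain; this
# gives the exact forward-backward magnitude (doubled stopband attenuation)
# with exactly zero phase at O(n log n), independent of filter length.

.filterCache <- new.env(parent = emptyenv())

memoGet <- function(key, compute) {
  if (is.null(.filterCache[[key]])) .filterCache[[key]] <- compute()
  .filterCache[[key]]
}

# Hamming-window FIR taps for a band. type "pass" needs both edges, "high"
# only the lower edge. Transition bandwidth is 0.1x the lower edge, floored
# at 2 Hz; the order follows the standard Hamming rule 3.3 * fs / tw.
firTaps <- function(fs, low, high = NULL, type = c("pass", "high")) {
  type <- match.arg(type)
  tw <- max(2, 0.1 * low)
  n <- ceiling(3.3 * fs / tw)
  if (n %% 2L == 1L) n <- n + 1L  # even order => odd symmetric taps
  key <- sprintf("fir|%g|%g|%s|%s", fs, low, type,
                 if (is.null(high)) "" else as.character(high))
  memoGet(key, function() {
    if (type == "high") signal::fir1(n, low / (fs / 2), type = "high")
    else signal::fir1(n, c(low, high) / (fs / 2), type = "pass")
  })
}

# |H|^2 of an FIR filter on the length-M DFT grid (polynomial evaluation at
# the grid points is the zero-padded FFT of the taps).
firResponseSq <- function(taps, M) {
  Mod(stats::fft(c(taps, numeric(M - length(taps)))))^2
}

# Combined |H|^2 of order-2 Butterworth band-stops (total width `width` Hz)
# at lineFreq and every harmonic fitting below Nyquist.
notchResponseSq <- function(fs, lineFreq, width, M) {
  key <- sprintf("notch|%g|%g|%g|%d", fs, lineFreq, width, M)
  memoGet(key, function() {
    resp <- rep(1, M)
    h <- lineFreq
    while (h + width / 2 < fs / 2) {
      flt <- signal::butter(2, c(h - width / 2, h + width / 2) / (fs / 2),
                            type = "stop")
      B <- stats::fft(c(flt$b, numeric(M - length(flt$b))))
      A <- stats::fft(c(flt$a, numeric(M - length(flt$a))))
      resp <- resp * (Mod(B) / Mod(A))^2
      h <- h + lineFreq
    }
    resp
  })
}

# Apply a real, zero-phase spectral response to each row of a channels x time
# matrix. Edges are odd-mirror padded by `pad` samples so filter ringing
# lands in the discarded margin; rows are processed in one mvfft batch.
applySpectral <- function(x, responseFor, pad) {
  n <- ncol(x)
  C <- nrow(x)
  p <- min(as.integer(pad), n - 1L)
  M <- stats::nextn(n + 2L * p, c(2L, 3L, 5L))
  resp <- responseFor(M)
  xp <- matrix(0, M, C)
  xt <- t(x)
  xp[p + seq_len(n), ] <- xt
  xp[seq_len(p), ] <- rep(2 * x[, 1L], each = p) -
    xt[seq(p + 1L, 2L), , drop = FALSE]
  xp[p + n + seq_len(p), ] <- rep(2 * x[, n], each = p) -
    xt[seq(n - 1L, n - p), , drop = FALSE]
  # The zero-phase response is real and even, so its impulse response is
  # real: filtering keeps real and imaginary parts independent. Pack
  # channel pairs as complex signals to halve the number of transforms.
  nPair <- ceiling(C / 2)
  zp <- matrix(0 + 0i, M, nPair)
  odd <- seq(1L, C, by = 2L)
  even <- seq(2L, C, by = 2L)
  zp[, seq_along(odd)] <- xp[, odd, drop = FALSE]
  if (length(even))
    zp[, seq_along(even)] <- zp[, seq_along(even), drop = FALSE] +
      1i * xp[, even, drop = FALSE]
  Z <- stats::mvfft(stats::mvfft(zp) * resp, inverse = TRUE) / M
  out <- matrix(0, C, n)
  rows <- p + seq_len(n)
  out[odd, ] <- t(Re(Z[rows, seq_along(odd), drop = FALSE]))
  if (length(even))
    out[even, ] <- t(Im(Z[rows, seq_along(even), drop = FALSE]))
  out
}

# Fourier resampling of each row to m samples (m <= n): truncate the
# spectrum symmetrically, which is ideal-lowpass anti-aliasing.
resampleFft <- function(x, m) {
  n <- ncol(x)
  X <- stats::mvfft(t(x))
  Y <- matrix(0 + 0i, m, nrow(x))
  half <- if (m %% 2L == 0L) m %/% 2L - 1L else (m - 1L) %/% 2L
  Y[1L, ] <- X[1L, ]
  if (half >= 1L) {
    ks <- seq_len(half)
    Y[1L + ks, ] <- X[1L + ks, , drop = FALSE]
    Y[m + 1L - ks, ] <- X[n + 1L - ks, , drop = FALSE]
  }
  if (m %% 2L == 0L) Y[m %/% 2L + 1L, ] <- Re(X[m %/% 2L + 1L, ])
  t(Re(stats::mvfft(Y, inverse = TRUE))) / n
}

#' Named analysis bands
#'
#' Resolves a band name to filter edges. `"hfo"` is the high-frequency band:
#' a band-pass 80-500 Hz when 500 Hz lies below Nyquist, otherwise a
#' high-pass above 80 Hz (the form used at a 1000 Hz common sampling rate);
#' `"hf_high"` forces the high-pass form. The comparison bands are delta
#' 1-4, theta 4-8, alpha 8-13, beta 13-30 and gamma 30-80 Hz. A numeric pair
#' is taken as explicit band-pass edges.
#'
#' @param band band name or numeric length-2 vector of edges in Hz.
#' @param fs sampling rate in Hz.
#' @return list with `low`, `high` (NULL for high-pass) and `type`.
#' @export
bandSpec <- function(band, fs) {
  if (is.numeric(band)) {
    if (length(band) != 2L || band[1L] <= 0 || diff(band) <= 0)
      stopf("numeric band must be ordered positive edges")
    spec <- list(low = band[1L], high = band[2L], type = "pass")
  } else {
    spec <- switch(match.arg(band, c("hfo", "hf_high", "delta", "theta",
                                     "alpha", "beta", "gamma")),
      hfo = if (500 < fs / 2) list(low = 80, high = 500, type = "pass")
            else list(low = 80, high = NULL, type = "high"),
      hf_high = list(low = 80, high = NULL, type = "high"),
      delta = list(low = 1, high = 4, type = "pass"),
      theta = list(low = 4, high = 8, type = "pass"),
      alpha = list(low = 8, high = 13, type = "pass"),
      beta = list(low = 13, high = 30, type = "pass"),
      gamma = list(low = 30, high = 80, type = "pass"))
  }
  edge <- if (is.null(spec$high)) spec$low else spec$high
  if (edge >= fs / 2)
    stopf("band edge %g Hz is at or above Nyquist (%g Hz)", edge, fs / 2)
  spec
}
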