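#' Configure the synthetic iEEG generator
#'
#' Builds a validated [SimConfig-class]. The defaults describe the cohorts
#' used throughout the package's own validation: 10 patients x 20 contacts,
#' 5-minute segments at the 1000 Hz common rate, unit-RMS pink (1/f)
#' background, transient 80-400 Hz oscillatory events of 30-100 ms at 4x
#' background RMS, 2 events/s on epileptic contacts against 0.2 events/s
#' elsewhere, and strong (0.9) shared rate/amplitude co-modulation of the
#' epileptic contacts.
#'
#' @param nPatients number of patients in a cohort.
#' @param nChannels contacts per patient (grouped into 8-contact shafts
#'   named "A1".."A8", "B1"..).
#' @param fracEpileptic fraction of contacts that are epileptic (>= 1
#'   contact); epileptic contacts form a contiguous block from "A1".
#' @param fs sampling rate in Hz.
#' @param duration segment length in seconds.
#' @param baselineExponent spectral slope of the 1/f^a background.
#' @param eventRateEpileptic,eventRateNormal mean event rates, events/s.
#' @param eventFreqRange event carrier frequency range, Hz, within
#'   \[80, fs/2).
#' @param eventDurationRange event duration range in seconds.
#' @param eventAmplitude event peak amplitude as a multiple of background
#'   RMS; 0 gives pure background.
#' @param coupling in \[0, 1\]: weight of the shared log-Gaussian latent
#'   intensity among epileptic contacts (0 = independent homogeneous
#'   Poisson events).
#' @param effectOutcome for poor-outcome patients, the number of residual
#'   epileptic-behaving contacts outside the labeled tissue, as a fraction
#'   of the labeled count (0 = none).
#' @param seed master seed; expanded into per-patient substreams.
#' @return a [SimConfig-class].
#' @export
simConfig <- function(nPatients = 10, nChannels = 20, fracEpileptic = 0.25,
                      fs = 1000, duration = 300, baselineExponent = 1,
                      eventRateEpileptic = 2, eventRateNormal = 0.2,
                      eventFreqRange = c(80, 400),
                      eventDurationRange = c(0.03, 0.1),
                      eventAmplitude = 4, coupling = 0.9,
                      effectOutcome = 0, seed = 1) {
  new("SimConfig", nPatients = nPatients, nChannels = nChannels,
      fracEpileptic = fracEpileptic, fs = fs, duration = duration,
      baselineExponent = baselineExponent,
      eventRateEpileptic = eventRateEpileptic,
      eventRateNormal = eventRateNormal,
      eventFreqRange = as.numeric(eventFreqRange),
      eventDurationRange = as.numeric(eventDurationRange),
      eventAmplitude = eventAmplitude, coupling = coupling,
      effectOutcome = effectOutcome, seed = seed)
}

# Gaussian 1/f^alpha noise at unit RMS via FFT spectral shaping.
pinkNoise <- function(n, alpha) {
  pinkNoiseMatrix(1L, n, alpha)[1L, ]
}

# C channels of independent 1/f^alpha noise, unit RMS each. The spectrum is
# drawn as unconstrained complex Gaussian, so the real and imaginary parts
# of its inverse transform are two independent channels with the target
# power spectrum: one inverse FFT yields two channels.
pinkNoiseMatrix <- function(C, n, alpha) {
  k <- seq_len(n) - 1L
  f <- pmin(k, n - k)            # two-sided frequency index
  scale <- if (alpha == 0) rep(1, n) else c(0, 1 / f[-1L]^(alpha / 2))
  nPair <- ceiling(C / 2)
  spec <- matrix(complex(real = stats::rnorm(n * nPair),
                         imaginary = stats::rnorm(n * nPair)),
                 n, nPair) * scale
  z <- stats::mvfft(spec, inverse = TRUE) / n
  out <- matrix(0, C, n)
  odd <- seq(1L, C, by = 2L)
  out[odd, ] <- t(Re(z[, seq_along(odd), drop = FALSE]))
  if (C > 1L) {
    even <- seq(2L, C, by = 2L)
    out[even, ] <- t(Im(z[, seq_along(even), drop = FALSE]))
  }
  out / sqrt(rowMeans(out^2) - rowMeans(out)^2)
}

# Shaft/contact names: 5-contact depth shafts A1..A5, B1..B5, ... With the
# default 25% epileptic fraction and 20 contacts the epileptic block is
# exactly one shaft, so labeled and unlabeled channels share the same
# bipolar chain topology (no structural strength bias under the null).
contactNames <- function(nChannels, perShaft = 5L) {
  shafts <- rep(LETTERS, each = perShaft)[seq_len(nChannels)]
  contacts <- rep(seq_len(perShaft), times = 26L)[seq_len(nChannels)]
  paste0(shafts, contacts)
}

simulateChannel <- function(cfg, n, lambdaPerSec, ampMod, background = NULL) {
  x <- if (is.null(background)) pinkNoise(n, cfg@baselineExponent)
       else background
  counts <- stats::rpois(length(lambdaPerSec), lambdaPerSec)
  total <- sum(counts)
  if (total == 0L || cfg@eventAmplitude == 0) return(x)
  secs <- rep(seq_along(counts), counts)
  t0 <- (secs - 1L) + stats::runif(total)
  f <- stats::runif(total, cfg@eventFreqRange[1L], cfg@eventFreqRange[2L])
  dur <- stats::runif(total, cfg@eventDurationRange[1L],
                      cfg@eventDurationRange[2L])
  amp <- cfg@eventAmplitude * exp(stats::rnorm(total, 0, 0.2)) * ampMod[secs]
  phase <- stats::runif(total, 0, 2 * pi)
  fs <- cfg@fs
  # Hann-windowed sinusoidal bursts added in place
  for (e in seq_len(total)) {
    len <- max(4L, round(dur[e] * fs))
    i0 <- floor(t0[e] * fs) + 1L
    iEnd <- min(i0 + len - 1L, n)
    k <- 0:(iEnd - i0)
    win <- 0.5 - 0.5 * cos(2 * pi * k / (len - 1L))
    x[i0:iEnd] <- x[i0:iEnd] +
      amp[e] * sin(2 * pi * f[e] * k / fs + phase[e]) * win
  }
  x
}

# Core patient generator. `residualCount` epileptic-behaving contacts
# immediately after the labeled block get truth = FALSE (poor-outcome
# patients whose treated zone missed part of the epileptic tissue).
simulatePatientCore <- function(cfg, patientIndex, patientSeed,
                                residualCount = 0L) {
  validObject(cfg)
  withSeed(patientSeed, {
    nCh <- as.integer(cfg@nChannels)
    n <- round(cfg@fs * cfg@duration)
    nSec <- floor(cfg@duration)
    nEp <- max(1L, round(cfg@fracEpileptic * nCh))
    residualCount <- min(as.integer(residualCount), nCh - nEp)
    behaving <- seq_len(nEp + residualCount)   # epileptic-behaving contacts
    truth <- seq_len(nCh) %in% seq_len(nEp)    # labeled epileptic tissue

    # shared latent intensity (log-Gaussian AR(1)) over seconds
    phi <- 0.9; sigma <- 0.8
    burn <- 50L
    eps <- stats::rnorm(nSec + burn, 0, sqrt(1 - phi^2))
    g <- as.numeric(stats::filter(eps, phi, method = "recursive"))
    g <- g[(burn + 1L):(nSec + burn)]
    latent <- exp(sigma * g - sigma^2 / 2)

    mat <- pinkNoiseMatrix(nCh, n, cfg@baselineExponent)
    for (i in seq_len(nCh)) {
      if (i %in% behaving) {
        lam <- cfg@eventRateEpileptic *
          ((1 - cfg@coupling) + cfg@coupling * latent)
        ampMod <- latent^(0.5 * cfg@coupling)
      } else {
        lam <- rep(cfg@eventRateNormal, nSec)
        ampMod <- rep(1, nSec)
      }
      mat[i, ] <- simulateChannel(cfg, n, lam, ampMod, background = mat[i, ])
    }
    rec <- RecordingSegment(mat, cfg@fs, contactNames(nCh),
                            patientId = sprintf("sim%02d", patientIndex))
    list(recording = rec, truth = truth)
  })
}

#' Simulate one patient
#'
#' Generates one multichannel segment: unit-RMS 1/f background everywhere,
#' plus Hann-windowed sinusoidal bursts whose per-second Poisson intensity
#' on epileptic contacts mixes a constant with a shared log-Gaussian latent
#' process (weight = `coupling`), so their per-epoch envelope skewness
#' co-varies over time; normal contacts receive independent low-rate bursts.
#' Deterministic given the config seed and patient index.
#'
#' @param cfg a [SimConfig-class].
#' @param patientIndex 1-based index within the cohort (selects the
#'   per-patient substream of `cfg@seed`).
#' @return list with `recording` ([RecordingSegment-class]) and `truth`
#'   (logical per contact).
#' @export
simulatePatient <- function(cfg, patientIndex = 1) {
  seeds <- deriveSeeds(cfg@seed, max(cfg@nPatients, patientIndex))
  simulatePatientCore(cfg, patientIndex, seeds[patientIndex])
}

#' Simulate a cohort with outcome groups
#'
#' Patients alternate between seizure-free (odd index; ILAE 1 / Engel 1)
#' and poor outcome (even index; ILAE 4 / Engel 3). When
#' `cfg@effectOutcome > 0`, each poor-outcome patient carries
#' `max(1, round(effectOutcome * nEpileptic))` residual epileptic-behaving
#' contacts outside the labeled tissue, emulating incomplete treatment of
#' the true epileptic network. Identical config (including seed) gives a
#' bit-identical cohort.
#'
#' @param cfg a [SimConfig-class].
#' @return a [SimCohort-class].
#' @export
simulateCohort <- function(cfg) {
  validObject(cfg)
  nP <- as.integer(cfg@nPatients)
  if (nP == 0L)
    return(new("SimCohort", recordings = list(), truth = list(),
               outcomes = data.frame(patient = character(),
                                     ilae = integer(), engel = integer(),
                                     group = character()),
               config = cfg))
  seeds <- deriveSeeds(cfg@seed, nP)
  nEp <- max(1L, round(cfg@fracEpileptic * cfg@nChannels))
  recs <- vector("list", nP); truths <- vector("list", nP)
  poor <- seq_len(nP) %% 2L == 0L
  for (i in seq_len(nP)) {
    res <- if (poor[i] && cfg@effectOutcome > 0)
      max(1L, round(cfg@effectOutcome * nEp)) else 0L
    p <- simulatePatientCore(cfg, i, seeds[i], residualCount = res)
    recs[[i]] <- p$recording
    truths[[i]] <- p$truth
  }
  outcomes <- data.frame(
    patient = vapply(recs, function(r) r@patientId, ""),
    ilae = ifelse(poor, 4L, 1L),
    engel = ifelse(poor, 3L, 1L),
    group = ifelse(poor, "poor", "seizure_free"),
    stringsAsFactors = FALSE)
  new("SimCohort", recordings = recs, truth = truths, outcomes = outcomes,
      config = cfg)
}

#' Map contact-level truth onto bipolar pairs
#'
#' A bipolar channel is labeled epileptic when either of its contacts lies
#' in the labeled tissue (a resection including a contact removes every
#' derivation it takes part in).
#'
#' @param truth logical vector named by contact, or unnamed and aligned
#'   with `contactNames`.
#' @param pairNames bipolar names "A1-A2" as produced by
#'   [rereferenceBipolar()].
#' @param contactNames contact names aligned with `truth` when it is
#'   unnamed.
#' @return logical vector aligned with `pairNames`.
#' @export
mapTruthToBipolar <- function(truth, pairNames, contactNames = names(truth)) {
  if (is.null(contactNames))
    stopf("truth must be named by contact or contactNames supplied")
  names(truth) <- contactNames
  parts <- strsplit(pairNames, "-", fixed = TRUE)
  vapply(parts, function(p) {
    if (!all(p %in% contactNames))
      stopf("pair contacts %s missing from truth", paste(p, collapse = ","))
    any(truth[p])
  }, logical(1L))
}
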