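test_that("bad channels are dropped in place, order preserved", {
  rec <- makeRecording(10)
  expect_equal(nChannels(removeBadChannels(rec)), 10)
  rec2 <- makeRecording(10, badFlags = rep(c(TRUE, FALSE, FALSE), length.out = 10))
  out <- removeBadChannels(rec2)
  expect_equal(nChannels(out), 6)
  expect_identical(channelNames(out),
                   channelNames(rec2)[!rec2@badFlags])
  expect_error(removeBadChannels(makeRecording(3, badFlags = rep(TRUE, 3))),
               "flagged bad")
  expect_error(RecordingSegment(matrix(0, 3, 10), 500,
                                c("A1", "A2", "A3"),
                                badFlags = c(TRUE, FALSE)),
               "align")
})

test_that("bipolar montage pairs adjacent contacts within one shaft", {
  rec <- makeRecording(4)  # A1..A4
  bp <- rereferenceBipolar(rec)
  expect_identical(channelNames(bp), c("A1-A2", "A2-A3", "A3-A4"))
  expect_equal(samples(bp)[1, ], samples(rec)[1, ] - samples(rec)[2, ])

  two <- RecordingSegment(matrix(rnorm(6 * 50), 6, 50), 500,
                          c("A1", "A2", "A3", "B1", "B2", "B3"))
  bp2 <- rereferenceBipolar(two)
  expect_equal(nChannels(bp2), 4)
  expect_false(any(grepl("A.-B.", channelNames(bp2))))

  bad <- RecordingSegment(matrix(0, 2, 50), 500, c("A1", "weird!"))
  expect_error(rereferenceBipolar(bad), "weird!")
})

test_that("a removed contact breaks the pair chain unless gaps are bridged", {
  rec <- makeRecording(4, badFlags = c(FALSE, FALSE, TRUE, FALSE))  # A3 bad
  bp <- rereferenceBipolar(rec)
  expect_identical(channelNames(bp), "A1-A2")
  bp2 <- rereferenceBipolar(rec, bridgeGaps = TRUE)
  expect_identical(channelNames(bp2), c("A1-A2", "A2-A4"))
})

test_that("Fourier resampling halves length and keeps spectral peaks", {
  fs <- 2000; t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 100 * t)
  bp <- BipolarRecording(rbind(x, x), c("A1-A2", "A2-A3"), fs)
  down <- resampleRecording(bp, 1000)
  expect_equal(ncol(samples(down)), length(x) / 2)
  expect_equal(samplingRate(down), 1000)
  spec <- Mod(fft(samples(down)[1, ]))[1:1000]
  peakHz <- (which.max(spec) - 1) / 2
  expect_equal(peakHz, 100)
  expect_identical(resampleRecording(bp, 2000), bp)
  expect_error(resampleRecording(bp, 4000), "upsampling")
  expect_error(resampleRecording(bp, 300), "80 Hz band")
})

test_that("band-pass passes the band and suppresses stopband", {
  fs <- 2000; t <- seq(0, 3 - 1 / fs, by = 1 / fs)
  inband <- sin(2 * pi * 150 * t)
  stopb <- sin(2 * pi * 50 * t)
  bp <- BipolarRecording(rbind(inband, stopb), c("A1-A2", "A2-A3"), fs)
  out <- filterBand(bp, "hfo")
  mid <- seq(round(0.1 * length(t)), round(0.9 * length(t)))
  rmsIn <- sqrt(mean(out@samples[1, mid]^2))
  rmsStop <- sqrt(mean(out@samples[2, mid]^2))
  expect_lt(abs(rmsIn - sqrt(0.5)) / sqrt(0.5), 0.01)
  expect_lt(rmsStop, 0.001 * sqrt(0.5))
  zero <- BipolarRecording(matrix(0, 2, 1000), c("A1-A2", "A2-A3"), fs)
  expect_equal(max(abs(samples(filterBand(zero, "hfo")))), 0)
})

test_that("high-pass mode engages when 500 Hz exceeds Nyquist", {
  spec <- bandSpec("hfo", 1000)
  expect_identical(spec$type, "high")
  expect_identical(bandSpec("hfo", 2000)$type, "pass")
  expect_error(bandSpec(c(80, 600), 1000), "Nyquist")
  expect_identical(bandSpec("delta", 1000)[c("low", "high")],
                   list(low = 1, high = 4))
})

test_that("notch removes line harmonics and passes neighbours", {
  fs <- 2000; t <- seq(0, 3 - 1 / fs, by = 1 / fs)
  mk <- function(f) sin(2 * pi * f * t)
  bp <- BipolarRecording(rbind(mk(60), mk(180), mk(130)),
                         c("A1-A2", "A2-A3", "A3-A4"), fs)
  out <- notchPowerline(bp, 60)
  mid <- seq(round(0.1 * length(t)), round(0.9 * length(t)))
  r <- apply(out@samples[, mid], 1, function(x) sqrt(mean(x^2)))
  expect_lt(r[1], 0.05 * sqrt(0.5))
  expect_lt(r[2], 0.05 * sqrt(0.5))
  expect_lt(abs(r[3] - sqrt(0.5)) / sqrt(0.5), 0.05)
})

test_that("zero-phase filtering keeps a symmetric pulse symmetric", {
  fs <- 2000
  n <- 4000
  t <- (seq_len(n) - n / 2) / fs
  pulse <- exp(-(t / 0.004)^2) * cos(2 * pi * 150 * t)
  bp <- BipolarRecording(rbind(pulse, pulse), c("A1-A2", "A2-A3"), fs)
  for (out in list(filterBand(bp, "hfo"), notchPowerline(bp, 60))) {
    y <- samples(out)[1, ]
    expect_lt(abs(which.max(abs(y)) - n / 2), 1 + 1e-9)
    # symmetry of the response around the peak
    k <- 300
    pk <- which.max(abs(y))
    expect_lt(max(abs(y[pk + 1:k] - y[pk - 1:k])), 0.02 * max(abs(y)))
  }
})

test_that("fused band+notch matches sequential application", {
  fs <- 1000
  set.seed(5)
  bp <- BipolarRecording(matrix(rnorm(2 * 8000), 2, 8000),
                         c("A1-A2", "A2-A3"), fs)
  fused <- sfconn:::bandNotch(bp, "hfo", 60)
  seqn <- notchPowerline(filterBand(bp, "hfo"), 60)
  mid <- 1000:7000
  expect_lt(max(abs(fused@samples[, mid] - seqn@samples[, mid])),
            1e-6 * stats::sd(seqn@samples[, mid]))
})

test_that("upper envelope interpolates local maxima", {
  fs <- 2000; t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 100 * t)
  a <- 1 + 0.5 * sin(2 * pi * 1.5 * t)
  am <- a * sin(2 * pi * 100 * t)
  bp <- BipolarRecording(rbind(x, am), c("A1-A2", "A2-A3"), fs)
  env <- upperEnvelope(bp)
  mid <- seq(round(0.1 * length(t)), round(0.9 * length(t)))
  expect_lt(max(abs(env@samples[1, mid] - 1)), 0.05)
  expect_lt(max(abs(env@samples[2, mid] - a[mid]) / a[mid]), 0.05)
  # envelope equals the signal exactly at detected maxima
  pk <- sfconn:::localMaxima(x)
  expect_identical(env@samples[1, pk], x[pk])
  expect_false(any(env@flatFlags))
})

test_that("degenerate constant channel gets flat envelope and a flag", {
  bp <- BipolarRecording(rbind(rep(2, 500), sin(2 * pi * 100 * (1:500) / 2000)),
                         c("A1-A2", "A2-A3"), 2000)
  expect_warning(env <- upperEnvelope(bp), "A1-A2")
  expect_true(env@flatFlags[1])
  expect_false(env@flatFlags[2])
  expect_equal(unique(env@samples[1, ]), 2)
})

test_that("local maxima are strict, plateau-aware and endpoint-free", {
  expect_identical(sfconn:::localMaxima(c(0, 1, 0, 2, 0)), c(2L, 4L))
  expect_identical(sfconn:::localMaxima(c(0, 1, 1, 0, 3, 0)), c(2L, 5L))
  expect_identical(sfconn:::localMaxima(c(5, 1, 2)), integer(0))
  expect_identical(sfconn:::localMaxima(rep(1, 10)), integer(0))
})

test_that("epoching drops the trailing remainder and validates input", {
  fs <- 100
  bp <- BipolarRecording(matrix(rnorm(2 * 1070), 2, 1070),
                         c("A1-A2", "A2-A3"), fs)
  env <- epochEnvelope(bp, 1)
  expect_equal(dim(env@values), c(2, 10, 100))
  expect_equal(env@values[2, 3, ], samples(bp)[2, 201:300])
  expect_error(epochEnvelope(bp, 0), "positive")
  short <- BipolarRecording(matrix(rnorm(2 * 150), 2, 150),
                            c("A1-A2", "A2-A3"), fs)
  expect_error(epochEnvelope(short, 1), "at least 2")
})

test_that("full preprocessing chain produces the expected geometry", {
  cfg <- tinyConfig()
  p <- simulatePatient(cfg, 1)
  env <- preprocessRecording(p$recording, band = "hfo", lineFreq = 60)
  expect_s4_class(env, "EnvelopeEpochs")
  expect_equal(dim(env@values),
               c(6, floor(cfg@duration), round(cfg@fs)))
  expect_identical(channelNames(env)[1], "A1-A2")
})
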