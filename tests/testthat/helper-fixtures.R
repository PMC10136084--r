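# Small fixtures built in code.

# A tiny referential recording with parseable shaft names.
makeRecording <- function(nCh = 4, n = 1000, fs = 500, seed = 1,
                          badFlags = rep(FALSE, nCh), patientId = "p1") {
  set.seed(seed)
  RecordingSegment(matrix(rnorm(nCh * n), nCh, n), fs,
                   contactNamesFor(nCh), badFlags = badFlags,
                   patientId = patientId)
}

contactNamesFor <- function(nCh, perShaft = 5) {
  paste0(rep(LETTERS, each = perShaft)[seq_len(nCh)],
         rep(seq_len(perShaft), times = 26)[seq_len(nCh)])
}

# A light cohort configuration for unit tests (seconds, not minutes).
tinyConfig <- function(...) {
  args <- list(nPatients = 2, nChannels = 8, fracEpileptic = 0.25,
               fs = 400, duration = 30, eventFreqRange = c(80, 150),
               eventRateEpileptic = 2, eventRateNormal = 0.2,
               coupling = 0.9, seed = 42)
  args[names(list(...))] <- list(...)
  do.call(simConfig, args)
}

# Pooled localization AUC for a config, no bootstrap (used by the
# parameter-recovery checks).
pooledAucFor <- function(cfg) {
  cohort <- simulateCohort(cfg)
  run <- runPipeline(cohort, runConfig(bootstrapB = 0), quiet = TRUE)
  run$evaluation$pooled$all@auc
}

# Brute-force AUC oracle: fraction of (positive, negative) score pairs
# correctly ordered, ties counted one half.
pairwiseAuc <- function(scores, truth) {
  pos <- scores[truth]; neg <- scores[!truth]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Rank-then-Pearson Spearman oracle with explicit average ranks and the
# textbook Pearson sum formula.
rankPearson <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  n <- length(x)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
  num / den
}
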