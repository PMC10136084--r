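#' Resolved pipeline configuration
#'
#' Collects every tunable of [runPipeline()] into one serializable list;
#' the resolved configuration is written next to the outputs of every run.
#'
#' @param band analysis band, see [bandSpec()].
#' @param lineFreq mains frequency in Hz.
#' @param targetFs optional common resampling rate in Hz.
#' @param epochLen epoch length in seconds.
#' @param mode "sfc" (envelope-skewness connectivity) or "direct"
#'   (per-epoch Spearman on the filtered signals).
#' @param bridgeGaps see [rereferenceBipolar()].
#' @param bootstrapB bootstrap iterations for CIs (0 to skip).
#' @param seed seed for bootstrap resampling.
#' @return a named list of class `RunConfig`.
#' @export
runConfig <- function(band = "hfo", lineFreq = 60, targetFs = NULL,
                      epochLen = 1, mode = c("sfc", "direct"),
                      bridgeGaps = FALSE, bootstrapB = 1000, seed = 1) {
  structure(list(band = band, lineFreq = lineFreq, targetFs = targetFs,
                 epochLen = epochLen, mode = match.arg(mode),
                 bridgeGaps = bridgeGaps, bootstrapB = bootstrapB,
                 seed = seed),
            class = "RunConfig")
}

# One patient through preprocessing + connectivity. Returns Y (NULL in
# direct mode), Z, s, pairNames, bipolar truth, and bookkeeping counts.
processPatient <- function(rec, truth, cfg) {
  id <- rec@patientId
  if (cfg$mode == "sfc") {
    env <- preprocessRecording(rec, band = cfg$band, lineFreq = cfg$lineFreq,
                               targetFs = cfg$targetFs,
                               epochLen = cfg$epochLen,
                               bridgeGaps = cfg$bridgeGaps)
    Y <- skewnessMatrix(env)
    Z <- buildAdjacency(Y)
    nT <- dim(env@values)[2L]
    degenerate <- sum(Y@degenerateMask)
  } else {
    filt <- preprocessFiltered(rec, band = cfg$band, lineFreq = cfg$lineFreq,
                               targetFs = cfg$targetFs,
                               bridgeGaps = cfg$bridgeGaps)
    Z <- bandConnectivityDirect(filt, cfg$epochLen)
    Y <- NULL
    nT <- floor(ncol(filt@samples) / round(filt@fs * cfg$epochLen))
    degenerate <- 0L
  }
  s <- nodeStrength(Z, patientId = id)
  keep <- !rec@badFlags
  truthBp <- mapTruthToBipolar(truth[keep], Z@channelNames,
                               contactNames = rec@channelNames[keep])
  list(patientId = id, Y = Y, Z = Z, s = s, truth = truthBp,
       nEpochs = nT, nBipolar = length(Z@channelNames),
       nDegenerate = degenerate)
}

#' Run the full analysis pipeline over a cohort
#'
#' Chains preprocessing, connectivity and evaluation for every patient:
#' bad-channel removal, bipolar montage, optional resampling, zero-phase
#' band filter, power-line notch, then either envelope-skewness
#' connectivity (mode "sfc") or direct per-epoch Spearman connectivity
#' (mode "direct"), node strengths, and cohort-level evaluation (pooled
#' and individual ROC/AUC, strength ANOVA, and - when both outcome groups
#' are present - outcome classification). A patient whose processing fails
#' is reported and skipped; the run continues. Deterministic given the
#' cohort and config.
#'
#' @param input a [SimCohort-class], or a directory written by
#'   [writeCohort()].
#' @param config a [runConfig()] list.
#' @param outDir optional output directory; when given, Y/Z/strength
#'   tables, ROC points, a JSON summary, the resolved config and a
#'   manifest are written there.
#' @param quiet suppress per-patient progress messages.
#' @return list with `patients` (per-patient results), `strengths`,
#'   `truth`, `outcomes`, `evaluation`, `config`.
#' @export
runPipeline <- function(input, config = runConfig(), outDir = NULL,
                        quiet = FALSE) {
  cohort <- if (is(input, "SimCohort")) input else readCohort(input)
  nP <- length(cohort@recordings)
  if (nP == 0L) stopf("empty cohort")
  patients <- vector("list", nP)
  ok <- logical(nP)
  for (i in seq_len(nP)) {
    rec <- cohort@recordings[[i]]
    res <- tryCatch(
      processPatient(rec, cohort@truth[[i]], config),
      error = function(e) {
        warnf("patient %s failed (%s); skipping", rec@patientId,
              conditionMessage(e))
        NULL
      })
    ok[i] <- !is.null(res)
    patients[[i]] <- res
    if (!quiet && ok[i])
      message(sprintf("%s: %d bipolar channels, %d epochs, %d degenerate cells",
                      res$patientId, res$nBipolar, res$nEpochs,
                      res$nDegenerate))
  }
  patients <- patients[ok]
  if (!length(patients)) stopf("no patient could be processed")
  strengths <- lapply(patients, `[[`, "s")
  truth <- lapply(patients, `[[`, "truth")
  outcomes <- if (nrow(cohort@outcomes)) cohort@outcomes[ok, , drop = FALSE]
              else NULL
  evaluation <- evaluateCohort(strengths, truth, outcomes,
                               B = config$bootstrapB, seed = config$seed)
  out <- list(patients = patients, strengths = strengths, truth = truth,
              outcomes = outcomes, evaluation = evaluation, config = config)
  class(out) <- "SfcRun"
  if (!is.null(outDir)) writeRunOutputs(out, outDir)
  out
}

#' @export
print.SfcRun <- function(x, ...) {
  cat(sprintf("SfcRun: %d patients, mode '%s', band '%s'\n",
              length(x$patients), x$config$mode,
              paste(x$config$band, collapse = "-")))
  ev <- x$evaluation
  cat(sprintf("  pooled AUC %.3f", ev$pooled$all@auc))
  if (!is.na(ev$pooled$all@ciLow))
    cat(sprintf(" (95%% CI %.3f-%.3f)", ev$pooled$all@ciLow,
                ev$pooled$all@ciHigh))
  cat(sprintf("; individual mean AUC %.3f\n", ev$individual$mean))
  if (!is.null(ev$outcome))
    cat(sprintf("  outcome AUC %.3f (group p = %.3g)\n",
                ev$outcome$roc@auc, ev$outcome$groupP))
  invisible(x)
}

#' Cohort-level evaluation
#'
#' Pooled localization (overall and, when outcomes are supplied, per
#' outcome group), patient-specific localization, one-way ANOVA of pooled
#' normalized strengths between epileptic and non-epileptic channels, and
#' surgical outcome classification when both groups are present.
#'
#' @param strengthList,truthList per-patient strengths and bipolar truth.
#' @param outcomes optional data.frame with columns `group` (or `ilae` /
#'   `engel`) per patient.
#' @param B bootstrap iterations.
#' @param seed bootstrap seed.
#' @return list with `pooled` (RocResult per group), `individual`,
#'   `anova`, `outcome` (or NULL).
#' @export
evaluateCohort <- function(strengthList, truthList, outcomes = NULL,
                           B = 1000, seed = 1) {
  pooled <- list(all = pooledLocalization(strengthList, truthList,
                                          B = B, seed = seed))
  outcome <- NULL
  if (!is.null(outcomes)) {
    grp <- if ("group" %in% names(outcomes)) as.character(outcomes$group)
           else outcomeGroup(outcomes$ilae, outcomes$engel)
    for (g in unique(grp)) {
      sel <- grp == g
      pooled[[g]] <- pooledLocalization(strengthList[sel], truthList[sel],
                                        B = B, seed = seed)
    }
    if (length(unique(grp)) == 2L)
      outcome <- outcomeClassification(strengthList, truthList, grp,
                                       B = B, seed = seed)
  }
  normAll <- unlist(lapply(strengthList,
                           function(s) normalizeStrengths(asStrengthNumeric(s))))
  truthAll <- unlist(lapply(truthList, as.logical))
  an <- strengthAnova(normAll,
                      ifelse(truthAll, "epileptic", "non_epileptic"))
  list(pooled = pooled,
       individual = individualLocalization(strengthList, truthList),
       anova = an, outcome = outcome)
}
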