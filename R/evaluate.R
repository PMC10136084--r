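asStrengthNumeric <- function(s) {
  if (is(s, "StrengthVector")) s@s else as.numeric(s)
}

#' Threshold a strength vector
#'
#' Channels whose strength strictly exceeds the threshold are labeled
#' epileptic; ties at the threshold fall to non-epileptic.
#'
#' @param s a [StrengthVector-class] or numeric vector.
#' @param threshold scalar.
#' @return logical vector.
#' @export
classifyChannels <- function(s, threshold) {
  asStrengthNumeric(s) > threshold
}

#' Confusion counts and rates
#'
#' @param pred,truth logical vectors of equal length; rates require at
#'   least one positive and one negative in `truth`.
#' @return list with TP, TN, FP, FN, sensitivity, specificity, fpr
#'   (fpr = 1 - specificity).
#' @export
confusionRates <- function(pred, truth) {
  if (length(pred) != length(truth))
    stopf("pred and truth lengths differ (%d vs %d)",
          length(pred), length(truth))
  pred <- as.logical(pred); truth <- as.logical(truth)
  if (!any(truth) || all(truth))
    stopf("rates undefined: truth needs both a positive and a negative")
  TP <- sum(pred & truth); FN <- sum(!pred & truth)
  FP <- sum(pred & !truth); TN <- sum(!pred & !truth)
  sens <- TP / (TP + FN)
  spec <- TN / (TN + FP)
  list(TP = TP, TN = TN, FP = FP, FN = FN,
       sensitivity = sens, specificity = spec, fpr = 1 - spec)
}

#' Per-patient strength normalization
#'
#' Subtracts the mean, then min-max rescales to \[0, 1\], removing the
#' influence of channel count and inter-patient baseline connectivity
#' level before strengths are pooled across patients. Affine-invariant:
#' a*s + b (a > 0) maps to the same output.
#'
#' @param s a [StrengthVector-class] or numeric vector (length >= 2,
#'   not constant).
#' @return same type as the input, normalized.
#' @export
normalizeStrengths <- function(s) {
  v <- asStrengthNumeric(s)
  if (length(v) < 2L) stopf("need at least 2 channels to normalize")
  if (max(v) == min(v))
    stopf("constant strength vector cannot be normalized")
  v <- v - mean(v)
  v <- (v - min(v)) / (max(v) - min(v))
  if (is(s, "StrengthVector"))
    new("StrengthVector", s = stats::setNames(v, names(s@s)),
        patientId = s@patientId)
  else v
}

#' Empirical ROC curve and AUC
#'
#' Sweeps thresholds over the unique score values (plus +/-Inf endpoints,
#' so the curve always passes through (0,0) and (1,1)); a score counts as
#' positive when it strictly exceeds the threshold. AUC is the trapezoidal
#' area, which equals the fraction of (positive, negative) score pairs
#' correctly ordered with ties credited one half (the normalized
#' Mann-Whitney U).
#'
#' @param scores numeric vector.
#' @param truth logical vector with at least one TRUE and one FALSE.
#' @return a [RocResult-class].
#' @export
rocAuc <- function(scores, truth) {
  truth <- as.logical(truth)
  if (length(scores) != length(truth))
    stopf("scores and truth lengths differ")
  P <- sum(truth); N <- sum(!truth)
  if (P == 0L || N == 0L)
    stopf("ROC needs both classes (got %d positives, %d negatives)", P, N)
  u <- sort(unique(scores), decreasing = TRUE)
  posAt <- vapply(u, function(v) sum(truth & scores == v), numeric(1))
  negAt <- vapply(u, function(v) sum(!truth & scores == v), numeric(1))
  sens <- c(0, cumsum(posAt) / P)
  fpr <- c(0, cumsum(negAt) / N)
  thr <- c(Inf, u)
  # final (1,1) point at threshold -Inf (strict ">" leaves min-score ties out)
  if (sens[length(sens)] < 1 || fpr[length(fpr)] < 1) {
    sens <- c(sens, 1); fpr <- c(fpr, 1); thr <- c(thr, -Inf)
  } else thr[length(thr)] <- -Inf
  auc <- sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
  new("RocResult", thresholds = thr, sensitivity = sens, fpr = fpr,
      auc = auc, ciLow = NA_real_, ciHigh = NA_real_,
      nPos = as.integer(P), nNeg = as.integer(N))
}

#' Bootstrap confidence interval for an AUC
#'
#' Resamples observations with replacement B times, recomputes the AUC,
#' and returns the 2.5/97.5 percentiles. A resample missing one class is
#' redrawn (up to 100 retries) and skipped if still degenerate.
#' Deterministic given `seed`.
#'
#' @param scores,truth as in [rocAuc()].
#' @param B bootstrap iterations (default 1000).
#' @param seed RNG seed for the resampling.
#' @return numeric c(low, high).
#' @export
bootstrapAucCI <- function(scores, truth, B = 1000, seed = 1) {
  truth <- as.logical(truth)
  n <- length(scores)
  withSeed(seed, {
    aucs <- rep(NA_real_, B)
    for (b in seq_len(B)) {
      for (tryIdx in seq_len(100L)) {
        idx <- sample.int(n, n, replace = TRUE)
        if (any(truth[idx]) && any(!truth[idx])) {
          aucs[b] <- rocAuc(scores[idx], truth[idx])@auc
          break
        }
      }
    }
    aucs <- aucs[!is.na(aucs)]
    stats::quantile(aucs, c(0.025, 0.975), names = FALSE)
  })
}

#' Pooled channel-level localization
#'
#' Normalizes each patient's strengths ([normalizeStrengths()]),
#' concatenates strengths and truth labels across patients, and computes a
#' single ROC/AUC with a bootstrap CI (resampling channels, the pooled
#' unit).
#'
#' @param strengthList list of [StrengthVector-class] or numeric vectors.
#' @param truthList list of logical vectors aligned with the strengths.
#' @param B bootstrap iterations (0 skips the CI).
#' @param seed bootstrap seed.
#' @return a [RocResult-class].
#' @export
pooledLocalization <- function(strengthList, truthList, B = 1000, seed = 1) {
  if (length(strengthList) == 0L) stopf("empty patient group")
  if (length(strengthList) != length(truthList))
    stopf("strengths and truths must pair up")
  scores <- unlist(lapply(strengthList,
                          function(s) normalizeStrengths(asStrengthNumeric(s))))
  truth <- unlist(lapply(truthList, as.logical))
  roc <- rocAuc(scores, truth)
  if (B > 0) {
    ci <- bootstrapAucCI(scores, truth, B = B, seed = seed)
    roc@ciLow <- ci[1L]; roc@ciHigh <- ci[2L]
  }
  roc
}

#' Patient-specific localization
#'
#' Computes each patient's own AUC on the normalized strengths, the group
#' mean, and a t-based 95% CI (mean +/- t[0.975, k-1] * SE). Patients with
#' a single truth class are excluded with a warning.
#'
#' @inheritParams pooledLocalization
#' @return list with `aucs`, `mean`, `ciLow`, `ciHigh`, `excluded`.
#' @export
individualLocalization <- function(strengthList, truthList) {
  if (length(strengthList) == 0L) stopf("empty patient group")
  aucs <- numeric(0); excluded <- character(0)
  for (i in seq_along(strengthList)) {
    tr <- as.logical(truthList[[i]])
    id <- if (is(strengthList[[i]], "StrengthVector"))
      strengthList[[i]]@patientId else as.character(i)
    if (!any(tr) || all(tr)) {
      excluded <- c(excluded, id)
      next
    }
    s <- normalizeStrengths(asStrengthNumeric(strengthList[[i]]))
    aucs <- c(aucs, rocAuc(s, tr)@auc)
  }
  if (length(excluded))
    warnf("patient(s) with a single label class excluded: %s",
          paste(excluded, collapse = ", "))
  if (!length(aucs)) stopf("no patient with both label classes")
  k <- length(aucs)
  m <- mean(aucs)
  half <- if (k > 1L) stats::qt(0.975, k - 1L) * stats::sd(aucs) / sqrt(k)
          else NA_real_
  list(aucs = aucs, mean = m, ciLow = m - half, ciHigh = m + half,
       excluded = excluded)
}

#' Outcome score for one patient
#'
#' Minus the mean normalized connectivity strength over channels outside
#' the labeled epileptic tissue. Residual epileptic network outside the
#' treated zone raises the outside mean, so higher (less negative) scores
#' predict seizure freedom.
#'
#' @param sNorm normalized strengths ([StrengthVector-class] or numeric).
#' @param truth logical epileptic labels aligned with the strengths.
#' @return scalar score.
#' @export
outcomeScore <- function(sNorm, truth) {
  v <- asStrengthNumeric(sNorm)
  truth <- as.logical(truth)
  if (length(v) != length(truth)) stopf("strengths and truth must align")
  if (all(truth)) stopf("no non-epileptic channel: outcome score undefined")
  -mean(v[!truth])
}

#' Surgical outcome classification
#'
#' Computes each patient's outcome score (normalizing strengths first) and
#' evaluates how well the score separates seizure-free from poor-outcome
#' patients (positive class = seizure-free), with a patient-level
#' bootstrap CI.
#'
#' @param strengthList,truthList per-patient strengths and channel truths.
#' @param groups character vector "seizure_free"/"poor" per patient.
#' @param B bootstrap iterations (0 skips the CI).
#' @param seed bootstrap seed.
#' @return list with `scores`, `roc` ([RocResult-class]), and `groupP`
#'   (one-way ANOVA p-value for the score difference between groups).
#' @export
outcomeClassification <- function(strengthList, truthList, groups,
                                  B = 1000, seed = 1) {
  groups <- as.character(groups)
  if (!all(groups %in% c("seizure_free", "poor")))
    stopf("groups must be 'seizure_free' or 'poor'")
  if (length(unique(groups)) < 2L)
    stopf("both outcome groups must be present")
  scores <- mapply(function(s, tr)
    outcomeScore(normalizeStrengths(asStrengthNumeric(s)), tr),
    strengthList, truthList)
  isFree <- groups == "seizure_free"
  roc <- rocAuc(scores, isFree)
  if (B > 0) {
    ci <- bootstrapAucCI(scores, isFree, B = B, seed = seed)
    roc@ciLow <- ci[1L]; roc@ciHigh <- ci[2L]
  }
  groupP <- if (min(table(isFree)) >= 2L)
    strengthAnova(scores, ifelse(isFree, "seizure_free", "poor"))$p
  else NA_real_
  list(scores = scores, roc = roc, groupP = groupP)
}

#' Group outcome labels from clinical scales
#'
#' Seizure-free iff ILAE class 1-2 or Engel class 1; poor iff ILAE 3-6 or
#' Engel 2-4. A patient meeting the seizure-free rule on either scale is
#' seizure-free.
#'
#' @param ilae ILAE classes 1-6 (NA when absent).
#' @param engel Engel classes 1-4 (NA when absent).
#' @return character vector "seizure_free"/"poor".
#' @export
outcomeGroup <- function(ilae = NA, engel = NA) {
  n <- max(length(ilae), length(engel))
  ilae <- rep_len(ilae, n); engel <- rep_len(engel, n)
  if (any(is.na(ilae) & is.na(engel)))
    stopf("each patient needs at least one outcome scale")
  free <- (!is.na(ilae) & ilae %in% 1:2) | (!is.na(engel) & engel == 1)
  ifelse(free, "seizure_free", "poor")
}

#' One-way ANOVA on connectivity strengths
#'
#' Tests the mean difference of values between groups (classical equal-
#' variance one-way F test; two-sided alpha 0.05 convention).
#'
#' @param values numeric vector.
#' @param labels group labels (>= 2 groups, each with >= 2 values).
#' @return list with `F`, `p`, `dfBetween`, `dfWithin`.
#' @export
strengthAnova <- function(values, labels) {
  labels <- factor(labels)
  if (nlevels(labels) < 2L) stopf("need at least 2 groups")
  if (any(table(labels) < 2L)) stopf("each group needs at least 2 values")
  ft <- stats::oneway.test(values ~ labels, var.equal = TRUE)
  list(F = unname(ft$statistic), p = ft$p.value,
       dfBetween = unname(ft$parameter[1L]),
       dfWithin = unname(ft$parameter[2L]))
}

#' Cohen's d for paired AUCs
#'
#' Effect size between two sets of patient-wise AUCs. The default paired
#' form is mean(a - b) / sd(a - b) with the sample (k-1) SD; zero spread of
#' the differences yields +/-Inf with a warning. `method = "pooled"` uses
#' the two-sample pooled-SD form instead.
#'
#' @param a,b numeric vectors, paired by patient (equal length for
#'   "paired").
#' @param method "paired" (default) or "pooled".
#' @return scalar effect size.
#' @export
cohensD <- function(a, b, method = c("paired", "pooled")) {
  method <- match.arg(method)
  if (method == "paired") {
    if (length(a) != length(b)) stopf("paired vectors must align")
    d <- a - b
    s <- stats::sd(d)
    if (s == 0) {
      if (mean(d) == 0) return(0)
      warnf("zero spread of paired differences: infinite effect size")
      return(sign(mean(d)) * Inf)
    }
    mean(d) / s
  } else {
    na <- length(a); nb <- length(b)
    sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
                 (na + nb - 2))
    if (sp == 0) {
      if (mean(a) == mean(b)) return(0)
      warnf("zero pooled spread: infinite effect size")
      return(sign(mean(a) - mean(b)) * Inf)
    }
    (mean(a) - mean(b)) / sp
  }
}
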