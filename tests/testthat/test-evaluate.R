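test_that("channel classification uses a strict threshold", {
  s <- c(a = 0.7, b = 0.6, c = 0.3)
  expect_identical(unname(classifyChannels(s, 0.5)), c(TRUE, TRUE, FALSE))
  expect_false(any(classifyChannels(s, 0.7)))   # ties fall to non-epileptic
  expect_true(all(classifyChannels(s, -Inf)))
})

test_that("confusion rates follow the standard definitions", {
  r <- confusionRates(c(TRUE, FALSE, TRUE, FALSE), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(r[c("sensitivity", "specificity", "fpr")],
               list(sensitivity = 1, specificity = 1, fpr = 0))
  r2 <- confusionRates(rep(TRUE, 4), c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(r2$sensitivity, 1); expect_equal(r2$fpr, 1)
  r3 <- confusionRates(c(TRUE, FALSE, FALSE, TRUE), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r3[c("TP", "FN", "FP", "TN")],
               list(TP = 1, FN = 1, FP = 1, TN = 1))
  expect_equal(r3$sensitivity, 0.5); expect_equal(r3$fpr, 0.5)
  expect_equal(r3$fpr, 1 - r3$specificity)
  expect_error(confusionRates(c(TRUE, TRUE), c(TRUE, TRUE)), "undefined")
  expect_error(confusionRates(TRUE, c(TRUE, FALSE)), "differ")
})

test_that("strength normalization mean-centres then min-max rescales", {
  expect_equal(normalizeStrengths(c(1, 2, 3)), c(0, 0.5, 1))
  s <- runif(20)
  expect_equal(normalizeStrengths(3.2 * s + 40), normalizeStrengths(s),
               tolerance = 1e-12)
  expect_error(normalizeStrengths(c(5, 5)), "constant")
  expect_error(normalizeStrengths(4), "at least 2")
  sv <- nodeStrength(matrix(c(0, .5, .2, .5, 0, .1, .2, .1, 0), 3, 3))
  nv <- normalizeStrengths(sv)
  expect_s4_class(nv, "StrengthVector")
  expect_equal(unname(strengths(nv)), c(1, 0.75, 0))
})

test_that("ROC endpoints, monotonicity and worked AUCs are right", {
  r <- rocAuc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r@auc, 1)
  expect_equal(c(r@fpr[1], r@sensitivity[1]), c(0, 0))
  expect_equal(c(r@fpr[length(r@fpr)], r@sensitivity[length(r@sensitivity)]),
               c(1, 1))
  expect_true(all(diff(r@sensitivity) >= 0) && all(diff(r@fpr) >= 0))
  expect_equal(rocAuc(c(0.9, 0.4, 0.6, 0.1), c(TRUE, FALSE, TRUE, FALSE))@auc, 1)
  expect_equal(rocAuc(c(0.9, 0.4, 0.6, 0.1), c(TRUE, TRUE, FALSE, FALSE))@auc, 0.75)
  expect_error(rocAuc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("AUC equals the ordered-pair fraction and pROC agrees", {
  set.seed(31)
  for (i in 1:60) {
    n <- sample(8:40, 1)
    sc <- sample(round(rnorm(n), 1))    # ties on purpose
    tr <- rnorm(n) + (sc > 0) > 0.3
    if (!any(tr) || all(tr)) next
    expect_equal(rocAuc(sc, tr)@auc, pairwiseAuc(sc, tr), tolerance = 1e-12)
  }
  skip_if_not_installed("pROC")
  set.seed(32)
  sc <- rnorm(60); tr <- rep(c(TRUE, FALSE), 30)
  expect_equal(rocAuc(sc, tr)@auc,
               as.numeric(pROC::auc(pROC::roc(tr, sc, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("shuffled labels give chance-level AUC", {
  set.seed(33)
  sc <- rnorm(2000)
  tr <- sample(rep(c(TRUE, FALSE), 1000))
  expect_lt(abs(rocAuc(sc, tr)@auc - 0.5), 0.05)
  # null distribution of shuffle AUCs is centred on one half
  sc2 <- rnorm(200); tr2 <- rep(c(TRUE, FALSE), 100)
  aucs <- replicate(1000, rocAuc(sc2, sample(tr2))@auc)
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})

test_that("bootstrap CI is deterministic, sane and brackets the estimate", {
  sc <- c(rnorm(30, 2), rnorm(30))
  tr <- rep(c(TRUE, FALSE), each = 30)
  ci <- bootstrapAucCI(sc, tr, B = 300, seed = 9)
  expect_identical(ci, bootstrapAucCI(sc, tr, B = 300, seed = 9))
  auc <- rocAuc(sc, tr)@auc
  expect_true(ci[1] <= auc && auc <= ci[2])
  perfect <- bootstrapAucCI(c(5, 6, 7, 1, 2, 3),
                            rep(c(TRUE, FALSE), each = 3), B = 100, seed = 1)
  expect_equal(perfect, c(1, 1))
})

test_that("pooled localization with one patient reduces to its own ROC", {
  set.seed(41)
  s <- runif(12); tr <- rep(c(TRUE, FALSE), 6)
  pooled <- pooledLocalization(list(s), list(tr), B = 0)
  expect_equal(pooled@auc, rocAuc(normalizeStrengths(s), tr)@auc)
  expect_error(pooledLocalization(list(), list()), "empty")
})

test_that("individual localization gives t-based confidence intervals", {
  s1 <- c(3, 2, 1); t1 <- c(TRUE, FALSE, FALSE)
  ind <- individualLocalization(list(s1, s1 * 2), list(t1, t1))
  expect_equal(ind$aucs, c(1, 1))
  expect_equal(ind$ciLow, 1); expect_equal(ind$ciHigh, 1)
  # closed-form t interval for two patients with AUCs 0.6 and 0.8
  mkScores <- function(auc) {
    # 1 positive vs 5 negatives: AUC = rank fraction
    c(pos = auc * 5 + 0.5, neg = 1:5)
  }
  sA <- c(3.5, 1:5); trA <- c(TRUE, rep(FALSE, 5))   # AUC 0.6
  sB <- c(4.5, 1:5)                                  # AUC 0.8
  ind2 <- individualLocalization(list(sA, sB), list(trA, trA))
  expect_equal(ind2$mean, 0.7)
  half <- qt(0.975, 1) * sd(c(0.6, 0.8)) / sqrt(2)
  expect_equal(ind2$ciLow, 0.7 - half, tolerance = 1e-12)
  expect_error(individualLocalization(list(), list()), "empty")
  expect_warning(
    ind3 <- individualLocalization(list(sA, c(1, 2)), list(trA, c(TRUE, TRUE))),
    "excluded")
  expect_length(ind3$aucs, 1)
})

test_that("outcome score is minus the mean outside strength", {
  expect_equal(outcomeScore(c(0.9, 0.1, 0.3), c(TRUE, FALSE, FALSE)), -0.2)
  expect_equal(outcomeScore(c(1, 0, 0), c(TRUE, FALSE, FALSE)), 0)
  expect_error(outcomeScore(c(1, 1), c(TRUE, TRUE)), "non-epileptic")
})

test_that("outcome grouping follows the either-scale seizure-free rule", {
  expect_identical(outcomeGroup(ilae = c(1, 2, 3, 6), engel = NA),
                   c("seizure_free", "seizure_free", "poor", "poor"))
  expect_identical(outcomeGroup(ilae = NA, engel = c(1, 2, 4)),
                   c("seizure_free", "poor", "poor"))
  expect_identical(outcomeGroup(ilae = 1, engel = 2), "seizure_free")
  expect_error(outcomeGroup(ilae = NA, engel = NA), "at least one")
})

test_that("outcome classification separates groups it should separate", {
  set.seed(51)
  mkPatient <- function(outsideHigh) {
    s <- runif(10, 0, 0.3)
    s[1:2] <- c(2, 1.8)                       # labeled epileptic channels
    if (outsideHigh) s[9:10] <- c(1.7, 1.6)   # residual outside tissue
    list(s = s, tr = c(TRUE, TRUE, rep(FALSE, 8)))
  }
  pats <- c(lapply(1:6, function(i) mkPatient(FALSE)),
            lapply(1:6, function(i) mkPatient(TRUE)))
  res <- outcomeClassification(lapply(pats, `[[`, "s"),
                               lapply(pats, `[[`, "tr"),
                               rep(c("seizure_free", "poor"), each = 6),
                               B = 100, seed = 2)
  expect_gt(res$roc@auc, 0.9)
  expect_lt(res$groupP, 0.01)
  expect_error(outcomeClassification(lapply(pats, `[[`, "s"),
                                     lapply(pats, `[[`, "tr"),
                                     rep("poor", 12)), "both outcome")
})

test_that("one-way ANOVA and Cohen's d match hand computations", {
  an <- strengthAnova(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(an$F, 13.5, tolerance = 1e-12)
  expect_equal(an$p, 1 - pf(13.5, 1, 4), tolerance = 1e-12)
  same <- strengthAnova(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)
  set.seed(6)
  sep <- strengthAnova(c(rnorm(5, 0, 1e-4), 1 + rnorm(5, 0, 1e-4)),
                       rep(c("a", "b"), each = 5))
  expect_lt(sep$p, 0.001)
  expect_error(strengthAnova(1:3, c("a", "a", "b")), "at least 2")

  expect_equal(cohensD(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cohensD(c(0.8, 0.6, 0.7, 0.6), c(0.6, 0.6, 0.6, 0.5)),
               0.1 / sd(c(0.2, 0, 0.1, 0.1)), tolerance = 1e-12)
  expect_equal(cohensD(c(0.8, 0.6, 0.7, 0.6), c(0.6, 0.6, 0.6, 0.5)),
               1.224745, tolerance = 1e-6)
  expect_warning(d <- cohensD(c(1, 1, 1), c(0.9, 0.9, 0.9)), "infinite")
  expect_identical(d, Inf)
  expect_equal(cohensD(c(1, 2, 3), c(4, 5, 6), method = "pooled"), -3)
})
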