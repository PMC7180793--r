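# tiny linearly separable cohort: class A near 0, class B near 1
separableFeatures <- function(n = 6, p = 4, gap = 1, seed = 51) {
  withr::with_seed(seed, {
    half <- n %/% 2
    m <- rbind(matrix(rnorm(half * p, 0, 0.05), half),
               matrix(rnorm((n - half) * p, gap, 0.05), n - half))
    FeatureMatrix(m, labels = rep(c("HC", "PD"), c(half, n - half)))
  })
}

test_that("every classifier separates a separable toy cohort under LOO", {
  fm <- separableFeatures()
  for (cls in c("NB", "DT", "RF", "KNN")) {
    res <- looScores(fm, classifier = cls, positive = "HC", seed = 1)
    expect_equal(nrow(res), 6L)
    expect_equal(res$predicted, res$label, label = cls)
  }
})

test_that("identical features carry no information into KNN scores", {
  fm <- FeatureMatrix(matrix(1, 6, 3), labels = rep(c("HC", "PD"), 3))
  res <- looScores(fm, classifier = "KNN", positive = "HC")
  # every training point ties, so each fold's score is the training
  # positive fraction: identical within each held-out class
  expect_length(unique(res$score[res$label == "HC"]), 1L)
  expect_length(unique(res$score[res$label == "PD"]), 1L)
})

test_that("LOO scores are deterministic given the seed, random forest included", {
  fm <- separableFeatures(n = 8, gap = 0.3)
  a <- looScores(fm, classifier = "RF", positive = "HC", seed = 7)
  b <- looScores(fm, classifier = "RF", positive = "HC", seed = 7)
  expect_identical(a, b)
})

test_that("single-class cohorts are rejected", {
  fm <- FeatureMatrix(matrix(rnorm(12), 4), labels = rep("HC", 4))
  expect_error(looScores(fm), "two classes")
})

test_that("metrics reproduce the published worked-example triples", {
  m <- classificationMetrics(c(TP = 13, FN = 3, FP = 2, TN = 11))
  expect_equal(unname(m), c(82.76, 81.25, 84.62))
  m <- classificationMetrics(c(TP = 14, FN = 2, FP = 1, TN = 19))
  expect_equal(unname(m), c(91.67, 87.50, 95.00))
  m <- classificationMetrics(c(TP = 16, FN = 0, FP = 0, TN = 13))
  expect_equal(unname(m), c(100, 100, 100))
})

test_that("zero denominators flag metrics as undefined", {
  expect_warning(m <- classificationMetrics(c(TP = 0, FN = 0, FP = 1,
                                              TN = 3)),
                 "sensitivity")
  expect_true(is.na(m[["sensitivity"]]))
  expect_false(is.na(m[["specificity"]]))
})

test_that("AUC is the rank statistic with ties counted one half", {
  expect_equal(aucScore(c(0.9, 0.8, 0.2, 0.1), c("p", "p", "n", "n"), "p"), 1)
  expect_equal(aucScore(rep(0.5, 6), rep(c("p", "n"), 3), "p"), 0.5)
  expect_equal(aucScore(c(0.9, 0.8, 0.3, 0.1), c("p", "n", "p", "n"), "p"),
               0.75)
  expect_error(aucScore(1:3, rep("p", 3), "p"), "both classes")
})

test_that("AUC matches pROC and is invariant to monotone transforms", {
  withr::local_seed(52)
  for (rep in 1:10) {
    scores <- runif(20)
    labels <- sample(rep(c("p", "n"), 10))
    a <- aucScore(scores, labels, "p")
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = labels, predictor = scores, levels = c("n", "p"),
      direction = "<", quiet = TRUE)))
    expect_equal(a, ref, tolerance = 1e-12)
    expect_equal(aucScore(qlogis(scores), labels, "p"), a)
    expect_equal(aucScore(scores, labels, "n"), 1 - a)
  }
})

test_that("swapping class roles swaps sensitivity and specificity", {
  predicted <- c("HC", "HC", "PD", "PD", "HC", "PD")
  label <- c("HC", "PD", "PD", "HC", "HC", "PD")
  mA <- classificationMetrics(confusionCounts(predicted, label, "HC"))
  mB <- classificationMetrics(confusionCounts(predicted, label, "PD"))
  expect_equal(mA[["sensitivity"]], mB[["specificity"]])
  expect_equal(mA[["specificity"]], mB[["sensitivity"]])
  expect_equal(mA[["accuracy"]], mB[["accuracy"]])
})

test_that("runExperiment covers the (tau, classifier) grid and counts add up", {
  p <- defaultProfiles()
  A <- lapply(1:4, function(i) generateSubject(p$HC, seed = 100 + i))
  B <- lapply(1:4, function(i) generateSubject(p$PD, seed = 200 + i))
  res <- runExperiment(A, B, tauGrid = c(5, 6), classifiers = c("NB", "KNN"),
                       m = 25, seed = 3)
  expect_equal(nrow(res), 4L)
  expect_setequal(res$tau, c(5, 6))
  expect_setequal(res$classifier, c("NB", "KNN"))
  expect_true(all(res$TP + res$FN == 4))
  expect_true(all(res$TN + res$FP == 4))
  expect_true(!is.unsorted(rev(res$auc)))
  expect_true(all(res$auc >= 0 & res$auc <= 1))

  one <- runExperiment(A, B, tauGrid = 5, classifiers = "KNN", m = 25,
                       seed = 3)
  expect_equal(nrow(one), 1L)
})

test_that("cohorts sharing a subject are rejected", {
  p <- defaultProfiles()
  A <- lapply(1:2, function(i) generateSubject(p$HC, seed = i))
  expect_error(runExperiment(A, A), "disjoint")
})
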