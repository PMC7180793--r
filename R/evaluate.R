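.CLASSIFIERS <- c("NB", "DT", "RF", "KNN")

# Hyperparameters of the four classifiers: decision-tree depth 5, 1200
# random-forest trees, 3 nearest neighbours; NB is Gaussian.
.defaultHyper <- function() list(maxDepth = 5L, nTrees = 1200L,
                                 nNeighbors = 3L)

# Train on (train, trainLabels), return positive-class scores for `test`.
# Scores are probability estimates: NB posterior, DT leaf class fraction,
# RF mean tree vote, KNN neighbour fraction. Deterministic given `seed`.
.fitPredict <- function(train, trainLabels, test, kind, positive,
                        seed = 42, hyper = .defaultHyper()) {
  kind <- match.arg(kind, .CLASSIFIERS)
  trainLabels <- factor(trainLabels)
  if (is.null(dim(test))) test <- matrix(test, nrow = 1L)
  if (kind == "NB") {
    # Gaussian NB cannot use zero-variance features; drop them
    keep <- apply(train, 2L, function(v) stats::sd(v) > 1e-12)
    if (!any(keep)) return(rep(mean(trainLabels == positive), nrow(test)))
    fit <- e1071::naiveBayes(train[, keep, drop = FALSE], trainLabels)
    pr <- stats::predict(fit, test[, keep, drop = FALSE], type = "raw")
    return(unname(pr[, positive]))
  }
  if (kind == "DT") {
    df <- data.frame(train)
    df$.y <- trainLabels
    fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                        control = rpart::rpart.control(
                          maxdepth = hyper$maxDepth, minsplit = 2L,
                          minbucket = 1L, cp = 0, xval = 0L))
    newdf <- data.frame(test)
    names(newdf) <- names(df)[seq_len(ncol(test))]
    pr <- stats::predict(fit, newdf, type = "prob")
    return(unname(pr[, positive]))
  }
  if (kind == "RF") {
    fit <- withSeed(seed,
      randomForest::randomForest(train, trainLabels, ntree = hyper$nTrees))
    pr <- stats::predict(fit, test, type = "prob")
    return(unname(pr[, positive]))
  }
  # KNN: fraction of positive labels among the 3 nearest training points
  # (Euclidean); all points tied at the k-th distance are included
  vapply(seq_len(nrow(test)), function(i) {
    d <- sqrt(colSums((t(train) - test[i, ])^2))
    k <- min(hyper$nNeighbors, length(d))
    kth <- sort(d)[k]
    nn <- which(d <= kth + 1e-12)
    mean(trainLabels[nn] == positive)
  }, numeric(1))
}

#' Leave-one-out cross-validated classification scores
#'
#' For each subject, trains the chosen classifier on all other subjects and
#' predicts the held-out one, so every subject is predicted exactly once.
#' Scores are positive-class probability estimates (NB posterior, decision
#' tree leaf class fraction, random forest mean tree vote, KNN neighbour
#' fraction); the predicted label is the positive class when the score is
#' at least 0.5. Deterministic given the seed.
#'
#' @param features a \linkS4class{FeatureMatrix} (at least two subjects per
#'   class).
#' @param classifier one of \code{"NB"}, \code{"DT"}, \code{"RF"},
#'   \code{"KNN"}.
#' @param positive label of the positive class; default the first factor
#'   level.
#' @param seed integer seed (random forest refitting).
#' @param hyper hyperparameter list, see details in
#'   \code{\link{runExperiment}}.
#' @return data.frame with one row per subject: \code{subject},
#'   \code{label}, \code{score}, \code{predicted}.
#' @export
looScores <- function(features, classifier = "NB",
                      positive = levels(featureLabels(features))[1L],
                      seed = 42, hyper = .defaultHyper()) {
  stopifnot(is(features, "FeatureMatrix"))
  x <- featureValues(features)
  y <- featureLabels(features)
  if (nlevels(droplevels(y)) < 2L)
    stop("leave-one-out classification needs two classes")
  n <- base::nrow(x)
  scores <- vapply(seq_len(n), function(i) {
    .fitPredict(x[-i, , drop = FALSE], droplevels(y[-i]),
                x[i, , drop = FALSE], classifier, positive,
                seed = seed + i, hyper = hyper)
  }, numeric(1))
  negative <- setdiff(levels(droplevels(y)), positive)[1L]
  data.frame(subject = if (is.null(rownames(x))) as.character(seq_len(n))
                       else rownames(x),
             label = as.character(y),
             score = scores,
             predicted = ifelse(scores >= 0.5, positive, negative),
             stringsAsFactors = FALSE)
}

#' Confusion matrix of predicted vs true labels
#'
#' @param predicted,label character vectors of predicted and true labels.
#' @param positive label counted as positive.
#' @return named numeric vector with components \code{TP}, \code{FN},
#'   \code{FP}, \code{TN}.
#' @export
confusionCounts <- function(predicted, label, positive) {
  c(TP = sum(label == positive & predicted == positive),
    FN = sum(label == positive & predicted != positive),
    FP = sum(label != positive & predicted == positive),
    TN = sum(label != positive & predicted != positive))
}

#' Accuracy, sensitivity and specificity of a confusion matrix
#'
#' accuracy = (TP+TN)/(TP+FP+TN+FN); sensitivity = TP/(TP+FN);
#' specificity = TN/(FP+TN). Reported as percentages rounded to two
#' decimals. A zero denominator yields \code{NA} with a warning rather
#' than a silent zero.
#'
#' @param cm named vector with components \code{TP}, \code{FN}, \code{FP},
#'   \code{TN} (as from \code{\link{confusionCounts}}).
#' @return named numeric vector \code{accuracy}, \code{sensitivity},
#'   \code{specificity}, in percent.
#' @examples
#' classificationMetrics(c(TP = 13, FN = 3, FP = 2, TN = 11))
#' @export
classificationMetrics <- function(cm) {
  cm <- cm[c("TP", "FN", "FP", "TN")]
  if (anyNA(cm)) stop("confusion matrix needs TP, FN, FP, TN")
  total <- sum(cm)
  pos <- cm[["TP"]] + cm[["FN"]]
  neg <- cm[["FP"]] + cm[["TN"]]
  safe <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined: zero denominator")
      return(NA_real_)
    }
    round(100 * num / den, 2L)
  }
  c(accuracy = safe(cm[["TP"]] + cm[["TN"]], total, "accuracy"),
    sensitivity = safe(cm[["TP"]], pos, "sensitivity"),
    specificity = safe(cm[["TN"]], neg, "specificity"))
}

#' Area under the ROC curve from pooled scores
#'
#' Rank-based AUC: the probability that a randomly chosen positive subject
#' scores higher than a randomly chosen negative one, with ties counted as
#' one half (equivalent to the Wilcoxon statistic). 1 is a perfect test,
#' 0.5 a random guess.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels class labels, same length.
#' @param positive label counted as positive.
#' @return AUC in [0, 1].
#' @export
aucScore <- function(scores, labels, positive) {
  pos <- labels == positive
  nPos <- sum(pos); nNeg <- sum(!pos)
  if (nPos == 0L || nNeg == 0L)
    stop("AUC needs both classes present")
  r <- rank(scores)
  (sum(r[pos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Run the full topological classification experiment
#'
#' Executes the whole pipeline for two cohorts over a grid of embedding
#' delays and a set of classifiers: startup removal and outlier
#' replacement, 2-D delay embedding, maxmin subsampling to \code{m}
#' landmarks, Rips persistence at the enclosing radius, H1 persistence
#' landscapes, and leave-one-out cross-validated classification. The first
#' cohort's group is the positive class. With \code{gridScope = "fold"}
#' (default) the landscape grid is fitted on each training fold only; with
#' \code{"global"} it is fitted once on all subjects.
#'
#' @param cohortA,cohortB lists of \linkS4class{StrideSeries}; cohort A is
#'   the positive class.
#' @param tauGrid integer vector of embedding delays (default 5:8).
#' @param classifiers subset of \code{c("NB","DT","RF","KNN")}.
#' @param tMin startup seconds removed (default 20).
#' @param d embedding dimension (default 2).
#' @param m landmark count for maxmin subsampling (default 50).
#' @param kMax,G landscape levels and grid size (defaults 5, 100).
#' @param gridScope \code{"fold"} or \code{"global"}.
#' @param seed integer seed driving subsampling and classifier refits.
#' @param hyper classifier hyperparameters: \code{maxDepth} (DT, 5),
#'   \code{nTrees} (RF, 1200), \code{nNeighbors} (KNN, 3).
#' @return data.frame with one row per (tau, classifier), sorted by AUC
#'   descending: confusion counts, accuracy/sensitivity/specificity (in
#'   percent) and AUC.
#' @export
runExperiment <- function(cohortA, cohortB, tauGrid = 5:8,
                          classifiers = .CLASSIFIERS, tMin = 20, d = 2,
                          m = 50, kMax = 5, G = 100,
                          gridScope = c("fold", "global"), seed = 42,
                          hyper = .defaultHyper()) {
  gridScope <- match.arg(gridScope)
  classifiers <- match.arg(classifiers, .CLASSIFIERS, several.ok = TRUE)
  stopifnot(length(cohortA) >= 2L, length(cohortB) >= 2L)
  idsA <- vapply(cohortA, subjectId, character(1))
  idsB <- vapply(cohortB, subjectId, character(1))
  if (anyDuplicated(c(idsA, idsB)))
    stop("cohorts must contain disjoint subjects")
  positive <- groupLabel(cohortA[[1L]])
  negative <- groupLabel(cohortB[[1L]])
  series <- c(cohortA, cohortB)
  labels <- factor(c(rep(positive, length(cohortA)),
                     rep(negative, length(cohortB))),
                   levels = c(positive, negative))
  cleaned <- lapply(series, function(s) {
    tryCatch(preprocessSeries(s, tMin = tMin),
             error = function(e) stop("subject '", subjectId(s), "': ",
                                      conditionMessage(e)))
  })

  results <- list()
  for (tau in tauGrid) {
    diagrams <- lapply(cleaned, function(s) {
      tryCatch({
        cloud <- maxminSubsample(delayEmbed(s, tau = tau, d = d), m = m,
                                 seed = seed)
        ripsDiagram(cloud)
      }, error = function(e) stop("subject '", subjectId(s), "' (tau = ",
                                  tau, "): ", conditionMessage(e)))
    })
    n <- length(diagrams)
    h1max <- function(idx) {
      deaths <- unlist(lapply(diagrams[idx], function(dg) {
        h1 <- persistencePairs(dg, dimension = 1L)
        h1$death[is.finite(h1$death)]
      }))
      if (length(deaths)) max(deaths) else 1
    }
    # feature rows per fold: train matrix and held-out row on the fold grid
    folds <- lapply(seq_len(n), function(i) {
      gm <- if (gridScope == "fold") h1max(setdiff(seq_len(n), i))
            else h1max(seq_len(n))
      fm <- vectorizeCohort(diagrams, labels, kMax = kMax, G = G,
                            gridMax = gm, tau = tau)
      list(train = featureValues(fm)[-i, , drop = FALSE],
           test = featureValues(fm)[i, , drop = FALSE])
    })
    for (cls in classifiers) {
      scores <- vapply(seq_len(n), function(i) {
        .fitPredict(folds[[i]]$train, droplevels(labels[-i]),
                    folds[[i]]$test, cls, positive,
                    seed = seed + i, hyper = hyper)
      }, numeric(1))
      predicted <- ifelse(scores >= 0.5, positive, negative)
      cm <- confusionCounts(predicted, as.character(labels), positive)
      met <- classificationMetrics(cm)
      results[[length(results) + 1L]] <- data.frame(
        task = paste(positive, "vs", negative), tau = tau, classifier = cls,
        TP = cm[["TP"]], FN = cm[["FN"]], FP = cm[["FP"]], TN = cm[["TN"]],
        accuracy = met[["accuracy"]], sensitivity = met[["sensitivity"]],
        specificity = met[["specificity"]],
        auc = aucScore(scores, as.character(labels), positive))
    }
  }
  out <- do.call(rbind, results)
  out <- out[order(-out$auc), , drop = FALSE]
  rownames(out) <- NULL
  out
}
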