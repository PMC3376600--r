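# Evaluation protocols (day split and pooled k-fold), confusion matrices,
# per-class metrics, and the principal-component view of the selected
# features.

#' Build a sequence-level confusion matrix
#'
#' @param observed,predicted aligned behaviour label vectors (one entry
#'   per 100 ms sequence).
#' @param classes class order (default flushing, landing, foraging).
#' @return integer matrix `counts[i, j]` = sequences observed as class i
#'   and predicted as class j; rows are observed, columns predicted.
#' @export
buildConfusion <- function(observed, predicted,
                           classes = behaviourLevels()) {
  if (length(observed) != length(predicted))
    stop("observed and predicted must have equal length")
  .checkBehaviour(c(observed, predicted))
  of <- factor(as.character(observed), levels = classes)
  pf <- factor(as.character(predicted), levels = classes)
  cm <- table(observed = of, predicted = pf)
  matrix(as.integer(cm), nrow = length(classes),
         dimnames = list(observed = classes, predicted = classes))
}

#' Per-class accuracy, precision and sensitivity
#'
#' For class c with TP = `counts[c, c]`, FP the rest of column c, FN the
#' rest of row c and TN the remainder: accuracy = (TP + TN) / total
#' (correct positive and negative predictions), precision = TP / (TP +
#' FP), sensitivity = TP / (TP + FN). Precision and sensitivity are NaN
#' when their denominator is zero.
#'
#' @param cm square confusion matrix (rows observed, columns predicted).
#' @param class class name or index.
#' @return named numeric: `accuracy`, `precision`, `sensitivity`.
#' @examples
#' cm <- matrix(c(129, 5, 16, 28, 219, 53, 5, 14, 581), 3, byrow = TRUE,
#'              dimnames = list(behaviourLevels(), behaviourLevels()))
#' perClassMetrics(cm, "flushing")
#' @export
perClassMetrics <- function(cm, class) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  c <- if (is.character(class)) match(class, rownames(cm)) else as.integer(class)
  if (is.na(c) || c < 1L || c > nrow(cm)) stop("unknown class: ", class)
  TP <- cm[c, c]
  FP <- sum(cm[-c, c])
  FN <- sum(cm[c, -c])
  TN <- total - TP - FP - FN
  c(accuracy = (TP + TN) / total,
    precision = if (TP + FP > 0) TP / (TP + FP) else NaN,
    sensitivity = if (TP + FN > 0) TP / (TP + FN) else NaN)
}

#' @rdname perClassMetrics
#' @return `metricsTable`: data.frame with one row per class.
#' @export
metricsTable <- function(cm) {
  cls <- rownames(cm)
  out <- t(vapply(cls, function(cc) perClassMetrics(cm, cc), numeric(3)))
  data.frame(behaviour = cls, out, row.names = NULL)
}

#' Round half-up (report convention)
#'
#' Plain `round()` rounds half to even; printed reports here round half
#' away from zero at 2 decimals.
#'
#' @param x numeric.
#' @param digits decimal places (default 2).
#' @export
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Run an evaluation protocol over a labeled feature set
#'
#' Two protocols: `"day_split"` trains on one day's sequences and tests
#' on the other day(s) (generalisation to unseen recording conditions);
#' `"mixed_kfold"` pools all data and runs k stratified, sequence-grouped
#' folds, refitting the full pipeline (screen, normalise, select, tune,
#' train) inside every training partition and summing the test confusion
#' across folds. Sample unit is the 100 ms sequence.
#'
#' @param features a [GfccFeatureSet-class] with day tags and labels.
#' @param protocol `"day_split"` or `"mixed_kfold"`.
#' @param k folds for the mixed protocol (default 5).
#' @param trainDay day tag to train on for `"day_split"` (default: first
#'   day in sorted order).
#' @param seed RNG seed (fold assignment and tuning).
#' @param dTarget,gridExponents,folds,tuneMaxSequences passed to
#'   [trainModelSet()].
#' @return list with `confusion` (3x3 matrix), `metrics` (data.frame from
#'   [metricsTable()]) and `predictions` (per-sequence data.frame).
#' @export
runProtocol <- function(features,
                        protocol = c("day_split", "mixed_kfold"),
                        k = 5L, trainDay = NULL, seed = 1L,
                        dTarget = 6L, gridExponents = -10:10,
                        folds = 5L, tuneMaxSequences = Inf) {
  protocol <- match.arg(protocol)
  stopifnot(is(features, "GfccFeatureSet"))
  days <- sort(unique(as.character(dayTag(features))))

  if (protocol == "day_split") {
    if (length(days) < 2L)
      stop("day_split needs at least 2 distinct day tags, got ",
           length(days))
    if (is.null(trainDay)) trainDay <- days[1L]
    if (!trainDay %in% days) stop("unknown trainDay: ", trainDay)
    trainCols <- dayTag(features) == trainDay
    ms <- trainModelSet(features[, trainCols], dTarget = dTarget,
                        gridExponents = gridExponents, folds = folds,
                        seed = seed, tuneMaxSequences = tuneMaxSequences)
    pred <- predictSequences(features[, !trainCols], ms)
  } else {
    if (k < 2L) stop("mixed_kfold needs k >= 2")
    seqIds <- as.character(sequenceId(features))
    fold <- .groupedFolds(as.character(behaviour(features)), seqIds,
                          k, deriveSeed(seed, 7))
    pred <- NULL
    for (f in seq_len(k)) {
      ms <- trainModelSet(features[, fold != f], dTarget = dTarget,
                          gridExponents = gridExponents, folds = folds,
                          seed = deriveSeed(seed, 20 + f),
                          tuneMaxSequences = tuneMaxSequences)
      pf <- predictSequences(features[, fold == f], ms)
      pf$fold <- f
      pred <- rbind(pred, pf)
    }
  }
  cm <- buildConfusion(pred$observed, pred$predicted)
  list(confusion = cm, metrics = metricsTable(cm), predictions = pred)
}

#' Project features onto their leading principal components
#'
#' Centres the observations and projects them onto the top principal
#' axes of the sample covariance; used to visualise the class structure
#' of the selected cepstral coefficients.
#'
#' @param x matrix with one observation per row, or a
#'   [GfccFeatureSet-class] (frames become rows).
#' @param nComponents number of components (default 3).
#' @return list with `scores` (n x nComponents), `explainedVariance`
#'   (the corresponding covariance eigenvalues, non-increasing) and
#'   `rotation` (loadings).
#' @export
pcaProject <- function(x, nComponents = 3L) {
  if (is(x, "GfccFeatureSet")) x <- t(cepstra(x))
  x <- as.matrix(x)
  if (ncol(x) < nComponents)
    stop("need at least ", nComponents, " features, got ", ncol(x))
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  keep <- seq_len(nComponents)
  list(scores = pc$x[, keep, drop = FALSE],
       explainedVariance = pc$sdev[keep]^2,
       rotation = pc$rotation[, keep, drop = FALSE])
}
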