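# Normalisation, class-size-scaled cost weighting, grid-searched pairwise
# RBF SVMs, and the one-versus-one directed-graph decision rule.

#' Fit / apply per-feature standardisation
#'
#' `fitNormalization` estimates per-feature mean and standard deviation on
#' training data; `applyNormalization` standardises a feature matrix with
#' those statistics, so training columns come out with zero mean and unit
#' variance and test data is transformed with training statistics only.
#'
#' @param x matrix with one observation per row (or a
#'   [GfccFeatureSet-class], whose frames become rows).
#' @return `fitNormalization`: a [NormalizationStats-class];
#'   `applyNormalization`: a standardised matrix.
#' @examples
#' st <- fitNormalization(matrix(c(1, 3), ncol = 1))
#' applyNormalization(matrix(c(1, 3), ncol = 1), st)  # -1, 1
#' @export
fitNormalization <- function(x) {
  if (is(x, "GfccFeatureSet")) x <- t(cepstra(x))
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 training rows")
  mu <- colMeans(x)
  # population standard deviation, so a column like (1, 3) maps to
  # exactly (-1, 1) and normalised columns have unit (population) variance
  sdev <- sqrt(colMeans(sweep(x, 2L, mu)^2))
  if (any(sdev == 0)) {
    bad <- which(sdev == 0)
    stop("constant feature column(s): ",
         paste(if (is.null(colnames(x))) bad else colnames(x)[bad],
               collapse = ", "),
         "; zero variance cannot be standardised")
  }
  names(mu) <- names(sdev) <- colnames(x)
  new("NormalizationStats", mean = mu, sd = sdev)
}

#' @rdname fitNormalization
#' @param stats a [NormalizationStats-class] from training data.
#' @export
applyNormalization <- function(x, stats) {
  if (is(x, "GfccFeatureSet")) x <- t(cepstra(x))
  x <- as.matrix(x)
  stopifnot(is(stats, "NormalizationStats"),
            ncol(x) == length(stats@mean))
  sweep(sweep(x, 2L, stats@mean), 2L, stats@sd, `/`)
}

#' Class-size-scaled soft-margin costs
#'
#' For a pairwise model with N1 and N2 training vectors per class, the
#' per-class cost multipliers are C1 = N/(2 N1) and C2 = N/(2 N2) with
#' N = N1 + N2, so the minority class is penalised more and
#' C1*N1 = C2*N2 always. The tuned grid cost C multiplies these.
#'
#' @param n1,n2 training vector counts of the two classes (positive).
#' @return list with `C1`, `C2`, `N`, `N1`, `N2`.
#' @examples
#' classWeights(50, 100)  # C1 = 1.5, C2 = 0.75
#' @export
classWeights <- function(n1, n2) {
  if (n1 <= 0 || n2 <= 0) stop("class counts must be positive")
  n <- n1 + n2
  list(C1 = n / (2 * n1), C2 = n / (2 * n2), N = n, N1 = n1, N2 = n2)
}

# Stratified, group-aware fold assignment: all observations sharing a
# group id (one 100 ms sequence) land in one fold, and each class's
# groups are spread round-robin over folds after a seeded shuffle.
# Returns an integer fold id per observation.
.groupedFolds <- function(labels, groups, k, seed) {
  if (is.null(groups)) groups <- seq_along(labels)
  gl <- tapply(as.character(labels), groups, function(v) v[1])
  ids <- names(gl)
  fold <- integer(length(ids)); names(fold) <- ids
  withSeed(seed, {
    for (cls in sort(unique(as.character(gl)))) {
      g <- ids[gl == cls]
      g <- sample(g)
      fold[g] <- rep_len(seq_len(k), length(g))
    }
  })
  unname(fold[as.character(groups)])
}

.pairKey <- function(a, b) {
  ord <- order(match(c(a, b), .BEHAVIOURS))
  paste(c(a, b)[ord], collapse = "|")
}

.fitPairSvm <- function(x, y, C, gamma) {
  counts <- table(y)
  cw <- classWeights(counts[[1L]], counts[[2L]])
  w <- c(cw$C1, cw$C2)
  names(w) <- names(counts)
  e1071::svm(x, y, type = "C-classification", kernel = "radial",
             gamma = gamma, cost = C, class.weights = w, scale = FALSE)
}

# Evaluate one pairwise model on a feature matrix. Accepts an e1071 svm
# fit or (for tests) a function(x) -> list(label=, decision=).
.predictPair <- function(model, x) {
  if (is.function(model)) {
    out <- model(x)
    return(list(label = as.character(out$label),
                decision = as.numeric(out$decision)))
  }
  p <- predict(model, x, decision.values = TRUE)
  dv <- attr(p, "decision.values")[, 1L]
  list(label = as.character(p), decision = as.numeric(dv))
}

#' Tune (C, gamma) for one pairwise SVM by grid search
#'
#' Evaluates every (C, gamma) pair on a power-of-two grid
#' (2^gridExponents in each direction) by stratified, sequence-grouped
#' k-fold cross-validation; each candidate model uses the class-size
#' cost multipliers of [classWeights()] on top of the grid C. The best
#' mean CV accuracy wins; ties break toward the smaller C, then the
#' smaller gamma.
#'
#' @param x feature matrix, one observation (frame) per row.
#' @param y two-class label vector.
#' @param groups grouping ids (sequence ids) kept intact across folds;
#'   `NULL` treats every row as its own group.
#' @param folds number of CV folds (default 5).
#' @param gridExponents integer exponents of the power-of-two grid
#'   (default -10:10, i.e. 2^-10 ... 2^10 in both C and gamma).
#' @param seed RNG seed for the fold assignment.
#' @return A [GridSearchResult-class].
#' @export
gridSearchPair <- function(x, y, groups = NULL, folds = 5L,
                           gridExponents = -10:10, seed = 1L) {
  x <- as.matrix(x)
  y <- factor(as.character(y))
  if (nlevels(y) != 2L)
    stop("grid search needs exactly 2 classes, got ", nlevels(y))
  if (min(table(y)) < folds)
    stop("class '", names(which.min(table(y))),
         "' has fewer observations than folds")
  fold <- .groupedFolds(y, groups, folds, seed)
  if (any(vapply(seq_len(folds), function(f)
        nlevels(droplevels(y[fold != f])) < 2L, NA)))
    stop("a class is absent from some training fold; need more groups")

  grid <- 2^gridExponents
  tab <- expand.grid(gamma = grid, C = grid)[, c("C", "gamma")]
  acc <- numeric(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    hits <- 0L; total <- 0L
    for (f in seq_len(folds)) {
      tr <- fold != f
      m <- .fitPairSvm(x[tr, , drop = FALSE], droplevels(y[tr]),
                       C = tab$C[i], gamma = tab$gamma[i])
      p <- predict(m, x[!tr, , drop = FALSE])
      hits <- hits + sum(as.character(p) == as.character(y[!tr]))
      total <- total + sum(!tr)
    }
    acc[i] <- hits / total
  }
  tab$accuracy <- acc
  # ties -> smaller C then smaller gamma: rows are in that order already
  best <- tab[order(-tab$accuracy, tab$C, tab$gamma)[1L], ]
  new("GridSearchResult", bestC = best$C, bestGamma = best$gamma,
      cvTable = tab)
}

#' Train the full one-versus-one model set
#'
#' End-to-end training on a labeled feature set containing all three
#' behaviours: screens structurally constant coefficients (the cosine
#' transform makes c20 identically zero), selects the `dTarget` most
#' class-separating coefficients by branch and bound on the raw training
#' cepstra, standardises the selected coefficients
#' ([fitNormalization()]), then for each of
#' the three class pairs tunes (C, gamma) with [gridSearchPair()] and
#' fits the final pairwise RBF SVM on all of the pair's rows with
#' class-size-scaled costs.
#'
#' @param features a [GfccFeatureSet-class] with all three behaviours.
#' @param dTarget number of coefficients to select (default 6).
#' @param gridExponents power-of-two grid exponents (default -10:10).
#' @param folds CV folds inside the grid search (default 5).
#' @param seed RNG seed (fold assignment, tuning subsample).
#' @param tuneMaxSequences cap on the number of sequences (per pair,
#'   stratified) used during grid-search tuning; the final fit always
#'   uses every training row. `Inf` disables the cap.
#' @return A [TrainedModelSet-class].
#' @export
trainModelSet <- function(features, dTarget = 6L, gridExponents = -10:10,
                          folds = 5L, seed = 1L, tuneMaxSequences = Inf) {
  stopifnot(is(features, "GfccFeatureSet"))
  X <- t(cepstra(features))
  labels <- as.character(behaviour(features))
  groups <- as.character(sequenceId(features))
  .checkBehaviour(labels)
  if (length(unique(labels)) < 3L)
    stop("all three behaviours must be present in training data")

  # screen structurally constant coefficients before standardisation
  sdev <- apply(X, 2L, sd)
  keep0 <- which(sdev > 0) - 1L              # 0-based original indices
  if (length(keep0) < dTarget)
    stop("fewer than dTarget non-constant coefficients")
  Xk <- X[, keep0 + 1L, drop = FALSE]
  colnames(Xk) <- paste0("c", keep0)

  # selection on raw training cepstra, then the selected coefficients are
  # standardised — the processing order of the original pipeline
  sel <- branchAndBoundSelect(Xk, labels, dTarget = dTarget)
  origIdx <- keep0[selectedIndices(sel) + 1L]   # back to c0..c20 indexing
  sel <- .selectionResult(origIdx, criterionValue(sel), dTarget)

  selPos <- match(origIdx, keep0)
  norm <- fitNormalization(Xk[, selPos, drop = FALSE])
  Xsel <- applyNormalization(Xk[, selPos, drop = FALSE], norm)

  pairs <- list(c("flushing", "landing"), c("flushing", "foraging"),
                c("landing", "foraging"))
  models <- list(); tuning <- list()
  for (pi in seq_along(pairs)) {
    pr <- pairs[[pi]]
    key <- .pairKey(pr[1], pr[2])
    rows <- labels %in% pr
    xp <- Xsel[rows, , drop = FALSE]
    yp <- factor(labels[rows], levels = pr)
    gp <- groups[rows]

    tuneRows <- seq_len(nrow(xp))
    nSeq <- length(unique(gp))
    if (is.finite(tuneMaxSequences) && nSeq > tuneMaxSequences) {
      pick <- withSeed(deriveSeed(seed, 100 + pi), {
        gl <- tapply(as.character(yp), gp, function(v) v[1])
        ids <- names(gl)
        keepIds <- unlist(lapply(unique(gl), function(cls) {
          g <- ids[gl == cls]
          sample(g, max(folds, round(length(g) * tuneMaxSequences / nSeq)))
        }))
        which(gp %in% keepIds)
      })
      tuneRows <- sort(pick)
    }
    gs <- gridSearchPair(xp[tuneRows, , drop = FALSE], yp[tuneRows],
                         groups = gp[tuneRows], folds = folds,
                         gridExponents = gridExponents,
                         seed = deriveSeed(seed, pi))
    models[[key]] <- .fitPairSvm(xp, yp, C = gs@bestC, gamma = gs@bestGamma)
    tuning[[key]] <- gs
  }

  new("TrainedModelSet", models = models, norm = norm, selection = sel,
      classLevels = .BEHAVIOURS, tuning = tuning,
      params = list(gridExponents = gridExponents, folds = folds,
                    seed = seed, screened = keep0,
                    tuneMaxSequences = tuneMaxSequences))
}

#' Classify feature frames through the one-versus-one directed graph
#'
#' Evaluates the flushing-versus-landing model first; the winner is then
#' evaluated against foraging in the corresponding pairwise model —
#' exactly two model evaluations per frame. Input must already be
#' restricted to the selected coefficients and normalised (as
#' [predictSequences()] does from a raw feature set).
#'
#' @param x normalised feature matrix, one frame per row, columns in the
#'   order of the model set's selected coefficients.
#' @param models a [TrainedModelSet-class].
#' @return data.frame with per-frame `label` and `confidence` (mean
#'   absolute decision value along the evaluated path).
#' @export
dagClassifyFrame <- function(x, models) {
  stopifnot(is(models, "TrainedModelSet"))
  x <- as.matrix(x)
  m1 <- models@models[["flushing|landing"]]
  if (is.null(m1)) stop("missing pairwise model flushing|landing")
  r1 <- .predictPair(m1, x)
  label <- character(nrow(x))
  conf <- numeric(nrow(x))
  for (w in c("flushing", "landing")) {
    rows <- r1$label == w
    if (!any(rows)) next
    key <- .pairKey(w, "foraging")
    m2 <- models@models[[key]]
    if (is.null(m2)) stop("missing pairwise model ", key)
    r2 <- .predictPair(m2, x[rows, , drop = FALSE])
    label[rows] <- r2$label
    conf[rows] <- (abs(r1$decision[rows]) + abs(r2$decision)) / 2
  }
  data.frame(label = label, confidence = conf)
}

#' Aggregate frame decisions into a sequence label
#'
#' The sequence label is the majority vote over its frames' DAG labels;
#' a tie goes to the tied label whose frames carry the largest mean
#' absolute decision value along their winning path.
#'
#' @param labels character vector of frame labels (length >= 1).
#' @param confidence per-frame mean absolute decision values (defaults
#'   to zeros, in which case ties break toward the canonical class
#'   order).
#' @return a single behaviour label.
#' @examples
#' majorityVote(c("foraging", "foraging", "landing"))
#' @export
majorityVote <- function(labels, confidence = numeric(length(labels))) {
  if (!length(labels)) stop("no frames to vote over")
  counts <- table(labels)
  top <- names(counts)[counts == max(counts)]
  if (length(top) == 1L) return(top)
  meanConf <- vapply(top, function(l) mean(confidence[labels == l]), 0)
  ord <- order(-meanConf, match(top, .BEHAVIOURS))
  top[ord][1L]
}

#' Classify every 100 ms sequence of a feature set
#'
#' Restricts the feature set to the model's selected coefficients,
#' applies the training normalisation, classifies each frame through the
#' directed graph and aggregates frames per sequence by [majorityVote()].
#'
#' @param features a [GfccFeatureSet-class].
#' @param models a [TrainedModelSet-class].
#' @return data.frame with one row per sequence: `sequence_id`, `day`,
#'   `observed`, `predicted`.
#' @export
predictSequences <- function(features, models) {
  stopifnot(is(features, "GfccFeatureSet"), is(models, "TrainedModelSet"))
  if (ncol(features) == 0L)
    return(data.frame(sequence_id = character(), day = character(),
                      observed = character(), predicted = character()))
  idx <- selectedIndices(models@selection)
  X <- t(cepstra(features))[, idx + 1L, drop = FALSE]
  colnames(X) <- paste0("c", idx)
  Xn <- applyNormalization(X, models@norm)
  fr <- dagClassifyFrame(Xn, models)

  seqIds <- as.character(sequenceId(features))
  obs <- as.character(behaviour(features))
  day <- as.character(dayTag(features))
  first <- !duplicated(seqIds)
  uniq <- seqIds[first]
  pred <- vapply(uniq, function(s) {
    rows <- seqIds == s
    majorityVote(fr$label[rows], fr$confidence[rows])
  }, "")
  data.frame(sequence_id = uniq, day = day[first], observed = obs[first],
             predicted = unname(pred))
}
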