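# Normalisation, class weighting, grid search, model training and the
# one-versus-one directed-graph decision rule.

stubModelSet <- function(fl_la, fl_fo, la_fo, counter = NULL) {
  mk <- function(winner, pair) {
    force(winner)
    function(x) {
      if (!is.null(counter)) counter$n <- counter$n + nrow(x)
      list(label = rep(winner, nrow(x)), decision = rep(1, nrow(x)))
    }
  }
  new("TrainedModelSet",
      models = list("flushing|landing" = mk(fl_la),
                    "flushing|foraging" = mk(fl_fo),
                    "landing|foraging" = mk(la_fo)),
      norm = new("NormalizationStats", mean = 0, sd = 1),
      selection = new("SelectionResult", selectedIndices = 0L,
                      criterionValue = 1, dTarget = 1L),
      classLevels = behaviourLevels(), tuning = list(), params = list())
}

test_that("normalisation gives zero-mean unit-variance training columns", {
  st <- fitNormalization(matrix(c(1, 3), ncol = 1))
  expect_equal(as.vector(applyNormalization(matrix(c(1, 3), ncol = 1), st)),
               c(-1, 1))

  set.seed(2)
  x <- matrix(rnorm(200, mean = 5, sd = 3), ncol = 4)
  st <- fitNormalization(x)
  xn <- applyNormalization(x, st)
  expect_lt(max(abs(colMeans(xn))), 1e-9)
  expect_lt(max(abs(colMeans(xn^2) - 1)), 1e-9)  # unit population variance

  # test data transformed with training statistics, not its own
  y <- matrix(rnorm(40, mean = 100), ncol = 4)
  yn <- applyNormalization(y, st)
  expect_gt(min(colMeans(yn)), 5)

  xc <- cbind(x, 7)
  colnames(xc) <- paste0("c", 0:4)
  expect_error(fitNormalization(xc), "c4")
})

test_that("class-size cost weights satisfy C1*N1 = C2*N2", {
  expect_equal(classWeights(50, 100)[c("C1", "C2")],
               list(C1 = 1.5, C2 = 0.75))
  w <- classWeights(10, 10)
  expect_equal(w$C1, 1); expect_equal(w$C2, 1)
  set.seed(4)
  for (i in 1:100) {
    n1 <- sample(1:5000, 1); n2 <- sample(1:5000, 1)
    w <- classWeights(n1, n2)
    expect_equal(w$C1 * n1, w$C2 * n2)
    expect_equal(w$C1 * n1, (n1 + n2) / 2)
  }
  expect_error(classWeights(0, 5), "positive")
})

test_that("grid search finds a perfect cell on separable clouds", {
  set.seed(10)
  x <- rbind(matrix(rnorm(200, 0), ncol = 2),
             matrix(rnorm(200, 8), ncol = 2))
  y <- rep(c("landing", "foraging"), each = 100)
  gs <- gridSearchPair(x, y, gridExponents = seq(-4, 4, 2), seed = 1)
  expect_equal(max(gs@cvTable$accuracy), 1)
  expect_true(gs@bestC %in% 2^seq(-4, 4, 2))
  expect_true(gs@bestGamma %in% 2^seq(-4, 4, 2))
})

test_that("grid search hovers at chance for label-independent features", {
  set.seed(20)
  x <- matrix(rnorm(400), ncol = 2)
  y <- rep(c("landing", "foraging"), 100)
  gs <- gridSearchPair(x, y, gridExponents = c(-2, 0, 2), seed = 1)
  expect_lt(max(gs@cvTable$accuracy), 0.70)   # chance = 0.5 + CV noise
})

test_that("grid search is deterministic under a fixed seed", {
  set.seed(30)
  x <- rbind(matrix(rnorm(120, 0), ncol = 2),
             matrix(rnorm(120, 3), ncol = 2))
  y <- rep(c("landing", "foraging"), each = 60)
  g1 <- gridSearchPair(x, y, gridExponents = c(-2, 0, 2), seed = 5)
  g2 <- gridSearchPair(x, y, gridExponents = c(-2, 0, 2), seed = 5)
  expect_identical(g1@cvTable, g2@cvTable)
  expect_identical(c(g1@bestC, g1@bestGamma), c(g2@bestC, g2@bestGamma))

  expect_error(gridSearchPair(x, rep("landing", 120)), "2 classes")
})

test_that("the trained model set separates well-separated clouds", {
  fs <- cloudFeatureSet(nSeqPerClass = 15, sep = 6, seed = 44)
  ms <- trainModelSet(fs, dTarget = 3, gridExponents = c(-2, 0, 2),
                      folds = 3, seed = 1)
  expect_identical(sort(names(ms@models)),
                   sort(c("flushing|landing", "flushing|foraging",
                          "landing|foraging")))
  expect_identical(length(ms@models), 3L)
  # training-set sequences classify perfectly in the separable regime
  p <- predictSequences(fs, ms)
  expect_equal(mean(p$observed == p$predicted), 1)

  expect_error(trainModelSet(fs[, behaviour(fs) != "landing"]),
               "three behaviours")
})

test_that("training is invariant to frame order", {
  fs <- cloudFeatureSet(nSeqPerClass = 12, sep = 6, seed = 55)
  test <- cloudFeatureSet(nSeqPerClass = 8, sep = 6, seed = 56)
  ms1 <- trainModelSet(fs, dTarget = 3, gridExponents = c(0, 2),
                       folds = 3, seed = 9)
  perm <- withr::with_seed(1, sample(ncol(fs)))
  ms2 <- trainModelSet(fs[, perm], dTarget = 3, gridExponents = c(0, 2),
                       folds = 3, seed = 9)
  expect_identical(predictSequences(test, ms1)$predicted,
                   predictSequences(test, ms2)$predicted)
})

test_that("the directed graph routes decisions through two models", {
  counter <- new.env(); counter$n <- 0
  ms <- stubModelSet("flushing", "foraging", "landing", counter)
  out <- dagClassifyFrame(matrix(0, 4, 1), ms)
  # flushing wins stage 1, then loses to foraging
  expect_identical(out$label, rep("foraging", 4))
  expect_identical(counter$n, 8)             # exactly 2 evaluations/frame

  ms2 <- stubModelSet("landing", "flushing", "landing")
  expect_identical(dagClassifyFrame(matrix(0, 2, 1), ms2)$label,
                   rep("landing", 2))

  # unanimous preference for one class survives any path
  ms3 <- stubModelSet("flushing", "flushing", "landing")
  expect_identical(dagClassifyFrame(matrix(0, 1, 1), ms3)$label, "flushing")

  msBad <- stubModelSet("flushing", "foraging", "landing")
  msBad@models[["flushing|foraging"]] <- NULL
  expect_error(dagClassifyFrame(matrix(0, 1, 1), msBad), "missing")
})

test_that("sequence labels come from majority vote with confidence ties", {
  expect_identical(majorityVote(c("foraging", "foraging", "landing")),
                   "foraging")
  expect_identical(majorityVote("landing"), "landing")
  expect_identical(majorityVote(rep("flushing", 3), c(0.1, 0.2, 0.3)),
                   "flushing")
  # three-way tie: the label with the strongest decisions wins
  expect_identical(
    majorityVote(c("flushing", "landing", "foraging"), c(0.1, 0.9, 0.5)),
    "landing")
  expect_error(majorityVote(character(0)), "no frames")
})

test_that("the pairwise solver agrees with an independent SVM", {
  skip_if_not_installed("kernlab")
  set.seed(60)
  x <- rbind(matrix(rnorm(300, 0), ncol = 3),
             matrix(rnorm(300, 3), ncol = 3))
  colnames(x) <- paste0("c", 0:2)
  y <- factor(rep(c("landing", "foraging"), each = 100),
              levels = c("landing", "foraging"))
  m1 <- flockBehaviour:::.fitPairSvm(x, y, C = 1, gamma = 0.5)
  m2 <- kernlab::ksvm(x, y, type = "C-svc",
                      kernel = kernlab::rbfdot(sigma = 0.5), C = 1,
                      scaled = FALSE)
  xt <- rbind(matrix(rnorm(150, 0), ncol = 3),
              matrix(rnorm(150, 3), ncol = 3))
  colnames(xt) <- paste0("c", 0:2)
  p1 <- as.character(predict(m1, xt))
  p2 <- as.character(kernlab::predict(m2, xt))
  expect_gt(mean(p1 == p2), 0.97)
})
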