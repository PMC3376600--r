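# Confusion matrices, per-class metrics, evaluation protocols and the
# principal-component view.

# Published-style confusion counts used as fixed arithmetic fixtures:
# rows observed (flushing, landing, foraging), columns predicted.
cmDaySplit <- matrix(c(129, 5, 16,
                       28, 219, 53,
                       5, 14, 581), 3, byrow = TRUE,
                     dimnames = list(observed = behaviourLevels(),
                                     predicted = behaviourLevels()))
cmMixed <- matrix(c(44, 10, 2,
                    10, 144, 4,
                    13, 28, 261), 3, byrow = TRUE,
                  dimnames = list(observed = behaviourLevels(),
                                  predicted = behaviourLevels()))

test_that("confusion matrices count observed-vs-predicted sequences", {
  obs <- rep(behaviourLevels(), each = 10)
  cm <- buildConfusion(obs, obs)
  expect_identical(unname(diag(cm)), rep(10L, 3))
  expect_identical(sum(cm) - sum(diag(cm)), 0L)

  cm0 <- buildConfusion(character(0), character(0))
  expect_true(all(cm0 == 0L))
  expect_error(buildConfusion(obs, obs[-1]), "equal length")
})

test_that("the day-split fixture reproduces its row totals", {
  expect_identical(unname(rowSums(cmDaySplit)), c(150, 300, 600))
  expect_identical(unname(rowSums(cmMixed)), c(56, 158, 302))
})

test_that("per-class metrics recover the published performance table", {
  # expected values recomputed from the confusion counts by the metric
  # definitions and rounded half-up to 2 decimals; the day-split landing
  # accuracy is 950/1050 = 0.9048 -> 0.90 (a report rounding it twice,
  # 0.9048 -> 0.905 -> 0.91, overstates it by one print unit)
  expectA <- rbind(flushing = c(0.95, 0.80, 0.86),
                   landing  = c(0.90, 0.92, 0.73),
                   foraging = c(0.92, 0.89, 0.97))
  expectB <- rbind(flushing = c(0.93, 0.66, 0.79),
                   landing  = c(0.90, 0.79, 0.91),
                   foraging = c(0.91, 0.98, 0.86))
  for (cl in behaviourLevels()) {
    expect_equal(unname(roundHalfUp(perClassMetrics(cmDaySplit, cl))),
                 unname(expectA[cl, ]))
    expect_equal(unname(roundHalfUp(perClassMetrics(cmMixed, cl))),
                 unname(expectB[cl, ]))
  }
  # spot values at full precision
  expect_equal(perClassMetrics(cmDaySplit, "flushing")[["sensitivity"]],
               129 / 150)
  expect_equal(perClassMetrics(cmMixed, "foraging")[["precision"]],
               261 / 267)
})

test_that("metrics behave on degenerate matrices", {
  d <- diag(c(5L, 6L, 7L))
  dimnames(d) <- list(behaviourLevels(), behaviourLevels())
  for (cl in behaviourLevels())
    expect_equal(unname(perClassMetrics(d, cl)), c(1, 1, 1))

  # a never-predicted class has undefined precision
  cm <- matrix(c(0, 5, 0, 0, 10, 0, 0, 3, 12), 3, byrow = TRUE,
               dimnames = list(behaviourLevels(), behaviourLevels()))
  m <- perClassMetrics(cm, "flushing")
  expect_true(is.nan(m[["precision"]]))
  expect_error(perClassMetrics(matrix(0, 3, 3), 1), "empty")

  set.seed(14)
  for (i in 1:20) {
    cm <- matrix(rpois(9, 20), 3,
                 dimnames = list(behaviourLevels(), behaviourLevels()))
    mt <- metricsTable(cm)
    expect_true(all(mt$accuracy >= 0 & mt$accuracy <= 1))
    expect_true(all(mt$precision >= 0 & mt$precision <= 1, na.rm = TRUE))
    expect_true(all(mt$sensitivity >= 0 & mt$sensitivity <= 1,
                    na.rm = TRUE))
  }
})

test_that("report rounding is half-up at 2 decimals", {
  expect_equal(roundHalfUp(0.905), 0.91)
  expect_equal(roundHalfUp(0.9048), 0.90)
  expect_equal(roundHalfUp(c(0.125, -0.125)), c(0.13, -0.13))
})

test_that("both protocols conserve and partition the test sequences", {
  fs <- cloudFeatureSet(nSeqPerClass = 16, sep = 6, seed = 71)
  resA <- runProtocol(fs, "day_split", seed = 1,
                      gridExponents = c(-2, 0, 2), folds = 3)
  nTest <- length(unique(sequenceId(fs)[dayTag(fs) != "day1"]))
  expect_identical(sum(resA$confusion), nTest)
  expect_true(all(resA$metrics$sensitivity > 0.9))  # separable clouds

  resB <- runProtocol(fs, "mixed_kfold", k = 4, seed = 1,
                      gridExponents = c(-2, 0, 2), folds = 3)
  expect_identical(sum(resB$confusion),
                   length(unique(sequenceId(fs))))
  # every sequence tested exactly once
  expect_identical(anyDuplicated(resB$predictions$sequence_id), 0L)
  expect_true(all(resB$metrics$sensitivity > 0.9))

  oneDay <- fs[, dayTag(fs) == "day1"]
  expect_error(runProtocol(oneDay, "day_split"), "2 distinct day tags")
  expect_error(runProtocol(fs, "mixed_kfold", k = 1), "k >= 2")
})

test_that("PCA projection matches a direct eigendecomposition", {
  set.seed(81)
  x <- matrix(rnorm(600), ncol = 6) %*% diag(c(4, 3, 2, 1, 0.5, 0.2))
  p <- pcaProject(x, 3)
  ev <- eigen(cov(x), symmetric = TRUE)$values
  expect_equal(p$explainedVariance, ev[1:3], tolerance = 1e-9)
  expect_lt(max(abs(colMeans(p$scores))), 1e-9)
  expect_true(all(diff(p$explainedVariance) <= 1e-12))

  # data confined to a plane has no third component
  y <- cbind(rnorm(100), rnorm(100))
  y3 <- cbind(y, y[, 1] + y[, 2])
  expect_lt(pcaProject(y3, 3)$explainedVariance[3], 1e-9)

  expect_error(pcaProject(matrix(0, 5, 2), 3), "at least 3")
})
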