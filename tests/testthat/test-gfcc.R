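# Frequency warping, filter bank construction and cepstral extraction.

test_that("greenwood constants derive from the hearing band", {
  sc <- greenwoodScale(500, 6000, 0.88)
  expect_equal(sc@A, 500 / (1 - 0.88), tolerance = 1e-9)  # 4166.667 Hz
  expect_equal(sc@a, log10(6000 / (500 / 0.12) + 0.88), tolerance = 1e-12)
  expect_equal(sc@a, 0.365488, tolerance = 1e-5)

  expect_error(greenwoodScale(500, 6000, k = 1), "between 0 and 1")
  expect_error(greenwoodScale(-5, 6000), "positive")
  expect_error(greenwoodScale(6000, 500), "fMin < fMax")
})

test_that("warping endpoint identities hold for any valid band", {
  set.seed(42)
  for (i in 1:50) {
    fMin <- runif(1, 20, 2000)
    fMax <- fMin + runif(1, 100, 20000)
    k <- runif(1, 0.05, 0.95)
    sc <- greenwoodScale(fMin, fMax, k)
    expect_lt(abs(perceivedFrequency(fMin, sc)), 1e-9)
    expect_lt(abs(perceivedFrequency(fMax, sc) - 1), 1e-9)
  }
})

test_that("the mel warping pins 1000 Hz to 1000 mel and 0 to 0", {
  sc <- melScale(100, 8000)
  expect_equal(perceivedFrequency(1000, sc), 1000, tolerance = 1e-9)
  expect_equal(perceivedFrequency(0, sc), 0)
  expect_error(perceivedFrequency(-1, sc), "non-negative")
})

test_that("the greenwood warp evaluates correctly away from endpoints", {
  sc <- greenwoodScale(500, 6000, 0.88)
  # direct evaluation: (1/a) log10(2000/4166.667 + 0.88)
  expect_equal(perceivedFrequency(2000, sc), 0.3653715, tolerance = 1e-6)
})

test_that("the inverse warp round-trips and the warp is monotone", {
  for (sc in list(greenwoodScale(500, 6000, 0.88), melScale(100, 10000))) {
    set.seed(7)
    f <- if (sc@family == "greenwood") runif(1000, 500, 6000)
         else runif(1000, 0, 10000)
    back <- inversePerceivedFrequency(perceivedFrequency(f, sc), sc)
    expect_lt(max(abs(back - f) / pmax(f, 1)), 1e-9)
    fs <- sort(f)
    expect_true(all(diff(perceivedFrequency(fs, sc)) > 0))
  }
  sc <- greenwoodScale(500, 6000)
  expect_equal(inversePerceivedFrequency(0, sc), 500, tolerance = 1e-9)
  expect_equal(inversePerceivedFrequency(1, sc), 6000, tolerance = 1e-9)
  expect_error(inversePerceivedFrequency(1.5, sc), "outside")
})

test_that("filter centres sit uniformly on the perceived axis", {
  sc <- greenwoodScale(500, 6000, 0.88)
  bank <- buildFilterbank(sc, nFilters = 20, nFft = 2048,
                          sampleRate = 44100)
  expect_identical(dim(filterWeights(bank)), c(20L, 1025L))
  ctr <- centerFrequencies(bank)
  expect_true(all(diff(ctr) > 0))
  expect_true(ctr[1] > 500 && ctr[20] < 6000)

  # uniform perceived spacing, and centres match an independent
  # recomputation of the grid
  p <- perceivedFrequency(ctr, sc)
  expect_lt(diff(range(diff(p))), 1e-9)
  dp <- (perceivedFrequency(6000, sc) - perceivedFrequency(500, sc)) / 21
  for (j in seq_len(20)) {
    expect_equal(ctr[j],
                 inversePerceivedFrequency(perceivedFrequency(500, sc) +
                                           j * dp, sc),
                 tolerance = 1e-9)
  }
})

test_that("every FFT bin inside the band is covered by some filter", {
  for (shape in c("hamming", "hanning", "triangular")) {
    bank <- buildFilterbank(greenwoodScale(500, 6000), nFilters = 20,
                            nFft = 2048, sampleRate = 44100, shape = shape)
    W <- filterWeights(bank)
    expect_true(all(W >= 0))
    expect_equal(unname(rowSums(W)), rep(1, 20), tolerance = 1e-12)
    binFreq <- (0:1024) * 44100 / 2048
    inBand <- binFreq > 500 & binFreq < 6000
    expect_true(all(colSums(W)[inBand] > 0))
  }
  expect_error(buildFilterbank(greenwoodScale(500, 30000),
                               sampleRate = 44100), "Nyquist")
})

test_that("a flat band-log-energy vector keeps only c0", {
  ct <- cepstralTransform(rep(2.5, 20))
  expect_equal(unname(ct[1, 1]), 20 * 2.5, tolerance = 1e-12)
  expect_lt(max(abs(ct[-1, 1])), 1e-9)
})

test_that("a DCT basis vector in band space maps to one coefficient", {
  bv <- cos(pi * ((0:19) + 0.5) / 20)
  ct <- cepstralTransform(bv)
  expect_equal(unname(ct[2, 1]), 10, tolerance = 1e-9)  # K/2
  expect_lt(max(abs(ct[-2, 1])), 1e-9)
  # the shifted-phase variant is a different transform
  expect_gt(max(abs(cepstralTransform(bv, phase = "shifted") - ct)), 0.1)
})

test_that("an all-zero frame maps to the floored flat-spectrum cepstrum", {
  bank <- buildFilterbank(greenwoodScale(500, 6000), sampleRate = 44100)
  z <- extractCepstra(numeric(2048), bank)
  expect_true(all(is.finite(z)))
  expect_equal(unname(z[1, 1]), 20 * log(1e-10), tolerance = 1e-9)
  expect_lt(max(abs(z[-1, 1])), 1e-9)
})

test_that("amplitude gain shifts c0 only", {
  bank <- buildFilterbank(greenwoodScale(500, 6000), sampleRate = 44100)
  set.seed(3)
  frame <- rnorm(2048) * 0.1
  g <- 3.7
  c1 <- extractCepstra(frame, bank)
  c2 <- extractCepstra(g * frame, bank)
  expect_equal(unname(c2[1, 1] - c1[1, 1]), 20 * 2 * log(g), tolerance = 1e-6)
  expect_lt(max(abs(c2[-1, 1] - c1[-1, 1])), 1e-6)
})

test_that("extractCepstra validates the frame length", {
  bank <- buildFilterbank(greenwoodScale(500, 6000), sampleRate = 44100)
  expect_error(extractCepstra(numeric(1024), bank), "does not match")
})

test_that("feature extraction tags frames with sequence metadata", {
  set.seed(11)
  clip <- AudioClip(runif(4410, -0.5, 0.5), 44100, sourceId = "clipA",
                    dayTag = "day2")
  tab <- data.frame(start_s = 0, end_s = 0.1, label = "flushing")
  fs <- extractFeatures(clip, tab)
  expect_s4_class(fs, "GfccFeatureSet")
  expect_identical(dim(cepstra(fs)), c(21L, 3L))
  expect_identical(length(unique(sequenceId(fs))), 1L)
  expect_true(all(behaviour(fs) == "flushing"))
  expect_true(all(dayTag(fs) == "day2"))

  empty <- extractFeatures(clip, data.frame(start_s = numeric(),
                                            end_s = numeric(),
                                            label = character()))
  expect_identical(ncol(empty), 0L)

  # determinism: identical clips produce bitwise-identical features
  fs2 <- extractFeatures(clip, tab)
  expect_identical(cepstra(fs), cepstra(fs2))
})
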