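# WAV round trips, label tables, and segmentation into 100 ms sequences
# and 2048-sample frames.

test_that("WAV files round-trip at both supported encodings", {
  f <- tempfile(fileext = ".wav")
  on.exit(unlink(f))

  # silence round-trips exactly
  writeWav(AudioClip(numeric(44100), 44100), f)
  clip <- readWav(f)
  expect_identical(length(audioSamples(clip)), 44100L)
  expect_identical(sampleRate(clip), 44100)
  expect_true(all(audioSamples(clip) == 0))

  # a 1 kHz sine survives 16-bit quantisation to within the LSB bound
  x <- 0.7 * sin(2 * pi * 1000 * (0:44099) / 44100)
  writeWav(AudioClip(x, 44100), f, bitDepth = 16)
  expect_lt(max(abs(audioSamples(readWav(f)) - x)), 1e-3)

  # 32-bit float is exact at single precision
  writeWav(AudioClip(x, 44100), f, bitDepth = 32)
  expect_lt(max(abs(audioSamples(readWav(f)) - x)), 1e-7)
})

test_that("multichannel input is averaged to mono on read", {
  f <- tempfile(fileext = ".wav")
  on.exit(unlink(f))
  x <- 0.5 * sin(2 * pi * 500 * (0:8819) / 44100)
  writeStereoWav16(x, -x, 44100, f)
  clip <- readWav(f)
  expect_identical(length(audioSamples(clip)), 8820L)
  expect_lt(max(abs(audioSamples(clip))), 1e-4)  # channels cancel
})

test_that("unreadable or non-WAV input raises a format error", {
  f <- tempfile(fileext = ".wav")
  on.exit(unlink(f))
  writeLines("definitely not audio", f)
  expect_error(readWav(f), "RIFF")
  expect_error(readWav(tempfile()), "no such file")
})

test_that("label tables round-trip, with comments and optional header", {
  f <- tempfile(fileext = ".tsv")
  on.exit(unlink(f))
  tab <- data.frame(start_s = c(0, 2.5), end_s = c(1.5, 10),
                    label = c("landing", "foraging"))
  writeLabelTable(tab, f)
  expect_equal(readLabelTable(f), tab)

  writeLines(c("# field session 1", "start_s\tend_s\tlabel",
               "0\t1.5\tlanding", "# mid-file note", "2.5\t10\tforaging"), f)
  expect_equal(readLabelTable(f), tab)

  writeLines(c("0\t1\tswimming"), f)
  expect_error(readLabelTable(f), "unknown behaviour")
})

test_that("labeled intervals tile into non-overlapping 100 ms windows", {
  clip <- AudioClip(numeric(round(1.3 * 44100)), 44100)
  win <- segmentSequences(clip, data.frame(start_s = 0, end_s = 1.05,
                                           label = "landing"))
  expect_identical(nrow(win), 10L)          # 0.05 s remainder dropped
  expect_true(all(win$length_samples == 4410L))
  expect_true(all(win$label == "landing"))
  # non-overlapping, consecutive tiling
  expect_identical(win$start_sample, as.integer(4410 * (0:9)))

  expect_identical(
    nrow(segmentSequences(clip, data.frame(start_s = numeric(),
                                           end_s = numeric(),
                                           label = character()))), 0L)
})

test_that("a 78 s labeled recording yields 780 sequences", {
  clip <- AudioClip(numeric(78 * 44100), 44100)
  win <- segmentSequences(clip, data.frame(start_s = 0, end_s = 78,
                                           label = "landing"))
  expect_identical(nrow(win), 780L)
})

test_that("segmentation validates intervals", {
  clip <- AudioClip(numeric(44100), 44100)
  expect_error(segmentSequences(clip, data.frame(
    start_s = c(0, 0.3), end_s = c(0.5, 0.8),
    label = c("landing", "landing"))), "overlap")
  expect_error(segmentSequences(clip, data.frame(
    start_s = 0, end_s = 2, label = "landing")), "past the clip")
})

test_that("an RMS fidelity floor drops quiet sequences", {
  x <- c(numeric(4410), rep(0.5, 4410))      # silent then loud window
  clip <- AudioClip(x, 44100)
  tab <- data.frame(start_s = 0, end_s = 0.2, label = "foraging")
  expect_identical(nrow(segmentSequences(clip, tab)), 2L)
  win <- segmentSequences(clip, tab, rmsFloor = 0.1)
  expect_identical(nrow(win), 1L)
  expect_identical(win$start_sample, 4410L)
})

test_that("framing walks the window at the hop size", {
  clip <- AudioClip(runif(4410, -1, 1), 44100)
  win <- segmentSequences(clip, data.frame(start_s = 0, end_s = 0.1,
                                           label = "foraging"))
  fr <- frameSequence(clip, win[1, ])
  expect_identical(dim(fr), c(2048L, 3L))    # offsets 0, 1024, 2048
  expect_identical(fr[, 1], audioSamples(clip)[1:2048])
  expect_identical(fr[, 3], audioSamples(clip)[2049:4096])

  w1 <- list(start_sample = 0L, length_samples = 2048L)
  expect_identical(ncol(frameSequence(clip, w1)), 1L)
  w2 <- list(start_sample = 0L, length_samples = 2047L)
  expect_error(frameSequence(clip, w2), "shorter than")
})

test_that("frame count matches floor((L - frameLen)/hop) + 1", {
  clip <- AudioClip(numeric(20000), 44100)
  for (L in c(2048L, 3000L, 4410L, 8820L, 10000L)) {
    w <- list(start_sample = 0L, length_samples = L)
    expect_identical(ncol(frameSequence(clip, w)),
                     as.integer((L - 2048) %/% 1024 + 1))
  }
})

test_that("analysis geometry follows the sampling rate", {
  expect_identical(defaultSequenceLength(44100), 4410L)
  expect_identical(defaultFrameLength(44100), 2048L)  # >= 46 ms, power of 2
  expect_identical(defaultSequenceLength(16000), 1600L)
  expect_identical(defaultFrameLength(16000), 1024L)
})
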