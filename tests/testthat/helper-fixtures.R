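# Shared fixtures: all built in code at test time.

# Gaussian-cloud feature set: three behaviour classes with class means
# `sep` apart in the first few coordinates, `framesPerSeq` frames per
# sequence, split over two days. Bypasses audio synthesis for classifier
# and protocol tests.
cloudFeatureSet <- function(nSeqPerClass = 20, framesPerSeq = 3, dim = 6,
                            sep = 4, sd = 1, seed = 1, days = c("day1", "day2")) {
  set.seed(seed)
  mats <- list(); seq_id <- character(); lab <- character(); day <- character()
  centers <- list(
    flushing = c(sep, 0, 0, rep(0, dim - 3)),
    landing  = c(0, sep, 0, rep(0, dim - 3)),
    foraging = c(0, 0, sep, rep(0, dim - 3))
  )
  for (cl in names(centers)) {
    for (s in seq_len(nSeqPerClass)) {
      m <- matrix(rnorm(dim * framesPerSeq, mean = centers[[cl]], sd = sd),
                  nrow = dim)
      mats[[length(mats) + 1L]] <- m
      id <- sprintf("%s_%03d", cl, s)
      seq_id <- c(seq_id, rep(id, framesPerSeq))
      lab <- c(lab, rep(cl, framesPerSeq))
      day <- c(day, rep(days[1 + (s %% length(days))], framesPerSeq))
    }
  }
  GfccFeatureSet(do.call(cbind, mats), sequenceId = seq_id, label = lab,
                 day = day)
}

# A random labeled matrix instance for selection tests.
randomSelectionInstance <- function(dim, nPerClass = 8, nClasses = 3) {
  labels <- rep(paste0("cls", seq_len(nClasses)), each = nPerClass)
  x <- matrix(rnorm(length(labels) * dim), ncol = dim)
  # random class-mean offsets so the optimum is non-trivial
  for (k in seq_len(nClasses)) {
    x[labels == paste0("cls", k), ] <-
      x[labels == paste0("cls", k), ] +
      matrix(rnorm(dim, sd = 1.5), nPerClass, dim, byrow = TRUE)
  }
  list(x = x, labels = labels)
}

# Write a 16-bit stereo PCM WAV by hand (the package writer is mono).
writeStereoWav16 <- function(left, right, rate, path) {
  q <- function(v) as.integer(pmin(32767, pmax(-32768, round(v * 32768))))
  inter <- as.vector(rbind(q(left), q(right)))
  con <- file(path, "wb"); on.exit(close(con))
  dataSize <- length(inter) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + dataSize), con, 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  writeBin(c(1L, 2L), con, 2L, endian = "little")
  writeBin(as.integer(rate), con, 4L, endian = "little")
  writeBin(as.integer(rate * 4L), con, 4L, endian = "little")
  writeBin(c(4L, 16L), con, 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(dataSize, con, 4L, endian = "little")
  writeBin(inter, con, 2L, endian = "little")
  path
}
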