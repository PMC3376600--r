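# WAV input/output and segmentation into labeled 100 ms sequences and
# 2048-sample analysis frames.
#
# The WAV reader/writer handles uncompressed RIFF PCM (16-bit integer and
# 32-bit IEEE float), which covers field-recorder output; anything
# compressed is rejected.

.wavReadChunkHeader <- function(con) {
  id <- rawToChar(readBin(con, "raw", 4L))
  size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  list(id = id, size = size)
}

#' Read a PCM WAV file as a mono AudioClip
#'
#' Reads uncompressed RIFF WAV audio (16-bit integer or 32-bit float PCM).
#' Multichannel input is averaged to mono; integer samples are scaled to
#' \[-1, 1\] by the full-scale value of the bit depth.
#'
#' @param path path to a `.wav` file.
#' @param dayTag grouping tag attached to the clip (default `"day1"`).
#' @return An [AudioClip-class]; `sourceId` is the file's base name.
#' @examples
#' f <- tempfile(fileext = ".wav")
#' writeWav(AudioClip(sin(2 * pi * 1000 * (0:4409) / 44100) * 0.5, 44100), f)
#' clip <- readWav(f)
#' sampleRate(clip)
#' @seealso [writeWav()]
#' @export
readWav <- function(path, dayTag = "day1") {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- .wavReadChunkHeader(con)
  wave <- rawToChar(readBin(con, "raw", 4L))
  if (!identical(riff$id, "RIFF") || !identical(wave, "WAVE"))
    stop("not a RIFF/WAVE file: ", path)

  fmt <- NULL
  samples <- NULL
  repeat {
    hdr <- tryCatch(.wavReadChunkHeader(con), error = function(e) NULL)
    if (is.null(hdr) || length(hdr$size) == 0L || !nzchar(hdr$id)) break
    if (hdr$id == "fmt ") {
      audioFormat <- readBin(con, "integer", 1L, 2L, signed = FALSE,
                             endian = "little")
      nChannels <- readBin(con, "integer", 1L, 2L, signed = FALSE,
                           endian = "little")
      rate <- readBin(con, "integer", 1L, 4L, endian = "little")
      readBin(con, "integer", 1L, 4L, endian = "little")  # byte rate
      readBin(con, "integer", 1L, 2L, signed = FALSE, endian = "little")
      bits <- readBin(con, "integer", 1L, 2L, signed = FALSE,
                      endian = "little")
      if (hdr$size > 16L) readBin(con, "raw", hdr$size - 16L)
      fmt <- list(format = audioFormat, channels = nChannels,
                  rate = rate, bits = bits)
    } else if (hdr$id == "data") {
      if (is.null(fmt)) stop("malformed WAV (data before fmt): ", path)
      if (fmt$format == 1L && fmt$bits == 16L) {
        n <- hdr$size %/% 2L
        samples <- readBin(con, "integer", n, 2L, signed = TRUE,
                           endian = "little") / 32768
      } else if (fmt$format == 3L && fmt$bits == 32L) {
        n <- hdr$size %/% 4L
        samples <- readBin(con, "double", n, 4L, endian = "little")
      } else {
        stop("unsupported WAV encoding in ", path,
             " (format tag ", fmt$format, ", ", fmt$bits,
             " bits); only 16-bit PCM and 32-bit float are read")
      }
    } else {
      readBin(con, "raw", hdr$size + (hdr$size %% 2L))  # skip (padded)
    }
    if (!is.null(fmt) && !is.null(samples)) break
  }
  if (is.null(samples)) stop("no data chunk found in ", path)
  if (fmt$channels > 1L) {
    usable <- length(samples) - length(samples) %% fmt$channels
    samples <- colMeans(matrix(samples[seq_len(usable)],
                               nrow = fmt$channels))
  }
  samples <- pmin(1, pmax(-1, samples))
  AudioClip(samples, fmt$rate, sourceId = basename(path), dayTag = dayTag)
}

#' Write an AudioClip (or samples) to a PCM WAV file
#'
#' @param clip an [AudioClip-class], or a numeric vector in \[-1, 1\] (then
#'   `sampleRate` must be given).
#' @param path output path.
#' @param bitDepth 16 (integer PCM, default) or 32 (IEEE float).
#' @param sampleRate required when `clip` is a bare numeric vector.
#' @return `path`, invisibly.
#' @seealso [readWav()]
#' @export
writeWav <- function(clip, path, bitDepth = 16, sampleRate = NULL) {
  if (is.numeric(clip)) {
    if (is.null(sampleRate)) stop("sampleRate required for a bare vector")
    clip <- AudioClip(clip, sampleRate)
  }
  stopifnot(is(clip, "AudioClip"), bitDepth %in% c(16, 32))
  x <- pmin(1, pmax(-1, audioSamples(clip)))
  rate <- as.integer(sampleRate(clip))
  bytesPer <- bitDepth %/% 8L
  dataSize <- length(x) * bytesPer

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + dataSize), con, 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  writeBin(c(if (bitDepth == 16) 1L else 3L, 1L), con, 2L,
           endian = "little")                      # format tag, channels
  writeBin(rate, con, 4L, endian = "little")
  writeBin(as.integer(rate * bytesPer), con, 4L, endian = "little")
  writeBin(c(as.integer(bytesPer), as.integer(bitDepth)), con, 2L,
           endian = "little")                      # block align, bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(dataSize), con, 4L, endian = "little")
  if (bitDepth == 16) {
    q <- as.integer(pmin(32767, pmax(-32768, round(x * 32768))))
    writeBin(q, con, 2L, endian = "little")
  } else {
    writeBin(x, con, 4L, endian = "little")
  }
  invisible(path)
}

#' Read / write a behaviour label table
#'
#' Tab-separated intervals, one per line: `start_s`, `end_s`, `label`.
#' Lines starting with `#` are comments; a header line is optional.
#'
#' @param path file path.
#' @return data.frame with numeric `start_s`, `end_s` and character `label`.
#' @export
readLabelTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines))
    return(data.frame(start_s = numeric(), end_s = numeric(),
                      label = character()))
  if (grepl("^start", lines[1], ignore.case = TRUE)) lines <- lines[-1]
  parts <- strsplit(lines, "\t")
  if (any(lengths(parts) < 3L))
    stop("label table needs 3 tab-separated columns: start_s, end_s, label")
  tab <- data.frame(
    start_s = as.numeric(vapply(parts, `[[`, "", 1L)),
    end_s   = as.numeric(vapply(parts, `[[`, "", 2L)),
    label   = trimws(vapply(parts, `[[`, "", 3L))
  )
  if (anyNA(tab$start_s) || anyNA(tab$end_s))
    stop("non-numeric interval bounds in ", path)
  .checkBehaviour(tab$label)
  tab
}

#' @rdname readLabelTable
#' @param table data.frame with columns `start_s`, `end_s`, `label`.
#' @export
writeLabelTable <- function(table, path) {
  stopifnot(all(c("start_s", "end_s", "label") %in% names(table)))
  write.table(table[c("start_s", "end_s", "label")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Default analysis geometry for a sampling rate
#'
#' The classification unit is a 100 ms sequence, i.e. `round(0.1 * fs)`
#' samples; the analysis frame is the smallest power of two covering at
#' least 46 ms, which is 2048 samples at 44.1 kHz.
#'
#' @param sampleRate sampling rate in Hz.
#' @return integer number of samples.
#' @export
defaultSequenceLength <- function(sampleRate) {
  .assertScalarNumeric(sampleRate, "sampleRate")
  as.integer(round(0.1 * sampleRate))
}

#' @rdname defaultSequenceLength
#' @export
defaultFrameLength <- function(sampleRate) {
  .assertScalarNumeric(sampleRate, "sampleRate")
  as.integer(2^ceiling(log2(0.046 * sampleRate)))
}

#' Tile labeled intervals with 100 ms sequence windows
#'
#' Each labeled interval is tiled with consecutive, non-overlapping
#' sequence windows of `round(0.1 * fs)` samples; a trailing remainder
#' shorter than one window is dropped. Each window inherits its interval's
#' behaviour label. Optionally, windows whose RMS amplitude falls below a
#' fidelity floor are excluded (off by default; mirrors discarding
#' low-fidelity observations at labelling time).
#'
#' @param clip an [AudioClip-class].
#' @param labelTable data.frame of non-overlapping intervals with columns
#'   `start_s`, `end_s`, `label` (see [readLabelTable()]).
#' @param rmsFloor optional RMS threshold in \[0, 1\]; `NULL` disables.
#' @return data.frame with one row per window: `clip`, `day`,
#'   `sequence_id`, `start_sample` (0-based), `length_samples`, `label`.
#' @examples
#' clip <- AudioClip(rnorm(44100) * 0.1, 44100)
#' segmentSequences(clip, data.frame(start_s = 0, end_s = 1,
#'                                   label = "foraging"))
#' @export
segmentSequences <- function(clip, labelTable, rmsFloor = NULL) {
  stopifnot(is(clip, "AudioClip"))
  empty <- data.frame(clip = character(), day = character(),
                      sequence_id = character(), start_sample = integer(),
                      length_samples = integer(), label = character())
  if (nrow(labelTable) == 0L) return(empty)
  .checkBehaviour(labelTable$label)

  fs <- sampleRate(clip)
  tab <- labelTable[order(labelTable$start_s), , drop = FALSE]
  if (any(tab$end_s <= tab$start_s))
    stop("label intervals must have end_s > start_s")
  if (nrow(tab) > 1L &&
      any(tab$start_s[-1] < tab$end_s[-nrow(tab)] - 1e-9))
    stop("label intervals overlap")
  if (max(tab$end_s) > duration(clip) + 1e-9)
    stop("label interval extends past the clip (",
         max(tab$end_s), " s > ", duration(clip), " s)")

  L <- defaultSequenceLength(fs)
  out <- lapply(seq_len(nrow(tab)), function(i) {
    s0 <- round(tab$start_s[i] * fs)
    s1 <- round(tab$end_s[i] * fs)
    n <- (s1 - s0) %/% L
    if (n <= 0L) return(NULL)
    starts <- s0 + (seq_len(n) - 1L) * L
    data.frame(clip = sourceId(clip), day = dayTag(clip),
               sequence_id = sprintf("%s:%08d", sourceId(clip), starts),
               start_sample = as.integer(starts),
               length_samples = L, label = tab$label[i])
  })
  win <- do.call(rbind, c(out, list(empty)))
  if (!is.null(rmsFloor) && nrow(win)) {
    x <- audioSamples(clip)
    rms <- vapply(seq_len(nrow(win)), function(i) {
      idx <- win$start_sample[i] + seq_len(win$length_samples[i])
      sqrt(mean(x[idx]^2))
    }, 0)
    win <- win[rms >= rmsFloor, , drop = FALSE]
  }
  rownames(win) <- NULL
  win
}

# 0-based frame offsets inside a window of length L.
.frameOffsets <- function(L, frameLen, hop) {
  if (L < frameLen)
    stop("window of ", L, " samples is shorter than the ", frameLen,
         "-sample analysis frame")
  seq.int(0L, L - frameLen, by = hop)
}

#' Cut a sequence window into overlapping analysis frames
#'
#' Frames start at 0, `hop`, `2*hop`, ... while they fit inside the window
#' (`floor((L - frameLen)/hop) + 1` frames for a window of `L` samples).
#' With the defaults (2048-sample frames, 50% hop) a 4410-sample sequence
#' yields 3 frames.
#'
#' @param clip the [AudioClip-class] the window refers to.
#' @param window one row of the data.frame from [segmentSequences()] (or
#'   any list with `start_sample` and `length_samples`).
#' @param frameLen frame length in samples (default 2048).
#' @param hop hop size in samples (default `frameLen/2`).
#' @return numeric matrix `frameLen x nFrames`, one frame per column.
#' @export
frameSequence <- function(clip, window, frameLen = 2048L,
                          hop = frameLen %/% 2L) {
  stopifnot(is(clip, "AudioClip"))
  s0 <- as.integer(window$start_sample)
  L <- as.integer(window$length_samples)
  offs <- .frameOffsets(L, frameLen, hop)
  x <- audioSamples(clip)
  vapply(offs, function(o) x[s0 + o + seq_len(frameLen)],
         numeric(frameLen))
}
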