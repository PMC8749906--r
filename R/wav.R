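#' Read and write mono 16-bit PCM WAV files
#'
#' Minimal RIFF/WAVE I/O for the audio format the pipeline consumes:
#' uncompressed PCM, 16-bit signed, single channel.  `writeWav()` clips
#' amplitudes to \[-0.99, 0.99\] before quantisation to avoid wrap-around
#' at full scale.  `readWav()` rejects compressed, multi-channel or
#' non-16-bit files.
#'
#' @param utterance An [Utterance-class] object.
#' @param path File path.
#' @param label,id Label and identifier to attach to the utterance read
#'   from disk (WAV carries neither).
#'
#' @return `readWav()` returns an [Utterance-class]; `writeWav()` returns
#'   `path` invisibly.
#' @examples
#' u <- generateUtterance("fluent", duration = 0.2, seed = 1)
#' f <- tempfile(fileext = ".wav")
#' writeWav(u, f)
#' v <- readWav(f, label = "fluent")
#' length(samples(v)) == length(samples(u))
#' @export
writeWav <- function(utterance, path) {
  stopIfNot(is(utterance, "Utterance"), "'utterance' must be an Utterance")
  x <- pmin(pmax(utterance@samples, -0.99), 0.99)
  pcm <- as.integer(round(x * 32767))
  fs <- as.integer(utterance@fs)
  con <- file(path, "wb")
  on.exit(close(con))
  dataBytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + dataBytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")        # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")         # PCM
  writeBin(1L, con, size = 2, endian = "little")         # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(fs * 2L, con, size = 4, endian = "little")    # byte rate
  writeBin(2L, con, size = 2, endian = "little")         # block align
  writeBin(16L, con, size = 2, endian = "little")        # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(dataBytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname writeWav
#' @export
readWav <- function(path, label = NA_character_, id = basename(path)) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  stopIfNot(identical(riff, "RIFF"), "not a RIFF file")
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  stopIfNot(identical(wave, "WAVE"), "not a WAVE file")
  fs <- NULL
  repeat {
    tag <- readChar(con, 4, useBytes = TRUE)
    if (length(tag) == 0L || nchar(tag) < 4L)
      stop("no data chunk found", call. = FALSE)
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(tag, "fmt ")) {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      stopIfNot(fmt[1] == 1L, "only uncompressed PCM WAV is supported")
      stopIfNot(fmt[2] == 1L, "only mono WAV is supported")
      fs <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 2, endian = "little")
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      stopIfNot(bits == 16L, "only 16-bit WAV is supported")
      if (size > 16L) readBin(con, "raw", size - 16L)
    } else if (identical(tag, "data")) {
      stopIfNot(!is.null(fs), "data chunk precedes fmt chunk")
      n <- size %/% 2L
      pcm <- readBin(con, "integer", n, size = 2, signed = TRUE,
                     endian = "little")
      return(new("Utterance", samples = pcm / 32767, fs = fs,
                 label = label, id = id))
    } else {
      readBin(con, "raw", size + size %% 2L)  # skip chunk (word-aligned)
    }
  }
}
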