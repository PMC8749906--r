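# Auditory front-end: FFT framing, A-weighting, one-third-octave band
# levels.  Output is a loudness-like frames x bands dB matrix, a crude
# analogue of the signal the inner ear forwards to the brain.

# Base-ten renard mantissas for nominal third-octave centre labels.
.r10 <- c(1, 1.25, 1.6, 2, 2.5, 3.15, 4, 5, 6.3, 8)

#' One-third-octave band table
#'
#' Base-ten third-octave bands (band ratio `10^(1/10)` per band, edges at
#' `fc * 10^(+-1/20)`) whose nominal centre frequencies fall within
#' `[fmin, fmax]`.  The default range yields the 21 standard bands from
#' 100 Hz to 10,000 Hz.  Edges are computed from the exact centres
#' `10^(k/10)` so consecutive bands tile the axis exactly; the `centre`
#' column carries the conventional nominal labels (100, 125, 160, ...).
#'
#' @param fmin,fmax Frequency range in Hz, `0 < fmin < fmax`.
#' @return A data.frame with columns `band` (base-ten band number),
#'   `centre` (nominal, Hz), `centreExact` (Hz), `lower`, `upper` (Hz).
#' @examples
#' nrow(thirdOctaveBands(100, 10000))  # 21
#' @export
thirdOctaveBands <- function(fmin = 100, fmax = 10000) {
  stopIfNot(is.numeric(fmin) && is.numeric(fmax) && fmin > 0 && fmin < fmax,
            "need 0 < fmin < fmax")
  k <- seq(floor(10 * log10(fmin)) - 1, ceiling(10 * log10(fmax)) + 1)
  nominal <- .r10[k %% 10 + 1] * 10^(k %/% 10)
  keep <- nominal >= fmin & nominal <= fmax
  k <- k[keep]
  data.frame(
    band = k,
    centre = nominal[keep],
    centreExact = 10^(k / 10),
    lower = 10^((k - 0.5) / 10),
    upper = 10^((k + 0.5) / 10)
  )
}

#' A-weighting power gain
#'
#' Linear power gain of the standard A-weighting curve (IEC 61672
#' analytic magnitude response), normalised to unity at 1,000 Hz.  In
#' decibels this is `10 * log10(aWeightingGain(f))`, e.g. about -19.1 dB
#' at 100 Hz.
#'
#' @param freq Frequencies in Hz (all > 0); vectorised.
#' @return Linear power gains, same length as `freq`.
#' @examples
#' aWeightingGain(1000)                    # 1
#' 10 * log10(aWeightingGain(100))         # about -19.1
#' @export
aWeightingGain <- function(freq) {
  stopIfNot(is.numeric(freq) && length(freq) >= 1L && all(freq > 0),
            "'freq' must be positive")
  ra <- function(f) {
    f2 <- f^2
    (12194^2 * f2^2) /
      ((f2 + 20.6^2) * sqrt((f2 + 107.7^2) * (f2 + 737.9^2)) * (f2 + 12194^2))
  }
  (ra(freq) / ra(1000))^2
}

#' Analyse an utterance into a frames x bands level matrix
#'
#' Splits the signal into consecutive non-overlapping 512-sample frames
#' (~23.2 ms at 22,050 Hz), takes each frame's FFT power spectrum,
#' applies the A-weighting power gain per FFT bin, sums the weighted bin
#' powers within each one-third-octave band (each bin's power is shared
#' across bands in proportion to the overlap of the bin's frequency span
#' with the band), and converts to dB with an additive
#' power floor so silence maps to a finite level.  Exactly the first
#' `nFrames` frames are retained; a 4-second signal provides 172 complete
#' frames, of which the final one is dropped to give the canonical
#' 171 x 21 matrix.
#'
#' @param utterance An [Utterance-class] at 22,050 Hz (other rates raise
#'   an error of class `stutterPCA_unsupported_rate`).
#' @param aWeighting Apply the A-weighting curve (default `TRUE`).
#' @param floorPower Additive linear-power floor before the dB transform.
#' @param nFrames Number of frames retained (default 171).
#' @param frameLength Samples per frame (default 512).
#' @param fmin,fmax Band range passed to [thirdOctaveBands()].
#'
#' @return A [FilterbankMatrix-class] with `nFrames` rows and one column
#'   per band (21 for the default range).
#' @examples
#' u <- generateUtterance("fluent", seed = 3)
#' fb <- analyzeUtterance(u)
#' dim(bandLevels(fb))  # 171 x 21
#' @export
analyzeUtterance <- function(utterance, aWeighting = TRUE,
                             floorPower = 1e-12, nFrames = 171,
                             frameLength = 512, fmin = 100, fmax = 10000) {
  stopIfNot(is(utterance, "Utterance"), "'utterance' must be an Utterance")
  fs <- utterance@fs
  if (fs != 22050)
    stop(structure(
      class = c("stutterPCA_unsupported_rate", "error", "condition"),
      list(message = sprintf(
        "unsupported sampling rate %g Hz (expected 22,050 Hz)", fs),
        call = sys.call())))
  x <- utterance@samples
  needed <- nFrames * frameLength
  stopIfNot(length(x) >= needed,
            sprintf("signal too short: need >= %d samples, got %d",
                    needed, length(x)))
  bands <- thirdOctaveBands(fmin, fmax)

  frames <- matrix(x[seq_len(needed)], nrow = frameLength, ncol = nFrames)
  spec <- stats::mvfft(frames)
  half <- seq_len(frameLength %/% 2 + 1L)          # one-sided bins 0..N/2
  power <- Mod(spec[half, , drop = FALSE])^2 / frameLength^2
  power[-c(1L, length(half)), ] <- 2 * power[-c(1L, length(half)), ]
  binFreq <- (half - 1L) * fs / frameLength

  if (aWeighting) {
    gain <- rep(0, length(binFreq))
    gain[binFreq > 0] <- aWeightingGain(binFreq[binFreq > 0])
    power <- power * gain
  }

  # A bin's power is split across bands in proportion to the overlap of
  # its frequency span (bin centre +- half the bin spacing) with each
  # band.  Narrow low bands (the 100 Hz band is 23 Hz wide against a
  # 43 Hz bin spacing) would otherwise contain no bin at all.
  df <- fs / frameLength
  binLo <- binFreq - df / 2
  binHi <- binFreq + df / 2
  Wb <- matrix(0, nrow(bands), length(binFreq))
  for (b in seq_len(nrow(bands))) {
    ov <- pmin(binHi, bands$upper[b]) - pmax(binLo, bands$lower[b])
    Wb[b, ] <- pmax(ov, 0) / df
  }
  bandPower <- Wb %*% power
  levels <- t(10 * log10(bandPower + floorPower))
  colnames(levels) <- as.character(bands$centre)

  new("FilterbankMatrix", levels = levels,
      frameDuration = frameLength / fs, centreFreqs = bands$centre,
      sampleId = utterance@id, label = utterance@label)
}

#' Analyse every utterance of a dataset
#'
#' @param dataset A [SpeechSet-class].
#' @param ... Passed to [analyzeUtterance()].
#' @return A list of [FilterbankMatrix-class] objects.
#' @export
analyzeDataset <- function(dataset, ...) {
  stopIfNot(is(dataset, "SpeechSet"), "'dataset' must be a SpeechSet")
  lapply(utterances(dataset), analyzeUtterance, ...)
}

#' Read/write a filterbank matrix as a delimited text table
#'
#' One row per frame, one column per band; the header carries the nominal
#' band centre frequencies.
#'
#' @param fb A [FilterbankMatrix-class].
#' @param path File path.
#' @param frameDuration,sampleId,label Metadata attached on read.
#' @return `writeFilterbank()` returns `path` invisibly; `readFilterbank()`
#'   a [FilterbankMatrix-class].
#' @export
writeFilterbank <- function(fb, path) {
  stopIfNot(is(fb, "FilterbankMatrix"), "'fb' must be a FilterbankMatrix")
  utils::write.table(fb@levels, path, sep = "\t", row.names = FALSE,
                     col.names = as.character(fb@centreFreqs), quote = FALSE)
  invisible(path)
}

#' @rdname writeFilterbank
#' @export
readFilterbank <- function(path, frameDuration = 512 / 22050,
                           sampleId = basename(path),
                           label = NA_character_) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  m <- as.matrix(tab)
  new("FilterbankMatrix", levels = unname(m),
      frameDuration = frameDuration,
      centreFreqs = suppressWarnings(as.numeric(colnames(tab))),
      sampleId = sampleId, label = label)
}
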