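# Synthetic speech-like signal generation.
#
# No clinical corpus ships with the package, so each disfluency class is
# emulated from filtered-noise and harmonic-pulse building blocks carrying
# the acoustic signature the analysis chain relies on:
#   block         - leading near-silence, then a plosive-like broadband
#                   burst, then ordinary syllables;
#   repetition    - a train of short (100-200 ms) voiced bursts separated
#                   by silent gaps, then continuous voicing;
#   prolongation  - >= 1 s of sustained band-limited noise with its energy
#                   concentrated above 3,150 Hz (sibilant-like), then
#                   ordinary syllables;
#   fluent        - continuous syllabic alternation with < 150 ms pauses.

# Raised-cosine onset/offset ramps, ~10 ms, to avoid clicks.
rampEnv <- function(m, fs, rampS = 0.01) {
  r <- min(round(rampS * fs), floor(m / 2))
  env <- rep(1, m)
  if (r > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(r) / r))
    env[seq_len(r)] <- ramp
    env[m + 1 - seq_len(r)] <- rev(ramp)
  }
  env
}

# Gaussian band-limited noise via FFT masking, unit RMS before scaling.
bandNoise <- function(durS, fs, flo, fhi, a) {
  m <- max(round(durS * fs), 8L)
  z <- stats::rnorm(m)
  Z <- stats::fft(z)
  freq <- (seq_len(m) - 1) * fs / m
  freq <- pmin(freq, fs - freq)              # fold to [0, fs/2]
  Z[freq < flo | freq > fhi] <- 0
  x <- Re(stats::fft(Z, inverse = TRUE)) / m
  r <- sqrt(mean(x^2))
  if (r > 0) x <- x / r
  a * x * rampEnv(m, fs)
}

# Formant-shaped harmonic weight at frequency f (Hz).
formantWeight <- function(f, formants, gains = c(1, 0.6), bws = c(220, 350)) {
  w <- 0.02
  for (i in seq_along(formants))
    w <- w + gains[i] * exp(-(f - formants[i])^2 / (2 * bws[i]^2))
  w
}

# Voiced burst: harmonic series at f0 with formant envelope, unit RMS.
voicedBurst <- function(durS, fs, f0, formants, a) {
  m <- max(round(durS * fs), 8L)
  t <- (seq_len(m) - 1) / fs
  nh <- max(1L, floor(min(4500, 0.45 * fs) / f0))
  fk <- f0 * seq_len(nh)
  wk <- formantWeight(fk, formants)
  ph <- stats::runif(nh, 0, 2 * pi)
  x <- sin(outer(t, 2 * pi * fk) + rep(ph, each = m)) %*% wk
  x <- drop(x)
  x <- x / sqrt(mean(x^2))
  a * x * rampEnv(m, fs)
}

# Add a segment into x starting at `startS` seconds (clipped to length).
placeSegment <- function(x, fs, startS, seg) {
  i0 <- round(startS * fs) + 1L
  if (i0 > length(x)) return(x)
  idx <- i0:min(length(x), i0 + length(seg) - 1L)
  x[idx] <- x[idx] + seg[seq_along(idx)]
  x
}

# Train of ordinary voiced syllables from `fromS` to `toS`.
addSyllables <- function(x, fs, fromS, toS, period, sylDur, f0, formants, a,
                         jitter) {
  starts <- seq(fromS, max(fromS, toS - sylDur), by = period)
  for (s in starts) {
    f0j <- f0 * (1 + stats::runif(1, -jitter, jitter))
    aj <- a * (1 + stats::runif(1, -jitter, jitter))
    sj <- s + stats::runif(1, -0.01, 0.01)
    x <- placeSegment(x, fs, max(0, sj),
                      voicedBurst(sylDur, fs, f0j, formants, aj))
  }
  x
}

#' Generate one synthetic utterance of a given disfluency class
#'
#' Produces a seeded, deterministic waveform carrying the acoustic
#' signature of its class (see the package vignette for what is and is not
#' emulated).  The default configuration matches the analysis chain:
#' 4 seconds at 22,050 Hz, i.e. 88,200 samples.
#'
#' @param label One of [disfluencyClasses()].
#' @param duration Utterance duration in seconds (> 0; default 4).
#' @param fs Sampling rate in Hz (>= 8,000; default 22,050).
#' @param seed Integer seed; identical `(label, duration, fs, seed,
#'   difficulty)` yields bit-identical samples.
#' @param difficulty `"easy"` (well-separated class signatures, low
#'   background noise) or `"hard"` (timing/amplitude jitter, added
#'   background noise, reduced spectral contrast).
#' @param id Identifier attached to the result.
#'
#' @return An [Utterance-class] with amplitudes clipped to \[-0.99, 0.99\].
#' @examples
#' u <- generateUtterance("prolongation", seed = 1)
#' u
#' @export
generateUtterance <- function(label, duration = 4, fs = 22050, seed = 1,
                              difficulty = c("easy", "hard"),
                              id = sprintf("%s_seed%d", label, seed)) {
  difficulty <- match.arg(difficulty)
  stopIfNot(is.character(label) && length(label) == 1L &&
              label %in% disfluencyClasses(),
            sprintf("unknown label '%s'", paste(label, collapse = ",")))
  stopIfNot(is.numeric(duration) && length(duration) == 1L && duration > 0,
            "'duration' must be a single positive number of seconds")
  stopIfNot(is.numeric(fs) && length(fs) == 1L && fs >= 8000,
            "'fs' must be at least 8,000 Hz")
  n <- round(duration * fs)
  hard <- difficulty == "hard"
  x <- withSeed(seed, {
    bg <- if (hard) 0.02 else 2e-4
    jitter <- if (hard) 0.25 else 0.08
    tj <- if (hard) 0.12 else 0.04          # timing jitter, s
    x <- bg * stats::rnorm(n)
    D <- duration
    fhiMax <- min(9500, 0.45 * fs)
    # utterances start at a variable point inside the 4-s window, as real
    # selections from running speech do
    t0 <- stats::runif(1, 0, if (hard) 0.5 else 0.3) * D / 4
    switch(label,
      fluent = {
        x <- addSyllables(x, fs, 0.05 * D / 4 + t0, D - 0.05, 0.35, 0.26,
                          125, c(450, 1400), 0.5, jitter)
      },
      block = {
        tB <- (if (hard) 1.0 else 1.55) * D / 4 + t0 + stats::runif(1, -tj, tj)
        burst <- bandNoise(0.12, fs, 500, min(8000, fhiMax), 0.75)
        x <- placeSegment(x, fs, tB, burst)
        x <- addSyllables(x, fs, tB + 0.35, D - 0.05, 0.35, 0.26,
                          125, c(450, 1400), 0.5, jitter)
      },
      repetition = {
        nb <- 5L
        t0 <- 0.15 * D / 4 + t0
        for (k in seq_len(nb)) {
          bd <- stats::runif(1, 0.12, 0.18)
          x <- placeSegment(x, fs, t0 + (k - 1) * 0.4 + stats::runif(1, -tj / 2, tj / 2),
                            voicedBurst(bd, fs,
                                        125 * (1 + stats::runif(1, -jitter, jitter)),
                                        c(450, 1400), 0.55))
        }
        x <- addSyllables(x, fs, t0 + nb * 0.4 + 0.25, D - 0.05, 0.35, 0.26,
                          125, c(450, 1400), 0.5, jitter)
      },
      prolongation = {
        flo <- if (hard) 2200 else 3150
        pd <- 2 * D / 4 + stats::runif(1, -tj, tj)
        x <- placeSegment(x, fs, 0.1 + t0,
                          bandNoise(pd, fs, flo, fhiMax, 0.45))
        x <- addSyllables(x, fs, 0.1 + t0 + pd + 0.15, D - 0.05, 0.35, 0.26,
                          125, c(450, 1400), 0.5, jitter)
      }
    )
    x
  })
  new("Utterance", samples = pmin(pmax(x, -0.99), 0.99), fs = fs,
      label = label, id = id)
}

#' Generate a labelled synthetic dataset
#'
#' Builds a [SpeechSet-class] with exactly the requested number of
#' utterances per class.  Each utterance receives a sub-seed derived from
#' the master seed and its position, so the whole dataset is reproducible
#' and individual utterances can be regenerated in isolation.
#'
#' The default class counts are the corpus composition the recognition
#' study is set up for: 55 blocks, 46 syllable repetitions, 59
#' prolongations and 38 fluent utterances (198 in total).
#'
#' @param classCounts Named integer vector mapping class labels to counts
#'   (all >= 0).
#' @param seed Master integer seed.
#' @param difficulty Passed to [generateUtterance()].
#' @param duration,fs Passed to [generateUtterance()].
#'
#' @return A [SpeechSet-class].
#' @examples
#' ds <- generateDataset(c(block = 2, fluent = 2), seed = 0)
#' classCounts(ds)
#' @export
generateDataset <- function(classCounts = c(block = 55, repetition = 46,
                                            prolongation = 59, fluent = 38),
                            seed = 1, difficulty = c("easy", "hard"),
                            duration = 4, fs = 22050) {
  difficulty <- match.arg(difficulty)
  cc <- unlist(classCounts)
  stopIfNot(!is.null(names(cc)) && all(names(cc) %in% disfluencyClasses()),
            "'classCounts' must be named with valid class labels")
  stopIfNot(all(is.finite(cc)) && all(cc >= 0) && all(cc == round(cc)),
            "class counts must be non-negative integers")
  utts <- vector("list", sum(cc))
  i <- 0L
  for (cls in intersect(disfluencyClasses(), names(cc))) {
    for (j in seq_len(cc[[cls]])) {
      i <- i + 1L
      utts[[i]] <- generateUtterance(
        cls, duration = duration, fs = fs,
        seed = deriveSeed(seed, i), difficulty = difficulty,
        id = sprintf("%s_%03d", cls, j)
      )
    }
  }
  new("SpeechSet", utterances = utts)
}

#' Generate a low-rank-plus-noise filterbank matrix
#'
#' Fixture generator for the component-selection machinery: a
#' frames-by-bands matrix built as a linear combination of `rank` fixed
#' smooth spectral basis profiles (a cosine/DCT family) with random
#' time-varying weights, plus i.i.d. Gaussian noise.  With `noiseSd = 0`
#' the centred matrix has numerical rank exactly `rank`; at the default
#' noise level the joint Kaiser-Guttman / cumulative-variance rule
#' ([selectComponents()]) recovers the injected rank in the large majority
#' of seeds.
#'
#' @param nFrames,nBands Matrix shape (defaults 171 x 21, the front-end's
#'   canonical output shape).
#' @param rank Number of spectral basis profiles, `1 <= rank <= nBands`
#'   (default 4, the retained component count the pipeline uses).
#' @param noiseSd Standard deviation of the additive noise (default 0.3).
#' @param seed Integer seed.
#' @param baseline Constant offset added to every entry (level-like units).
#'
#' @return A [FilterbankMatrix-class].
#' @examples
#' fb <- generateLowRankFilterbank(seed = 42)
#' dim(bandLevels(fb))
#' @export
generateLowRankFilterbank <- function(nFrames = 171, nBands = 21, rank = 4,
                                      noiseSd = 0.3, seed = 1, baseline = 50) {
  stopIfNot(rank >= 1 && rank <= nBands,
            "'rank' must satisfy 1 <= rank <= nBands")
  stopIfNot(noiseSd >= 0, "'noiseSd' must be non-negative")
  X <- withSeed(seed, {
    j <- seq_len(nBands) - 0.5
    B <- sapply(seq_len(rank), function(k) {
      b <- cos(pi * (k - 1) * j / nBands)
      b / sqrt(sum(b^2))
    })
    B <- matrix(B, nrow = nBands)
    sds <- seq(3, 1.5, length.out = rank)
    W <- matrix(stats::rnorm(nFrames * rank), nFrames, rank) %*% diag(sds, rank)
    W %*% t(B) + noiseSd * matrix(stats::rnorm(nFrames * nBands),
                                  nFrames, nBands) + baseline
  })
  cf <- if (nBands == 21) thirdOctaveBands()$centre else numeric(0)
  new("FilterbankMatrix", levels = X, frameDuration = 512 / 22050,
      centreFreqs = cf, sampleId = sprintf("lowrank_seed%d", seed),
      label = NA_character_)
}

#' Write a dataset to disk as WAV files with a manifest
#'
#' Writes each utterance of a [SpeechSet-class] as a 16-bit mono WAV file,
#' a tab-separated manifest (`id`, `path`, `label`), and a JSON sidecar
#' recording the generator parameters.
#'
#' @param dataset A [SpeechSet-class].
#' @param dir Output directory (created if needed).
#' @param params Optional named list written to the JSON sidecar.
#' @return The manifest path, invisibly.
#' @export
writeDataset <- function(dataset, dir, params = list()) {
  stopIfNot(is(dataset, "SpeechSet"), "'dataset' must be a SpeechSet")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(utterances(dataset), function(u) {
    p <- file.path(dir, paste0(utteranceId(u), ".wav"))
    writeWav(u, p)
    data.frame(id = utteranceId(u), path = p, label = utteranceLabel(u),
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mf <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, mf, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(params, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(mf)
}
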