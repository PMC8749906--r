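test_that("generated utterances have the requested length and are valid", {
  u <- fixtureUtterance("fluent", seed = 7)
  expect_length(samples(u), 88200)          # 4 s x 22,050 Hz
  expect_true(all(is.finite(samples(u))))
  expect_true(all(abs(samples(u)) <= 0.99))
  u2 <- generateUtterance("repetition", duration = 1.5, fs = 16000, seed = 3)
  expect_length(samples(u2), 24000)
})

test_that("generation is deterministic per (label, seed) and leaves the RNG alone", {
  a <- generateUtterance("block", seed = 11)
  set.seed(999)
  before <- .Random.seed
  b <- generateUtterance("block", seed = 11)
  expect_identical(samples(a), samples(b))
  expect_identical(before, .Random.seed)    # caller RNG stream untouched
  c <- generateUtterance("block", seed = 12)
  expect_false(identical(samples(a), samples(c)))
})

test_that("invalid generator arguments are rejected", {
  expect_error(generateUtterance("shout", seed = 1), "unknown label")
  expect_error(generateUtterance("block", duration = 0, seed = 1), "positive")
  expect_error(generateUtterance("block", fs = 4000, seed = 1), "8,000")
})

test_that("block utterances open with near-silence before the burst", {
  fs <- 22050
  for (seed in c(2, 21, 77)) {
    x <- samples(generateUtterance("block", seed = seed))
    rmsHead <- sqrt(mean(x[1:(0.5 * fs)]^2))
    # burst lives after the silent stop; take the loudest 0.12 s
    seg <- sapply(seq(1.2 * fs, 2.4 * fs, by = 0.02 * fs), function(i)
      sqrt(mean(x[i:(i + 0.12 * fs)]^2)))
    expect_lt(rmsHead, 0.05 * max(seg))
  }
})

test_that("prolongations concentrate energy above 3,150 Hz relative to fluent speech", {
  hfFraction <- function(label, seed) {
    fb <- fixtureFilterbank(label, seed)
    p <- colMeans(10^(bandLevels(fb) / 10))
    hf <- centreFreqs(fb) >= 3150
    sum(p[hf]) / sum(p)
  }
  expect_gt(hfFraction("prolongation", 1), hfFraction("fluent", 1))
  expect_gt(hfFraction("prolongation", 1), 0.3)
})

test_that("repetitions contain several separated voiced bursts", {
  fs <- 22050
  x <- samples(generateUtterance("repetition", seed = 5))
  # 50 ms RMS envelope over the burst-train region (first 2.2 s)
  win <- round(0.05 * fs)
  env <- sapply(seq(1, 2.2 * fs - win, by = win), function(i)
    sqrt(mean(x[i:(i + win - 1)]^2)))
  active <- env > 0.25 * max(env)
  nBursts <- sum(diff(c(FALSE, active)) == 1)
  expect_gte(nBursts, 3)
  expect_true(any(!active))                 # silent gaps between bursts
})

test_that("generateDataset honours class counts and per-seed determinism", {
  counts <- c(block = 3, repetition = 2, prolongation = 2, fluent = 1)
  ds <- generateDataset(counts, seed = 0)
  expect_s4_class(ds, "SpeechSet")
  expect_length(ds, 8)
  expect_equal(as.vector(classCounts(ds)[names(counts)]),
               unname(counts), ignore_attr = TRUE)
  ds2 <- generateDataset(counts, seed = 0)
  expect_identical(samples(ds[[5]]), samples(ds2[[5]]))
  one <- generateDataset(c(block = 1), seed = 0)
  expect_length(one, 1)
  expect_identical(utteranceLabel(one[[1]]), "block")
  expect_error(generateDataset(c(block = -1), seed = 0), "non-negative")
})

test_that("easy-mode classes separate by >= 3 dB in at least 5 bands", {
  profiles <- sapply(disfluencyClasses(), function(cls) {
    rowMeans(sapply(1:3, function(s)
      colMeans(bandLevels(fixtureFilterbank(cls, s)))))
  })
  pairs <- utils::combn(ncol(profiles), 2)
  for (p in seq_len(ncol(pairs))) {
    diffs <- abs(profiles[, pairs[1, p]] - profiles[, pairs[2, p]])
    expect_gte(sum(diffs >= 3), 5)
  }
})

test_that("low-rank fixture has the requested shape and exact rank when noiseless", {
  fb <- generateLowRankFilterbank(seed = 42)
  expect_equal(dim(bandLevels(fb)), c(171, 21))
  clean <- generateLowRankFilterbank(rank = 3, noiseSd = 0, seed = 5)
  X <- scale(bandLevels(clean), scale = FALSE)
  expect_equal(sum(svd(X)$d > 1e-8 * max(svd(X)$d)), 3)
  expect_error(generateLowRankFilterbank(rank = 22), "rank")
  expect_identical(bandLevels(generateLowRankFilterbank(seed = 9)),
                   bandLevels(generateLowRankFilterbank(seed = 9)))
})

test_that("rank-1 noiseless fixture gives one correlation eigenvalue = n_bands", {
  fb <- generateLowRankFilterbank(rank = 1, noiseSd = 0, seed = 3)
  ev <- eigen(cor(bandLevels(fb)), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(ev[1], 21, tolerance = 1e-8)
  expect_lt(max(abs(ev[-1])), 1e-8)
})

test_that("WAV round-trip preserves samples to 16-bit precision", {
  u <- generateUtterance("fluent", duration = 0.3, seed = 4)
  f <- withr::local_tempfile(fileext = ".wav")
  writeWav(u, f)
  v <- readWav(f, label = "fluent")
  expect_equal(sampleRate(v), 22050)
  expect_equal(samples(v), samples(u), tolerance = 2 / 32767)
  expect_identical(utteranceLabel(v), "fluent")
})

test_that("writeDataset emits WAVs, a manifest and a JSON sidecar", {
  ds <- generateDataset(c(fluent = 2), seed = 1, duration = 0.3)
  dir <- withr::local_tempdir()
  writeDataset(ds, dir, params = list(seed = 1))
  man <- read.delim(file.path(dir, "manifest.tsv"))
  expect_equal(nrow(man), 2)
  expect_true(all(file.exists(man$path)))
  side <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(side$seed, 1)
})
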