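# Shared fixtures: all built in code at test time.

# Small utterance cache so several tests can reuse the same waveforms.
fixtureUtterance <- local({
  cache <- list()
  function(label, seed = 1, ...) {
    key <- paste(label, seed, sep = "_")
    if (is.null(cache[[key]]))
      cache[[key]] <<- generateUtterance(label, seed = seed, ...)
    cache[[key]]
  }
})

fixtureFilterbank <- local({
  cache <- list()
  function(label, seed = 1) {
    key <- paste(label, seed, sep = "_")
    if (is.null(cache[[key]]))
      cache[[key]] <<- analyzeUtterance(fixtureUtterance(label, seed))
    cache[[key]]
  }
})

# Random standardized matrix for PCA property tests.
randomStandardized <- function(d, m, seed) {
  set.seed(seed)
  standardizeLevels(matrix(rnorm(d * m), d, m))
}

# Tiny, quickly separable feature set: 4 classes with distinct means.
toyFeatures <- function(nPerClass, nFeat = 12, seed = 1, sepScale = 3) {
  set.seed(seed)
  classes <- disfluencyClasses()
  x <- do.call(rbind, lapply(seq_along(classes), function(k) {
    mu <- sepScale * sin(seq_len(nFeat) * k)
    matrix(rnorm(nPerClass * nFeat), nPerClass, nFeat) +
      rep(mu, each = nPerClass)
  }))
  list(x = x, y = rep(classes, each = nPerClass))
}
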