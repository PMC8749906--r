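# Kohonen self-organising map baseline feature extractor: a 5 x 5 map
# vector-quantises 21-dimensional band-level frames; each utterance then
# becomes the 171-long sequence of winning-unit indices.

poolFrames <- function(frames) {
  if (is.list(frames))
    frames <- do.call(rbind, lapply(frames, function(f)
      if (is(f, "FilterbankMatrix")) bandLevels(f) else f))
  else if (is(frames, "FilterbankMatrix"))
    frames <- bandLevels(frames)
  stopIfNot(is.matrix(frames) && nrow(frames) >= 1L,
            "'frames' must be a non-empty matrix or list of matrices")
  frames
}

#' Train a Kohonen self-organising map on pooled frames
#'
#' Online (per-frame) Kohonen updates with a constant learning rate and a
#' bubble neighbourhood whose radius decreases linearly from `nbStart` to
#' 0 over the epochs: at each presentation, every unit within Chebyshev
#' grid distance `radius` of the best-matching unit moves towards the
#' frame by `lr * (x - w)`.  Frames are standardized per band with the
#' training-set mean/sd before training (Euclidean distances across dB
#' bands of unequal variance would otherwise be dominated by the
#' high-variance bands); the standardization is stored in the model.
#'
#' @param frames Pooled training frames: a frames x bands matrix, a
#'   [FilterbankMatrix-class], or a list of either.
#' @param gridShape Integer `(rows, cols)` of the map (default 5 x 5).
#' @param epochs Training epochs (default 100).
#' @param lr Constant learning rate (default 0.1).
#' @param nbStart Initial neighbourhood radius (default 3).
#' @param seed Integer seed controlling codebook initialisation and the
#'   per-epoch presentation order.
#'
#' @return A [SOMModel-class] with a quantization-error log (mean
#'   Euclidean distance to the best-matching unit, per epoch).
#' @examples
#' fb <- generateLowRankFilterbank(seed = 1)
#' som <- trainSOM(fb, epochs = 10, seed = 0)
#' som
#' @export
trainSOM <- function(frames, gridShape = c(5L, 5L), epochs = 100, lr = 0.1,
                     nbStart = 3, seed = 1) {
  X <- poolFrames(frames)
  stopIfNot(epochs >= 1, "'epochs' must be at least 1")
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  Z <- sweep(sweep(X, 2, ctr), 2, scl, `/`)
  nUnits <- prod(gridShape)
  res <- withSeed(seed, {
    lo <- apply(Z, 2, min)
    hi <- apply(Z, 2, max)
    w0 <- matrix(stats::runif(nUnits * ncol(Z)), nUnits, ncol(Z))
    w0 <- sweep(sweep(w0, 2, hi - lo, `*`), 2, lo, `+`)
    orders <- vapply(seq_len(epochs), function(e) sample.int(nrow(Z)) - 1L,
                     integer(nrow(Z)))
    radii <- if (epochs == 1) 0 else nbStart * (1 - (seq_len(epochs) - 1) /
                                                  (epochs - 1))
    .somTrainCpp(w0, Z, orders, lr, radii,
                 as.integer(gridShape[1]), as.integer(gridShape[2]))
  })
  new("SOMModel", weights = res$weights,
      gridShape = as.integer(gridShape), center = ctr, scale = scl,
      quantError = res$qe, epochs = as.integer(epochs), lr = lr,
      nbStart = as.numeric(nbStart), seed = as.integer(seed))
}

#' Best-matching-unit sequence of a sample
#'
#' Maps each frame of a filterbank matrix to the index of its nearest
#' codebook vector (Euclidean distance on the model's standardized scale;
#' ties broken by the lowest index).  Indices are 0-based and row-major
#' (`row * ncols + col`), so a 5 x 5 map yields winners in \[0, 24\]; the
#' canonical 171-frame sample becomes a 171-long winner sequence.
#'
#' @param sample A [FilterbankMatrix-class] or frames x bands matrix.
#' @param model A trained [SOMModel-class].
#' @return Integer vector of winning-unit indices, one per frame.
#' @export
bmuSequence <- function(sample, model) {
  stopIfNot(is(model, "SOMModel"), "'model' must be a SOMModel")
  X <- if (is(sample, "FilterbankMatrix")) bandLevels(sample) else sample
  stopIfNot(is.matrix(X) && ncol(X) == ncol(model@weights),
            "sample dimension does not match the codebook")
  Z <- sweep(sweep(X, 2, model@center), 2, model@scale, `/`)
  W <- model@weights
  D <- outer(rowSums(Z^2), rowSums(W^2), `+`) - 2 * Z %*% t(W)
  as.integer(max.col(-D, ties.method = "first") - 1L)
}

#' Build the samples x frames winner table of a dataset
#'
#' SOM counterpart of [featureTable()]: each sample becomes its
#' best-matching-unit sequence; rows are samples.
#'
#' @param filterbanks List of [FilterbankMatrix-class] objects.
#' @param model A trained [SOMModel-class].
#' @return Integer matrix with attribute `labels` and sample-id row names.
#' @export
winnerTable <- function(filterbanks, model) {
  feats <- t(vapply(filterbanks, bmuSequence,
                    integer(nrow(bandLevels(filterbanks[[1]]))),
                    model = model))
  rownames(feats) <- vapply(filterbanks, utteranceId, character(1))
  attr(feats, "labels") <- vapply(filterbanks, utteranceLabel, character(1))
  feats
}

#' Serialise / restore a SOM model as JSON
#'
#' @param model A [SOMModel-class].
#' @param path File path.
#' @return `writeSOMModel()` returns `path` invisibly; `readSOMModel()` a
#'   [SOMModel-class].
#' @export
writeSOMModel <- function(model, path) {
  stopIfNot(is(model, "SOMModel"), "'model' must be a SOMModel")
  jsonlite::write_json(list(
    weights = as.numeric(t(model@weights)),   # row-major
    gridShape = model@gridShape, dim = ncol(model@weights),
    center = model@center, scale = model@scale,
    quantError = model@quantError, epochs = model@epochs,
    lr = model@lr, nbStart = model@nbStart, seed = model@seed
  ), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname writeSOMModel
#' @export
readSOMModel <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("SOMModel",
      weights = matrix(o$weights, nrow = prod(o$gridShape),
                       ncol = o$dim, byrow = TRUE),
      gridShape = as.integer(o$gridShape),
      center = as.numeric(o$center), scale = as.numeric(o$scale),
      quantError = as.numeric(o$quantError), epochs = as.integer(o$epochs),
      lr = as.numeric(o$lr), nbStart = as.numeric(o$nbStart),
      seed = as.integer(o$seed))
}
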