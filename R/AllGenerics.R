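#' @include AllClasses.R
NULL

#' Accessors for package classes
#'
#' Small accessor generics in the Bioconductor style: `samples()` and
#' `sampleRate()` for [Utterance-class]; `utteranceLabel()` and
#' `utteranceId()` for utterances and filterbank matrices; `bandLevels()`,
#' `frameDuration()` and `centreFreqs()` for [FilterbankMatrix-class];
#' `eigenValues()`, `eigenVectors()` and `nComponents()` for
#' [PCAModel-class]; `codebook()` and `quantError()` for [SOMModel-class];
#' `confusionMatrix()`, `accuracy()`, `errorRate()`, `perClassAccuracy()`
#' and `certainty()` for [ClassificationReport-class].
#'
#' @param object An object of the relevant class.
#' @return The slot contents (see the class documentation).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))
#' @rdname accessors
#' @export
setGeneric("sampleRate", function(object) standardGeneric("sampleRate"))
#' @rdname accessors
#' @export
setGeneric("utteranceLabel", function(object) standardGeneric("utteranceLabel"))
#' @rdname accessors
#' @export
setGeneric("utteranceId", function(object) standardGeneric("utteranceId"))
#' @rdname accessors
#' @export
setGeneric("utterances", function(object) standardGeneric("utterances"))
#' @rdname accessors
#' @export
setGeneric("classCounts", function(object) standardGeneric("classCounts"))
#' @rdname accessors
#' @export
setGeneric("bandLevels", function(object) standardGeneric("bandLevels"))
#' @rdname accessors
#' @export
setGeneric("frameDuration", function(object) standardGeneric("frameDuration"))
#' @rdname accessors
#' @export
setGeneric("centreFreqs", function(object) standardGeneric("centreFreqs"))
#' @rdname accessors
#' @export
setGeneric("eigenValues", function(object) standardGeneric("eigenValues"))
#' @rdname accessors
#' @export
setGeneric("eigenVectors", function(object) standardGeneric("eigenVectors"))
#' @rdname accessors
#' @export
setGeneric("nComponents", function(object) standardGeneric("nComponents"))
#' @rdname accessors
#' @export
setGeneric("codebook", function(object) standardGeneric("codebook"))
#' @rdname accessors
#' @export
setGeneric("quantError", function(object) standardGeneric("quantError"))
#' @rdname accessors
#' @export
setGeneric("confusionMatrix", function(object) standardGeneric("confusionMatrix"))
#' @rdname accessors
#' @export
setGeneric("accuracy", function(object) standardGeneric("accuracy"))
#' @rdname accessors
#' @export
setGeneric("errorRate", function(object) standardGeneric("errorRate"))
#' @rdname accessors
#' @export
setGeneric("perClassAccuracy", function(object) standardGeneric("perClassAccuracy"))
#' @rdname accessors
#' @export
setGeneric("certainty", function(object) standardGeneric("certainty"))

#' @rdname accessors
setMethod("samples", "Utterance", function(object) object@samples)
#' @rdname accessors
setMethod("sampleRate", "Utterance", function(object) object@fs)
#' @rdname accessors
setMethod("utteranceLabel", "Utterance", function(object) object@label)
#' @rdname accessors
setMethod("utteranceId", "Utterance", function(object) object@id)
#' @rdname accessors
setMethod("utterances", "SpeechSet", function(object) object@utterances)

#' @rdname accessors
setMethod("classCounts", "SpeechSet", function(object) {
  labs <- vapply(object@utterances, utteranceLabel, character(1))
  table(factor(labs, levels = disfluencyClasses()))
})

#' @rdname accessors
setMethod("utteranceLabel", "FilterbankMatrix", function(object) object@label)
#' @rdname accessors
setMethod("utteranceId", "FilterbankMatrix", function(object) object@sampleId)
#' @rdname accessors
setMethod("bandLevels", "FilterbankMatrix", function(object) object@levels)
#' @rdname accessors
setMethod("frameDuration", "FilterbankMatrix", function(object) object@frameDuration)
#' @rdname accessors
setMethod("centreFreqs", "FilterbankMatrix", function(object) object@centreFreqs)

#' @rdname accessors
setMethod("eigenValues", "PCAModel", function(object) object@eigenvalues)
#' @rdname accessors
setMethod("eigenVectors", "PCAModel", function(object) object@eigenvectors)
#' @rdname accessors
setMethod("nComponents", "PCAModel", function(object) object@l)

#' @rdname accessors
setMethod("codebook", "SOMModel", function(object) object@weights)
#' @rdname accessors
setMethod("quantError", "SOMModel", function(object) object@quantError)

#' @rdname accessors
setMethod("confusionMatrix", "ClassificationReport", function(object) object@confusion)
#' @rdname accessors
setMethod("accuracy", "ClassificationReport", function(object) object@accuracy)
#' @rdname accessors
setMethod("errorRate", "ClassificationReport", function(object) object@errorRate)
#' @rdname accessors
setMethod("perClassAccuracy", "ClassificationReport", function(object) object@perClass)
#' @rdname accessors
setMethod("certainty", "ClassificationReport", function(object) object@certainty)

#' @param x,i A `SpeechSet` and an index, for `length()` and `[[`.
#' @rdname accessors
#' @export
setMethod("length", "SpeechSet", function(x) length(x@utterances))

#' @rdname accessors
#' @export
setMethod("[[", "SpeechSet", function(x, i) x@utterances[[i]])

setMethod("show", "Utterance", function(object) {
  cat(sprintf(
    "Utterance '%s': %d samples @ %g Hz (%.3f s), label = %s\n",
    object@id, length(object@samples), object@fs,
    length(object@samples) / object@fs, object@label
  ))
})

setMethod("show", "SpeechSet", function(object) {
  cc <- classCounts(object)
  cat(sprintf("SpeechSet of %d utterances\n", length(object)))
  cat("  ", paste(sprintf("%s: %d", names(cc), cc), collapse = ", "), "\n")
})

setMethod("show", "FilterbankMatrix", function(object) {
  cat(sprintf(
    "FilterbankMatrix '%s': %d frames x %d bands (%.1f ms frames), label = %s\n",
    object@sampleId, nrow(object@levels), ncol(object@levels),
    1000 * object@frameDuration, object@label
  ))
})

setMethod("show", "PCAModel", function(object) {
  ev <- object@eigenvalues
  cat(sprintf(
    "PCAModel: %d variables, l = %d retained (%.1f%% of variance)\n",
    object@m, object@l, 100 * sum(ev[seq_len(object@l)]) / sum(ev)
  ))
  cat("  eigenvalues:", paste(sprintf("%.3f", utils::head(ev, 6)), collapse = " "),
      if (length(ev) > 6) "...\n" else "\n")
})

setMethod("show", "SOMModel", function(object) {
  cat(sprintf(
    "SOMModel: %d x %d map, %d-dim codebook, %d epochs (final QE %.4f)\n",
    object@gridShape[1], object@gridShape[2], ncol(object@weights),
    object@epochs, utils::tail(object@quantError, 1)
  ))
})

setMethod("show", "MLPModel", function(object) {
  cat(sprintf(
    "MLPModel: %d-%d-%d (tanh hidden, softmax output), final CE %.4f\n",
    nrow(object@W1), ncol(object@W1), ncol(object@W2),
    utils::tail(object@trainLoss, 1)
  ))
})

setMethod("show", "ClassificationReport", function(object) {
  cat(sprintf("ClassificationReport: acc = %.4f, error rate = %.4f\n",
              object@accuracy, object@errorRate))
  cat("Per-class accuracy:\n")
  print(round(object@perClass, 4))
  cat("Confusion matrix (true x predicted):\n")
  print(object@confusion)
})
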