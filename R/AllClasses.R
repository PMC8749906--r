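#' @import methods
NULL

#' Disfluency class labels
#'
#' The four utterance categories the package distinguishes: blocks (silent
#' stops before words starting with plosives), syllable repetitions,
#' sound-initial prolongations, and fluent speech.
#'
#' @return Character vector of the four labels, in canonical order.
#' @examples
#' disfluencyClasses()
#' @export
disfluencyClasses <- function() {
  c("block", "repetition", "prolongation", "fluent")
}

#' Utterance: a labelled mono waveform
#'
#' An `Utterance` holds a short mono speech (or speech-like) signal as
#' amplitude samples in \[-1, 1\] together with its sampling rate, class
#' label and an identifier.  The canonical configuration is a 4-second
#' signal at 22,050 Hz (88,200 samples).
#'
#' @slot samples Numeric vector of amplitudes in \[-1, 1\].
#' @slot fs Sampling rate in Hz.
#' @slot label One of [disfluencyClasses()], or `NA` for unlabelled audio.
#' @slot id Opaque identifier string.
#'
#' @seealso [generateUtterance()], [analyzeUtterance()], [readWav()]
#' @exportClass Utterance
setClass("Utterance",
  representation(
    samples = "numeric",
    fs = "numeric",
    label = "character",
    id = "character"
  ),
  prototype(samples = numeric(0), fs = 22050, label = NA_character_, id = "")
)

setValidity("Utterance", function(object) {
  msg <- character(0)
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "'fs' must be a single positive number")
  if (anyNA(object@samples) || any(!is.finite(object@samples)))
    msg <- c(msg, "'samples' must be finite")
  else if (length(object@samples) &&
           (max(object@samples) > 1 || min(object@samples) < -1))
    msg <- c(msg, "'samples' must lie within [-1, 1]")
  if (length(object@label) != 1L)
    msg <- c(msg, "'label' must be a single string")
  else if (!is.na(object@label) && !object@label %in% disfluencyClasses())
    msg <- c(msg, sprintf("unknown label '%s'", object@label))
  if (length(msg)) msg else TRUE
})

#' SpeechSet: a labelled collection of utterances
#'
#' Container for a list of [Utterance-class] objects, as produced by
#' [generateDataset()].  Supports `length()`, `[[` and `lapply()`-style
#' iteration via [utterances()].
#'
#' @slot utterances List of `Utterance` objects.
#' @exportClass SpeechSet
setClass("SpeechSet", representation(utterances = "list"))

setValidity("SpeechSet", function(object) {
  ok <- vapply(object@utterances, function(u) is(u, "Utterance"), logical(1))
  if (all(ok)) TRUE else "all elements must be Utterance objects"
})

#' FilterbankMatrix: one-third-octave band levels over time frames
#'
#' The front-end representation of one utterance: a frames-by-bands matrix
#' of band levels in dB, one row per 512-sample analysis frame, one column
#' per one-third-octave band.  The canonical shape for a 4-second
#' 22,050 Hz utterance is 171 x 21.  Synthetic low-rank fixtures produced
#' by [generateLowRankFilterbank()] may use other shapes.
#'
#' @slot levels Numeric matrix, frames x bands, dB.
#' @slot frameDuration Duration of one analysis frame in seconds.
#' @slot centreFreqs Nominal band centre frequencies in Hz (one per column).
#' @slot sampleId Identifier of the source utterance.
#' @slot label Class label inherited from the source utterance (may be `NA`).
#'
#' @seealso [analyzeUtterance()], [extractFeatures()], [bmuSequence()]
#' @exportClass FilterbankMatrix
setClass("FilterbankMatrix",
  representation(
    levels = "matrix",
    frameDuration = "numeric",
    centreFreqs = "numeric",
    sampleId = "character",
    label = "character"
  ),
  prototype(frameDuration = 512 / 22050, sampleId = "", label = NA_character_)
)

setValidity("FilterbankMatrix", function(object) {
  msg <- character(0)
  if (any(!is.finite(object@levels)))
    msg <- c(msg, "'levels' must be finite")
  if (length(object@centreFreqs) &&
      length(object@centreFreqs) != ncol(object@levels))
    msg <- c(msg, "'centreFreqs' must have one entry per band column")
  if (length(object@frameDuration) != 1L || object@frameDuration <= 0)
    msg <- c(msg, "'frameDuration' must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' PCAModel: correlation-matrix principal component model
#'
#' Eigendecomposition of the band correlation matrix of one standardized
#' filterbank matrix, plus the retained component count.  Eigenvalues are
#' in descending order; eigenvector columns are orthonormal with a fixed
#' sign convention (the largest-magnitude entry of each column is
#' positive).  When the model was fitted through [fitPCA()] on a matrix
#' carrying standardization attributes, the per-band means and standard
#' deviations are stored so new data can be projected onto the same model.
#'
#' @slot eigenvalues Numeric vector, descending, non-negative; sums to the
#'   number of variables (trace of a correlation matrix).
#' @slot eigenvectors Orthonormal m x m matrix, one eigenvector per column.
#' @slot l Retained component count.
#' @slot m Number of variables (bands).
#' @slot center,scale Per-variable standardization parameters (may be
#'   empty when the model was fitted on a pre-standardized matrix of
#'   unknown origin).
#'
#' @seealso [fitPCA()], [selectComponents()], [residualDistances()]
#' @exportClass PCAModel
setClass("PCAModel",
  representation(
    eigenvalues = "numeric",
    eigenvectors = "matrix",
    l = "integer",
    m = "integer",
    center = "numeric",
    scale = "numeric"
  )
)

setValidity("PCAModel", function(object) {
  msg <- character(0)
  m <- object@m
  if (length(object@eigenvalues) != m)
    msg <- c(msg, "need one eigenvalue per variable")
  if (is.unsorted(rev(object@eigenvalues)))
    msg <- c(msg, "eigenvalues must be in descending order")
  if (any(object@eigenvalues < -1e-10))
    msg <- c(msg, "eigenvalues must be non-negative")
  if (!all(dim(object@eigenvectors) == c(m, m)))
    msg <- c(msg, "eigenvector matrix must be m x m")
  if (object@l < 1L || object@l > m)
    msg <- c(msg, "'l' must satisfy 1 <= l <= m")
  if (length(msg)) msg else TRUE
})

#' SOMModel: trained 5 x 5 Kohonen map
#'
#' Codebook of a self-organising map trained on pooled filterbank frames.
#' Unit `k` (0-based, row-major: `row * ncol + col`) owns codebook row
#' `k + 1`.  Training frames are standardized per band before fitting;
#' the standardization parameters are stored so new frames are mapped
#' consistently by [bmuSequence()].
#'
#' @slot weights Units x bands codebook matrix (25 x 21 by default).
#' @slot gridShape Integer vector `(rows, cols)` of the map grid.
#' @slot center,scale Per-band standardization of the training frames.
#' @slot quantError Mean quantization error per training epoch.
#' @slot epochs,lr,nbStart,seed Training hyperparameters.
#'
#' @seealso [trainSOM()], [bmuSequence()]
#' @exportClass SOMModel
setClass("SOMModel",
  representation(
    weights = "matrix",
    gridShape = "integer",
    center = "numeric",
    scale = "numeric",
    quantError = "numeric",
    epochs = "integer",
    lr = "numeric",
    nbStart = "numeric",
    seed = "integer"
  )
)

setValidity("SOMModel", function(object) {
  msg <- character(0)
  if (length(object@gridShape) != 2L || any(object@gridShape < 1L))
    msg <- c(msg, "'gridShape' must be two positive integers")
  if (nrow(object@weights) != prod(object@gridShape))
    msg <- c(msg, "codebook must have one row per grid unit")
  if (any(!is.finite(object@weights)))
    msg <- c(msg, "codebook weights must be finite")
  if (length(msg)) msg else TRUE
})

#' MLPModel: 171-8-4 multilayer perceptron
#'
#' A single-hidden-layer perceptron with tanh hidden units and a softmax
#' output layer, trained under categorical cross-entropy.  Inputs are
#' z-scored with the training-set statistics stored in the model.
#'
#' @slot W1,b1 Hidden-layer weights (inputs x hidden) and biases.
#' @slot W2,b2 Output-layer weights (hidden x classes) and biases.
#' @slot center,scale Input standardization parameters.
#' @slot classes Class labels in output order.
#' @slot trainLoss Cross-entropy at each optimizer evaluation.
#' @slot valLoss Validation cross-entropy at each evaluation (empty when
#'   no validation set was supplied).
#'
#' @seealso [trainMLP()], [predictProba()], [evaluateModel()]
#' @exportClass MLPModel
setClass("MLPModel",
  representation(
    W1 = "matrix", b1 = "numeric",
    W2 = "matrix", b2 = "numeric",
    center = "numeric", scale = "numeric",
    classes = "character",
    trainLoss = "numeric",
    valLoss = "numeric"
  )
)

setValidity("MLPModel", function(object) {
  msg <- character(0)
  if (ncol(object@W1) != length(object@b1))
    msg <- c(msg, "hidden layer weight/bias sizes disagree")
  if (nrow(object@W2) != ncol(object@W1))
    msg <- c(msg, "hidden and output layer sizes disagree")
  if (ncol(object@W2) != length(object@b2) ||
      ncol(object@W2) != length(object@classes))
    msg <- c(msg, "output layer size must match the number of classes")
  if (length(msg)) msg else TRUE
})

#' ClassificationReport: confusion matrix and accuracy summary
#'
#' Test-set evaluation of a classifier: the confusion matrix (true classes
#' in rows), overall accuracy `acc = Nc / Nt`, error rate `eps = 1 - acc`,
#' per-class accuracy (confusion diagonal over row sums), and the
#' per-case classification certainty (the maximum class-membership
#' probability emitted by the softmax output).
#'
#' @slot confusion 4 x 4 contingency matrix, true class x predicted class.
#' @slot accuracy Overall accuracy in \[0, 1\].
#' @slot errorRate `1 - accuracy`.
#' @slot perClass Named per-class accuracy.
#' @slot certainty Per-case maximum output probability.
#' @slot predicted Predicted label per case.
#'
#' @seealso [evaluateModel()]
#' @exportClass ClassificationReport
setClass("ClassificationReport",
  representation(
    confusion = "matrix",
    accuracy = "numeric",
    errorRate = "numeric",
    perClass = "numeric",
    certainty = "numeric",
    predicted = "character"
  )
)

setValidity("ClassificationReport", function(object) {
  msg <- character(0)
  if (nrow(object@confusion) != ncol(object@confusion))
    msg <- c(msg, "confusion matrix must be square")
  if (abs(object@accuracy + object@errorRate - 1) > 1e-12)
    msg <- c(msg, "accuracy and error rate must sum to 1")
  if (length(msg)) msg else TRUE
})
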