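# Per-utterance correlation-matrix PCA and the reconstruction
# residual-distance feature (a Q/SPE-style statistic).
#
# Conventions used throughout: sample (d-1) variance; eigenvalues in
# descending order; eigenvector sign fixed so each column's
# largest-magnitude entry is positive (reproducible loadings).

#' Standardize a levels matrix column-wise
#'
#' `z_ij = (x_ij - mean_j) / sd_j` with the sample standard deviation
#' (divisor d-1).  The returned matrix carries `"scaled:center"` and
#' `"scaled:scale"` attributes, so a [PCAModel-class] fitted on it can
#' standardize new data identically.
#'
#' @param X Numeric matrix (frames x bands) or a [FilterbankMatrix-class].
#' @return The standardized matrix.
#' @examples
#' Z <- standardizeLevels(matrix(c(0, 2, 10, 30), 2))
#' round(Z, 4)
#' @export
standardizeLevels <- function(X) {
  if (is(X, "FilterbankMatrix")) X <- bandLevels(X)
  stopIfNot(is.matrix(X) && is.numeric(X), "'X' must be a numeric matrix")
  stopIfNot(nrow(X) >= 2, "need at least 2 observations")
  sds <- apply(X, 2, stats::sd)
  bad <- which(sds < 1e-12 | !is.finite(sds))
  if (length(bad)) {
    nm <- colnames(X)[bad]
    if (is.null(nm)) nm <- as.character(bad)
    stop(sprintf("zero-variance column(s): %s", paste(nm, collapse = ", ")),
         call. = FALSE)
  }
  scale(X)
}

#' Fit a correlation-matrix PCA
#'
#' Eigendecomposition of the correlation matrix `S = Z'Z / (d-1)` of a
#' standardized matrix: `S = E Lambda E'`.  The trace of `S` equals the
#' number of variables, so the eigenvalues sum to `m`; the variance of
#' the i-th component score equals `lambda_i`.
#'
#' @param Z Standardized matrix as returned by [standardizeLevels()].
#' @param l Retained component count; by default chosen by
#'   [selectComponents()] on the eigenvalue spectrum.
#' @param varThreshold Passed to [selectComponents()] when `l` is `NULL`.
#' @return A [PCAModel-class].
#' @examples
#' Z <- standardizeLevels(bandLevels(generateLowRankFilterbank(seed = 1)))
#' fitPCA(Z)
#' @export
fitPCA <- function(Z, l = NULL, varThreshold = 0.75) {
  stopIfNot(is.matrix(Z) && all(is.finite(Z)),
            "'Z' must be a finite numeric matrix")
  d <- nrow(Z)
  m <- ncol(Z)
  S <- crossprod(Z) / (d - 1)
  eig <- eigen(S, symmetric = TRUE)
  ev <- eig$values
  stopIfNot(all(ev > -1e-10), "correlation matrix is not positive semidefinite")
  ev <- pmax(ev, 0)
  E <- eig$vectors
  for (j in seq_len(m)) {                 # deterministic sign convention
    i0 <- which.max(abs(E[, j]))
    if (E[i0, j] < 0) E[, j] <- -E[, j]
  }
  if (is.null(l)) l <- selectComponents(ev, varThreshold)
  ctr <- attr(Z, "scaled:center")
  scl <- attr(Z, "scaled:scale")
  new("PCAModel", eigenvalues = ev, eigenvectors = E,
      l = as.integer(l), m = as.integer(m),
      center = if (is.null(ctr)) numeric(0) else as.numeric(ctr),
      scale = if (is.null(scl)) numeric(0) else as.numeric(scl))
}

#' Select the number of principal components to retain
#'
#' Joint Kaiser-Guttman / cumulative-variance rule: retain
#' `l = max(nK, lV)` where `nK` is the number of eigenvalues greater than
#' unity (at least 1) and `lV` is the smallest count whose cumulative
#' explained variance reaches `varThreshold` (default 75%).
#'
#' @param eigenvalues Non-negative eigenvalues in descending order.
#' @param varThreshold Cumulative explained-variance fraction required.
#' @return Integer component count.
#' @examples
#' selectComponents(c(2.0, 1.2, 0.5, 0.3))  # 2
#' selectComponents(c(1.4, 1.2, 1.1, 0.3))  # 3
#' selectComponents(c(2.9, 0.5, 0.4, 0.2))  # 2
#' @export
selectComponents <- function(eigenvalues, varThreshold = 0.75) {
  ev <- as.numeric(eigenvalues)
  stopIfNot(length(ev) >= 1L, "'eigenvalues' must be non-empty")
  stopIfNot(all(is.finite(ev)) && all(ev >= 0) && sum(ev) > 0,
            "'eigenvalues' must be non-negative with positive sum")
  stopIfNot(!is.unsorted(rev(ev)), "'eigenvalues' must be descending")
  nK <- max(1L, sum(ev > 1))
  cumvar <- cumsum(ev) / sum(ev)
  lV <- which(cumvar >= varThreshold)[1]
  max(nK, lV)
}

#' Project standardized data onto the retained components
#'
#' `G = Z E_l`: the scores matrix whose columns are uncorrelated and have
#' variance `lambda_i`.
#'
#' @param Z Standardized matrix.
#' @param model A [PCAModel-class] fitted on data with the same variables.
#' @param l Number of components (defaults to the model's retained count).
#' @return d x l scores matrix.
#' @export
pcaScores <- function(Z, model, l = nComponents(model)) {
  stopIfNot(is(model, "PCAModel"), "'model' must be a PCAModel")
  stopIfNot(l >= 1 && l <= model@m, "'l' out of range")
  stopIfNot(ncol(Z) == model@m, "variable count mismatch")
  Z %*% model@eigenvectors[, seq_len(l), drop = FALSE]
}

#' Reconstruct standardized data from component scores
#'
#' `Y = G E_l'`, the rank-`l` PCA prediction of the standardized data
#' (the standardized mean is zero, so no offset is added).
#'
#' @param G Scores matrix from [pcaScores()].
#' @param model The [PCAModel-class] that produced `G`.
#' @return d x m reconstruction on the standardized scale.
#' @export
pcaReconstruct <- function(G, model) {
  stopIfNot(is(model, "PCAModel"), "'model' must be a PCAModel")
  l <- ncol(G)
  stopIfNot(l >= 1 && l <= model@m, "score matrix has too many columns")
  G %*% t(model@eigenvectors[, seq_len(l), drop = FALSE])
}

#' Residual distance of each observation from the PCA model
#'
#' `d_i = sqrt( sum_j (z_ij - y_ij)^2 / (m - l) )`: the RMS residual per
#' unexplained degree of freedom.  An observation lying in the span of
#' the retained components has distance exactly 0; the further an
#' observation lies from the model plane, the larger its distance.
#'
#' @param Z Standardized data.
#' @param Y Reconstruction from [pcaReconstruct()].
#' @param l Number of retained components used for `Y` (must be < m).
#' @return Non-negative numeric vector, one distance per observation.
#' @export
residualDistances <- function(Z, Y, l) {
  stopIfNot(all(dim(Z) == dim(Y)), "'Z' and 'Y' must be conformable")
  m <- ncol(Z)
  stopIfNot(l >= 1 && l < m,
            "'l' must be smaller than the number of variables (m - l > 0)")
  sqrt(rowSums((Z - Y)^2) / (m - l))
}

#' Factor loadings of the model
#'
#' `a_jk = sqrt(lambda_k) * e_jk`: for a correlation-matrix PCA these are
#' the correlation coefficients between standardized variable `j` and
#' component score `k`, which makes them directly interpretable (|a| close
#' to 1 means the band essentially builds that component).
#'
#' @param model A [PCAModel-class].
#' @param l Number of components (defaults to all `m`).
#' @return m x l matrix, variables in rows, components in columns.
#' @export
factorLoadings <- function(model, l = model@m) {
  stopIfNot(is(model, "PCAModel"), "'model' must be a PCAModel")
  stopIfNot(all(model@eigenvalues > -1e-10), "negative eigenvalue")
  k <- seq_len(l)
  sweep(model@eigenvectors[, k, drop = FALSE], 2,
        sqrt(pmax(model@eigenvalues[k], 0)), `*`)
}

#' Per-variable contribution to the PCA model
#'
#' `S_j = 1 - SV_j / SV0_j` where `SV_j` is the sample variance of the
#' residual column `z_j - y_j` and `SV0_j` the variance of the
#' standardized column (unity).  A contribution near 1 means the variable
#' is fully used by the model; near 0, that the retained components
#' ignore it.
#'
#' @param Z Standardized data.
#' @param Y Reconstruction from [pcaReconstruct()].
#' @return Numeric vector in \[0, 1\], one entry per variable.
#' @export
variableContributions <- function(Z, Y) {
  stopIfNot(all(dim(Z) == dim(Y)), "'Z' and 'Y' must be conformable")
  sv <- apply(Z - Y, 2, stats::var)
  sv0 <- apply(Z, 2, stats::var)
  pmin(pmax(1 - sv / sv0, 0), 1)
}

#' Extract the residual-distance feature vector of one sample
#'
#' The full per-utterance feature chain: standardize the frames x bands
#' level matrix, fit a correlation-matrix PCA, retain `l` components
#' (fixed override by default; data-driven [selectComponents()] when
#' `lOverride = NULL`), project, reconstruct, and return the per-frame
#' residual distances.  For the canonical 171 x 21 input the result is a
#' feature vector of length 171.
#'
#' A pooled mode is available by passing a pre-fitted `model` (with
#' stored standardization parameters): the sample is then standardized
#' and projected with that common model instead of its own.
#'
#' @param sample A [FilterbankMatrix-class] or numeric matrix.
#' @param lOverride Fixed retained component count (default 4); `NULL`
#'   selects per sample via [selectComponents()].
#' @param varThreshold Passed to [selectComponents()].
#' @param model Optional pooled [PCAModel-class] (default `NULL`: fit per
#'   sample).
#' @return Numeric vector of residual distances (one per frame).
#' @examples
#' fb <- analyzeUtterance(generateUtterance("block", seed = 2))
#' length(extractFeatures(fb))  # 171
#' @export
extractFeatures <- function(sample, lOverride = 4, varThreshold = 0.75,
                            model = NULL) {
  X <- if (is(sample, "FilterbankMatrix")) bandLevels(sample) else sample
  if (is.null(model)) {
    Z <- standardizeLevels(X)
    model <- fitPCA(Z, l = lOverride, varThreshold = varThreshold)
  } else {
    stopIfNot(length(model@center) == ncol(X),
              "pooled model lacks standardization parameters for this data")
    Z <- sweep(sweep(X, 2, model@center), 2, model@scale, `/`)
    if (!is.null(lOverride)) model@l <- as.integer(lOverride)
  }
  l <- nComponents(model)
  G <- pcaScores(Z, model, l)
  Y <- pcaReconstruct(G, model)
  residualDistances(Z, Y, l)
}

#' Build the samples x frames feature table of a dataset
#'
#' Applies [extractFeatures()] to each filterbank matrix and stacks the
#' distance vectors into an `n_samples x n_frames` matrix (198 x 171 for
#' the canonical corpus layout), with the class labels as an attribute.
#'
#' @param filterbanks List of [FilterbankMatrix-class] objects.
#' @param ... Passed to [extractFeatures()].
#' @return Numeric matrix with attribute `labels` (character vector) and
#'   row names from the sample ids.
#' @export
featureTable <- function(filterbanks, ...) {
  feats <- t(vapply(filterbanks, extractFeatures,
                    numeric(nrow(bandLevels(filterbanks[[1]]))), ...))
  rownames(feats) <- vapply(filterbanks, utteranceId, character(1))
  attr(feats, "labels") <- vapply(filterbanks, utteranceLabel, character(1))
  feats
}
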