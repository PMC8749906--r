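test_that("standardization matches the hand-computed example and its contract", {
  X <- matrix(c(0, 2, 10, 30), 2, 2)        # [[0,10],[2,30]]
  Z <- standardizeLevels(X)
  expect_equal(unclass(Z)[, 1], c(-0.7071, 0.7071), tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_equal(unclass(Z)[, 2], c(-0.7071, 0.7071), tolerance = 1e-4,
               ignore_attr = TRUE)
  Z2 <- randomStandardized(40, 7, seed = 2)
  expect_lt(max(abs(colMeans(Z2))), 1e-9)
  expect_lt(max(abs(apply(Z2, 2, sd) - 1)), 1e-9)
  Xc <- cbind(rnorm(10), rep(5, 10))
  colnames(Xc) <- c("a", "b")
  expect_error(standardizeLevels(Xc), "zero-variance.*b")
})

test_that("fitPCA eigenvalues sum to m and eigenvectors are orthonormal", {
  for (seed in 1:5) {
    Z <- randomStandardized(60, 9, seed)
    mod <- fitPCA(Z)
    expect_equal(sum(eigenValues(mod)), 9, tolerance = 1e-6)
    E <- eigenVectors(mod)
    expect_lt(max(abs(crossprod(E) - diag(9))), 1e-8)
    expect_false(is.unsorted(rev(eigenValues(mod))))
  }
})

test_that("two perfectly correlated variables give eigenvalues {2, 0}", {
  x <- rnorm(30)
  Z <- standardizeLevels(cbind(x, 3 * x + 1))
  mod <- fitPCA(Z, l = 1)
  expect_equal(eigenValues(mod), c(2, 0), tolerance = 1e-10)
  A <- factorLoadings(mod, l = 1)
  expect_equal(abs(as.numeric(A)), c(1, 1), tolerance = 1e-8)
})

test_that("eigenpairs agree with an independent SVD route on random matrices", {
  # oracle: singular values of Z/sqrt(d-1) squared are the eigenvalues;
  # right singular vectors are the eigenvectors (up to sign)
  set.seed(100)
  cases <- data.frame(d = sample(10:200, 100, replace = TRUE),
                      m = sample(2:21, 100, replace = TRUE))
  for (i in seq_len(nrow(cases))) {
    d <- cases$d[i]; m <- cases$m[i]
    if (d <= m) d <- m + 2
    Z <- standardizeLevels(matrix(rnorm(d * m), d, m))
    mod <- fitPCA(Z, l = 1)
    sv <- svd(unclass(Z) / sqrt(d - 1))
    expect_equal(eigenValues(mod), sv$d^2, tolerance = 1e-8)
    V <- sv$v
    for (j in seq_len(m)) {                 # align the sign convention
      i0 <- which.max(abs(V[, j]))
      if (V[i0, j] < 0) V[, j] <- -V[, j]
    }
    # compare only well-separated eigenspaces (random data: all separated)
    expect_lt(max(abs(abs(eigenVectors(mod)) - abs(V))), 1e-6)
  }
})

test_that("component selection implements the joint Kaiser/variance rule", {
  expect_equal(selectComponents(c(2.0, 1.2, 0.5, 0.3)), 2)
  expect_equal(selectComponents(c(1.4, 1.2, 1.1, 0.3)), 3)
  expect_equal(selectComponents(c(2.9, 0.5, 0.4, 0.2)), 2)
  expect_equal(selectComponents(c(0.9, 0.05, 0.05)), 1)  # nK floor of 1
  expect_equal(selectComponents(c(4, 0, 0, 0)), 1)
  expect_error(selectComponents(numeric(0)), "non-empty")
  expect_error(selectComponents(c(1, 2, 3)), "descending")
})

test_that("scores are uncorrelated with variance equal to the eigenvalues", {
  Z <- randomStandardized(171, 21, seed = 8)
  mod <- fitPCA(Z, l = 4)
  G <- pcaScores(Z, mod, l = 21)
  C <- cov(G)
  expect_lt(max(abs(C - diag(diag(C)))), 1e-6)
  expect_equal(diag(C), eigenValues(mod), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("full-rank projection reconstructs the data exactly", {
  Z <- randomStandardized(50, 6, seed = 3)
  mod <- fitPCA(Z, l = 6)
  Y <- pcaReconstruct(pcaScores(Z, mod, 6), mod)
  expect_lt(max(abs(Y - unclass(Z))), 1e-8)
})

test_that("residuals are orthogonal to every retained eigenvector", {
  Z <- randomStandardized(80, 10, seed = 4)
  mod <- fitPCA(Z, l = 3)
  G <- pcaScores(Z, mod, 3)
  R <- unclass(Z) - pcaReconstruct(G, mod)
  proj <- R %*% eigenVectors(mod)[, 1:3]
  expect_lt(max(abs(proj)), 1e-8)
})

test_that("residual distance matches hand arithmetic and is zero in-span", {
  # hand case: residual row (0.3, -0.4, 0), m = 3, l = 1
  Z <- matrix(c(0.3, -0.4, 0), 1, 3)
  d <- residualDistances(Z, matrix(0, 1, 3), l = 1)
  expect_equal(d, sqrt(0.25 / 2), tolerance = 1e-12)

  # rank-2 noiseless data reconstructed with l = 2 has distance exactly 0
  set.seed(5)
  B <- matrix(rnorm(10), 5, 2)
  W <- matrix(rnorm(40), 20, 2)
  Z <- standardizeLevels(W %*% t(B))
  mod <- fitPCA(Z, l = 2)
  d <- residualDistances(unclass(Z), pcaReconstruct(pcaScores(Z, mod, 2), mod),
                         l = 2)
  expect_true(all(d >= 0))
  expect_lt(max(d), 1e-8)
  expect_error(residualDistances(Z, unclass(Z), l = 5), "smaller")
})

test_that("mean residual distance is non-increasing in l", {
  Z <- randomStandardized(100, 12, seed = 6)
  mod <- fitPCA(Z, l = 1)
  meanDist <- sapply(1:11, function(l) {
    Y <- pcaReconstruct(pcaScores(Z, mod, l), mod)
    mean(residualDistances(unclass(Z), Y, l))
  })
  expect_true(all(diff(meanDist) <= 1e-12))
})

test_that("factor loadings equal variable-score correlations (correlation PCA)", {
  Z <- randomStandardized(150, 8, seed = 7)
  mod <- fitPCA(Z, l = 8)
  A <- factorLoadings(mod)
  G <- pcaScores(Z, mod, 8)
  for (k in 1:5) {
    r <- cor(unclass(Z), G[, k])
    expect_equal(as.numeric(A[, k]), as.numeric(r), tolerance = 1e-6)
  }
  expect_true(all(abs(A) <= 1 + 1e-9))
  expect_equal(rowSums(A^2), rep(1, 8), tolerance = 1e-8,
               ignore_attr = TRUE)          # communality at l = m
})

test_that("variable contributions are 1 at full rank, ~0 for pure noise, in [0,1]", {
  Z <- randomStandardized(171, 10, seed = 9)
  mod <- fitPCA(Z, l = 10)
  Yfull <- pcaReconstruct(pcaScores(Z, mod, 10), mod)
  expect_equal(variableContributions(unclass(Z), Yfull), rep(1, 10),
               tolerance = 1e-8, ignore_attr = TRUE)

  # strong 2-component structure in 8 variables + 1 independent noise variable
  set.seed(10)
  W <- matrix(rnorm(171 * 2), 171, 2)
  B <- matrix(rnorm(16, sd = 2), 8, 2)
  X <- cbind(W %*% t(B) + 0.1 * matrix(rnorm(171 * 8), 171, 8), rnorm(171))
  Zs <- standardizeLevels(X)
  mod2 <- fitPCA(Zs, l = 2)
  Y2 <- pcaReconstruct(pcaScores(Zs, mod2, 2), mod2)
  S <- variableContributions(unclass(Zs), Y2)
  expect_lt(S[9], 0.15)                     # noise variable barely used
  expect_true(all(S[1:8] > 0.9))
  expect_true(all(S >= 0 & S <= 1))
})

test_that("explained variance bookkeeping: sum(lambda[1:l])/m = 1 - mean residual variance", {
  Z <- randomStandardized(120, 15, seed = 11)
  mod <- fitPCA(Z, l = 5)
  Y <- pcaReconstruct(pcaScores(Z, mod, 5), mod)
  sv <- apply(unclass(Z) - Y, 2, var)
  lhs <- sum(eigenValues(mod)[1:5]) / 15
  expect_equal(lhs, 1 - mean(sv), tolerance = 1e-6)
})

test_that("extractFeatures chains the stages and is deterministic", {
  fb <- fixtureFilterbank("fluent", 2)
  d1 <- extractFeatures(fb)
  expect_length(d1, 171)
  expect_true(all(d1 >= 0))
  expect_identical(d1, extractFeatures(fb))
  # per-sample component selection also works
  dAuto <- extractFeatures(fb, lOverride = NULL)
  expect_length(dAuto, 171)
})

test_that("silence frames lie closer to the model than the plosive burst (blocks)", {
  for (s in c(2, 5, 11)) {
    u <- generateUtterance("block", seed = s)
    fb <- analyzeUtterance(u)
    d <- extractFeatures(fb)
    # leading 0.49 s is near-silence by construction; the plosive burst
    # surrounds the global waveform peak
    pk <- which.max(abs(samples(u))) / sampleRate(u)
    tt <- (seq_along(d) - 0.5) * frameDuration(fb)
    burst <- which(abs(tt - pk) < 0.06)
    expect_lt(mean(d[1:21]), mean(d[burst]))
  }
})

test_that("a pooled model standardizes and projects new samples consistently", {
  fbs <- lapply(1:3, function(s) fixtureFilterbank("fluent", s))
  pooled <- do.call(rbind, lapply(fbs, bandLevels))
  mod <- fitPCA(standardizeLevels(pooled), l = 4)
  d <- extractFeatures(fbs[[1]], model = mod)
  expect_length(d, 171)
  expect_true(all(is.finite(d)))
})

test_that("featureTable stacks distance vectors with labels attached", {
  fbs <- list(fixtureFilterbank("block", 2), fixtureFilterbank("fluent", 2))
  ft <- featureTable(fbs)
  expect_equal(dim(ft), c(2, 171))
  expect_identical(attr(ft, "labels"), c("block", "fluent"))
})
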