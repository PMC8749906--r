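test_that("the stratified split reproduces the canonical partition sizes", {
  labs <- rep(disfluencyClasses(), c(55, 46, 59, 38))
  sp <- splitDataset(labs, seed = 0)
  expect_equal(lengths(sp), c(train = 140, validation = 29, test = 29))
  # disjoint and exhaustive
  all <- c(sp$train, sp$validation, sp$test)
  expect_equal(sort(all), seq_along(labs))
  expect_equal(anyDuplicated(all), 0)
  # per-class test counts
  testCounts <- table(factor(labs[sp$test], levels = disfluencyClasses()))
  expect_equal(as.vector(testCounts), c(9, 5, 12, 3))
  trainCounts <- table(factor(labs[sp$train], levels = disfluencyClasses()))
  expect_equal(as.vector(trainCounts), c(37, 36, 42, 25))
  # seeded determinism and variation across seeds
  expect_identical(splitDataset(labs, seed = 0), sp)
  expect_false(identical(splitDataset(labs, seed = 1), sp))
  expect_error(splitDataset(labs[1:50], seed = 0), "available")
})

test_that("the trained network has the specified architecture and softmax outputs", {
  toy <- toyFeatures(12, nFeat = 171, seed = 1)
  mod <- trainMLP(toy$x, toy$y, hidden = 8, iters = 30, seed = 0)
  expect_equal(dim(mod@W1), c(171, 8))
  expect_equal(dim(mod@W2), c(8, 4))
  P <- predictProba(mod, toy$x)
  expect_equal(rowSums(P), rep(1, nrow(P)), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(all(P >= 0 & P <= 1))
  expect_error(trainMLP(toy$x[1:5, ], rep("block", 5)), "two classes")
  expect_error(predictProba(mod, toy$x[, 1:10]), "dimension")
})

test_that("analytic cross-entropy gradients match central finite differences", {
  set.seed(3)
  nin <- 7; nh <- 4; nc <- 3; n <- 15
  Zx <- matrix(rnorm(n * nin), n, nin)
  y <- sample(1:nc, n, replace = TRUE)
  Tmat <- diag(nc)[y, ]
  nPar <- nin * nh + nh + nh * nc + nc
  theta <- runif(nPar, -0.5, 0.5)
  g <- stutterPCA:::.mlpLossGrad(theta, Zx, Tmat, nin, nh, nc)$grad
  eps <- 1e-6
  fd <- vapply(seq_len(nPar), function(i) {
    tp <- theta; tp[i] <- tp[i] + eps
    tm <- theta; tm[i] <- tm[i] - eps
    (stutterPCA:::.mlpLossGrad(tp, Zx, Tmat, nin, nh, nc, wantGrad = FALSE)$loss -
       stutterPCA:::.mlpLossGrad(tm, Zx, Tmat, nin, nh, nc, wantGrad = FALSE)$loss) /
      (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(g - fd)) / max(abs(fd)), 1e-5)
})

test_that("training reduces the cross-entropy and fits easy synthetic features", {
  toy <- toyFeatures(15, nFeat = 20, seed = 2)
  mod <- trainMLP(toy$x, toy$y, hidden = 8, iters = 100, seed = 0)
  expect_lt(tail(mod@trainLoss, 1), mod@trainLoss[1])
  rep <- evaluateModel(mod, toy$x, toy$y)
  expect_gte(accuracy(rep), 0.95)
})

test_that("validation retention keeps the best-validation weights", {
  toy <- toyFeatures(15, nFeat = 10, seed = 4)
  val <- toyFeatures(5, nFeat = 10, seed = 5)
  mod <- trainMLP(toy$x, toy$y, xval = val$x, yval = val$y,
                  hidden = 4, iters = 60, seed = 0)
  expect_gt(length(mod@valLoss), 0)
  # the retained weights reproduce the best validation loss observed
  Zv <- sweep(sweep(val$x, 2, mod@center), 2, mod@scale, `/`)
  P <- predictProba(mod, val$x)
  Tv <- outer(val$y, mod@classes, `==`) * 1
  ce <- -mean(log(pmax(rowSums(Tv * P), 1e-300)))
  expect_equal(ce, min(mod@valLoss), tolerance = 1e-10)
})

test_that("the momentum-SGD fallback also learns", {
  toy <- toyFeatures(15, nFeat = 10, seed = 6)
  mod <- trainMLP(toy$x, toy$y, hidden = 6, iters = 200, seed = 0,
                  optimizer = "sgd", lr = 0.1, momentum = 0.3)
  expect_lt(tail(mod@trainLoss, 1), mod@trainLoss[1])
})

test_that("probability rows are deterministic and duplicate with duplicated inputs", {
  toy <- toyFeatures(10, nFeat = 8, seed = 7)
  mod <- trainMLP(toy$x, toy$y, hidden = 4, iters = 20, seed = 1)
  P1 <- predictProba(mod, toy$x)
  P2 <- predictProba(mod, toy$x)
  expect_identical(P1, P2)
  Pd <- predictProba(mod, toy$x[c(1, 1), ])
  expect_equal(Pd[1, ], Pd[2, ], ignore_attr = TRUE)
})

test_that("evaluation report satisfies acc + eps = 1 and confusion bookkeeping", {
  toy <- toyFeatures(12, nFeat = 10, seed = 8)
  mod <- trainMLP(toy$x, toy$y, hidden = 6, iters = 80, seed = 0)
  rep <- evaluateModel(mod, toy$x, toy$y)
  expect_identical(accuracy(rep) + errorRate(rep), 1)
  conf <- confusionMatrix(rep)
  expect_equal(rowSums(conf), table(factor(toy$y, levels = mod@classes)),
               ignore_attr = TRUE)
  expect_equal(accuracy(rep), sum(diag(conf)) / sum(conf))
  expect_true(all(certainty(rep) >= 0.25 & certainty(rep) <= 1))
  # all-correct toy: duplicate a trivially separable single pattern
  idx <- c(1, 13, 25, 37)
  repOne <- evaluateModel(mod, toy$x[idx, ], toy$y[idx])
  if (accuracy(repOne) == 1) expect_equal(errorRate(repOne), 0)
  expect_error(evaluateModel(mod, toy$x[0, , drop = FALSE], character(0)),
               "non-empty")
})

test_that("label-shuffled data scores at chance level", {
  accs <- vapply(1:10, function(s) {
    set.seed(s)
    x <- matrix(rnorm(120 * 15), 120, 15)
    y <- sample(rep(disfluencyClasses(), each = 30))
    tr <- 1:80; te <- 81:120
    mod <- trainMLP(x[tr, ], y[tr], hidden = 4, iters = 40, seed = s)
    accuracy(evaluateModel(mod, x[te, ], y[te]))
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.25), 0.15)
})

test_that("MLP models survive a JSON round-trip", {
  toy <- toyFeatures(8, nFeat = 6, seed = 9)
  mod <- trainMLP(toy$x, toy$y, hidden = 3, iters = 15, seed = 2)
  f <- withr::local_tempfile(fileext = ".json")
  writeMLPModel(mod, f)
  m2 <- readMLPModel(f)
  expect_equal(predictProba(m2, toy$x), predictProba(mod, toy$x),
               tolerance = 1e-12)
})
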