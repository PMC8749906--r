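# Four-class MLP classifier (inputs-8-4, tanh hidden, softmax output)
# trained under categorical cross-entropy with full-batch BFGS, plus the
# stratified corpus split and the accuracy / error-rate report.

#' Default train/validation/test split plan
#'
#' The stratified corpus split the recognition study uses: per class
#' (blocks, syllable repetitions, prolongations, fluent) the training /
#' validation / test counts are 37/9/9, 36/5/5, 42/5/12 and 25/10/3,
#' giving partitions of 140, 29 and 29 of the 198 samples.
#'
#' @return data.frame with columns `label`, `train`, `validation`, `test`.
#' @examples
#' colSums(defaultSplitPlan()[, -1])
#' @export
defaultSplitPlan <- function() {
  data.frame(
    label = disfluencyClasses(),
    train = c(37L, 36L, 42L, 25L),
    validation = c(9L, 5L, 5L, 10L),
    test = c(9L, 5L, 12L, 3L)
  )
}

#' Stratified random train/validation/test split
#'
#' Assigns sample indices to the three partitions so that each class
#' contributes exactly the counts of the plan; assignment within a class
#' is a seeded random permutation.  The partitions are disjoint and,
#' when the plan consumes every sample, exhaustive.
#'
#' @param labels Character vector of class labels, one per sample.
#' @param plan A plan like [defaultSplitPlan()].
#' @param seed Integer seed.
#' @return List with integer index vectors `train`, `validation`, `test`.
#' @examples
#' labs <- rep(disfluencyClasses(), c(55, 46, 59, 38))
#' sp <- splitDataset(labs, seed = 0)
#' lengths(sp)
#' @export
splitDataset <- function(labels, plan = defaultSplitPlan(), seed = 1) {
  stopIfNot(all(c("label", "train", "validation", "test") %in% names(plan)),
            "'plan' must have columns label, train, validation, test")
  out <- list(train = integer(0), validation = integer(0), test = integer(0))
  withSeed(seed, {
    for (r in seq_len(nrow(plan))) {
      cls <- plan$label[r]
      need <- plan$train[r] + plan$validation[r] + plan$test[r]
      idx <- which(labels == cls)
      stopIfNot(length(idx) >= need,
                sprintf("class '%s': plan needs %d samples, only %d available",
                        cls, need, length(idx)))
      idx <- sample(idx)
      out$train <- c(out$train, idx[seq_len(plan$train[r])])
      out$validation <- c(out$validation,
                          idx[plan$train[r] + seq_len(plan$validation[r])])
      out$test <- c(out$test,
                    idx[plan$train[r] + plan$validation[r] +
                          seq_len(plan$test[r])])
    }
  })
  lapply(out, sort)
}

# forward pass; returns list(H, P) for gradient reuse
.mlpForward <- function(Zx, W1, b1, W2, b2) {
  H <- tanh(sweep(Zx %*% W1, 2, b1, `+`))
  A <- sweep(H %*% W2, 2, b2, `+`)
  A <- A - apply(A, 1, max)                 # stable softmax
  P <- exp(A)
  P <- P / rowSums(P)
  list(H = H, P = P)
}

.unpack <- function(theta, nin, nh, nc) {
  i <- 0L
  W1 <- matrix(theta[i + seq_len(nin * nh)], nin, nh); i <- i + nin * nh
  b1 <- theta[i + seq_len(nh)]; i <- i + nh
  W2 <- matrix(theta[i + seq_len(nh * nc)], nh, nc); i <- i + nh * nc
  b2 <- theta[i + seq_len(nc)]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

# mean categorical cross-entropy and its analytic gradient (internal;
# finite-difference-checked in the test suite)
.mlpLossGrad <- function(theta, Zx, Tmat, nin, nh, nc, wantGrad = TRUE) {
  p <- .unpack(theta, nin, nh, nc)
  fw <- .mlpForward(Zx, p$W1, p$b1, p$W2, p$b2)
  n <- nrow(Zx)
  loss <- -mean(log(pmax(rowSums(Tmat * fw$P), 1e-300)))
  if (!wantGrad) return(list(loss = loss))
  dA <- (fw$P - Tmat) / n
  gW2 <- crossprod(fw$H, dA)
  gb2 <- colSums(dA)
  dH <- (dA %*% t(p$W2)) * (1 - fw$H^2)
  gW1 <- crossprod(Zx, dH)
  gb1 <- colSums(dH)
  list(loss = loss, grad = c(as.numeric(gW1), gb1, as.numeric(gW2), gb2))
}

#' Train the MLP classifier
#'
#' Fits a single-hidden-layer perceptron (tanh hidden units, softmax
#' output) under mean categorical cross-entropy.  Inputs are z-scored
#' with the training-set statistics.  The default optimizer is full-batch
#' BFGS (quasi-Newton with line search) run for at most `iters`
#' iterations from small seeded random initial weights (uniform in
#' \[-0.1, 0.1\]); when a validation set is supplied, the weights with
#' the best validation loss seen during optimisation are retained.  A
#' momentum-SGD fallback (`optimizer = "sgd"`, with `lr` and `momentum`)
#' is provided for comparison.
#'
#' @param x Training feature matrix (cases x features).
#' @param y Training labels (character or factor).
#' @param xval,yval Optional validation set.
#' @param hidden Hidden-layer size (default 8).
#' @param iters Maximum optimizer iterations (default 100).
#' @param seed Integer seed for weight initialisation.
#' @param classes Class label ordering of the output layer.
#' @param optimizer `"bfgs"` (default) or `"sgd"`.
#' @param lr,momentum Used by the SGD fallback only.
#'
#' @return An [MLPModel-class].
#' @export
trainMLP <- function(x, y, xval = NULL, yval = NULL, hidden = 8, iters = 100,
                     seed = 1, classes = sort(unique(as.character(y))),
                     optimizer = c("bfgs", "sgd"), lr = 0.1, momentum = 0.3) {
  optimizer <- match.arg(optimizer)
  x <- as.matrix(x)
  y <- as.character(y)
  stopIfNot(nrow(x) == length(y), "'x' and 'y' sizes disagree")
  stopIfNot(length(classes) >= 2,
            "training set must contain at least two classes")
  stopIfNot(all(y %in% classes), "labels outside 'classes'")

  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  Zx <- sweep(sweep(x, 2, ctr), 2, scl, `/`)
  Tmat <- outer(y, classes, `==`) * 1
  nin <- ncol(x); nh <- as.integer(hidden); nc <- length(classes)
  nPar <- nin * nh + nh + nh * nc + nc

  Zv <- NULL; Tv <- NULL
  if (!is.null(xval)) {
    Zv <- sweep(sweep(as.matrix(xval), 2, ctr), 2, scl, `/`)
    Tv <- outer(as.character(yval), classes, `==`) * 1
  }

  theta0 <- withSeed(seed, stats::runif(nPar, -0.1, 0.1))

  trace <- new.env(parent = emptyenv())
  trace$train <- numeric(0)
  trace$val <- numeric(0)
  trace$best <- theta0
  trace$bestVal <- Inf

  # record training/validation loss at accepted iterates only: BFGS
  # evaluates the gradient once per accepted step, while the objective is
  # also probed at line-search trial points that never become iterates
  recordPoint <- function(theta) {
    r <- .mlpLossGrad(theta, Zx, Tmat, nin, nh, nc, wantGrad = FALSE)
    trace$train <- c(trace$train, r$loss)
    if (!is.null(Zv)) {
      v <- .mlpLossGrad(theta, Zv, Tv, nin, nh, nc, wantGrad = FALSE)$loss
      trace$val <- c(trace$val, v)
      if (v < trace$bestVal) {
        trace$bestVal <- v
        trace$best <- theta
      }
    }
    r$loss
  }

  if (optimizer == "bfgs") {
    fit <- stats::optim(
      theta0,
      fn = function(theta)
        .mlpLossGrad(theta, Zx, Tmat, nin, nh, nc, wantGrad = FALSE)$loss,
      gr = function(theta) {
        recordPoint(theta)
        .mlpLossGrad(theta, Zx, Tmat, nin, nh, nc)$grad
      },
      method = "BFGS",
      control = list(maxit = as.integer(iters), reltol = 1e-10)
    )
    if (is.null(Zv) || !length(trace$train)) recordPoint(fit$par)
    thetaFinal <- fit$par
  } else {
    theta <- theta0
    vel <- numeric(nPar)
    for (it in seq_len(iters)) {
      g <- .mlpLossGrad(theta, Zx, Tmat, nin, nh, nc)$grad
      vel <- momentum * vel - lr * g
      theta <- theta + vel
      recordPoint(theta)
    }
    thetaFinal <- theta
  }

  thetaBest <- if (!is.null(Zv)) trace$best else thetaFinal
  p <- .unpack(thetaBest, nin, nh, nc)
  new("MLPModel", W1 = p$W1, b1 = p$b1, W2 = p$W2, b2 = p$b2,
      center = ctr, scale = scl, classes = classes,
      trainLoss = trace$train, valLoss = trace$val)
}

#' Class-membership probabilities
#'
#' Softmax outputs of the trained network, one probability row per case
#' (rows sum to 1); the argmax column is the predicted class and the row
#' maximum is the classification certainty.
#'
#' @param model An [MLPModel-class].
#' @param x Feature matrix (cases x features).
#' @return Numeric matrix, cases x classes, with class column names.
#' @export
predictProba <- function(model, x) {
  stopIfNot(is(model, "MLPModel"), "'model' must be an MLPModel")
  x <- as.matrix(x)
  stopIfNot(ncol(x) == nrow(model@W1),
            sprintf("feature dimension %d does not match model input %d",
                    ncol(x), nrow(model@W1)))
  Zx <- sweep(sweep(x, 2, model@center), 2, model@scale, `/`)
  P <- .mlpForward(Zx, model@W1, model@b1, model@W2, model@b2)$P
  colnames(P) <- model@classes
  P
}

#' Evaluate a classifier on a test set
#'
#' Computes the confusion matrix (true classes in rows), overall accuracy
#' `acc = Nc / Nt`, error rate `eps = 1 - acc`, per-class accuracy
#' (confusion diagonal over row sums) and the per-case certainty (maximum
#' output probability).
#'
#' @param model An [MLPModel-class].
#' @param x Test feature matrix.
#' @param labels True labels.
#' @return A [ClassificationReport-class].
#' @export
evaluateModel <- function(model, x, labels) {
  labels <- as.character(labels)
  stopIfNot(length(labels) >= 1L, "test set must be non-empty")
  stopIfNot(nrow(as.matrix(x)) == length(labels),
            "'x' and 'labels' sizes disagree")
  P <- predictProba(model, x)
  pred <- model@classes[max.col(P, ties.method = "first")]
  cls <- model@classes
  conf <- table(factor(labels, levels = cls), factor(pred, levels = cls))
  conf <- unclass(as.matrix(conf))
  acc <- sum(diag(conf)) / sum(conf)
  rs <- rowSums(conf)
  perClass <- ifelse(rs > 0, diag(conf) / rs, NA_real_)
  names(perClass) <- cls
  new("ClassificationReport", confusion = conf, accuracy = acc,
      errorRate = 1 - acc, perClass = perClass,
      certainty = apply(P, 1, max), predicted = pred)
}

#' Serialise / restore an MLP model as JSON
#'
#' Flat numeric arrays (row-major weight matrices) plus the input
#' standardization and class ordering.
#'
#' @param model An [MLPModel-class].
#' @param path File path.
#' @return `writeMLPModel()` returns `path` invisibly; `readMLPModel()` an
#'   [MLPModel-class].
#' @export
writeMLPModel <- function(model, path) {
  stopIfNot(is(model, "MLPModel"), "'model' must be an MLPModel")
  jsonlite::write_json(list(
    sizes = c(nrow(model@W1), ncol(model@W1), ncol(model@W2)),
    W1 = as.numeric(t(model@W1)), b1 = model@b1,
    W2 = as.numeric(t(model@W2)), b2 = model@b2,
    center = model@center, scale = model@scale, classes = model@classes,
    trainLoss = model@trainLoss, valLoss = model@valLoss
  ), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname writeMLPModel
#' @export
readMLPModel <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  s <- as.integer(o$sizes)
  new("MLPModel",
      W1 = matrix(o$W1, s[1], s[2], byrow = TRUE), b1 = as.numeric(o$b1),
      W2 = matrix(o$W2, s[2], s[3], byrow = TRUE), b2 = as.numeric(o$b2),
      center = as.numeric(o$center), scale = as.numeric(o$scale),
      classes = as.character(o$classes),
      trainLoss = as.numeric(o$trainLoss),
      valLoss = as.numeric(o$valLoss))
}
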