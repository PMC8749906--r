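# Configuration-driven end-to-end runs: synthesize -> analyse -> features
# (PCA residual distances or SOM winner sequences) -> stratified split ->
# MLP training -> evaluation, with on-disk artifacts and a comparison of
# the two feature-extraction arms.

#' Build a validated pipeline run configuration
#'
#' @param seed Master integer seed; every stage derives its own sub-seed
#'   from it, so a run is a pure function of the configuration.
#' @param classCounts Per-class utterance counts (default: the corpus
#'   composition of [generateDataset()]).
#' @param difficulty Synthetic-speech difficulty, `"easy"` or `"hard"`.
#' @param featureMethod `"pca"` or `"som"`.
#' @param lOverride Retained component count for the PCA arm (default 4;
#'   `NULL` for per-sample selection).
#' @param plan Split plan (default [defaultSplitPlan()], scaled to
#'   `classCounts` when those differ from the canonical corpus).
#' @param som Named list of SOM hyperparameters (`gridShape`, `epochs`,
#'   `lr`, `nbStart`).
#' @param mlp Named list of MLP hyperparameters (`hidden`, `iters`).
#' @param outDir Optional artifact directory (`NULL`: nothing written).
#' @return A list of class `"RunConfig"`.
#' @export
runConfig <- function(seed = 0,
                      classCounts = c(block = 55, repetition = 46,
                                      prolongation = 59, fluent = 38),
                      difficulty = c("easy", "hard"),
                      featureMethod = c("pca", "som"),
                      lOverride = 4,
                      plan = NULL,
                      som = list(gridShape = c(5L, 5L), epochs = 100,
                                 lr = 0.1, nbStart = 3),
                      mlp = list(hidden = 8, iters = 100),
                      outDir = NULL) {
  difficulty <- match.arg(difficulty)
  featureMethod <- match.arg(featureMethod)
  cc <- unlist(classCounts)
  stopIfNot(all(cc >= 0), "class counts must be non-negative")
  if (is.null(plan)) {
    plan <- defaultSplitPlan()
    canonical <- c(block = 55, repetition = 46, prolongation = 59,
                   fluent = 38)
    if (!isTRUE(all.equal(as.numeric(cc[plan$label]),
                          as.numeric(canonical[plan$label])))) {
      # proportional fallback plan: ~70/15/15 per class, at least 1 test case
      plan <- data.frame(label = names(cc))
      plan$train <- pmax(1L, floor(0.7 * cc))
      plan$validation <- pmax(1L, floor(0.15 * cc))
      plan$test <- cc - plan$train - plan$validation
      stopIfNot(all(plan$test >= 1),
                "class counts too small for an automatic split plan")
    }
  }
  structure(list(seed = as.integer(seed), classCounts = cc,
                 difficulty = difficulty, featureMethod = featureMethod,
                 lOverride = lOverride, plan = plan, som = som, mlp = mlp,
                 outDir = outDir),
            class = "RunConfig")
}

# stage sub-seeds, kept within 32-bit integer range
.stageSeed <- function(seed, stage) {
  deriveSeed(seed, match(stage, c("dataset", "split", "som", "mlp")) * 131L)
}

#' Run the full recognition pipeline
#'
#' Executes every stage of the configured run: synthesize the labelled
#' dataset, analyse each utterance into a 171 x 21 band-level matrix,
#' extract per-sample features (PCA residual distances or SOM winner
#' sequences), split stratified into training/validation/test, train the
#' MLP and evaluate it on the test partition.  When `config$outDir` is
#' set, the feature table, split manifest, model JSON, report JSON and a
#' resolved copy of the configuration are written there.
#'
#' @param config A configuration from [runConfig()].
#' @param dataset Optional pre-built [SpeechSet-class]; when supplied the
#'   synthesis stage is skipped (used to run both feature arms on the
#'   identical data).
#' @param filterbanks Optional pre-computed list of
#'   [FilterbankMatrix-class], skipping the front-end stage.
#' @return A list with elements `report` ([ClassificationReport-class]),
#'   `model`, `features`, `split`, `trainReport`, `validationReport`,
#'   and `config`.
#' @examples
#' \donttest{
#' cfg <- runConfig(seed = 0, classCounts = c(block = 8, repetition = 8,
#'                                            prolongation = 8, fluent = 8),
#'                  som = list(gridShape = c(5L, 5L), epochs = 10,
#'                             lr = 0.1, nbStart = 3),
#'                  mlp = list(hidden = 8, iters = 40))
#' res <- runPipeline(cfg)
#' accuracy(res$report)
#' }
#' @export
runPipeline <- function(config, dataset = NULL, filterbanks = NULL) {
  stopIfNot(inherits(config, "RunConfig"),
            "'config' must come from runConfig()")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  if (is.null(filterbanks)) {
    if (is.null(dataset))
      dataset <- stage("synthesize",
        generateDataset(config$classCounts,
                        seed = .stageSeed(config$seed, "dataset"),
                        difficulty = config$difficulty))
    filterbanks <- stage("frontend", analyzeDataset(dataset))
  }
  labels <- vapply(filterbanks, utteranceLabel, character(1))

  feats <- stage("features", switch(config$featureMethod,
    pca = featureTable(filterbanks, lOverride = config$lOverride),
    som = {
      som <- trainSOM(filterbanks,
                      gridShape = config$som$gridShape,
                      epochs = config$som$epochs, lr = config$som$lr,
                      nbStart = config$som$nbStart,
                      seed = .stageSeed(config$seed, "som"))
      w <- winnerTable(filterbanks, som)
      attr(w, "somModel") <- som
      w
    }))

  split <- stage("split",
    splitDataset(labels, plan = config$plan,
                 seed = .stageSeed(config$seed, "split")))

  model <- stage("train",
    trainMLP(feats[split$train, , drop = FALSE], labels[split$train],
             xval = feats[split$validation, , drop = FALSE],
             yval = labels[split$validation],
             hidden = config$mlp$hidden, iters = config$mlp$iters,
             seed = .stageSeed(config$seed, "mlp"),
             classes = disfluencyClasses()))

  report <- stage("evaluate",
    evaluateModel(model, feats[split$test, , drop = FALSE],
                  labels[split$test]))
  trainReport <- evaluateModel(model, feats[split$train, , drop = FALSE],
                               labels[split$train])
  valReport <- evaluateModel(model, feats[split$validation, , drop = FALSE],
                             labels[split$validation])

  res <- list(report = report, trainReport = trainReport,
              validationReport = valReport, model = model,
              features = feats, split = split, labels = labels,
              config = config)
  if (!is.null(config$outDir)) writeRunArtifacts(res, config$outDir)
  res
}

# Write the artifacts of a finished run under one directory.
writeRunArtifacts <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  feats <- res$features
  ft <- data.frame(id = rownames(feats), label = res$labels, feats,
                   check.names = FALSE)
  utils::write.table(ft, file.path(dir, "features.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  part <- rep(NA_character_, nrow(feats))
  part[res$split$train] <- "train"
  part[res$split$validation] <- "validation"
  part[res$split$test] <- "test"
  splitDf <- data.frame(id = rownames(feats), partition = part)
  utils::write.table(splitDf, file.path(dir, "split.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  writeMLPModel(res$model, file.path(dir, "model.json"))
  writeReport(res$report, file.path(dir, "report.json"))
  cfg <- res$config
  cfg$plan <- as.list(cfg$plan)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  jsonlite::write_json(
    list(files = list.files(dir), featureMethod = res$config$featureMethod,
         seed = res$config$seed),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Serialise a classification report as JSON
#'
#' @param report A [ClassificationReport-class].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
writeReport <- function(report, path) {
  stopIfNot(is(report, "ClassificationReport"),
            "'report' must be a ClassificationReport")
  jsonlite::write_json(list(
    accuracy = report@accuracy, errorRate = report@errorRate,
    perClass = as.list(report@perClass),
    confusion = list(classes = rownames(report@confusion),
                     counts = as.numeric(t(report@confusion))),
    certainty = report@certainty, predicted = report@predicted
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run both feature-extraction arms on identical data
#'
#' Generates one synthetic dataset, runs the PCA-residual arm and the
#' SOM-winner arm on the very same filterbank matrices and split seed,
#' and assembles comparison tables in the layout of the study's summary:
#' recognition rates (training/validation/test, %) per arm, overall
#' accuracy and error rate per arm, and per-class test accuracy (%).
#'
#' @param config A [runConfig()] configuration; its `featureMethod` is
#'   ignored (both arms run).
#' @return List with `pca` and `som` full results plus data.frames
#'   `rates`, `accError`, `perClass`.
#' @export
compareArms <- function(config) {
  dataset <- generateDataset(config$classCounts,
                             seed = .stageSeed(config$seed, "dataset"),
                             difficulty = config$difficulty)
  filterbanks <- analyzeDataset(dataset)
  cfgP <- config; cfgP$featureMethod <- "pca"
  cfgS <- config; cfgS$featureMethod <- "som"
  resP <- runPipeline(cfgP, filterbanks = filterbanks)
  resS <- runPipeline(cfgS, filterbanks = filterbanks)
  pct <- function(x) round(100 * x, 2)
  rates <- data.frame(
    method = c("PCA", "SOM"),
    training = c(pct(accuracy(resP$trainReport)),
                 pct(accuracy(resS$trainReport))),
    validation = c(pct(accuracy(resP$validationReport)),
                   pct(accuracy(resS$validationReport))),
    test = c(pct(accuracy(resP$report)), pct(accuracy(resS$report)))
  )
  accError <- data.frame(
    method = c("PCA", "SOM"),
    acc = c(accuracy(resP$report), accuracy(resS$report)),
    errorRate = c(errorRate(resP$report), errorRate(resS$report))
  )
  perClass <- rbind(PCA = pct(perClassAccuracy(resP$report)),
                    SOM = pct(perClassAccuracy(resS$report)))
  list(pca = resP, som = resS, rates = rates, accError = accError,
       perClass = as.data.frame(perClass))
}

#' Plot the residual-distance trace of one sample
#'
#' Distance-versus-time curve of a residual-distance feature vector: one
#' point per analysis frame, at the frame midpoints (0 to ~3.97 s for the
#' canonical 171-frame sample).  Low-distance stretches correspond to
#' silence, which the per-utterance PCA model treats as its baseline;
#' voiced and high-frequency fragments stand off the model.
#'
#' @param sample The [FilterbankMatrix-class] the features came from.
#' @param features Residual-distance vector from [extractFeatures()].
#' @param out Output image path (PNG).
#' @param width,height,res Device geometry passed to [grDevices::png()].
#' @return `out`, invisibly.
#' @export
plotDistanceTrace <- function(sample, features, out, width = 800,
                              height = 400, res = 96) {
  stopIfNot(is(sample, "FilterbankMatrix"),
            "'sample' must be a FilterbankMatrix")
  stopIfNot(length(features) == nrow(bandLevels(sample)),
            "feature length does not match the sample's frame count")
  tt <- (seq_along(features) - 0.5) * frameDuration(sample)
  grDevices::png(out, width = width, height = height, res = res)
  on.exit(grDevices::dev.off())
  graphics::plot(tt, features, type = "l", xlab = "time [s]",
                 ylab = "distance from PCA model",
                 main = utteranceId(sample))
  invisible(out)
}
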