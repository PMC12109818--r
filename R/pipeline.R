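#' Feature-extraction configuration
#'
#' Bundles the parameters of the extraction pipeline with the defaults used
#' throughout: 3-s epochs, S-transform over 0.1-46 Hz with width 1, the six
#' default bands, entropy window k = 20 and 8 CSP components.
#'
#' @param epochLen epoch length in seconds.
#' @param fmin,fmax S-transform frequency range in Hz.
#' @param width S-transform window-width parameter.
#' @param bands band table, see [defaultBands()].
#' @param windowK entropy sliding-window width in samples (5, 10 or 20 in
#'   the reference protocol).
#' @param nCSP CSP components per binary model.
#' @return An `ExtractionConfig` object.
#' @export
extractionConfig <- function(epochLen = 3, fmin = 0.1, fmax = 46.0, width = 1,
                             bands = defaultBands(), windowK = 20, nCSP = 8) {
  new("ExtractionConfig", epochLen = as.numeric(epochLen),
      fmin = as.numeric(fmin), fmax = as.numeric(fmax),
      width = as.numeric(width), bands = .checkBands(bands),
      windowK = as.integer(windowK), nCSP = as.integer(nCSP))
}

#' @exportClass ExtractionConfig
#' @rdname extractionConfig
setClass("ExtractionConfig",
  representation(epochLen = "numeric", fmin = "numeric", fmax = "numeric",
                 width = "numeric", bands = "data.frame", windowK = "integer",
                 nCSP = "integer")
)

setValidity("ExtractionConfig", function(object) {
  if (object@epochLen <= 0) return("'epochLen' must be > 0")
  if (!(object@fmin > 0 && object@fmin < object@fmax))
    return("need 0 < fmin < fmax")
  if (object@windowK < 2L) return("'windowK' must be >= 2")
  if (object@nCSP < 2L || object@nCSP %% 2L != 0L)
    return("'nCSP' must be a positive even number")
  TRUE
})

setMethod("show", "ExtractionConfig", function(object) {
  cat(sprintf(
    "ExtractionConfig: %g s epochs, ST %g-%g Hz width %g, k=%d, %d CSP comps, bands: %s\n",
    object@epochLen, object@fmin, object@fmax, object@width, object@windowK,
    object@nCSP, paste(object@bands$name, collapse = ", ")))
})

#' Classifier specification
#'
#' The two classifier back ends of the evaluation protocol with their fixed
#' hyperparameters: an RBF-kernel SVM with `C = 20` and the `"scale"` gamma
#' heuristic `1 / (n_features * var(X))`, and a random forest with 256
#' trees.  No tuning loop is applied.
#'
#' @param kind `"svm_rbf"` or `"random_forest"`.
#' @param C SVM soft-margin cost.
#' @param gamma `"scale"` or a numeric RBF width.
#' @param nTrees number of random-forest trees.
#' @param seed RNG seed used when fitting stochastic classifiers.
#' @return A `ClassifierSpec` object.
#' @export
classifierSpec <- function(kind = c("svm_rbf", "random_forest"), C = 20,
                           gamma = "scale", nTrees = 256, seed = 1) {
  kind <- match.arg(kind)
  obj <- new("ClassifierSpec")
  obj@kind <- kind
  obj@cost <- as.numeric(C)
  obj@gamma <- gamma
  obj@nTrees <- as.integer(nTrees)
  obj@seed <- as.integer(seed)
  obj
}

#' @exportClass ClassifierSpec
#' @rdname classifierSpec
setClass("ClassifierSpec",
  representation(kind = "character", cost = "numeric", gamma = "ANY",
                 nTrees = "integer", seed = "integer"),
  prototype(kind = "svm_rbf", cost = 20, gamma = "scale", nTrees = 256L,
            seed = 1L)
)

setMethod("show", "ClassifierSpec", function(object) {
  if (object@kind == "svm_rbf")
    cat(sprintf("ClassifierSpec: RBF-SVM, C=%g, gamma=%s, seed %d\n",
                object@cost, paste(object@gamma), object@seed))
  else
    cat(sprintf("ClassifierSpec: random forest, %d trees, seed %d\n",
                object@nTrees, object@seed))
})

.trainClassifier <- function(spec, X, y) {
  y <- factor(y)
  if (spec@kind == "svm_rbf") {
    g <- if (identical(spec@gamma, "scale")) {
      v <- stats::var(as.vector(X)) * (length(X) - 1) / length(X)
      1 / (ncol(X) * v)
    } else as.numeric(spec@gamma)
    e1071::svm(X, y, kernel = "radial", cost = spec@cost, gamma = g,
               scale = FALSE)
  } else {
    set.seed(spec@seed)
    randomForest::randomForest(X, y, ntree = spec@nTrees)
  }
}

.predictClassifier <- function(model, X) as.character(stats::predict(model, X))

#' Split a continuous recording into fixed-length epochs
#'
#' Consecutive non-overlapping windows of `round(epochLen * fs)` samples;
#' a trailing remainder shorter than one epoch is dropped.  The segment
#' label propagates to every epoch.
#'
#' @param recording channels x samples numeric matrix (or a
#'   [SignalEpoch-class], whose data and label are used).
#' @param fs sampling rate in Hz.
#' @param epochLen epoch length in seconds (default 3).
#' @param label emotion code attached to each epoch.
#' @return List of [SignalEpoch-class] objects.
#' @examples
#' eps <- epochSplit(matrix(rnorm(2 * 1350), 2), fs = 200, epochLen = 3,
#'                   label = 1)
#' length(eps)  # 2; 150 trailing samples dropped
#' @export
epochSplit <- function(recording, fs, epochLen = 3, label = NA_real_) {
  if (is(recording, "SignalEpoch")) {
    if (is.na(label)) label <- recording@label
    fs <- recording@fs
    recording <- recording@data
  }
  if (is.vector(recording)) recording <- matrix(recording, nrow = 1L)
  n <- round(epochLen * fs)
  nEp <- ncol(recording) %/% n
  if (nEp < 1L) stop("recording shorter than one epoch")
  lapply(seq_len(nEp), function(i) {
    signalEpoch(recording[, ((i - 1L) * n + 1L):(i * n), drop = FALSE],
                fs = fs, label = label, t0 = (i - 1L) * n / fs)
  })
}

#' Band series for a list of epochs
#'
#' Runs the S-transform and magnitude band grouping on every epoch.  This
#' is the expensive stage of the pipeline; the result can be reused across
#' entropy window widths and bands.
#'
#' @param epochs list of [SignalEpoch-class].
#' @param cfg an [extractionConfig()].
#' @return List of [BandSeries-class], one per epoch.
#' @export
epochBandSeries <- function(epochs, cfg = extractionConfig()) {
  lapply(epochs, function(ep)
    bandGroup(stransform(ep, fmin = cfg@fmin, fmax = cfg@fmax,
                         width = cfg@width), cfg@bands))
}

#' Per-epoch entropy matrices for one band
#'
#' @param bsList list of [BandSeries-class] from [epochBandSeries()].
#' @param band band name (must appear in the band table).
#' @param k entropy window width.
#' @return List of channels x (N - k + 1) matrices.
#' @export
bandEntropy <- function(bsList, band, k) {
  bandsTab <- bsList[[1L]]@bands
  b <- match(band, bandsTab$name)
  if (is.na(b)) stop("unknown band '", band, "'")
  lapply(bsList, function(bs) {
    v <- bs@values[, b, , drop = FALSE]
    dim(v) <- dim(v)[c(1L, 3L)]
    t(apply(v, 1L, slidingDE, k = k))
  })
}

#' Extract CSP feature tables per band
#'
#' Full extraction pipeline: S-transform, band grouping, Stockwell entropy
#' with window `cfg@windowK`, then CSP per band.  CSP filters are fitted on
#' the epochs in `trainIdx` only (all epochs by default) and applied to
#' every epoch.  With two classes in `labels` one binary model is fitted
#' per band (8 features); with three, one-vs-rest models are concatenated
#' (24 features).
#'
#' @param epochs list of labeled [SignalEpoch-class].
#' @param cfg an [extractionConfig()].
#' @param labels epoch labels; defaults to the labels carried by `epochs`.
#' @param trainIdx indices of epochs the CSP may see while fitting.
#' @return Named list of [FeatureTable-class], one per band.
#' @export
extractFeatures <- function(epochs, cfg = extractionConfig(),
                            labels = vapply(epochs, epochLabel, numeric(1)),
                            trainIdx = seq_along(epochs)) {
  classes <- intersect(c(1, 0, -1), unique(labels))
  if (any(table(labels[trainIdx]) < 2L))
    stop("need at least 2 training epochs per class")
  bsList <- epochBandSeries(epochs, cfg)
  out <- lapply(cfg@bands$name, function(bn) {
    ent <- bandEntropy(bsList, bn, cfg@windowK)
    models <- fitMulticlassCSP(ent[trainIdx], labels[trainIdx],
                               nComponents = cfg@nCSP, band = bn)
    X <- t(vapply(ent, function(e) multiclassFeatures(models, e),
                  numeric(length(models) * cfg@nCSP)))
    new("FeatureTable", X = X, y = as.numeric(labels), band = bn,
        window = cfg@windowK)
  })
  names(out) <- cfg@bands$name
  out
}

## deterministic stratified fold assignment
.stratifiedFolds <- function(y, nFolds, seed) {
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  folds <- integer(length(y))
  for (cl in unique(y)) {
    ix <- which(y == cl)
    folds[ix] <- sample(rep_len(seq_len(nFolds), length(ix)))
  }
  folds
}

.taskName <- function(y) {
  cls <- intersect(c(1, 0, -1), unique(y))
  if (length(cls) == 2L) paste(cls, collapse = " vs ") else "3-class"
}

#' Stratified k-fold cross-validation of the entropy-CSP pipeline
#'
#' Splits epochs into stratified folds and, within each fold, fits the CSP
#' spatial filters and the classifier on the training portion only before
#' scoring the held-out fold -- the spatial filters never see test data
#' (`leakCSP = TRUE` deliberately re-fits CSP on all epochs, for leakage
#' audits only).
#'
#' @param entropy list of channels x T entropy matrices (one per epoch),
#'   e.g. from [bandEntropy()].
#' @param labels epoch labels.
#' @param classifier a [classifierSpec()].
#' @param nFolds number of stratified folds (default 5).
#' @param seed RNG seed for the fold assignment.
#' @param nComponents CSP components per binary model.
#' @param leakCSP if `TRUE`, fit CSP on all epochs (audit mode; inflates
#'   accuracy estimates).
#' @param band,window metadata stored in the report.
#' @return A [CVReport-class].
#' @export
crossval <- function(entropy, labels, classifier = classifierSpec(),
                     nFolds = 5, seed = 1, nComponents = 8,
                     leakCSP = FALSE, band = NA_character_,
                     window = NA_integer_) {
  labels <- as.numeric(labels)
  if (any(table(labels) < nFolds))
    stop("every class needs at least nFolds epochs")
  folds <- .stratifiedFolds(labels, nFolds, seed)
  leakModels <- if (leakCSP)
    fitMulticlassCSP(entropy, labels, nComponents, band) else NULL
  acc <- vapply(seq_len(nFolds), function(fo) {
    tr <- folds != fo
    te <- !tr
    models <- if (leakCSP) leakModels else
      fitMulticlassCSP(entropy[tr], labels[tr], nComponents, band)
    Xtr <- t(vapply(entropy[tr], function(e) multiclassFeatures(models, e),
                    numeric(length(models) * nComponents)))
    Xte <- t(vapply(entropy[te], function(e) multiclassFeatures(models, e),
                    numeric(length(models) * nComponents)))
    fit <- .trainClassifier(classifier, Xtr, labels[tr])
    mean(.predictClassifier(fit, Xte) == as.character(labels[te]))
  }, numeric(1))
  new("CVReport", task = .taskName(labels), band = band,
      window = as.integer(window), folds = acc, accMean = mean(acc),
      accSd = stats::sd(acc), seed = as.numeric(seed),
      classifier = classifier@kind,
      details = list(mode = sprintf("cv%d", nFolds), nEpochs = length(labels),
                     leakCSP = leakCSP))
}

#' Stratified holdout evaluation of the entropy-CSP pipeline
#'
#' Single stratified train/test split (default 80/20); CSP and the
#' classifier are fitted on the training portion only.
#'
#' @inheritParams crossval
#' @param testFraction fraction of each class held out for testing.
#' @return A [CVReport-class] whose `folds` slot holds the single holdout
#'   accuracy.
#' @export
holdoutEval <- function(entropy, labels, classifier = classifierSpec(),
                        testFraction = 0.2, seed = 1, nComponents = 8,
                        band = NA_character_, window = NA_integer_) {
  labels <- as.numeric(labels)
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  te <- logical(length(labels))
  for (cl in unique(labels)) {
    ix <- which(labels == cl)
    nTest <- max(1L, round(testFraction * length(ix)))
    te[sample(ix, nTest)] <- TRUE
  }
  if (any(table(labels[!te]) < 2L)) stop("training class too small after split")
  models <- fitMulticlassCSP(entropy[!te], labels[!te], nComponents, band)
  Xtr <- t(vapply(entropy[!te], function(e) multiclassFeatures(models, e),
                  numeric(length(models) * nComponents)))
  Xte <- t(vapply(entropy[te], function(e) multiclassFeatures(models, e),
                  numeric(length(models) * nComponents)))
  fit <- .trainClassifier(classifier, Xtr, labels[!te])
  acc <- mean(.predictClassifier(fit, Xte) == as.character(labels[te]))
  new("CVReport", task = .taskName(labels), band = band,
      window = as.integer(window), folds = acc, accMean = acc, accSd = 0,
      seed = as.numeric(seed), classifier = classifier@kind,
      details = list(mode = "holdout", testFraction = testFraction,
                     nEpochs = length(labels), nTest = sum(te)))
}

#' Evaluate one band/window/task combination end to end
#'
#' Convenience wrapper: selects the epochs belonging to `task`, computes
#' band entropy and runs [crossval()] or [holdoutEval()].
#'
#' @param bsList list of [BandSeries-class] from [epochBandSeries()].
#' @param labels labels for `bsList`.
#' @param band band name.
#' @param k entropy window width.
#' @param task numeric vector of class codes to include, e.g. `c(1, -1)`,
#'   or `NULL` for all three.
#' @param classifier a [classifierSpec()].
#' @param mode `"cv"` (stratified 5-fold) or `"holdout"` (80/20).
#' @param seed RNG seed for the split.
#' @param nComponents CSP components per binary model.
#' @return A [CVReport-class].
#' @export
evaluateTask <- function(bsList, labels, band = "gamma", k = 20, task = NULL,
                         classifier = classifierSpec(), mode = c("cv", "holdout"),
                         seed = 1, nComponents = 8) {
  mode <- match.arg(mode)
  labels <- as.numeric(labels)
  keep <- if (is.null(task)) rep(TRUE, length(labels)) else labels %in% task
  ent <- bandEntropy(bsList[keep], band, k)
  if (mode == "cv")
    crossval(ent, labels[keep], classifier, seed = seed,
             nComponents = nComponents, band = band, window = k)
  else
    holdoutEval(ent, labels[keep], classifier, seed = seed,
                nComponents = nComponents, band = band, window = k)
}
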