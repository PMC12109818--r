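## Spatial second-moment matrix of one epoch, normalized to unit trace.
## Moments are taken about zero (uncentered): for Stockwell-entropy epochs
## the class information is a level shift of the entropy, which centering
## would destroy; for zero-mean signals this is the ordinary covariance.
.epochCov <- function(x) {
  C <- tcrossprod(x) / ncol(x)
  tr <- sum(diag(C))
  if (tr <= 0) stop("epoch has zero total power; cannot normalize covariance")
  C / tr
}

#' Fit a binary common-spatial-pattern model
#'
#' Averages the trace-normalized spatial covariance of each class and
#' solves the generalized eigenproblem `Ca w = lambda (Ca + Cb) w` (via
#' whitening of the composite covariance).  The retained filters are the
#' `nComponents / 2` eigenvectors with the largest and the
#' `nComponents / 2` with the smallest eigenvalues -- the directions whose
#' variance ratio between the two classes is most extreme -- ordered by
#' descending eigenvalue.  The first nonzero entry of each filter is forced
#' positive for reproducibility.
#'
#' If the composite covariance is numerically rank deficient a small ridge
#' `delta * I`, `delta = 1e-8 * trace / channels`, is added with a warning.
#'
#' @param epochsA,epochsB lists of channels x T numeric matrices (entropy
#'   series per epoch), one list per class.
#' @param nComponents even number of filters to retain (default 8).
#' @param classPair length-2 labels stored in the model.
#' @param band optional band name stored in the model.
#' @return A [CSPModel-class].
#' @examples
#' a <- replicate(6, diag(c(3, 1)) %*% matrix(rnorm(40), 2), simplify = FALSE)
#' b <- replicate(6, diag(c(1, 3)) %*% matrix(rnorm(40), 2), simplify = FALSE)
#' fitCSP(a, b, nComponents = 2)
#' @export
fitCSP <- function(epochsA, epochsB, nComponents = 8,
                   classPair = c("A", "B"), band = NA_character_) {
  if (!length(epochsA) || !length(epochsB))
    stop("both classes need at least one epoch")
  nch <- nrow(epochsA[[1L]])
  all_ok <- all(vapply(c(epochsA, epochsB), nrow, integer(1)) == nch)
  if (!all_ok) stop("all epochs must have the same channel count")
  if (ncol(epochsA[[1L]]) < 2L) stop("epochs need at least 2 time samples")
  nComponents <- as.integer(nComponents)
  if (nComponents %% 2L != 0L) stop("nComponents must be even")
  if (nComponents > nch) stop("nComponents cannot exceed the channel count")

  Ca <- Reduce(`+`, lapply(epochsA, .epochCov)) / length(epochsA)
  Cb <- Reduce(`+`, lapply(epochsB, .epochCov)) / length(epochsB)
  Cc <- Ca + Cb
  ec <- eigen(Cc, symmetric = TRUE)
  tol <- 1e-10 * max(ec$values)
  if (min(ec$values) < tol) {
    delta <- 1e-8 * sum(diag(Cc)) / nch
    warning("composite covariance is rank deficient; adding ridge ",
            format(delta))
    Cc <- Cc + delta * diag(nch)
    ec <- eigen(Cc, symmetric = TRUE)
  }
  P <- ec$vectors %*% diag(1 / sqrt(ec$values), nch) %*% t(ec$vectors)
  S <- P %*% Ca %*% P
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)         # eigenvalues descending
  W <- t(P %*% es$vectors)                 # rows: w' Ca w = lambda, w' Cc w = 1
  half <- nComponents / 2L
  sel <- c(seq_len(half), nch - rev(seq_len(half)) + 1L)
  W <- W[sel, , drop = FALSE]
  lambda <- es$values[sel]
  ## deterministic sign: first element exceeding tolerance made positive
  for (r in seq_len(nrow(W))) {
    nz <- which(abs(W[r, ]) > 1e-12)[1L]
    if (!is.na(nz) && W[r, nz] < 0) W[r, ] <- -W[r, ]
  }
  new("CSPModel", filters = W, eigenvalues = pmin(pmax(lambda, 0), 1),
      nComponents = nComponents,
      classPair = as.character(classPair), band = as.character(band))
}

#' @rdname cspFeatures
#' @section Feature map:
#' The epoch is projected onto the filters, `Z = W x`, and the feature for
#' component j is the normalized log-variance
#' `log(var(Z_j) / sum_m var(Z_m))`, with variances taken about zero (see
#' [fitCSP()]).  By construction `sum(exp(features)) == 1`.
#' @examples
#' a <- replicate(6, diag(c(3, 1)) %*% matrix(rnorm(40), 2), simplify = FALSE)
#' b <- replicate(6, diag(c(1, 3)) %*% matrix(rnorm(40), 2), simplify = FALSE)
#' m <- fitCSP(a, b, nComponents = 2)
#' cspFeatures(m, a[[1]])
#' @export
setMethod("cspFeatures", signature("CSPModel", "matrix"), function(model, x) {
  if (ncol(model@filters) != nrow(x))
    stop("epoch channel count (", nrow(x), ") does not match model (",
         ncol(model@filters), ")")
  Z <- model@filters %*% x
  v <- rowMeans(Z * Z)
  tot <- sum(v)
  if (tot <= 0) stop("degenerate epoch: zero total variance after projection")
  log(v / tot)
})

#' Fit one-vs-rest CSP models for a multiclass task
#'
#' Fits one binary CSP model per class present in `labels`, contrasting
#' that class against the pooled remaining epochs.  With exactly two
#' classes this reduces to a single binary model.  Feature vectors from the
#' per-class models are concatenated by [multiclassFeatures()], giving
#' `n_classes * nComponents` features (24 for three classes with the
#' default 8 components).
#'
#' @param epochs list of channels x T entropy matrices.
#' @param labels epoch labels (values in 1, 0, -1), same length as `epochs`.
#' @param nComponents components per binary model (default 8).
#' @param band optional band name stored in the models.
#' @return List of [CSPModel-class] objects (one per class; a single model
#'   for a binary problem).
#' @export
fitMulticlassCSP <- function(epochs, labels, nComponents = 8,
                             band = NA_character_) {
  labels <- as.numeric(labels)
  classes <- intersect(c(1, 0, -1), unique(labels))
  if (length(classes) < 2L) stop("need at least 2 classes")
  counts <- table(labels)
  if (any(counts < 2L))
    stop("every class needs at least 2 epochs; got counts ",
         paste(counts, collapse = ", "))
  if (length(classes) == 2L) {
    return(list(fitCSP(epochs[labels == classes[1L]],
                       epochs[labels == classes[2L]],
                       nComponents,
                       classPair = as.character(classes), band = band)))
  }
  lapply(classes, function(cl) {
    fitCSP(epochs[labels == cl], epochs[labels != cl], nComponents,
           classPair = c(as.character(cl), "rest"), band = band)
  })
}

#' Concatenated one-vs-rest CSP features for one epoch
#'
#' @param models list of [CSPModel-class] as from [fitMulticlassCSP()].
#' @param x channels x T entropy matrix.
#' @return Numeric vector of length `sum(nComponents)`.
#' @export
multiclassFeatures <- function(models, x) {
  unlist(lapply(models, cspFeatures, x = x), use.names = FALSE)
}

#' Serialize / restore a CSP model
#'
#' Plain-JSON serialization of filters, eigenvalues and metadata so fitted
#' models can be reused across sessions.
#'
#' @param model a [CSPModel-class].
#' @param path file path.
#' @return `writeCSPModel`: `path` invisibly; `readCSPModel`: the model.
#' @export
writeCSPModel <- function(model, path) {
  stopifnot(is(model, "CSPModel"))
  obj <- list(filters = model@filters, eigenvalues = model@eigenvalues,
              nComponents = model@nComponents, classPair = model@classPair,
              band = model@band)
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname writeCSPModel
#' @export
readCSPModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  f <- obj$filters
  if (!is.matrix(f)) f <- matrix(f, nrow = obj$nComponents, byrow = TRUE)
  new("CSPModel", filters = f,
      eigenvalues = as.numeric(obj$eigenvalues),
      nComponents = as.integer(obj$nComponents),
      classPair = as.character(obj$classPair),
      band = if (is.null(obj$band)) NA_character_ else as.character(obj$band))
}
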