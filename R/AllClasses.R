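#' @import methods
NULL

.EMOTION_CODES <- c(1, 0, -1)

#' SignalEpoch: one fixed-length multichannel window of signal
#'
#' A `SignalEpoch` holds a channels x samples matrix of real signal together
#' with its sampling rate and, optionally, an emotion-state label
#' (1 = positive, 0 = neutral, -1 = negative, `NA` = unlabeled).
#'
#' @slot data numeric matrix, channels x samples.
#' @slot fs sampling rate in Hz.
#' @slot label emotion code (1, 0, -1) or `NA_real_`.
#' @slot t0 epoch start time in seconds (provenance only).
#'
#' @seealso [signalEpoch()], [makeSignal()], [epochSplit()]
#' @exportClass SignalEpoch
setClass("SignalEpoch",
  representation(data = "matrix", fs = "numeric", label = "numeric",
                 t0 = "numeric"),
  prototype(fs = 200, label = NA_real_, t0 = 0)
)

setValidity("SignalEpoch", function(object) {
  if (!is.numeric(object@data)) return("'data' must be a numeric matrix")
  if (!all(is.finite(object@data))) return("'data' contains non-finite samples")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    return("'fs' must be a single positive number")
  if (length(object@label) != 1L ||
      !(is.na(object@label) || object@label %in% .EMOTION_CODES))
    return("'label' must be one of 1, 0, -1 or NA")
  if (length(object@t0) != 1L || !is.finite(object@t0))
    return("'t0' must be a single finite number")
  TRUE
})

#' Construct a SignalEpoch
#'
#' @param data numeric matrix (channels x samples) or a numeric vector,
#'   which is treated as a single channel.
#' @param fs sampling rate in Hz.
#' @param label emotion code 1, 0, -1 or `NA` for unlabeled data.
#' @param t0 epoch start time in seconds.
#' @return A [SignalEpoch-class] object.
#' @examples
#' ep <- signalEpoch(matrix(rnorm(2 * 400), 2), fs = 200)
#' nChannels(ep)
#' @export
signalEpoch <- function(data, fs = 200, label = NA_real_, t0 = 0) {
  if (is.vector(data)) data <- matrix(data, nrow = 1L)
  new("SignalEpoch", data = data, fs = as.numeric(fs),
      label = as.numeric(label), t0 = as.numeric(t0))
}

#' TimeFrequencyMap: complex S-transform coefficients
#'
#' Complex coefficients over channel x frequency x time as produced by
#' [stransform()].  The time axis has the same length as the input epoch;
#' analysis frequencies are multiples of 1/duration clipped to the requested
#' range (zero excluded).
#'
#' @slot coef complex array, channels x n_freqs x samples.
#' @slot freqs strictly increasing analysis frequencies in Hz.
#' @slot fs sampling rate in Hz.
#' @slot width dimensionless Gaussian window-width parameter.
#' @exportClass TimeFrequencyMap
setClass("TimeFrequencyMap",
  representation(coef = "array", freqs = "numeric", fs = "numeric",
                 width = "numeric")
)

setValidity("TimeFrequencyMap", function(object) {
  d <- dim(object@coef)
  if (length(d) != 3L) return("'coef' must be a 3-d array")
  if (length(object@freqs) != d[2L])
    return("length(freqs) must equal dim(coef)[2]")
  if (any(diff(object@freqs) <= 0))
    return("'freqs' must be strictly increasing")
  if (any(object@freqs <= 0) || any(object@freqs >= object@fs / 2))
    return("'freqs' must lie strictly inside (0, fs/2)")
  TRUE
})

#' BandSeries: per-band aggregated S-transform coefficient series
#'
#' Real-valued series over channel x band x time obtained by aggregating
#' S-transform coefficients within each frequency band, either as mean
#' magnitude ([bandGroup()], non-negative envelope-like series) or by
#' coherent phase-restored synthesis ([bandSynthesize()], an oscillating
#' band-limited reconstruction of the signal).
#'
#' @slot values numeric array, channels x n_bands x samples.
#' @slot bands band table (see [defaultBands()]).
#' @slot fs sampling rate in Hz.
#' @slot aggregation either `"magnitude"` or `"synthesis"`.
#' @exportClass BandSeries
setClass("BandSeries",
  representation(values = "array", bands = "data.frame", fs = "numeric",
                 aggregation = "character")
)

setValidity("BandSeries", function(object) {
  d <- dim(object@values)
  if (length(d) != 3L) return("'values' must be a 3-d array")
  if (!all(is.finite(object@values))) return("'values' contains non-finite entries")
  if (nrow(object@bands) != d[2L])
    return("nrow(bands) must equal dim(values)[2]")
  if (!object@aggregation %in% c("magnitude", "synthesis"))
    return("'aggregation' must be 'magnitude' or 'synthesis'")
  if (object@aggregation == "magnitude" && any(object@values < 0))
    return("magnitude aggregation cannot produce negative values")
  TRUE
})

#' EntropySeries: sliding-window differential entropy
#'
#' Sliding-window differential entropy over channel x band x window-position,
#' produced by [stockwellEntropy()].  For a source of N samples and a window
#' of k samples the position axis has exactly N - k + 1 entries.
#'
#' @slot values numeric array, channels x n_bands x (N - k + 1), in nats.
#' @slot window window width k in samples.
#' @slot sourceLen source series length N in samples.
#' @slot bands band table.
#' @exportClass EntropySeries
setClass("EntropySeries",
  representation(values = "array", window = "integer", sourceLen = "integer",
                 bands = "data.frame")
)

setValidity("EntropySeries", function(object) {
  d <- dim(object@values)
  if (length(d) != 3L) return("'values' must be a 3-d array")
  if (!all(is.finite(object@values))) return("'values' contains non-finite entries")
  if (d[3L] != object@sourceLen - object@window + 1L)
    return("position axis must have length sourceLen - window + 1")
  if (nrow(object@bands) != d[2L])
    return("nrow(bands) must equal dim(values)[2]")
  TRUE
})

#' CSPModel: fitted common-spatial-pattern filters
#'
#' Spatial filters obtained from the generalized eigendecomposition of two
#' class covariance matrices (see [fitCSP()]).  Rows of `filters` are
#' generalized eigenvectors ordered by descending eigenvalue; the retained
#' components are the extremes of the eigenvalue spectrum (half largest,
#' half smallest).
#'
#' @slot filters numeric matrix, n_components x channels.
#' @slot eigenvalues eigenvalues in [0, 1] of the retained components,
#'   descending.
#' @slot nComponents number of retained components (even).
#' @slot classPair labels of the two classes, the second possibly `"rest"`.
#' @slot band name of the frequency band the model was fitted on (or `NA`).
#' @exportClass CSPModel
setClass("CSPModel",
  representation(filters = "matrix", eigenvalues = "numeric",
                 nComponents = "integer", classPair = "character",
                 band = "character"),
  prototype(band = NA_character_)
)

setValidity("CSPModel", function(object) {
  if (nrow(object@filters) != object@nComponents)
    return("nrow(filters) must equal nComponents")
  if (object@nComponents %% 2L != 0L)
    return("nComponents must be even")
  if (length(object@eigenvalues) != object@nComponents)
    return("length(eigenvalues) must equal nComponents")
  if (any(object@eigenvalues < -1e-8) || any(object@eigenvalues > 1 + 1e-8))
    return("eigenvalues must lie in [0, 1]")
  if (is.unsorted(rev(object@eigenvalues), strictly = FALSE))
    return("eigenvalues must be sorted in descending order")
  if (length(object@classPair) != 2L)
    return("classPair must have length 2")
  TRUE
})

#' FeatureTable: per-epoch CSP log-variance features
#'
#' @slot X numeric matrix, n_epochs x n_features (8 per fitted binary CSP
#'   model; concatenated across one-vs-rest models for multiclass tasks).
#' @slot y epoch labels (1, 0, -1).
#' @slot band band name.
#' @slot window entropy window width k.
#' @exportClass FeatureTable
setClass("FeatureTable",
  representation(X = "matrix", y = "numeric", band = "character",
                 window = "integer")
)

setValidity("FeatureTable", function(object) {
  if (!all(is.finite(object@X))) return("'X' contains non-finite entries")
  if (nrow(object@X) != length(object@y))
    return("nrow(X) must equal length(y)")
  if (!all(object@y %in% .EMOTION_CODES))
    return("'y' values must be in {1, 0, -1}")
  TRUE
})

#' CVReport: accuracy report for one evaluation run
#'
#' Per-fold (or single-holdout) accuracies with their mean and standard
#' deviation, plus the task, band, entropy window and seed that produced
#' them.
#'
#' @slot task task description, e.g. `"1 vs 0"` or `"3-class"`.
#' @slot band band name.
#' @slot window entropy window width k.
#' @slot folds per-fold (or holdout) accuracies in [0, 1].
#' @slot accMean mean accuracy.
#' @slot accSd standard deviation of fold accuracies.
#' @slot seed RNG seed used for the splits.
#' @slot classifier classifier kind (`"svm_rbf"` or `"random_forest"`).
#' @slot details free-form metadata (mode, number of epochs, ...).
#' @exportClass CVReport
setClass("CVReport",
  representation(task = "character", band = "character", window = "integer",
                 folds = "numeric", accMean = "numeric", accSd = "numeric",
                 seed = "numeric", classifier = "character", details = "list"),
  prototype(band = NA_character_, window = NA_integer_, details = list())
)

setValidity("CVReport", function(object) {
  if (any(object@folds < 0) || any(object@folds > 1))
    return("fold accuracies must lie in [0, 1]")
  if (abs(object@accMean - mean(object@folds)) > 1e-8)
    return("accMean inconsistent with folds")
  sdref <- if (length(object@folds) > 1L) stats::sd(object@folds) else 0
  if (abs(object@accSd - sdref) > 1e-8)
    return("accSd inconsistent with folds")
  TRUE
})

#' SessionContainer: a recording session of labeled segments
#'
#' An ordered collection of continuous multichannel segments sharing one
#' sampling rate, each carrying an emotion label.  This is the unit written
#' and read by [writeSession()] / [readSession()].
#'
#' @slot segments list of [SignalEpoch-class] objects.
#' @slot fs sampling rate in Hz.
#' @slot subject subject identifier.
#' @slot session session identifier.
#' @exportClass SessionContainer
setClass("SessionContainer",
  representation(segments = "list", fs = "numeric", subject = "character",
                 session = "character"),
  prototype(subject = "synthetic", session = "1")
)

setValidity("SessionContainer", function(object) {
  if (!all(vapply(object@segments, is, logical(1), "SignalEpoch")))
    return("'segments' must be a list of SignalEpoch objects")
  fss <- vapply(object@segments, function(s) s@fs, numeric(1))
  if (length(fss) && any(fss != object@fs))
    return("all segments must share the container sampling rate")
  TRUE
})
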