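#' Discrete Stockwell (S-)transform
#'
#' @param x a [SignalEpoch-class] or a channels x samples numeric matrix.
#' @param ... passed to methods; see [stransform,SignalEpoch-method].
#' @return A [TimeFrequencyMap-class].
#' @export
setGeneric("stransform", function(x, ...) standardGeneric("stransform"))

#' Group S-transform coefficients into frequency bands (mean magnitude)
#'
#' @param tfr a [TimeFrequencyMap-class].
#' @param bands a band table as returned by [defaultBands()].
#' @return A [BandSeries-class] with `aggregation = "magnitude"`.
#' @export
setGeneric("bandGroup", function(tfr, bands = defaultBands())
  standardGeneric("bandGroup"))

#' Coherent band-limited synthesis from S-transform coefficients
#'
#' @param tfr a [TimeFrequencyMap-class].
#' @param bands a band table as returned by [defaultBands()].
#' @return A [BandSeries-class] with `aggregation = "synthesis"`.
#' @export
setGeneric("bandSynthesize", function(tfr, bands = defaultBands())
  standardGeneric("bandSynthesize"))

#' Sliding-window differential entropy of a BandSeries
#'
#' @param x a [BandSeries-class].
#' @param k sliding-window width in samples.
#' @param ... passed on to [slidingDE()].
#' @return An [EntropySeries-class].
#' @export
setGeneric("stockwellEntropy", function(x, k, ...)
  standardGeneric("stockwellEntropy"))

#' CSP log-variance features for one epoch
#'
#' @param model a [CSPModel-class].
#' @param x channels x T numeric matrix of per-epoch entropy series.
#' @return Numeric vector of length `nComponents(model)`.
#' @export
setGeneric("cspFeatures", function(model, x) standardGeneric("cspFeatures"))

## ---- small accessor generics ------------------------------------------

#' @rdname accessors
#' @param object an object of one of the package classes.
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))

#' @rdname accessors
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("epochData", function(object) standardGeneric("epochData"))

#' @rdname accessors
#' @export
setGeneric("epochLabel", function(object) standardGeneric("epochLabel"))

#' @rdname accessors
#' @export
setGeneric("tfrCoef", function(object) standardGeneric("tfrCoef"))

#' @rdname accessors
#' @export
setGeneric("tfrFreqs", function(object) standardGeneric("tfrFreqs"))

#' @rdname accessors
#' @export
setGeneric("bandValues", function(object) standardGeneric("bandValues"))

#' @rdname accessors
#' @export
setGeneric("bandTable", function(object) standardGeneric("bandTable"))

#' @rdname accessors
#' @export
setGeneric("entropyValues", function(object) standardGeneric("entropyValues"))

#' @rdname accessors
#' @export
setGeneric("cspFilters", function(object) standardGeneric("cspFilters"))

#' @rdname accessors
#' @export
setGeneric("cspEigenvalues", function(object) standardGeneric("cspEigenvalues"))

#' @rdname accessors
#' @export
setGeneric("nComponents", function(object) standardGeneric("nComponents"))

#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(object) standardGeneric("featureMatrix"))

#' @rdname accessors
#' @export
setGeneric("featureLabels", function(object) standardGeneric("featureLabels"))

#' @rdname accessors
#' @export
setGeneric("foldAccuracies", function(object) standardGeneric("foldAccuracies"))

#' @rdname accessors
#' @export
setGeneric("sessionSegments", function(object) standardGeneric("sessionSegments"))
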