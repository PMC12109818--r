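#' Accessors for stentropy classes
#'
#' Small accessor functions exposing the slots of the package classes
#' without touching `@` directly.
#'
#' @name accessors
#' @return The corresponding slot value.
NULL

#' @rdname accessors
setMethod("nChannels", "SignalEpoch", function(object) nrow(object@data))
#' @rdname accessors
setMethod("nSamples", "SignalEpoch", function(object) ncol(object@data))
#' @rdname accessors
setMethod("samplingRate", "SignalEpoch", function(object) object@fs)
#' @rdname accessors
setMethod("epochData", "SignalEpoch", function(object) object@data)
#' @rdname accessors
setMethod("epochLabel", "SignalEpoch", function(object) object@label)

#' @rdname accessors
setMethod("nChannels", "TimeFrequencyMap", function(object) dim(object@coef)[1L])
#' @rdname accessors
setMethod("nSamples", "TimeFrequencyMap", function(object) dim(object@coef)[3L])
#' @rdname accessors
setMethod("samplingRate", "TimeFrequencyMap", function(object) object@fs)
#' @rdname accessors
setMethod("tfrCoef", "TimeFrequencyMap", function(object) object@coef)
#' @rdname accessors
setMethod("tfrFreqs", "TimeFrequencyMap", function(object) object@freqs)

#' @rdname accessors
setMethod("bandValues", "BandSeries", function(object) object@values)
#' @rdname accessors
setMethod("bandTable", "BandSeries", function(object) object@bands)
#' @rdname accessors
setMethod("nChannels", "BandSeries", function(object) dim(object@values)[1L])
#' @rdname accessors
setMethod("nSamples", "BandSeries", function(object) dim(object@values)[3L])

#' @rdname accessors
setMethod("entropyValues", "EntropySeries", function(object) object@values)
#' @rdname accessors
setMethod("bandTable", "EntropySeries", function(object) object@bands)
#' @rdname accessors
setMethod("nChannels", "EntropySeries", function(object) dim(object@values)[1L])

#' @rdname accessors
setMethod("cspFilters", "CSPModel", function(object) object@filters)
#' @rdname accessors
setMethod("cspEigenvalues", "CSPModel", function(object) object@eigenvalues)
#' @rdname accessors
setMethod("nComponents", "CSPModel", function(object) object@nComponents)

#' @rdname accessors
setMethod("featureMatrix", "FeatureTable", function(object) object@X)
#' @rdname accessors
setMethod("featureLabels", "FeatureTable", function(object) object@y)

#' @rdname accessors
setMethod("foldAccuracies", "CVReport", function(object) object@folds)

#' @rdname accessors
setMethod("sessionSegments", "SessionContainer", function(object) object@segments)
#' @rdname accessors
setMethod("samplingRate", "SessionContainer", function(object) object@fs)

## ---- show methods ------------------------------------------------------

setMethod("show", "SignalEpoch", function(object) {
  cat(sprintf("SignalEpoch: %d channel(s) x %d samples @ %g Hz (%.3g s), label: %s\n",
              nrow(object@data), ncol(object@data), object@fs,
              ncol(object@data) / object@fs,
              if (is.na(object@label)) "unlabeled" else object@label))
})

setMethod("show", "TimeFrequencyMap", function(object) {
  cat(sprintf(
    "TimeFrequencyMap: %d channel(s) x %d frequencies x %d times\n  freqs: %.3g-%.3g Hz, fs %g Hz, width %g\n",
    dim(object@coef)[1L], dim(object@coef)[2L], dim(object@coef)[3L],
    min(object@freqs), max(object@freqs), object@fs, object@width))
})

setMethod("show", "BandSeries", function(object) {
  cat(sprintf("BandSeries (%s): %d channel(s) x %d band(s) x %d samples\n  bands: %s\n",
              object@aggregation, dim(object@values)[1L],
              dim(object@values)[2L], dim(object@values)[3L],
              paste(object@bands$name, collapse = ", ")))
})

setMethod("show", "EntropySeries", function(object) {
  cat(sprintf(
    "EntropySeries: %d channel(s) x %d band(s) x %d positions (window k=%d over N=%d)\n",
    dim(object@values)[1L], dim(object@values)[2L], dim(object@values)[3L],
    object@window, object@sourceLen))
})

setMethod("show", "CSPModel", function(object) {
  cat(sprintf("CSPModel: %d components over %d channels (%s vs %s%s)\n",
              object@nComponents, ncol(object@filters),
              object@classPair[1L], object@classPair[2L],
              if (is.na(object@band)) "" else paste0(", band ", object@band)))
  cat("  eigenvalues:", paste(sprintf("%.3f", object@eigenvalues), collapse = " "), "\n")
})

setMethod("show", "FeatureTable", function(object) {
  cat(sprintf("FeatureTable: %d epochs x %d features (band %s, window k=%s)\n",
              nrow(object@X), ncol(object@X), object@band, object@window))
})

setMethod("show", "CVReport", function(object) {
  cat(sprintf("CVReport [%s]: task %s, band %s, k=%s\n",
              object@classifier, object@task, object@band, object@window))
  cat(sprintf("  accuracy %.3f +/- %.3f over %d fold(s): %s\n",
              object@accMean, object@accSd, length(object@folds),
              paste(sprintf("%.3f", object@folds), collapse = " ")))
})

setMethod("show", "SessionContainer", function(object) {
  labs <- vapply(object@segments, function(s) s@label, numeric(1))
  cat(sprintf("SessionContainer: subject %s, session %s, %d segment(s) @ %g Hz\n",
              object@subject, object@session, length(object@segments), object@fs))
  if (length(labs)) cat("  labels:", paste(labs, collapse = " "), "\n")
})
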