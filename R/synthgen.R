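#' Specification of a deterministic test signal
#'
#' Describes a single-channel test signal: a pure sine, a linear-frequency
#' chirp, or a fixed-frequency tone with a linear amplitude ramp.  The
#' amplitude always interpolates linearly from `amplitude0` at t = 0 to
#' `amplitude1` at t = duration; for a constant-amplitude signal leave
#' `amplitude1` at its default (equal to `amplitude0`).
#'
#' The chirp uses the linear sweep phase
#' \deqn{\phi(t) = 2\pi\,(f_0 t + (f_1 - f_0)\, t^2 / (2 D)),}
#' so the instantaneous frequency runs linearly from `f0` to `f1` over the
#' duration `D`.
#'
#' @param kind one of `"sine"`, `"chirp"`, `"amp_ramp_sine"`,
#'   `"fixed_freq_amp_ramp"`.  The two ramp kinds are synonyms: a tone at
#'   `f0` whose amplitude ramps from `amplitude0` to `amplitude1`.
#' @param f0 start (or only) frequency in Hz.
#' @param f1 end frequency of a chirp in Hz; defaults to `f0`.
#' @param amplitude0,amplitude1 amplitudes in arbitrary units
#'   (`amplitude1` defaults to `amplitude0`).
#' @param duration signal length in seconds.
#' @param fs sampling rate in Hz.
#' @return An object of class `SignalSpec`.
#' @examples
#' sweep <- signalSpec("chirp", f0 = 0, f1 = 46, duration = 3, fs = 200)
#' tone  <- signalSpec("sine", f0 = 5)
#' @export
signalSpec <- function(kind = c("sine", "chirp", "amp_ramp_sine",
                                "fixed_freq_amp_ramp"),
                       f0, f1 = f0, amplitude0 = 1, amplitude1 = amplitude0,
                       duration = 3, fs = 200) {
  kind <- match.arg(kind)
  new("SignalSpec", kind = kind, f0 = as.numeric(f0), f1 = as.numeric(f1),
      amplitude0 = as.numeric(amplitude0), amplitude1 = as.numeric(amplitude1),
      duration = as.numeric(duration), fs = as.numeric(fs))
}

#' @exportClass SignalSpec
#' @rdname signalSpec
setClass("SignalSpec",
  representation(kind = "character", f0 = "numeric", f1 = "numeric",
                 amplitude0 = "numeric", amplitude1 = "numeric",
                 duration = "numeric", fs = "numeric")
)

setValidity("SignalSpec", function(object) {
  scal <- function(x) length(x) == 1L && is.finite(x)
  if (!scal(object@fs) || object@fs <= 0) return("invalid field 'fs': must be > 0")
  if (!scal(object@duration) || object@duration <= 0)
    return("invalid field 'duration': must be > 0")
  if (!scal(object@f0) || object@f0 < 0 || object@f0 >= object@fs / 2)
    return("invalid field 'f0': must satisfy 0 <= f0 < fs/2")
  if (!scal(object@f1) || object@f1 < 0 || object@f1 >= object@fs / 2)
    return("invalid field 'f1': must satisfy 0 <= f1 < fs/2")
  if (!scal(object@amplitude0) || object@amplitude0 < 0)
    return("invalid field 'amplitude0': must be >= 0")
  if (!scal(object@amplitude1) || object@amplitude1 < 0)
    return("invalid field 'amplitude1': must be >= 0")
  TRUE
})

setMethod("show", "SignalSpec", function(object) {
  cat(sprintf("SignalSpec: %s, f %g->%g Hz, amplitude %g->%g, %g s @ %g Hz\n",
              object@kind, object@f0, object@f1, object@amplitude0,
              object@amplitude1, object@duration, object@fs))
})

#' Generate a deterministic test signal
#'
#' Realizes a [signalSpec()] as a single-channel, unlabeled
#' [SignalEpoch-class] of exactly `round(duration * fs)` samples at
#' t = 0, 1/fs, 2/fs, ...  A sine is `amplitude(t) * sin(2 pi f0 t)`; a
#' chirp sweeps the instantaneous frequency linearly from `f0` to `f1`.
#'
#' @param spec a `SignalSpec`.
#' @return A [SignalEpoch-class] (1 x n matrix, label `NA`).
#' @examples
#' ep <- makeSignal(signalSpec("sine", f0 = 5, fs = 200, duration = 3))
#' nSamples(ep)  # 600
#' @export
makeSignal <- function(spec) {
  stopifnot(is(spec, "SignalSpec"))
  validObject(spec)
  n <- round(spec@duration * spec@fs)
  t <- (seq_len(n) - 1) / spec@fs
  amp <- spec@amplitude0 + (spec@amplitude1 - spec@amplitude0) * t / spec@duration
  phase <- if (spec@kind == "chirp") {
    2 * pi * (spec@f0 * t + (spec@f1 - spec@f0) * t^2 / (2 * spec@duration))
  } else {
    2 * pi * spec@f0 * t
  }
  signalEpoch(amp * sin(phase), fs = spec@fs)
}

#' Specification of a synthetic 3-class emotive EEG dataset
#'
#' Describes a randomized multichannel dataset with one epoch population per
#' emotion code (1, 0, -1).  Every channel of every epoch carries a
#' 1/f^alpha Gaussian background (unit variance) plus band-limited Gaussian
#' noise in `classBand` (unit variance); on the `effectChannels` of an
#' epoch's own class the band-noise variance is multiplied by `effectGain`.
#' Classes therefore differ only through the spatial pattern of band-limited
#' variance, which is the structure CSP is designed to recover.
#'
#' @param nChannels number of channels (SEED-style default 62).
#' @param nEpochsPerClass epochs generated per emotion code.
#' @param fs sampling rate in Hz.
#' @param epochLen epoch length in seconds.
#' @param classBand numeric `c(low, high)` frequency interval in Hz carrying
#'   the class effect (default the Gamma band, 30-46 Hz).
#' @param effectChannels named list with elements `"1"`, `"0"`, `"-1"`
#'   giving the channel indices boosted for each class.  Defaults to three
#'   disjoint 8-channel blocks.
#' @param effectGain multiplicative variance factor >= 1 (1 = null data).
#' @param noiseExponent spectral slope alpha of the 1/f^alpha background.
#' @param seed integer RNG seed; identical specs give identical data.
#' @return An object of class `EmotiveEEGSpec`.
#' @export
emotiveEEGSpec <- function(nChannels = 62, nEpochsPerClass = 60, fs = 200,
                           epochLen = 3, classBand = c(30, 46),
                           effectChannels = NULL, effectGain = 6,
                           noiseExponent = 1, seed = 1) {
  if (is.null(effectChannels)) {
    if (nChannels < 24)
      stop("default effectChannels need nChannels >= 24; supply effectChannels")
    effectChannels <- list(`1` = 1:8, `0` = 9:16, `-1` = 17:24)
  }
  new("EmotiveEEGSpec", nChannels = as.integer(nChannels),
      nEpochsPerClass = as.integer(nEpochsPerClass), fs = as.numeric(fs),
      epochLen = as.numeric(epochLen), classBand = as.numeric(classBand),
      effectChannels = effectChannels, effectGain = as.numeric(effectGain),
      noiseExponent = as.numeric(noiseExponent), seed = as.integer(seed))
}

#' @exportClass EmotiveEEGSpec
#' @rdname emotiveEEGSpec
setClass("EmotiveEEGSpec",
  representation(nChannels = "integer", nEpochsPerClass = "integer",
                 fs = "numeric", epochLen = "numeric", classBand = "numeric",
                 effectChannels = "list", effectGain = "numeric",
                 noiseExponent = "numeric", seed = "integer")
)

setValidity("EmotiveEEGSpec", function(object) {
  if (object@nChannels < 1L) return("invalid field 'nChannels'")
  if (object@nEpochsPerClass < 1L) return("invalid field 'nEpochsPerClass'")
  if (object@fs <= 0) return("invalid field 'fs'")
  if (object@epochLen <= 0) return("invalid field 'epochLen'")
  if (length(object@classBand) != 2L || object@classBand[1L] >= object@classBand[2L] ||
      object@classBand[2L] >= object@fs / 2)
    return("invalid field 'classBand': need low < high < fs/2")
  if (!setequal(names(object@effectChannels), c("1", "0", "-1")))
    return("invalid field 'effectChannels': names must be '1', '0', '-1'")
  chs <- unlist(object@effectChannels)
  if (any(chs < 1) || any(chs > object@nChannels))
    return("invalid field 'effectChannels': indices outside 1..nChannels")
  if (object@effectGain < 1) return("invalid field 'effectGain': must be >= 1")
  TRUE
})

setMethod("show", "EmotiveEEGSpec", function(object) {
  cat(sprintf(
    "EmotiveEEGSpec: %d ch x %g s @ %g Hz, %d epochs/class\n  effect: x%g variance in %g-%g Hz, 1/f^%g background, seed %d\n",
    object@nChannels, object@epochLen, object@fs, object@nEpochsPerClass,
    object@effectGain, object@classBand[1L], object@classBand[2L],
    object@noiseExponent, object@seed))
})

## colored Gaussian noise with power spectrum ~ f^(-alpha), unit variance;
## DC removed; deterministic given the RNG state
.noise1f <- function(n, fs, alpha) {
  z <- stats::rnorm(n)
  if (alpha == 0) return(z)
  k <- seq_len(n) - 1
  f <- pmin(k, n - k) * fs / n          # symmetric -> real output
  s <- c(0, f[-1]^(-alpha / 2))
  s <- s / sqrt(mean(s^2))
  Re(stats::fft(stats::fft(z) * s, inverse = TRUE) / n)
}

## band-limited Gaussian noise, unit variance (theoretical scaling)
.noiseBand <- function(n, fs, band) {
  z <- stats::rnorm(n)
  k <- seq_len(n) - 1
  f <- pmin(k, n - k) * fs / n
  mask <- f >= band[1L] & f <= band[2L]
  if (!any(mask)) stop("classBand contains no frequency bins at this epoch length")
  Z <- stats::fft(z)
  Z[!mask] <- 0i
  Re(stats::fft(Z, inverse = TRUE) / n) / sqrt(sum(mask) / n)
}

#' Generate a labeled synthetic 3-class EEG dataset
#'
#' Realizes an [emotiveEEGSpec()] as a list of labeled
#' [SignalEpoch-class] objects (classes interleaved 1, 0, -1, 1, 0, ...).
#' Reproducible: two calls with equal specs produce identical data; the
#' caller's RNG state is left untouched.
#'
#' @param spec an `EmotiveEEGSpec`.
#' @return List of `3 * nEpochsPerClass` labeled [SignalEpoch-class] objects.
#' @examples
#' spec <- emotiveEEGSpec(nChannels = 24, nEpochsPerClass = 4, seed = 7)
#' eps <- makeEmotiveDataset(spec)
#' table(vapply(eps, epochLabel, numeric(1)))
#' @export
makeEmotiveDataset <- function(spec) {
  stopifnot(is(spec, "EmotiveEEGSpec"))
  validObject(spec)
  eff <- spec@effectChannels
  if (identical(eff[["1"]], eff[["0"]]) && identical(eff[["0"]], eff[["-1"]]))
    warning("all classes share identical effect channels: classes are ",
            "inseparable by construction")
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(spec@seed)
  n <- round(spec@epochLen * spec@fs)
  out <- vector("list", 3L * spec@nEpochsPerClass)
  i <- 0L
  for (rep in seq_len(spec@nEpochsPerClass)) {
    for (lab in c(1, 0, -1)) {
      gain <- rep(1, spec@nChannels)
      gain[eff[[as.character(lab)]]] <- sqrt(spec@effectGain)
      x <- matrix(0, spec@nChannels, n)
      for (ch in seq_len(spec@nChannels)) {
        x[ch, ] <- .noise1f(n, spec@fs, spec@noiseExponent) +
          gain[ch] * .noiseBand(n, spec@fs, spec@classBand)
      }
      i <- i + 1L
      out[[i]] <- signalEpoch(x, fs = spec@fs, label = lab,
                              t0 = (rep - 1) * spec@epochLen)
    }
  }
  out
}
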