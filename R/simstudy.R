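## population standard deviation (divide by n), matching the population
## variance convention of the entropy estimator
.popSd <- function(x) sqrt(mean((x - mean(x))^2))

#' Entropy trace of a test signal
#'
#' Runs one signal through the simulation-study pipeline: S-transform,
#' coherent synthesis of one frequency band ([bandSynthesize()]), then
#' sliding differential entropy.  Entropies are reported on the simulation
#' study's decibel-style scale, `10 * log(2 pi e s^2)` -- `entropyScale = 20`
#' times the nat value of [slidingDE()]; pass `entropyScale = 1` for plain
#' nats.
#'
#' @param epoch a single-channel [SignalEpoch-class].
#' @param k entropy window width in samples.
#' @param band band name, or `NA` to pick the band containing `f` via
#'   [bandForFrequency()].
#' @param f frequency used to select the band when `band` is `NA`.
#' @param fmin,fmax,width S-transform parameters.
#' @param bands band table.
#' @param entropyScale scale factor on the nat-valued entropy (default 20,
#'   the tabulated convention).
#' @return Numeric vector of entropy values, length N - k + 1.
#' @export
entropyTrace <- function(epoch, k, band = NA_character_, f = NULL,
                         fmin = 0.1, fmax = 46.0, width = 1,
                         bands = defaultBands(), entropyScale = 20) {
  stopifnot(is(epoch, "SignalEpoch"))
  if (is.na(band)) {
    if (is.null(f)) stop("supply either 'band' or 'f'")
    band <- bandForFrequency(f, bands)
  }
  tfr <- stransform(epoch, fmin = fmin, fmax = fmax, width = width)
  sy <- bandSynthesize(tfr, bands)
  b <- match(band, bands$name)
  if (is.na(b)) stop("unknown band '", band, "'")
  entropyScale * slidingDE(sy@values[1L, b, ], k)
}

#' Standard deviation of the Stockwell-entropy sequence of a pure sine
#'
#' The central quantity of the frequency/amplitude study: generate
#' `sin(2 pi f t)`, decompose with the S-transform, synthesize the band
#' containing `f`, take the sliding differential entropy with window `k`,
#' and return the (population) standard deviation of the resulting
#' sequence.  Large values mean the entropy fluctuates along the epoch
#' (unstable feature); values near zero mean the window always sees the
#' same variance, which happens as soon as `k` samples span at least one
#' full cycle of `f`.
#'
#' The returned value is amplitude invariant (an amplitude change shifts
#' the whole entropy sequence by a constant `2 * entropyScale * log(c)`).
#'
#' @param f sine frequency in Hz (must be below `fs/2`).
#' @param k entropy window width in samples.
#' @param fs sampling rate in Hz.
#' @param duration signal duration in seconds (default one 3-s epoch).
#' @param amplitude sine amplitude (result does not depend on it).
#' @inheritParams entropyTrace
#' @return Standard deviation of the entropy sequence (scaled nats).
#' @examples
#' entropyStd(41, 5)   # high-frequency tone: stable, well below 1
#' @export
entropyStd <- function(f, k, fs = 200, duration = 3, amplitude = 1,
                       fmin = 0.1, fmax = 46.0, width = 1,
                       bands = defaultBands(), entropyScale = 20) {
  if (f >= fs / 2) stop("'f' must be below the Nyquist frequency")
  ep <- makeSignal(signalSpec("sine", f0 = f, amplitude0 = amplitude,
                              duration = duration, fs = fs))
  tr <- entropyTrace(ep, k, f = f, fmin = fmin, fmax = fmax, width = width,
                     bands = bands, entropyScale = entropyScale)
  .popSd(tr)
}

#' Frequencies tabulated by the frequency/amplitude study
#'
#' The band-edge and within-band frequencies at which the stability of
#' Stockwell entropy is tabulated (two per band from Delta to Beta, plus a
#' dense sweep across Gamma).
#'
#' @return Integer vector of frequencies in Hz.
#' @export
gridFrequencies <- function() {
  c(1, 3, 4, 7, 8, 12, 13, 30, 31, 36, 41, 42, 43, 44, 45)
}

#' Entropy-stability grid over frequency and window width
#'
#' Applies [entropyStd()] over a frequency x window grid and returns a
#' table with one row per frequency and one standard-deviation column per
#' window width, plus the band assignment of each frequency.
#'
#' @param frequencies frequencies in Hz (default [gridFrequencies()]).
#' @param windows entropy window widths (default `c(5, 10, 20)`).
#' @inheritParams entropyStd
#' @return A data.frame with columns `band`, `frequency` and `std_w<k>`
#'   per window; generation parameters are attached as attribute
#'   `"params"`.
#' @examples
#' buildStdGrid(frequencies = c(1, 41), windows = c(5, 20))
#' @export
buildStdGrid <- function(frequencies = gridFrequencies(),
                         windows = c(5, 10, 20), fs = 200, duration = 3,
                         bands = defaultBands(), entropyScale = 20,
                         width = 1) {
  cols <- c(list(band = character(0), frequency = numeric(0)),
            stats::setNames(rep(list(numeric(0)), length(windows)),
                            sprintf("std_w%d", windows)))
  if (!length(frequencies)) {
    out <- as.data.frame(cols, stringsAsFactors = FALSE)
  } else {
    rows <- lapply(frequencies, function(f) {
      stds <- vapply(windows, function(k)
        entropyStd(f, k, fs = fs, duration = duration, bands = bands,
                   entropyScale = entropyScale, width = width), numeric(1))
      c(list(band = bandForFrequency(f, bands), frequency = f),
        as.list(stds))
    })
    out <- do.call(rbind, lapply(rows, function(r)
      as.data.frame(stats::setNames(r, names(cols)), stringsAsFactors = FALSE)))
  }
  attr(out, "params") <- list(fs = fs, duration = duration,
                              aggregation = "synthesis",
                              entropyScale = entropyScale, width = width,
                              windows = windows)
  out
}

#' Scenario traces: how frequency and amplitude drive Stockwell entropy
#'
#' Recreates the five qualitative scenarios of the frequency/amplitude
#' study as entropy-versus-time traces over the full analysis band:
#'
#' * `a` -- swept frequency 0 to 46 Hz, constant amplitude;
#' * `b` -- swept frequency, amplitude ramping up (1 to 2);
#' * `c` -- swept frequency, amplitude ramping down (2 to 1);
#' * `d` -- fixed 5 Hz tone, amplitude ramping up (1 to 2);
#' * `e` -- fixed-amplitude tones at 13 Hz and 30 Hz.
#'
#' @param fs sampling rate in Hz.
#' @param duration signal duration in seconds.
#' @param k entropy window width.
#' @param entropyScale entropy scale factor (see [entropyTrace()]).
#' @return Named list of data.frames with columns `time` (s), `entropy`
#'   and, for scenario `e`, `frequency`.
#' @export
runScenarios <- function(fs = 200, duration = 3, k = 20, entropyScale = 20) {
  fullTrace <- function(spec) {
    ep <- makeSignal(spec)
    tr <- entropyTrace(ep, k, band = "all", entropyScale = entropyScale)
    data.frame(time = (seq_along(tr) - 1) / fs, entropy = tr)
  }
  chirp <- function(a0, a1)
    signalSpec("chirp", f0 = 0, f1 = 46, amplitude0 = a0, amplitude1 = a1,
               duration = duration, fs = fs)
  e13 <- fullTrace(signalSpec("sine", f0 = 13, duration = duration, fs = fs))
  e30 <- fullTrace(signalSpec("sine", f0 = 30, duration = duration, fs = fs))
  e13$frequency <- 13
  e30$frequency <- 30
  list(
    a = fullTrace(chirp(1, 1)),
    b = fullTrace(chirp(1, 2)),
    c = fullTrace(chirp(2, 1)),
    d = fullTrace(signalSpec("amp_ramp_sine", f0 = 5, amplitude0 = 1,
                             amplitude1 = 2, duration = duration, fs = fs)),
    e = rbind(e13, e30)
  )
}
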