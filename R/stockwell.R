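#' Canonical EEG frequency bands
#'
#' The six analysis bands used throughout the package: the full band plus
#' the five canonical EEG rhythms, with the Gamma band capped at 46 Hz
#' (the upper edge of the preprocessing passband).
#'
#' Band membership is half-open, `low <= f < high`, except that bands
#' reaching the top of the analyzed range (46 Hz) include their upper edge,
#' so no interior edge frequency (4, 8, 12, 30 Hz) is counted twice.
#'
#' @return A data.frame with columns `name`, `low`, `high` (Hz).
#' @examples
#' defaultBands()
#' @export
defaultBands <- function() {
  data.frame(
    name = c("all", "delta", "theta", "alpha", "beta", "gamma"),
    low  = c(0.1, 0.1, 4, 8, 12, 30),
    high = c(46, 4, 8, 12, 30, 46),
    stringsAsFactors = FALSE
  )
}

.checkBands <- function(bands) {
  stopifnot(is.data.frame(bands),
            all(c("name", "low", "high") %in% names(bands)))
  if (any(bands$low >= bands$high))
    stop("each band must satisfy low < high")
  bands
}

## logical selector of tfr frequency bins for one band row
.bandBins <- function(freqs, low, high, topEdge) {
  freqs >= low & (if (topEdge) freqs <= high else freqs < high)
}

#' Frequency band containing a given frequency
#'
#' Returns the name of the narrowest band of `bands` containing `f` under
#' the package edge convention (half-open, top band closed).
#'
#' @param f frequency in Hz.
#' @param bands band table, see [defaultBands()].
#' @return Band name (character).
#' @examples
#' bandForFrequency(4)   # "theta": Delta is half-open at 4 Hz
#' bandForFrequency(31)  # "gamma"
#' @export
bandForFrequency <- function(f, bands = defaultBands()) {
  bands <- .checkBands(bands)
  top <- max(bands$high)
  hit <- bands$low <= f & (f < bands$high | (bands$high == top & f <= top))
  if (!any(hit)) stop("no band contains frequency ", f, " Hz")
  cand <- bands[hit, , drop = FALSE]
  cand$name[which.min(cand$high - cand$low)]
}

#' Discrete S-transform of a multichannel epoch
#'
#' FFT-based discrete Stockwell transform.  For each analysis frequency f
#' the spectrum is shifted by f, multiplied by a Gaussian voice window whose
#' frequency-domain standard deviation is proportional to f / width (so the
#' time window narrows as frequency grows), and inverse-transformed.  The
#' analysis frequencies are the DFT bins `m / duration` clipped to
#' `[fmin, fmax]`; zero frequency is excluded.  No zero padding is applied,
#' so for a periodic input the transform is exactly circular.
#'
#' The voice windows take value 1 at zero frequency offset, which gives the
#' transform the defining marginal property: summing coefficients over time
#' recovers the DFT of the input at each analysis frequency exactly.
#'
#' @param x a [SignalEpoch-class] or a channels x samples numeric matrix.
#' @param fmin,fmax analysis frequency range in Hz (defaults 0.1 and 46).
#' @param width dimensionless window-width parameter; larger values widen
#'   the time window (finer frequency resolution).  Default 1, the
#'   classical S-transform.
#' @param fs sampling rate in Hz; required for the matrix method.
#' @return A [TimeFrequencyMap-class].
#' @examples
#' ep <- makeSignal(signalSpec("sine", f0 = 10, fs = 200, duration = 3))
#' tfr <- stransform(ep)
#' dim(tfrCoef(tfr))
#' @rdname stransform
#' @export
setMethod("stransform", "SignalEpoch",
  function(x, fmin = 0.1, fmax = 46.0, width = 1, ...) {
    .stransform(x@data, x@fs, fmin, fmax, width)
  })

#' @rdname stransform
#' @param ... unused.
#' @export
setMethod("stransform", "matrix",
  function(x, fs, fmin = 0.1, fmax = 46.0, width = 1, ...) {
    .stransform(x, fs, fmin, fmax, width)
  })

.stransform <- function(x, fs, fmin, fmax, width) {
  if (!all(is.finite(x))) stop("input signal contains non-finite samples")
  n <- ncol(x)
  if (n < 2L) stop("need at least 2 samples")
  if (!(fmin > 0 && fmin < fmax)) stop("need 0 < fmin < fmax")
  if (fmax >= fs / 2) stop("fmax must be below the Nyquist frequency fs/2")
  df <- fs / n
  mv <- seq.int(max(1L, ceiling(fmin / df - 1e-9)), floor(fmax / df + 1e-9))
  if (!length(mv)) stop("no analysis frequencies in [fmin, fmax]")
  nch <- nrow(x)
  X <- stats::mvfft(t(x))                       # n x ch spectrum
  j <- 0:(n - 1)
  jw <- ifelse(j > n / 2, j - n, j)             # wrapped bin offsets
  coef <- array(0i, dim = c(nch, length(mv), n))
  for (i in seq_along(mv)) {
    m <- mv[i]
    G <- exp(-2 * pi^2 * width^2 * jw^2 / m^2)  # G(0) = 1
    idx <- ((m + j) %% n) + 1L
    voice <- stats::mvfft(X[idx, , drop = FALSE] * G, inverse = TRUE) / n
    coef[, i, ] <- t(voice)
  }
  new("TimeFrequencyMap", coef = coef, freqs = mv * df, fs = fs,
      width = width)
}

#' @rdname bandGroup
#' @section Aggregation:
#' For each band and time point the aggregate is the mean of `|coef|` over
#' the frequency bins falling in the band (half-open edges; bands reaching
#' the top of the analyzed range include their upper edge).  The mean --
#' rather than the sum -- keeps values comparable across bands of different
#' widths.
#' @examples
#' ep <- makeSignal(signalSpec("sine", f0 = 10, fs = 200, duration = 3))
#' bs <- bandGroup(stransform(ep))
#' dim(bandValues(bs))  # 1 x 6 x 600
#' @export
setMethod("bandGroup", "TimeFrequencyMap", function(tfr, bands = defaultBands()) {
  bands <- .checkBands(bands)
  top <- max(bands$high)
  nch <- dim(tfr@coef)[1L]
  nt <- dim(tfr@coef)[3L]
  vals <- array(0, dim = c(nch, nrow(bands), nt))
  mag <- abs(tfr@coef)
  for (b in seq_len(nrow(bands))) {
    sel <- .bandBins(tfr@freqs, bands$low[b], bands$high[b],
                     topEdge = bands$high[b] == top)
    if (!any(sel))
      stop("band '", bands$name[b], "' overlaps no frequency bins of the transform")
    vals[, b, ] <- colMeans(aperm(mag[, sel, , drop = FALSE], c(2, 1, 3)))
  }
  new("BandSeries", values = vals, bands = bands, fs = tfr@fs,
      aggregation = "magnitude")
})

#' @rdname bandSynthesize
#' @section Synthesis:
#' For each band, the coefficients of its frequency bins are summed
#' coherently with their analysis phase restored,
#' `Re sum_f S(tau, f) exp(2 pi i f tau)`, i.e. the band-limited inverse of
#' the transform.  For a pure tone whose frequency falls on an analysis bin
#' the synthesized series is exactly proportional to the tone, so the
#' series oscillates at the signal frequency instead of tracking its
#' envelope.  This is the aggregation used by the frequency/amplitude
#' simulation study ([entropyStd()]).
#' @examples
#' ep <- makeSignal(signalSpec("sine", f0 = 10, fs = 200, duration = 3))
#' sy <- bandSynthesize(stransform(ep))
#' @export
setMethod("bandSynthesize", "TimeFrequencyMap", function(tfr, bands = defaultBands()) {
  bands <- .checkBands(bands)
  top <- max(bands$high)
  nch <- dim(tfr@coef)[1L]
  nt <- dim(tfr@coef)[3L]
  tau <- (seq_len(nt) - 1) / tfr@fs
  vals <- array(0, dim = c(nch, nrow(bands), nt))
  ## phase ramps exp(2*pi*i*f*tau), one row per analysis frequency
  ramp <- exp(2i * pi * outer(tfr@freqs, tau))
  for (b in seq_len(nrow(bands))) {
    sel <- .bandBins(tfr@freqs, bands$low[b], bands$high[b],
                     topEdge = bands$high[b] == top)
    if (!any(sel))
      stop("band '", bands$name[b], "' overlaps no frequency bins of the transform")
    for (ch in seq_len(nch)) {
      v <- tfr@coef[ch, sel, , drop = FALSE]
      dim(v) <- dim(v)[2:3]
      vals[ch, b, ] <- 2 * Re(colSums(v * ramp[sel, , drop = FALSE]))
    }
  }
  new("BandSeries", values = vals, bands = bands, fs = tfr@fs,
      aggregation = "synthesis")
})

#' Zero-phase bandpass preprocessing
#'
#' Applies a 4th-order Butterworth bandpass (default 0.1-46 Hz) forward and
#' backward (`signal::filtfilt`), giving zero phase distortion and doubling
#' the effective filter order.
#'
#' @param recording channels x samples numeric matrix.
#' @param fs sampling rate in Hz; recordings are expected at 200 Hz and a
#'   warning is emitted otherwise.
#' @param low,high passband edges in Hz.
#' @param order Butterworth prototype order (per pass).
#' @return Filtered matrix of the same shape.
#' @examples
#' x <- matrix(rnorm(2 * 1000), 2)
#' y <- preprocessEEG(x, fs = 200)
#' @export
preprocessEEG <- function(recording, fs, low = 0.1, high = 46, order = 4) {
  if (is.vector(recording)) recording <- matrix(recording, nrow = 1L)
  if (fs != 200)
    warning("recordings are expected at fs = 200 Hz; got ", fs, " Hz")
  if (high >= fs / 2) stop("passband edge 'high' must be below Nyquist")
  n <- ncol(recording)
  minLen <- 3 * (2 * order + 1)
  if (n < minLen)
    stop("recording too short for filter warm-up: need at least ",
         minLen, " samples, got ", n)
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  out <- recording
  for (ch in seq_len(nrow(recording)))
    out[ch, ] <- signal::filtfilt(bf, recording[ch, ])
  out
}

#' Write a BandSeries as a long-format table
#'
#' One row per (channel, band, time index) with the aggregated value;
#' mainly for inspection and plotting outside R.
#'
#' @param bs a [BandSeries-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeBandSeries <- function(bs, path) {
  stopifnot(is(bs, "BandSeries"))
  d <- dim(bs@values)
  long <- data.frame(
    channel = rep(seq_len(d[1L]), times = d[2L] * d[3L]),
    band = rep(rep(bs@bands$name, each = d[1L]), times = d[3L]),
    time_index = rep(seq_len(d[3L]), each = d[1L] * d[2L]),
    value = as.vector(bs@values)
  )
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
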