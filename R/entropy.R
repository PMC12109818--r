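#' Sliding-window differential entropy
#'
#' Differential entropy of a Gaussian variable is `0.5 * log(2 pi e s^2)`
#' (natural log, nats).  `slidingDE` applies this plug-in formula to every
#' window of `k` consecutive samples (stride 1), using the variance of the
#' window, and returns the resulting sequence of length `N - k + 1`.
#'
#' The variance estimator divides by `k` (the population form), matching
#' the plug-in Gaussian model; set `estimator = "sample"` for the k - 1
#' divisor.  Variances are floored at `varFloor` before the log so that
#' constant windows (zero variance, e.g. the steady magnitude of a pure
#' tone) give a large negative value rather than `-Inf`.
#'
#' @param x numeric vector of length N.
#' @param k window width, `2 <= k <= N`.
#' @param varFloor variance floor (default 1e-12).
#' @param estimator `"population"` (divide by k, default) or `"sample"`.
#' @return Numeric vector of length `N - k + 1` (nats).
#' @examples
#' slidingDE(c(1, 2, 3, 4, 5), 5)  # 0.5 * log(2 * pi * exp(1) * 2)
#' @export
slidingDE <- function(x, k, varFloor = 1e-12,
                      estimator = c("population", "sample")) {
  estimator <- match.arg(estimator)
  n <- length(x)
  k <- as.integer(k)
  if (k > n) stop("window width k (", k, ") exceeds series length N (", n, ")")
  if (k < 2L) stop("window width k must be at least 2")
  if (!all(is.finite(x))) stop("input series contains non-finite values")
  ## rolling moments by cumulative sums; the series is centered globally
  ## first so the S2 - S1^2/k cancellation stays well conditioned
  x <- x - mean(x)
  s1 <- cumsum(x)
  s2 <- cumsum(x * x)
  i0 <- seq_len(n - k + 1L)
  S1 <- s1[i0 + k - 1L] - c(0, s1)[i0]
  S2 <- s2[i0 + k - 1L] - c(0, s2)[i0]
  v <- pmax(S2 / k - (S1 / k)^2, 0)
  if (estimator == "sample") v <- v * k / (k - 1)
  0.5 * log(2 * pi * exp(1) * pmax(v, varFloor))
}

#' @rdname stockwellEntropy
#' @section Stockwell entropy:
#' Applying [slidingDE()] independently to every (channel, band) row of a
#' [BandSeries-class] yields the Stockwell entropy: a sliding-window
#' differential-entropy sequence per channel and frequency band of the
#' S-transform decomposition.
#' @param varFloor,estimator passed to [slidingDE()].
#' @examples
#' ep <- makeSignal(signalSpec("sine", f0 = 10, fs = 200, duration = 3))
#' es <- stockwellEntropy(bandGroup(stransform(ep)), k = 20)
#' dim(entropyValues(es))  # 1 x 6 x 581
#' @export
setMethod("stockwellEntropy", "BandSeries",
  function(x, k, varFloor = 1e-12, estimator = c("population", "sample")) {
    estimator <- match.arg(estimator)
    d <- dim(x@values)
    n <- d[3L]
    k <- as.integer(k)
    if (k > n) stop("window width k (", k, ") exceeds the series length (", n, ")")
    out <- array(0, dim = c(d[1L], d[2L], n - k + 1L))
    for (ch in seq_len(d[1L])) {
      for (b in seq_len(d[2L])) {
        out[ch, b, ] <- tryCatch(
          slidingDE(x@values[ch, b, ], k, varFloor, estimator),
          error = function(e) stop("channel ", ch, ", band '",
                                   x@bands$name[b], "': ", conditionMessage(e)))
      }
    }
    new("EntropySeries", values = out, window = k, sourceLen = as.integer(n),
        bands = x@bands)
  })

#' Write an EntropySeries as a long-format table
#'
#' One row per (channel, band, window position) with the entropy in nats.
#'
#' @param es an [EntropySeries-class].
#' @param path output CSV path.
#' @param epoch optional epoch identifier stored in the first column.
#' @return `path`, invisibly.
#' @export
writeEntropySeries <- function(es, path, epoch = 1L) {
  stopifnot(is(es, "EntropySeries"))
  d <- dim(es@values)
  long <- data.frame(
    epoch = epoch,
    channel = rep(seq_len(d[1L]), times = d[2L] * d[3L]),
    band = rep(rep(es@bands$name, each = d[1L]), times = d[3L]),
    position = rep(seq_len(d[3L]), each = d[1L] * d[2L]),
    entropy = as.vector(es@values)
  )
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
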