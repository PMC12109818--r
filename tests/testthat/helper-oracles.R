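# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths (direct loops, direct integral evaluation,
# closed forms) so that agreement is evidence, not tautology.

# brute-force sliding differential entropy (population variance)
bruteDE <- function(x, k, floor = 1e-12) {
  n <- length(x)
  vapply(seq_len(n - k + 1L), function(i) {
    w <- x[i:(i + k - 1L)]
    v <- mean((w - mean(w))^2)
    0.5 * log(2 * pi * exp(1) * max(v, floor))
  }, numeric(1))
}

# direct evaluation of the continuous S-transform integral
#   S(tau, f) = int x(t) w(tau - t) exp(-2 pi i f t) dt
# with the Gaussian window w(t) = |f|/(sqrt(2 pi) width) exp(-t^2 f^2 / (2 width^2)),
# discretized as a Riemann sum on the sample grid.
integralST <- function(x, fs, tau, f, width = 1) {
  t <- (seq_along(x) - 1) / fs
  w <- abs(f) / (sqrt(2 * pi) * width) * exp(-(tau - t)^2 * f^2 / (2 * width^2))
  sum(x * w * exp(-2i * pi * f * t)) / fs
}

# rank-based AUC of scores for binary labels (TRUE = positive)
rankAUC <- function(scores, positive) {
  r <- rank(scores)
  n1 <- sum(positive)
  n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

popSd <- function(x) sqrt(mean((x - mean(x))^2))

# dominant frequency of short consecutive segments, by plain FFT magnitude
segmentDominantFreq <- function(x, fs, nSeg) {
  n <- length(x) %/% nSeg
  vapply(seq_len(nSeg), function(i) {
    seg <- x[((i - 1) * n + 1):(i * n)]
    mag <- Mod(stats::fft(seg))[2:(n %/% 2)]
    (which.max(mag)) * fs / n
  }, numeric(1))
}

# small entropy-epoch factory: channels x T Gaussian matrices with a level
# shift on selected channels (mimics what band entropy looks like downstream)
shiftedEpochs <- function(nEpochs, nCh, T, shiftCh = integer(0), shift = 0) {
  replicate(nEpochs, {
    m <- matrix(rnorm(nCh * T), nCh)
    m[shiftCh, ] <- m[shiftCh, , drop = FALSE] + shift
    m
  }, simplify = FALSE)
}
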