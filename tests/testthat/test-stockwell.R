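test_that("S-transform is linear and vanishes on zero input", {
  x <- matrix(rnorm(2 * 128), 2)
  tfr1 <- stransform(x, fs = 128, fmin = 1, fmax = 40)
  tfr2 <- stransform(2 * x, fs = 128, fmin = 1, fmax = 40)
  expect_equal(tfrCoef(tfr2), 2 * tfrCoef(tfr1))

  z <- stransform(matrix(0, 1, 128), fs = 128, fmin = 1, fmax = 40)
  expect_true(all(tfrCoef(z) == 0i))
})

test_that("S-transform input validation", {
  x <- matrix(rnorm(100), 1)
  expect_error(stransform(x, fs = 100, fmin = 1, fmax = 50), "Nyquist")
  xb <- x; xb[5] <- NA
  expect_error(stransform(xb, fs = 100, fmin = 1, fmax = 40), "finite")
})

test_that("a pure tone matches direct evaluation of the transform integral", {
  ep <- makeSignal(signalSpec("sine", f0 = 10, fs = 200, duration = 3))
  tfr <- stransform(ep)
  fi <- which.min(abs(tfrFreqs(tfr) - 10))
  expect_equal(tfrFreqs(tfr)[fi], 10)
  x <- epochData(ep)[1, ]
  # interior time points, on- and off-tone frequencies
  for (tau in c(1.0, 1.5, 2.0)) {
    for (f in c(10, 15)) {
      ours <- tfrCoef(tfr)[1, which.min(abs(tfrFreqs(tfr) - f)),
                           round(tau * 200) + 1]
      expect_equal(Mod(ours), Mod(integralST(x, 200, tau, f)),
                   tolerance = 0.15)
    }
  }
  # magnitude at the tone is ~A/2 and ~constant over interior times
  mid <- Mod(tfrCoef(tfr)[1, fi, 200:400])
  expect_equal(mean(mid), 0.5, tolerance = 0.05)
  expect_lt(popSd(mid) / mean(mid), 0.05)
  # energy concentration: far-away voices carry much less
  far <- which(abs(tfrFreqs(tfr) - 10) >= 20)
  expect_gt(mean(mid) / mean(Mod(tfrCoef(tfr)[1, far, 200:400])), 20)
})

test_that("time-summed coefficients recover the Fourier spectrum", {
  set.seed(3)
  for (rep in 1:3) {
    x <- matrix(rnorm(256), 1)
    tfr <- stransform(x, fs = 256, fmin = 2, fmax = 100)
    X <- stats::fft(x[1, ])
    bins <- round(tfrFreqs(tfr)) + 1L
    marg <- apply(tfrCoef(tfr)[1, , ], 1, sum)
    expect_lt(max(Mod(marg - X[bins]) / Mod(X[bins])), 1e-6)
  }
})

test_that("temporal resolution sharpens with frequency", {
  # impulse-like burst: the voice at 2f has a narrower time spread than at f
  x <- matrix(0, 1, 256); x[1, 128] <- 1
  tfr <- stransform(x, fs = 256, fmin = 2, fmax = 100)
  spread <- function(f) {
    w <- Mod(tfrCoef(tfr)[1, which.min(abs(tfrFreqs(tfr) - f)), ])
    w <- w / sum(w)
    i <- seq_along(w)
    sqrt(sum(w * (i - sum(w * i))^2))
  }
  expect_lt(spread(40), spread(20))
  expect_lt(spread(80), spread(40))
})

test_that("coefficient magnitudes follow integer circular shifts", {
  set.seed(4)
  x <- rnorm(128)
  s <- 17L
  xs <- c(x[(s + 1):128], x[1:s])
  t1 <- Mod(tfrCoef(stransform(matrix(x, 1), fs = 128, fmin = 2, fmax = 60)))
  t2 <- Mod(tfrCoef(stransform(matrix(xs, 1), fs = 128, fmin = 2, fmax = 60)))
  expect_lt(max(abs(t2[1, , ] - t1[1, , c((s + 1):128, 1:s)])), 1e-8)
})

test_that("band grouping aggregates magnitudes per band", {
  ep <- makeSignal(signalSpec("sine", f0 = 10, fs = 200, duration = 3))
  tfr <- stransform(ep)
  bs <- bandGroup(tfr)
  expect_equal(dim(bandValues(bs))[2], 6L)

  # degenerate single band spanning the whole range = global magnitude mean
  solo <- bandGroup(tfr, data.frame(name = "solo", low = 0.1, high = 46))
  expect_equal(bandValues(solo)[1, 1, ],
               colMeans(Mod(tfrCoef(tfr)[1, , ])))

  # a 10 Hz tone dominates the Alpha sub-band
  m <- apply(bandValues(bs), 2, mean)
  names(m) <- bandTable(bs)$name
  sub <- m[c("delta", "theta", "beta", "gamma")]
  expect_true(all(m["alpha"] > sub))

  expect_error(bandGroup(tfr, data.frame(name = "void", low = 46.2,
                                         high = 46.3)), "void")
})

test_that("coherent band synthesis reconstructs an in-band tone", {
  ep <- makeSignal(signalSpec("sine", f0 = 10, fs = 200, duration = 3))
  sy <- bandSynthesize(stransform(ep))
  alpha <- bandValues(sy)[1, match("alpha", bandTable(sy)$name), ]
  # proportional to the tone itself: correlation ~1 with sin(2 pi 10 t)
  ref <- sin(2 * pi * 10 * (0:599) / 200)
  expect_gt(abs(cor(alpha, ref)), 0.9999)
})

test_that("zero-phase bandpass shapes the spectrum as specified", {
  rms <- function(m) sqrt(mean(m^2))
  x60 <- epochData(makeSignal(signalSpec("sine", f0 = 60, fs = 200,
                                         duration = 5)))
  y60 <- preprocessEEG(x60, fs = 200)
  expect_gt(20 * log10(rms(x60) / rms(y60)), 20)

  x10 <- epochData(makeSignal(signalSpec("sine", f0 = 10, fs = 200,
                                         duration = 5)))
  y10 <- preprocessEEG(x10, fs = 200)
  expect_equal(rms(y10) / rms(x10), 1, tolerance = 0.05)

  expect_true(all(preprocessEEG(matrix(0, 1, 500), fs = 200) == 0))
  expect_error(preprocessEEG(matrix(0, 1, 10), fs = 200), "warm-up")
  expect_warning(preprocessEEG(matrix(rnorm(500), 1), fs = 250), "200")
})
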