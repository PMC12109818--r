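test_that("deterministic test signals match their closed forms", {
  ep <- makeSignal(signalSpec("sine", f0 = 5, amplitude0 = 1, fs = 200,
                              duration = 3))
  x <- epochData(ep)[1, ]
  expect_length(x, 600L)
  expect_identical(x[1], 0)
  expect_equal(max(x), 1, tolerance = 1e-3)
  t <- (0:599) / 200
  expect_equal(x, sin(2 * pi * 5 * t))

  zero <- makeSignal(signalSpec("sine", f0 = 5, amplitude0 = 0))
  expect_true(all(epochData(zero) == 0))

  ramp <- makeSignal(signalSpec("amp_ramp_sine", f0 = 5, amplitude0 = 1,
                                amplitude1 = 2, duration = 3, fs = 200))
  env <- 1 + t / 3
  expect_equal(epochData(ramp)[1, ], env * sin(2 * pi * 5 * t))
})

test_that("signal specs reject invalid fields by name", {
  expect_error(signalSpec("sine", f0 = -1), "f0")
  expect_error(signalSpec("chirp", f0 = 0, f1 = 150, fs = 200), "f1")
  expect_error(signalSpec("sine", f0 = 5, amplitude0 = -2), "amplitude0")
  expect_error(signalSpec("sine", f0 = 5, duration = 0), "duration")
})

test_that("chirp sweeps its instantaneous frequency linearly", {
  # oracle: zero crossings around mid-duration estimate the local frequency
  ep <- makeSignal(signalSpec("chirp", f0 = 0, f1 = 46, fs = 200,
                              duration = 3))
  x <- epochData(ep)[1, ]
  mid <- x[251:350]  # 0.5 s around t = 1.5 s
  crossings <- sum(diff(sign(mid)) != 0)
  fmid <- crossings / 2 / 0.5
  expect_equal(fmid, 23, tolerance = 0.1)

  # dominant frequency of consecutive segments is nondecreasing
  dom <- segmentDominantFreq(x, 200, 6)
  expect_true(all(diff(dom) >= 0))
})

test_that("a sine concentrates its power in the nearest DFT bin", {
  for (f0 in c(5, 12, 31)) {
    x <- epochData(makeSignal(signalSpec("sine", f0 = f0, fs = 200,
                                         duration = 3)))[1, ]
    p <- Mod(stats::fft(x))^2
    half <- p[2:300]
    nearest <- which.min(abs((1:299) / 3 - f0))
    expect_gt(half[nearest] / sum(half), 0.45)  # + mirrored half at -f0
    expect_gt(2 * half[nearest] / sum(p[-1]), 0.9)
  }
})

test_that("the emotive EEG generator is reproducible and class-structured", {
  spec <- emotiveEEGSpec(nChannels = 24, nEpochsPerClass = 2, seed = 5)
  a <- makeEmotiveDataset(spec)
  b <- makeEmotiveDataset(spec)
  expect_length(a, 6L)
  expect_identical(lapply(a, epochData), lapply(b, epochData))
  labs <- vapply(a, epochLabel, numeric(1))
  expect_equal(sort(unique(labs)), c(-1, 0, 1))
  expect_true(all(vapply(a, function(e) all(dim(epochData(e)) == c(24, 600)),
                         logical(1))))

  # default SEED-like geometry: 62 x 600
  big <- makeEmotiveDataset(emotiveEEGSpec(nEpochsPerClass = 1, seed = 1))
  expect_equal(dim(epochData(big[[1]])), c(62L, 600L))
})

test_that("effect channels carry ~gain-fold band-limited variance", {
  # oracle: in-band variance via the periodogram (Parseval), independent of
  # the generator's own construction
  spec <- emotiveEEGSpec(nChannels = 24, nEpochsPerClass = 6, effectGain = 6,
                         classBand = c(30, 46), seed = 9)
  eps <- makeEmotiveDataset(spec)
  bandVar <- function(x) {
    n <- length(x)
    f <- pmin(0:(n - 1), n - (0:(n - 1))) * 200 / n
    sum(Mod(stats::fft(x))[f >= 30 & f <= 46]^2) / n^2
  }
  pos <- eps[vapply(eps, epochLabel, numeric(1)) == 1]
  vEff <- mean(vapply(pos, function(e)
    mean(apply(epochData(e)[1:8, ], 1, bandVar)), numeric(1)))
  vBg <- mean(vapply(pos, function(e)
    mean(apply(epochData(e)[9:24, ], 1, bandVar)), numeric(1)))
  expect_equal(vEff / vBg, 6, tolerance = 0.25)
})

test_that("identical effect subsets for all classes warn", {
  spec <- emotiveEEGSpec(nChannels = 8, nEpochsPerClass = 1,
                         effectChannels = list(`1` = 1:2, `0` = 1:2,
                                               `-1` = 1:2), seed = 1)
  expect_warning(makeEmotiveDataset(spec), "inseparable")
})
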