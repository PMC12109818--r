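test_that("sliding differential entropy matches the Gaussian closed form", {
  # population variance of 1..5 is 2
  expect_equal(slidingDE(c(1, 2, 3, 4, 5), 5),
               0.5 * log(2 * pi * exp(1) * 2), tolerance = 1e-12)
  # sample-variance variant uses the k-1 divisor
  expect_equal(slidingDE(c(1, 2, 3, 4, 5), 5, estimator = "sample"),
               0.5 * log(2 * pi * exp(1) * 2.5), tolerance = 1e-12)
})

test_that("sliding entropy agrees with the brute-force oracle", {
  set.seed(11)
  for (k in c(2, 5, 37)) {
    x <- rnorm(200) * rexp(1, 0.1)
    expect_equal(slidingDE(x, k), bruteDE(x, k), tolerance = 1e-9)
  }
})

test_that("window bookkeeping: lengths, floors and errors", {
  expect_length(slidingDE(rnorm(600), 5), 596L)
  expect_length(slidingDE(rnorm(7), 7), 1L)
  expect_error(slidingDE(rnorm(5), 6), "exceeds")
  expect_error(slidingDE(rnorm(5), 1), "at least 2")
  # constant series engages the variance floor everywhere
  flo <- 0.5 * log(2 * pi * exp(1) * 1e-12)
  expect_equal(slidingDE(rep(3.2, 50), 10), rep(flo, 41L))
})

test_that("entropy is translation invariant and log-equivariant in scale", {
  set.seed(12)
  for (rep in 1:20) {
    x <- rnorm(100, sd = runif(1, 0.5, 4))
    k <- sample(2:30, 1)
    e <- slidingDE(x, k)
    expect_equal(slidingDE(x + 7.3, k), e, tolerance = 1e-7)
    cc <- runif(1, 0.2, 9)
    expect_equal(slidingDE(cc * x, k), e + log(cc), tolerance = 1e-7)
  }
})

test_that("mean entropy of iid Gaussian windows converges to the true DE", {
  # true differential entropy of N(0, 4) is 0.5*log(2*pi*e*4); the plug-in
  # estimator's bias shrinks ~1/k
  target <- 0.5 * log(2 * pi * exp(1) * 4)
  set.seed(13)
  x <- rnorm(6000, sd = 2)
  err25 <- abs(mean(slidingDE(x, 25)) - target)
  err200 <- abs(mean(slidingDE(x, 200)) - target)
  expect_lt(err25, 0.08)
  expect_lt(err200, 0.03)
})

test_that("stockwellEntropy maps every channel x band row and keeps shape", {
  ep <- signalEpoch(matrix(rnorm(3 * 400), 3), fs = 200)
  bs <- bandGroup(stransform(ep))
  es <- stockwellEntropy(bs, k = 20)
  expect_equal(dim(entropyValues(es)), c(3L, 6L, 381L))
  expect_equal(es@window, 20L)
  expect_equal(es@sourceLen, 400L)
  # row-wise agreement with slidingDE
  expect_equal(entropyValues(es)[2, 3, ],
               slidingDE(bandValues(bs)[2, 3, ], 20))
  # errors carry channel/band context
  expect_error(stockwellEntropy(bs, k = 1), "at least 2")
  expect_error(stockwellEntropy(bs, k = 500), "exceeds")
})

test_that("scaling a band row shifts only that entropy row, by log(c)", {
  ep <- signalEpoch(matrix(rnorm(2 * 300), 2), fs = 200)
  bs <- bandGroup(stransform(ep))
  bs2 <- bs
  bs2@values[1, 4, ] <- 3 * bs2@values[1, 4, ]
  e1 <- entropyValues(stockwellEntropy(bs, 10))
  e2 <- entropyValues(stockwellEntropy(bs2, 10))
  expect_equal(e2[1, 4, ], e1[1, 4, ] + log(3), tolerance = 1e-7)
  e2[1, 4, ] <- e1[1, 4, ]
  expect_equal(e2, e1)
})
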