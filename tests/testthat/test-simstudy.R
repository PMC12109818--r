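test_that("entropy std is amplitude invariant", {
  expect_equal(entropyStd(5, 10, amplitude = 3), entropyStd(5, 10),
               tolerance = 1e-8)
  expect_equal(entropyStd(41, 20, amplitude = 0.1), entropyStd(41, 20),
               tolerance = 1e-8)
})

test_that("high-frequency tones are stabler than low-frequency tones", {
  for (k in c(5, 10, 20))
    expect_lt(entropyStd(41, k), entropyStd(1, k))
  # the tabulated convention: low-frequency instability exceeds 10,
  # Gamma-band stability stays below 1
  expect_gt(entropyStd(1, 5), 10)
  expect_lt(entropyStd(41, 5), 1)
})

test_that("the std grid has one row per frequency and a monotone trend", {
  g <- buildStdGrid(frequencies = c(1, 4, 8, 13, 31, 36), windows = c(5, 20))
  expect_equal(nrow(g), 6L)
  expect_named(g, c("band", "frequency", "std_w5", "std_w20"))
  expect_equal(g$band, c("delta", "theta", "alpha", "beta", "gamma", "gamma"))
  expect_true(all(g$std_w5 >= 0))
  # rank correlation between frequency and std is strongly negative
  expect_lte(cor(g$frequency, g$std_w5, method = "spearman"), -0.9)
  expect_lte(cor(g$frequency, g$std_w20, method = "spearman"), -0.9)

  empty <- buildStdGrid(frequencies = numeric(0))
  expect_equal(nrow(empty), 0L)
  expect_equal(attr(empty, "params")$aggregation, "synthesis")
})

test_that("window widths converge at high frequency", {
  spread <- function(f) {
    s <- vapply(c(5, 10, 20), function(k) entropyStd(f, k), numeric(1))
    max(s) - min(s)
  }
  expect_lt(max(spread(31), spread(41)), min(spread(1), spread(3)))
})

test_that("scenario traces reproduce the qualitative frequency/amplitude story", {
  sc <- runScenarios()
  expect_named(sc, c("a", "b", "c", "d", "e"))
  half <- function(df) df[df$time > max(df$time) / 2, ]
  slope <- function(df) unname(coef(stats::lm(entropy ~ time, df))[2])
  # rising amplitude on the sweep: entropy climbs over the stable
  # high-frequency half; falling amplitude: it drops
  expect_gt(slope(half(sc$b)), 0)
  expect_lt(slope(half(sc$c)), 0)
  # constant amplitude: much flatter than either ramp
  expect_lt(abs(slope(half(sc$a))),
            min(abs(slope(half(sc$b))), abs(slope(half(sc$c)))))
  # fixed-amplitude tones: the 30 Hz trace is stabler than the 13 Hz trace
  e13 <- sc$e$entropy[sc$e$frequency == 13]
  e30 <- sc$e$entropy[sc$e$frequency == 30]
  expect_lt(popSd(e30), popSd(e13))
  # fixed 5 Hz tone with rising amplitude: net growth start to end
  d <- sc$d$entropy
  q <- length(d) %/% 4
  expect_gt(mean(d[(3 * q):length(d)]), mean(d[1:q]))
})
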