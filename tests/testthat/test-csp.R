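# exact 2-channel epochs with population covariance diag(v1, v2):
# orthogonal zero-mean rows of length 4
toyEpoch <- function(v1, v2) {
  rbind(sqrt(v1) * c(1, -1, 1, -1), sqrt(v2) * c(1, 1, -1, -1))
}

test_that("CSP recovers the closed-form 2-channel generalized eigensolution", {
  a <- list(toyEpoch(10, 1))
  b <- list(toyEpoch(1, 10))
  m <- fitCSP(a, b, nComponents = 2)
  expect_equal(cspEigenvalues(m), c(10 / 11, 1 / 11), tolerance = 1e-10)
  # first filter along channel 1, last along channel 2
  expect_equal(abs(cspFilters(m)), diag(2), tolerance = 1e-10)

  # filters simultaneously diagonalize both class covariances
  Ca <- diag(c(10, 1)) / 11
  Cb <- diag(c(1, 10)) / 11
  Da <- cspFilters(m) %*% Ca %*% t(cspFilters(m))
  Db <- cspFilters(m) %*% Cb %*% t(cspFilters(m))
  expect_lt(max(abs(Da[row(Da) != col(Da)])), 1e-8)
  expect_lt(max(abs(Db[row(Db) != col(Db)])), 1e-8)
  # under composite normalization the diagonal pairs sum to one
  expect_equal(diag(Da) + diag(Db), c(1, 1), tolerance = 1e-8)
})

test_that("statistically identical classes give eigenvalues near 1/2", {
  set.seed(21)
  a <- shiftedEpochs(30, 4, 80)
  b <- shiftedEpochs(30, 4, 80)
  m <- fitCSP(a, b, nComponents = 4)
  expect_true(all(abs(cspEigenvalues(m) - 0.5) < 0.12))
})

test_that("label swap reverses the eigenvalue order but keeps the filters", {
  set.seed(22)
  a <- shiftedEpochs(20, 4, 60, shiftCh = 1, shift = 1.5)
  b <- shiftedEpochs(20, 4, 60, shiftCh = 3, shift = 1.5)
  mab <- fitCSP(a, b, nComponents = 4)
  mba <- fitCSP(b, a, nComponents = 4)
  expect_equal(cspEigenvalues(mba), 1 - rev(cspEigenvalues(mab)),
               tolerance = 1e-8)
  expect_equal(cspFilters(mba),
               cspFilters(mab)[4:1, , drop = FALSE], tolerance = 1e-6)
})

test_that("component count and input contracts are enforced", {
  a <- shiftedEpochs(5, 10, 40)
  b <- shiftedEpochs(5, 10, 40)
  m <- fitCSP(a, b, nComponents = 8)
  expect_equal(nrow(cspFilters(m)), 8L)
  expect_error(fitCSP(a, list(matrix(rnorm(8 * 40), 8)), 4), "channel")
  expect_error(fitCSP(a, b, nComponents = 3), "even")
  expect_error(fitCSP(list(), b), "at least one epoch")
})

test_that("log-variance features are softmax-normalized and ordered", {
  a <- list(toyEpoch(10, 1))
  b <- list(toyEpoch(1, 10))
  m <- fitCSP(a, b, nComponents = 2)
  f <- cspFeatures(m, a[[1]])
  expect_equal(sum(exp(f)), 1, tolerance = 1e-12)
  expect_gt(f[1], f[2])  # class-A epoch loads on the class-A filter

  # equal variance in all projected components: every feature log(1/m)
  mEye <- m
  mEye@filters <- diag(2)
  xx <- matrix(rnorm(200), 2)
  xx[2, ] <- xx[1, ]
  expect_equal(cspFeatures(mEye, xx), rep(log(0.5), 2))

  expect_error(cspFeatures(m, matrix(0, 2, 10)), "degenerate")
  expect_error(cspFeatures(m, matrix(1, 3, 10)), "channel")
})

test_that("one-vs-rest multiclass models concatenate and degrade gracefully", {
  set.seed(23)
  eps <- c(shiftedEpochs(8, 6, 50, 1:2, 2),
           shiftedEpochs(8, 6, 50, 3:4, 2),
           shiftedEpochs(8, 6, 50, 5:6, 2))
  y <- rep(c(1, 0, -1), each = 8)
  mods <- fitMulticlassCSP(eps, y, nComponents = 4)
  expect_length(mods, 3L)
  # each class is separable from the pooled rest
  expect_true(all(vapply(mods, function(m) cspEigenvalues(m)[1], numeric(1)) > 0.5))
  expect_length(multiclassFeatures(mods, eps[[1]]), 12L)

  # two classes reduce to a single binary model
  bin <- fitMulticlassCSP(eps[y != 0], y[y != 0], nComponents = 4)
  expect_length(bin, 1L)
  expect_length(multiclassFeatures(bin, eps[[1]]), 4L)

  expect_error(fitMulticlassCSP(eps[1:9], c(rep(1, 8), 0), 4), "at least 2")
})

test_that("the first CSP feature separates gamma-effect synthetic classes", {
  spec <- emotiveEEGSpec(nChannels = 24, nEpochsPerClass = 12, effectGain = 6,
                         seed = 31)
  eps <- makeEmotiveDataset(spec)
  labs <- vapply(eps, epochLabel, numeric(1))
  keep <- labs %in% c(1, 0)
  bs <- epochBandSeries(eps[keep])
  ent <- bandEntropy(bs, "gamma", 20)
  y <- labs[keep]
  m <- fitCSP(ent[y == 1], ent[y == 0], nComponents = 8)
  f1 <- vapply(ent, function(e) cspFeatures(m, e)[1], numeric(1))
  expect_gt(rankAUC(f1, y == 1), 0.9)
})

test_that("CSP models survive a serialization round trip", {
  set.seed(24)
  m <- fitCSP(shiftedEpochs(6, 5, 40, 1, 2), shiftedEpochs(6, 5, 40, 2, 2),
              nComponents = 4, classPair = c("1", "0"), band = "gamma")
  p <- tempfile(fileext = ".json")
  writeCSPModel(m, p)
  m2 <- readCSPModel(p)
  expect_equal(cspFilters(m2), cspFilters(m))
  expect_equal(cspEigenvalues(m2), cspEigenvalues(m))
  expect_identical(m2@classPair, m@classPair)
  unlink(p)
})
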