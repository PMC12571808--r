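test_that("context assembly concatenates [h'; q; t] with trial-relative time", {
  m <- randomTinyModel(1)
  x <- buildContext(rep(0.5, 4), c(0, 1), 1.0, 2.0)
  expect_length(x, 4 + 2 + 1)
  expect_equal(x[7], 0.5)
  expect_equal(buildContext(rep(0, 4), c(1, 0), 0, 2)[7], 0)
  x2 <- buildContext(rep(0.5, 4), c(1, 0), 1.0, 2.0)
  expect_equal(which(x != x2), c(5, 6))   # only the one-hot block flips
  expect_error(buildContext(rep(0.5, 4), c(1, 0), 3, 2), "outside")
})

test_that("an untrained flow is the identity on log(tau/tauRef)", {
  # fresh model: flow output layers are zero, so z = log(tau / tauRef)
  m <- stanFlowModel("u", nUnits = 1, nStimuli = 1, deltaMs = 1, binMs = 1,
                     hidden = 4, embed = 2, layers = 6, width = 8,
                     tauRef = 1, trialDuration = 1, seed = 2)
  x <- stanflow:::emptyHistoryContext(m)
  ft <- forwardTransform(m, 1.0, x)
  expect_equal(ft$z, 0)
  expect_equal(ft$logDet, 0)               # -log(tau) at tau = 1
  # density of tau is standard log-normal: ll(1) = log(1/sqrt(2 pi))
  expect_equal(logLikelihood(m, 1.0, x), log(1 / sqrt(2 * pi)),
               tolerance = 1e-12)
})

test_that("forward and inverse transforms round-trip to 1e-6", {
  m <- randomTinyModel(3)
  x <- buildContext(rnorm(4, 0, 0.5), c(1, 0), 0.7, 2)
  set.seed(5)
  tau <- rexp(1000, 15) + 1e-5
  z <- forwardTransform(m, tau, x)$z
  back <- inverseTransform(m, z, x)
  expect_lt(max(abs(back - tau) / tau), 1e-6)
})

test_that("the density integrates to one for random parameter draws", {
  for (s in 1:3) {
    m <- randomTinyModel(s * 7)
    x <- buildContext(rnorm(4, 0, 0.5), c(0, 1), 0.2, 2)
    # integrate in y = log tau between the z = -10 and z = +10 preimages,
    # split at the mode so the adaptive rule cannot miss a narrow peak
    f <- function(y) exp(logLikelihood(m, exp(y), x) + y)
    yq <- sort(log(inverseTransform(m, c(-10, 0, 10), x)))
    I <- integrate(f, yq[1], yq[2], rel.tol = 1e-9)$value +
      integrate(f, yq[2], yq[3], rel.tol = 1e-9)$value
    expect_equal(I, 1, tolerance = 1e-3)
  }
})

test_that("every layer is monotone increasing in its input", {
  for (s in 1:5) {
    m <- randomTinyModel(s)
    x <- buildContext(rnorm(4, 0, 0.5), c(1, 0), 0.5, 2)
    co <- flowCoefficients(m, x)
    y <- seq(-8, 8, length.out = 200)
    for (k in seq_along(co$s)) {
      v <- exp(co$s[k]) * y + co$t[k]
      u <- v + co$a[k] * tanh(v + co$c[k])
      expect_true(all(diff(u) > 0))
    }
  }
})

test_that("log-likelihood is finite over a wide tau range", {
  m <- randomTinyModel(13)
  x <- buildContext(rnorm(4, 0, 0.5), c(1, 0), 0.1, 2)
  tau <- 10^seq(-6, 3, length.out = 50)
  expect_true(all(is.finite(logLikelihood(m, tau, x))))
})

test_that("sampling is seeded, positive, and log-normal for the identity flow", {
  m <- stanFlowModel("u", nUnits = 1, nStimuli = 1, deltaMs = 1, binMs = 1,
                     hidden = 4, embed = 2, layers = 4, width = 8,
                     tauRef = 0.05, trialDuration = 1, seed = 4)
  s1 <- sampleISI(m, n = 1e4, seed = 42)
  s2 <- sampleISI(m, n = 1e4, seed = 42)
  expect_identical(s1, s2)
  expect_true(all(s1 > 0))
  # identity flow: tau = tauRef * exp(Z), median tauRef; CI via binomial
  expect_lt(abs(median(log(s1 / 0.05))), 3 * sqrt(pi / 2) / sqrt(1e4))
})

test_that("average NLL of self-samples matches the model's differential entropy", {
  # identity flow: tau ~ LogNormal(log tauRef, 1); entropy = 1/2 log(2 pi e) + log tauRef
  m <- stanFlowModel("u", nUnits = 1, nStimuli = 1, deltaMs = 1, binMs = 1,
                     hidden = 4, embed = 2, layers = 3, width = 8,
                     tauRef = 0.05, trialDuration = 1, seed = 6)
  x <- stanflow:::emptyHistoryContext(m)
  s <- sampleISI(m, x, n = 4000, seed = 7)
  nll <- -mean(logLikelihood(m, s, x))
  H <- 0.5 * log(2 * pi * exp(1)) + log(0.05)
  expect_equal(nll, H, tolerance = 5 * 1.6 / sqrt(4000))
})
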