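# independent oracle: direct 200-term series summation of Eq. for the surprise
surpriseSeries <- function(n, rT, nTerms = 200) {
  j <- n:(n + nTerms)
  logTerms <- j * log(rT) - lfactorial(j)
  mx <- max(logTerms)
  rT - (mx + log(sum(exp(logTerms - mx))))
}

test_that("Poisson Surprise matches direct series summation on an (rT, n) grid", {
  for (rT in c(0.1, 0.5, 1, 2, 5, 10)) {
    for (n in c(0:10, 20, 35, 50)) {
      expect_equal(poissonSurprise(n, rT, 1), surpriseSeries(n, rT),
                   tolerance = 1e-9, label = sprintf("rT=%g n=%d", rT, n))
    }
  }
  expect_equal(poissonSurprise(0, 3, 1), 0)      # full series -> log e^{rT}
  expect_equal(poissonSurprise(3, 1, 1), 1 - log(exp(1) - 2.5),
               tolerance = 1e-9)
  expect_error(poissonSurprise(2, 0, 1), "positive")
})

test_that("Poisson Surprise is strictly increasing in n at fixed rT", {
  S <- poissonSurprise(1:20, 1, 1)
  expect_true(all(diff(S) > 0))
})

test_that("burst detection: regular trains have none, a planted triplet is found", {
  expect_equal(nrow(detectBursts(seq(0, 10, by = 0.5))), 0)
  # 1 Hz background with one 100 Hz triplet at 5.00/5.01/5.02 (12 spikes)
  st <- sort(c(0:5, 5.01, 5.02, 6:9))
  b <- detectBursts(st, p = 0.2)
  expect_equal(nrow(b), 1)
  expect_equal(b$nSpikes, 3)
  expect_equal(b$startTime, 5)
  expect_equal(b$endTime, 5.02)
  # a tight pair without a third spike is not a burst
  expect_equal(nrow(detectBursts(c(0, 1, 2, 3, 3.01, 4, 5, 6, 7, 8),
                                 p = 0.2)), 0)
})

test_that("detected bursts are disjoint, ordered, and locally surprise-maximal", {
  set.seed(9)
  st <- sort(c(runif(40, 0, 20),
               5 + cumsum(rexp(5, 100)), 14 + cumsum(rexp(6, 100))))
  b <- detectBursts(st, p = 0.2)
  expect_gt(nrow(b), 0)
  if (nrow(b) > 1) expect_true(all(b$start[-1] > b$end[-nrow(b)]))
  r <- 1 / mean(diff(st))
  for (k in seq_len(nrow(b))) {
    S <- stanflow:::surpriseOfRange(st, b$start[k], b$end[k], r)
    if (b$end[k] < length(st))
      expect_lte(stanflow:::surpriseOfRange(st, b$start[k], b$end[k] + 1, r), S)
    if (b$end[k] - b$start[k] >= 1)
      expect_lte(stanflow:::surpriseOfRange(st, b$start[k] + 1, b$end[k], r), S)
  }
})

test_that("burst features: zero-filling, ratios, and translation invariance", {
  expect_warning(f0 <- burstFeatures(numeric(0)), "empty")
  expect_true(all(f0 == 0))
  f1 <- burstFeatures(seq(0, 4.9, by = 0.25), 5)   # regular -> no bursts
  expect_true(all(f1 == 0))
  st <- sort(c(seq(0.3, 4.7, by = 0.31), 2 + c(0, 0.008, 0.016, 0.024)))
  f <- burstFeatures(st, 5)
  nb <- detectBursts(st, 0.2)
  expect_equal(unname(f["pctBurstSpikes"]),
               100 * sum(nb$nSpikes) / length(st))
  expect_equal(unname(f["burstFreq"]), nrow(nb) / 5)
  expect_equal(burstFeatures(st + 0.123, 5), f)
})

test_that("the type classifier is exact on separable features and symmetric in labels", {
  set.seed(10)
  X <- rbind(matrix(runif(60, 0.8, 1.0), 10), matrix(runif(60, 0.0, 0.2), 10))
  colnames(X) <- stanflow:::burstFeatureNames
  y <- rep(c("PN", "LN"), each = 10)
  m <- fitTypeClassifier(X, y, scaleTestSeparately = FALSE)
  pred <- classifyNeurons(m, X)
  expect_equal(mean(pred$predicted == y), 1.0)
  ySwap <- rep(c("LN", "PN"), each = 10)
  m2 <- fitTypeClassifier(X, ySwap, scaleTestSeparately = FALSE)
  pred2 <- classifyNeurons(m2, X)
  expect_true(all((pred$predicted == "PN") == (pred2$predicted == "LN")))
  expect_error(fitTypeClassifier(X, rep("PN", 20)), "two classes")
})

test_that("simulated PN-like and LN-like units separate on held-out data", {
  st <- typeClassificationStudy(nPerClass = 12, duration = 5, seed = 3)
  expect_gte(st$accuracy, 0.9)
})
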