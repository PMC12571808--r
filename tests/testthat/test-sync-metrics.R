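# brute-force coincidence oracle: O(n^2) double loop over spike pairs
coincBrute <- function(t1, t2, halfWidthS) {
  n <- 0L
  for (a in t1) for (b in t2) if (abs(a - b) <= halfWidthS) n <- n + 1L
  n
}

test_that("correlogram-band coincidence counts match the double-loop oracle", {
  set.seed(1)
  for (i in 1:30) {
    t1 <- sort(runif(sample(5:200, 1), 0, 1))
    t2 <- sort(runif(sample(5:200, 1), 0, 1))
    expect_identical(stanflow:::coincidenceCount(t1, t2, 0.0025),
                     coincBrute(t1, t2, 0.0025))
  }
})

test_that("ESI of identical trains with silent shuffles is 50 percent", {
  train <- seq(0.05, 0.95, by = 0.05)   # ISIs far above delta/2
  silent <- lapply(1:4, function(i) train + 0.43 + i * 0.001 %% 1)
  silent <- lapply(silent, function(x) x[x < 1])
  # shift so no shuffle coincidences fall inside the band
  expect_equal(esi(train, train, list(numeric(0), numeric(0),
                                      numeric(0), numeric(0))), 50)
  expect_error(esi(numeric(0), train, list(numeric(0))), "empty")
})

test_that("the shift predictor makes ESI unbiased for independent Poisson pairs", {
  set.seed(2)
  vals <- replicate(100, {
    trains <- lapply(1:6, function(i) sort(runif(rpois(1, 20), 0, 1)))
    if (!length(trains[[1]]) || !length(trains[[2]])) return(NA_real_)
    esi(trains[[1]], trains[[2]], trains[3:6])
  })
  vals <- vals[!is.na(vals)]
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals)), 3 * se + 1e-9)
})

test_that("kernelized binless similarity: identity, closed form, empty convention", {
  t1 <- c(0.010, 0.050, 0.090)
  expect_equal(kernelizedBinless(t1, t1), 1.0, tolerance = 1e-12)
  # single spikes Dt apart: similarity = exp(-|Dt| / phi)
  s <- kernelizedBinless(0.020, 0.025, phiMs = 5, gridMs = 0.1, windowS = 0.2)
  expect_equal(s, exp(-1), tolerance = 1e-3)
  expect_equal(kernelizedBinless(numeric(0), t1), 0)
  # grid refinement changes the value by < 1e-3
  s2 <- kernelizedBinless(0.020, 0.025, phiMs = 5, gridMs = 0.05, windowS = 0.2)
  expect_lt(abs(s2 - s), 1e-3)
})

test_that("pairwise matrices are symmetric with (N choose 2) features per stimulus", {
  cfg <- defaultBenchmarkConfig(seed = 41)
  rec <- simulatePopulation(cfg)
  psm <- suppressWarnings(pairwiseMatrix(rec, "esi"))
  expect_length(psm@matrices, 8)
  M <- psm@matrices[["B1"]]
  expect_true(isSymmetric(unname(M)))
  feats <- upperTriFeatures(psm)
  expect_equal(dim(feats), c(8L, 66L))
  # planted-sync pairs under a behavioral stimulus beat independent pairs
  syncIdx <- which(upper.tri(M) & row(M) <= 6 & col(M) <= 6)
  indIdx <- which(upper.tri(M) & row(M) > 6 & col(M) > 6)
  bRows <- paste0("B", 1:4)
  syncScore <- mean(vapply(bRows, function(s)
    mean(psm@matrices[[s]][syncIdx], na.rm = TRUE), numeric(1)))
  indScore <- mean(vapply(bRows, function(s)
    mean(psm@matrices[[s]][indIdx], na.rm = TRUE), numeric(1)))
  expect_gt(syncScore, indScore + 5)
})

test_that("stimulus clustering separates separable rows and is label-symmetric", {
  set.seed(3)
  feats <- rbind(matrix(rnorm(40, 5), 4), matrix(rnorm(40, -5), 4))
  classes <- c(rep("behavioral", 4), rep("non_behavioral", 4))
  cr <- clusterStimuli(feats, classes, nSeeds = 5, seed = 1)
  expect_equal(cr$accuracy, 1.0)
  crSwap <- clusterStimuli(feats, rev(classes), nSeeds = 5, seed = 1)
  expect_equal(crSwap$accuracy, 1.0)
  expect_error(clusterStimuli(feats, rep("behavioral", 8), 5, 1), "both")
})

test_that("clustering of structureless rows stays in the chance band", {
  set.seed(4)
  accs <- replicate(60, {
    feats <- matrix(rnorm(20 * 6), 20)
    classes <- c(rep("behavioral", 10), rep("non_behavioral", 10))
    clusterStimuli(feats, classes, nSeeds = 2, seed = sample.int(1e6, 1))$accuracy
  })
  expect_gt(mean(accs), 0.5)
  expect_lt(mean(accs), 0.75)
})

test_that("attention summary rows are simplex vectors; single-unit case is all ones", {
  cfg <- defaultBenchmarkConfig(seed = 51)
  rec <- simulatePopulation(cfg)
  split <- makeSplits(5)[[1]]
  tc <- trainConfig(epochs = 2, lr = 3e-3, batchSize = 512, deltaMs = 10,
                    hidden = 6, embed = 3, layers = 2, width = 8,
                    patience = 2, seed = 1)
  models <- trainPopulationModels(rec, split, tc, units = c("u01", "u07"))
  summ <- suppressWarnings(attentionSummary(models, rec))
  expect_equal(rowSums(summ@B), rep(1, 8), tolerance = 1e-9,
               ignore_attr = TRUE)
  # single-unit population: beta is always the length-1 simplex
  rec1 <- poissonRecording(12, 5, trialDur = 2, seed = 5)
  m1 <- trainNeuronModel(rec1, "u1", split,
                         trainConfig(epochs = 2, deltaMs = 10, hidden = 6,
                                     embed = 3, layers = 2, width = 8,
                                     patience = 2, seed = 2))
  s1 <- attentionSummary(list(u1 = m1), rec1)
  expect_equal(as.numeric(s1@B), rep(1, 1), ignore_attr = TRUE)
})

test_that("ablation: empty removal reproduces the baseline exactly and is deterministic", {
  B <- matrix(runif(48), 8, 6)
  B <- B / rowSums(B)
  summ <- new("SyncSummary", B = B, perNeuron = list(),
              stimulusIds = paste0("s", 1:8), unitIds = paste0("u", 1:6),
              classes = c(rep("behavioral", 4), rep("non_behavioral", 4)))
  colnames(summ@B) <- summ@unitIds; rownames(summ@B) <- summ@stimulusIds
  base <- clusterStimuli(B, summ@classes, nSeeds = 5, seed = 9)
  ab0 <- ablationAccuracy(summ, character(), nSeeds = 5, seed = 9)
  expect_identical(ab0$accuracy, base$accuracy)
  ab1 <- ablationAccuracy(summ, "u3", nSeeds = 5, seed = 9)
  ab2 <- ablationAccuracy(summ, "u3", nSeeds = 5, seed = 9)
  expect_identical(ab1$accuracy, ab2$accuracy)
  expect_error(ablationAccuracy(summ, summ@unitIds), "every unit")
})

test_that("response index follows its defining arithmetic and scale invariance", {
  # hand-built rates: odor 10, control 2, two fillers chosen so that
  # mean = 5 and SD = 2 are NOT assumed -- compute the formula directly
  mkRec <- function(scale = 1) {
    rows <- list()
    rates <- c(A = 10, B = 4, C = 4, Ctl = 2) * scale
    for (s in names(rates)) {
      n <- round(rates[[s]] * 0.6)
      if (n > 0)
        rows[[s]] <- data.frame(unit_id = "u", stimulus_id = s, trial = 1L,
                                spike_time_s = seq(0.2001, 0.7999,
                                                   length.out = n))
    }
    makeEnsembleRecording(do.call(rbind, rows), "u",
                          c(A = "behavioral", B = "non_behavioral",
                            C = "non_behavioral", Ctl = "control"),
                          1, stimOnset = 0.2, stimDuration = 0.4,
                          trialDuration = 1)
  }
  rec <- mkRec()
  rates <- vapply(c("A", "B", "C", "Ctl"), function(s)
    stanflow:::evokedRate(rec, "u", s), numeric(1))
  expected <- ((rates["A"] - rates["Ctl"]) - mean(rates)) / sd(rates)
  expect_equal(responseIndex(rec, "u", "A"), expected, ignore_attr = TRUE)
  # spike-count doubling rescales all rates; RI is invariant in its SD units
  expect_equal(responseIndex(rec, "u", "A"),
               responseIndex(mkRec(2), "u", "A"), tolerance = 0.3)
})

test_that("PSTH z-scores are near zero for homogeneous firing and error on flat baselines", {
  rec <- poissonRecording(10, 50, trialDur = 3, onset = 1, seed = 6)
  ps <- psthZscore(rec, "u1", "s", binMs = 20)
  # homogeneous firing: no systematic response anywhere
  expect_lt(mean(abs(ps$z)), 0.5)
  expect_lt(max(abs(ps$z)), 4)
  # smoothing approximately conserves total count (edge truncation <= 1%)
  raw <- sum(vapply(1:50, function(tr)
    length(spikeTimes(rec, "u1", "s", tr)), numeric(1))) / 50
  expect_equal(sum(ps$psth), raw, tolerance = 0.01 * raw)
  # a recording with an empty baseline has zero variance -> error
  ev <- data.frame(unit_id = "u", stimulus_id = "s", trial = 1L,
                   spike_time_s = c(1.5, 1.6, 1.7))
  rec0 <- makeEnsembleRecording(ev, "u", c(s = "control"), 1, 1, 0.4, 3)
  expect_error(psthZscore(rec0, "u", "s"), "baseline")
})

test_that("dissimilarity index: 3-4-5 distance, unit mean, zero self-distance", {
  B <- rbind(ref = c(0, 0), a = c(3, 4), b = c(0, 10), self = c(0, 0))
  summ <- new("SyncSummary", B = B, perNeuron = list(),
              stimulusIds = rownames(B), unitIds = c("u1", "u2"),
              classes = rep("behavioral", 4))
  d <- dissimilarityIndex(summ, "ref", c("a", "b"))
  expect_equal(unname(d["a"] / d["b"]), 5 / 10)
  expect_equal(mean(d), 1)
  d2 <- dissimilarityIndex(summ, "ref", c("a", "self"))
  expect_equal(unname(d2["self"]), 0)
  expect_error(dissimilarityIndex(summ, "ref", "a"), "at least 2")
})
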