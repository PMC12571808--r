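test_that("simulation is deterministic and honors planted structure", {
  cfg <- defaultBenchmarkConfig(seed = 11)
  rec1 <- simulatePopulation(cfg)
  rec2 <- simulatePopulation(cfg)
  expect_identical(rec1@spikes, rec2@spikes)
  truth <- plantedTruth(cfg)
  expect_equal(unname(truth$syncGroup), rep("G1", 6))
  expect_setequal(names(truth$syncGroup), sprintf("u%02d", 1:6))
  expect_equal(sum(truth$unitType == "PN_like"), 6)
  expect_equal(sum(truth$stimulusClass == "behavioral"), 4)
})

test_that("a homogeneous Poisson unit has the configured mean count", {
  # LN-like with gamma shape 1 is an exponential-renewal (Poisson) process
  stim <- data.frame(id = "s", class = "control", syncGroup = NA_character_)
  cfg <- simulationConfig(nUnits = 1, groupAssignments = "independent",
                          unitTypes = "LN_like", stimuli = stim,
                          trialsPerStimulus = 100, trialDuration = 10,
                          stimOnset = 10, stimDuration = 0.4,
                          baselineRate = 10, evokedRates = matrix(10, 1, 1),
                          gammaShape = 1, rateGainSd = 0, seed = 4)
  rec <- simulatePopulation(cfg)
  counts <- vapply(1:100, function(tr) length(spikeTimes(rec, "u01", "s", tr)),
                   numeric(1))
  # expected 100 per trial; mean of 100 trials within 3 SE (SE = 10/sqrt(100))
  expect_lt(abs(mean(counts) - 100), 3)
})

test_that("perfect synchrony copies the mother train exactly", {
  stim <- data.frame(id = "s", class = "behavioral", syncGroup = "G")
  cfg <- simulationConfig(nUnits = 2, groupAssignments = c("G", "G"),
                          unitTypes = c("LN_like", "LN_like"), stimuli = stim,
                          trialsPerStimulus = 2, trialDuration = 3,
                          stimOnset = 1, stimDuration = 0.4,
                          baselineRate = 0, evokedRates = matrix(30, 2, 1),
                          syncCopyProb = 1, syncJitterMs = 0, seed = 9)
  rec <- simulatePopulation(cfg)
  for (tr in 1:2)
    expect_identical(spikeTimes(rec, "u01", "s", tr),
                     spikeTimes(rec, "u02", "s", tr))
})

test_that("evoked rate exceeds baseline for responsive units", {
  cfg <- defaultBenchmarkConfig(seed = 21)
  rec <- simulatePopulation(cfg)
  win <- c(rec@stimOnset, rec@stimOnset + rec@stimDuration)
  rateIn <- function(u, s, a, b) mean(vapply(1:5, function(tr) {
    st <- spikeTimes(rec, u, s, tr)
    sum(st >= a & st < b) / (b - a)
  }, numeric(1)))
  # sync units under a behavioral stimulus: near 25 Hz evoked vs ~5 baseline
  ev <- mean(vapply(sprintf("u%02d", 1:6), function(u)
    rateIn(u, "B1", win[1], win[2]), numeric(1)))
  base <- mean(vapply(sprintf("u%02d", 1:6), function(u)
    rateIn(u, "B1", 0, rec@stimOnset), numeric(1)))
  expect_gt(ev, 2.5 * base)
})

test_that("same-group pairs show a central cross-correlogram peak; independent pairs do not", {
  cfg <- defaultBenchmarkConfig(seed = 31)
  rec <- simulatePopulation(cfg)
  clip <- function(u, tr) {
    st <- spikeTimes(rec, u, "B1", tr)
    st[st >= rec@stimOnset & st < rec@stimOnset + 0.4]
  }
  central <- function(u1, u2) {
    cc <- do.call(rbind, lapply(1:5, function(tr)
      crossCorrelogram(clip(u1, tr), clip(u2, tr), binMs = 1, spanMs = 50)))
    agg <- aggregate(count ~ lagMs, cc, sum)
    peak <- sum(agg$count[abs(agg$lagMs) <= 5])      # 10 central bins
    chance <- sum(agg$count[abs(agg$lagMs) > 25]) * (10 / 50)
    c(peak = peak, chance = chance)
  }
  syncPair <- central("u01", "u02")
  excess <- syncPair["peak"] - syncPair["chance"]
  expect_gt(excess, 5 * sqrt(syncPair["chance"] + 1))
  indPair <- central("u07", "u08")   # both near-baseline under B1
  expect_lt(abs(indPair["peak"] - indPair["chance"]),
            5 * sqrt(indPair["chance"] + 1) + 3)
})

test_that("PN-like spontaneous trains are bursty (CV > 1) and LN-like regular (CV < 1)", {
  cfg <- simulationConfig(
    nUnits = 2, groupAssignments = rep("independent", 2),
    unitTypes = c("PN_like", "LN_like"),
    stimuli = data.frame(id = "s", class = "control",
                         syncGroup = NA_character_),
    trialsPerStimulus = 1, trialDuration = 60, stimOnset = 60,
    stimDuration = 0.4, baselineRate = 5, evokedRates = matrix(5, 2, 1),
    seed = 13)
  rec <- simulatePopulation(cfg)
  cv <- function(u) {
    isi <- diff(spikeTimes(rec, u, "s", 1))
    sd(isi) / mean(isi)
  }
  expect_gt(cv("u01"), 1)
  expect_lt(cv("u02"), 1)
})

test_that("truth labels survive a config round-trip through serialization", {
  cfg <- defaultBenchmarkConfig(seed = 3)
  truth <- plantedTruth(cfg)
  json <- jsonlite::toJSON(lapply(truth, as.list), auto_unbox = TRUE)
  back <- jsonlite::fromJSON(json)
  expect_equal(unlist(back$stimulusClass), truth$stimulusClass)
  expect_equal(unlist(back$syncGroup), truth$syncGroup)
  expect_equal(unlist(back$unitType), truth$unitType)
})
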