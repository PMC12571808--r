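# Small in-code fixtures shared across the suite.

# a two-unit, two-stimulus recording with hand-placed spikes
tinyRecording <- function() {
  events <- data.frame(
    unit_id = c("a", "a", "a", "b", "b", "b", "a", "b"),
    stimulus_id = c(rep("s1", 6), "s2", "s2"),
    trial = 1L,
    spike_time_s = c(0.010, 0.025, 0.045, 0.012, 0.030, 0.800, 0.5, 0.6))
  makeEnsembleRecording(events, unitIds = c("a", "b"),
                        stimuli = c(s1 = "behavioral", s2 = "control"),
                        trialsPerStimulus = 1, stimOnset = 0.2,
                        stimDuration = 0.4, trialDuration = 1)
}

# homogeneous Poisson recording: one unit, one stimulus, many trials
poissonRecording <- function(rateHz, nTrials, trialDur = 3, onset = 1,
                             seed = 1) {
  set.seed(seed)
  rows <- list()
  for (tr in seq_len(nTrials)) {
    n <- rpois(1, rateHz * trialDur)
    if (n == 0) next
    rows[[length(rows) + 1L]] <- data.frame(
      unit_id = "u1", stimulus_id = "s", trial = tr,
      spike_time_s = sort(runif(n, 0, trialDur)))
  }
  makeEnsembleRecording(do.call(rbind, rows), unitIds = "u1",
                        stimuli = c(s = "control"),
                        trialsPerStimulus = nTrials, stimOnset = onset,
                        stimDuration = 0.4, trialDuration = trialDur)
}

# brute-force simplex projection by support-set enumeration (independent of
# the sort-threshold algorithm under test)
projectSimplexBrute <- function(z) {
  n <- length(z)
  best <- NULL
  bestDist <- Inf
  for (mask in 1:(2^n - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    tau <- (sum(z[S]) - 1) / length(S)
    p <- numeric(n)
    p[S] <- z[S] - tau
    if (any(p[S] < -1e-12)) next
    if (any(p < 0)) next
    d <- sum((p - z)^2)
    if (d < bestDist - 1e-15) { bestDist <- d; best <- p }
  }
  best
}

# a tiny model with randomized parameters for transform-level tests
randomTinyModel <- function(seed = 1, layers = 3) {
  m <- stanFlowModel("u", nUnits = 2, nStimuli = 2, deltaMs = 4, binMs = 1,
                     hidden = 4, embed = 2, layers = layers, width = 6,
                     trialDuration = 2, seed = seed)
  set.seed(seed + 100)
  m@par <- m@par + rnorm(length(m@par), 0, 0.3)
  m
}
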