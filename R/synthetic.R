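## Population spike-train simulator with planted synchronization, stimulus
## classes and PN-like / LN-like spontaneous dynamics.
##
## Evoked drive is realized as an excess process superposed on the unit's own
## spontaneous background: independent responsive units receive an independent
## Poisson excess at (evoked - baseline) Hz during the stimulation window;
## members of a sync group share one mother Poisson excess train and keep each
## mother spike with probability syncCopyProb plus Gaussian jitter.  PN-like
## units draw an alternating burst renewal process for spontaneous activity
## (bursty, ISI CV > 1); LN-like units draw a high-shape gamma renewal process
## (regular, ISI CV < 1).

#' Build a SimulationConfig
#'
#' @param nUnits number of units.
#' @param groupAssignments per-unit sync-group id or \code{"independent"}.
#' @param unitTypes per-unit \code{"PN_like"} or \code{"LN_like"}.
#' @param stimuli data.frame with columns \code{id}, \code{class}
#'   (behavioral / non_behavioral / control) and \code{syncGroup} (group the
#'   stimulus drives through a shared mother process; NA for none).
#' @param trialsPerStimulus trials per stimulus (default 5).
#' @param trialDuration,stimOnset,stimDuration trial timing in seconds
#'   (defaults 3.0, 1.0 and 0.4).
#' @param baselineRate spontaneous rate in Hz (recycled over units).
#' @param evokedRates nUnits x nStimuli matrix of evoked rates (Hz).
#' @param syncCopyProb,syncJitterMs mother-process thinning probability and
#'   spike-time jitter (ms; default 2, inside the 5 ms coincidence window of
#'   the ESI).
#' @param rateGainSd sd (log scale) of the per-trial multiplicative response
#'   gain (log-normal, mean 1; default 0.5). The gain is shared by a sync
#'   group through its mother process and drawn independently per responsive
#'   unit otherwise, emulating the trial-to-trial response variability of real
#'   ensemble recordings; it is what makes planted synchrony a predictive
#'   (and hence attention-detectable) structure rather than a pure
#'   coincidence structure.
#' @param burstIntraRate,burstMeanLength,burstInterRate PN-like burst process
#'   (defaults 100 Hz within burst, mean 4 spikes, 2 Hz burst initiation).
#' @param gammaShape LN-like gamma renewal shape (default 9, ISI CV = 1/3).
#' @param seed RNG seed.
#' @return a validated \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(nUnits, groupAssignments, unitTypes, stimuli,
                             trialsPerStimulus = 5, trialDuration = 3.0,
                             stimOnset = 1.0, stimDuration = 0.4,
                             baselineRate = 5, evokedRates,
                             syncCopyProb = 0.9, syncJitterMs = 2,
                             rateGainSd = 0.5,
                             burstIntraRate = 100, burstMeanLength = 4,
                             burstInterRate = 2, gammaShape = 9, seed = 1) {
  if (is.null(stimuli$syncGroup)) stimuli$syncGroup <- NA_character_
  cfg <- new("SimulationConfig",
             nUnits = as.integer(nUnits),
             groupAssignments = as.character(groupAssignments),
             unitTypes = as.character(unitTypes),
             stimuli = stimuli,
             trialsPerStimulus = as.integer(trialsPerStimulus),
             trialDuration = trialDuration, stimOnset = stimOnset,
             stimDuration = stimDuration,
             baselineRate = rep_len(baselineRate, nUnits),
             evokedRates = evokedRates,
             syncCopyProb = syncCopyProb, syncJitterMs = syncJitterMs,
             rateGainSd = rateGainSd,
             burstIntraRate = burstIntraRate, burstMeanLength = burstMeanLength,
             burstInterRate = burstInterRate, gammaShape = gammaShape,
             seed = as.integer(seed))
  validObject(cfg)
  cfg
}

## homogeneous Poisson train on [0, dur)
rPoissonTrain <- function(rate, dur) {
  if (rate <= 0 || dur <= 0) return(numeric())
  n <- rpois(1, rate * dur)
  sort(runif(n, 0, dur))
}

## gamma renewal train on [0, dur): ISI ~ Gamma(shape, rate = shape * rate_hz)
rGammaRenewalTrain <- function(rate, shape, dur) {
  if (rate <= 0 || dur <= 0) return(numeric())
  out <- numeric(0)
  # random start: first interval from the same law (stationarity is not needed)
  t <- rgamma(1, shape, rate = shape * rate)
  while (t < dur) {
    out <- c(out, t)
    t <- t + rgamma(1, shape, rate = shape * rate)
  }
  out
}

## alternating burst renewal: Exp(interRate) gaps to burst onset, geometric
## burst length (mean burstMeanLength spikes), Exp(intraRate) within-burst ISIs
rBurstTrain <- function(interRate, intraRate, meanLen, dur) {
  out <- numeric(0)
  t <- rexp(1, interRate)
  while (t < dur) {
    len <- rgeom(1, 1 / meanLen) + 1L
    burst <- t + c(0, cumsum(rexp(max(len - 1L, 0L), intraRate)))
    burst <- burst[burst < dur]
    out <- c(out, burst)
    if (!length(burst)) break
    t <- burst[length(burst)] + rexp(1, interRate)
  }
  out
}

spontaneousTrainFor <- function(cfg, unit) {
  if (cfg@unitTypes[unit] == "PN_like")
    rBurstTrain(cfg@burstInterRate, cfg@burstIntraRate, cfg@burstMeanLength,
                cfg@trialDuration)
  else
    rGammaRenewalTrain(cfg@baselineRate[unit], cfg@gammaShape, cfg@trialDuration)
}

#' Simulate a population recording from a SimulationConfig
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return an \linkS4class{EnsembleRecording} with units \code{u01, u02, ...}.
#' @export
simulatePopulation <- function(config) {
  validObject(config)
  if (nrow(config@stimuli) == 0) stop("stimulus list is empty")
  units <- sprintf("u%02d", seq_len(config@nUnits))
  spikes <- list()
  jit <- config@syncJitterMs / 1000
  for (si in seq_len(nrow(config@stimuli))) {
    stim <- config@stimuli$id[si]
    driven <- config@stimuli$syncGroup[si]
    for (tr in seq_len(config@trialsPerStimulus)) {
      # deterministic per-trial substream
      set.seed((config@seed * 100003L + si * 1009L + tr) %% 2147483647L)
      win0 <- config@stimOnset
      winDur <- config@stimDuration
      gain <- function() if (config@rateGainSd > 0)
        rlnorm(1, -config@rateGainSd^2 / 2, config@rateGainSd) else 1
      mother <- NULL
      if (!is.na(driven) && driven != "")
        mother <- win0 + rPoissonTrain(max(config@evokedRates[, si]) * gain(),
                                       winDur)
      for (ui in seq_len(config@nUnits)) {
        st <- spontaneousTrainFor(config, ui)
        excess <- config@evokedRates[ui, si] - config@baselineRate[ui]
        inGroup <- !is.na(driven) && driven != "" &&
          config@groupAssignments[ui] == driven
        if (inGroup && !is.null(mother)) {
          keep <- mother[runif(length(mother)) <= config@syncCopyProb]
          if (jit > 0 && length(keep)) keep <- keep + rnorm(length(keep), 0, jit)
          keep <- keep[keep >= 0 & keep <= config@trialDuration]
          st <- c(st, keep)
        } else if (excess > 0) {
          st <- c(st, win0 + rPoissonTrain(excess * gain(), winDur))
        }
        st <- sort(unique(st))
        spikes[[spikeKey(units[ui], stim, tr)]] <- st
      }
    }
  }
  rec <- new("EnsembleRecording",
             unitIds = units,
             stimuli = data.frame(id = config@stimuli$id,
                                  class = config@stimuli$class,
                                  stringsAsFactors = FALSE),
             trialsPerStimulus = config@trialsPerStimulus,
             spikes = spikes, stimOnset = config@stimOnset,
             stimDuration = config@stimDuration,
             trialDuration = config@trialDuration)
  validObject(rec)
  rec
}

#' Ground-truth labels planted by a SimulationConfig
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return list with \code{stimulusClass} (id -> class), \code{syncGroup}
#'   (unit -> group, grouped units only) and \code{unitType} (unit -> type).
#' @export
plantedTruth <- function(config) {
  units <- sprintf("u%02d", seq_len(config@nUnits))
  grouped <- config@groupAssignments != "independent"
  list(stimulusClass = setNames(config@stimuli$class, config@stimuli$id),
       syncGroup = setNames(config@groupAssignments[grouped], units[grouped]),
       unitType = setNames(config@unitTypes, units))
}

#' The benchmark study conditions
#'
#' Twelve units: units 1-6 form one synchronized group of PN-like cells, units
#' 7-12 are independent LN-like cells. Eight stimuli: four behavioral stimuli
#' drive the whole sync group through a shared mother process (the
#' blend-evoked synchronized response); each of the three non-behavioral
#' stimuli evokes a distinct pair of the independent units, emulating single
#' odorants and partial blends that activate only small neuron subsets; the
#' control evokes nothing. Five trials, 3 s trials with a 400 ms stimulation
#' window starting at 1 s; 5 Hz baseline, 25 Hz evoked on responsive units.
#'
#' @param seed RNG seed for the simulation.
#' @return a \linkS4class{SimulationConfig}.
#' @export
defaultBenchmarkConfig <- function(seed = 1) {
  nU <- 12L
  groups <- c(rep("G1", 6), rep("independent", 6))
  types <- c(rep("PN_like", 6), rep("LN_like", 6))
  stimuli <- data.frame(
    id = c(paste0("B", 1:4), paste0("N", 1:3), "Ctl"),
    class = c(rep("behavioral", 4), rep("non_behavioral", 3), "control"),
    syncGroup = c(rep("G1", 4), rep(NA_character_, 4)),
    stringsAsFactors = FALSE)
  ev <- matrix(5, nU, nrow(stimuli))
  ev[1:6, 1:4] <- 25             # behavioral stimuli drive the sync group
  ev[7:8, 5] <- 25               # each non-behavioral stimulus evokes a
  ev[9:10, 6] <- 25              # distinct pair of independent units
  ev[11:12, 7] <- 25
  simulationConfig(nUnits = nU, groupAssignments = groups, unitTypes = types,
                   stimuli = stimuli, evokedRates = ev, seed = seed)
}

#' Spontaneous (pre-stimulus) spike train of one unit
#'
#' Concatenates the pre-onset epochs of every (stimulus, trial) series, shifted
#' end to end, until at least \code{duration} seconds are collected.
#'
#' @param rec an \linkS4class{EnsembleRecording}.
#' @param unit unit identifier.
#' @param duration target segment length in seconds (default 5).
#' @return list with \code{times} (spike times within the concatenated
#'   segment) and \code{duration} (actual segment length, s).
#' @export
spontaneousTrain <- function(rec, unit, duration = 5) {
  epoch <- rec@stimOnset
  out <- numeric(0)
  total <- 0
  for (s in rec@stimuli$id) for (tr in seq_len(rec@trialsPerStimulus)) {
    st <- spikeTimes(rec, unit, s, tr)
    out <- c(out, st[st < epoch] + total)
    total <- total + epoch
    if (total >= duration) return(list(times = out, duration = total))
  }
  list(times = out, duration = total)
}
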