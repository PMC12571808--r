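## S4 containers for population spike-train data and fitted models.

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' EnsembleRecording: population spike trains with stimulus metadata
#'
#' Spike times (seconds, strictly increasing) for every (unit, stimulus, trial)
#' series of a simultaneously recorded ensemble, together with the stimulus
#' table (identifier and behavioral class) and the trial timing metadata.
#'
#' @slot unitIds ordered unit identifiers.
#' @slot stimuli data.frame with columns \code{id} and \code{class}
#'   (\code{"behavioral"}, \code{"non_behavioral"} or \code{"control"}).
#' @slot trialsPerStimulus number of trials recorded for every stimulus.
#' @slot spikes named list; element \code{"unit\\rstimulus\\rtrial"} holds the
#'   numeric spike-time vector of that series.
#' @slot stimOnset stimulus onset within a trial (s).
#' @slot stimDuration stimulation length (s), 0.4 by default upstream.
#' @slot trialDuration total trial length (s).
#' @export
setClass("EnsembleRecording",
  representation(
    unitIds = "character",
    stimuli = "data.frame",
    trialsPerStimulus = "integer",
    spikes = "list",
    stimOnset = "numeric",
    stimDuration = "numeric",
    trialDuration = "numeric"
  )
)

setValidity("EnsembleRecording", function(object) {
  msg <- character()
  if (anyDuplicated(object@unitIds)) msg <- c(msg, "duplicate unit identifiers")
  if (anyDuplicated(object@stimuli$id)) msg <- c(msg, "duplicate stimulus identifiers")
  if (!all(object@stimuli$class %in% c("behavioral", "non_behavioral", "control")))
    msg <- c(msg, "stimulus class must be behavioral, non_behavioral or control")
  expected <- length(object@unitIds) * nrow(object@stimuli) * object@trialsPerStimulus
  if (length(object@spikes) != expected)
    msg <- c(msg, sprintf("expected %d spike series, found %d", expected, length(object@spikes)))
  for (key in names(object@spikes)) {
    st <- object@spikes[[key]]
    if (length(st)) {
      if (any(diff(st) <= 0))
        msg <- c(msg, sprintf("spike times not strictly increasing in series '%s'",
                              gsub("\r", "/", key)))
      if (st[1] < 0 || st[length(st)] > object@trialDuration)
        msg <- c(msg, sprintf("spike time outside [0, trial_duration] in series '%s'",
                              gsub("\r", "/", key)))
    }
  }
  if (length(msg)) msg else TRUE
})

#' BinnedSpikeArray: units x time count matrix
#'
#' @slot counts N x T nonnegative integer count matrix, rows ordered as the
#'   recording's units, columns time-increasing.
#' @slot binMs bin width (ms).
#' @slot t0 time of the first bin's left edge (s).
#' @export
setClass("BinnedSpikeArray",
  representation(counts = "matrix", binMs = "numeric", t0 = "numeric"))

setValidity("BinnedSpikeArray", function(object) {
  if (any(object@counts < 0)) return("negative counts")
  if (object@binMs <= 0) return("bin width must be positive")
  TRUE
})

#' BinnedWindow: Delta-bin history window ending at the previous spike
#'
#' @slot window N x (delta_ms / bin_ms) matrix; bins before recording start are
#'   zero-padded.
#' @slot targetUnit index of the unit whose ISI is being modeled.
#' @slot lastSpikeTime t_{i-1} (s).
#' @slot deltaMs window length (ms).
#' @slot binMs bin width (ms).
#' @export
setClass("BinnedWindow",
  representation(window = "matrix", targetUnit = "integer",
                 lastSpikeTime = "numeric", deltaMs = "numeric", binMs = "numeric"))

#' ISISequence: interspike intervals of one series
#'
#' @slot unit,stimulus,trial series identity.
#' @slot isis positive interarrival times (s).
#' @slot lastSpikeTimes matching t_{i-1} values (s).
#' @export
setClass("ISISequence",
  representation(unit = "character", stimulus = "character", trial = "integer",
                 isis = "numeric", lastSpikeTimes = "numeric"))

setValidity("ISISequence", function(object) {
  if (length(object@isis) != length(object@lastSpikeTimes))
    return("isis and lastSpikeTimes lengths differ")
  if (any(object@isis <= 0)) return("interspike intervals must be positive")
  TRUE
})

#' SimulationConfig: study conditions for the population simulator
#'
#' @slot nUnits number of units.
#' @slot groupAssignments per-unit sync group id or \code{"independent"}.
#' @slot unitTypes per-unit \code{"PN_like"} or \code{"LN_like"}.
#' @slot stimuli data.frame with \code{id}, \code{class} and \code{syncGroup}
#'   (the group whose mother process the stimulus drives; \code{NA} for none).
#' @slot trialsPerStimulus trials per stimulus (5 in the emulated recordings).
#' @slot trialDuration,stimOnset,stimDuration trial timing (s).
#' @slot baselineRate spontaneous rate (Hz) per unit.
#' @slot evokedRates nUnits x nStimuli matrix of evoked rates (Hz) during the
#'   stimulation window.
#' @slot syncCopyProb probability a sync-group member keeps each mother spike.
#' @slot syncJitterMs Gaussian jitter (ms) applied to kept mother spikes.
#' @slot rateGainSd sd (log scale) of the per-trial multiplicative response
#'   gain; shared within a sync group via its mother process, independent per
#'   responsive unit otherwise. 0 disables trial-to-trial gain variability.
#' @slot burstIntraRate,burstMeanLength,burstInterRate PN-like burst process:
#'   within-burst Poisson rate (Hz), geometric mean burst length (spikes),
#'   inter-burst rate (Hz).
#' @slot gammaShape shape of the gamma renewal process of LN-like units.
#' @slot seed RNG seed.
#' @export
setClass("SimulationConfig",
  representation(
    nUnits = "integer", groupAssignments = "character", unitTypes = "character",
    stimuli = "data.frame", trialsPerStimulus = "integer",
    trialDuration = "numeric", stimOnset = "numeric", stimDuration = "numeric",
    baselineRate = "numeric", evokedRates = "matrix",
    syncCopyProb = "numeric", syncJitterMs = "numeric", rateGainSd = "numeric",
    burstIntraRate = "numeric", burstMeanLength = "numeric",
    burstInterRate = "numeric", gammaShape = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nUnits < 1) msg <- c(msg, "need at least one unit")
  if (nrow(object@stimuli) < 1) msg <- c(msg, "stimulus list is empty")
  if (length(object@groupAssignments) != object@nUnits)
    msg <- c(msg, "groupAssignments length != nUnits")
  if (length(object@unitTypes) != object@nUnits)
    msg <- c(msg, "unitTypes length != nUnits")
  if (!all(object@unitTypes %in% c("PN_like", "LN_like")))
    msg <- c(msg, "unitTypes must be PN_like or LN_like")
  if (object@syncCopyProb < 0 || object@syncCopyProb > 1)
    msg <- c(msg, "syncCopyProb must lie in [0, 1]")
  if (any(object@baselineRate < 0) || any(object@evokedRates < 0))
    msg <- c(msg, "rates must be nonnegative")
  if (!identical(dim(object@evokedRates),
                 c(object@nUnits, nrow(object@stimuli))))
    msg <- c(msg, "evokedRates must be nUnits x nStimuli")
  if (length(msg)) msg else TRUE
})

#' StanFlowModel: attention + flow parameters for one neuron
#'
#' All trainable parameters live in one flat numeric vector \code{par}; the
#' layout is fixed by \code{dims} = (N, Delta_bins, hidden, embed, Q, layers,
#' width) and mirrored by the compiled core.
#'
#' @slot unitId the modeled unit.
#' @slot par flat parameter vector.
#' @slot dims named integer vector (N, delta, hidden, embed, Q, layers, width).
#' @slot tauRef ISI reference scale (s) for the log transform.
#' @slot aMax bound on each layer's tanh-bend gate (monotonicity margin).
#' @slot binarize whether history windows are binarized before encoding.
#' @slot binMs,deltaMs discretization of the history window.
#' @slot stimulusIds stimulus order defining the one-hot encoding.
#' @slot trialDuration trial length used to rescale t_{i-1} to [0, 1].
#' @slot fit list with training metadata (split, log, validation NLL).
#' @export
setClass("StanFlowModel",
  representation(
    unitId = "character", par = "numeric", dims = "integer",
    tauRef = "numeric", aMax = "numeric", binarize = "logical",
    binMs = "numeric", deltaMs = "numeric", stimulusIds = "character",
    trialDuration = "numeric", fit = "list"))

#' SyncSummary: stimulus x unit attention summary matrix B
#'
#' @slot B Q x N matrix, the mean over units of the per-neuron matrices.
#' @slot perNeuron list of Q x N matrices B^n, one per modeled unit.
#' @slot stimulusIds,unitIds row/column order.
#' @slot classes behavioral class per stimulus row.
#' @export
setClass("SyncSummary",
  representation(B = "matrix", perNeuron = "list",
                 stimulusIds = "character", unitIds = "character",
                 classes = "character"))

setValidity("SyncSummary", function(object) {
  if (!identical(dim(object@B),
                 c(length(object@stimulusIds), length(object@unitIds))))
    return("B must be nStimuli x nUnits")
  TRUE
})

#' PairwiseSyncMatrix: per-stimulus symmetric unit-pair synchronization scores
#'
#' @slot matrices named list (per stimulus) of symmetric N x N matrices;
#'   diagonal is NA.
#' @slot method \code{"esi"} or \code{"kb"}.
#' @slot params method parameters (delta/T or phi, in ms).
#' @slot unitIds unit order.
#' @export
setClass("PairwiseSyncMatrix",
  representation(matrices = "list", method = "character",
                 params = "list", unitIds = "character"))

#' NeuronTypeModel: burst-feature logistic classifier for PN vs LN
#'
#' @slot coefficients logistic regression coefficients (intercept + features).
#' @slot featureNames the six burst features, in order.
#' @slot trainBounds 2 x p matrix of min/max used to scale training features.
#' @slot scaleTestSeparately if TRUE (the default), prediction rescales test
#'   features with the test set's own min/max bounds.
#' @slot levels class labels; second level is the "positive" (PN) class.
#' @export
setClass("NeuronTypeModel",
  representation(coefficients = "numeric", featureNames = "character",
                 trainBounds = "matrix", scaleTestSeparately = "logical",
                 levels = "character"))

## ---- show methods ----

setMethod("show", "EnsembleRecording", function(object) {
  cat(sprintf("EnsembleRecording: %d units, %d stimuli x %d trials, %.3g s trials\n",
              length(object@unitIds), nrow(object@stimuli),
              object@trialsPerStimulus, object@trialDuration))
  cat(sprintf("  stimulation: onset %.3g s, duration %.3g s\n",
              object@stimOnset, object@stimDuration))
  n <- sum(vapply(object@spikes, length, integer(1)))
  cat(sprintf("  %d spikes total\n", n))
})

setMethod("show", "BinnedSpikeArray", function(object) {
  cat(sprintf("BinnedSpikeArray: %d units x %d bins (%.3g ms bins, t0 = %.3g s), %d spikes\n",
              nrow(object@counts), ncol(object@counts), object@binMs,
              object@t0, sum(object@counts)))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig: %d units (%d sync-grouped), %d stimuli x %d trials, seed %d\n",
              object@nUnits, sum(object@groupAssignments != "independent"),
              nrow(object@stimuli), object@trialsPerStimulus, object@seed))
})

setMethod("show", "StanFlowModel", function(object) {
  dm <- object@dims
  cat(sprintf("StanFlowModel for unit '%s': N=%d, Delta=%d bins, hidden=%d, %d flow layers (%d parameters)\n",
              object@unitId, dm[["N"]], dm[["delta"]], dm[["hidden"]],
              dm[["layers"]], length(object@par)))
  if (!is.null(object@fit$valNLL))
    cat(sprintf("  validation NLL %.4f (rotation %s)\n", object@fit$valNLL,
                as.character(object@fit$rotation %||% NA)))
})

setMethod("show", "SyncSummary", function(object) {
  cat(sprintf("SyncSummary: %d stimuli x %d units (averaged over %d neuron models)\n",
              nrow(object@B), ncol(object@B), length(object@perNeuron)))
})

setMethod("show", "PairwiseSyncMatrix", function(object) {
  cat(sprintf("PairwiseSyncMatrix [%s]: %d stimuli, %d units\n",
              object@method, length(object@matrices), length(object@unitIds)))
})

## ---- accessors ----

#' Accessors for EnsembleRecording
#'
#' @param rec an \linkS4class{EnsembleRecording}.
#' @return \code{unitIds}: character vector of unit identifiers;
#'   \code{stimulusIds}: stimulus identifiers; \code{stimulusClasses}: named
#'   character vector of behavioral classes; \code{trialsPerStimulus},
#'   \code{stimOnset}, \code{stimDuration}, \code{trialDuration}: scalars.
#' @export
unitIds <- function(rec) rec@unitIds

#' @rdname unitIds
#' @export
stimulusIds <- function(rec) rec@stimuli$id

#' @rdname unitIds
#' @export
stimulusClasses <- function(rec) setNames(rec@stimuli$class, rec@stimuli$id)

#' @rdname unitIds
#' @export
trialsPerStimulus <- function(rec) rec@trialsPerStimulus

#' @rdname unitIds
#' @export
stimOnset <- function(rec) rec@stimOnset

#' @rdname unitIds
#' @export
stimDuration <- function(rec) rec@stimDuration

#' @rdname unitIds
#' @export
trialDuration <- function(rec) rec@trialDuration

spikeKey <- function(unit, stimulus, trial) paste(unit, stimulus, trial, sep = "\r")

#' Spike times of one (unit, stimulus, trial) series
#'
#' @param rec an \linkS4class{EnsembleRecording}.
#' @param unit unit identifier.
#' @param stimulus stimulus identifier.
#' @param trial trial index (1-based).
#' @return numeric vector of spike times in seconds (possibly empty).
#' @export
spikeTimes <- function(rec, unit, stimulus, trial) {
  key <- spikeKey(unit, stimulus, trial)
  if (!key %in% names(rec@spikes))
    stop(sprintf("no series for unit '%s', stimulus '%s', trial %s",
                 unit, stimulus, trial))
  rec@spikes[[key]]
}

#' Attention summary matrix of a SyncSummary
#' @param x a \linkS4class{SyncSummary}.
#' @return the Q x N matrix B.
#' @export
summaryMatrix <- function(x) x@B

`%||%` <- function(a, b) if (is.null(a)) b else a
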