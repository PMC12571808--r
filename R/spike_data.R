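## Domain I/O, binning, history windowing and ISI extraction.

#' Construct an EnsembleRecording from a spike table
#'
#' @param events data.frame with columns \code{unit_id}, \code{stimulus_id},
#'   \code{trial} (1-based) and \code{spike_time_s}. Series with no spikes may
#'   simply be absent from the table.
#' @param unitIds,stimuli unit order and stimulus table (\code{id},
#'   \code{class}); stimuli may be a named character vector id -> class.
#' @param trialsPerStimulus,stimOnset,stimDuration,trialDuration metadata.
#' @return a validated \linkS4class{EnsembleRecording}.
#' @export
makeEnsembleRecording <- function(events, unitIds, stimuli, trialsPerStimulus,
                                  stimOnset, stimDuration = 0.4, trialDuration) {
  if (is.character(stimuli) || (is.vector(stimuli) && !is.null(names(stimuli))))
    stimuli <- data.frame(id = names(stimuli), class = unname(stimuli),
                          stringsAsFactors = FALSE)
  stopifnot(all(c("id", "class") %in% names(stimuli)))
  need <- c("unit_id", "stimulus_id", "trial", "spike_time_s")
  if (!all(need %in% names(events)))
    stop("events table must have columns unit_id, stimulus_id, trial, spike_time_s")
  dup <- duplicated(events[, need])
  if (any(dup)) {
    off <- events[dup, , drop = FALSE]
    stop(sprintf("duplicate (unit, stimulus, trial, time) rows, e.g. %s/%s/%d @ %.6f s",
                 off$unit_id[1], off$stimulus_id[1], off$trial[1], off$spike_time_s[1]))
  }
  bad_unit <- setdiff(unique(events$unit_id), unitIds)
  if (length(bad_unit)) stop("events reference unknown units: ",
                             paste(bad_unit, collapse = ", "))
  bad_stim <- setdiff(unique(events$stimulus_id), stimuli$id)
  if (length(bad_stim)) stop("events reference unknown stimuli: ",
                             paste(bad_stim, collapse = ", "))

  spikes <- list()
  for (u in unitIds) for (s in stimuli$id) for (tr in seq_len(trialsPerStimulus)) {
    sel <- events$unit_id == u & events$stimulus_id == s & events$trial == tr
    spikes[[spikeKey(u, s, tr)]] <- sort(as.numeric(events$spike_time_s[sel]))
  }
  rec <- new("EnsembleRecording",
             unitIds = as.character(unitIds), stimuli = stimuli,
             trialsPerStimulus = as.integer(trialsPerStimulus), spikes = spikes,
             stimOnset = stimOnset, stimDuration = stimDuration,
             trialDuration = trialDuration)
  validObject(rec)
  rec
}

#' Read / write a recording as an events CSV plus metadata JSON
#'
#' \code{loadRecording(path)} expects \code{<path>.csv} (columns
#' \code{unit_id,stimulus_id,trial,spike_time_s}) and \code{<path>.json}
#' (keys \code{unit_ids}, \code{stimuli} (id -> class),
#' \code{trials_per_stimulus}, \code{stim_onset_s}, \code{stim_duration_s},
#' \code{trial_duration_s}); \code{path} may also name the CSV directly.
#' \code{writeRecording} emits both files.
#'
#' @param path file stem (or events CSV path) to read from / write to.
#' @return \code{loadRecording}: a validated \linkS4class{EnsembleRecording};
#'   \code{writeRecording}: the stem, invisibly.
#' @export
loadRecording <- function(path) {
  stem <- sub("\\.csv$", "", path)
  csv <- paste0(stem, ".csv")
  meta_path <- paste0(stem, ".json")
  if (!file.exists(csv)) stop("events file not found: ", csv)
  if (!file.exists(meta_path)) stop("metadata file not found: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  need <- c("unit_ids", "stimuli", "trials_per_stimulus", "stim_onset_s",
            "stim_duration_s", "trial_duration_s")
  missing_keys <- setdiff(need, names(meta))
  if (length(missing_keys))
    stop("metadata missing keys: ", paste(missing_keys, collapse = ", "))
  events <- read.csv(csv, stringsAsFactors = FALSE)
  stim <- unlist(meta$stimuli)
  makeEnsembleRecording(events,
                        unitIds = as.character(meta$unit_ids),
                        stimuli = stim,
                        trialsPerStimulus = meta$trials_per_stimulus,
                        stimOnset = meta$stim_onset_s,
                        stimDuration = meta$stim_duration_s,
                        trialDuration = meta$trial_duration_s)
}

#' @rdname loadRecording
#' @param rec an \linkS4class{EnsembleRecording} to serialize.
#' @export
writeRecording <- function(rec, path) {
  stem <- sub("\\.csv$", "", path)
  rows <- list()
  for (key in names(rec@spikes)) {
    st <- rec@spikes[[key]]
    if (!length(st)) next
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    rows[[length(rows) + 1L]] <- data.frame(
      unit_id = parts[1], stimulus_id = parts[2], trial = as.integer(parts[3]),
      spike_time_s = st, stringsAsFactors = FALSE)
  }
  events <- if (length(rows)) do.call(rbind, rows) else
    data.frame(unit_id = character(), stimulus_id = character(),
               trial = integer(), spike_time_s = numeric())
  write.csv(events, paste0(stem, ".csv"), row.names = FALSE)
  meta <- list(
    unit_ids = rec@unitIds,
    stimuli = as.list(setNames(rec@stimuli$class, rec@stimuli$id)),
    trials_per_stimulus = rec@trialsPerStimulus,
    stim_onset_s = rec@stimOnset,
    stim_duration_s = rec@stimDuration,
    trial_duration_s = rec@trialDuration)
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

## bin index of a time; half-open [left, right) bins, final bin closed on the right
binIndex <- function(t, binMs, nBins, t0 = 0) {
  idx <- floor((t - t0) / (binMs / 1000)) + 1L
  idx[t - t0 >= nBins * binMs / 1000] <- nBins  # right edge of the last bin
  as.integer(idx)
}

#' Bin the population spike trains of one (stimulus, trial)
#'
#' Counts spikes of every unit into half-open \code{[left, right)} bins (the
#' final bin is closed on the right), covering the whole trial.
#'
#' @param rec an \linkS4class{EnsembleRecording}.
#' @param stimulus,trial the series to bin.
#' @param binMs bin width in milliseconds (default 1).
#' @return a \linkS4class{BinnedSpikeArray} with N rows in unit order.
#' @export
binSpikes <- function(rec, stimulus, trial, binMs = 1) {
  stopifnot(binMs > 0)
  if (!stimulus %in% rec@stimuli$id) stop("unknown stimulus: ", stimulus)
  if (!trial %in% seq_len(rec@trialsPerStimulus)) stop("unknown trial: ", trial)
  nBins <- as.integer(ceiling(rec@trialDuration * 1000 / binMs))
  counts <- matrix(0L, nrow = length(rec@unitIds), ncol = nBins,
                   dimnames = list(rec@unitIds, NULL))
  for (i in seq_along(rec@unitIds)) {
    st <- spikeTimes(rec, rec@unitIds[i], stimulus, trial)
    if (!length(st)) next
    idx <- binIndex(st, binMs, nBins)
    tab <- tabulate(idx, nbins = nBins)
    counts[i, ] <- tab
  }
  new("BinnedSpikeArray", counts = counts, binMs = binMs, t0 = 0)
}

#' Extract the Delta-window of population history ending at a spike
#'
#' Returns the \code{deltaMs / binMs} most recent columns of the binned array,
#' ending at (and including) the bin that contains \code{lastSpikeTime};
#' columns that would precede the recording start are zero-padded.
#'
#' @param binned a \linkS4class{BinnedSpikeArray}.
#' @param targetUnit index (or id when the array has rownames) of the modeled unit.
#' @param lastSpikeTime t_{i-1} in seconds.
#' @param deltaMs window length in ms; must be a positive multiple of the bin width.
#' @return a \linkS4class{BinnedWindow}.
#' @export
windowHistory <- function(binned, targetUnit, lastSpikeTime, deltaMs) {
  binMs <- binned@binMs
  nb <- deltaMs / binMs
  if (nb <= 0 || abs(nb - round(nb)) > 1e-9)
    stop("deltaMs must be a positive multiple of binMs")
  nb <- as.integer(round(nb))
  nBins <- ncol(binned@counts)
  span <- nBins * binMs / 1000
  if (lastSpikeTime < binned@t0 || lastSpikeTime > binned@t0 + span)
    stop(sprintf("lastSpikeTime %.6f s outside binned span [%.6f, %.6f]",
                 lastSpikeTime, binned@t0, binned@t0 + span))
  if (is.character(targetUnit))
    targetUnit <- match(targetUnit, rownames(binned@counts))
  end <- binIndex(lastSpikeTime, binMs, nBins, binned@t0)
  start <- end - nb + 1L
  win <- matrix(0, nrow = nrow(binned@counts), ncol = nb)
  take <- max(start, 1L):end
  win[, (nb - length(take) + 1L):nb] <- binned@counts[, take, drop = FALSE]
  rownames(win) <- rownames(binned@counts)
  new("BinnedWindow", window = win, targetUnit = as.integer(targetUnit),
      lastSpikeTime = lastSpikeTime, deltaMs = deltaMs, binMs = binMs)
}

#' Interspike intervals of one series
#'
#' @param rec an \linkS4class{EnsembleRecording}.
#' @param unit,stimulus,trial the series.
#' @return an \linkS4class{ISISequence}; empty when the series has < 2 spikes.
#' @export
extractISIs <- function(rec, unit, stimulus, trial) {
  st <- spikeTimes(rec, unit, stimulus, trial)
  if (length(st) < 2)
    return(new("ISISequence", unit = as.character(unit),
               stimulus = as.character(stimulus), trial = as.integer(trial),
               isis = numeric(), lastSpikeTimes = numeric()))
  new("ISISequence", unit = as.character(unit), stimulus = as.character(stimulus),
      trial = as.integer(trial), isis = diff(st),
      lastSpikeTimes = st[-length(st)])
}
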