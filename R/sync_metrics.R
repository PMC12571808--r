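## Synchronization quantification and evaluation: attention summary matrix B,
## cross-correlogram ESI with shift predictor, kernelized binless similarity,
## stimulus clustering, unit ablation, response index, z-scored PSTH and
## dissimilarity index.

#' Attention synchronization summary matrix B
#'
#' For each modeled unit n and stimulus q, the spatial attention weights
#' beta_i are averaged over all spikes i in the evaluation trials (and over
#' rotations when several models per unit are supplied), giving the rows of
#' B^n; B is the mean of the B^n over units. Rows are simplex vectors.
#'
#' @param models named list (by unit) of trained \linkS4class{StanFlowModel}s,
#'   or of lists of models (one per rotation).
#' @param rec the \linkS4class{EnsembleRecording} the models were trained on.
#' @param evalTrials trial indices to evaluate on; \code{NULL} uses each
#'   model's own validation + test trials.
#' @param window optional \code{c(from, to)} in seconds: only spikes inside
#'   this epoch contribute. When comparing against the windowed pairwise
#'   indices (ESI/KB score the T ms after stimulus onset), use the same
#'   response window here so all methods see the same epoch; \code{NULL}
#'   (default) averages over every spike of the trial.
#' @return a \linkS4class{SyncSummary}.
#' @export
attentionSummary <- function(models, rec, evalTrials = NULL, window = NULL) {
  Q <- nrow(rec@stimuli); N <- length(rec@unitIds)
  perNeuron <- list()
  for (unit in names(models)) {
    ms <- models[[unit]]
    if (is(ms, "StanFlowModel")) ms <- list(ms)
    acc <- matrix(0, Q, N, dimnames = list(rec@stimuli$id, rec@unitIds))
    cnt <- matrix(0, Q, N)
    for (model in ms) {
      trials <- evalTrials %||% c(model@fit$split$val, model@fit$split$test)
      ds <- buildTrainingSet(rec, unit, trials, model@deltaMs, model@binMs)
      if (ds$n == 0) next
      if (!is.null(window)) {
        ti <- ds$tlast + ds$tau
        keep <- which(ti >= window[1] & ti < window[2])
        if (!length(keep)) next
        ds <- c(datasetSlice(ds, keep),
                list(stimulus = ds$stimulus[keep]))
      }
      enc <- stanflow_encode(model@par, model@dims, ds$windows, ds$q,
                             model@binarize)
      for (qi in seq_len(Q)) {
        sel <- ds$stimulus == rec@stimuli$id[qi]
        if (!any(sel)) next
        acc[qi, ] <- acc[qi, ] + rowSums(enc$beta[, sel, drop = FALSE])
        cnt[qi, ] <- cnt[qi, ] + sum(sel)
      }
    }
    empty <- rowSums(cnt) == 0
    if (any(empty))
      warning(sprintf("unit '%s': no spikes under stimuli %s; rows skipped",
                      unit, paste(rec@stimuli$id[empty], collapse = ", ")))
    Bn <- acc / cnt
    perNeuron[[unit]] <- Bn
  }
  if (!length(perNeuron)) stop("no models supplied")
  arr <- array(unlist(perNeuron), dim = c(Q, N, length(perNeuron)))
  B <- apply(arr, c(1, 2), mean, na.rm = TRUE)
  dimnames(B) <- list(rec@stimuli$id, rec@unitIds)
  new("SyncSummary", B = B, perNeuron = perNeuron,
      stimulusIds = rec@stimuli$id, unitIds = rec@unitIds,
      classes = rec@stimuli$class)
}

## pairs of spikes with |t1 - t2| <= half-width (seconds); vectorized scan
coincidenceCount <- function(t1, t2, halfWidthS) {
  if (!length(t1) || !length(t2)) return(0L)
  t2 <- sort(t2)
  lo <- findInterval(t1 - halfWidthS, t2, left.open = TRUE)
  hi <- findInterval(t1 + halfWidthS, t2)
  sum(hi - lo)
}

#' Ensemble Synchronization Index (ESI) of a unit pair
#'
#' Coincident events in the central +/- delta/2 band of the cross-correlogram,
#' corrected by the shift predictor (mean over four trial-shifted pairings),
#' normalized by the total spike count of the pair:
#' SI\% = ([CE]_raw - [CE]_shuffle) / (C1 + C2) x 100.
#'
#' Trains must already be restricted to the analysis window (the T ms after
#' stimulus onset).
#'
#' @param train1,train2 spike times (s) of the pair in the analysis window.
#' @param shuffleTrains list of trains of unit 2 from other trials (the four
#'   trial shifts of the shift predictor).
#' @param deltaMs central peak width delta (default 5 ms).
#' @return SI as a percentage.
#' @export
esi <- function(train1, train2, shuffleTrains, deltaMs = 5) {
  if (!length(train1) || !length(train2))
    stop("ESI undefined for an empty train")
  C <- length(train1) + length(train2)
  w <- deltaMs / 2 / 1000
  raw <- coincidenceCount(train1, train2, w)
  shuf <- mean(vapply(shuffleTrains, function(tt)
    as.numeric(coincidenceCount(train1, tt, w)), numeric(1)))
  (raw - shuf) / C * 100
}

#' Cross-correlogram of two spike trains
#'
#' @param train1,train2 spike times (s).
#' @param binMs lag bin width (default 1 ms).
#' @param spanMs maximum |lag| (default 50 ms).
#' @return data.frame with bin centers (\code{lagMs}) and \code{count}.
#' @export
crossCorrelogram <- function(train1, train2, binMs = 1, spanMs = 50) {
  lags <- as.numeric(outer(train2, train1, "-")) * 1000
  lags <- lags[abs(lags) <= spanMs]
  breaks <- seq(-spanMs, spanMs, by = binMs)
  h <- hist(lags, breaks = breaks, plot = FALSE)
  data.frame(lagMs = h$mids, count = h$counts)
}

#' Kernelized binless similarity of two spike trains
#'
#' Each train is convolved with the causal exponential kernel
#' h(t) = exp(-t / phi) u(t) on a fine grid; the similarity is the cosine of
#' the two filtered signals, in [0, 1]. A train with no spikes has
#' similarity 0 by convention.
#'
#' @param train1,train2 spike times (s) within the analysis window.
#' @param phiMs kernel time constant (default 5 ms).
#' @param gridMs grid resolution (default 0.1 ms).
#' @param windowS analysis window length (s); default covers both trains.
#' @return similarity in [0, 1].
#' @export
kernelizedBinless <- function(train1, train2, phiMs = 5, gridMs = 0.1,
                              windowS = NULL) {
  if (!length(train1) || !length(train2)) return(0)
  windowS <- windowS %||% (max(train1, train2) + 5 * phiMs / 1000)
  grid <- seq(0, windowS, by = gridMs / 1000)
  s1 <- kbFilter(train1, grid, phiMs)
  s2 <- kbFilter(train2, grid, phiMs)
  kbCosine(s1, s2)
}

kbFilter <- function(st, grid, phiMs) {
  s <- numeric(length(grid))
  for (tk in st) {
    dt <- grid - tk
    keep <- dt >= 0
    s[keep] <- s[keep] + exp(-dt[keep] / (phiMs / 1000))
  }
  s
}

kbCosine <- function(s1, s2) {
  n1 <- sqrt(sum(s1^2)); n2 <- sqrt(sum(s2^2))
  if (n1 == 0 || n2 == 0) return(0)
  sum(s1 * s2) / (n1 * n2)
}

#' Pairwise synchronization matrices, one per stimulus
#'
#' Trial 1 provides the raw pairing; the other trials provide the shift
#' predictor (ESI) or the shuffle correction (KB, subtracted mean similarity
#' against the other trials of the partner unit). Failed pairs (e.g. empty
#' trains) become NA with a warning.
#'
#' @param rec an \linkS4class{EnsembleRecording}.
#' @param method \code{"esi"} or \code{"kb"}.
#' @param deltaMs ESI central peak width (ms).
#' @param TMs analysis window after onset (ms, default 1000).
#' @param phiMs KB kernel time constant (ms).
#' @param gridMs KB grid (ms).
#' @param rawTrial trial used as the raw pairing (default 1).
#' @return a \linkS4class{PairwiseSyncMatrix}.
#' @export
pairwiseMatrix <- function(rec, method = c("esi", "kb"), deltaMs = 5,
                           TMs = 1000, phiMs = 5, gridMs = 0.1, rawTrial = 1) {
  method <- match.arg(method)
  if (length(rec@unitIds) < 2) stop("need at least 2 units")
  N <- length(rec@unitIds)
  t0 <- rec@stimOnset; t1 <- min(t0 + TMs / 1000, rec@trialDuration)
  clip <- function(st) st[st >= t0 & st < t1] - t0
  shifts <- setdiff(seq_len(rec@trialsPerStimulus), rawTrial)
  mats <- list()
  nFail <- 0L
  grid <- seq(0, t1 - t0, by = gridMs / 1000)
  for (s in rec@stimuli$id) {
    M <- matrix(NA_real_, N, N, dimnames = list(rec@unitIds, rec@unitIds))
    trains <- lapply(rec@unitIds, function(u)
      lapply(seq_len(rec@trialsPerStimulus), function(tr)
        clip(spikeTimes(rec, u, s, tr))))
    filts <- if (method == "kb")
      lapply(trains, function(tt) lapply(tt, kbFilter, grid, phiMs))
    for (i in seq_len(N - 1)) for (j in (i + 1):N) {
      ti <- trains[[i]][[rawTrial]]
      val <- tryCatch({
        if (method == "esi") {
          esi(ti, trains[[j]][[rawTrial]],
              lapply(shifts, function(tr) trains[[j]][[tr]]), deltaMs)
        } else {
          raw <- kbCosine(filts[[i]][[rawTrial]], filts[[j]][[rawTrial]])
          shuf <- mean(vapply(shifts, function(tr)
            kbCosine(filts[[i]][[rawTrial]], filts[[j]][[tr]]), numeric(1)))
          raw - shuf
        }
      }, error = function(e) NA_real_)
      if (is.na(val)) nFail <- nFail + 1L
      M[i, j] <- M[j, i] <- val
    }
    mats[[s]] <- M
  }
  if (nFail > 0)
    warning(nFail, " unit pairs could not be scored (empty trains); entries are NA")
  params <- if (method == "esi") list(deltaMs = deltaMs, TMs = TMs)
            else list(phiMs = phiMs, gridMs = gridMs, TMs = TMs)
  new("PairwiseSyncMatrix", matrices = mats, method = method,
      params = params, unitIds = rec@unitIds)
}

#' Per-stimulus feature rows from a pairwise matrix (upper triangle)
#'
#' @param psm a \linkS4class{PairwiseSyncMatrix}.
#' @param naFill value substituted for unscored pairs (default 0).
#' @return Q x (N choose 2) matrix, rows named by stimulus.
#' @export
upperTriFeatures <- function(psm, naFill = 0) {
  rows <- t(vapply(psm@matrices, function(M) {
    v <- M[upper.tri(M)]
    v[is.na(v)] <- naFill
    v
  }, numeric(sum(upper.tri(psm@matrices[[1]])))))
  rownames(rows) <- names(psm@matrices)
  rows
}

#' Two-class stimulus clustering of synchronization features
#'
#' Reduces the Q x p feature rows to 2 dimensions (PCA) and applies 2-means;
#' accuracy is the best of the two label assignments against the behavioral
#' annotation, so it lies in [0.5, 1]. Repeated over \code{nSeeds} k-means
#' initializations. Clustering on the raw rows (no reduction) is available as
#' a robustness option.
#'
#' @param features Q x p numeric matrix (rows = stimuli).
#' @param classes behavioral class per row; behavioral vs the rest is scored.
#' @param nSeeds number of seeded k-means repetitions (default 10).
#' @param seed base RNG seed.
#' @param reduce \code{"pca"} (default) or \code{"none"}.
#' @return list with \code{accuracy} (mean), \code{sd}, \code{accuracies},
#'   \code{embedding}, \code{labels} (from the first repetition).
#' @export
clusterStimuli <- function(features, classes, nSeeds = 10, seed = 1,
                           reduce = c("pca", "none")) {
  reduce <- match.arg(reduce)
  stopifnot(nrow(features) >= 4)
  y <- classes == "behavioral"
  if (all(y) || !any(y)) stop("both stimulus classes must be present")
  emb <- if (reduce == "pca") {
    keep <- apply(features, 2, function(col) sd(col) > 0)
    f <- features[, keep, drop = FALSE]
    ncomp <- min(2, ncol(f), nrow(f) - 1)
    if (ncomp < 1) features[, 1, drop = FALSE]
    else prcomp(f, center = TRUE, scale. = FALSE)$x[, seq_len(ncomp), drop = FALSE]
  } else features
  accs <- numeric(nSeeds)
  labels1 <- NULL
  for (i in seq_len(nSeeds)) {
    set.seed(seed + i - 1L)
    km <- kmeans(emb, centers = 2, nstart = 10)
    agree <- mean((km$cluster == 1) == y)
    accs[i] <- max(agree, 1 - agree)
    if (i == 1) labels1 <- km$cluster
  }
  list(accuracy = mean(accs), sd = sd(accs), accuracies = accs,
       embedding = emb, labels = labels1)
}

#' Clustering accuracy after removing units from the attention summary
#'
#' Drops the units' columns from B, renormalizes each row back onto the
#' simplex, and reruns the stimulus clustering. Clustering is done on the raw
#' reduced rows by default: re-fitting a 2-D projection for every ablated
#' matrix would make the accuracies incomparable across removals (the
#' embedding axes change discontinuously with the input columns).
#'
#' @param summary a \linkS4class{SyncSummary}.
#' @param removeUnits unit ids (or indices) to remove; may be empty.
#' @param nSeeds,seed clustering repetitions.
#' @param reduce passed to \code{\link{clusterStimuli}} (default
#'   \code{"none"}, see above).
#' @return the \code{\link{clusterStimuli}} report on the reduced matrix.
#' @export
ablationAccuracy <- function(summary, removeUnits = character(),
                             nSeeds = 10, seed = 1, reduce = "none") {
  B <- summary@B
  if (is.numeric(removeUnits)) removeUnits <- summary@unitIds[removeUnits]
  keep <- setdiff(summary@unitIds, removeUnits)
  if (!length(keep)) stop("cannot remove every unit")
  Bk <- B[, keep, drop = FALSE]
  rs <- rowSums(Bk)
  rs[rs == 0] <- 1
  Bk <- Bk / rs
  clusterStimuli(Bk, summary@classes, nSeeds = nSeeds, seed = seed,
                 reduce = reduce)
}

evokedRate <- function(rec, unit, stimulus, windowS = 0.6) {
  t0 <- rec@stimOnset; t1 <- t0 + windowS
  mean(vapply(seq_len(rec@trialsPerStimulus), function(tr) {
    st <- spikeTimes(rec, unit, stimulus, tr)
    sum(st >= t0 & st < t1) / windowS
  }, numeric(1)))
}

#' Response index of a unit to an odor stimulus
#'
#' RI = ((r_odor - r_control) - r_mean) / SD, with firing rates averaged over
#' trials in the 0-600 ms window after stimulus onset; r_mean and SD are taken
#' across all stimuli.
#'
#' @param rec an \linkS4class{EnsembleRecording} with a \code{control} stimulus.
#' @param unit unit identifier.
#' @param odor stimulus identifier.
#' @param windowS response window length (default 0.6 s).
#' @return the response index (dimensionless).
#' @export
responseIndex <- function(rec, unit, odor, windowS = 0.6) {
  ctl <- rec@stimuli$id[rec@stimuli$class == "control"]
  if (!length(ctl)) stop("no control stimulus in the recording")
  if (nrow(rec@stimuli) < 2) stop("need at least 2 stimuli")
  rates <- vapply(rec@stimuli$id, function(s) evokedRate(rec, unit, s, windowS),
                  numeric(1))
  SD <- sd(rates)
  if (SD == 0) stop("zero rate variance across stimuli; RI undefined")
  ((rates[[odor]] - rates[[ctl[1]]]) - mean(rates)) / SD
}

#' z-scored peristimulus time histogram of one unit
#'
#' Trial-averaged spike counts binned at \code{binMs}, smoothed with a
#' Gaussian kernel (sd = \code{smoothSdBins} bins, truncated at 3 sd), and
#' z-scored against the mean and SD of the \code{baselineMs} pre-onset bins.
#' Baseline statistics are taken from the unsmoothed pre-onset bins (the
#' baseline firing-rate variability); smoothing would correlate neighboring
#' baseline bins and deflate the SD estimate.
#'
#' @param rec an \linkS4class{EnsembleRecording}.
#' @param unit,stimulus the series (averaged over trials).
#' @param binMs PSTH bin width (default 20 ms).
#' @param smoothSdBins Gaussian smoothing sd in bins (default 3).
#' @param baselineMs pre-onset baseline length (default 200 ms).
#' @return data.frame with bin centers (\code{timeS}), the smoothed PSTH
#'   (spikes/bin averaged over trials) and its z-score.
#' @export
psthZscore <- function(rec, unit, stimulus, binMs = 20, smoothSdBins = 3,
                       baselineMs = 200) {
  nBins <- as.integer(ceiling(rec@trialDuration * 1000 / binMs))
  counts <- numeric(nBins)
  for (tr in seq_len(rec@trialsPerStimulus)) {
    st <- spikeTimes(rec, unit, stimulus, tr)
    if (length(st))
      counts <- counts + tabulate(binIndex(st, binMs, nBins), nbins = nBins)
  }
  psth <- counts / rec@trialsPerStimulus
  half <- 3 * smoothSdBins
  kern <- dnorm(-half:half, sd = smoothSdBins)
  kern <- kern / sum(kern)
  sm <- numeric(nBins)
  for (i in seq_len(nBins)) {
    lo <- max(1, i - half); hi <- min(nBins, i + half)
    sm[i] <- sum(psth[lo:hi] * kern[(lo - i + half + 1):(hi - i + half + 1)])
  }
  onsetBin <- binIndex(rec@stimOnset, binMs, nBins)
  nBase <- floor(baselineMs / binMs)
  baseIdx <- (onsetBin - nBase):(onsetBin - 1)
  baseIdx <- baseIdx[baseIdx >= 1]
  if (length(baseIdx) < 2) stop("baseline window too short")
  mu <- mean(psth[baseIdx]); sig <- sd(psth[baseIdx])
  if (sig == 0)
    stop("zero baseline variance; use a longer baseline or more trials")
  data.frame(timeS = (seq_len(nBins) - 0.5) * binMs / 1000,
             psth = sm, z = (sm - mu) / sig)
}

#' Normalized dissimilarity of attention rows against a reference stimulus
#'
#' Euclidean distance between the reference row of B and each comparison row,
#' divided by the mean of those distances (so they average to 1).
#'
#' @param summary a \linkS4class{SyncSummary}.
#' @param reference reference stimulus id.
#' @param comparisons at least two comparison stimulus ids.
#' @return named vector of normalized distances.
#' @export
dissimilarityIndex <- function(summary, reference, comparisons) {
  if (length(comparisons) < 2) stop("need at least 2 comparison stimuli")
  B <- summary@B
  if (!reference %in% rownames(B)) stop("unknown reference stimulus")
  ref <- B[reference, ]
  d <- vapply(comparisons, function(s) sqrt(sum((B[s, ] - ref)^2)), numeric(1))
  d / mean(d)
}
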