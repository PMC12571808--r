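## Per-neuron joint training of attention + flow by maximum likelihood, the
## trial-rotation cross-validation scheme, autoregressive spike-train
## generation, and generation-fidelity evaluation.

#' Trial-rotation cross-validation splits
#'
#' Rotation r uses trials \{r, r+1, r+2\} (mod n) for training, r+3 for
#' validation and r+4 for testing (1-based trial indices).
#'
#' @param nTrials number of trials per stimulus (default 5).
#' @return list of splits, each with \code{train}, \code{val}, \code{test}
#'   and \code{rotation}.
#' @export
makeSplits <- function(nTrials = 5) {
  if (nTrials < 3) stop("need at least 3 trials for a train/val/test rotation")
  lapply(seq_len(nTrials), function(r) {
    idx <- ((r - 1L + 0:4) %% as.integer(nTrials)) + 1L
    list(train = idx[1:3], val = idx[4], test = idx[5], rotation = r)
  })
}

stimulusOnehot <- function(stimulusIds, stimulus) {
  q <- numeric(length(stimulusIds))
  q[match(stimulus, stimulusIds)] <- 1
  q
}

#' Build the (window, stimulus, t_{i-1}, tau_i) training examples of one unit
#'
#' One example per spike i >= 2 of the unit in each (stimulus, trial in
#' \code{trials}): the N x Delta population history window ending at the bin
#' containing t_{i-1}, the stimulus one-hot, t_{i-1} and the target ISI.
#'
#' @param rec an \linkS4class{EnsembleRecording}.
#' @param unit the modeled unit.
#' @param trials trial indices to draw examples from.
#' @param deltaMs,binMs window length and bin width (ms).
#' @return list with \code{windows} (N x Delta x B array), \code{q} (Q x B),
#'   \code{trel} (t_{i-1} / trial duration), \code{tlast}, \code{tau},
#'   \code{stimulus}, \code{trial}.
#' @export
buildTrainingSet <- function(rec, unit, trials, deltaMs = 20, binMs = 1) {
  stopifnot(unit %in% rec@unitIds)
  nb <- as.integer(round(deltaMs / binMs))
  N <- length(rec@unitIds)
  wins <- list(); qs <- list(); tlast <- numeric(); tau <- numeric()
  stim_out <- character(); trial_out <- integer()
  for (s in rec@stimuli$id) {
    qv <- stimulusOnehot(rec@stimuli$id, s)
    for (tr in trials) {
      st <- spikeTimes(rec, unit, s, tr)
      if (length(st) < 2) next
      binned <- binSpikes(rec, s, tr, binMs)
      nBins <- ncol(binned@counts)
      for (i in 2:length(st)) {
        t0 <- st[i - 1]
        end <- binIndex(t0, binMs, nBins)
        start <- end - nb + 1L
        win <- matrix(0, N, nb)
        take <- max(start, 1L):end
        win[, (nb - length(take) + 1L):nb] <- binned@counts[, take, drop = FALSE]
        wins[[length(wins) + 1L]] <- win
        qs[[length(qs) + 1L]] <- qv
        tlast <- c(tlast, t0)
        tau <- c(tau, st[i] - t0)
        stim_out <- c(stim_out, s)
        trial_out <- c(trial_out, tr)
      }
    }
  }
  B <- length(wins)
  windows <- array(0, dim = c(N, nb, max(B, 1L)))
  for (b in seq_len(B)) windows[, , b] <- wins[[b]]
  list(windows = windows,
       q = if (B) do.call(cbind, qs) else matrix(0, nrow(rec@stimuli), 0),
       trel = tlast / rec@trialDuration, tlast = tlast, tau = tau,
       stimulus = stim_out, trial = trial_out, n = B)
}

datasetSlice <- function(ds, idx) {
  list(windows = ds$windows[, , idx, drop = FALSE],
       q = ds$q[, idx, drop = FALSE], trel = ds$trel[idx],
       tau = ds$tau[idx], n = length(idx))
}

#' Mean negative log-likelihood of a dataset under a model
#'
#' @param model a \linkS4class{StanFlowModel}.
#' @param ds dataset from \code{\link{buildTrainingSet}}.
#' @return mean NLL (nats per ISI).
#' @export
datasetNLL <- function(model, ds) {
  if (ds$n == 0) return(NA_real_)
  stanflow_nll_grad(model@par, model@dims, ds$windows, ds$q, ds$trel, ds$tau,
                    model@tauRef, model@aMax, model@binarize, FALSE)$nll
}

#' Training configuration defaults
#'
#' @param epochs,lr,batchSize optimization settings (Adam).
#' @param deltaMs,binMs history window discretization.
#' @param hidden,embed,layers,width model sizes.
#' @param tauRef,aMax,binarize flow/encoder settings.
#' @param patience early-stopping patience in epochs.
#' @param seed RNG seed controlling initialization and shuffling.
#' @return a named list.
#' @export
trainConfig <- function(epochs = 200, lr = 1e-3, batchSize = 128,
                        deltaMs = 20, binMs = 1, hidden = 32, embed = 8,
                        layers = 6, width = 64, tauRef = 0.05, aMax = 0.9,
                        binarize = FALSE, patience = 20, seed = 1) {
  stopifnot(epochs >= 1, lr > 0, batchSize >= 1, patience >= 1)
  as.list(environment())
}

adamStep <- function(state, par, grad, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- b1 * state$m + (1 - b1) * grad
  state$v <- b2 * state$v + (1 - b2) * grad^2
  mhat <- state$m / (1 - b1^state$t)
  vhat <- state$v / (1 - b2^state$t)
  state$par <- par - lr * mhat / (sqrt(vhat) + eps)
  state
}

#' Train one neuron's attention + flow model by maximum likelihood
#'
#' Minimizes the mean negative log-likelihood over the training trials with
#' Adam; the checkpoint with the best validation NLL is retained, and the test
#' trial is never consulted.
#'
#' @param rec an \linkS4class{EnsembleRecording}.
#' @param unit the modeled unit.
#' @param split one element of \code{\link{makeSplits}}.
#' @param config a \code{\link{trainConfig}} list.
#' @param quiet suppress progress output.
#' @return a trained \linkS4class{StanFlowModel}; \code{fit} holds the
#'   training log, the best validation NLL and the split.
#' @export
trainNeuronModel <- function(rec, unit, split, config = trainConfig(),
                             quiet = TRUE) {
  train <- buildTrainingSet(rec, unit, split$train, config$deltaMs, config$binMs)
  if (train$n == 0)
    stop(sprintf("unit '%s' has no training examples (every series has < 2 spikes)", unit))
  val <- buildTrainingSet(rec, unit, split$val, config$deltaMs, config$binMs)

  model <- stanFlowModel(unit, nUnits = length(rec@unitIds),
                         nStimuli = nrow(rec@stimuli),
                         stimulusIds = rec@stimuli$id,
                         deltaMs = config$deltaMs, binMs = config$binMs,
                         hidden = config$hidden, embed = config$embed,
                         layers = config$layers, width = config$width,
                         tauRef = config$tauRef, aMax = config$aMax,
                         binarize = config$binarize,
                         trialDuration = rec@trialDuration, seed = config$seed)
  par <- model@par
  st <- list(t = 0, m = numeric(length(par)), v = numeric(length(par)), par = par)
  bestVal <- Inf; bestPar <- par; bestEpoch <- 0L; bad <- 0L
  log_rows <- vector("list", config$epochs)
  set.seed(config$seed + 1L)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(train$n)
    nb <- ceiling(train$n / config$batchSize)
    epochNLL <- 0
    for (ib in seq_len(nb)) {
      idx <- ord[((ib - 1) * config$batchSize + 1):min(ib * config$batchSize, train$n)]
      bs <- datasetSlice(train, idx)
      res <- stanflow_nll_grad(st$par, model@dims, bs$windows, bs$q, bs$trel,
                               bs$tau, model@tauRef, model@aMax,
                               model@binarize, TRUE)
      st <- adamStep(st, st$par, res$grad, config$lr)
      epochNLL <- epochNLL + res$nll * length(idx)
    }
    epochNLL <- epochNLL / train$n
    valNLL <- if (val$n > 0)
      stanflow_nll_grad(st$par, model@dims, val$windows, val$q, val$trel,
                        val$tau, model@tauRef, model@aMax, model@binarize,
                        FALSE)$nll
    else epochNLL
    log_rows[[ep]] <- data.frame(epoch = ep, trainNLL = epochNLL, valNLL = valNLL)
    if (!quiet) message(sprintf("epoch %3d  train %.4f  val %.4f", ep, epochNLL, valNLL))
    if (is.finite(valNLL) && valNLL < bestVal - 1e-6) {
      bestVal <- valNLL; bestPar <- st$par; bestEpoch <- ep; bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= config$patience) break
    }
  }
  model@par <- bestPar
  model@fit <- list(log = do.call(rbind, log_rows[!vapply(log_rows, is.null, TRUE)]),
                    valNLL = bestVal, bestEpoch = bestEpoch,
                    rotation = split$rotation, split = split, config = config)
  model
}

#' Autoregressive generation of one unit's spike train
#'
#' Teacher-forced rollout: the other units' history comes from a held-out
#' empirical trial, the target unit's own row is replaced by the spikes
#' generated so far. Starting from the trial start (empty own history), the
#' window at the last spike is encoded, an ISI is sampled from the flow, and
#' the next spike is emitted until the duration is exceeded.
#'
#' @param model a trained \linkS4class{StanFlowModel}.
#' @param rec an \linkS4class{EnsembleRecording} providing the context trial.
#' @param stimulus stimulus identifier.
#' @param contextTrial trial whose other-unit activity conditions the rollout
#'   (use the split's held-out test trial).
#' @param durationS rollout length in seconds (default: trial duration).
#' @param seed RNG seed.
#' @param maxSpikes runaway guard (error beyond this many spikes).
#' @return strictly increasing generated spike times (s).
#' @export
generateSpikeTrain <- function(model, rec, stimulus, contextTrial,
                               durationS = NULL, seed = 1, maxSpikes = 1e5) {
  durationS <- durationS %||% rec@trialDuration
  binned <- binSpikes(rec, stimulus, contextTrial, model@binMs)
  counts <- binned@counts
  uidx <- match(model@unitId, rec@unitIds)
  counts[uidx, ] <- 0L
  nb <- as.integer(round(model@deltaMs / model@binMs))
  nBins <- ncol(counts)
  qv <- stimulusOnehot(rec@stimuli$id, stimulus)
  set.seed(seed)
  times <- numeric(0)
  t <- 0
  repeat {
    end <- binIndex(t, model@binMs, nBins)
    start <- end - nb + 1L
    win <- matrix(0, nrow(counts), nb)
    take <- max(start, 1L):end
    win[, (nb - length(take) + 1L):nb] <- counts[, take, drop = FALSE]
    enc <- stanflow_encode(model@par, model@dims,
                           array(win, c(nrow(win), nb, 1)),
                           matrix(qv, ncol = 1), model@binarize)
    x <- buildContext(as.numeric(enc$context), qv, min(t, model@trialDuration),
                      model@trialDuration)
    z <- rnorm(1)
    tau <- inverseTransform(model, z, x)
    t <- t + tau
    if (t > durationS) break
    times <- c(times, t)
    if (length(times) > maxSpikes)
      stop("generation runaway: more than ", maxSpikes, " spikes")
    bi <- binIndex(t, model@binMs, nBins)
    counts[uidx, bi] <- counts[uidx, bi] + 1L
  }
  times
}

#' Compare empirical and generated spike statistics
#'
#' Two-sample Kolmogorov-Smirnov test on the ISI samples, a two-sided t-test
#' on per-trial firing rates, and (when response-index vectors are supplied)
#' their Pearson correlation.
#'
#' @param empiricalISIs,generatedISIs ISI samples (s).
#' @param empiricalRates,generatedRates per-trial firing rates (Hz).
#' @param empiricalRI,generatedRI optional response-index vectors.
#' @return list with \code{ks} (statistic, p), \code{rateT} (statistic, p) and
#'   optionally \code{riCorrelation}.
#' @export
evaluateGeneration <- function(empiricalISIs, generatedISIs,
                               empiricalRates, generatedRates,
                               empiricalRI = NULL, generatedRI = NULL) {
  if (length(empiricalISIs) < 2 || length(generatedISIs) < 2)
    stop("need at least 2 ISIs on each side")
  if (length(empiricalRates) < 2 || length(generatedRates) < 2)
    stop("need at least 2 rates on each side")
  ks <- suppressWarnings(ks.test(empiricalISIs, generatedISIs))
  tt <- t.test(empiricalRates, generatedRates)
  out <- list(ks = list(statistic = unname(ks$statistic), p = ks$p.value),
              rateT = list(statistic = unname(tt$statistic), p = tt$p.value))
  if (!is.null(empiricalRI) && !is.null(generatedRI))
    out$riCorrelation <- stats::cor(empiricalRI, generatedRI)
  out
}

#' Fit the conditional flow to a plain ISI sample (constant context)
#'
#' Wraps the full model with a single-unit, single-bin, all-zero history and a
#' single stimulus so the conditioning vector is constant: what remains is the
#' flow's ability to match an arbitrary ISI distribution.
#'
#' @param isis positive ISI sample (s).
#' @param epochs,lr,batchSize,layers,width,hidden,tauRef optimization and
#'   model settings (reduced defaults suited to the 1-D task).
#' @param valFraction fraction held out for model selection.
#' @param seed RNG seed.
#' @return a trained \linkS4class{StanFlowModel}; sample from it with
#'   \code{\link{sampleISI}}.
#' @export
fitISIFlow <- function(isis, epochs = 200, lr = 3e-3, batchSize = 512,
                       layers = 6, width = 32, hidden = 4, tauRef = 0.05,
                       valFraction = 0.15, seed = 1) {
  stopifnot(all(isis > 0), length(isis) >= 10)
  model <- stanFlowModel("isi", nUnits = 1, nStimuli = 1, deltaMs = 1,
                         binMs = 1, hidden = hidden, embed = 2,
                         layers = layers, width = width, tauRef = tauRef,
                         trialDuration = 1, seed = seed)
  n <- length(isis)
  set.seed(seed)
  vidx <- sample.int(n, max(2, round(valFraction * n)))
  mkds <- function(tt) list(windows = array(0, c(1, 1, length(tt))),
                            q = matrix(1, 1, length(tt)),
                            trel = numeric(length(tt)), tau = tt, n = length(tt))
  train <- mkds(isis[-vidx]); val <- mkds(isis[vidx])
  par <- model@par
  st <- list(t = 0, m = numeric(length(par)), v = numeric(length(par)), par = par)
  bestVal <- Inf; bestPar <- par
  for (ep in seq_len(epochs)) {
    ord <- sample.int(train$n)
    nbatch <- ceiling(train$n / batchSize)
    for (ib in seq_len(nbatch)) {
      idx <- ord[((ib - 1) * batchSize + 1):min(ib * batchSize, train$n)]
      bs <- datasetSlice(train, idx)
      res <- stanflow_nll_grad(st$par, model@dims, bs$windows, bs$q, bs$trel,
                               bs$tau, model@tauRef, model@aMax, FALSE, TRUE)
      st <- adamStep(st, st$par, res$grad, lr)
    }
    valNLL <- stanflow_nll_grad(st$par, model@dims, val$windows, val$q,
                                val$trel, val$tau, model@tauRef, model@aMax,
                                FALSE, FALSE)$nll
    if (valNLL < bestVal) { bestVal <- valNLL; bestPar <- st$par }
  }
  model@par <- bestPar
  model@fit <- list(valNLL = bestVal)
  model
}
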