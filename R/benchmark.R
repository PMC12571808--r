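## Reduced-scale end-to-end studies on the simulator benchmark: per-neuron
## model training, attention-summary clustering vs the ESI/KB baselines,
## unit ablation, and the PN/LN typing study.

#' Train one model per unit on a recording
#'
#' @param rec an \linkS4class{EnsembleRecording}.
#' @param split a \code{\link{makeSplits}} element.
#' @param config a \code{\link{trainConfig}}.
#' @param units units to model (default: all).
#' @return named list of trained \linkS4class{StanFlowModel}s.
#' @export
trainPopulationModels <- function(rec, split, config = trainConfig(),
                                  units = NULL) {
  units <- units %||% rec@unitIds
  models <- list()
  for (i in seq_along(units)) {
    cfg <- config
    cfg$seed <- config$seed + i
    models[[units[i]]] <- trainNeuronModel(rec, units[i], split, cfg)
  }
  models
}

#' End-to-end clustering study on the simulator benchmark
#'
#' For each seed: simulate the benchmark conditions, train one reduced-size
#' attention + flow model per unit on one trial rotation, form the attention
#' summary matrix B, and score 2-means stimulus-clustering accuracy of (i) the
#' rows of B, (ii) the ESI pairwise features and (iii) the KB pairwise
#' features; optionally score the accuracy after ablating each unit in turn.
#'
#' @param nSeeds number of simulated replicates (default 10).
#' @param deltaMs history window length (default 20 ms).
#' @param epochs training epochs (default 50).
#' @param nRotations trial rotations trained and averaged per seed (default 2;
#'   the attention summary pools spikes over the rotations' held-out trials).
#' @param methods subset of \code{c("sta", "esi", "kb")}.
#' @param ablate also compute leave-one-unit-out accuracies (default FALSE).
#' @param seed base seed.
#' @param hidden,width,layers,embed reduced model sizes for the study.
#' @param batchSize,lr,patience optimization settings.
#' @return list with \code{perSeed} (data.frame of accuracies), \code{ablation}
#'   (data.frame or NULL), and \code{summaries} (SyncSummary per seed).
#' @export
benchmarkClusteringStudy <- function(nSeeds = 10, deltaMs = 20, epochs = 50,
                                     nRotations = 2,
                                     methods = c("sta", "esi", "kb"),
                                     ablate = FALSE, seed = 1,
                                     hidden = 12, width = 24, layers = 3,
                                     embed = 4, batchSize = 256, lr = 3e-3,
                                     patience = 8) {
  methods <- match.arg(methods, several.ok = TRUE)
  rows <- list(); abl <- list(); summaries <- list()
  for (i in seq_len(nSeeds)) {
    simSeed <- (seed * 1009L + i) %% 2147483647L
    cfg <- defaultBenchmarkConfig(seed = simSeed)
    rec <- simulatePopulation(cfg)
    truth <- plantedTruth(cfg)
    classes <- rec@stimuli$class
    row <- list(seed = simSeed)
    if ("sta" %in% methods) {
      splits <- makeSplits(cfg@trialsPerStimulus)
      perRot <- lapply(seq_len(nRotations), function(r) {
        tc <- trainConfig(epochs = epochs, lr = lr, batchSize = batchSize,
                          deltaMs = deltaMs, hidden = hidden, embed = embed,
                          layers = layers, width = width, patience = patience,
                          seed = simSeed + 50L * (r - 1L))
        trainPopulationModels(rec, splits[[((i - 1 + 2 * (r - 1)) %% 5) + 1]], tc)
      })
      models <- lapply(rec@unitIds, function(u) lapply(perRot, `[[`, u))
      names(models) <- rec@unitIds
      # same analysis epoch as the ESI/KB baselines (T = 1 s after onset)
      summ <- suppressWarnings(attentionSummary(
        models, rec, window = rec@stimOnset + c(0, 1)))
      summaries[[i]] <- summ
      row$sta <- clusterStimuli(summ@B, classes, nSeeds = 10,
                                seed = simSeed)$accuracy
      if (ablate) {
        base <- ablationAccuracy(summ, character(), nSeeds = 10,
                                 seed = simSeed)$accuracy
        for (u in rec@unitIds) {
          acc <- ablationAccuracy(summ, u, nSeeds = 10, seed = simSeed)$accuracy
          abl[[length(abl) + 1L]] <- data.frame(
            seed = simSeed, unit = u,
            group = ifelse(u %in% names(truth$syncGroup), "sync", "independent"),
            accuracy = acc, baseline = base)
        }
      }
    }
    if ("esi" %in% methods) {
      feats <- upperTriFeatures(suppressWarnings(pairwiseMatrix(rec, "esi")))
      row$esi <- clusterStimuli(feats, classes, nSeeds = 10,
                                seed = simSeed)$accuracy
    }
    if ("kb" %in% methods) {
      feats <- upperTriFeatures(suppressWarnings(pairwiseMatrix(rec, "kb")))
      row$kb <- clusterStimuli(feats, classes, nSeeds = 10,
                               seed = simSeed)$accuracy
    }
    rows[[i]] <- as.data.frame(row)
  }
  list(perSeed = do.call(rbind, rows),
       ablation = if (length(abl)) do.call(rbind, abl) else NULL,
       summaries = summaries)
}

#' PN-like vs LN-like typing study on simulated spontaneous activity
#'
#' Simulates \code{nPerClass} bursty (PN-like) and \code{nPerClass} regular
#' (LN-like) units with \code{duration} seconds of spontaneous activity each,
#' extracts the six burst features, fits the logistic classifier on a
#' stratified half of the units and reports held-out accuracy.
#'
#' @param nPerClass units per class (default 20).
#' @param duration spontaneous segment length (s, default 5).
#' @param seed RNG seed.
#' @return list with \code{accuracy}, \code{recall}, \code{precision} (PN as
#'   positive class), the fitted \code{model}, \code{features} and
#'   \code{labels}.
#' @export
typeClassificationStudy <- function(nPerClass = 20, duration = 5, seed = 1) {
  nU <- 2L * nPerClass
  stimuli <- data.frame(id = "Ctl", class = "control",
                        syncGroup = NA_character_, stringsAsFactors = FALSE)
  cfg <- simulationConfig(
    nUnits = nU,
    groupAssignments = rep("independent", nU),
    unitTypes = rep(c("PN_like", "LN_like"), each = nPerClass),
    stimuli = stimuli, trialsPerStimulus = 1,
    trialDuration = duration, stimOnset = duration, stimDuration = 0.4,
    baselineRate = 5, evokedRates = matrix(5, nU, 1), seed = seed)
  rec <- simulatePopulation(cfg)
  truth <- plantedTruth(cfg)
  feats <- t(vapply(rec@unitIds, function(u)
    burstFeatures(spontaneousTrain(rec, u, duration)$times, duration),
    numeric(6)))
  colnames(feats) <- burstFeatureNames
  labels <- ifelse(truth$unitType[rec@unitIds] == "PN_like", "PN", "LN")
  set.seed(seed)
  trainIdx <- c(sample(which(labels == "PN"), nPerClass %/% 2),
                sample(which(labels == "LN"), nPerClass %/% 2))
  testIdx <- setdiff(seq_len(nU), trainIdx)
  model <- fitTypeClassifier(feats[trainIdx, ], labels[trainIdx])
  pred <- classifyNeurons(model, feats[testIdx, ])
  truthTest <- labels[testIdx]
  acc <- mean(pred$predicted == truthTest)
  tp <- sum(pred$predicted == "PN" & truthTest == "PN")
  list(accuracy = acc,
       recall = tp / sum(truthTest == "PN"),
       precision = if (sum(pred$predicted == "PN")) tp / sum(pred$predicted == "PN") else NA,
       model = model, features = feats, labels = labels,
       predictions = pred)
}
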