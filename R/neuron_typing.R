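## PN/LN classification from spontaneous spiking: Poisson-Surprise burst
## detection, six burst features, min-max scaling and a logistic classifier.

#' Poisson Surprise of a spike set
#'
#' S = rT - log sum_{j >= n} (rT)^j / j!, the negative log-probability that a
#' Poisson process at rate r produces at least n events in a span T. Computed
#' through the (log) Poisson survival function for numerical stability; S >= 0.
#'
#' @param n observed number of spikes (>= 0).
#' @param rate mean firing rate r (Hz).
#' @param span time span T of the set (s); \code{rate * span} must be positive.
#' @return the surprise value (nats), vectorized over \code{n}.
#' @export
poissonSurprise <- function(n, rate, span) {
  rT <- rate * span
  if (any(rT <= 0)) stop("rate * span must be positive")
  if (any(n < 0)) stop("n must be nonnegative")
  # sum_{j>=n} (rT)^j/j! = e^{rT} P(X >= n), so S = -log P(X >= n)
  -ppois(n - 1, rT, lower.tail = FALSE, log.p = TRUE)
}

surpriseOfRange <- function(st, i, j, rate) {
  span <- st[j] - st[i]
  if (span <= 0) return(0)
  poissonSurprise(j - i + 1, rate, span)
}

#' Detect bursts by the Poisson-Surprise criterion
#'
#' Seeds are successive spike pairs whose ISI is below p times the mean ISI.
#' Each seed is extended forward one spike at a time while the set's Poisson
#' Surprise strictly increases, then the earliest spikes are pruned while that
#' strictly increases the Surprise. Sets with at least 3 spikes are kept;
#' overlapping sets are merged. The rate r is the whole-segment mean rate.
#'
#' @param spikeTimes strictly increasing spike times (s).
#' @param p seed coefficient in (0, 1); default 0.2.
#' @return data.frame with one row per burst: \code{start}, \code{end} (spike
#'   indices), \code{startTime}, \code{endTime}, \code{nSpikes},
#'   \code{surprise}; zero rows when no bursts are found.
#' @export
detectBursts <- function(spikeTimes, p = 0.2) {
  stopifnot(p > 0, p < 1)
  empty <- data.frame(start = integer(), end = integer(),
                      startTime = numeric(), endTime = numeric(),
                      nSpikes = integer(), surprise = numeric())
  n <- length(spikeTimes)
  if (n < 3) return(empty)
  isis <- diff(spikeTimes)
  meanISI <- mean(isis)
  rate <- 1 / meanISI
  seeds <- which(isis < p * meanISI)
  if (!length(seeds)) return(empty)
  sets <- list()
  used_until <- 0L
  for (s0 in seeds) {
    if (s0 <= used_until) next       # already inside a detected set
    i <- s0; j <- s0 + 1L
    S <- surpriseOfRange(spikeTimes, i, j, rate)
    while (j < n) {
      S2 <- surpriseOfRange(spikeTimes, i, j + 1L, rate)
      if (S2 > S) { j <- j + 1L; S <- S2 } else break
    }
    while (j - i >= 1L) {
      S2 <- surpriseOfRange(spikeTimes, i + 1L, j, rate)
      if (S2 > S) { i <- i + 1L; S <- S2 } else break
    }
    if (j - i + 1L >= 3L) {
      sets[[length(sets) + 1L]] <- c(i, j)
      used_until <- j
    }
  }
  if (!length(sets)) return(empty)
  # merge overlapping index ranges
  merged <- list(sets[[1]])
  for (k in seq_along(sets)[-1]) {
    last <- merged[[length(merged)]]
    cur <- sets[[k]]
    if (cur[1] <= last[2]) merged[[length(merged)]] <- c(last[1], max(last[2], cur[2]))
    else merged[[length(merged) + 1L]] <- cur
  }
  do.call(rbind, lapply(merged, function(r) {
    data.frame(start = r[1], end = r[2],
               startTime = spikeTimes[r[1]], endTime = spikeTimes[r[2]],
               nSpikes = r[2] - r[1] + 1L,
               surprise = surpriseOfRange(spikeTimes, r[1], r[2], rate))
  }))
}

burstFeatureNames <- c("withinBurstMaxFreq", "withinBurstNSpikes",
                       "pctBurstSpikes", "burstFreq", "meanSurprise",
                       "maxSurprise")

#' Six burst features of a spontaneous spike train
#'
#' Within-burst maximum instantaneous spiking frequency (1 / min within-burst
#' ISI, Hz), mean number of spikes per burst, percentage of spikes inside
#' bursts, burst frequency (bursts/s over the segment), and mean and maximum
#' Poisson Surprise. All zero when no bursts are detected.
#'
#' @param spikeTimes spike times (s) of the spontaneous segment.
#' @param segmentDuration segment length (s, default 5).
#' @param p burst-detection coefficient (default 0.2).
#' @return named numeric vector of the six features.
#' @export
burstFeatures <- function(spikeTimes, segmentDuration = 5, p = 0.2) {
  feats <- setNames(numeric(6), burstFeatureNames)
  if (!length(spikeTimes)) {
    warning("empty spike train; all burst features are zero")
    return(feats)
  }
  bursts <- detectBursts(spikeTimes, p)
  if (!nrow(bursts)) return(feats)
  maxFreq <- max(vapply(seq_len(nrow(bursts)), function(k) {
    idx <- bursts$start[k]:bursts$end[k]
    1 / min(diff(spikeTimes[idx]))
  }, numeric(1)))
  feats["withinBurstMaxFreq"] <- maxFreq
  feats["withinBurstNSpikes"] <- mean(bursts$nSpikes)
  feats["pctBurstSpikes"] <- 100 * sum(bursts$nSpikes) / length(spikeTimes)
  feats["burstFreq"] <- nrow(bursts) / segmentDuration
  feats["meanSurprise"] <- mean(bursts$surprise)
  feats["maxSurprise"] <- max(bursts$surprise)
  feats
}

minMaxScale <- function(X, bounds = NULL) {
  X <- as.matrix(X)
  if (is.null(bounds))
    bounds <- rbind(lo = apply(X, 2, min), hi = apply(X, 2, max))
  out <- X
  for (j in seq_len(ncol(X))) {
    rng <- bounds["hi", j] - bounds["lo", j]
    if (rng == 0) {
      warning("constant feature '", colnames(X)[j], "'; scaled value set to 0.5")
      out[, j] <- 0.5
    } else out[, j] <- (X[, j] - bounds["lo", j]) / rng
  }
  list(X = out, bounds = bounds)
}

#' Fit the PN/LN logistic classifier on burst features
#'
#' Features are min-max scaled to [0, 1] with the training set's bounds; at
#' prediction time, test features are by default rescaled with the test set's
#' own bounds (separate scalers), which makes the classifier robust to overall
#' rate-scale differences between preparations; set
#' \code{scaleTestSeparately = FALSE} for conventional train-bounds scaling.
#'
#' @param features matrix/data.frame of the six burst features (rows = units).
#' @param labels class labels, e.g. \code{"PN"} / \code{"LN"}; both must occur.
#' @param scaleTestSeparately see above (default TRUE).
#' @return a \linkS4class{NeuronTypeModel}.
#' @export
fitTypeClassifier <- function(features, labels, scaleTestSeparately = TRUE) {
  X <- as.matrix(features)
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) != 2) stop("need exactly two classes in the training labels")
  sc <- minMaxScale(X)
  y <- as.integer(labels == lev[2])
  # burst features of clean bursty-vs-regular units are completely separable,
  # where plain maximum-likelihood logistic coefficients are non-identified;
  # a light ridge penalty keeps the fit stable without changing the model
  fit <- suppressWarnings(glmnet::glmnet(sc$X, y, family = "binomial",
                                         alpha = 0, lambda = 0.01,
                                         standardize = FALSE))
  co <- as.numeric(stats::coef(fit))
  names(co) <- c("(Intercept)", colnames(X))
  new("NeuronTypeModel", coefficients = co,
      featureNames = colnames(X), trainBounds = sc$bounds,
      scaleTestSeparately = scaleTestSeparately, levels = lev)
}

#' Classify units from burst features
#'
#' @param model a \linkS4class{NeuronTypeModel}.
#' @param features matrix/data.frame of the six burst features.
#' @return data.frame with \code{predicted} (class label) and
#'   \code{probability} (of the second, alphabetically later, class).
#' @export
classifyNeurons <- function(model, features) {
  X <- as.matrix(features)[, model@featureNames, drop = FALSE]
  sc <- if (model@scaleTestSeparately) minMaxScale(X)
        else minMaxScale(X, model@trainBounds)
  eta <- model@coefficients[1] +
    as.numeric(sc$X %*% model@coefficients[-1])
  pr <- 1 / (1 + exp(-eta))
  data.frame(predicted = ifelse(pr >= 0.5, model@levels[2], model@levels[1]),
             probability = pr, row.names = rownames(X))
}
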