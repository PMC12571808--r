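## Spatial-temporal attention encoder: sparsemax, temporal softmax weights,
## spatial sparsemax weights, mean-normalized reweighting, context encoding.
## These R functions are the reference implementations of the individual
## stages; training uses the fused compiled path (src/stanflow.cpp), and the
## two are held to agree in the test suite.

#' Sparsemax: Euclidean projection onto the probability simplex
#'
#' Sort-threshold algorithm: entries below the data-dependent threshold are
#' exactly zero, so the output is a sparse simplex vector.
#'
#' @param logits finite numeric vector, length >= 1.
#' @return nonnegative vector of the same length summing to 1.
#' @export
sparsemax <- function(logits) {
  if (!length(logits)) stop("sparsemax of an empty vector")
  if (any(!is.finite(logits))) stop("sparsemax requires finite logits")
  z <- sort(logits, decreasing = TRUE)
  k <- seq_along(z)
  cum <- cumsum(z)
  supp <- which(1 + k * z > cum)
  kz <- supp[length(supp)]
  tau <- (cum[kz] - 1) / kz
  pmax(logits - tau, 0)
}

## parameter layout shared with src/stanflow.cpp
stanflowParamLayout <- function(dims) {
  N <- dims[["N"]]; Dlt <- dims[["delta"]]; H <- dims[["hidden"]]
  d <- dims[["embed"]]; Q <- dims[["Q"]]; K <- dims[["layers"]]
  M <- dims[["width"]]; X <- H + Q + 1
  layout <- list(
    Wx1 = c(4 * H, N), Wh1 = c(4 * H, H), b1 = c(4 * H, 1),
    We = c(d, Dlt), be = c(d, 1),
    Wa = c(Dlt, H), ba = c(Dlt, 1),
    wb = c(H + d + Q, 1), bb = c(1, 1),
    Wx2 = c(4 * H, N), Wh2 = c(4 * H, H), b2 = c(4 * H, 1))
  for (k in seq_len(K)) {
    layout[[paste0("Ws1_", k)]] <- c(M, X)
    layout[[paste0("bs1_", k)]] <- c(M, 1)
    layout[[paste0("ws2_", k)]] <- c(M, 1)
    layout[[paste0("bs2_", k)]] <- c(1, 1)
    layout[[paste0("Wt1_", k)]] <- c(M, X)
    layout[[paste0("bt1_", k)]] <- c(M, 1)
    layout[[paste0("Wt2_", k)]] <- c(3, M)
    layout[[paste0("bt2_", k)]] <- c(3, 1)
  }
  layout
}

unpackParams <- function(par, dims) {
  layout <- stanflowParamLayout(dims)
  out <- list()
  o <- 0L
  for (nm in names(layout)) {
    dd <- layout[[nm]]
    n <- dd[1] * dd[2]
    out[[nm]] <- matrix(par[(o + 1):(o + n)], dd[1], dd[2])
    o <- o + n
  }
  stopifnot(o == length(par))
  out
}

packParams <- function(plist, dims) {
  layout <- stanflowParamLayout(dims)
  unlist(lapply(names(layout), function(nm) as.numeric(plist[[nm]])),
         use.names = FALSE)
}

## Small uniform init scaled by fan-in; flow output layers start at zero so the
## flow begins as the identity map on log tau.  The spatial head starts
## activity-aligned: the first embedding coordinate measures a unit's recent
## spike count and carries a positive weight into the spatial logit, so
## attention initially amplifies recently active units (the regime sparsemax
## is meant for) instead of an arbitrary random direction; training is free to
## move away from this.
initStanFlowPar <- function(dims) {
  layout <- stanflowParamLayout(dims)
  plist <- list()
  for (nm in names(layout)) {
    dd <- layout[[nm]]
    fan <- max(dd[2], 1)
    r <- 1 / sqrt(fan)
    v <- matrix(runif(dd[1] * dd[2], -r, r), dd[1], dd[2])
    if (grepl("^b", nm)) v[] <- 0
    if (grepl("^(ws2|bs2|Wt2|bt2)_", nm)) v[] <- 0
    plist[[nm]] <- v
  }
  # 0.8 puts a single in-window spike near tanh saturation, so the initial
  # attention tracks recent spike PRESENCE rather than raw burst counts
  plist$We[1, ] <- 0.8
  H <- dims[["hidden"]]
  plist$wb[] <- plist$wb / 10
  plist$wb[H + 1] <- 1
  packParams(plist, dims)
}

#' Construct a (untrained) per-neuron attention + flow model
#'
#' @param unitId identifier of the modeled unit.
#' @param nUnits population size N.
#' @param nStimuli number of stimuli Q (one-hot context block).
#' @param stimulusIds stimulus order defining the one-hot encoding.
#' @param deltaMs,binMs history window length and bin width (ms); defaults 20
#'   and 1 (a 20 ms window resolves the 5 ms synchrony scale).
#' @param hidden recurrent hidden size of both encoders (default 32).
#' @param embed per-unit spatial embedding dimension d (default 8).
#' @param layers number of flow layers K (default 6).
#' @param width hidden width of the flow's scale/shift networks (default 64).
#' @param tauRef ISI reference scale in seconds (default 0.05); ISIs are
#'   modeled on the log(tau / tauRef) scale to enforce positivity.
#' @param aMax bound of each layer's monotone tanh bend (default 0.9).
#' @param binarize binarize history windows before encoding (default FALSE).
#' @param trialDuration trial length (s), used to rescale t_{i-1} to [0, 1].
#' @param seed RNG seed for the parameter initialization.
#' @return a \linkS4class{StanFlowModel}.
#' @export
stanFlowModel <- function(unitId, nUnits, nStimuli,
                          stimulusIds = as.character(seq_len(nStimuli)),
                          deltaMs = 20, binMs = 1, hidden = 32, embed = 8,
                          layers = 6, width = 64, tauRef = 0.05, aMax = 0.9,
                          binarize = FALSE, trialDuration = 3, seed = 1) {
  nb <- deltaMs / binMs
  stopifnot(abs(nb - round(nb)) < 1e-9, nb >= 1)
  dims <- c(N = as.integer(nUnits), delta = as.integer(round(nb)),
            hidden = as.integer(hidden), embed = as.integer(embed),
            Q = as.integer(nStimuli), layers = as.integer(layers),
            width = as.integer(width))
  set.seed(seed)
  par <- initStanFlowPar(dims)
  stopifnot(length(par) == stanflow_param_length(dims))
  new("StanFlowModel", unitId = as.character(unitId), par = par, dims = dims,
      tauRef = tauRef, aMax = aMax, binarize = binarize, binMs = binMs,
      deltaMs = deltaMs, stimulusIds = as.character(stimulusIds),
      trialDuration = trialDuration, fit = list())
}

asWindowMatrix <- function(window) {
  if (is(window, "BinnedWindow")) window@window else as.matrix(window)
}

lstmForwardR <- function(Wx, Wh, b, X) {
  H <- ncol(Wh)
  h <- numeric(H); cc <- numeric(H)
  hs <- matrix(0, H, ncol(X))
  for (t in seq_len(ncol(X))) {
    z <- as.numeric(Wx %*% X[, t] + Wh %*% h) + b
    gi <- 1 / (1 + exp(-z[1:H]))
    gf <- 1 / (1 + exp(-z[(H + 1):(2 * H)]))
    gg <- tanh(z[(2 * H + 1):(3 * H)])
    go <- 1 / (1 + exp(-z[(3 * H + 1):(4 * H)]))
    cc <- gf * cc + gi * gg
    h <- go * tanh(cc)
    hs[, t] <- h
  }
  list(hiddenLast = h, hiddenSeq = hs)
}

maybeBinarize <- function(model, W) {
  if (model@binarize) (W > 0) + 0 else W
}

#' Temporal attention weights over the history window
#'
#' Runs the first recurrent encoder over the window's time axis and maps its
#' final hidden state through a tanh-affine head and a softmax:
#' alpha = softmax(tanh(Wa h + ba)), a simplex vector over the Delta bins.
#'
#' @param model a \linkS4class{StanFlowModel}.
#' @param window a \linkS4class{BinnedWindow} or N x Delta matrix.
#' @return list with \code{alpha}, \code{hiddenLast} (h*) and
#'   \code{hiddenSeq} (hidden x Delta).
#' @export
temporalWeights <- function(model, window) {
  W <- maybeBinarize(model, asWindowMatrix(window))
  dm <- model@dims
  if (!identical(dim(W), c(dm[["N"]], dm[["delta"]])))
    stop(sprintf("window must be %d x %d", dm[["N"]], dm[["delta"]]))
  p <- unpackParams(model@par, dm)
  f1 <- lstmForwardR(p$Wx1, p$Wh1, as.numeric(p$b1), W)
  u <- tanh(as.numeric(p$Wa %*% f1$hiddenLast) + as.numeric(p$ba))
  e <- exp(u - max(u))
  list(alpha = e / sum(e), hiddenLast = f1$hiddenLast, hiddenSeq = f1$hiddenSeq)
}

#' Per-unit spatial embedding of the history window
#'
#' One shared affine map applied to each unit's Delta-length history row:
#' e_m = We S[m, ] + be.
#'
#' @inheritParams temporalWeights
#' @return N x d matrix of embeddings (rows are units).
#' @export
embedWindow <- function(model, window) {
  W <- maybeBinarize(model, asWindowMatrix(window))
  p <- unpackParams(model@par, model@dims)
  t(p$We %*% t(W) + as.numeric(p$be))
}

#' Spatial attention weights over the population
#'
#' Per unit m, a scalar logit tanh(wb . [h*; e_m; q] + bb); sparsemax across
#' the N logits yields the sparse simplex weight vector beta.
#'
#' @param model a \linkS4class{StanFlowModel}.
#' @param hiddenLast final hidden state h* of the first encoder.
#' @param embedding N x d embedding matrix.
#' @param stimulusOnehot one-hot stimulus vector of length Q.
#' @return beta, a sparse simplex vector of length N.
#' @export
spatialWeights <- function(model, hiddenLast, embedding, stimulusOnehot) {
  dm <- model@dims
  if (nrow(embedding) == 0) stop("empty population")
  p <- unpackParams(model@par, dm)
  wb <- as.numeric(p$wb)
  H <- dm[["hidden"]]; d <- dm[["embed"]]; Q <- dm[["Q"]]
  stopifnot(length(hiddenLast) == H, ncol(embedding) == d,
            length(stimulusOnehot) == Q)
  base <- sum(wb[1:H] * hiddenLast) + sum(wb[(H + d + 1):(H + d + Q)] * stimulusOnehot) +
    as.numeric(p$bb)
  logits <- tanh(as.numeric(embedding %*% wb[(H + 1):(H + d)]) + base)
  sparsemax(logits)
}

#' Reweight a history window with mean-normalized attention weights
#'
#' W = beta alpha^T; since both weight vectors sum to 1, mean(W) = 1 / (N
#' Delta), so the mean-normalized weights are N Delta beta alpha^T. Applied
#' elementwise to the window.
#'
#' @param window N x Delta matrix (or \linkS4class{BinnedWindow}).
#' @param alpha temporal simplex weights (length Delta).
#' @param beta spatial simplex weights (length N).
#' @return the reweighted N x Delta matrix.
#' @export
reweightWindow <- function(window, alpha, beta) {
  W <- asWindowMatrix(window)
  tol <- 1e-8
  if (any(alpha < -tol) || abs(sum(alpha) - 1) > 1e-6)
    stop("alpha must lie on the probability simplex")
  if (any(beta < -tol) || abs(sum(beta) - 1) > 1e-6)
    stop("beta must lie on the probability simplex")
  if (length(beta) != nrow(W) || length(alpha) != ncol(W))
    stop("weight lengths must match the window shape")
  (nrow(W) * ncol(W)) * (beta %o% alpha) * W
}

#' Context vector from the reweighted window
#'
#' Final hidden state of the second recurrent encoder run over the reweighted
#' window's time axis.
#'
#' @param model a \linkS4class{StanFlowModel}.
#' @param reweighted N x Delta reweighted window.
#' @return numeric context vector h' of length \code{hidden}.
#' @export
encodeContext <- function(model, reweighted) {
  dm <- model@dims
  W <- asWindowMatrix(reweighted)
  if (!identical(dim(W), c(dm[["N"]], dm[["delta"]])))
    stop(sprintf("reweighted window must be %d x %d", dm[["N"]], dm[["delta"]]))
  p <- unpackParams(model@par, dm)
  lstmForwardR(p$Wx2, p$Wh2, as.numeric(p$b2), W)$hiddenLast
}

#' Full attention encoding of one window (reference path)
#'
#' Chains \code{temporalWeights}, \code{embedWindow}, \code{spatialWeights},
#' \code{reweightWindow} and \code{encodeContext}.
#'
#' @inheritParams temporalWeights
#' @param stimulusOnehot one-hot stimulus vector of length Q.
#' @return list with \code{alpha}, \code{beta}, \code{reweighted},
#'   \code{context}, \code{hiddenLast} and \code{embedding}.
#' @export
encodeWindow <- function(model, window, stimulusOnehot) {
  tw <- temporalWeights(model, window)
  E <- embedWindow(model, window)
  beta <- spatialWeights(model, tw$hiddenLast, E, stimulusOnehot)
  W <- maybeBinarize(model, asWindowMatrix(window))
  rw <- reweightWindow(W, tw$alpha, beta)
  list(alpha = tw$alpha, beta = beta, reweighted = rw,
       context = encodeContext(model, rw), hiddenLast = tw$hiddenLast,
       embedding = E)
}
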