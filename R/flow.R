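## Conditional normalizing flow over interspike intervals: exact likelihood,
## forward/inverse transforms, and seeded sampling.
##
## The target is scalar, so every layer is a strictly monotone map of
## y = log(tau / tauRef): v = exp(s(x)) y + t(x) followed by the gated bend
## u = v + a(x) tanh(v + c(x)) with |a| <= aMax < 1.  The Jacobian of each
## layer is the positive scalar exp(s) (1 + a sech^2(v + c)), so the
## change-of-variables likelihood is exact, and the inverse is obtained by a
## safeguarded Newton iteration on the (globally monotone) bend.

#' Assemble the flow's conditioning vector x = [h'; q; t_{i-1}]
#'
#' @param context context vector h' from \code{\link{encodeContext}}.
#' @param stimulusOnehot one-hot stimulus encoding (length Q).
#' @param lastSpikeTime t_{i-1} in seconds.
#' @param trialDuration trial length (s); the last coordinate is
#'   \code{lastSpikeTime / trialDuration}, i.e. trial-relative in [0, 1].
#' @return numeric vector of length hidden + Q + 1.
#' @export
buildContext <- function(context, stimulusOnehot, lastSpikeTime, trialDuration) {
  if (any(!is.finite(context))) stop("non-finite context")
  if (lastSpikeTime < 0 || lastSpikeTime > trialDuration)
    stop("lastSpikeTime outside [0, trialDuration]")
  c(context, stimulusOnehot, lastSpikeTime / trialDuration)
}

checkContextDim <- function(model, x) {
  dm <- model@dims
  X <- dm[["hidden"]] + dm[["Q"]] + 1L
  if (length(x) != X)
    stop(sprintf("context vector must have length %d (hidden + Q + 1)", X))
  invisible(X)
}

#' Per-layer flow coefficients for a conditioning vector
#'
#' @param model a \linkS4class{StanFlowModel}.
#' @param x conditioning vector from \code{\link{buildContext}}.
#' @return list of K-vectors \code{s}, \code{t}, \code{a}, \code{c}.
#' @export
flowCoefficients <- function(model, x) {
  checkContextDim(model, x)
  co <- stanflow_flow_coeffs(model@par, model@dims, matrix(x, ncol = 1),
                             model@aMax)
  lapply(co, as.numeric)
}

#' Forward flow transform of ISIs
#'
#' Maps tau > 0 to the latent z through y = log(tau / tauRef) and the K
#' monotone layers; also returns the total log |dz / dtau|.
#'
#' @param model a \linkS4class{StanFlowModel}.
#' @param tau positive ISI values (seconds); vectorized.
#' @param x conditioning vector (shared by all tau).
#' @return list with \code{z} and \code{logDet} (per element).
#' @export
forwardTransform <- function(model, tau, x) {
  if (any(tau <= 0)) stop("tau must be positive")
  co <- flowCoefficients(model, x)
  y <- log(tau / model@tauRef)
  logDet <- -log(tau)             # d log(tau/tauRef) / d tau = 1 / tau
  for (k in seq_along(co$s)) {
    v <- exp(co$s[k]) * y + co$t[k]
    th <- tanh(v + co$c[k])
    D <- 1 + co$a[k] * (1 - th^2)
    logDet <- logDet + co$s[k] + log(D)
    y <- v + co$a[k] * th
  }
  list(z = y, logDet = logDet)
}

## invert u = v + a tanh(v + c) by Newton with bisection safeguard
invertBend <- function(u, a, cc, tol = 1e-13, maxit = 100) {
  v <- u
  for (it in seq_len(maxit)) {
    th <- tanh(v + cc)
    g <- v + a * th - u
    if (all(abs(g) < tol)) break
    v <- v - g / (1 + a * (1 - th^2))
  }
  v
}

#' Inverse flow transform
#'
#' @param model a \linkS4class{StanFlowModel}.
#' @param z latent values.
#' @param x conditioning vector.
#' @return positive ISI values tau with forwardTransform(tau, x)$z == z.
#' @export
inverseTransform <- function(model, z, x) {
  co <- flowCoefficients(model, x)
  y <- z
  for (k in rev(seq_along(co$s))) {
    v <- invertBend(y, co$a[k], co$c[k])
    y <- (v - co$t[k]) * exp(-co$s[k])
  }
  model@tauRef * exp(y)
}

#' Exact conditional log-likelihood of ISIs
#'
#' log N(z; 0, 1) + log |dz / dtau|, with the per-layer scalar Jacobians
#' accumulated as a sum (the triangular-Jacobian simplification).
#'
#' @inheritParams forwardTransform
#' @return numeric vector of log-densities.
#' @export
logLikelihood <- function(model, tau, x) {
  ft <- forwardTransform(model, tau, x)
  dnorm(ft$z, log = TRUE) + ft$logDet
}

#' Sample ISIs from the conditional flow
#'
#' Draws z ~ N(0, 1), inverts the flow and exponentiates; always positive.
#'
#' @param model a \linkS4class{StanFlowModel}.
#' @param x conditioning vector; \code{NULL} uses the encoding of an all-zero
#'   history window at trial start (the empty-history context).
#' @param n number of samples.
#' @param seed RNG seed.
#' @return n positive ISI samples (seconds).
#' @export
sampleISI <- function(model, x = NULL, n, seed = 1) {
  stopifnot(n >= 1)
  if (is.null(x)) x <- emptyHistoryContext(model)
  set.seed(seed)
  z <- rnorm(n)
  inverseTransform(model, z, x)
}

## context of an empty history at trial start with the first stimulus
emptyHistoryContext <- function(model, stimulusOnehot = NULL, lastSpikeTime = 0) {
  dm <- model@dims
  if (is.null(stimulusOnehot)) {
    stimulusOnehot <- numeric(dm[["Q"]])
    stimulusOnehot[1] <- 1
  }
  win <- matrix(0, dm[["N"]], dm[["delta"]])
  ctx <- encodeContext(model, win)  # weights do not matter for a zero window
  buildContext(ctx, stimulusOnehot, lastSpikeTime, model@trialDuration)
}
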