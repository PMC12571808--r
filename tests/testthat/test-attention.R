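test_that("sparsemax matches brute-force simplex projection on random vectors", {
  set.seed(1)
  for (i in 1:300) {
    n <- sample(2:8, 1)
    z <- rnorm(n, sd = sample(c(0.1, 1, 5), 1))
    expect_equal(sparsemax(z), projectSimplexBrute(z), tolerance = 1e-8)
  }
})

test_that("sparsemax fixed points, symmetry and one-hot gap cases are exact", {
  expect_equal(sparsemax(c(0.5, 0.3, 0.2)), c(0.5, 0.3, 0.2))  # simplex input
  expect_equal(sparsemax(c(2, 0)), c(1, 0))                    # gap >= 1
  expect_equal(sparsemax(rep(3.7, 3)), rep(1 / 3, 3))          # symmetry
  set.seed(2)
  for (i in 1:50) {   # any vector with one entry larger by >= 1 is one-hot
    n <- sample(2:8, 1)
    z <- runif(n, -1, 1)
    j <- sample(n, 1)
    z[j] <- max(z[-j]) + 1 + runif(1)
    p <- sparsemax(z)
    expect_equal(p[j], 1)
    expect_equal(sum(p), 1)
  }
  expect_error(sparsemax(numeric()), "empty")
})

test_that("temporal weights are a simplex and uniform for zeroed heads", {
  m <- randomTinyModel(5)
  # zero the temporal head -> softmax of constants -> uniform
  p <- stanflow:::unpackParams(m@par, m@dims)
  p$Wa[] <- 0; p$ba[] <- 0
  m0 <- m; m0@par <- stanflow:::packParams(p, m@dims)
  win <- matrix(rpois(8, 1), 2, 4)
  expect_equal(temporalWeights(m0, win)$alpha, rep(0.25, 4))
  set.seed(3)
  for (i in 1:20) {
    mm <- randomTinyModel(i)
    a <- temporalWeights(mm, matrix(rpois(8, 1), 2, 4))$alpha
    expect_true(all(a >= 0))
    expect_equal(sum(a), 1)
  }
})

test_that("spatial weights: single unit, identical embeddings, dominant logit", {
  m1 <- stanFlowModel("u", nUnits = 1, nStimuli = 2, deltaMs = 4, binMs = 1,
                      hidden = 4, embed = 2, layers = 2, width = 4, seed = 1)
  tw <- temporalWeights(m1, matrix(1, 1, 4))
  E <- embedWindow(m1, matrix(1, 1, 4))
  expect_equal(spatialWeights(m1, tw$hiddenLast, E, c(1, 0)), 1)
  # identical embeddings -> uniform beta
  m <- randomTinyModel(7)
  tw <- temporalWeights(m, matrix(0, 2, 4))
  E <- matrix(0.3, 2, 2)
  expect_equal(spatialWeights(m, tw$hiddenLast, E, c(0, 1)), c(0.5, 0.5))
})

test_that("reweighting is exact: identity under uniform weights, masking, algebraic sum", {
  W <- matrix(rpois(12, 2), 3, 4)
  aU <- rep(1 / 4, 4); bU <- rep(1 / 3, 3)
  expect_equal(reweightWindow(W, aU, bU), W, ignore_attr = TRUE)
  b1 <- c(0, 0, 1)
  rw <- reweightWindow(W, aU, b1)
  expect_true(all(rw[1:2, ] == 0))
  set.seed(4)
  for (i in 1:20) {
    a <- sparsemax(rnorm(4)); b <- sparsemax(rnorm(3))
    rw <- reweightWindow(W, a, b)
    # direct double loop
    ref <- 0
    for (n in 1:3) for (t in 1:4) ref <- ref + 12 * b[n] * a[t] * W[n, t]
    expect_equal(sum(rw), ref)
  }
  expect_error(reweightWindow(W, c(2, 0, 0, 0) * 2, bU), "simplex")
})

test_that("context encoding is deterministic and sensitive to spike placement", {
  m <- randomTinyModel(9)
  win <- matrix(0, 2, 4); win[1, 2] <- 1
  q <- c(1, 0)
  c1 <- encodeWindow(m, win, q)$context
  c2 <- encodeWindow(m, win, q)$context
  expect_identical(c1, c2)
  win2 <- matrix(0, 2, 4); win2[1, 3] <- 1   # moved spike
  c3 <- encodeWindow(m, win2, q)$context
  expect_gt(max(abs(c3 - c1)), 1e-6)
  # all-zero window gives the fixed zero response
  z1 <- encodeContext(m, matrix(0, 2, 4))
  expect_identical(z1, encodeContext(m, matrix(0, 2, 4)))
})

test_that("the reference R encoder and the compiled fused path agree", {
  set.seed(11)
  m <- randomTinyModel(11)
  for (i in 1:5) {
    win <- matrix(rpois(8, 0.7), 2, 4)
    q <- c(0, 1)
    r <- encodeWindow(m, win, q)
    cc <- stanflow:::stanflow_encode(m@par, m@dims, array(win, c(2, 4, 1)),
                                     matrix(q, ncol = 1), m@binarize)
    expect_equal(r$alpha, as.numeric(cc$alpha), tolerance = 1e-12)
    expect_equal(r$beta, as.numeric(cc$beta), tolerance = 1e-12)
    expect_equal(r$context, as.numeric(cc$context), tolerance = 1e-12)
  }
})

test_that("analytic gradients match finite differences end to end", {
  set.seed(21)
  m <- randomTinyModel(21, layers = 2)
  B <- 3L
  wins <- array(rpois(2 * 4 * B, 0.5), c(2, 4, B))
  qm <- rbind(c(1, 0, 1), c(0, 1, 0))
  trel <- runif(B); tau <- rexp(B, 30)
  f <- function(p) stanflow:::stanflow_nll_grad(
    p, m@dims, wins, qm, trel, tau, m@tauRef, m@aMax, FALSE, FALSE)$nll
  g <- stanflow:::stanflow_nll_grad(m@par, m@dims, wins, qm, trel, tau,
                                    m@tauRef, m@aMax, FALSE, TRUE)$grad
  eps <- 1e-5
  idx <- sort(sample(seq_along(m@par), 80))
  fd <- vapply(idx, function(i) {
    p1 <- m@par; p2 <- m@par
    p1[i] <- p1[i] + eps; p2[i] <- p2[i] - eps
    (f(p1) - f(p2)) / (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(fd - g[idx]) / pmax(1, abs(fd))), 1e-4)
})
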