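test_that("total effects are additive across marks and honor zero weights", {
  corpus <- makeTestCorpus(Q = 1, n = 12, M = 2, seed = 21)
  H <- corpusTracks(corpus)[[1]]
  m0 <- TADModel(markNames(H), degree = 3, mMax = mMax(corpus))
  expect_equal(unname(totalEffects(H, m0)), matrix(0, 12, 3))
  # constant weight vector c -> constant effect c (partition of unity)
  W <- array(0, c(4, 2, 3))
  W[, 1, 1] <- 1.7
  mc <- TADModel(markNames(H), 3, weights = W, mMax = mMax(corpus))
  expect_equal(totalEffects(H, mc)[, "b"], rep(1.7, 12))
  # two marks = sum of single-mark effect tables
  set.seed(22)
  W2 <- array(rnorm(4 * 2 * 3), c(4, 2, 3))
  mF <- TADModel(markNames(H), 3, weights = W2, mMax = mMax(corpus))
  Wa <- W2
  Wa[, 2, ] <- 0
  Wb <- W2
  Wb[, 1, ] <- 0
  mA <- TADModel(markNames(H), 3, weights = Wa, mMax = mMax(corpus))
  mB <- TADModel(markNames(H), 3, weights = Wb, mMax = mMax(corpus))
  expect_equal(
    totalEffects(H, mF),
    totalEffects(H, mA) + totalEffects(H, mB)
  )
  expect_error(totalEffects(H, TADModel(c("x", "y"), 3)), "mark sets")
})

test_that("partition score sums weighted class effects", {
  E0 <- randomEffectTable(4)
  expect_equal(partitionScore(DomainPartition(cbind(1, 4), 4), E0 * 0), 0)
  E <- matrix(0, 2, 3, dimnames = list(NULL, c("b", "i", "e")))
  E[, "b"] <- 1
  expect_equal(partitionScore(DomainPartition(cbind(1, 2), 2), E), 2)
  E3 <- matrix(0, 3, 3, dimnames = list(NULL, c("b", "i", "e")))
  E3[, "e"] <- c(1, 2, 3)
  empty <- DomainPartition(matrix(integer(0), 0, 2), 3)
  expect_equal(partitionScore(empty, E3), 6)
  # class weights scale their class's bins only
  E4 <- randomEffectTable(5)
  cw <- c(b = 2, i = 3, e = 0.5)
  D <- DomainPartition(cbind(2, 4), 5)
  manual <- unname(2 * (E4[2, "b"] + E4[4, "b"]) + 3 * E4[3, "i"] +
    0.5 * (E4[1, "e"] + E4[5, "e"]))
  expect_equal(partitionScore(D, E4, cw), manual)
})

test_that("recursive log partition function equals exhaustive enumeration", {
  zero2 <- matrix(0, 2, 3, dimnames = list(NULL, c("b", "i", "e")))
  zero3 <- matrix(0, 3, 3, dimnames = list(NULL, c("b", "i", "e")))
  expect_equal(logPartitionFunction(zero2), log(2))
  expect_equal(logPartitionFunction(zero3), log(4))
  set.seed(23)
  for (rep in 1:15) {
    n <- sample(2:10, 1)
    E <- randomEffectTable(n)
    cw <- c(b = runif(1, .5, 2), i = runif(1, .5, 2), e = runif(1, .5, 2))
    expect_equal(logPartitionFunction(E, cw), enumLogZ(E, cw),
      tolerance = 1e-12
    )
  }
  # log-space guarantee: huge effects stay finite
  big <- matrix(700, 50, 3, dimnames = list(NULL, c("b", "i", "e")))
  expect_true(is.finite(logPartitionFunction(big)))
  expect_true(is.finite(logPartitionFunction(-big)))
})

test_that("forward-backward marginals are exact and normalized", {
  zero2 <- matrix(0, 2, 3, dimnames = list(NULL, c("b", "i", "e")))
  fb2 <- forwardBackward(zero2)
  # n=2: partitions {} and {[1,2]} equally likely -> P(bin1 = sb) = 1/2
  expect_equal(unname(fb2$stateMarginals[1, "sb"]), 0.5)
  expect_equal(unname(fb2$classMarginals[1, "b"]), 0.5)
  set.seed(24)
  for (rep in 1:10) {
    n <- sample(2:8, 1)
    E <- randomEffectTable(n)
    cw <- c(b = runif(1, .5, 2), i = 1, e = runif(1, .5, 2))
    fb <- forwardBackward(E, cw)
    expect_equal(rowSums(fb$stateMarginals), rep(1, n), tolerance = 1e-12)
    expect_equal(fb$classMarginals, enumClassMarginals(E, cw),
      tolerance = 1e-10
    )
    expect_equal(fb$logZ, logPartitionFunction(E, cw), tolerance = 1e-12)
  }
})

test_that("log-likelihood is a log-probability and shift invariant", {
  corpus <- makeTestCorpus(Q = 2, n = 15, M = 2, seed = 25)
  model <- testModel(corpus, degree = 3, seed = 26)
  unitModel <- TADModel(markNames(corpus), 3,
    weights = modelWeights(model),
    mMax = mMax(corpus)
  ) # unit class weights
  expect_lt(logLikelihood(corpus, unitModel), 0)
  # adding a constant to every class effect leaves the likelihood unchanged
  E <- randomEffectTable(8)
  D <- samplePartitionFromEffects(randomEffectTable(8), seed = 3)
  ll0 <- partitionScore(D, E) - logPartitionFunction(E)
  ll1 <- partitionScore(D, E + 0.83) - logPartitionFunction(E + 0.83)
  expect_equal(ll0, ll1, tolerance = 1e-10)
})

test_that("analytic gradient matches central finite differences", {
  corpus <- makeTestCorpus(Q = 2, n = 20, M = 3, seed = 27)
  model <- testModel(corpus, degree = 3, seed = 28)
  g <- logLikelihoodGradient(corpus, model)
  h <- 1e-5
  set.seed(29)
  for (k in sample(length(g), 10)) {
    Wp <- modelWeights(model)
    Wp[k] <- Wp[k] + h
    Wm <- modelWeights(model)
    Wm[k] <- Wm[k] - h
    mk <- function(W) {
      TADModel(markNames(corpus), 3,
        weights = W,
        classWeights = classWeights(model), mMax = mMax(corpus)
      )
    }
    fd <- (logLikelihood(corpus, mk(Wp)) - logLikelihood(corpus, mk(Wm))) /
      (2 * h)
    expect_equal(g[k], fd, tolerance = 1e-5)
  }
})

test_that("negative log-likelihood is convex in the weights", {
  corpus <- makeTestCorpus(Q = 1, n = 15, M = 2, seed = 30)
  nll <- function(W) {
    -logLikelihood(corpus, TADModel(markNames(corpus), 2,
      weights = W, mMax = mMax(corpus)
    ))
  }
  set.seed(31)
  dims <- c(3, 2, 3)
  for (rep in 1:20) {
    W1 <- array(rnorm(prod(dims), 0, 1), dims)
    W2 <- array(rnorm(prod(dims), 0, 1), dims)
    t <- runif(1)
    expect_lte(
      nll(t * W1 + (1 - t) * W2),
      t * nll(W1) + (1 - t) * nll(W2) + 1e-9
    )
  }
})
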