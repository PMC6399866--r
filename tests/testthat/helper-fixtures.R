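# Shared fixture builders and independent oracles. Oracles here are
# deliberately brute-force (enumeration, per-base accumulation, finite
# differences, quadrature) and never share code with the paths they check.

lse <- function(x) {
  m <- max(x)
  if (!is.finite(m)) {
    return(m)
  }
  m + log(sum(exp(x - m)))
}

randomEffectTable <- function(n, sd = 1) {
  matrix(rnorm(n * 3, 0, sd), n, 3, dimnames = list(NULL, c("b", "i", "e")))
}

# log Z by exhaustive enumeration of all valid partitions
enumLogZ <- function(E, cw = c(b = 1, i = 1, e = 1)) {
  n <- nrow(E)
  parts <- enumeratePartitions(n)
  lse(vapply(
    parts,
    function(p) partitionScore(DomainPartition(p, n), E, cw), numeric(1)
  ))
}

# exact class marginals by enumeration
enumClassMarginals <- function(E, cw = c(b = 1, i = 1, e = 1)) {
  n <- nrow(E)
  parts <- enumeratePartitions(n)
  sc <- vapply(
    parts,
    function(p) partitionScore(DomainPartition(p, n), E, cw), numeric(1)
  )
  pr <- exp(sc - lse(sc))
  cm <- matrix(0, n, 3, dimnames = list(NULL, c("b", "i", "e")))
  for (k in seq_along(parts)) {
    idx <- attr(labelStates(DomainPartition(parts[[k]], n)), "classIndex")
    cm[cbind(seq_len(n), idx)] <- cm[cbind(seq_len(n), idx)] + pr[k]
  }
  cm
}

# small random corpus: marker densities i.i.d. uniform, partitions sampled
# from random effect tables (so all three classes appear)
makeTestCorpus <- function(Q = 2, n = 20, M = 3, seed = 1) {
  set.seed(seed)
  tracks <- list()
  parts <- list()
  for (q in seq_len(Q)) {
    H <- MarkerMatrix(
      matrix(runif(n * M), n, M, dimnames = list(NULL, paste0("m", 1:M))),
      trackId = paste0("t", q)
    )
    D <- samplePartitionFromEffects(
      randomEffectTable(n, sd = 0.5),
      trackId = paste0("t", q)
    )
    tracks[[q]] <- H
    parts[[q]] <- D
  }
  TrainingCorpus(tracks, parts)
}

testModel <- function(corpus, degree = 3, weightSd = 0.3, seed = 1) {
  set.seed(seed)
  M <- length(markNames(corpus))
  W <- array(rnorm((degree + 1) * M * 3, 0, weightSd), c(degree + 1, M, 3))
  TADModel(
    markNames = markNames(corpus), degree = degree, weights = W,
    classWeights = computeClassWeights(corpus), mMax = mMax(corpus)
  )
}

# effect functions on a grid, centered across classes per mark (removes the
# per-mark gauge freedom: adding any shared function of the density to all
# three classes of one mark leaves the likelihood unchanged)
centeredEffectFunctions <- function(model, grid = seq(0, 1, length.out = 51)) {
  sapply(markNames(model), function(m) {
    F <- sapply(c("b", "i", "e"), function(p) {
      bernsteinEval(modelWeights(model)[, m, p], grid)
    })
    F - rowMeans(F)
  }, simplify = "array")
}

groupNormsOf <- function(model) {
  apply(modelWeights(model), 2, function(x) sqrt(sum(x^2)))
}
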