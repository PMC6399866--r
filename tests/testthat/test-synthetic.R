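test_that("sampled effect functions honor shape and sparsity structure", {
  spec <- syntheticSpec(nMarks = 6, nInformative = 3, monotone = TRUE)
  truth <- sampleEffectFunctions(spec, seed = 81)
  W <- modelWeights(truth)
  for (p in 1:3) {
    for (m in 1:3) expect_true(all(diff(W[, m, p]) >= 0))
  }
  expect_true(all(W[, 4:6, ] == 0)) # noise marks carry no effect
  expect_equal(max(W), spec$amplitude)
  # zero informative marks -> all-zero truth
  spec0 <- syntheticSpec(nMarks = 3, nInformative = 0)
  expect_true(all(modelWeights(sampleEffectFunctions(spec0, seed = 1)) == 0))
  # determinism
  t2 <- sampleEffectFunctions(spec, seed = 81)
  expect_identical(modelWeights(truth), modelWeights(t2))
  # concave option
  specC <- syntheticSpec(nMarks = 2, nInformative = 2, concave = TRUE)
  Wc <- modelWeights(sampleEffectFunctions(specC, seed = 82))
  for (p in 1:3) {
    for (m in 1:2) {
      expect_true(all(diff(Wc[, m, p], differences = 2) <= 1e-12))
    }
  }
})

test_that("the partition sampler draws exactly from the chain distribution", {
  # neutral effects over 3 bins: the 4 valid partitions are equally likely
  E3 <- matrix(0, 3, 3, dimnames = list(NULL, c("b", "i", "e")))
  set.seed(83)
  nd <- replicate(3000, nrow(domains(samplePartitionFromEffects(E3))))
  # P(empty) = 1/4; binomial 3 sigma
  expect_lt(abs(mean(nd == 0) - 0.25), 3 * sqrt(0.25 * 0.75 / 3000))
  # overwhelming gap preference -> empty partition
  Ee <- matrix(0, 6, 3, dimnames = list(NULL, c("b", "i", "e")))
  Ee[, "e"] <- 50
  expect_equal(nrow(domains(samplePartitionFromEffects(Ee, seed = 84))), 0L)
  # all draws valid partitions
  set.seed(85)
  for (rep in 1:20) {
    D <- samplePartitionFromEffects(randomEffectTable(sample(2:20, 1)))
    expect_true(validObject(D))
  }
})

test_that("sampler frequencies match enumeration probabilities", {
  set.seed(86)
  n <- 5
  E <- randomEffectTable(n, sd = 0.7)
  parts <- enumeratePartitions(n)
  sc <- vapply(
    parts,
    function(p) partitionScore(DomainPartition(p, n), E), numeric(1)
  )
  pr <- exp(sc - lse(sc))
  keys <- vapply(
    parts,
    function(p) paste(t(p), collapse = ","), character(1)
  )
  draws <- replicate(3000, {
    paste(t(domains(samplePartitionFromEffects(E))), collapse = ",")
  })
  obs <- table(factor(draws, levels = keys))
  expect_gt(suppressWarnings(chisq.test(obs, p = pr)$p.value), 0.01)
})

test_that("class-conditional marker draws are informative only when meant", {
  spec <- syntheticSpec(nTracks = 1, nBins = 400, seed = 87)
  fx <- makeFixtureCorpus(spec)
  H <- densities(corpusTracks(fx$corpus)[[1]])
  expect_true(all(H >= 0 & H <= 1))
  idx <- attr(labelStates(corpusPartitions(fx$corpus)[[1]]), "classIndex")
  isB <- idx == 1
  auc <- function(x, y) {
    r <- rank(c(x, y))
    (sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2) /
      (length(x) * length(y))
  }
  # informative marks separate boundary bins from the rest; noise does not
  aucInf <- auc(H[isB, "inf01"], H[!isB, "inf01"])
  aucNoise <- auc(H[isB, "noise01"], H[!isB, "noise01"])
  expect_gt(aucInf, 0.7)
  expect_lt(abs(aucNoise - 0.5), 0.1)
})

test_that("fixture corpora are reproducible and internally consistent", {
  spec <- syntheticSpec(nTracks = 2, nBins = 60, seed = 88)
  fx1 <- makeFixtureCorpus(spec)
  fx2 <- makeFixtureCorpus(spec)
  expect_identical(
    densities(corpusTracks(fx1$corpus)[[2]]),
    densities(corpusTracks(fx2$corpus)[[2]])
  )
  expect_identical(
    domains(corpusPartitions(fx1$corpus)[[1]]),
    domains(corpusPartitions(fx2$corpus)[[1]])
  )
  expect_true(validObject(fx1$corpus))
  for (D in corpusPartitions(fx1$corpus)) expect_true(validObject(D))
  # model mode: partitions come from the truth model itself
  specM <- syntheticSpec(nTracks = 2, nBins = 60, mode = "model", seed = 89)
  fxM <- makeFixtureCorpus(specM)
  expect_true(validObject(fxM$corpus))
  expect_identical(
    domains(makeFixtureCorpus(specM)$corpus@partitions[[1]]),
    domains(fxM$corpus@partitions[[1]])
  )
})

test_that("models round-trip through JSON losslessly", {
  spec <- syntheticSpec(nMarks = 3, nInformative = 2)
  truth <- sampleEffectFunctions(spec, seed = 90)
  path <- withr::local_tempfile(fileext = ".json")
  modelToJson(truth, path)
  back <- modelFromJson(path)
  expect_identical(modelWeights(back), modelWeights(truth))
  expect_identical(markNames(back), markNames(truth))
  expect_equal(classWeights(back), classWeights(truth))
  expect_equal(mMax(back), mMax(truth))
  expect_identical(bernsteinDegree(back), bernsteinDegree(truth))
  # string form round-trips too
  js <- modelToJson(truth)
  expect_identical(modelWeights(modelFromJson(js)), modelWeights(truth))
})

test_that("effect functions are recovered from model-mode corpora", {
  # data sampled from known monotone effects; compare gauge-aligned
  # (class-centered) effect functions on a grid
  maes <- vapply(0:1, function(seed) {
    fx <- makeFixtureCorpus(syntheticSpec(mode = "model", seed = seed))
    fit <- fitAlternating(
      fx$corpus,
      tadHyperparams(lambda1 = 0.05, lambda2 = 0.05)
    )
    mean(abs(centeredEffectFunctions(fx$truth) -
      centeredEffectFunctions(fittedModel(fit))))
  }, numeric(1))
  expect_true(all(maes <= 0.15))
})
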