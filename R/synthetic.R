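#' Specification of a synthetic training corpus
#'
#' Describes a corpus with the model's own statistical structure: a known
#' set of informative marks whose densities depend on each bin's domain
#' role, plus pure-noise marks, over partitions with TAD-like domain
#' lengths. Two generation modes are available. \code{"classcond"}
#' (default) samples each track's partition from a baseline chain with
#' constant class biases and then draws marker densities from
#' class-conditional beta distributions -- the marker-enrichment structure
#' observed around real domain boundaries. \code{"model"} draws densities
#' first (i.i.d. beta) and samples the partition exactly from the
#' conditional model at known effect functions, for parameter-recovery
#' experiments.
#'
#' @param nTracks number of (track, partition) pairs Q.
#' @param nBins bins per track.
#' @param nMarks total marks; the first \code{nInformative} are
#'   informative (named \code{infNN}), the rest noise (\code{noiseNN}).
#' @param nInformative number of informative marks.
#' @param degree Bernstein degree of the ground-truth effect functions.
#' @param monotone,concave shape of the sampled true effect functions.
#' @param amplitude range of each true effect function over [0, 1].
#' @param betaParams list of beta (shape1, shape2) pairs for informative
#'   marks, one per class \code{b}, \code{i}, \code{e}. The defaults
#'   separate boundary-enriched from depleted marks clearly.
#' @param noiseBeta beta parameters of noise marks (default uniform).
#' @param domainBias constant (b, i, e) effects of the baseline chain the
#'   partitions are sampled from; the defaults give domains a few hundred
#'   kb long at 40 kb bins covering most of the track, with regular gaps.
#' @param mode generation mode, see above.
#' @param resolution nominal bin width in bp (metadata only).
#' @param seed integer; the whole corpus is reproducible from it.
#' @return list of class \code{SyntheticSpec}.
#' @export
syntheticSpec <- function(nTracks = 8L, nBins = 500L, nMarks = 12L,
                          nInformative = 4L, degree = 5L, monotone = TRUE,
                          concave = FALSE, amplitude = 2,
                          betaParams = list(
                            b = c(6, 2), i = c(4, 3), e = c(2, 5)
                          ),
                          noiseBeta = c(1, 1),
                          domainBias = c(b = -2, i = 0.15, e = 0),
                          mode = c("classcond", "model"),
                          resolution = 40000, seed = 0L) {
  mode <- match.arg(mode)
  stopifnot(
    nInformative <= nMarks, nTracks >= 1, nBins >= 2,
    is.finite(amplitude)
  )
  marks <- c(
    sprintf("inf%02d", seq_len(nInformative)),
    sprintf("noise%02d", seq_len(nMarks - nInformative))
  )
  names(domainBias) <- .CLASSES
  structure(
    list(
      nTracks = as.integer(nTracks), nBins = as.integer(nBins),
      nMarks = as.integer(nMarks), nInformative = as.integer(nInformative),
      degree = as.integer(degree), monotone = monotone, concave = concave,
      amplitude = amplitude, betaParams = betaParams,
      noiseBeta = noiseBeta, domainBias = domainBias, mode = mode,
      resolution = resolution, seed = as.integer(seed),
      markNames = marks
    ),
    class = "SyntheticSpec"
  )
}

#' Sample ground-truth effect functions
#'
#' Draws one monotone (optionally concave) Bernstein weight vector per
#' (class, informative mark), rising from 0 to the spec amplitude with
#' random increments; noise marks get exactly zero weights. Deterministic
#' given a seed.
#'
#' @param spec a \code{\link{syntheticSpec}}.
#' @param seed optional integer seed (defaults to the RNG state already
#'   in effect).
#' @return a \linkS4class{TADModel} holding the true parameters (unit
#'   class weights, mMax = 1).
#' @export
sampleEffectFunctions <- function(spec, seed = NULL) {
  .checkSeed(seed)
  A <- spec$degree
  W <- array(0, c(A + 1L, spec$nMarks, 3L))
  for (p in seq_len(3L)) {
    for (m in seq_len(spec$nInformative)) {
      u <- stats::runif(A)
      if (spec$concave) u <- sort(u, decreasing = TRUE)
      W[, m, p] <- spec$amplitude * c(0, cumsum(u)) / sum(u)
    }
  }
  TADModel(
    markNames = spec$markNames, degree = A, weights = W,
    mMax = rep(1, spec$nMarks),
    flags = list(
      monotone = spec$monotone, concave = spec$concave,
      nonnegative = TRUE
    ),
    resolutionBp = spec$resolution
  )
}

#' Exact sampling of a domain partition
#'
#' Forward-filter backward-sample over the four-state chain: run the
#' log-space forward recursion of the partition function, draw the final
#' state from its terminal weights, then walk backwards drawing each
#' state from its exact conditional given the future. The result is an
#' exact draw from P(D | effects), always a valid partition.
#'
#' @param E effect table (nBins x 3).
#' @param classWeights named (b, i, e) weights entering the per-bin
#'   scores.
#' @param seed optional integer seed.
#' @return a \linkS4class{DomainPartition}.
#' @export
#' @param trackId track name for the returned partition.
samplePartitionFromEffects <- function(E, classWeights = c(b = 1, i = 1, e = 1),
                                       seed = NULL, trackId = "track") {
  .checkSeed(seed)
  S <- .stateScores(E, classWeights)
  n <- nrow(S)
  la <- .fbChain(S)$la
  drawFrom <- function(logw, states) {
    w <- exp(logw - max(logw))
    states[sample.int(length(states), 1L, prob = w)]
  }
  ## predecessors of each state (indices into sb, i, eb, e)
  predOf <- list(c(3L, 4L), c(1L, 2L), c(1L, 2L), c(3L, 4L))
  states <- integer(n)
  states[n] <- drawFrom(la[n, c(3L, 4L)], c(3L, 4L))
  if (n > 1L) {
    for (v in (n - 1L):1L) {
      pre <- predOf[[states[v + 1L]]]
      states[v] <- drawFrom(la[v, pre], pre)
    }
  }
  statesToPartition(.STATES[states], trackId = trackId)
}

#' @param model a \linkS4class{TADModel} (the generating truth).
#' @param H a \linkS4class{MarkerMatrix}.
#' @rdname samplePartitionFromEffects
#' @export
samplePartition <- function(model, H, seed = NULL) {
  E <- totalEffects(H, model)
  samplePartitionFromEffects(E, model@classWeights,
    seed = seed,
    trackId = trackId(H)
  )
}

#' Sample class-conditional marker densities for a partition
#'
#' Informative marks draw each bin's density from the beta distribution of
#' that bin's class (boundary, interior, inter-domain); noise marks draw
#' i.i.d. from the noise beta regardless of class. Densities therefore lie
#' in [0, 1), matching the normalized domain of the effect functions.
#'
#' @param spec a \code{\link{syntheticSpec}}.
#' @param D a \linkS4class{DomainPartition} supplying the class labels.
#' @param seed optional integer seed.
#' @return a \linkS4class{MarkerMatrix}.
#' @export
sampleMarkerMatrix <- function(spec, D, seed = NULL) {
  .checkSeed(seed)
  n <- D@nBins
  idx <- attr(labelStates(D), "classIndex")
  H <- matrix(0, n, spec$nMarks, dimnames = list(NULL, spec$markNames))
  for (m in seq_len(spec$nMarks)) {
    if (m <= spec$nInformative) {
      for (p in seq_len(3L)) {
        sel <- idx == p
        par <- spec$betaParams[[.CLASSES[p]]]
        H[sel, m] <- stats::rbeta(sum(sel), par[1L], par[2L])
      }
    } else {
      H[, m] <- stats::rbeta(n, spec$noiseBeta[1L], spec$noiseBeta[2L])
    }
  }
  MarkerMatrix(H,
    trackId = trackId(D), resolutionBp = spec$resolution,
    mMax = rep(1, spec$nMarks)
  )
}

#' Build a complete synthetic corpus with known ground truth
#'
#' Draws Q tracks according to the spec's generation mode and returns both
#' the corpus and the generating truth, so training, inference and
#' evaluation can be exercised end-to-end and checked against known
#' parameters. All randomness flows from \code{spec$seed} through one
#' sequential stream, so the corpus is bit-reproducible.
#'
#' @param spec a \code{\link{syntheticSpec}}.
#' @return list with \code{corpus} (a \linkS4class{TrainingCorpus} whose
#'   mMax is fixed at 1 to match the truth's normalization), \code{truth}
#'   (the generating \linkS4class{TADModel}; in \code{"model"} mode the
#'   constant class biases are folded into the informative marks' weight
#'   vectors so the truth fully describes the sampler), and \code{spec}.
#' @export
makeFixtureCorpus <- function(spec) {
  set.seed(spec$seed)
  truth <- sampleEffectFunctions(spec)
  if (spec$mode == "model") {
    ## fold the partition-shaping class biases into the truth weights
    ## (a constant weight vector is a constant effect function), spread
    ## over the informative marks
    for (p in seq_len(3L)) {
      add <- spec$domainBias[p] / spec$nInformative
      truth@weights[, seq_len(spec$nInformative), p] <-
        truth@weights[, seq_len(spec$nInformative), p] + add
    }
  }
  biasE <- matrix(rep(spec$domainBias, each = spec$nBins),
    ncol = 3L,
    dimnames = list(NULL, .CLASSES)
  )
  tracks <- vector("list", spec$nTracks)
  parts <- vector("list", spec$nTracks)
  for (q in seq_len(spec$nTracks)) {
    ## "sim", not "track": a BED line starting with the word "track" is a
    ## track-definition line to BED parsers, so track ids must avoid it
    id <- sprintf("sim%02d", q)
    if (spec$mode == "classcond") {
      D <- samplePartitionFromEffects(biasE, trackId = id)
      H <- sampleMarkerMatrix(spec, D)
    } else {
      Hd <- matrix(
        stats::rbeta(
          spec$nBins * spec$nMarks,
          spec$noiseBeta[1L], spec$noiseBeta[2L]
        ),
        spec$nBins, spec$nMarks,
        dimnames = list(NULL, spec$markNames)
      )
      H <- MarkerMatrix(Hd,
        trackId = id, resolutionBp = spec$resolution,
        mMax = rep(1, spec$nMarks)
      )
      D <- samplePartition(truth, H)
      D@trackId <- id
    }
    tracks[[q]] <- H
    parts[[q]] <- D
  }
  corpus <- TrainingCorpus(tracks, parts,
    mMax = structure(rep(1, spec$nMarks), names = spec$markNames)
  )
  list(corpus = corpus, truth = truth, spec = spec)
}
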