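#' Per-bin clustering induced by a domain partition
#'
#' Each domain becomes one cluster. Non-domain bins become singleton
#' clusters by default (\code{gapMode = "singleton"}), so a trivially
#' gap-heavy prediction is not rewarded; \code{gapMode = "merged"} instead
#' pools all gap bins into one cluster.
#'
#' @param D a \linkS4class{DomainPartition}.
#' @param gapMode how non-domain bins are clustered.
#' @return integer vector of cluster labels, one per bin.
#' @export
partitionClustering <- function(D, gapMode = c("singleton", "merged")) {
  gapMode <- match.arg(gapMode)
  n <- D@nBins
  labels <- integer(n)
  d <- D@domains
  nxt <- 1L
  for (k in seq_len(nrow(d))) {
    labels[d[k, 1L]:d[k, 2L]] <- nxt
    nxt <- nxt + 1L
  }
  gaps <- which(labels == 0L)
  if (length(gaps)) {
    if (gapMode == "merged") {
      labels[gaps] <- nxt
    } else {
      labels[gaps] <- nxt + seq_along(gaps) - 1L
    }
  }
  labels
}

#' Variation of information between two partitions
#'
#' VI(P1, P2) = H(P1) + H(P2) - 2 I(P1; P2) in natural logs, a metric on
#' clusterings (0 = identical). \code{nvi} divides by log(nBins), the VI
#' between the one-cluster and the all-singletons clustering, giving a
#' score in [0, 1] where lower means closer agreement.
#'
#' @param P1,P2 \linkS4class{DomainPartition} objects over the same number
#'   of bins, or integer label vectors of equal length.
#' @param gapMode forwarded to \code{\link{partitionClustering}} when
#'   partitions are given.
#' @return single numeric.
#' @export
#' @examples
#' D <- DomainPartition(cbind(2, 5), 10)
#' nvi(D, D) # 0
variationOfInformation <- function(P1, P2, gapMode = "singleton") {
  l1 <- if (is(P1, "DomainPartition")) partitionClustering(P1, gapMode) else P1
  l2 <- if (is(P2, "DomainPartition")) partitionClustering(P2, gapMode) else P2
  if (length(l1) != length(l2)) {
    stop("partitions must cover the same number of bins")
  }
  n <- length(l1)
  joint <- table(l1, l2) / n
  p1 <- rowSums(joint)
  p2 <- colSums(joint)
  ent <- function(p) -sum(p[p > 0] * log(p[p > 0]))
  h12 <- ent(as.vector(joint))
  ## VI = 2 H(P1,P2) - H(P1) - H(P2)  (equivalent to H1 + H2 - 2I)
  2 * h12 - ent(p1) - ent(p2)
}

#' @rdname variationOfInformation
#' @export
nvi <- function(P1, P2, gapMode = "singleton") {
  n <- if (is(P1, "DomainPartition")) P1@nBins else length(P1)
  if (n < 2L) {
    stop("need at least two bins for a normalized score")
  }
  variationOfInformation(P1, P2, gapMode) / log(n)
}

#' Coherence score of a model on held-out tracks
#'
#' The exponential of the negative mean per-bin log-likelihood over test
#' tracks (per-bin so tracks of different lengths are comparable); higher
#' is better. \code{normalizeCoherence} divides a vector of raw scores by
#' its maximum, so the best model in a comparison scores 1.00.
#'
#' @param corpus a \linkS4class{TrainingCorpus} of test tracks.
#' @param model a \linkS4class{TADModel}.
#' @param useClassWeights use the model's training class weights in the
#'   likelihood instead of unit weights (default FALSE: a proper
#'   probability).
#' @return single positive numeric.
#' @export
coherenceScore <- function(corpus, model, useClassWeights = FALSE) {
  stopifnot(length(corpus@tracks) >= 1L)
  cw <- if (useClassWeights) model@classWeights else c(b = 1, i = 1, e = 1)
  nlls <- vapply(seq_along(corpus@tracks), function(q) {
    E <- totalEffects(corpus@tracks[[q]], model)
    -(partitionScore(corpus@partitions[[q]], E, cw) -
      logPartitionFunction(E, cw)) / nBins(corpus@tracks[[q]])
  }, numeric(1))
  exp(-mean(nlls))
}

#' @param scores numeric vector of raw coherence scores.
#' @rdname coherenceScore
#' @export
normalizeCoherence <- function(scores) {
  scores / max(scores)
}

#' Length-preserving random shuffle of a domain partition
#'
#' Places domains with the same multiset of lengths uniformly at random
#' among the valid non-overlapping arrangements (length order randomized),
#' the null used to check that predictions exploit the marker signal
#' rather than generic domain-length structure.
#'
#' @param D a \linkS4class{DomainPartition}.
#' @param nBins optional track length override.
#' @param seed integer seed making the placement deterministic.
#' @return a \linkS4class{DomainPartition} with the same domain lengths.
#' @export
shuffleDomains <- function(D, nBins = NULL, seed = NULL) {
  if (is.null(nBins)) nBins <- D@nBins
  .checkSeed(seed)
  lens <- D@domains[, 2L] - D@domains[, 1L] + 1L
  k <- length(lens)
  if (k == 0L) {
    return(DomainPartition(matrix(integer(0), 0, 2), nBins, D@trackId))
  }
  free <- nBins - sum(lens)
  if (free < 0L) {
    stop("domain lengths cannot fit in nBins")
  }
  lens <- if (k > 1L) sample(lens) else lens
  ## uniform composition of the free bins into k+1 gaps via the standard
  ## stars-and-bars draw
  gaps <- if (free == 0L) {
    rep(0L, k + 1L)
  } else {
    pos <- sort(sample.int(free + k, k))
    c(pos[1L] - 1L, diff(pos) - 1L, free + k - pos[k])
  }
  starts <- integer(k)
  cur <- 0L
  for (j in seq_len(k)) {
    cur <- cur + gaps[j]
    starts[j] <- cur + 1L
    cur <- cur + lens[j]
  }
  DomainPartition(cbind(starts, starts + lens - 1L), nBins, D@trackId)
}
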