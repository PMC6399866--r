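## Design matrix of Bernstein kernels for one track: n x (M * (A+1)),
## columns blocked by mark. With weights for one class flattened the same
## way, the class effect table is a single matrix product.
.basisTensor <- function(H, mMax, degree) {
  P <- normalizeDensity(H@densities, mMax[markNames(H)])
  M <- ncol(P)
  blocks <- lapply(seq_len(M), function(m) bernsteinBasisMatrix(P[, m], degree))
  Phi <- do.call(cbind, blocks)
  attr(Phi, "nMarks") <- M
  Phi
}

#' Per-bin class effects of all marks
#'
#' Sums each mark's effect function over the normalized densities of one
#' track, giving for every bin the total additive effect toward each of
#' the three classes (boundary, interior, inter-domain).
#'
#' @param H a \linkS4class{MarkerMatrix}.
#' @param model a \linkS4class{TADModel} over the same marks.
#' @return numeric nBins x 3 matrix with columns \code{b}, \code{i},
#'   \code{e} (an effect table).
#' @export
totalEffects <- function(H, model) {
  if (!identical(markNames(H), markNames(model))) {
    stop("mark sets of track and model differ")
  }
  Phi <- .basisTensor(H, mMax(model), model@degree)
  E <- Phi %*% matrix(model@weights, ncol = 3L)
  colnames(E) <- .CLASSES
  E
}

## per-bin per-state scores (class weights applied), n x 4 over (sb,i,eb,e)
.stateScores <- function(E, classWeights) {
  cbind(
    classWeights[["b"]] * E[, "b"], classWeights[["i"]] * E[, "i"],
    classWeights[["b"]] * E[, "b"], classWeights[["e"]] * E[, "e"]
  )
}

#' Score of one partition under an effect table
#'
#' The unnormalized log-probability F of a partition: class-weighted
#' boundary effects at each domain's two boundary bins, interior effects
#' strictly inside domains, and inter-domain effects elsewhere.
#'
#' @param D a \linkS4class{DomainPartition}.
#' @param E effect table from \code{\link{totalEffects}} (nBins x 3).
#' @param classWeights named (b, i, e) positive weights; default unit.
#' @return single numeric score.
#' @export
partitionScore <- function(D, E, classWeights = c(b = 1, i = 1, e = 1)) {
  stopifnot(validObject(D), nrow(E) == D@nBins)
  idx <- attr(labelStates(D), "classIndex")
  cw <- classWeights[.CLASSES][idx]
  sum(cw * E[cbind(seq_len(nrow(E)), idx)])
}

#' Log partition function of the domain chain
#'
#' Sums exp(F) over every valid non-overlapping partition of the track
#' (domains of length >= 2, including the empty partition) by the
#' four-state forward recursion, entirely in log space so arbitrarily
#' large effects cannot overflow.
#'
#' @inheritParams partitionScore
#' @param E effect table (nBins x 3).
#' @return log Z as a single numeric.
#' @export
#' @examples
#' # two bins, neutral effects: partitions are {} and {[1,2]}, so log 2
#' logPartitionFunction(matrix(0, 2, 3, dimnames = list(NULL, c("b", "i", "e"))))
logPartitionFunction <- function(E, classWeights = c(b = 1, i = 1, e = 1)) {
  .logZChain(.stateScores(E, classWeights))
}

#' Forward-backward state marginals
#'
#' Exact per-bin posterior probabilities of the four chain states under
#' the model, plus the three-class marginals with the two boundary states
#' pooled. The forward- and backward-side normalizers agree with
#' \code{\link{logPartitionFunction}} by construction.
#'
#' @inheritParams logPartitionFunction
#' @return list with \code{stateMarginals} (nBins x 4 over sb, i, eb, e),
#'   \code{classMarginals} (nBins x 3 over b, i, e) and \code{logZ}.
#' @export
forwardBackward <- function(E, classWeights = c(b = 1, i = 1, e = 1)) {
  fb <- .fbChain(.stateScores(E, classWeights))
  sm <- exp(fb$la + fb$lb - fb$logZ)
  colnames(sm) <- .STATES
  cm <- cbind(b = sm[, 1L] + sm[, 3L], i = sm[, 2L], e = sm[, 4L])
  list(stateMarginals = sm, classMarginals = cm, logZ = fb$logZ)
}

#' Enumerate all valid domain partitions of a short track
#'
#' Exhaustive enumeration (there are 2^(n-1) valid partitions of n bins),
#' used as the independent oracle for the recursive partition function,
#' the marginals, the exact sampler, and the inference DP.
#'
#' @param n number of bins (capped at 14).
#' @return list of integer matrices with columns (s, e); the first element
#'   is the empty partition.
#' @export
enumeratePartitions <- function(n) {
  stopifnot(n >= 1L, n <= 14L)
  memo <- vector("list", n + 1L)
  memo[[1L]] <- list(matrix(integer(0), 0L, 2L)) # 0 bins
  for (k in seq_len(n)) {
    out <- lapply(memo[[k]], function(p) p) # bin k is a gap
    for (L in 2:k) {
      if (L > k) break
      s <- k - L + 1L
      out <- c(out, lapply(memo[[s]], function(p) rbind(p, c(s, k))))
    }
    memo[[k + 1L]] <- out
  }
  memo[[n + 1L]]
}

#' Log-likelihood of a corpus under a model
#'
#' Sum over tracks of (partition score minus log partition function),
#' using the model's class weights in both terms so that the per-track
#' probabilities normalize.
#'
#' @param corpus a \linkS4class{TrainingCorpus}.
#' @param model a \linkS4class{TADModel}.
#' @return single numeric log-likelihood (<= 0 when class weights are 1).
#' @export
logLikelihood <- function(corpus, model) {
  ll <- 0
  for (q in seq_along(corpus@tracks)) {
    E <- totalEffects(corpus@tracks[[q]], model)
    ll <- ll + partitionScore(corpus@partitions[[q]], E, model@classWeights) -
      logPartitionFunction(E, model@classWeights)
  }
  ll
}

## Precompute everything data-dependent once per corpus: basis tensors,
## class indicator matrices, bin counts. Training loops only do matrix
## products and the forward-backward recursions after this.
.prepareCorpus <- function(corpus, degree) {
  marks <- markNames(corpus)
  lapply(seq_along(corpus@tracks), function(q) {
    H <- corpus@tracks[[q]]
    D <- corpus@partitions[[q]]
    idx <- attr(labelStates(D), "classIndex")
    n <- nBins(H)
    Y <- matrix(0, n, 3L, dimnames = list(NULL, .CLASSES))
    Y[cbind(seq_len(n), idx)] <- 1
    list(
      Phi = .basisTensor(H, corpus@mMax, degree),
      Y = Y, n = n, D = D
    )
  })
}

## NLL and gradient in packed-weight coordinates. Gradient of the NLL for
## coefficient (i, m, p): -cw_p * sum_v Phi[v, (m,i)] * (Y[v,p] - P[v,p]),
## the standard observed-minus-expected CRF form with the sb/eb marginals
## pooled into the boundary class.
.nllGrad <- function(wvec, prep, classWeights, degree, nMarks,
                     gradient = TRUE) {
  Wmat <- matrix(wvec, ncol = 3L)
  nll <- 0
  grad <- if (gradient) matrix(0, length(wvec) / 3L, 3L) else NULL
  cw <- classWeights[.CLASSES]
  for (tr in prep) {
    E <- tr$Phi %*% Wmat
    colnames(E) <- .CLASSES
    fb <- forwardBackward(E, cw)
    F <- sum(rep(cw, each = tr$n) * tr$Y * E)
    nll <- nll - (F - fb$logZ)
    if (gradient) {
      R <- tr$Y - fb$classMarginals
      R <- sweep(R, 2L, cw, "*")
      grad <- grad - crossprod(tr$Phi, R)
    }
  }
  list(value = nll, gradient = if (gradient) as.vector(grad) else NULL)
}

#' Gradient of the log-likelihood
#'
#' Analytic gradient with respect to every Bernstein weight, in the same
#' array layout as \code{modelWeights(model)}.
#'
#' @inheritParams logLikelihood
#' @return numeric array (A+1) x marks x 3.
#' @export
logLikelihoodGradient <- function(corpus, model) {
  prep <- .prepareCorpus(corpus, model@degree)
  res <- .nllGrad(
    .packWeights(model@weights), prep, model@classWeights,
    model@degree, length(model@markNames)
  )
  -.unpackWeights(res$gradient, model@degree, model@markNames)
}
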