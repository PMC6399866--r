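#' Training hyperparameters
#'
#' Bundles the regularization strengths and solver settings. \code{lambda1}
#' scales the group-lasso penalty (squared block l1 norm of the per-mark,
#' per-class weight groups), \code{lambda2} the curvature smoothness
#' penalty. Shape flags constrain every effect function: nondecreasing
#' (\code{monotone}), concave, and/or nonnegative weights.
#'
#' @param lambda1,lambda2 non-negative regularization strengths.
#' @param degree Bernstein degree A of every effect function.
#' @param monotone,concave,nonnegative logical shape constraints.
#' @param maxOuterIters cap on alternating (weights / group-scale) rounds.
#' @param tol relative objective-change convergence tolerance of the
#'   outer loop.
#' @param maxInnerIters iteration cap of the inner quasi-Newton solver.
#' @param seed integer seed governing CV fold shuffling (the solver itself
#'   is deterministic).
#' @return list of class \code{tadHyperparams}.
#' @export
tadHyperparams <- function(lambda1 = 1, lambda2 = 0.1, degree = 5L,
                           monotone = FALSE, concave = FALSE,
                           nonnegative = FALSE, maxOuterIters = 25L,
                           tol = 1e-6, maxInnerIters = 500L, seed = 1L) {
  stopifnot(lambda1 >= 0, lambda2 >= 0, tol > 0, degree >= 1)
  structure(
    list(
      lambda1 = lambda1, lambda2 = lambda2, degree = as.integer(degree),
      monotone = monotone, concave = concave, nonnegative = nonnegative,
      maxOuterIters = as.integer(maxOuterIters), tol = tol,
      maxInnerIters = as.integer(maxInnerIters), seed = as.integer(seed)
    ),
    class = "tadHyperparams"
  )
}

.asHyperparams <- function(hp) {
  if (inherits(hp, "tadHyperparams")) hp else do.call(tadHyperparams, hp)
}

## group-block index helper: columns of the flattened (A+1) x M x 3 layout
.groupIndex <- function(m, p, degree, nMarks) {
  ((p - 1L) * nMarks + (m - 1L)) * (degree + 1L) + seq_len(degree + 1L)
}

#' Regularized training objective
#'
#' Negative log-likelihood plus the group-lasso penalty
#' lambda1 * sum_p (sum_m ||w_mp||)^2 and the curvature penalty
#' lambda2 * sum_{p,m} w_mp' S w_mp.
#'
#' @param corpus a \linkS4class{TrainingCorpus}.
#' @param model a \linkS4class{TADModel}.
#' @param hp a \code{\link{tadHyperparams}} (or plain list of its fields).
#' @return single numeric objective value.
#' @export
regularizedObjective <- function(corpus, model, hp) {
  hp <- .asHyperparams(hp)
  norms <- .groupNorms(model@weights)
  S <- curvatureForm(model@degree)
  curv <- sum(apply(model@weights, c(2L, 3L), curvaturePenalty, S = S))
  -logLikelihood(corpus, model) +
    hp$lambda1 * sum(colSums(norms)^2) + hp$lambda2 * curv
}

#' Cauchy-Schwarz surrogate objective
#'
#' Replaces the squared block l1 norm by sum_{p,m} ||w_mp||^2 / gamma_mp
#' with simplex-constrained group scales gamma. The surrogate upper-bounds
#' the true objective for any feasible gamma and touches it at the scales
#' from \code{\link{gammaUpdate}}. A group with zero weights contributes 0
#' whatever its scale (the 0 * infinity limit convention); a zero scale
#' with nonzero weights yields +Inf.
#'
#' @inheritParams regularizedObjective
#' @param gamma marks x classes matrix of non-negative scales, each column
#'   summing to 1.
#' @return single numeric (possibly \code{Inf}).
#' @export
surrogateObjective <- function(corpus, model, gamma, hp) {
  hp <- .asHyperparams(hp)
  norms <- .groupNorms(model@weights)
  S <- curvatureForm(model@degree)
  curv <- sum(apply(model@weights, c(2L, 3L), curvaturePenalty, S = S))
  grp <- ifelse(norms == 0, 0, ifelse(gamma == 0, Inf, norms^2 / gamma))
  -logLikelihood(corpus, model) + hp$lambda1 * sum(grp) + hp$lambda2 * curv
}

#' Closed-form group-scale update
#'
#' The scales attaining equality in the Cauchy-Schwarz bound:
#' gamma_mp = ||w_mp|| / sum_m' ||w_m'p||, per class. If every group in a
#' class has zero norm the scales fall back to uniform.
#'
#' @param model a \linkS4class{TADModel}, or a weights array
#'   (A+1) x marks x 3.
#' @return marks x classes matrix with columns summing to 1.
#' @export
gammaUpdate <- function(model) {
  W <- if (is(model, "TADModel")) model@weights else model
  norms <- .groupNorms(W)
  tot <- colSums(norms)
  gamma <- norms
  for (p in seq_len(3L)) {
    gamma[, p] <- if (tot[p] > 0) norms[, p] / tot[p] else 1 / nrow(norms)
  }
  gamma
}

## stacked shape-constraint matrix (G w <= 0) for one group, or NULL
.shapeConstraints <- function(hp) {
  G <- NULL
  if (hp$monotone) G <- monotoneConstraints(hp$degree)
  if (hp$concave) G <- rbind(G, concaveConstraints(hp$degree))
  if (hp$nonnegative && (hp$monotone || hp$concave)) {
    G <- rbind(G, -diag(hp$degree + 1L))
  }
  G
}

## strictly feasible point for every supported constraint combination:
## strictly positive, strictly increasing, strictly concave
.strictFeasible <- function(degree, delta = 1e-3) {
  x <- (0:degree) / degree
  delta * (0.2 + x - 0.5 * x^2)
}

## core solver: minimize the surrogate at fixed gamma over the weights of
## the active groups (gamma above the exclusion threshold). Groups whose
## scale has collapsed to ~0 are fixed at exactly zero -- the limit the
## surrogate prescribes -- which is what makes unselected marks exactly
## sparse. Uses L-BFGS-B, or a log-barrier method (constrOptim) when
## monotone/concave constraints are on.
.fitWeightsCore <- function(prep, classWeights, gamma, hp, warm = NULL,
                            activeTol = 1e-8) {
  A <- hp$degree
  M <- nrow(gamma)
  nw <- (A + 1L) * M * 3L
  if (is.null(warm)) warm <- numeric(nw)
  S <- curvatureForm(A)
  active <- which(gamma > activeTol) # linear index into M x 3
  actIdx <- unlist(lapply(active, function(g) {
    p <- (g - 1L) %/% M + 1L
    m <- (g - 1L) %% M + 1L
    .groupIndex(m, p, A, M)
  }))
  coefL1 <- hp$lambda1 / pmax(gamma[active], activeTol)

  full <- function(wact) {
    w <- numeric(nw)
    w[actIdx] <- wact
    w
  }
  penalty <- function(wact) {
    Wg <- matrix(wact, nrow = A + 1L) # columns = active groups
    sum(coefL1 * colSums(Wg^2)) + hp$lambda2 * sum(Wg * (S %*% Wg))
  }
  penaltyGrad <- function(wact) {
    Wg <- matrix(wact, nrow = A + 1L)
    as.vector(2 * sweep(Wg, 2L, coefL1, "*") + 2 * hp$lambda2 * (S %*% Wg))
  }
  cache <- new.env(parent = emptyenv())
  nllAt <- function(wact) {
    key <- wact
    if (!is.null(cache$key) && identical(cache$key, key)) {
      return(cache$val)
    }
    val <- .nllGrad(full(wact), prep, classWeights, A, M)
    cache$key <- key
    cache$val <- val
    val
  }
  fn <- function(wact) nllAt(wact)$value + penalty(wact)
  gr <- function(wact) nllAt(wact)$gradient[actIdx] + penaltyGrad(wact)

  w0 <- warm[actIdx]
  G1 <- .shapeConstraints(hp)
  if (is.null(G1)) {
    lower <- if (hp$nonnegative) 0 else -Inf
    w0 <- pmax(w0, lower)
    opt <- stats::optim(w0, fn, gr,
      method = "L-BFGS-B", lower = lower,
      control = list(maxit = hp$maxInnerIters, factr = 1e7, pgtol = 1e-6)
    )
    if (!opt$convergence %in% c(0L, 1L)) {
      stop("inner solver failed: ", opt$message)
    }
    wact <- opt$par
  } else {
    nGrp <- length(active)
    nr <- nrow(G1)
    ui <- matrix(0, nr * nGrp, (A + 1L) * nGrp) # block-diagonal -G
    for (g in seq_len(nGrp)) {
      ui[(g - 1L) * nr + seq_len(nr), (g - 1L) * (A + 1L) + seq_len(A + 1L)] <-
        -G1
    }
    ci <- rep(0, nrow(ui))
    if (length(w0) && any(ui %*% w0 <= 1e-10)) {
      strict <- rep(.strictFeasible(A), nGrp)
      w0 <- 0.5 * w0 + 0.5 * strict
      ## blending with a strictly feasible point keeps feasibility strict
      if (any(ui %*% w0 <= 0)) w0 <- strict
    }
    opt <- stats::constrOptim(w0, fn, gr,
      ui = ui, ci = ci, method = "BFGS",
      outer.iterations = 50L, outer.eps = 1e-7,
      control = list(maxit = hp$maxInnerIters, reltol = 1e-12)
    )
    wact <- opt$par
  }
  full(wact)
}

#' Fit effect-function weights at fixed group scales
#'
#' Minimizes the smooth surrogate objective in the Bernstein weights with
#' the group scales held fixed, honoring any shape constraints in
#' \code{hp}. This is the inner step of \code{\link{fitAlternating}}.
#'
#' @inheritParams regularizedObjective
#' @param gamma marks x classes group-scale matrix (columns on the
#'   simplex).
#' @param warmStart optional \linkS4class{TADModel} supplying starting
#'   weights.
#' @return a fitted \linkS4class{TADModel}.
#' @export
fitWeightsGivenGamma <- function(corpus, gamma, hp, warmStart = NULL) {
  hp <- .asHyperparams(hp)
  stopifnot(validObject(corpus))
  marks <- markNames(corpus)
  prep <- .prepareCorpus(corpus, hp$degree)
  cw <- computeClassWeights(corpus)
  warm <- if (!is.null(warmStart)) .packWeights(warmStart@weights) else NULL
  wvec <- .fitWeightsCore(prep, cw, gamma, hp, warm = warm)
  TADModel(
    markNames = marks, degree = hp$degree,
    weights = .unpackWeights(wvec, hp$degree, marks),
    classWeights = cw, mMax = corpus@mMax,
    flags = list(
      monotone = hp$monotone, concave = hp$concave,
      nonnegative = hp$nonnegative
    ),
    resolutionBp = corpus@tracks[[1L]]@resolutionBp
  )
}

#' Train the model by alternating optimization
#'
#' Alternates between the inner weight fit (quasi-Newton on the smooth
#' surrogate, \code{\link{fitWeightsGivenGamma}}) and the closed-form
#' group-scale update (\code{\link{gammaUpdate}}), starting from zero
#' weights and uniform scales. Each round can only lower the true
#' regularized objective (majorize-minimize), so the recorded trace is
#' non-increasing; the loop stops when the relative objective change
#' drops below \code{hp$tol}.
#'
#' @inheritParams regularizedObjective
#' @param zeroThreshold group-norm level below which a (mark, class) group
#'   counts as zero when reporting selected marks.
#' @return a \linkS4class{TADFit}.
#' @export
fitAlternating <- function(corpus, hp = tadHyperparams(),
                           zeroThreshold = 1e-6) {
  hp <- .asHyperparams(hp)
  stopifnot(validObject(corpus))
  marks <- markNames(corpus)
  M <- length(marks)
  A <- hp$degree
  prep <- .prepareCorpus(corpus, A)
  cw <- computeClassWeights(corpus)
  S <- curvatureForm(A)

  trueObjective <- function(wvec) {
    W <- .unpackWeights(wvec, A, marks)
    norms <- .groupNorms(W)
    curv <- sum(apply(W, c(2L, 3L), curvaturePenalty, S = S))
    .nllGrad(wvec, prep, cw, A, M, gradient = FALSE)$value +
      hp$lambda1 * sum(colSums(norms)^2) + hp$lambda2 * curv
  }

  wvec <- numeric((A + 1L) * M * 3L)
  gamma <- matrix(1 / M, M, 3L, dimnames = list(marks, .CLASSES))
  trace <- numeric(0)
  prevObj <- Inf
  converged <- FALSE
  for (it in seq_len(hp$maxOuterIters)) {
    wnew <- .fitWeightsCore(prep, cw, gamma, hp, warm = wvec)
    obj <- trueObjective(wnew)
    if (obj > prevObj) {
      ## safeguarded majorize-minimize: a step that fails to decrease the
      ## true objective (possible only through inner-solver inaccuracy)
      ## is rejected; no further progress is available at this accuracy
      converged <- TRUE
      break
    }
    wvec <- wnew
    trace <- c(trace, obj)
    gamma <- gammaUpdate(.unpackWeights(wvec, A, marks))
    if (is.finite(prevObj) &&
      abs(prevObj - obj) <= hp$tol * max(1, abs(obj))) {
      converged <- TRUE
      break
    }
    prevObj <- obj
  }
  W <- .unpackWeights(wvec, A, marks)
  model <- TADModel(
    markNames = marks, degree = A, weights = W, classWeights = cw,
    mMax = corpus@mMax,
    flags = list(
      monotone = hp$monotone, concave = hp$concave,
      nonnegative = hp$nonnegative
    ),
    resolutionBp = corpus@tracks[[1L]]@resolutionBp
  )
  norms <- .groupNorms(W)
  sel <- marks[apply(norms, 1L, max) > zeroThreshold]
  new("TADFit",
    model = model, gamma = gamma, objectiveTrace = trace,
    selectedMarks = sel, converged = converged, hyperparams = unclass(hp)
  )
}

## mean per-bin log-likelihood of held-out tracks under a model, with unit
## class weights (a proper probability, comparable across lambda choices)
.heldOutPerBinLL <- function(model, tracks, partitions) {
  unit <- c(b = 1, i = 1, e = 1)
  lls <- vapply(seq_along(tracks), function(q) {
    E <- totalEffects(tracks[[q]], model)
    (partitionScore(partitions[[q]], E, unit) -
      logPartitionFunction(E, unit)) / nBins(tracks[[q]])
  }, numeric(1))
  mean(lls)
}

#' Nested cross-validation over regularization strengths
#'
#' Outer K-fold split over tracks; within each outer training set, an
#' inner (K-1)-fold cross-validation picks the (lambda1, lambda2) pair
#' with the best mean held-out per-bin log-likelihood, the model is refit
#' on the whole outer training set at that pair, and scored on the
#' held-out fold. The inner loop never sees the outer test tracks.
#'
#' @param corpus a \linkS4class{TrainingCorpus} with at least K tracks.
#' @param lambdaGrid data.frame with columns \code{lambda1},
#'   \code{lambda2}.
#' @param K number of outer folds (>= 2); K equal to the number of tracks
#'   gives leave-one-track-out.
#' @param hp base hyperparameters (lambdas are overridden per grid point;
#'   \code{hp$seed} shuffles the fold assignment).
#' @return list with \code{perFold} (data.frame: fold, chosen lambdas,
#'   held-out per-bin log-likelihood) and \code{folds} (the track index
#'   assignment).
#' @export
nestedCV <- function(corpus, lambdaGrid, K, hp = tadHyperparams()) {
  hp <- .asHyperparams(hp)
  Q <- length(corpus@tracks)
  if (K < 2L || Q < K) {
    stop("need K >= 2 and at least K tracks")
  }
  lambdaGrid <- as.data.frame(lambdaGrid)
  stopifnot(all(c("lambda1", "lambda2") %in% names(lambdaGrid)))
  set.seed(hp$seed)
  folds <- sample(rep(seq_len(K), length.out = Q))
  subCorpus <- function(idx) {
    TrainingCorpus(corpus@tracks[idx], corpus@partitions[idx],
      mMax = corpus@mMax
    )
  }
  perFold <- NULL
  for (k in seq_len(K)) {
    trainIdx <- which(folds != k)
    testIdx <- which(folds == k)
    if (length(trainIdx) < 2L) {
      stop("each outer training set needs at least two tracks for inner CV")
    }
    innerK <- min(max(2L, K - 1L), length(trainIdx))
    innerFolds <- sample(rep(seq_len(innerK), length.out = length(trainIdx)))
    gridScore <- vapply(seq_len(nrow(lambdaGrid)), function(g) {
      hpG <- hp
      hpG$lambda1 <- lambdaGrid$lambda1[g]
      hpG$lambda2 <- lambdaGrid$lambda2[g]
      inner <- vapply(seq_len(innerK), function(j) {
        fitIdx <- trainIdx[innerFolds != j]
        valIdx <- trainIdx[innerFolds == j]
        if (length(fitIdx) == 0L) {
          return(NA_real_)
        }
        fit <- fitAlternating(subCorpus(fitIdx), hpG)
        .heldOutPerBinLL(
          fit@model, corpus@tracks[valIdx], corpus@partitions[valIdx]
        )
      }, numeric(1))
      mean(inner, na.rm = TRUE)
    }, numeric(1))
    gBest <- which.max(gridScore)
    hpBest <- hp
    hpBest$lambda1 <- lambdaGrid$lambda1[gBest]
    hpBest$lambda2 <- lambdaGrid$lambda2[gBest]
    fit <- fitAlternating(subCorpus(trainIdx), hpBest)
    score <- .heldOutPerBinLL(
      fit@model, corpus@tracks[testIdx], corpus@partitions[testIdx]
    )
    perFold <- rbind(perFold, data.frame(
      fold = k, lambda1 = hpBest$lambda1, lambda2 = hpBest$lambda2,
      testLogLik = score
    ))
  }
  list(perFold = perFold, folds = folds)
}

#' Bayesian information criterion of a fitted model
#'
#' BIC = -2 log L + k log n with k the number of weights above the zero
#' threshold in absolute value and n the total number of bins in the
#' corpus. The log-likelihood uses the model's class weights (the
#' training objective), so models fitted on the same corpus are
#' comparable.
#'
#' @inheritParams regularizedObjective
#' @param zeroTol absolute weight level below which a coefficient does not
#'   count as a parameter.
#' @return single numeric BIC (lower is better).
#' @export
bicScore <- function(corpus, model, zeroTol = 1e-6) {
  k <- sum(abs(model@weights) > zeroTol)
  n <- sum(vapply(corpus@tracks, nBins, 1L))
  -2 * logLikelihood(corpus, model) + k * log(n)
}

#' Greedy forward mark-subset selection by BIC
#'
#' Starting from the empty set, repeatedly adds the candidate mark whose
#' inclusion (after refitting) gives the lowest BIC, recording the
#' BIC-versus-size trace. The elbow of that trace identifies a
#' non-redundant subset of marks.
#'
#' @inheritParams regularizedObjective
#' @param candidateMarks marks to search over (default: all).
#' @param maxSize stop after this many marks.
#' @return list with \code{order} (marks in inclusion order), \code{bic}
#'   (BIC after each inclusion), and \code{best} (the prefix of
#'   \code{order} minimizing BIC).
#' @export
selectMinimalSubset <- function(corpus, candidateMarks = markNames(corpus),
                                hp = tadHyperparams(),
                                maxSize = length(candidateMarks)) {
  if (length(candidateMarks) == 0L) {
    stop("candidate mark set must be non-empty")
  }
  hp <- .asHyperparams(hp)
  selected <- character(0)
  bicTrace <- numeric(0)
  remaining <- candidateMarks
  while (length(selected) < maxSize && length(remaining) > 0L) {
    scores <- vapply(remaining, function(m) {
      sub <- subsetMarks(corpus, c(selected, m))
      fit <- fitAlternating(sub, hp)
      bicScore(sub, fit@model)
    }, numeric(1))
    bestM <- remaining[which.min(scores)]
    selected <- c(selected, bestM)
    remaining <- setdiff(remaining, bestM)
    bicTrace <- c(bicTrace, min(scores))
  }
  list(
    order = selected, bic = bicTrace,
    best = selected[seq_len(which.min(bicTrace))]
  )
}

#' Enumerate all k-subsets of a mark set
#'
#' Deterministic lexicographic enumeration (in the order the marks are
#' given) of every k-element subset, the candidate pool for exhaustive
#' small-subset model scans.
#'
#' @param marks character vector of mark names.
#' @param k subset size, 0 <= k <= length(marks).
#' @return list of character vectors, one per subset.
#' @export
#' @examples
#' length(enumerateKSubsets(letters[1:5], 2)) # choose(5, 2) = 10
enumerateKSubsets <- function(marks, k) {
  stopifnot(k >= 0, k <= length(marks))
  if (k == 0L) {
    return(list(character(0)))
  }
  utils::combn(marks, k, simplify = FALSE)
}
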