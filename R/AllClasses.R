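#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' MarkerMatrix: binned histone-mark densities for one genomic track
#'
#' Holds a bins-by-marks matrix of non-negative densities (typically
#' log-transformed RPKM at a fixed bin resolution), together with the
#' per-mark maximum densities \code{mMax} used to map raw densities onto
#' the unit interval where the Bernstein effect functions live.
#'
#' @slot trackId single string naming the track (e.g. a chromosome).
#' @slot resolutionBp bin width in base pairs.
#' @slot densities numeric matrix, one row per bin, one column per mark;
#'   column names are the mark names.
#' @slot mMax named numeric vector of per-mark maxima (positive); shared
#'   across a corpus so normalized densities are comparable between tracks.
#' @export
setClass("MarkerMatrix",
  representation(
    trackId = "character",
    resolutionBp = "numeric",
    densities = "matrix",
    mMax = "numeric"
  )
)

setValidity("MarkerMatrix", function(object) {
  d <- object@densities
  if (length(object@trackId) != 1L) {
    return("trackId must be a single string")
  }
  if (length(object@resolutionBp) != 1L || object@resolutionBp <= 0) {
    return("resolutionBp must be a single positive number")
  }
  if (nrow(d) < 1L) {
    return("need at least one bin")
  }
  if (is.null(colnames(d)) || anyDuplicated(colnames(d))) {
    return("densities must have unique column (mark) names")
  }
  if (any(d < 0)) {
    return("densities must be non-negative")
  }
  if (!identical(names(object@mMax), colnames(d))) {
    return("mMax names must match mark names")
  }
  if (any(object@mMax <= 0)) {
    return("mMax must be strictly positive")
  }
  if (any(apply(d, 2, max) > object@mMax + 1e-9)) {
    return("mMax must dominate the observed per-mark maxima")
  }
  TRUE
})

#' @param trackId,resolutionBp,densities,mMax see the class slots.
#'   When \code{mMax} is NULL it is computed from \code{densities}
#'   (all-zero marks get mMax = 1 so normalization stays defined).
#' @rdname MarkerMatrix-class
#' @export
MarkerMatrix <- function(densities, trackId = "track", resolutionBp = 40000,
                         mMax = NULL) {
  densities <- as.matrix(densities)
  if (is.null(colnames(densities))) {
    colnames(densities) <- paste0("mark", seq_len(ncol(densities)))
  }
  if (is.null(mMax)) {
    mMax <- apply(densities, 2, max)
    mMax[mMax <= 0] <- 1
  }
  if (is.null(names(mMax))) names(mMax) <- colnames(densities)
  new("MarkerMatrix",
    trackId = trackId, resolutionBp = as.numeric(resolutionBp),
    densities = densities, mMax = mMax
  )
}

#' DomainPartition: a non-overlapping set of domains over a binned track
#'
#' Domains are stored as 1-based inclusive bin intervals [s, e] with
#' e - s >= 1 (every domain spans at least two bins: its start boundary
#' and its end boundary), sorted and mutually disjoint. Bins in no domain
#' are inter-domain gaps.
#'
#' @slot trackId single string naming the track.
#' @slot nBins number of bins on the track.
#' @slot domains integer matrix with columns \code{s} and \code{e}.
#' @export
setClass("DomainPartition",
  representation(
    trackId = "character",
    nBins = "integer",
    domains = "matrix"
  )
)

setValidity("DomainPartition", function(object) {
  d <- object@domains
  if (length(object@nBins) != 1L || object@nBins < 1L) {
    return("nBins must be a single positive integer")
  }
  if (ncol(d) != 2L) {
    return("domains must have two columns (s, e)")
  }
  if (nrow(d) == 0L) {
    return(TRUE)
  }
  if (any(d < 1L) || any(d[, 2L] > object@nBins)) {
    return("domain bounds must lie in [1, nBins]")
  }
  if (any(d[, 2L] - d[, 1L] < 1L)) {
    return("every domain must span at least 2 bins (e - s >= 1)")
  }
  if (is.unsorted(d[, 1L], strictly = TRUE)) {
    return("domains must be sorted by start")
  }
  if (nrow(d) > 1L && any(d[-1L, 1L] <= d[-nrow(d), 2L])) {
    return("domains must not overlap")
  }
  TRUE
})

#' @param domains two-column matrix (or data.frame) of 1-based inclusive
#'   bin intervals; may have zero rows for the empty partition.
#' @param nBins,trackId see the class slots.
#' @rdname DomainPartition-class
#' @export
DomainPartition <- function(domains, nBins, trackId = "track") {
  domains <- as.matrix(domains)
  if (length(domains) == 0L) {
    domains <- matrix(integer(0), 0L, 2L)
  }
  storage.mode(domains) <- "integer"
  dimnames(domains) <- list(NULL, c("s", "e"))
  if (nrow(domains) > 1L) {
    domains <- domains[order(domains[, 1L]), , drop = FALSE]
  }
  new("DomainPartition",
    trackId = trackId, nBins = as.integer(nBins), domains = domains
  )
}

#' TrainingCorpus: paired marker tracks and domain partitions
#'
#' A list of (MarkerMatrix, DomainPartition) pairs sharing the same mark
#' set and a corpus-wide \code{mMax}, the unit for density normalization.
#'
#' @slot tracks list of \linkS4class{MarkerMatrix}.
#' @slot partitions list of \linkS4class{DomainPartition}, parallel to
#'   \code{tracks}.
#' @slot mMax corpus-wide per-mark maxima.
#' @export
setClass("TrainingCorpus",
  representation(
    tracks = "list",
    partitions = "list",
    mMax = "numeric"
  )
)

setValidity("TrainingCorpus", function(object) {
  if (length(object@tracks) == 0L) {
    return("corpus must contain at least one track")
  }
  if (length(object@tracks) != length(object@partitions)) {
    return("tracks and partitions must be parallel lists")
  }
  marks <- colnames(object@tracks[[1L]]@densities)
  for (q in seq_along(object@tracks)) {
    H <- object@tracks[[q]]
    D <- object@partitions[[q]]
    if (!is(H, "MarkerMatrix") || !is(D, "DomainPartition")) {
      return("tracks must be MarkerMatrix, partitions DomainPartition")
    }
    if (!identical(colnames(H@densities), marks)) {
      return("all tracks must share the same ordered mark names")
    }
    if (H@trackId != D@trackId) {
      return(sprintf("pair %d: track ids differ", q))
    }
    if (nrow(H@densities) != D@nBins) {
      return(sprintf("pair %d: bin counts differ", q))
    }
  }
  if (!identical(names(object@mMax), marks)) {
    return("corpus mMax names must match mark names")
  }
  TRUE
})

#' @param tracks,partitions parallel lists of tracks and their partitions.
#' @param mMax optional corpus-wide maxima; computed with
#'   \code{\link{computeMMax}} when NULL. Each track's own mMax slot is
#'   overwritten with the shared value.
#' @rdname TrainingCorpus-class
#' @export
TrainingCorpus <- function(tracks, partitions, mMax = NULL) {
  if (is.null(mMax)) {
    mMax <- computeMMax(tracks)
  }
  tracks <- lapply(tracks, function(H) {
    H@mMax <- mMax
    H
  })
  new("TrainingCorpus", tracks = tracks, partitions = partitions, mMax = mMax)
}

#' TADModel: fitted or specified model parameters
#'
#' The learnable object: one degree-A Bernstein weight vector per
#' (effect class, mark), the class weights used to rebalance the training
#' loss, and the per-mark density maxima fixing the [0,1] normalization.
#'
#' @slot markNames ordered mark names.
#' @slot degree Bernstein polynomial degree A.
#' @slot weights numeric array (A+1) x marks x classes, classes ordered
#'   (b, i, e).
#' @slot classWeights named positive numeric (b, i, e).
#' @slot mMax named per-mark maxima.
#' @slot flags list of logical shape constraints
#'   (monotone, concave, nonnegative).
#' @slot resolutionBp bin width the model was trained at (NA if unknown).
#' @export
setClass("TADModel",
  representation(
    markNames = "character",
    degree = "integer",
    weights = "array",
    classWeights = "numeric",
    mMax = "numeric",
    flags = "list",
    resolutionBp = "numeric"
  )
)

setValidity("TADModel", function(object) {
  A <- object@degree
  M <- length(object@markNames)
  if (A < 1L) {
    return("degree must be >= 1")
  }
  if (!identical(dim(object@weights), c(A + 1L, M, 3L))) {
    return("weights must be an (A+1) x M x 3 array")
  }
  if (any(!is.finite(object@weights))) {
    return("weights must be finite")
  }
  if (!identical(names(object@classWeights), .CLASSES)) {
    return("classWeights must be named (b, i, e)")
  }
  if (any(object@classWeights <= 0)) {
    return("classWeights must be strictly positive")
  }
  if (!identical(names(object@mMax), object@markNames)) {
    return("mMax must be named by markNames")
  }
  flg <- object@flags
  if (!all(c("monotone", "concave", "nonnegative") %in% names(flg))) {
    return("flags must contain monotone, concave, nonnegative")
  }
  TRUE
})

#' @param markNames,degree,weights,classWeights,mMax,flags,resolutionBp see
#'   the class slots; \code{weights} defaults to all zeros.
#' @rdname TADModel-class
#' @export
TADModel <- function(markNames, degree = 5L, weights = NULL,
                     classWeights = c(b = 1, i = 1, e = 1),
                     mMax = NULL,
                     flags = list(
                       monotone = FALSE, concave = FALSE,
                       nonnegative = FALSE
                     ),
                     resolutionBp = NA_real_) {
  degree <- as.integer(degree)
  M <- length(markNames)
  if (is.null(weights)) {
    weights <- array(0, c(degree + 1L, M, 3L))
  }
  dimnames(weights) <- list(NULL, markNames, .CLASSES)
  if (is.null(mMax)) {
    mMax <- rep(1, M)
  }
  names(mMax) <- markNames
  names(classWeights) <- .CLASSES
  flags <- modifyList(
    list(monotone = FALSE, concave = FALSE, nonnegative = FALSE), flags
  )
  new("TADModel",
    markNames = markNames, degree = degree, weights = weights,
    classWeights = classWeights, mMax = mMax, flags = flags,
    resolutionBp = as.numeric(resolutionBp)
  )
}

#' TADFit: result of regularized alternating training
#'
#' @slot model the fitted \linkS4class{TADModel}.
#' @slot gamma marks x classes matrix of group scales from the
#'   Cauchy-Schwarz surrogate (each column sums to 1).
#' @slot objectiveTrace regularized objective after each outer iteration.
#' @slot selectedMarks marks whose weight group norm exceeds the zero
#'   threshold in at least one class.
#' @slot converged logical.
#' @slot hyperparams the hyperparameter list used.
#' @export
setClass("TADFit",
  representation(
    model = "TADModel",
    gamma = "matrix",
    objectiveTrace = "numeric",
    selectedMarks = "character",
    converged = "logical",
    hyperparams = "list"
  )
)

setValidity("TADFit", function(object) {
  tr <- object@objectiveTrace
  if (length(tr) > 1L && any(diff(tr) > 1e-8 * pmax(1, abs(tr[-length(tr)])))) {
    return("objective trace must be non-increasing (within slack)")
  }
  if (any(abs(colSums(object@gamma) - 1) > 1e-8)) {
    return("gamma columns must sum to 1")
  }
  TRUE
})
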