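#' @rdname MarkerMatrix-class
#' @param x,object a MarkerMatrix, DomainPartition, TrainingCorpus, TADModel
#'   or TADFit.
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' @rdname MarkerMatrix-class
#' @export
setGeneric("markNames", function(x) standardGeneric("markNames"))

#' @rdname MarkerMatrix-class
#' @export
setGeneric("densities", function(x) standardGeneric("densities"))

#' @rdname MarkerMatrix-class
#' @export
setGeneric("trackId", function(x) standardGeneric("trackId"))

#' @rdname MarkerMatrix-class
#' @export
setGeneric("resolutionBp", function(x) standardGeneric("resolutionBp"))

#' @rdname MarkerMatrix-class
#' @export
setGeneric("mMax", function(x) standardGeneric("mMax"))

#' @rdname DomainPartition-class
#' @param x object to extract from.
#' @export
setGeneric("domains", function(x) standardGeneric("domains"))

#' @rdname TADModel-class
#' @export
setGeneric("classWeights", function(x) standardGeneric("classWeights"))

#' @rdname TADModel-class
#' @export
setGeneric("modelWeights", function(x) standardGeneric("modelWeights"))

#' @rdname TADModel-class
#' @export
setGeneric("bernsteinDegree", function(x) standardGeneric("bernsteinDegree"))

#' @rdname TADFit-class
#' @param x a TADFit.
#' @export
setGeneric("fittedModel", function(x) standardGeneric("fittedModel"))

#' @rdname TADFit-class
#' @export
setGeneric("selectedMarks", function(x) standardGeneric("selectedMarks"))

#' @rdname TADFit-class
#' @export
setGeneric("objectiveTrace", function(x) standardGeneric("objectiveTrace"))

setMethod("nBins", "MarkerMatrix", function(x) nrow(x@densities))
setMethod("nBins", "DomainPartition", function(x) x@nBins)
setMethod("markNames", "MarkerMatrix", function(x) colnames(x@densities))
setMethod("markNames", "TrainingCorpus", function(x) {
  colnames(x@tracks[[1L]]@densities)
})
setMethod("markNames", "TADModel", function(x) x@markNames)
setMethod("densities", "MarkerMatrix", function(x) x@densities)
setMethod("trackId", "MarkerMatrix", function(x) x@trackId)
setMethod("trackId", "DomainPartition", function(x) x@trackId)
setMethod("resolutionBp", "MarkerMatrix", function(x) x@resolutionBp)
setMethod("mMax", "MarkerMatrix", function(x) x@mMax)
setMethod("mMax", "TrainingCorpus", function(x) x@mMax)
setMethod("mMax", "TADModel", function(x) x@mMax)
setMethod("domains", "DomainPartition", function(x) x@domains)
setMethod("classWeights", "TADModel", function(x) x@classWeights)
setMethod("modelWeights", "TADModel", function(x) x@weights)
setMethod("bernsteinDegree", "TADModel", function(x) x@degree)
setMethod("fittedModel", "TADFit", function(x) x@model)
setMethod("selectedMarks", "TADFit", function(x) x@selectedMarks)
setMethod("objectiveTrace", "TADFit", function(x) x@objectiveTrace)

#' @rdname TrainingCorpus-class
#' @param x a TrainingCorpus.
#' @export
setGeneric("corpusTracks", function(x) standardGeneric("corpusTracks"))

#' @rdname TrainingCorpus-class
#' @export
setGeneric("corpusPartitions", function(x) standardGeneric("corpusPartitions"))

setMethod("corpusTracks", "TrainingCorpus", function(x) x@tracks)
setMethod("corpusPartitions", "TrainingCorpus", function(x) x@partitions)

setMethod("length", "TrainingCorpus", function(x) length(x@tracks))
setMethod("length", "DomainPartition", function(x) nrow(x@domains))

setMethod("show", "MarkerMatrix", function(object) {
  cat(sprintf(
    "MarkerMatrix '%s': %d bins x %d marks at %g bp\n",
    object@trackId, nrow(object@densities), ncol(object@densities),
    object@resolutionBp
  ))
  cat("  marks:", paste(colnames(object@densities), collapse = ", "), "\n")
})

setMethod("show", "DomainPartition", function(object) {
  d <- object@domains
  cov <- if (nrow(d)) sum(d[, 2L] - d[, 1L] + 1L) else 0L
  cat(sprintf(
    "DomainPartition '%s': %d domains over %d bins (%.1f%% covered)\n",
    object@trackId, nrow(d), object@nBins, 100 * cov / object@nBins
  ))
})

setMethod("show", "TrainingCorpus", function(object) {
  cat(sprintf(
    "TrainingCorpus: %d track(s), %d marks, %d total bins\n",
    length(object@tracks), length(object@mMax),
    sum(vapply(object@tracks, nBins, 1L))
  ))
})

setMethod("show", "TADModel", function(object) {
  cat(sprintf(
    "TADModel: %d marks, Bernstein degree %d\n",
    length(object@markNames), object@degree
  ))
  on <- names(Filter(isTRUE, object@flags))
  cat(
    "  shape constraints:",
    if (length(on)) paste(on, collapse = ", ") else "none", "\n"
  )
  gn <- .groupNorms(object@weights)
  nz <- rownames(gn)[apply(gn, 1L, max) > 1e-6]
  cat(sprintf(
    "  active marks (%d/%d): %s\n", length(nz), nrow(gn),
    paste(nz, collapse = ", ")
  ))
})

setMethod("show", "TADFit", function(object) {
  cat(sprintf(
    "TADFit: %d outer iteration(s), %sconverged, objective %.6g\n",
    length(object@objectiveTrace),
    if (object@converged) "" else "NOT ",
    utils::tail(object@objectiveTrace, 1L)
  ))
  cat("  selected marks:", paste(object@selectedMarks, collapse = ", "), "\n")
})
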