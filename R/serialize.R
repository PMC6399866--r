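#' Serialize a model to JSON
#'
#' Writes every field needed to reapply the model to new tracks: bin
#' resolution, Bernstein degree, mark names, per-mark maxima, class
#' weights, shape flags and one weight vector per (class, mark). Numbers
#' are written at full precision, so write/read round-trips are lossless.
#'
#' @param model a \linkS4class{TADModel}.
#' @param path file path; when NULL the JSON string is returned instead.
#' @return \code{path} invisibly, or the JSON string.
#' @export
modelToJson <- function(model, path = NULL) {
  eff <- lapply(.CLASSES, function(p) {
    cls <- lapply(model@markNames, function(m) unname(model@weights[, m, p]))
    names(cls) <- model@markNames
    cls
  })
  names(eff) <- .CLASSES
  obj <- list(
    resolution = model@resolutionBp,
    degree = model@degree,
    marks = model@markNames,
    m_max = as.list(model@mMax),
    class_weights = as.list(model@classWeights),
    flags = model@flags,
    effects = eff
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17), null = "null")
  if (is.null(path)) {
    return(as.character(js))
  }
  writeLines(js, path)
  invisible(path)
}

#' @param json file path or JSON string produced by \code{modelToJson}.
#' @rdname modelToJson
#' @export
modelFromJson <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  marks <- obj$marks
  A <- as.integer(obj$degree)
  W <- array(0, c(A + 1L, length(marks), 3L))
  for (p in seq_along(.CLASSES)) {
    for (m in seq_along(marks)) {
      W[, m, p] <- obj$effects[[.CLASSES[p]]][[marks[m]]]
    }
  }
  TADModel(
    markNames = marks, degree = A, weights = W,
    classWeights = unlist(obj$class_weights)[.CLASSES],
    mMax = unlist(obj$m_max)[marks],
    flags = lapply(obj$flags, isTRUE),
    resolutionBp = if (is.null(obj$resolution)) NA_real_ else obj$resolution
  )
}

#' Write a training report for a fit
#'
#' JSON sidecar with the objective trace, selected marks, group scales and
#' hyperparameters of a \linkS4class{TADFit}.
#'
#' @param fit a \linkS4class{TADFit}.
#' @param path output file path.
#' @return \code{path} invisibly.
#' @export
writeFitReport <- function(fit, path) {
  obj <- list(
    objective_trace = fit@objectiveTrace,
    selected_marks = fit@selectedMarks,
    converged = fit@converged,
    gamma = apply(fit@gamma, 2L, as.list),
    hyperparams = fit@hyperparams[c(
      "lambda1", "lambda2", "degree",
      "monotone", "concave", "nonnegative", "tol"
    )]
  )
  writeLines(
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA),
    path
  )
  invisible(path)
}
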