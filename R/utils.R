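#' @keywords internal
#' @import methods
#' @importFrom utils modifyList combn read.delim write.table tail
#' @importFrom stats dbinom optim constrOptim runif rbeta
#' @importFrom Rcpp evalCpp
#' @useDynLib ntdp, .registration = TRUE
"_PACKAGE"

## State space of the linear chain: domain start, interior, domain end,
## inter-domain gap. Order is fixed everywhere.
.STATES <- c("sb", "i", "eb", "e")
## Effect-function class backing each state (sb and eb share the boundary
## class "b": the model has three effect classes but four chain states).
.STATE_CLASS <- c(sb = "b", i = "i", eb = "b", e = "e")
.CLASSES <- c("b", "i", "e")

logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) {
    return(m)
  }
  m + log(sum(exp(x - m)))
}

## two-argument version used in the tight forward/backward loops
.lse2 <- function(a, b) {
  m <- if (a > b) a else b
  if (!is.finite(m)) {
    return(m)
  }
  m + log(exp(a - m) + exp(b - m))
}

#' Allowed state transitions of the domain chain
#'
#' Binary 4x4 matrix over the states \code{sb} (domain start), \code{i}
#' (interior), \code{eb} (domain end), \code{e} (inter-domain gap); entry
#' (y, x) is 1 when a bin in state \code{x} may follow a bin in state
#' \code{y}. Because every domain spans at least two bins, \code{sb} can
#' never be followed by \code{sb} or \code{e}, and a track must start in
#' \code{sb} or \code{e} and end in \code{eb} or \code{e}.
#'
#' @return An integer matrix with dimnames over the four states.
#' @export
#' @examples
#' transitionMatrix()
transitionMatrix <- function() {
  T <- matrix(0L, 4, 4, dimnames = list(.STATES, .STATES))
  allowed <- rbind(
    c("sb", "i"), c("sb", "eb"), c("i", "i"), c("i", "eb"),
    c("eb", "sb"), c("eb", "e"), c("e", "sb"), c("e", "e")
  )
  T[allowed] <- 1L
  T
}

## flatten / restore the full weight set W: array (A+1) x M x 3 <-> vector.
## Column-major order: coefficient index fastest, then mark, then class.
.packWeights <- function(W) as.vector(W)

.unpackWeights <- function(w, degree, markNames) {
  array(w,
    dim = c(degree + 1L, length(markNames), 3L),
    dimnames = list(NULL, markNames, .CLASSES)
  )
}

.groupNorms <- function(W) {
  ## per (mark, class) Euclidean norm of the weight vector -> M x 3 matrix
  apply(W, c(2L, 3L), function(w) sqrt(sum(w^2)))
}

.checkSeed <- function(seed) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}
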