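#' Bernstein basis polynomials
#'
#' \code{bernsteinBasis} evaluates the i-th degree-A Bernstein kernel
#' b_{i,A}(p) = C(A,i) p^i (1-p)^(A-i); \code{bernsteinBasisMatrix} returns
#' all A+1 kernels at once. Evaluation goes through \code{dbinom}, which
#' works in log space internally, so large degrees stay stable.
#'
#' @param i basis index in 0..A.
#' @param degree polynomial degree A.
#' @param p evaluation points in [0, 1] (vectorized).
#' @return \code{bernsteinBasis}: numeric vector along \code{p};
#'   \code{bernsteinBasisMatrix}: length(p) x (A+1) matrix whose rows sum
#'   to 1 (partition of unity).
#' @export
#' @examples
#' bernsteinBasis(1, 2, 0.5) # 2 * 0.5 * 0.5 = 0.5
#' rowSums(bernsteinBasisMatrix(c(0.1, 0.9), 6))
bernsteinBasis <- function(i, degree, p) {
  stopifnot(i >= 0, i <= degree)
  if (any(p < 0 | p > 1)) {
    stop("p must lie in [0, 1]")
  }
  stats::dbinom(i, size = degree, prob = p)
}

#' @rdname bernsteinBasis
#' @export
bernsteinBasisMatrix <- function(p, degree) {
  if (any(p < 0 | p > 1)) {
    stop("p must lie in [0, 1]")
  }
  vapply(0:degree, function(i) stats::dbinom(i, degree, p), numeric(length(p)))
}

#' Evaluate a Bernstein effect function
#'
#' f(p) = sum_i w[i] b_{i,A}(p) with A = length(w) - 1. Interpolates its
#' first and last weight at the endpoints and reproduces constants when
#' all weights are equal.
#'
#' @param weights numeric weight vector w[0..A].
#' @param p evaluation points in [0, 1].
#' @return numeric vector of function values.
#' @export
bernsteinEval <- function(weights, p) {
  A <- length(weights) - 1L
  drop(bernsteinBasisMatrix(p, A) %*% weights)
}

#' Second derivative of a Bernstein effect function
#'
#' Uses the closed form through second differences of the weights:
#' f''(p) = A(A-1) sum_k (w[k+2] - 2 w[k+1] + w[k]) b_{k,A-2}(p). Degrees
#' below 2 give identically zero.
#'
#' @inheritParams bernsteinEval
#' @return numeric vector of second-derivative values.
#' @export
bernsteinSecondDeriv <- function(weights, p) {
  A <- length(weights) - 1L
  if (A < 2L) {
    return(numeric(length(p)))
  }
  d2 <- diff(weights, differences = 2L)
  A * (A - 1) * drop(bernsteinBasisMatrix(p, A - 2L) %*% d2)
}

#' Curvature penalty quadratic form
#'
#' The smoothness penalty R(f) = integral of f''(p)^2 over [0, 1] is a
#' quadratic form w' S w in the Bernstein weights. Writing f'' through the
#' second-difference operator D (so f'' = A(A-1) * Bernstein_{A-2}(D w)),
#' S = A^2 (A-1)^2 D' B D with B[k, l] = C(A-2,k) C(A-2,l)
#' beta(k+l+1, 2A-3-k-l), the Gram matrix of the degree-(A-2) basis. Beta
#' values are computed in log space. S is symmetric positive semidefinite
#' and annihilates arithmetic-progression (linear) weight vectors.
#'
#' @param degree polynomial degree A.
#' @return symmetric (A+1) x (A+1) matrix (all zeros when A < 2).
#' @export
#' @examples
#' w <- c(0, 0, 1) # f(p) = p^2, f'' = 2, R(f) = 4
#' curvaturePenalty(w)
curvatureForm <- function(degree) {
  A <- as.integer(degree)
  if (A < 2L) {
    return(matrix(0, A + 1L, A + 1L))
  }
  B <- .bernsteinGram(A)
  D <- matrix(0, A - 1L, A + 1L)
  for (r in seq_len(A - 1L)) {
    D[r, r:(r + 2L)] <- c(1, -2, 1)
  }
  S <- A^2 * (A - 1)^2 * crossprod(D, B %*% D)
  (S + t(S)) / 2
}

## Gram matrix of the degree-(A-2) Bernstein basis (scaled binomials times
## beta-function integrals, assembled in log space)
.bernsteinGram <- function(A) {
  k <- 0:(A - 2L)
  outer(k, k, function(ki, kj) {
    exp(lchoose(A - 2L, ki) + lchoose(A - 2L, kj) +
      lbeta(ki + kj + 1, 2 * A - 3 - ki - kj))
  })
}

#' @param weights Bernstein weight vector.
#' @param S optional precomputed form from \code{curvatureForm}; when NULL
#'   the penalty is evaluated through the second differences of the
#'   weights, which makes it exactly zero for linear (arithmetic
#'   progression) weight vectors.
#' @rdname curvatureForm
#' @export
curvaturePenalty <- function(weights, S = NULL) {
  if (!is.null(S)) {
    return(drop(crossprod(weights, S %*% weights)))
  }
  A <- length(weights) - 1L
  if (A < 2L) {
    return(0)
  }
  d <- diff(weights, differences = 2L)
  B <- .bernsteinGram(A)
  A^2 * (A - 1)^2 * drop(crossprod(d, B %*% d))
}

#' Linear shape-constraint systems for Bernstein weights
#'
#' Return matrices G with the convention G w <= 0. Monotonicity
#' (nondecreasing f) is w[i] - w[i+1] <= 0 for i = 0..A-1; concavity is
#' w[i-1] - 2 w[i] + w[i+1] <= 0 for interior i = 1..A-1. Because the
#' Bernstein representation is variation diminishing, these weight-level
#' constraints guarantee the corresponding shape of f on all of [0, 1].
#'
#' @param degree polynomial degree A (>= 1 for monotone, >= 2 for concave).
#' @return numeric constraint matrix with A (monotone) or A-1 (concave)
#'   rows and A+1 columns.
#' @export
monotoneConstraints <- function(degree) {
  A <- as.integer(degree)
  stopifnot(A >= 1L)
  G <- matrix(0, A, A + 1L)
  for (r in seq_len(A)) {
    G[r, r] <- 1
    G[r, r + 1L] <- -1
  }
  G
}

#' @rdname monotoneConstraints
#' @export
concaveConstraints <- function(degree) {
  A <- as.integer(degree)
  stopifnot(A >= 2L)
  G <- matrix(0, A - 1L, A + 1L)
  for (r in seq_len(A - 1L)) {
    G[r, r:(r + 2L)] <- c(1, -2, 1)
  }
  G
}
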