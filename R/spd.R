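# Geometry of the SPD manifold under the affine-invariant Riemannian metric:
# matrix functions via eigendecomposition, distances, geodesics, Karcher
# means and tangent-space maps.

symmetrize <- function(A) (A + t(A)) / 2

spdEigen <- function(A, floorEv = 1e-12) {
  e <- eigen(symmetrize(A), symmetric = TRUE)
  e$values <- pmax(e$values, floorEv)
  e
}

spdApply <- function(A, f) {
  e <- spdEigen(A)
  e$vectors %*% (f(e$values) * t(e$vectors))
}

spdSqrt <- function(A) spdApply(A, sqrt)
spdInvSqrt <- function(A) spdApply(A, function(v) 1 / sqrt(v))
spdLogm <- function(A) spdApply(A, log)
symExpm <- function(S) {
  e <- eigen(symmetrize(S), symmetric = TRUE)
  e$vectors %*% (exp(e$values) * t(e$vectors))
}

assertSpd <- function(A, tol = 1e-9, what = "matrix") {
  stopIfNot(is.matrix(A) && nrow(A) == ncol(A),
            paste(what, "must be square"))
  stopIfNot(max(abs(A - t(A))) <= tol * max(1, max(abs(A))),
            paste(what, "must be symmetric"))
  stopIfNot(min(eigen(symmetrize(A), symmetric = TRUE,
                      only.values = TRUE)$values) > 0,
            paste(what, "must be positive definite"))
}

#' Affine-invariant Riemannian distance between SPD matrices
#'
#' \eqn{\delta(A,B) = \|\log(A^{-1/2} B A^{-1/2})\|_F}: symmetric, zero iff
#' \eqn{A = B}, and invariant under congruence transformations
#' \eqn{C \mapsto W C W^T} with invertible \eqn{W}.
#'
#' @param A,B SPD matrices of equal dimension.
#' @return nonnegative distance.
#' @export
airmDistance <- function(A, B) {
  assertSpd(A, what = "A"); assertSpd(B, what = "B")
  stopIfNot(nrow(A) == nrow(B), "A and B must have equal dimension")
  W <- spdInvSqrt(A)
  ev <- eigen(symmetrize(W %*% B %*% W), symmetric = TRUE,
              only.values = TRUE)$values
  sqrt(sum(log(pmax(ev, 1e-300))^2))
}

#' Geodesic between SPD matrices
#'
#' Point at parameter \code{t} on the affine-invariant geodesic from A to B:
#' \eqn{A^{1/2} (A^{-1/2} B A^{-1/2})^t A^{1/2}}; t = 1/2 is the two-point
#' geometric mean.
#'
#' @param A,B SPD matrices.
#' @param t position in [0,1].
#' @export
spdGeodesic <- function(A, B, t) {
  Ah <- spdSqrt(A); Aih <- spdInvSqrt(A)
  symmetrize(Ah %*% spdApply(Aih %*% B %*% Aih, function(v) v^t) %*% Ah)
}

#' Karcher (geometric / Frechet) mean of SPD matrices
#'
#' Fixed-point iteration for the weighted Riemannian barycenter: the mean M
#' satisfies \eqn{\sum_i w_i \log(M^{-1/2} C_i M^{-1/2}) = 0}. Iteration
#' stops when the Frobenius norm of the weighted log-sum falls below
#' \code{tol}; non-convergence within \code{maxIter} raises a numerical
#' error with diagnostics.
#'
#' @param mats list of SPD matrices (or p x p x n array).
#' @param weights nonnegative weights, normalized internally.
#' @param tol convergence tolerance on the tangent-space gradient norm.
#' @param maxIter iteration cap.
#' @param stepSize geodesic step size of the fixed-point update.
#' @return the SPD mean.
#' @export
riemannianMean <- function(mats, weights = NULL, tol = 1e-9, maxIter = 100,
                           stepSize = 1) {
  if (is.array(mats) && length(dim(mats)) == 3)
    mats <- lapply(seq_len(dim(mats)[3]), function(i) mats[, , i])
  stopIfNot(length(mats) >= 1, "need at least one matrix")
  if (length(mats) == 1) return(mats[[1]])
  if (is.null(weights)) weights <- rep(1, length(mats))
  weights <- weights / sum(weights)
  M <- symmetrize(Reduce(`+`, Map(`*`, mats, weights)))  # arithmetic init
  for (it in seq_len(maxIter)) {
    Mih <- spdInvSqrt(M)
    Mh <- spdSqrt(M)
    Tn <- matrix(0, nrow(M), ncol(M))
    for (i in seq_along(mats))
      Tn <- Tn + weights[i] * spdLogm(Mih %*% mats[[i]] %*% Mih)
    gnorm <- sqrt(sum(Tn^2))
    if (gnorm < tol) return(symmetrize(M))
    M <- symmetrize(Mh %*% symExpm(stepSize * Tn) %*% Mh)
  }
  stop("numerical error: Karcher mean did not converge in ", maxIter,
       " iterations (last gradient norm ", format(gnorm), ", n = ",
       length(mats), ", p = ", nrow(M), ")", call. = FALSE)
}

upperTriIndex <- function(p) which(upper.tri(diag(p), diag = TRUE))

tangentWeights <- function(p) {
  W <- matrix(sqrt(2), p, p)
  diag(W) <- 1
  W[upperTriIndex(p)]
}

#' Project covariance frames to the tangent space at a reference point
#'
#' Each SPD frame C maps to the vectorized upper triangle (off-diagonals
#' scaled by sqrt(2)) of \eqn{\log(R^{-1/2} C R^{-1/2})}. The Euclidean norm
#' of the vector equals the affine-invariant distance from the reference R
#' to C, so Euclidean classifiers in the tangent space respect the manifold
#' geometry locally. A saved reference can be reused on new cohorts: the
#' projection needs no refit.
#'
#' @param frames a \code{CovarianceFrameSeries}, list of SPD matrices, or
#'   p x p x n array.
#' @param reference SPD reference matrix.
#' @return a \code{TangentVectors} object.
#' @export
tangentProject <- function(frames, reference) {
  assertSpd(reference, what = "reference")
  mats <- framesAsList(frames)
  p <- nrow(reference)
  Rih <- spdInvSqrt(reference)
  idx <- upperTriIndex(p)
  wts <- tangentWeights(p)
  V <- do.call(rbind, lapply(mats, function(C) {
    assertSpd(C, what = "frame")
    S <- spdLogm(Rih %*% C %*% Rih)
    S[idx] * wts
  }))
  new("TangentVectors", reference = reference, vectors = V)
}

#' Map a tangent vector back to the SPD manifold
#'
#' Inverse of \code{\link{tangentProject}}:
#' \eqn{C = R^{1/2} \exp(S) R^{1/2}} where S is the unvectorized symmetric
#' matrix.
#'
#' @param v tangent vector of length p(p+1)/2.
#' @param reference SPD reference matrix.
#' @return SPD matrix.
#' @export
tangentExp <- function(v, reference) {
  p <- nrow(reference)
  S <- matrix(0, p, p)
  S[upperTriIndex(p)] <- v / tangentWeights(p)
  S <- S + t(S) - diag(diag(S))
  Rh <- spdSqrt(reference)
  symmetrize(Rh %*% symExpm(S) %*% Rh)
}

framesAsList <- function(frames) {
  if (is(frames, "CovarianceFrameSeries"))
    return(lapply(seq_len(nFrames(frames)), function(i)
      frames@matrices[, , i]))
  if (is.array(frames) && length(dim(frames)) == 3)
    return(lapply(seq_len(dim(frames)[3]), function(i) frames[, , i]))
  if (is.list(frames)) return(frames)
  stop("cannot interpret frames input", call. = FALSE)
}
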