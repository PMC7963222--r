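#' @title Voigt (Mandel) vector representations of symmetric tensors
#' @name voigt
#' @description
#' Symmetric second- and fourth-order tensors are carried as 6- and 21-vectors
#' with sqrt(2)-scaled off-diagonal entries (Mandel convention), so that every
#' double contraction becomes a plain dot product:
#' `voigt6(A) %*% voigt6(B) == sum(A * B)` and, for symmetric 6x6 matrices
#' representing fourth-order tensors, `voigt21(P) %*% voigt21(Q) == sum(P * Q)`.
#' Ordering: `[xx, yy, zz, sqrt2*yz, sqrt2*xz, sqrt2*xy]` for 6-vectors; the
#' six diagonal entries followed by the fifteen row-wise upper-triangle
#' entries (times sqrt(2)) for 21-vectors.
NULL

# upper-triangle index table for the 6x6 -> 21 mapping, row-wise
.v21_ut <- local({
  ij <- which(upper.tri(matrix(0, 6, 6)), arr.ind = TRUE)
  ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
})

.check_symmetric <- function(A, n, tol = 1e-10, what = "matrix") {
  if (!is.matrix(A) || !all(dim(A) == c(n, n)) || !is.numeric(A))
    stop(sprintf("expected a numeric %dx%d %s", n, n, what))
  scale <- max(1, max(abs(A)))
  if (max(abs(A - t(A))) > tol * scale)
    stop(sprintf("%s is not symmetric within tolerance %g", what, tol))
  invisible(A)
}

#' Map a symmetric 3x3 matrix to its 6-vector Voigt form
#'
#' @param A symmetric numeric 3x3 matrix.
#' @return numeric 6-vector `[xx, yy, zz, sqrt2*yz, sqrt2*xz, sqrt2*xy]`.
#' @seealso [voigt6_inv()], [voigt21()]
#' @export
#' @examples
#' voigt6(diag(3))          # c(1, 1, 1, 0, 0, 0)
#' A <- diag(c(1, 2, 3))
#' sum(voigt6(A) * voigt6(A)) # == sum(A * A) == 14
voigt6 <- function(A) {
  .check_symmetric(A, 3L)
  s2 <- sqrt(2)
  c(A[1, 1], A[2, 2], A[3, 3], s2 * A[2, 3], s2 * A[1, 3], s2 * A[1, 2])
}

#' Reconstruct the symmetric 3x3 matrix from its Voigt 6-vector
#'
#' Exact inverse of [voigt6()].
#' @param v numeric 6-vector.
#' @return symmetric 3x3 matrix.
#' @export
voigt6_inv <- function(v) {
  stopifnot(is.numeric(v), length(v) == 6L)
  s <- 1 / sqrt(2)
  matrix(c(v[1], s * v[6], s * v[5],
           s * v[6], v[2], s * v[4],
           s * v[5], s * v[4], v[3]), 3, 3)
}

#' Map a symmetric 6x6 matrix to its 21-vector Voigt form
#'
#' Applied to the outer square of a Voigt 6-vector this turns fourth-order
#' double contractions into 21-vector dot products.
#'
#' @param M symmetric numeric 6x6 matrix (e.g. `tcrossprod(voigt6(B))`).
#' @return numeric 21-vector.
#' @export
voigt21 <- function(M) {
  .check_symmetric(M, 6L)
  c(diag(M), sqrt(2) * M[.v21_ut])
}

#' Reconstruct the symmetric 6x6 matrix from its Voigt 21-vector
#'
#' Exact inverse of [voigt21()].
#' @param v numeric 21-vector.
#' @return symmetric 6x6 matrix.
#' @export
voigt21_inv <- function(v) {
  stopifnot(is.numeric(v), length(v) == 21L)
  M <- diag(v[1:6])
  off <- v[7:21] / sqrt(2)
  M[.v21_ut] <- off
  M[.v21_ut[, c(2, 1)]] <- off
  M
}

# evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
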