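# Complex sparse matrices as a pair of real Matrix::dgCMatrix objects.
# The Matrix package has no complex sparse classes, so the package carries a
# thin wrapper: matrix-vector products act on the (re, im) parts, and direct
# factorization goes through the equivalent real 2n x 2n block system
#   [ Re(A)  -Im(A) ] [ Re(x) ]   [ Re(b) ]
#   [ Im(A)   Re(A) ] [ Im(x) ] = [ Im(b) ]
# factored once with Matrix's sparse LU and reused for all right-hand sides.

#' Create a complex sparse matrix from triplets
#'
#' @param i,j integer row/column indices.
#' @param x complex values (duplicates are summed, as in
#'   [Matrix::sparseMatrix()]).
#' @param dims integer length-2 dimensions.
#' @return an object of class `zspmat` holding the real and imaginary parts
#'   as `dgCMatrix` objects.
#' @export
zsp_matrix <- function(i, j, x, dims) {
  re <- Matrix::sparseMatrix(i = i, j = j, x = Re(x), dims = dims,
                             repr = "C")
  im <- Matrix::sparseMatrix(i = i, j = j, x = Im(x), dims = dims,
                             repr = "C")
  structure(list(re = Matrix::drop0(re), im = Matrix::drop0(im),
                 dim = as.integer(dims)),
            class = "zspmat")
}

#' @export
dim.zspmat <- function(x) x$dim

zsp_zero <- function(dims) {
  z <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = dims, repr = "C")
  structure(list(re = z, im = z, dim = as.integer(dims)), class = "zspmat")
}

#' Complex sparse matrix-vector / matrix-matrix product
#'
#' @param A a `zspmat`.
#' @param x complex vector or matrix with `dim(A)[2]` rows.
#' @param conjugate_transpose if `TRUE`, applies the conjugate transpose of
#'   `A` instead.
#' @return complex vector or matrix.
#' @export
zsp_mult <- function(A, x, conjugate_transpose = FALSE) {
  xr <- Re(x); xi <- Im(x)
  if (conjugate_transpose) {
    yr <- Matrix::crossprod(A$re, xr) + Matrix::crossprod(A$im, xi)
    yi <- Matrix::crossprod(A$re, xi) - Matrix::crossprod(A$im, xr)
  } else {
    yr <- A$re %*% xr - A$im %*% xi
    yi <- A$re %*% xi + A$im %*% xr
  }
  y <- as.matrix(yr) + 1i * as.matrix(yi)
  if (is.null(dim(x))) drop(y) else y
}

#' @export
`+.zspmat` <- function(e1, e2) {
  stopifnot(inherits(e1, "zspmat"), inherits(e2, "zspmat"),
            all(e1$dim == e2$dim))
  structure(list(re = e1$re + e2$re, im = e1$im + e2$im, dim = e1$dim),
            class = "zspmat")
}

#' @export
`-.zspmat` <- function(e1, e2) {
  if (missing(e2)) {
    structure(list(re = -e1$re, im = -e1$im, dim = e1$dim), class = "zspmat")
  } else {
    stopifnot(all(e1$dim == e2$dim))
    structure(list(re = e1$re - e2$re, im = e1$im - e2$im, dim = e1$dim),
              class = "zspmat")
  }
}

#' Scale a complex sparse matrix by a complex scalar
#' @param A a `zspmat`.
#' @param s a complex scalar.
#' @export
zsp_scale <- function(A, s) {
  structure(list(re = Re(s) * A$re - Im(s) * A$im,
                 im = Re(s) * A$im + Im(s) * A$re,
                 dim = A$dim),
            class = "zspmat")
}

#' Transpose (not conjugated) of a complex sparse matrix
#' @param A a `zspmat`.
#' @export
zsp_t <- function(A) {
  structure(list(re = Matrix::t(A$re), im = Matrix::t(A$im),
                 dim = rev(A$dim)),
            class = "zspmat")
}

#' Frobenius-type norms and symmetry checks
#' @param A a `zspmat`.
#' @export
zsp_norm <- function(A) {
  sqrt(sum(A$re@x^2) + sum(A$im@x^2))
}

#' Factorize a complex sparse matrix for repeated solves
#'
#' Builds and LU-factorizes the equivalent real block system once; the
#' returned object solves `A x = b` (and `A^H x = b`) for many right-hand
#' sides at triangular-solve cost.
#'
#' @param A a square `zspmat`.  The FEM system matrices handled here are
#'   complex-symmetric (`t(A) = A`, without conjugation); this is verified at
#'   factorization time and exploited for conjugate-transpose solves.
#' @return an object of class `zsp_lu`.
#' @export
zsp_factorize <- function(A) {
  n <- A$dim[1L]
  stopifnot(A$dim[2L] == n)
  sym <- zsp_norm(A - zsp_t(A)) <= 1e-10 * max(zsp_norm(A), 1e-300)
  K <- rbind(cbind(A$re, -A$im), cbind(A$im, A$re))
  fac <- Matrix::lu(K)
  structure(list(lu = fac, n = n, symmetric = sym), class = "zsp_lu")
}

#' Solve a factorized complex sparse system
#'
#' @param fac a `zsp_lu` from [zsp_factorize()].
#' @param b complex vector or matrix of right-hand sides.
#' @param conjugate_transpose solve with the conjugate transpose
#'   (`A^H x = b`) instead; used by adjoint operators.  For a
#'   complex-symmetric matrix `A^H = Conj(A)`, so the solve reuses the same
#'   factorization via `Conj(solve(A, Conj(b)))`.
#' @return complex solution with the shape of `b`.
#' @export
zsp_solve <- function(fac, b, conjugate_transpose = FALSE) {
  vec <- is.null(dim(b))
  b <- as.matrix(b)
  n <- fac$n
  stopifnot(nrow(b) == n)
  if (conjugate_transpose) {
    if (!isTRUE(fac$symmetric)) {
      stop("conjugate-transpose solve requires a complex-symmetric matrix")
    }
    return(Conj(zsp_solve(fac, Conj(if (vec) drop(b) else b))))
  }
  rhs <- rbind(Re(b), Im(b))
  xr <- Matrix::solve(fac$lu, rhs)
  x <- as.matrix(xr[seq_len(n), , drop = FALSE]) +
    1i * as.matrix(xr[n + seq_len(n), , drop = FALSE])
  if (vec) drop(x) else x
}
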