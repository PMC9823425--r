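# R-side driver for the supernodal complex-symmetric LDL^T factorization.
# The fill-reducing ordering and supernode partition come from CHOLMOD's
# supernodal Cholesky of a symmetric positive-definite proxy with the same
# sparsity pattern (a diagonally dominant matrix carried on the pattern of
# |Re A| + |Im A|); the complex numeric phase runs in compiled code.

#' Supernodal LDL^T factorization of a complex-symmetric sparse matrix
#'
#' Factors `A = L D L^T` (transpose, not conjugate transpose) with a
#' supernodal left-to-right numeric phase on CHOLMOD's symbolic structure.
#' Pivoting is static: near-zero diagonal pivots are perturbed and
#' reported; callers are expected to wrap solves in iterative refinement
#' (as [solve_forward()] does).
#'
#' @param A a square complex-symmetric `zspmat`.
#' @param tiny_rel relative static-pivot threshold.
#' @return a `zsyldl` factorization object.
#' @export
zsyldl_factorize <- function(A, tiny_rel = 1e-14) {
  n <- A$dim[1L]
  stopifnot(A$dim[2L] == n)
  # SPD proxy on the union pattern: diagonally dominant Laplacian-like
  S <- abs(A$re) + abs(A$im)
  S <- Matrix::forceSymmetric(S + Matrix::t(S))
  dd <- Matrix::rowSums(S) + 1
  S <- S + Matrix::Diagonal(n, dd)
  ch <- Matrix::Cholesky(S, LDL = FALSE, super = TRUE, perm = TRUE)
  if (!methods::is(ch, "dCHMsuper")) {
    stop("supernodal symbolic analysis unavailable for this pattern")
  }
  sup <- ch@super; pi_ <- ch@pi; px <- ch@px; s <- ch@s; perm <- ch@perm
  rm(ch, S)
  .release_memory()
  fac <- zsyldl_factor_cpp(
    n, sup, pi_, px, s, perm,
    A$re@p, A$re@i, A$re@x,
    A$im@p, A$im@i, A$im@x, tiny_rel)
  if (fac$n_static > 0) {
    warning("static pivot perturbation applied to ", fac$n_static,
            " diagonal entries; rely on iterative refinement")
  }
  structure(list(n = n, super = sup, pi = pi_, px = px, s = s,
                 perm = perm, x = fac$x, d = fac$d,
                 n_static = fac$n_static),
            class = "zsyldl")
}

#' Solve with a supernodal LDL^T factorization
#'
#' @param fac a `zsyldl` object from [zsyldl_factorize()].
#' @param b complex vector or matrix of right-hand sides.
#' @param conjugate_transpose solve `A^H x = b`; for a complex-symmetric
#'   matrix this is `Conj(solve(A, Conj(b)))`.
#' @return complex solution with the shape of `b`.
#' @export
zsyldl_solve <- function(fac, b, conjugate_transpose = FALSE) {
  vec <- is.null(dim(b))
  B <- as.matrix(b)
  if (conjugate_transpose) {
    x <- Conj(zsyldl_solve(fac, Conj(B)))
    return(if (vec) drop(x) else x)
  }
  storage.mode(B) <- "complex"
  x <- zsyldl_solve_cpp(fac$n, fac$super, fac$pi, fac$px, fac$s,
                        fac$perm, fac$x, fac$d, B)
  if (vec) drop(x) else x
}
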