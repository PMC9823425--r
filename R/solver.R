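# Solver selection for the discretized wave equation.
#
# Small systems are factorized by sparse LU of the equivalent real block
# system (Matrix/CSparse); that route's fill-in and scalar kernels make it
# impractical beyond a few thousand edges, so larger systems use the
# package's supernodal complex-symmetric LDL^T factorization (CHOLMOD
# symbolic analysis, BLAS-blocked numeric phase in compiled code).  Both
# routes are exact direct methods; forward solves add iterative refinement
# against the assembled operator.

#' Build a solver for a discretized wave-equation system
#'
#' Chooses the direct sparse-LU route for small systems and the supernodal
#' complex-symmetric LDL^T factorization for large ones.  The returned
#' handle is accepted by [solve_wave()], [solve_system()] and
#' [solve_forward()].
#'
#' @param A the assembled complex-symmetric system `zspmat`
#'   (`U - V + A_abc`).
#' @param mesh,kb2,kb_boundary,U accepted for interface stability; the
#'   direct factorizations only need `A`.
#' @param method `"auto"`, `"direct"` (real-block sparse LU) or `"ldl"`
#'   (supernodal complex-symmetric LDL^T).
#' @param direct_threshold edge count up to which the real-block LU is
#'   used in `"auto"` mode.
#' @return a `wave_solver` object.
#' @export
wave_solver <- function(A, mesh = NULL, kb2 = NULL, kb_boundary = NULL,
                        U = NULL, method = c("auto", "direct", "ldl"),
                        direct_threshold = 800L) {
  method <- match.arg(method)
  n <- A$dim[1L]
  if (method == "auto") {
    method <- if (n <= direct_threshold) "direct" else "ldl"
  }
  if (method == "direct") {
    structure(list(type = "direct", fac = zsp_factorize(A), A = A),
              class = "wave_solver")
  } else {
    structure(list(type = "ldl", fac = zsyldl_factorize(A), A = A),
              class = "wave_solver")
  }
}

#' Solve a wave-equation system with a `wave_solver`
#'
#' @param sv a [wave_solver()].
#' @param b complex vector or matrix of right-hand sides.
#' @param tol unused by the direct backends; kept so callers can state
#'   their target residual uniformly.
#' @param conjugate_transpose solve `A^H x = b` instead (valid for the
#'   complex-symmetric systems assembled by this package).
#' @return complex solution with the shape of `b`.
#' @export
solve_wave <- function(sv, b, tol = 1e-12, conjugate_transpose = FALSE) {
  if (sv$type == "direct") {
    zsp_solve(sv$fac, b, conjugate_transpose = conjugate_transpose)
  } else {
    zsyldl_solve(sv$fac, b, conjugate_transpose = conjugate_transpose)
  }
}

#' Curl-conforming interpolation between edge-element spaces
#'
#' Builds the sparse matrix mapping coarse edge coefficients to fine edge
#' coefficients by evaluating the line integral of the interpolated coarse
#' field along every fine edge (2-point Gauss rule, exact for the linear
#' Whitney fields within a cell).  On nested structured meshes this is an
#' exact embedding of the coarse space.
#'
#' @param mesh_coarse,mesh_fine structured `tet_mesh` objects covering the
#'   same box.
#' @return a real `dgCMatrix` of dimension E_fine x E_coarse.
#' @export
edge_interpolation <- function(mesh_coarse, mesh_fine) {
  mc <- mesh_coarse
  gcell <- .tet_lambda_gradients(mc)
  op <- .oriented_local_pairs(mc)
  r1 <- mc$nodes[mc$tets[, 1L], , drop = FALSE]
  Ef <- nrow(mesh_fine$edges)
  a <- mesh_fine$nodes[mesh_fine$edges[, 1L], , drop = FALSE]
  b <- mesh_fine$nodes[mesh_fine$edges[, 2L], , drop = FALSE]
  tv <- b - a
  gl <- c(0.5 - 0.5 / sqrt(3), 0.5 + 0.5 / sqrt(3))

  ii <- jj <- vector("list", 2L); xx <- vector("list", 2L)
  for (q in 1:2) {
    pts <- a + gl[q] * tv
    ti <- .locate_points_structured(mc, pts)
    lam <- matrix(0, Ef, 4L)
    d <- pts - r1[ti, , drop = FALSE]
    for (p in 2:4) {
      gp <- gcell[[p]][ti, , drop = FALSE]
      lam[, p] <- rowSums(gp * d)
    }
    lam[, 1L] <- 1 - lam[, 2L] - lam[, 3L] - lam[, 4L]
    iq <- matrix(rep(seq_len(Ef), 6L), Ef)
    jq <- mc$tet_edges[ti, , drop = FALSE]
    xq <- matrix(0, Ef, 6L)
    gather <- function(sel, comp) {
      Gc <- cbind(gcell[[1L]][ti, comp], gcell[[2L]][ti, comp],
                  gcell[[3L]][ti, comp], gcell[[4L]][ti, comp])
      Gc[cbind(seq_len(Ef), sel)]
    }
    for (k in 1:6) {
      pa <- op$pa[ti, k]; pb <- op$pb[ti, k]
      la <- lam[cbind(seq_len(Ef), pa)]
      lb <- lam[cbind(seq_len(Ef), pb)]
      w <- numeric(Ef)
      for (comp in 1:3) {
        wk <- la * gather(pb, comp) - lb * gather(pa, comp)
        w <- w + wk * tv[, comp]
      }
      xq[, k] <- 0.5 * w
    }
    ii[[q]] <- as.vector(iq); jj[[q]] <- as.vector(jq)
    xx[[q]] <- as.vector(xq)
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(Ef, nrow(mc$edges)))
}

# vectorized point location on a structured mesh: hex from coordinates,
# then the first of its 6 tets containing the point
.locate_points_structured <- function(mesh, pts) {
  g <- mesh$grid
  idx <- floor(sweep(sweep(pts, 2L, g$origin), 2L, g$h, "/"))
  idx <- pmin(pmax(idx, 0L), matrix(g$n - 1L, nrow(pts), 3L, byrow = TRUE))
  hexid <- 1 + idx[, 1L] + g$n[1L] * (idx[, 2L] + g$n[2L] * idx[, 3L])
  npts <- nrow(pts)
  found <- rep(NA_integer_, npts)
  gcell <- .tet_lambda_gradients(mesh)
  r1 <- mesh$nodes[mesh$tets[, 1L], , drop = FALSE]
  for (j in 0:5) {
    open <- which(is.na(found))
    if (!length(open)) break
    tj <- hexid[open] + g$n_hex * j
    d <- pts[open, , drop = FALSE] - r1[tj, , drop = FALSE]
    lam2 <- rowSums(gcell[[2L]][tj, , drop = FALSE] * d)
    lam3 <- rowSums(gcell[[3L]][tj, , drop = FALSE] * d)
    lam4 <- rowSums(gcell[[4L]][tj, , drop = FALSE] * d)
    lam1 <- 1 - lam2 - lam3 - lam4
    tol <- -1e-11
    ok <- lam1 >= tol & lam2 >= tol & lam3 >= tol & lam4 >= tol
    found[open[ok]] <- tj[ok]
  }
  if (anyNA(found)) {
    for (k in which(is.na(found))) {
      found[k] <- locate_point(mesh, pts[k, ], tol = 1e-8)
    }
  }
  found
}
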