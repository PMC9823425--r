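# Assembly of the discretized vector wave equation
#   (U - V + A_abc) e = b
# with lowest-order edge elements: U is the curl-curl (stiffness) matrix,
# V the kb^2-weighted mass matrix, and A_abc the first-order absorbing
# boundary term on the outer surface (the outgoing-wave condition
# n x curl E = -j k n x (n x E) contributes +j k times the tangential
# surface product to the weak form).  All element integrals are closed
# form: the curl of a Whitney edge function is constant per tetrahedron and
# products of barycentric functions integrate to V/20 (1 + delta_pq).

.MU0 <- 1.25663706212e-6
.EPS0 <- 8.8541878128e-12

# gather helper: out[i, ] = g[[sel[i]]][i, ] for per-tet vertex selections
.gather_grad <- function(g, sel) {
  I <- length(sel)
  out <- matrix(0, I, 3L)
  idx <- cbind(seq_len(I), sel)
  for (comp in 1:3) {
    Gc <- cbind(g[[1L]][, comp], g[[2L]][, comp],
                g[[3L]][, comp], g[[4L]][, comp])
    out[, comp] <- Gc[idx]
  }
  out
}

.rows_cross <- function(x, y) {
  cbind(x[, 2L] * y[, 3L] - x[, 3L] * y[, 2L],
        x[, 3L] * y[, 1L] - x[, 1L] * y[, 3L],
        x[, 1L] * y[, 2L] - x[, 2L] * y[, 1L])
}

.rows_dot <- function(x, y) {
  x[, 1L] * y[, 1L] + x[, 2L] * y[, 2L] + x[, 3L] * y[, 3L]
}

#' Assemble the curl-curl (stiffness) matrix
#'
#' `U[i, j] = integral over the mesh of curl(N_i) . curl(N_j)`, computed in
#' closed form (the curl of each edge function is constant per tetrahedron).
#' The result is symmetric and real-valued; it is returned as a complex
#' sparse [zsp_matrix()] so it composes with the other system terms.
#'
#' @param mesh a `tet_mesh` with edges enumerated.
#' @return an E x E `zspmat`.
#' @export
assemble_stiffness <- function(mesh) {
  if (any(mesh$volumes <= 0)) {
    stop("degenerate (zero-volume) tetrahedron at index ",
         which(mesh$volumes <= 0)[1L])
  }
  g <- .tet_lambda_gradients(mesh)
  op <- .oriented_local_pairs(mesh)
  I <- nrow(mesh$tets)
  curls <- vector("list", 6L)
  for (k in 1:6) {
    ga <- .gather_grad(g, op$pa[, k])
    gb <- .gather_grad(g, op$pb[, k])
    curls[[k]] <- 2 * .rows_cross(ga, gb)
  }
  ii <- jj <- integer(36L * I); xx <- numeric(36L * I)
  pos <- 0L
  for (k in 1:6) for (l in 1:6) {
    sl <- pos + seq_len(I)
    ii[sl] <- mesh$tet_edges[, k]
    jj[sl] <- mesh$tet_edges[, l]
    xx[sl] <- mesh$volumes * .rows_dot(curls[[k]], curls[[l]])
    pos <- pos + I
  }
  zsp_matrix(ii, jj, complex(real = xx), dims = c(nrow(mesh$edges),
                                                  nrow(mesh$edges)))
}

# closed-form 6x6 edge mass blocks per tet, scaled by a per-cell factor;
# returns triplet vectors (shared by assemble_mass and the coupling matrices)
.mass_block_triplets <- function(mesh, cell_factor) {
  g <- .tet_lambda_gradients(mesh)
  op <- .oriented_local_pairs(mesh)
  I <- nrow(mesh$tets)
  gdot <- array(0, dim = c(I, 4L, 4L))
  for (p in 1:4) for (q in p:4) {
    d <- .rows_dot(g[[p]], g[[q]])
    gdot[, p, q] <- d
    gdot[, q, p] <- d
  }
  sel <- function(m, selp, selq) m[cbind(seq_len(I), selp, selq)]
  Spq <- function(selp, selq) mesh$volumes / 20 * (1 + (selp == selq))
  ii <- jj <- integer(36L * I)
  xx <- complex(36L * I)
  pos <- 0L
  for (k in 1:6) for (l in 1:6) {
    a <- op$pa[, k]; b <- op$pb[, k]
    cc <- op$pa[, l]; d <- op$pb[, l]
    blk <- sel(gdot, b, d) * Spq(a, cc) - sel(gdot, b, cc) * Spq(a, d) -
           sel(gdot, a, d) * Spq(b, cc) + sel(gdot, a, cc) * Spq(b, d)
    slc <- pos + seq_len(I)
    ii[slc] <- mesh$tet_edges[, k]
    jj[slc] <- mesh$tet_edges[, l]
    xx[slc] <- cell_factor * blk
    pos <- pos + I
  }
  list(i = ii, j = jj, x = xx)
}

#' Assemble the wavenumber-weighted mass matrix
#'
#' `V[i, j] = integral of kb2 N_i . N_j`, with the squared wavenumber `kb2`
#' constant within each cell (sampled at the barycenter).
#'
#' @param mesh a `tet_mesh`.
#' @param kb2 complex vector of per-cell squared wavenumbers (length = number
#'   of tetrahedra).
#' @return an E x E complex-symmetric `zspmat`.
#' @export
assemble_mass <- function(mesh, kb2) {
  I <- nrow(mesh$tets)
  if (length(kb2) == 1L) kb2 <- rep(kb2, I)
  if (length(kb2) != I) stop("kb2 must have one value per tetrahedron")
  tr <- .mass_block_triplets(mesh, as.complex(kb2))
  zsp_matrix(tr$i, tr$j, tr$x, dims = c(nrow(mesh$edges), nrow(mesh$edges)))
}

# global edge id for node pairs (a < b); mesh$edges keys are sorted
.edge_lookup <- function(mesh, a, b) {
  nn <- nrow(mesh$nodes)
  lo <- pmin(a, b); hi <- pmax(a, b)
  keys <- (as.numeric(mesh$edges[, 1L]) - 1) * nn +
    as.numeric(mesh$edges[, 2L])
  id <- findInterval((as.numeric(lo) - 1) * nn + as.numeric(hi), keys)
  bad <- id < 1L | keys[pmax(id, 1L)] != (as.numeric(lo) - 1) * nn +
    as.numeric(hi)
  if (any(bad)) stop("node pair is not a mesh edge")
  id
}

#' Assemble the first-order absorbing boundary term
#'
#' `A_abc = j kb integral over the outer surface of (n x N_i) . (n x N_j)`,
#' assembled triangle-by-triangle.  The tangential trace of an edge function
#' on a face is the two-dimensional Whitney function of that face, so only
#' the three edges of each boundary triangle contribute.
#'
#' @param mesh a `tet_mesh`.
#' @param kb_boundary complex background wavenumber at the outer boundary
#'   (rad/m).
#' @return an E x E complex-symmetric `zspmat`.
#' @export
assemble_abc <- function(mesh, kb_boundary) {
  E <- nrow(mesh$edges)
  if (kb_boundary == 0) return(zsp_zero(c(E, E)))
  f <- mesh$boundary_faces
  if (nrow(f) == 0L) stop("mesh has no boundary faces")
  .check_boundary_closed(mesh)
  r1 <- mesh$nodes[f[, 1L], , drop = FALSE]
  r2 <- mesh$nodes[f[, 2L], , drop = FALSE]
  r3 <- mesh$nodes[f[, 3L], , drop = FALSE]
  nvec <- .rows_cross(r2 - r1, r3 - r1)
  area <- sqrt(.rows_dot(nvec, nvec)) / 2
  nhat <- nvec / (2 * area)
  gs <- list(.rows_cross(nhat, r3 - r2) / (2 * area),
             .rows_cross(nhat, r1 - r3) / (2 * area),
             .rows_cross(nhat, r2 - r1) / (2 * area))
  fp <- rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L))  # local face vertex pairs
  nf <- nrow(f)
  # orient each face edge low node -> high node
  pa <- pb <- matrix(0L, nf, 3L)
  eid <- matrix(0L, nf, 3L)
  for (k in 1:3) {
    p <- fp[k, 1L]; q <- fp[k, 2L]
    swap <- f[, p] > f[, q]
    pa[, k] <- ifelse(swap, q, p)
    pb[, k] <- ifelse(swap, p, q)
    eid[, k] <- .edge_lookup(mesh, f[, p], f[, q])
  }
  tdot <- array(0, dim = c(nf, 3L, 3L))
  for (p in 1:3) for (q in p:3) {
    d <- .rows_dot(gs[[p]], gs[[q]])
    tdot[, p, q] <- d
    tdot[, q, p] <- d
  }
  sel <- function(m, sp, sq) m[cbind(seq_len(nf), sp, sq)]
  Spq <- function(sp, sq) area / 12 * (1 + (sp == sq))
  ii <- jj <- integer(9L * nf); xx <- numeric(9L * nf)
  pos <- 0L
  for (k in 1:3) for (l in 1:3) {
    a <- pa[, k]; b <- pb[, k]; cc <- pa[, l]; d <- pb[, l]
    blk <- sel(tdot, b, d) * Spq(a, cc) - sel(tdot, b, cc) * Spq(a, d) -
           sel(tdot, a, d) * Spq(b, cc) + sel(tdot, a, cc) * Spq(b, d)
    slc <- pos + seq_len(nf)
    ii[slc] <- eid[, k]
    jj[slc] <- eid[, l]
    xx[slc] <- blk
    pos <- pos + nf
  }
  zsp_matrix(ii, jj, (1i * kb_boundary) * xx, dims = c(E, E))
}

# every edge of the boundary triangulation must be shared by exactly two
# boundary faces for the surface to be closed
.check_boundary_closed <- function(mesh) {
  f <- mesh$boundary_faces
  nn <- nrow(mesh$nodes)
  ek <- c((pmin(f[, 1L], f[, 2L]) - 1) * nn + pmax(f[, 1L], f[, 2L]),
          (pmin(f[, 1L], f[, 3L]) - 1) * nn + pmax(f[, 1L], f[, 3L]),
          (pmin(f[, 2L], f[, 3L]) - 1) * nn + pmax(f[, 2L], f[, 3L]))
  cnt <- table(ek)
  if (any(cnt != 2L)) stop("mesh boundary surface is not closed")
  invisible(TRUE)
}

#' Assemble and factorize the full wave-equation system
#'
#' Builds `U`, `V` (with the requested per-cell squared wavenumber) and the
#' absorbing boundary term, forms `A = U - V + A_abc` (the sign under which
#' the boundary absorbs outgoing waves) and prepares a solver for repeated
#' forward/adjoint solves.
#'
#' @param mesh a `tet_mesh`.
#' @param kb2 per-cell complex squared wavenumber entering `V`.
#' @param kb_boundary complex wavenumber of the (background) medium touching
#'   the outer boundary.
#' @param factorize prepare a solver for the system matrix (set `FALSE` to
#'   skip when only the matrices are needed).
#' @param solver solver selection passed to [wave_solver()]: `"auto"`
#'   (direct below its size threshold, multilevel above), `"direct"` or
#'   `"multilevel"`.
#' @param ... further arguments to [wave_solver()].
#' @return a `fem_system` list with `U`, `V`, `A_abc`, `A` and the solver
#'   handle `fac`.
#' @export
assemble_system <- function(mesh, kb2, kb_boundary, factorize = TRUE,
                            solver = "auto", ...) {
  U <- assemble_stiffness(mesh)
  V <- assemble_mass(mesh, kb2)
  A_abc <- assemble_abc(mesh, kb_boundary)
  A <- U - V + A_abc
  fac <- if (factorize) {
    wave_solver(A, mesh, kb2, kb_boundary, U = U, method = solver, ...)
  } else NULL
  structure(list(U = U, V = V, A_abc = A_abc, A = A, fac = fac,
                 kb2 = kb2, kb_boundary = kb_boundary,
                 n_edges = nrow(mesh$edges)),
            class = "fem_system")
}

#' Solve with either solver handle
#'
#' Dispatches to [solve_wave()] for `wave_solver` handles and to
#' [zsp_solve()] for plain factorizations.
#'
#' @param fac a `wave_solver` or `zsp_lu` object.
#' @param b complex right-hand side(s).
#' @param tol relative residual tolerance (iterative solvers).
#' @param conjugate_transpose solve the conjugate-transposed system.
#' @export
solve_system <- function(fac, b, tol = 1e-12,
                         conjugate_transpose = FALSE) {
  if (inherits(fac, "wave_solver")) {
    solve_wave(fac, b, tol = tol,
               conjugate_transpose = conjugate_transpose)
  } else {
    zsp_solve(fac, b, conjugate_transpose = conjugate_transpose)
  }
}

#' Solve the factorized wave-equation system
#'
#' Direct sparse solve with iterative refinement; errors if the relative
#' residual cannot be brought below `tol`.
#'
#' @param sys a `fem_system` from [assemble_system()].
#' @param rhs complex right-hand side vector (or matrix of columns).
#' @param tol relative residual tolerance.
#' @return complex solution with the shape of `rhs`.
#' @export
solve_forward <- function(sys, rhs, tol = 1e-12) {
  if (is.null(sys$fac)) stop("system was assembled without factorization")
  bnorm <- sqrt(sum(Mod(rhs)^2))
  if (bnorm == 0) return(rhs * 0)
  x <- solve_system(sys$fac, rhs, tol = tol)
  for (k in 1:3) {
    r <- rhs - zsp_mult(sys$A, x)
    rel <- sqrt(sum(Mod(r)^2)) / bnorm
    if (rel <= tol) return(x)
    x <- x + solve_system(sys$fac, r, tol = tol)
  }
  r <- rhs - zsp_mult(sys$A, x)
  rel <- sqrt(sum(Mod(r)^2)) / bnorm
  if (rel > tol) {
    stop(sprintf("forward solve stagnated at relative residual %.3e", rel))
  }
  x
}
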