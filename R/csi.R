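# Contrast source inversion.
#
# Two discretizations of the contrast source are carried side by side:
#  * "standard": one complex 3-vector coefficient per cell, the contrast
#    source being constant in amplitude and direction within each cell and
#    tied to the field sampled at the cell barycenter;
#  * "novel": 6I scalar coefficients on the edge basis restricted cell-wise
#    (each basis function is a Whitney function windowed by the cell's pulse
#    function), so the contrast source shares the field's basis and varies
#    linearly within each cell.
# The novel coupling matrix in its "linear" evaluation mode makes the
# discretized wave equation exactly consistent:  R omega(chi, e_tot) equals
# (V_target - V_background) e_tot to machine precision.  Its "barycenter"
# mode freezes the source basis at the cell barycenter and reproduces the
# standard discretization within the scalar-coefficient machinery.

#' Dielectric contrast from a material map
#'
#' `chi = (eps_target - eps_b) / eps_b` per cell, zeroed outside the domain
#' of interest.
#'
#' @param materials a `material_map`.
#' @param doi_mask logical per-cell mask of the domain of interest
#'   (default: all cells).
#' @return a `contrast` object with `chi` and `doi_mask`.
#' @export
contrast_from_materials <- function(materials, doi_mask = NULL) {
  I <- length(materials$eps_b)
  if (is.null(doi_mask)) doi_mask <- rep(TRUE, I)
  if (any(materials$eps_b[doi_mask] == 0)) {
    stop("background permittivity is zero inside the domain of interest")
  }
  chi <- (materials$eps_target - materials$eps_b) / materials$eps_b
  chi[!doi_mask] <- 0 + 0i
  structure(list(chi = chi, doi_mask = doi_mask), class = "contrast")
}

# closed-form per-tet ingredients shared by the coupling variants:
# oriented gradients and the constant vectors (g_b - g_a)/4 = N_k(r_i)
.coupling_geometry <- function(mesh) {
  g <- .tet_lambda_gradients(mesh)
  op <- .oriented_local_pairs(mesh)
  nk <- vector("list", 6L)
  for (k in 1:6) {
    ga <- .gather_grad(g, op$pa[, k])
    gb <- .gather_grad(g, op$pb[, k])
    nk[[k]] <- (gb - ga) / 4       # value of edge function k at barycenter
  }
  list(g = g, op = op, nk = nk)
}

#' Assemble a contrast-source coupling matrix
#'
#' Maps contrast-source coefficients to the right-hand side of the
#' discretized wave equation, weighted by the background squared wavenumber.
#' Variants:
#' \describe{
#'   \item{novel / linear}{`R[m, (i,e)] = kb2_i * integral over cell i of
#'     N_m . N_e`, in closed form (an E x 6I scalar sparse matrix).}
#'   \item{novel / barycenter}{the source function frozen at the cell
#'     barycenter: `kb2_i * (integral of N_m) . N_e(r_i)`.}
#'   \item{standard}{the per-cell vector form `R_[m, i] = kb2_i * integral
#'     over cell i of N_m`, stored as three E x I sparse matrices (one per
#'     Cartesian component).}
#' }
#'
#' @param mesh a `tet_mesh`.
#' @param kb2 per-cell complex background squared wavenumber.
#' @param variant `"novel"` or `"standard"`.
#' @param eval_mode `"linear"` or `"barycenter"` (novel variant only).
#' @param doi_mask logical per-cell mask; columns of cells outside the mask
#'   are dropped (their contrast sources cannot radiate).
#' @return a `coupling_matrix` object.
#' @export
assemble_coupling <- function(mesh, kb2, variant = c("novel", "standard"),
                              eval_mode = c("linear", "barycenter"),
                              doi_mask = NULL) {
  variant <- match.arg(variant)
  eval_mode <- match.arg(eval_mode)
  I <- nrow(mesh$tets)
  E <- nrow(mesh$edges)
  if (length(kb2) == 1L) kb2 <- rep(kb2, I)
  stopifnot(length(kb2) == I)
  if (is.null(doi_mask)) doi_mask <- rep(TRUE, I)
  fac <- as.complex(kb2) * doi_mask
  if (variant == "standard") {
    geo <- .coupling_geometry(mesh)
    comp <- vector("list", 3L)
    for (cc in 1:3) {
      ii <- jj <- integer(6L * I); xx <- complex(6L * I)
      pos <- 0L
      for (k in 1:6) {
        sl <- pos + seq_len(I)
        ii[sl] <- mesh$tet_edges[, k]
        jj[sl] <- seq_len(I)
        xx[sl] <- fac * mesh$volumes * geo$nk[[k]][, cc]
        pos <- pos + I
      }
      comp[[cc]] <- zsp_matrix(ii, jj, xx, dims = c(E, I))
    }
    out <- list(variant = variant, eval_mode = "barycenter",
                Rx = comp[[1L]], Ry = comp[[2L]], Rz = comp[[3L]],
                n_cells = I, n_edges = E)
  } else if (eval_mode == "linear") {
    tr <- .mass_block_triplets(mesh, fac)
    # rows keep the test-edge ids; columns move to the (cell, local edge)
    # numbering n = (i-1)*6 + e
    l_idx <- rep(rep(1:6, each = I), times = 6L)
    cell <- rep.int(seq_len(I), 36L)
    out <- list(variant = variant, eval_mode = eval_mode,
                R = zsp_matrix(tr$i, (cell - 1L) * 6L + l_idx, tr$x,
                               dims = c(E, 6L * I)),
                n_cells = I, n_edges = E)
  } else {
    geo <- .coupling_geometry(mesh)
    ii <- jj <- integer(36L * I); xx <- complex(36L * I)
    pos <- 0L
    for (k in 1:6) for (l in 1:6) {
      sl <- pos + seq_len(I)
      ii[sl] <- mesh$tet_edges[, k]
      jj[sl] <- (seq_len(I) - 1L) * 6L + l
      xx[sl] <- fac * mesh$volumes *
        .rows_dot(geo$nk[[k]], geo$nk[[l]])
      pos <- pos + I
    }
    out <- list(variant = variant, eval_mode = eval_mode,
                R = zsp_matrix(ii, jj, xx, dims = c(E, 6L * I)),
                n_cells = I, n_edges = E)
  }
  class(out) <- "coupling_matrix"
  out
}

apply_coupling <- function(R, omega) {
  if (R$variant == "novel") {
    zsp_mult(R$R, omega)
  } else {
    zsp_mult(R$Rx, omega[, 1L]) + zsp_mult(R$Ry, omega[, 2L]) +
      zsp_mult(R$Rz, omega[, 3L])
  }
}

apply_coupling_adjoint <- function(R, y) {
  if (R$variant == "novel") {
    zsp_mult(R$R, y, conjugate_transpose = TRUE)
  } else {
    cbind(zsp_mult(R$Rx, y, conjugate_transpose = TRUE),
          zsp_mult(R$Ry, y, conjugate_transpose = TRUE),
          zsp_mult(R$Rz, y, conjugate_transpose = TRUE))
  }
}

#' Bundle the operators used by the inversion
#'
#' Collects the factorized background system, the coupling matrix of the
#' chosen contrast-source discretization, the measurement operator and the
#' cell-wise field-sampling maps over the domain of interest.
#'
#' @param mesh inversion `tet_mesh`.
#' @param kb2 per-cell background squared wavenumber.
#' @param sys factorized background `fem_system` on `mesh`.
#' @param meas measurement `zspmat` (T x E) from [measurement_matrix()].
#' @param variant,eval_mode contrast-source discretization, as in
#'   [assemble_coupling()].
#' @param doi_mask logical per-cell domain-of-interest mask.
#' @param tol forward-solve relative residual tolerance.
#' @return a `csi_operators` object.
#' @export
csi_operators <- function(mesh, kb2, sys, meas,
                          variant = c("novel", "standard"),
                          eval_mode = c("linear", "barycenter"),
                          doi_mask = NULL, tol = 1e-12) {
  variant <- match.arg(variant)
  eval_mode <- match.arg(eval_mode)
  I <- nrow(mesh$tets)
  if (is.null(doi_mask)) doi_mask <- rep(TRUE, I)
  R <- assemble_coupling(mesh, kb2, variant, eval_mode, doi_mask)
  if (variant == "novel") {
    # cell-wise edge-coefficient selection P: (6I x E), one unit entry per
    # row; rows of masked-out cells are empty
    rows <- (rep(seq_len(I), each = 6L) - 1L) * 6L + rep(1:6, times = I)
    cols <- as.vector(t(mesh$tet_edges))
    keep <- rep(doi_mask, each = 6L)
    P <- Matrix::sparseMatrix(i = rows[keep], j = cols[keep],
                              x = 1, dims = c(6L * I, nrow(mesh$edges)))
    samp <- list(P = P)
  } else {
    geo <- .coupling_geometry(mesh)
    Bc <- vector("list", 3L)
    for (cc in 1:3) {
      ii <- jj <- integer(6L * I); xx <- numeric(6L * I)
      pos <- 0L
      for (k in 1:6) {
        sl <- pos + seq_len(I)
        ii[sl] <- seq_len(I)
        jj[sl] <- mesh$tet_edges[, k]
        xx[sl] <- geo$nk[[k]][, cc] * doi_mask
        pos <- pos + I
      }
      Bc[[cc]] <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                                       dims = c(I, nrow(mesh$edges)))
    }
    samp <- list(Bx = Bc[[1L]], By = Bc[[2L]], Bz = Bc[[3L]])
  }
  structure(list(mesh = mesh, kb2 = kb2, sys = sys, meas = meas, R = R,
                 samp = samp, variant = variant, eval_mode = eval_mode,
                 doi_mask = doi_mask, tol = tol,
                 n_unknowns = if (variant == "novel") 6L * sum(doi_mask)
                              else 3L * sum(doi_mask)),
            class = "csi_operators")
}

.real_sp_mult <- function(P, x, transpose = FALSE) {
  if (transpose) {
    drop(as.matrix(Matrix::crossprod(P, Re(x)))) +
      1i * drop(as.matrix(Matrix::crossprod(P, Im(x))))
  } else {
    drop(as.matrix(P %*% Re(x))) + 1i * drop(as.matrix(P %*% Im(x)))
  }
}

# field sampling in omega-space: for the novel variant the per-cell copies
# of the edge coefficients; for the standard variant the 3-vector field at
# the barycenters
sample_field <- function(ops, field_coeffs) {
  if (ops$variant == "novel") {
    .real_sp_mult(ops$samp$P, field_coeffs)
  } else {
    cbind(.real_sp_mult(ops$samp$Bx, field_coeffs),
          .real_sp_mult(ops$samp$By, field_coeffs),
          .real_sp_mult(ops$samp$Bz, field_coeffs))
  }
}

# adjoint of sample_field composed with multiplication by chi
sample_field_adjoint <- function(ops, omega_like) {
  if (ops$variant == "novel") {
    .real_sp_mult(ops$samp$P, omega_like, transpose = TRUE)
  } else {
    .real_sp_mult(ops$samp$Bx, omega_like[, 1L], transpose = TRUE) +
      .real_sp_mult(ops$samp$By, omega_like[, 2L], transpose = TRUE) +
      .real_sp_mult(ops$samp$Bz, omega_like[, 3L], transpose = TRUE)
  }
}

# X(chi): edge coefficients -> omega space
apply_X <- function(ops, chi, field_coeffs) {
  s <- sample_field(ops, field_coeffs)
  if (ops$variant == "novel") rep(chi, each = 6L) * s else chi * s
}

apply_X_adjoint <- function(ops, chi, omega_like) {
  if (ops$variant == "novel") {
    sample_field_adjoint(ops, Conj(rep(chi, each = 6L)) * omega_like)
  } else {
    sample_field_adjoint(ops, Conj(chi) * omega_like)
  }
}

#' Contrast sources from exact contrast and total field
#'
#' The discretized object equation evaluated exactly: for the novel variant
#' the coefficient of cell `i`, local edge `e` is `chi_i` times the total
#' field's coefficient on that edge; for the standard variant the 3-vector
#' `chi_i * E_tot(r_i)` with the field summed at the barycenter.
#'
#' @param ops a [csi_operators()] bundle.
#' @param chi per-cell complex contrast (a `contrast` object or plain
#'   vector).
#' @param etot complex edge-coefficient vector (or E x T matrix) of the
#'   total field on the same mesh.
#' @return the contrast-source array (list of per-transmitter arrays when
#'   `etot` has several columns).
#' @export
omega_from_exact <- function(ops, chi, etot) {
  if (inherits(chi, "contrast")) chi <- chi$chi
  if (length(chi) != ops$R$n_cells) stop("contrast/mesh size mismatch")
  if (!is.null(dim(etot)) && ncol(etot) > 1L) {
    return(lapply(seq_len(ncol(etot)), function(t) {
      apply_X(ops, chi, etot[, t])
    }))
  }
  apply_X(ops, chi, drop(etot))
}

#' The object-domain operator G_D
#'
#' Radiates a contrast source: solves the discretized wave equation
#' `(U - V - A_abc) e_sct = R omega` for the scattered-field edge
#' coefficients in the whole domain.
#'
#' @param ops a [csi_operators()] bundle.
#' @param omega contrast-source array.
#' @return complex E-vector of scattered-field coefficients.
#' @export
apply_GD <- function(ops, omega) {
  solve_forward(ops$sys, apply_coupling(ops$R, omega), tol = ops$tol)
}

#' The data-domain operator G_S and its adjoint
#'
#' `apply_GS` composes [apply_GD()] with the acquisition's measurement
#' functional, returning the modelled scattered data at the T receivers;
#' `apply_GS_adjoint` maps a data-residual vector back to contrast-source
#' space, satisfying the inner-product identity
#' `<GS omega, d> = <omega, GS^H d>`.
#'
#' @param ops a [csi_operators()] bundle.
#' @param omega contrast-source array.
#' @return complex vector of length T.
#' @export
apply_GS <- function(ops, omega) {
  zsp_mult(ops$meas, apply_GD(ops, omega))
}

#' @rdname apply_GS
#' @param d complex data vector of length T.
#' @export
apply_GS_adjoint <- function(ops, d) {
  y <- zsp_mult(ops$meas, d, conjugate_transpose = TRUE)
  z <- solve_system(ops$sys$fac, y, tol = ops$tol,
                    conjugate_transpose = TRUE)
  apply_coupling_adjoint(ops$R, z)
}

.om_norm2 <- function(x) sum(Mod(x)^2)
.om_redot <- function(a, b) Re(sum(Conj(a) * b))

#' Data-domain cost functional F_S
#'
#' `sum_t ||d_t - GS omega_t||^2 / sum_t ||d_t||^2`.  At `omega = 0` the
#' value is exactly 1.
#'
#' @param ops a [csi_operators()] bundle.
#' @param omegas list of per-transmitter contrast-source arrays.
#' @param data T x T complex scattered-data matrix (receivers in rows).
#' @return nonnegative scalar.
#' @export
cost_FS <- function(ops, omegas, data) {
  den <- sum(Mod(data)^2)
  if (den == 0) stop("scattered data are identically zero")
  num <- 0
  for (t in seq_along(omegas)) {
    num <- num + .om_norm2(data[, t] - apply_GS(ops, omegas[[t]]))
  }
  num / den
}

#' Object-domain cost functional F_D
#'
#' `sum_t ||chi E_inc_t - omega_t + chi GD omega_t||^2 /
#'  sum_t ||chi E_inc_t||^2`, all quantities in contrast-source coefficient
#' space.
#'
#' @param ops a [csi_operators()] bundle.
#' @param chi per-cell contrast (vector or `contrast`).
#' @param omegas list of per-transmitter contrast-source arrays.
#' @param einc E x T matrix of incident-field edge coefficients.
#' @return nonnegative scalar.
#' @export
cost_FD <- function(ops, chi, omegas, einc) {
  if (inherits(chi, "contrast")) chi <- chi$chi
  den <- 0
  for (t in seq_along(omegas)) {
    den <- den + .om_norm2(apply_X(ops, chi, einc[, t]))
  }
  if (den == 0) {
    stop("||chi E_inc|| vanishes: initialize via backpropagation ",
         "(the cost functional is undefined at chi = 0 / omega = 0)")
  }
  num <- 0
  for (t in seq_along(omegas)) {
    et <- einc[, t] + apply_GD(ops, omegas[[t]])
    num <- num + .om_norm2(apply_X(ops, chi, et) - omegas[[t]])
  }
  num / den
}

#' Backpropagation initial guess
#'
#' `omega_t0 = gamma_t GS^H d_t` with the one-parameter minimizer
#' `gamma_t = ||GS^H d_t||^2 / ||GS GS^H d_t||^2` of the data error
#' `||d_t - gamma GS GS^H d_t||`.  Transmitters with zero data get a zero
#' initial guess and a warning.
#'
#' @param ops a [csi_operators()] bundle.
#' @param data T x T complex scattered-data matrix.
#' @return list of per-transmitter contrast-source arrays.
#' @export
backprop_init <- function(ops, data) {
  Tn <- ncol(data)
  if (all(Mod(data) == 0)) stop("all-zero data: nothing to backpropagate")
  out <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    d <- data[, t]
    if (all(Mod(d) == 0)) {
      warning("transmitter ", t, " has zero data; zero initial guess")
      g <- apply_GS_adjoint(ops, d)   # zeros with the right shape
      out[[t]] <- g
      next
    }
    g <- apply_GS_adjoint(ops, d)
    gg <- apply_GS(ops, g)
    out[[t]] <- (.om_norm2(g) / .om_norm2(gg)) * g
  }
  out
}

# cell-wise least-squares contrast update given the total fields
.chi_update <- function(ops, omegas, efields) {
  I <- ops$R$n_cells
  num <- rep(0 + 0i, I); den <- rep(0, I)
  for (t in seq_along(omegas)) {
    s <- sample_field(ops, efields[[t]])
    if (ops$variant == "novel") {
      v <- Conj(s) * omegas[[t]]
      num <- num + colSums(matrix(v, nrow = 6L))
      den <- den + colSums(matrix(Mod(s)^2, nrow = 6L))
    } else {
      num <- num + rowSums(Conj(s) * omegas[[t]])
      den <- den + rowSums(Mod(s)^2)
    }
  }
  list(num = num, den = den)
}

#' Run the CSI inversion
#'
#' Backpropagation initialization followed by alternating updates: one
#' Polak-Ribiere conjugate-gradient step with exact (closed-form) line
#' search on the contrast sources of every transmitter, then the cell-wise
#' least-squares contrast update restricted to the domain of interest.
#' The data and object cost terms `F_S`, `F_D` and their sum are logged at
#' every iteration.
#'
#' @param ops a [csi_operators()] bundle.
#' @param data T x T complex scattered-data matrix (receivers in rows,
#'   transmitters in columns).
#' @param einc E x T matrix of incident-field edge coefficients on the
#'   inversion mesh.
#' @param n_iter number of CSI iterations.
#' @param chi_ref optional per-cell reference contrast; when given, the
#'   history tracks the relative error of the reconstructed contrast over
#'   `track_cells`.
#' @param track_cells optional cell index set (defaults to cells where
#'   `chi_ref != 0`).
#' @param verbose print progress every 10 iterations.
#' @return a `csi_result` with the final contrast `chi`, contrast sources,
#'   and per-iteration `history` (n, FS, FD, FCSI, and tracking columns).
#' @export
run_csi <- function(ops, data, einc, n_iter = 100L, chi_ref = NULL,
                    track_cells = NULL, verbose = FALSE) {
  Tn <- ncol(data)
  stopifnot(nrow(einc) == ops$R$n_edges, ncol(einc) == Tn)
  den_S <- sum(Mod(data)^2)
  if (den_S == 0) stop("scattered data are identically zero")
  if (!is.null(chi_ref) && is.null(track_cells)) {
    track_cells <- which(Mod(chi_ref) > 0)
  }

  omegas <- backprop_init(ops, data)
  e_d <- lapply(omegas, function(w) apply_GD(ops, w))
  gs <- lapply(omegas, function(w) apply_GS(ops, w))
  efields <- lapply(seq_len(Tn), function(t) einc[, t] + e_d[[t]])
  upd <- .chi_update(ops, omegas, efields)
  chi <- ifelse(upd$den > 1e-30, upd$num / pmax(upd$den, 1e-300), 0 + 0i)
  chi[!ops$doi_mask] <- 0 + 0i

  grad_prev <- dir_prev <- vector("list", Tn)
  hist_rows <- vector("list", n_iter)
  n_up <- 0L
  fcsi_prev <- Inf

  for (n in seq_len(n_iter)) {
    den_D <- 0
    xinc <- vector("list", Tn)
    for (t in seq_len(Tn)) {
      xinc[[t]] <- apply_X(ops, chi, einc[, t])
      den_D <- den_D + .om_norm2(xinc[[t]])
    }
    if (den_D == 0) {
      stop("||chi E_inc|| vanished during the iterations")
    }
    eta_S <- 1 / den_S
    eta_D <- 1 / den_D

    # contrast-source update: one PR-CG step per transmitter
    for (t in seq_len(Tn)) {
      rho <- data[, t] - gs[[t]]
      r <- apply_X(ops, chi, efields[[t]]) - omegas[[t]]
      y <- zsp_mult(ops$meas, rho, conjugate_transpose = TRUE)
      # combined adjoint solve: A^H z = -eta_S M^H rho + eta_D X^H r
      xr <- apply_X_adjoint(ops, chi, r)
      z <- solve_system(ops$sys$fac, -eta_S * y + eta_D * xr,
                        tol = ops$tol, conjugate_transpose = TRUE)
      g <- -eta_D * r + apply_coupling_adjoint(ops$R, z)

      beta <- 0
      if (!is.null(grad_prev[[t]])) {
        gp2 <- .om_norm2(grad_prev[[t]])
        if (gp2 > 0) {
          beta <- max(0, .om_redot(g - grad_prev[[t]], g) / gp2)
        }
      }
      v <- if (beta > 0) -g + beta * dir_prev[[t]] else -g
      gd_v <- apply_GD(ops, v)
      a <- zsp_mult(ops$meas, gd_v)
      bvec <- apply_X(ops, chi, gd_v) - v
      denom <- eta_S * .om_norm2(a) + eta_D * .om_norm2(bvec)
      if (!is.finite(denom) || denom <= 0) {
        stop("degenerate line search at iteration ", n,
             " (transmitter ", t, ")")
      }
      alpha <- (eta_S * .om_redot(a, rho) - eta_D * .om_redot(bvec, r)) /
        denom
      if (!is.finite(alpha)) {
        stop("non-finite step length at iteration ", n)
      }
      omegas[[t]] <- omegas[[t]] + alpha * v
      gs[[t]] <- gs[[t]] + alpha * a
      e_d[[t]] <- e_d[[t]] + alpha * gd_v
      efields[[t]] <- einc[, t] + e_d[[t]]
      grad_prev[[t]] <- g
      dir_prev[[t]] <- v
    }

    # contrast update (cell-wise closed form)
    upd <- .chi_update(ops, omegas, efields)
    keep <- upd$den <= 1e-30
    chi_new <- upd$num / pmax(upd$den, 1e-300)
    chi_new[keep] <- chi[keep]
    chi_new[!ops$doi_mask] <- 0 + 0i
    chi <- chi_new

    # cost bookkeeping with the updated (chi, omega)
    FS <- 0
    for (t in seq_len(Tn)) FS <- FS + .om_norm2(data[, t] - gs[[t]])
    FS <- FS * eta_S
    den_D2 <- 0; num_D <- 0
    for (t in seq_len(Tn)) {
      xi <- apply_X(ops, chi, einc[, t])
      den_D2 <- den_D2 + .om_norm2(xi)
      num_D <- num_D + .om_norm2(apply_X(ops, chi, efields[[t]]) -
                                   omegas[[t]])
    }
    FD <- num_D / den_D2
    FCSI <- FS + FD
    row <- data.frame(n = n, FS = FS, FD = FD, FCSI = FCSI)
    if (!is.null(chi_ref)) {
      tc <- track_cells
      row$chi_err <- Mod(mean(chi[tc]) - mean(chi_ref[tc])) /
        Mod(mean(chi_ref[tc]))
    }
    hist_rows[[n]] <- row
    if (verbose && n %% 10L == 0L) {
      message(sprintf("iter %3d  FS=%.3e FD=%.3e FCSI=%.3e", n, FS, FD,
                      FCSI))
    }
    if (FCSI > fcsi_prev) n_up <- n_up + 1L else n_up <- 0L
    fcsi_prev <- FCSI
    if (n_up >= 5L) {
      warning("cost functional increased for 5 consecutive iterations; ",
              "stopping at iteration ", n)
      hist_rows <- hist_rows[seq_len(n)]
      break
    }
  }

  structure(list(chi = chi, omegas = omegas,
                 history = do.call(rbind, hist_rows),
                 variant = ops$variant, eval_mode = ops$eval_mode,
                 n_unknowns = ops$n_unknowns),
            class = "csi_result")
}

#' @export
print.csi_result <- function(x, ...) {
  h <- x$history[nrow(x$history), ]
  cat("csi_result (", x$variant, "/", x$eval_mode, "): ",
      nrow(x$history), " iterations, FCSI = ", format(h$FCSI, digits = 4),
      " (FS = ", format(h$FS, digits = 4),
      ", FD = ", format(h$FD, digits = 4), ")\n", sep = "")
  invisible(x)
}
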